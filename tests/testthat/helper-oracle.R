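# Independent transcription of the model equations, vectorized over the
# four units, used to cross-check the package's vector field.  Kept
# deliberately separate from the package implementation (matrix algebra
# instead of per-unit loops).
oracle_derivs <- function(V, h, b, d, p, E_ex = -10, E_inh = -90) {
  f <- pmin(1, pmax(0, (V - p$V_min) / (p$V_max - p$V_min)))
  minf <- 1 / (1 + exp((V - p$V_mNaP) / p$k_mNaP))
  hinf <- 1 / (1 + exp((V - p$V_hNaP) / p$k_hNaP))
  tau <- p$tau_NaP_max / cosh((V - p$V_tauNaP) / p$k_tauNaP)
  I_L <- p$g_L * (V - p$E_L)
  I_NaP <- p$g_NaP * minf * h * (V - p$E_Na)
  I_syn <- d * (V - E_ex) + as.vector(t(b) %*% f) * (V - E_inh)
  list(dV = -(I_L + I_NaP + I_syn) / p$C, dh = (hinf - h) / tau)
}

# build a burst train object directly from onset/offset vectors
make_bursts <- function(onsets, offsets, unit = 1) {
  structure(data.frame(onset = onsets, offset = offsets),
            unit = unit, class = c("cpg_bursts", "data.frame"))
}
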