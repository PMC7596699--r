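p <- unit_params()

test_that("gating functions match hand-evaluated sigmoids and limits", {
  expect_equal(m_inf(p$V_mNaP, p), 0.5)
  expect_equal(m_inf(-46, p), 1 / (1 + exp(1)))
  expect_equal(m_inf(200, p), 1, tolerance = 1e-10)
  expect_lt(m_inf(-200, p), 1e-10)

  expect_equal(h_inf(p$V_hNaP, p), 0.5)
  expect_equal(h_inf(-40, p), 1 / (1 + exp(1)))
  expect_equal(h_inf(-300, p), 1, tolerance = 1e-10)

  # monotonicity over a dense voltage grid
  V <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(m_inf(V, p)) > 0))
  expect_true(all(diff(h_inf(V, p)) < 0))
  expect_true(!is.unsorted(rate_fun(V, p)))
})

test_that("inactivation time constant peaks at its centre and is even", {
  expect_equal(tau_h(p$V_tauNaP, p), p$tau_NaP_max)
  expect_equal(tau_h(-60, p), 1500 / cosh(1))
  x <- c(5, 20, 77)
  expect_equal(tau_h(p$V_tauNaP + x, p), tau_h(p$V_tauNaP - x, p))
  expect_true(all(tau_h(seq(-200, 100, 1), p) > 0))
})

test_that("rate function is piecewise linear between threshold and saturation", {
  expect_equal(rate_fun(p$V_min, p), 0)
  expect_equal(rate_fun(p$V_max, p), 1)
  expect_equal(rate_fun(-25, p), 0.5)
  expect_equal(rate_fun(-60, p), 0)
  expect_equal(rate_fun(10, p), 1)
})

test_that("drive coupling subtracts the flexor drive from the gross extensor drive", {
  expect_equal(net_extensor_drives(drive_config(0.7, 0.7, D_E0 = 1.4)),
               c(0.7, 0.7))
  expect_equal(net_extensor_drives(drive_config(0, 0, D_E0 = 1.4)),
               c(1.4, 1.4))
  expect_warning(
    dE <- net_extensor_drives(drive_config(1.6, 0.2, D_E0 = 1.4)),
    "clamped")
  expect_equal(dE, c(0, 1.2))
  # uncoupled: explicit extensor drives regardless of flexor drive
  expect_equal(net_extensor_drives(
    drive_config(0.9, 0.9, coupled = FALSE, d_E_left = 0.7)), c(0.7, 0.7))
})

test_that("synaptic current reproduces hand-computed values", {
  quiet <- network_state(c(-40, -80, -80, -80))
  net0 <- network_config(FF = 0, EF = 0, EF_within = 0, FE_within = 0)
  expect_equal(synaptic_current(1, quiet, net0, rep(0, 4)), 0)
  expect_equal(synaptic_current(1, quiet, net0, c(0.5, 0, 0, 0)), -15)
  # one active inhibitory input at half rate: f(-25) = 0.5, weight 1
  st <- network_state(c(-40, -25, -80, -80))
  net1 <- network_config(FF = 1, EF = 0, EF_within = 0, FE_within = 0)
  expect_equal(synaptic_current(1, st, net1, c(0.5, 0, 0, 0)), 10)
  expect_error(synaptic_current(5, st, net1, rep(0, 4)), "1..4")
})

test_that("derivatives agree with an independent transcription of the equations", {
  net <- network_config(FF = 0.4, EF = 0.2)
  drv <- drive_config(0.3, 0.55)
  d4 <- effective_drives(drv)
  set.seed(42)
  for (k in 1:40) {
    V <- runif(4, -85, 20)
    h <- runif(4)
    got <- cpg_derivatives(network_state(V, h), net, drv)
    want <- oracle_derivs(V, h, net$b, d4, p)
    expect_equal(got$dV, want$dV, tolerance = 1e-12)
    expect_equal(got$dh, want$dh, tolerance = 1e-12)
    # current breakdown sums to the negated numerator of the V equation
    tot <- rowSums(got$currents[, c("I_L", "I_NaP", "I_syn")])
    expect_equal(got$dV, -tot / p$C, tolerance = 1e-12)
  }
})

test_that("trivial equilibria of the vector field", {
  net0 <- network_config(FF = 0, EF = 0, EF_within = 0, FE_within = 0,
                         units = unit_params(g_NaP = 0))
  drv0 <- drive_config(0, 0, coupled = FALSE, d_E_left = 0)
  st <- network_state(rep(-65, 4), params = net0$units[[1]])
  dd <- cpg_derivatives(st, net0, drv0)
  expect_equal(dd$dV, rep(0, 4), tolerance = 1e-12)
  # gates at their voltage-matched steady state do not move
  st2 <- network_state(c(-30, -55, -70, -40))
  dd2 <- cpg_derivatives(st2, network_config(), drive_config(0.3))
  expect_equal(dd2$dh, rep(0, 4), tolerance = 1e-12)
})

test_that("vector field confines gates to [0,1] and voltages to the physical range", {
  net <- network_config(FF = 0.4, EF = 0.3)
  drv <- drive_config(0.6, 0.6)
  for (V1 in seq(-90, 50, by = 10)) {
    V <- c(V1, -50, -20, -70)
    d0 <- cpg_derivatives(network_state(V, rep(0, 4)), net, drv)
    d1 <- cpg_derivatives(network_state(V, rep(1, 4)), net, drv)
    expect_true(all(d0$dh >= 0))
    expect_true(all(d1$dh <= 0))
  }
  # dV points inward at the ends of [E_inh, E_Na] = [-90, 50]
  dlo <- cpg_derivatives(network_state(rep(-90, 4), rep(0.5, 4)), net, drv)
  dhi <- cpg_derivatives(network_state(rep(50, 4), rep(0.5, 4)), net, drv)
  expect_true(all(dlo$dV >= 0))
  expect_true(all(dhi$dV <= 0))
})

test_that("left-right relabelling commutes with the vector field", {
  net <- network_config(FF = 0.35, EF = 0.15)
  drv <- drive_config(0.3, 0.6)
  mir <- c(2, 1, 4, 3)
  drv_m <- drive_config(0.6, 0.3)
  set.seed(7)
  for (k in 1:10) {
    V <- runif(4, -80, 0); h <- runif(4)
    a <- cpg_derivatives(network_state(V, h), net, drv)
    b <- cpg_derivatives(network_state(V[mir], h[mir]), net, drv_m)
    expect_equal(a$dV[mir], b$dV, tolerance = 1e-12)
    expect_equal(a$dh[mir], b$dh, tolerance = 1e-12)
  }
})

test_that("constructors reject invalid parameters with named messages", {
  expect_error(unit_params(C = -1), "C must be > 0")
  expect_error(unit_params(k_mNaP = 2), "k_mNaP")
  expect_error(unit_params(V_min = 10, V_max = 0), "V_max")
  b_bad <- matrix(0, 4, 4); b_bad[1, 4] <- 0.3
  expect_error(network_config(b = b_bad), "structural zeros")
  expect_error(drive_config(-0.1), "drives")
})
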