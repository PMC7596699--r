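test_that("integration relaxes to the leak/drive fixed point without INaP", {
  net0 <- network_config(FF = 0, EF = 0, EF_within = 0, FE_within = 0,
                         units = unit_params(g_NaP = 0))
  drv <- drive_config(0.5, 0, coupled = FALSE, d_E_left = 0)
  tr <- simulate_cpg(net0, drv, duration = 3000)
  # V* = (g_L E_L + d E_ex) / (g_L + d)
  expect_equal(tail(tr$V1, 1), (2.8 * -65 + 0.5 * -10) / 3.3,
               tolerance = 1e-6)
  expect_equal(tail(tr$V2, 1), -65, tolerance = 1e-6)
  expect_equal(tail(tr$V4, 1), -65, tolerance = 1e-6)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  net <- network_config(FF = 0, EF = 0)
  drv <- drive_config(0.4)
  a <- simulate_cpg(net, drv, duration = 3000, engine = "compiled")
  b <- simulate_cpg(net, drv, duration = 3000, engine = "R")
  expect_lt(max(abs(a$V1 - b$V1)), 1e-5)
  expect_lt(max(abs(a$h1 - b$h1)), 1e-7)
})

test_that("adaptive and fixed-step solvers agree on cycle metrics", {
  net <- network_config(FF = 0, EF = 0)
  drv <- drive_config(0.4)
  m1 <- cycle_metrics(detect_bursts(
    simulate_cpg(net, drv, duration = 30000), 1))
  m2 <- cycle_metrics(detect_bursts(
    simulate_cpg(net, drv, duration = 30000, method = "rk4"), 1))
  expect_lt(abs(m1$period - m2$period) / m1$period, 0.005)
  expect_lt(abs(m1$flexion_duration - m2$flexion_duration) /
              m1$flexion_duration, 0.005)
})

test_that("burst detector recovers planted schedules and respects edges", {
  sched <- data.frame(onset = c(100, 900, 1700, 2500, 3300),
                      offset = c(400, 1200, 2000, 2800, 3600))
  tr <- generate_fixture(fixture_spec(sched))
  b <- detect_bursts(tr, 1, transient = 0)
  expect_equal(nrow(b), 5)
  expect_equal(b$onset, sched$onset, tolerance = 1e-9)
  expect_equal(b$offset, sched$offset, tolerance = 1e-9)
  # a window starting inside a burst discards that burst
  b2 <- detect_bursts(tr, 1, transient = 200)
  expect_equal(nrow(b2), 4)
  expect_equal(b2$onset[1], 900)
  # silent unit yields an empty train
  expect_equal(nrow(detect_bursts(tr, 3, transient = 0)), 0)
})

test_that("cycle metrics compute period, phase durations and duty cycle", {
  b <- make_bursts(c(0, 1000, 2000), c(300, 1300, 2300))
  m <- cycle_metrics(b)
  expect_equal(m$period, 1000)
  expect_equal(m$flexion_duration, 300)
  expect_equal(m$extension_duration, 700)
  expect_equal(m$frequency, 1)
  expect_equal(m$duty_cycle, 0.3)
  expect_true(m$regular)
  expect_error(cycle_metrics(make_bursts(c(0, 1000), c(300, 1300))),
               "non-oscillatory")
})

test_that("phase difference measures the circular left-right offset", {
  l <- make_bursts(seq(0, 9000, 1000), seq(0, 9000, 1000) + 300)
  expect_equal(phase_difference(l, l)$phase, 0)
  r <- make_bursts(seq(500, 9500, 1000), seq(500, 9500, 1000) + 300, unit = 2)
  pd <- phase_difference(l, r)
  expect_equal(pd$phase, 0.5)
  expect_lt(pd$dispersion, 1e-10)
  far <- make_bursts(seq(50000, 53000, 1000), seq(50000, 53000, 1000) + 300)
  expect_error(phase_difference(l, far), "overlap")
})

test_that("isolated half-center is quiescent, bursting, then tonic as drive grows", {
  expect_equal(classify_unit_mode(drive = 0), "quiescent")
  expect_equal(classify_unit_mode(drive = 0.3), "bursting")
  expect_equal(classify_unit_mode(drive = 1.2), "tonic")
})

test_that("mirrored configurations yield mirrored trajectories with bounded state", {
  net <- network_config(FF = 0.4, EF = 0.2)
  init <- default_state("antiphase")
  init_m <- network_state(init$V[c(2, 1, 4, 3)], init$h[c(2, 1, 4, 3)])
  a <- simulate_cpg(net, drive_config(0.3, 0.55), duration = 15000,
                    init = init)
  b <- simulate_cpg(net, drive_config(0.55, 0.3), duration = 15000,
                    init = init_m)
  expect_equal(a$V1, b$V2, tolerance = 1e-6)
  expect_equal(a$V3, b$V4, tolerance = 1e-6)
  V <- as.matrix(a[, paste0("V", 1:4)])
  h <- as.matrix(a[, paste0("h", 1:4)])
  expect_true(all(V >= -90 & V <= 50))
  expect_true(all(h >= 0 & h <= 1))
})
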