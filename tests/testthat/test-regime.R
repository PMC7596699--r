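test_that("coordination ratio counts fast bursts per slow cycle", {
  slow <- make_bursts(seq(0, 12000, 1000), seq(0, 12000, 1000) + 300)
  expect_equal(coordination_ratio(slow, slow)$n, 1L)
  fast <- make_bursts(seq(0, 12500, 500), seq(0, 12500, 500) + 150, unit = 2)
  cr <- coordination_ratio(slow, fast)
  expect_equal(cr$n, 2L)
  expect_equal(cr$label, "1:2")
  # alternating 1 and 2 bursts per cycle is intermittent
  on_mix <- sort(c(seq(0, 12000, 1000), seq(250, 12250, 2000)))
  mix <- make_bursts(on_mix, on_mix + 100, unit = 2)
  expect_equal(coordination_ratio(slow, mix)$label, "intermittent")
  # silent fast side gives a zero count, not an error
  silent <- make_bursts(numeric(0), numeric(0), unit = 2)
  expect_equal(coordination_ratio(slow, silent)$n, 0L)
  short <- make_bursts(seq(0, 5000, 1000), seq(0, 5000, 1000) + 300)
  expect_error(coordination_ratio(short, fast), "slow cycles")
})

test_that("caption-point regimes reproduce their coordination classes", {
  e1 <- classify_symmetric(0.3, FF = 0.4, EF = 0.05)
  expect_equal(e1$label, "asymmetric_alternation")
  # the two seeds land on mirror-image attractors
  expect_equal(e1$seeds$antiphase$phase + e1$seeds$inphase$phase, 1,
               tolerance = 0.05)
  e2 <- classify_symmetric(0.3, FF = 0.4, EF = 0.3)
  expect_equal(e2$label, "anti_phase")
  expect_equal(e2$seeds$antiphase$phase, 0.5, tolerance = 0.02)
})

test_that("reference commissural point is monostable anti-phase across drives", {
  for (dr in c(0.3, 0.65)) {
    r <- classify_symmetric(dr, FF = 0.4, EF = 0.2)
    expect_equal(r$label, "anti_phase")
    expect_equal(unname(vapply(r$seeds, `[[`, character(1), "label")),
                 c("anti_phase", "anti_phase"))
  }
})

test_that("equal-phase drive locates the flexion-extension crossover", {
  sw <- single_rg_sweep(seq(0.4, 0.7, by = 0.1), duration = 30000)
  d_eq <- equal_phase_drive(sw)
  expect_gt(d_eq, 0.4)
  expect_lt(d_eq, 0.7)
  # degenerate input: flexion identical to extension everywhere
  deg <- structure(data.frame(drive = c(0.2, 0.3), flexion = c(300, 300),
                              extension = c(300, 300)),
                   class = c("cpg_sweep", "data.frame"))
  expect_warning(d0 <- equal_phase_drive(deg), "degenerate")
  expect_equal(d0, 0.2)
  # monotone curves with no sign change
  nc <- structure(data.frame(drive = c(0.2, 0.3), flexion = c(100, 120),
                              extension = c(700, 600)),
                  class = c("cpg_sweep", "data.frame"))
  expect_error(equal_phase_drive(nc), "no flexion-extension crossover")
})

test_that("split-belt sweep keeps 1:1 while the fast flexion lengthens", {
  sb <- split_belt_sweep(fast_grid = seq(0.5, 0.8, by = 0.1))
  expect_true(all(sb$n == 1))
  expect_true(all(diff(sb$flexion_fast) > 0))
  expect_true(all(diff(sb$extension_fast) < 0))
  # symmetric first point: both sides identical
  expect_equal(sb$flexion_slow[1], sb$flexion_fast[1], tolerance = 0.01)
})

test_that("frequency map flags quiescent cells and the intrinsic-bursting boundary", {
  fm <- frequency_map(flexor_grid = c(0, 0.3, 1.2),
                      extensor_grid = c(0, 0.9),
                      duration = 30000)
  expect_equal(fm$frequency["0", "0"], 0)          # no excitation anywhere
  expect_gt(fm$frequency["0.3", "0.9"], 0.1)       # flexor-driven bursting
  expect_equal(unname(fm$flexor_mode),
               c("quiescent", "bursting", "tonic"))
  expect_equal(fm$rhythmic_boundary, 0.3)
})
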