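test_that("alignment simulation is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123)
  f1 <- tempfile(fileext = ".sam")
  f2 <- tempfile(fileext = ".sam")
  write_sam(simulate_alignments(cfg), f1)
  write_sam(simulate_alignments(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the reads
  f3 <- tempfile(fileext = ".sam")
  write_sam(simulate_alignments(simulation_config(seed = 124)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("without a deletion no read is alternate beyond the configured
           background", {
  sim <- simulate_alignments(simulation_config(seed = 9, deletion = NULL))
  lab <- classify_alignments(sim$alignments)
  expect_equal(sum(lab == "ALTERNATE"), 0)
  expect_equal(nrow(sim$truth), 0)
  simbg <- simulate_alignments(simulation_config(
    seed = 9, deletion = NULL, background_clip_rate = 0.05))
  labbg <- classify_alignments(simbg$alignments)
  rate <- mean(labbg == "ALTERNATE")
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("an implanted deletion yields clipped breakpoint reads and
           discordant straddling pairs", {
  cfg <- simulation_config(seed = 33, deletion = c(pos = 1000, len = 300))
  sim <- simulate_alignments(cfg)
  a <- sim$alignments
  clipped <- grepl("S", a$cigar)
  expect_gt(sum(clipped), 0)
  # left-anchored clips end at the left breakpoint; right-anchored start at
  # the right breakpoint
  left <- a[grepl("^[0-9]+M[0-9]+S$", a$cigar), ]
  m_len <- as.integer(sub("M.*", "", left$cigar))
  expect_true(all(left$pos + m_len == 1000))
  right <- a[grepl("^[0-9]+S[0-9]+M$", a$cigar), ]
  expect_true(all(right$pos == 1300))
  expect_true(any(flag_is_discordant(a$flag)))
  # no read aligns inside the deleted interval
  spans <- vapply(a$cigar, oracle_ref_span, numeric(1))
  inside <- a$pos >= 1000 & a$pos + spans <= 1300
  expect_equal(sum(inside), 0)
})

test_that("deletion geometry is validated", {
  expect_error(
    simulate_alignments(simulation_config(deletion = c(pos = 4900,
                                                       len = 300))),
    "fit inside"
  )
  expect_warning(
    simulate_alignments(simulation_config(seed = 1,
                                          deletion = c(pos = 1000,
                                                       len = 50))),
    "shorter than the read length"
  )
})

test_that("qPCR generator is the exact inverse of the analysis at zero
           noise and honours its seed", {
  m <- simulate_qpcr_ct(0.5, noise_sd = 0)
  expect_equal(mean(m$ct_so) - mean(m$ct_hygB), 0)
  m8 <- simulate_qpcr_ct(0.8, efficiency = 2, noise_sd = 0)
  expect_equal(mean(m8$ct_so) - mean(m8$ct_hygB), 2, tolerance = 1e-12)
  a <- simulate_qpcr_ct(0.3, noise_sd = 0.1, seed = 42)
  b <- simulate_qpcr_ct(0.3, noise_sd = 0.1, seed = 42)
  expect_identical(a, b)
})

test_that("noise-free plate counts reproduce the deconvolution algebra
           exactly", {
  truth <- c(inl = 0.55, pan = 0.35, het = 0.10)
  counts <- simulate_plate_counts(truth, noise = FALSE)
  est <- plate_frequencies(counts)
  expect_equal(c(est$f_inl_homokaryon, est$f_pan_homokaryon,
                 est$f_heterokaryon), unname(truth), tolerance = 1e-12)
  # no heterokaryons -> unsupplemented plates stay empty
  none <- simulate_plate_counts(c(inl = 0.6, pan = 0.4, het = 0),
                                noise = FALSE)
  expect_true(all(none$count[none$medium == "none"] == 0))
})

test_that("transfer dynamics are constant under neutrality and settle at
           the configured equilibrium", {
  neutral <- simulation_config(seed = 1, fitness_slope = 0, het_rate = 0,
                               n_transfers = 4)
  ts <- simulate_transfer_series(neutral, stochastic = FALSE)
  expect_equal(ts$f_cheater, rep(0.1, 5))
  expect_equal(ts$f_het, rep(0, 5))

  sel <- simulation_config(seed = 1, fitness_root = 0.3, fitness_slope = 5,
                           het_rate = 0, n_transfers = 20, f0 = 0.1)
  traj <- simulate_transfer_series(sel, stochastic = FALSE)
  expect_equal(traj$f_cheater[traj$transfer == 20], 0.3, tolerance = 1e-3)
  # the trajectory contracts towards the fixed point (damped approach)
  gap <- abs(traj$f_cheater - 0.3)
  expect_lt(gap[21], gap[1] / 100)
  expect_true(all(utils::tail(gap, 5) < 1e-3))
})

test_that("stochastic transfer series are reproducible and heterokaryons
           accumulate when formation is on", {
  cfg <- simulation_config(seed = 77)
  t1 <- simulate_transfer_series(cfg)
  t2 <- simulate_transfer_series(cfg)
  expect_identical(t1, t2)
  expect_gt(t1$f_het[t1$transfer == 1], 0.1)
  expect_false(attr(t1, "terminated"))
})

test_that("bottleneck sampling preserves the expected frequency", {
  n <- 2000
  f <- 0.27
  means <- withr::with_seed(88, {
    vapply(1:1000, function(i) stats::rbinom(1, n, f) / n, numeric(1))
  })
  expect_lt(abs(mean(means) - f), 0.001)
  # the simulator's own bottleneck shows no drift in the mean either
  cfg <- simulation_config(fitness_slope = 0, het_rate = 0, n_transfers = 1,
                           f0 = 0.27, yield_decline = 0)
  ends <- vapply(1:300, function(s) {
    cfg$seed <- s
    simulate_transfer_series(cfg)$f_cheater[2]
  }, numeric(1))
  expect_lt(abs(mean(ends) - 0.27), 0.002)
})

test_that("a catastrophic yield collapse terminates the series with a
           flag", {
  cfg <- simulation_config(seed = 3, yield_max = 10, yield_decline = 1,
                           f0 = 0.95, fitness_slope = 0, het_rate = 0,
                           n_transfers = 4, bottleneck_fraction = 0.01)
  ts <- simulate_transfer_series(cfg)
  expect_true(attr(ts, "terminated"))
  expect_lt(max(ts$transfer), 4)
})

test_that("unknown configuration fields are rejected", {
  expect_error(simulation_config(window = 100), "unknown config")
})
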