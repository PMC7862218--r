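test_that("flag set membership is exact: brute force over all 12-bit flags", {
  expect_true(all(flag_is_discordant(c(67, 131, 115, 179, 81, 161, 97, 145,
                                       65, 129, 113, 177))))
  expect_false(flag_is_discordant(99))
  hits <- which(flag_is_discordant(0:4095)) - 1
  expect_length(hits, 12)
  expect_setequal(hits, DISCORDANT_FLAGS)
  expect_error(flag_is_discordant(-1), "non-negative")
})

test_that("classification is the union of clip/indel CIGAR and listed flags,
           and partitions mapped records", {
  obs <- tibble::tibble(
    flag = c(99L, 99L, 177L, 81L, 147L, 99L),
    cigar = c("50M10S", "100M", "100M", "90M", "40M2I58M", "30M5D70M")
  )
  lab <- classify_alignments(obs)
  expect_equal(as.character(lab),
               c("ALTERNATE", "NORMAL", "ALTERNATE", "ALTERNATE",
                 "ALTERNATE", "ALTERNATE"))
  expect_equal(sum(lab == "ALTERNATE") + sum(lab == "NORMAL"), nrow(obs))
  # unmapped records are refused, not silently classified
  expect_error(
    classify_alignments(tibble::tibble(flag = 4L, cigar = "*")),
    "unmapped"
  )
})

test_that("window tiling is half-open from zero with a truncated tail", {
  w <- tile_windows(250, 100)
  expect_equal(w$window_start, c(0, 100, 200))
  expect_equal(w$window_end, c(100, 200, 250))
  expect_equal(nrow(tile_windows(100, 100)), 1)
  expect_equal(nrow(tile_windows(41102378, 100)), ceiling(41102378 / 100))
  expect_equal(nrow(tile_windows(41102378, 100)), 411024)
  expect_error(tile_windows(0, 100), "positive")
  expect_error(tile_windows(100, 0), "positive")
})

test_that("window coverage matches a per-base brute-force oracle", {
  withr::with_seed(11, {
    n <- 120
    obs <- tibble::tibble(
      contig = "ctg",
      pos = sample(0:1900, n, replace = TRUE),
      flag = sample(c(99L, 147L, 97L, 145L), n, replace = TRUE),
      cigar = sample(c("100M", "60M40S", "50M10D40M", "80M5I15M"), n,
                     replace = TRUE),
      mapq = 60L
    )
  })
  len <- 2000
  prof <- window_profiles(obs, c(ctg = len), window = 100)
  d_all <- oracle_depth(obs, len)
  lab <- classify_alignments(obs)
  d_alt <- oracle_depth(obs[lab == "ALTERNATE", ], len)
  starts <- prof$window_start
  tot_oracle <- vapply(seq_along(starts), function(i) {
    sum(d_all[(starts[i] + 1):prof$window_end[i]])
  }, numeric(1))
  alt_oracle <- vapply(seq_along(starts), function(i) {
    sum(d_alt[(starts[i] + 1):prof$window_end[i]])
  }, numeric(1))
  expect_equal(prof$total_coverage, tot_oracle)
  expect_equal(prof$alt_coverage, alt_oracle)
  # conservation: windowed total equals total reference-consuming bases
  spans <- vapply(obs$cigar, oracle_ref_span, numeric(1))
  clipped_tail <- sum(pmax(obs$pos + spans - len, 0))
  expect_equal(sum(prof$total_coverage), sum(spans) - clipped_tail)
  # fractions bounded and defined only where covered
  ok <- !is.na(prof$alt_fraction)
  expect_true(all(prof$alt_fraction[ok] >= 0 & prof$alt_fraction[ok] <= 1))
  expect_true(all(prof$total_coverage[!ok] == 0))
})

test_that("alternate fraction is invariant under duplicating the read set", {
  withr::with_seed(21, {
    obs <- tibble::tibble(
      contig = "ctg",
      pos = sample(0:900, 50, replace = TRUE),
      flag = sample(c(99L, 81L), 50, replace = TRUE),
      cigar = sample(c("100M", "70M30S"), 50, replace = TRUE),
      mapq = 60L
    )
  })
  p1 <- window_profiles(obs, c(ctg = 1000))
  p2 <- window_profiles(dplyr::bind_rows(obs, obs), c(ctg = 1000))
  expect_equal(p2$alt_fraction, p1$alt_fraction)
  expect_equal(p2$total_coverage, 2 * p1$total_coverage)
})

test_that("pure read sets give fraction 0 or 1", {
  normal <- tibble::tibble(contig = "c", pos = rep(0L, 10), flag = 99L,
                           cigar = "100M", mapq = 60L)
  p <- window_profiles(normal, c(c = 100))
  expect_equal(p$alt_fraction, 0)
  all_alt <- dplyr::mutate(normal, cigar = "60M40S")
  expect_equal(window_profiles(all_alt, c(c = 100))$alt_fraction, 1)
})

test_that("profile comparison ranks by |difference| and drops uncovered
           windows", {
  obs <- tibble::tibble(contig = "c", pos = c(0L, 150L), flag = 99L,
                        cigar = "100M", mapq = 60L)
  p <- window_profiles(obs, c(c = 400), window = 100)
  cmp <- compare_profiles(p, p)
  expect_true(all(cmp$abs_difference == 0))
  # window [300,400) has no coverage in either sample -> absent
  expect_false(300 %in% cmp$window_start)
  # mismatched tilings error
  p2 <- window_profiles(obs, c(c = 400), window = 200)
  expect_error(compare_profiles(p, p2), "tiled identically")
})

test_that("an implanted deletion puts its breakpoint-flanking windows on
           top of the ranking, through the SAM round trip", {
  cfg <- simulation_config(seed = 42, deletion = c(pos = 1200, len = 400))
  evo <- simulate_alignments(cfg)
  anc <- simulate_alignments(simulation_config(seed = 43, deletion = NULL))
  f_anc <- tempfile(fileext = ".sam")
  f_evo <- tempfile(fileext = ".sam")
  write_sam(anc, f_anc)
  write_sam(evo, f_evo)
  tab <- sv_scan(f_anc, f_evo, window = 100)
  truth <- breakpoint_windows(evo$truth, window = 100)
  expect_true(all(tab$start[1:2] %in% truth$window_start))
  # ranks are a permutation starting at 1
  expect_equal(tab$rank, seq_len(nrow(tab)))
  # BED-like columns
  expect_named(tab, c("contig", "start", "end", "alt_frac_a", "alt_frac_b",
                      "abs_diff", "rank"))
})

test_that("reading a SAM file recovers the written alignment columns", {
  sim <- simulate_alignments(simulation_config(seed = 5))
  f <- tempfile(fileext = ".sam")
  write_sam(sim, f)
  got <- read_alignments(f)
  expect_equal(got$contig_lengths, sim$contig_lengths)
  expect_equal(nrow(got$alignments), nrow(sim$alignments))
  ord_in <- order(sim$alignments$pos, sim$alignments$qname,
                  sim$alignments$flag)
  ord_out <- order(got$alignments$pos, got$alignments$flag)
  # scanBam returns records in file order; compare as sorted multisets
  expect_equal(sort(got$alignments$pos), sort(sim$alignments$pos))
  expect_equal(sort(got$alignments$cigar), sort(sim$alignments$cigar))
  expect_equal(sort(got$alignments$flag), sort(sim$alignments$flag))
})
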