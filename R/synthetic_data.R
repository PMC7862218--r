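#' Simulation configuration
#'
#' Collects the knobs of all synthetic-data generators with defaults chosen
#' to mirror the assay conditions the analysis chain was built for:
#' 150 bp paired-end reads at ~25x depth; six qPCR technical replicates with
#' 0.1-cycle noise at perfect doubling efficiency within a 40-cycle program;
#' four replicate counting plates per medium; serial transfers of 1% of the
#' spores every cycle, four transfers. The frequency-dependent fitness
#' function is an explicitly phenomenological stand-in:
#' `S(f) = exp(slope * (root - f))`, log-linear with neutrality at
#' `f = root` (default 0.3).
#'
#' @param ... Overrides of any default field.
#' @return Named list of class `"sim_config"`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # alignment simulation
    contig = "chrI",
    reference_length = 5000,
    read_length = 150,
    mean_depth = 25,
    insert_size = 400,
    deletion = c(pos = 1000, len = 300),
    background_clip_rate = 0,
    # qPCR simulation
    efficiency = 2.0,
    ct_noise_sd = 0.1,
    n_ct_replicates = 6L,
    base_ct = 20,
    max_cycles = 40,
    # plating simulation
    genotype_freqs = c(inl = 0.55, pan = 0.35, het = 0.10),
    colonies_per_plate = 400,
    n_plates = 4L,
    dilution = 1,
    volume = 0.1,
    # transfer / competition simulation
    fitness_root = 0.3,
    fitness_slope = 5,
    het_rate = 0.5,
    yield_max = 2e8,
    yield_decline = 0.8,
    bottleneck_fraction = 0.01,
    n_transfers = 4L,
    f0 = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# Map a coordinate on the deletion-bearing (mutant) genome back to the
# reference: positions at/after the junction shift right by the deletion.
.mut_to_ref <- function(x, del_pos, del_len) {
  ifelse(x < del_pos, x, x + del_len)
}

#' Simulate paired-end alignments over a reference with an implanted deletion
#'
#' Generates error-free paired-end reads from a genome carrying an optional
#' homozygous deletion, reported in reference coordinates as a SAM-style
#' alignment table. Reads crossing a deletion breakpoint carry soft clips
#' (the unalignable side of the junction is clipped, anchored on its longer
#' side); pairs whose mates fall on opposite sides of the deletion get
#' discordant flags (97/145) from the recognised set; all other pairs carry
#' proper-pair flags (99/147). Coverage is uniform on the mutant genome.
#'
#' @param cfg A [simulation_config()]; fields used: `seed`, `contig`,
#'   `reference_length`, `read_length`, `mean_depth`, `insert_size`,
#'   `deletion` (named `c(pos =, len =)` in reference coordinates, or
#'   `NULL`), `background_clip_rate`.
#' @return List with `alignments` (tibble: `qname`, `flag`, `contig`, `pos`
#'   0-based, `mapq`, `cigar`, `mate_pos`, `tlen`), `contig_lengths`, and
#'   `truth` (tibble of breakpoint reference coordinates; empty when no
#'   deletion).
#' @export
simulate_alignments <- function(cfg = simulation_config()) {
  L <- cfg$reference_length
  rl <- cfg$read_length
  ins <- cfg$insert_size
  del <- cfg$deletion
  if (!is.null(del)) {
    dp <- del[["pos"]]; dl <- del[["len"]]
    if (dp < 0 || dl <= 0 || dp + dl > L) {
      stop("deletion does not fit inside the reference", call. = FALSE)
    }
    if (dl < rl) {
      warning("deletion shorter than the read length may not force clips",
              call. = FALSE)
    }
  } else {
    dp <- NA; dl <- 0
  }
  L_mut <- L - dl
  if (ins > L_mut) stop("insert size exceeds the (mutant) genome",
                        call. = FALSE)
  n_pairs <- max(1L, round(cfg$mean_depth * L_mut / (2 * rl)))

  aln <- withr::with_seed(cfg$seed, {
    starts <- floor(stats::runif(n_pairs, 0, L_mut - ins + 1))
    clip_bg <- if (cfg$background_clip_rate > 0) {
      stats::runif(2 * n_pairs) < cfg$background_clip_rate
    } else rep(FALSE, 2 * n_pairs)

    place_read <- function(a) {
      # a: 0-based mutant-coordinate start of an rl-long read
      b <- a + rl
      if (is.na(dp) || b <= dp || a >= dp) {
        pos <- if (is.na(dp)) a else .mut_to_ref(a, dp, dl)
        list(pos = pos, cigar = sprintf("%dM", rl), crosses = FALSE)
      } else {
        left <- dp - a
        right <- rl - left
        if (left >= right) {
          list(pos = a, cigar = sprintf("%dM%dS", left, right),
               crosses = TRUE)
        } else {
          list(pos = dp + dl, cigar = sprintf("%dS%dM", left, right),
               crosses = TRUE)
        }
      }
    }

    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      s <- starts[i]
      r1 <- place_read(s)
      r2 <- place_read(s + ins - rl)
      straddle <- !is.na(dp) && (s + rl <= dp) && (s + ins - rl >= dp)
      fl1 <- if (straddle) 97L else 99L
      fl2 <- if (straddle) 145L else 147L
      cg1 <- r1$cigar; cg2 <- r2$cigar
      if (clip_bg[2 * i - 1] && !r1$crosses) {
        cg1 <- sprintf("%dM%dS", rl - 10L, 10L)
      }
      if (clip_bg[2 * i] && !r2$crosses) {
        cg2 <- sprintf("%dM%dS", rl - 10L, 10L)
      }
      tl <- .mut_to_ref(s + ins, dp, dl) - .mut_to_ref(s, dp, dl)
      if (is.na(dp)) tl <- ins
      qn <- sprintf("sim_%06d", i)
      rows[[i]] <- tibble::tibble(
        qname = qn,
        flag = c(fl1, fl2),
        contig = cfg$contig,
        pos = c(r1$pos, r2$pos),
        mapq = 60L,
        cigar = c(cg1, cg2),
        mate_pos = c(r2$pos, r1$pos),
        tlen = c(tl, -tl)
      )
    }
    dplyr::bind_rows(rows)
  })

  truth <- if (!is.null(del)) {
    tibble::tibble(contig = cfg$contig, breakpoint = c(dp, dp + dl))
  } else {
    tibble::tibble(contig = character(), breakpoint = numeric())
  }
  cl <- stats::setNames(L, cfg$contig)
  list(alignments = aln, contig_lengths = cl, truth = truth)
}

#' Write a simulated alignment set to a SAM file
#'
#' Deterministic formatting: the same alignment table always produces
#' byte-identical output.
#'
#' @param sim Result of [simulate_alignments()] (or a compatible list with
#'   `alignments` and `contig_lengths`).
#' @param path Output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  a <- sim$alignments
  cl <- sim$contig_lengths
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(cl), as.integer(cl))
  )
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                  a$qname, a$flag, a$contig, a$pos + 1L, a$mapq, a$cigar,
                  a$mate_pos + 1L, a$tlen)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Windows carrying evidence of the true breakpoints of a simulated deletion
#'
#' A clipped read localizes a breakpoint only to within its aligned anchor:
#' the matched portion of a read clipped at a junction at coordinate `p`
#' extends up to a read length to either side of `p`, and that is where the
#' alternate coverage lands. The truth region for a windowed scan is
#' therefore `[p - slop, p + slop)` with `slop` equal to the read length;
#' all windows overlapping it are returned.
#'
#' @param truth Truth tibble from [simulate_alignments()].
#' @param window Window size in bp.
#' @param slop Localization half-width in bp; default the simulated read
#'   length (150).
#' @return Tibble with `contig`, `window_start` for each breakpoint-evidence
#'   window (deduplicated).
#' @export
breakpoint_windows <- function(truth, window = 100, slop = 150) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    lo <- max(truth$breakpoint[i] - slop, 0)
    hi <- truth$breakpoint[i] + slop
    starts <- seq((lo %/% window) * window, ((hi - 1) %/% window) * window,
                  by = window)
    tibble::tibble(contig = truth$contig[i], window_start = starts)
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Simulate a duplexed qPCR Ct measurement at a known mixture fraction
#'
#' Inverse of the analysis model: for a true deletion-nucleus frequency `f`,
#' the expected Ct difference is `log_E(f / (1 - f))`; technical replicates
#' get independent Gaussian noise. Boundary frequencies (0 or 1) yield a
#' censored measurement with the absent amplicon's replicates pinned at the
#' cycle ceiling.
#'
#' @param true_f_dso True deletion-nucleus frequency in `[0, 1]`.
#' @param efficiency Amplification efficiency per cycle (> 1), default 2.
#' @param noise_sd Replicate noise SD in cycles, default 0.1.
#' @param n_replicates Technical replicates per amplicon, default 6.
#' @param base_ct Ct of the *hygB* amplicon at its template abundance,
#'   default 20.
#' @param max_cycles Cycle ceiling, default 40.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `ct_so`, `ct_hygB` (numeric vectors) and `true_f_dso`.
#' @export
simulate_qpcr_ct <- function(true_f_dso, efficiency = 2.0, noise_sd = 0.1,
                             n_replicates = 6L, base_ct = 20,
                             max_cycles = 40, seed = NULL) {
  if (true_f_dso < 0 || true_f_dso > 1) {
    stop("`true_f_dso` must be in [0, 1]", call. = FALSE)
  }
  if (efficiency <= 1) stop("`efficiency` must exceed 1", call. = FALSE)
  gen <- function() {
    noise <- function() {
      if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd) else
        rep(0, n_replicates)
    }
    if (true_f_dso == 0) {
      list(ct_so = rep(base_ct, n_replicates) + noise(),
           ct_hygB = rep(max_cycles, n_replicates),
           true_f_dso = true_f_dso)
    } else if (true_f_dso == 1) {
      list(ct_so = rep(max_cycles, n_replicates),
           ct_hygB = rep(base_ct, n_replicates) + noise(),
           true_f_dso = true_f_dso)
    } else {
      delta <- log(true_f_dso / (1 - true_f_dso)) / log(efficiency)
      list(ct_so = rep(base_ct + delta, n_replicates) + noise(),
           ct_hygB = rep(base_ct, n_replicates) + noise(),
           true_f_dso = true_f_dso)
    }
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate colony counts of the three-medium plating design
#'
#' For each plate, the spores landing on it are a multinomial draw over the
#' three genotype classes; the observed count is the number of classes able
#' to grow on that plate's medium (inositol medium: inl-requiring
#' homokaryons + heterokaryons; pantothenate medium: pan-requiring
#' homokaryons + heterokaryons; unsupplemented: heterokaryons only). In
#' noise-free mode the counts equal their expectations, making the
#' deconvolution an exact inverse.
#'
#' @param genotype_freqs Named vector `c(inl =, pan =, het =)` summing to 1.
#' @param colonies_per_plate Expected spores deposited per plate (> 0).
#' @param n_plates Replicate plates per medium, default 4.
#' @param dilution,volume Dilution factor and plated volume recorded in the
#'   output table.
#' @param noise Draw multinomial counts (default) or return exact
#'   expectations.
#' @param seed Optional RNG seed.
#' @return Tibble in the plate-count table schema (`sample`, `transfer`,
#'   `medium`, `plate`, `count`, `dilution`, `volume`).
#' @export
simulate_plate_counts <- function(genotype_freqs, colonies_per_plate = 400,
                                  n_plates = 4L, dilution = 1, volume = 0.1,
                                  noise = TRUE, seed = NULL) {
  f <- genotype_freqs[c("inl", "pan", "het")]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
    stop("`genotype_freqs` must be named (inl, pan, het), non-negative, ",
         "and sum to 1", call. = FALSE)
  }
  if (colonies_per_plate <= 0) {
    stop("`colonies_per_plate` must be positive", call. = FALSE)
  }
  viable <- list(inl = c("inl", "het"), pan = c("pan", "het"),
                 none = "het")
  gen <- function() {
    rows <- list()
    for (medium in names(viable)) {
      for (p in seq_len(n_plates)) {
        cnt <- if (noise) {
          x <- stats::rmultinom(1, colonies_per_plate, f)[, 1]
          sum(x[viable[[medium]]])
        } else {
          colonies_per_plate * sum(f[viable[[medium]]])
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample = "sim", transfer = 0L, medium = medium, plate = p,
          count = cnt, dilution = dilution, volume = volume
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate pairwise competition outcomes under log-linear frequency
#' dependence
#'
#' Generates (realized initial, final) frequency pairs at a grid of nominal
#' starting frequencies. The generating fitness model is the same log-linear
#' form the default fit assumes: `S(f) = exp(slope * (root - f))`, with the
#' final frequency `min(f * S(f), 1)`. Both the realized initial and the
#' final frequency are estimated by binomial colony counting, adding the
#' sampling noise of the plating step.
#'
#' @param f_nominal Nominal starting frequencies (default the assay grid
#'   0.1 to 0.9 by 0.1).
#' @param root Equilibrium frequency of the generating model, default 0.3.
#' @param slope Steepness of the log-linear decline, default 5.
#' @param n_replicates Biological replicates per frequency, default 3.
#' @param n_colonies Colonies counted per estimate, default 300.
#' @param noise Apply binomial counting noise (default) or return exact
#'   values.
#' @param seed Optional RNG seed.
#' @return Tibble with `replicate`, `f_initial` (realized), `f_final`.
#' @export
simulate_competition_records <- function(f_nominal = seq(0.1, 0.9, by = 0.1),
                                         root = 0.3, slope = 5,
                                         n_replicates = 3L, n_colonies = 300,
                                         noise = TRUE, seed = NULL) {
  stopifnot(all(f_nominal > 0 & f_nominal < 1))
  gen <- function() {
    rows <- list()
    rep_id <- 0L
    for (f0 in f_nominal) {
      for (r in seq_len(n_replicates)) {
        rep_id <- rep_id + 1L
        f_init <- if (noise) {
          stats::rbinom(1, n_colonies, f0) / n_colonies
        } else f0
        if (f_init == 0) next  # mutant absent from the inoculum sample
        s_true <- exp(slope * (root - f_init))
        f_fin_true <- min(f_init * s_true, 1)
        f_fin <- if (noise) {
          stats::rbinom(1, n_colonies, f_fin_true) / n_colonies
        } else f_fin_true
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = rep_id, f_initial = f_init, f_final = f_fin
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a serial-transfer experiment with bottlenecks
#'
#' Phenomenological dynamics of a cheater/wild-type mixture over repeated
#' growth-and-transfer cycles. Each cycle: (1) the cheater's class weight is
#' multiplied by `S(f) = exp(slope * (root - f))` evaluated at the effective
#' cheater frequency (homokaryotic cheaters plus half the heterokaryons),
#' wild type and heterokaryons are neutral; (2) a fraction
#' `het_rate * 2 * f_c * f_w` of spores becomes heterokaryotic (mass-action
#' stand-in for fusion between the two homokaryon classes, drawn equally
#' from both); (3) total spore yield declines linearly with the effective
#' cheater frequency; (4) a bottleneck transfers `bottleneck_fraction` of
#' the yield, with multinomial sampling of the transferred spores.
#'
#' This is an explicit stand-in for the qualitative mechanism (fragmentation
#' of poorly fused mycelia), not a mechanistic model; all rates are free
#' parameters.
#'
#' @param cfg A [simulation_config()]; fields used: `seed`, `f0`,
#'   `n_transfers`, `fitness_root`, `fitness_slope`, `het_rate`,
#'   `yield_max`, `yield_decline`, `bottleneck_fraction`.
#' @param stochastic Apply the multinomial bottleneck (default); `FALSE`
#'   gives the deterministic (infinite population) dynamics.
#' @return Tibble with `transfer` (0 = inoculum), `f_cheater`, `f_wt`,
#'   `f_het`, `yield`, `n_transferred`; attribute `terminated` is `TRUE`
#'   when the bottleneck extinguished the whole population early.
#' @export
simulate_transfer_series <- function(cfg = simulation_config(),
                                     stochastic = TRUE) {
  run <- function() {
    state <- c(cheater = cfg$f0, wt = 1 - cfg$f0, het = 0)
    out <- list(tibble::tibble(transfer = 0L, f_cheater = state[[1]],
                               f_wt = state[[2]], f_het = state[[3]],
                               yield = NA_real_, n_transferred = NA_real_))
    terminated <- FALSE
    for (t in seq_len(cfg$n_transfers)) {
      fc_eff <- state[["cheater"]] + state[["het"]] / 2
      s <- exp(cfg$fitness_slope * (cfg$fitness_root - fc_eff))
      w <- c(state[["cheater"]] * s, state[["wt"]], state[["het"]])
      w <- w / sum(w)
      formed <- min(cfg$het_rate * 2 * w[1] * w[2], 2 * min(w[1], w[2]))
      w <- c(w[1] - formed / 2, w[2] - formed / 2, w[3] + formed)
      fc_eff <- w[1] + w[3] / 2
      yield <- cfg$yield_max * max(1 - cfg$yield_decline * fc_eff, 0)
      n_next <- round(cfg$bottleneck_fraction * yield)
      if (stochastic) {
        if (n_next < 1) {
          terminated <- TRUE
          break
        }
        counts <- stats::rmultinom(1, n_next, w)[, 1]
        state <- counts / n_next
      } else {
        state <- w
        n_next <- cfg$bottleneck_fraction * yield
      }
      names(state) <- c("cheater", "wt", "het")
      out[[t + 1]] <- tibble::tibble(transfer = t, f_cheater = state[[1]],
                                     f_wt = state[[2]], f_het = state[[3]],
                                     yield = yield, n_transferred = n_next)
    }
    res <- dplyr::bind_rows(out)
    attr(res, "terminated") <- terminated
    res
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}
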