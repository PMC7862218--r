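#' Average technical qPCR replicates
#'
#' @param replicates Non-empty numeric vector of Ct values (cycles).
#' @param sd_warn Warn when the replicate standard deviation exceeds this
#'   (cycles); default 0.5.
#' @return List with `mean_ct`, `n`, `sd`.
#' @examples
#' aggregate_ct(c(19.8, 20.2))
#' @export
aggregate_ct <- function(replicates, sd_warn = 0.5) {
  if (length(replicates) == 0 || !is.numeric(replicates) ||
      anyNA(replicates)) {
    stop("`replicates` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  s <- if (length(replicates) > 1) stats::sd(replicates) else NA_real_
  if (!is.na(s) && s > sd_warn) {
    warning("replicate Ct standard deviation ", signif(s, 3),
            " exceeds ", sd_warn, " cycles", call. = FALSE)
  }
  list(mean_ct = mean(replicates), n = length(replicates), sd = s)
}

#' Convert a Ct difference to nuclear genotype frequencies
#'
#' The duplex design amplifies the *hygB* cassette (marking the deletion
#' nuclei) and the intact *so* locus (marking wild-type nuclei) from the same
#' genomic DNA. With amplification efficiency `E` per cycle, a Ct difference
#' `delta_ct = Ct(so) - Ct(hygB)` implies the template-abundance ratio
#' `r = E^delta_ct` of deletion to wild-type nuclei, hence a deletion-nucleus
#' frequency `f = r / (1 + r)`. At `delta_ct = 0` the two genotypes are at
#' 50/50; at `delta_ct = 2` with perfect doubling (`E = 2`) the split is
#' 80/20.
#'
#' The sign convention is fixed so that positive `delta_ct` (the *hygB*
#' amplicon crossing threshold earlier) means more deletion template; it
#' satisfies `f(-delta) = 1 - f(delta)` exactly.
#'
#' @param delta_ct Ct difference, `mean Ct(so) - mean Ct(hygB)`, in cycles.
#'   Vectorised.
#' @param efficiency Per-cycle amplification efficiency `E > 1`; 2 means
#'   perfect doubling (default).
#' @return Tibble with `delta_ct`, `f_dso` (deletion-nucleus frequency),
#'   `f_wt = 1 - f_dso`.
#' @examples
#' frequency_from_delta_ct(0)  # 50/50
#' frequency_from_delta_ct(2)  # 80/20
#' @export
frequency_from_delta_ct <- function(delta_ct, efficiency = 2.0) {
  if (!is.numeric(efficiency) || length(efficiency) != 1 || efficiency <= 1) {
    stop("`efficiency` must be a single value > 1 (2 = perfect doubling)",
         call. = FALSE)
  }
  if (!is.numeric(delta_ct) || anyNA(delta_ct)) {
    stop("`delta_ct` must be numeric without NAs", call. = FALSE)
  }
  r <- efficiency^delta_ct
  f <- r / (1 + r)
  tibble::tibble(delta_ct = delta_ct, f_dso = f, f_wt = 1 - f)
}

#' Genotype frequencies from one Ct measurement
#'
#' Averages the technical replicates of each amplicon, forms
#' `delta_ct = mean Ct(so) - mean Ct(hygB)`, and converts it to nuclear
#' genotype frequencies. Replicates sitting at the cycle ceiling (no
#' amplification within the run) censor the estimate to frequency 0 or 1
#' rather than exponentiating the ceiling.
#'
#' @param ct_so,ct_hygB Numeric vectors of technical-replicate Ct values for
#'   the *so* and *hygB* amplicons (typically six each).
#' @param efficiency Per-cycle amplification efficiency, default 2.
#' @param max_cycles Cycle ceiling of the amplification program (default 40);
#'   replicates at or above it count as non-amplifying.
#' @param sd_warn Passed to [aggregate_ct()].
#' @return One-row tibble with `mean_ct_so`, `mean_ct_hygB`, `sd_ct_so`,
#'   `sd_ct_hygB`, `n_so`, `n_hygB`, `delta_ct`, `f_dso`, `f_wt`,
#'   `censored` (`"none"`, `"no_so"`, `"no_hygB"`, `"no_signal"`).
#' @examples
#' frequency_from_measurement(rep(22, 6), rep(21, 6))  # f_dso = 2/3
#' @export
frequency_from_measurement <- function(ct_so, ct_hygB, efficiency = 2.0,
                                       max_cycles = 40, sd_warn = 0.5) {
  so_dead <- all(ct_so >= max_cycles)
  hyg_dead <- all(ct_hygB >= max_cycles)
  if (so_dead && hyg_dead) {
    return(tibble::tibble(mean_ct_so = NA_real_, mean_ct_hygB = NA_real_,
                          sd_ct_so = NA_real_, sd_ct_hygB = NA_real_,
                          n_so = length(ct_so), n_hygB = length(ct_hygB),
                          delta_ct = NA_real_, f_dso = NA_real_,
                          f_wt = NA_real_, censored = "no_signal"))
  }
  agg_so <- aggregate_ct(ct_so, sd_warn = sd_warn)
  agg_hyg <- aggregate_ct(ct_hygB, sd_warn = sd_warn)
  if (so_dead || hyg_dead) {
    # only one template detectable: the sample is effectively pure
    f <- if (so_dead) 1 else 0
    return(tibble::tibble(mean_ct_so = agg_so$mean_ct,
                          mean_ct_hygB = agg_hyg$mean_ct,
                          sd_ct_so = agg_so$sd, sd_ct_hygB = agg_hyg$sd,
                          n_so = agg_so$n, n_hygB = agg_hyg$n,
                          delta_ct = NA_real_, f_dso = f, f_wt = 1 - f,
                          censored = if (so_dead) "no_so" else "no_hygB"))
  }
  delta <- agg_so$mean_ct - agg_hyg$mean_ct
  est <- frequency_from_delta_ct(delta, efficiency)
  tibble::tibble(mean_ct_so = agg_so$mean_ct, mean_ct_hygB = agg_hyg$mean_ct,
                 sd_ct_so = agg_so$sd, sd_ct_hygB = agg_hyg$sd,
                 n_so = agg_so$n, n_hygB = agg_hyg$n,
                 delta_ct = delta, f_dso = est$f_dso, f_wt = est$f_wt,
                 censored = "none")
}

#' Read a long-format Ct table
#'
#' @param path TSV with columns `sample`, `amplicon` (`"so"` or `"hygB"`),
#'   `replicate`, `ct`.
#' @return Tibble of the same columns, types checked.
#' @export
read_ct_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "amplicon", "replicate", "ct")
  if (!all(need %in% names(tbl))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tbl$amplicon), c("so", "hygB"))
  if (length(bad) > 0) {
    stop("unknown amplicon value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Per-sample genotype frequencies from a Ct table
#'
#' @param ct_table Long-format tibble as returned by [read_ct_table()].
#' @inheritParams frequency_from_measurement
#' @return Tibble with one row per sample (see
#'   [frequency_from_measurement()] for columns).
#' @export
qpcr_frequencies <- function(ct_table, efficiency = 2.0, max_cycles = 40,
                             sd_warn = 0.5) {
  samples <- unique(ct_table$sample)
  rows <- lapply(samples, function(s) {
    sub <- ct_table[ct_table$sample == s, , drop = FALSE]
    so <- sub$ct[sub$amplicon == "so"]
    hyg <- sub$ct[sub$amplicon == "hygB"]
    if (length(so) == 0 || length(hyg) == 0) {
      stop("sample ", s, " is missing one amplicon", call. = FALSE)
    }
    out <- frequency_from_measurement(so, hyg, efficiency, max_cycles,
                                      sd_warn)
    dplyr::bind_cols(tibble::tibble(sample = s), out)
  })
  dplyr::bind_rows(rows)
}
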