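#' Colony-forming concentration from a plate count
#'
#' @param count Colonies counted (>= 0). Vectorised.
#' @param dilution_factor Fold dilution of the suspension plated (> 0).
#' @param volume_plated Volume plated, in ml (> 0).
#' @return Spores per ml: `count * dilution_factor / volume_plated`.
#' @examples
#' concentration(50, 1000, 0.1)  # 5e5 per ml
#' @export
concentration <- function(count, dilution_factor, volume_plated) {
  if (any(count < 0, na.rm = TRUE)) {
    stop("`count` must be non-negative", call. = FALSE)
  }
  if (any(dilution_factor <= 0) || any(volume_plated <= 0)) {
    stop("dilution factor and plated volume must be positive", call. = FALSE)
  }
  count * dilution_factor / volume_plated
}

#' Deconvolve genotype frequencies from three-medium plate counts
#'
#' The complementation plating design: spores plated on medium supplemented
#' with inositol grow if they are inositol-requiring homokaryons or
#' heterokaryons; on pantothenate medium, pantothenate-requiring homokaryons
#' or heterokaryons; on unsupplemented medium only heterokaryons grow (the
#' two auxotrophies complement inside one spore). Subtracting the
#' unsupplemented concentration from each supplemented one isolates the two
#' homokaryon classes:
#' `c_het = c_none`, `c_inl_homo = c_inl - c_none`,
#' `c_pan_homo = c_pan - c_none`.
#'
#' Sampling noise can drive a subtraction negative; such estimates are
#' clipped to zero and flagged, then frequencies renormalised. An optional
#' maximum-likelihood mode fits the three observed pooled counts as Poisson
#' draws from the same forward model, which avoids the clipping pathology on
#' noisy counts.
#'
#' @param c_inl,c_pan,c_none Concentrations (spores/ml) on the
#'   inositol-supplemented, pantothenate-supplemented, and unsupplemented
#'   media. For `method = "ml"` pass raw pooled *counts* (equal effective
#'   plating volumes assumed).
#' @param method `"subtraction"` (default, the closed-form estimator) or
#'   `"ml"` (constrained Poisson maximum likelihood).
#' @return One-row tibble with `f_inl_homokaryon`, `f_pan_homokaryon`,
#'   `f_heterokaryon` (summing to 1) and `clipped` (logical: a negative
#'   subtraction was truncated).
#' @examples
#' deconvolve_genotypes(60, 50, 10)  # 0.5 / 0.4 / 0.1
#' @export
deconvolve_genotypes <- function(c_inl, c_pan, c_none,
                                 method = c("subtraction", "ml")) {
  method <- match.arg(method)
  if (any(c(c_inl, c_pan, c_none) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (c_inl == 0 && c_pan == 0 && c_none == 0) {
    stop("all three concentrations are zero; frequencies undefined",
         call. = FALSE)
  }
  if (method == "subtraction") {
    inl_homo <- c_inl - c_none
    pan_homo <- c_pan - c_none
    clipped <- inl_homo < 0 || pan_homo < 0
    if (clipped) {
      warning("negative homokaryon estimate clipped to 0 ",
              "(unsupplemented count exceeds a supplemented count); ",
              "consider method = \"ml\"", call. = FALSE)
      inl_homo <- max(inl_homo, 0)
      pan_homo <- max(pan_homo, 0)
    }
    tot <- inl_homo + pan_homo + c_none
    tibble::tibble(f_inl_homokaryon = inl_homo / tot,
                   f_pan_homokaryon = pan_homo / tot,
                   f_heterokaryon = c_none / tot,
                   clipped = clipped)
  } else {
    # Poisson ML over the 2-simplex, softmax parameterisation; the overall
    # scale has closed form given the frequencies
    nll <- function(par) {
      w <- exp(c(par, 0))
      f <- w / sum(w)
      mu <- c(f[1] + f[3], f[2] + f[3], f[3])
      obs <- c(c_inl, c_pan, c_none)
      A <- sum(obs) / sum(mu)
      lam <- pmax(A * mu, 1e-12)
      -sum(stats::dpois(round(obs), lam, log = TRUE))
    }
    fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead")
    w <- exp(c(fit$par, 0))
    f <- w / sum(w)
    tibble::tibble(f_inl_homokaryon = f[1], f_pan_homokaryon = f[2],
                   f_heterokaryon = f[3], clipped = FALSE)
  }
}

#' Mutant frequency from phenotype counts
#'
#' On the counting plates the fusion mutant is distinguishable from the wild
#' type by colony phenotype. The end frequency is paired with the *realized*
#' initial frequency (itself estimated from plating the inoculum) so that
#' competitive success downstream is corrected for pipetting error in the
#' nominal mix.
#'
#' @param mutant_colonies,wildtype_colonies Colony counts (total > 0).
#' @param realized_initial_frequency Realized initial mutant frequency from
#'   inoculum plating, in (0, 1].
#' @return Tibble with `f_mutant` and `f_initial` (the realized initial
#'   frequency, passed through for [competitive_success()]).
#' @examples
#' phenotype_frequency(25, 75, 0.2)
#' @export
phenotype_frequency <- function(mutant_colonies, wildtype_colonies,
                                realized_initial_frequency) {
  total <- mutant_colonies + wildtype_colonies
  if (any(total <= 0)) {
    stop("total colony count must be positive", call. = FALSE)
  }
  if (any(mutant_colonies < 0) || any(wildtype_colonies < 0)) {
    stop("colony counts must be non-negative", call. = FALSE)
  }
  tibble::tibble(f_mutant = mutant_colonies / total,
                 f_initial = realized_initial_frequency)
}

#' Read a long-format plate-count table
#'
#' @param path TSV with columns `sample`, `transfer`, `medium` (`"inl"`,
#'   `"pan"`, `"none"`), `plate`, `count`, `dilution`, `volume`.
#' @return Tibble, types and medium levels checked.
#' @export
read_plate_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "transfer", "medium", "plate", "count", "dilution",
            "volume")
  if (!all(need %in% names(tbl))) {
    stop("plate-count table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tbl$medium), c("inl", "pan", "none"))
  if (length(bad) > 0) {
    stop("unknown medium value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Genotype frequencies per sample and transfer from plate counts
#'
#' Replicate plates of a medium are pooled by summing counts and plated
#' volumes (at a common dilution the pooled concentration equals the
#' concentration of the summed counts at the summed volume), then the pooled
#' concentrations are deconvolved per sample/transfer.
#'
#' @param counts Tibble as returned by [read_plate_counts()].
#' @param method Passed to [deconvolve_genotypes()].
#' @return Tibble with `sample`, `transfer`, the three genotype frequencies,
#'   and `clipped`.
#' @export
plate_frequencies <- function(counts, method = "subtraction") {
  pooled <- counts |>
    dplyr::group_by(.data$sample, .data$transfer, .data$medium) |>
    dplyr::summarise(
      conc = sum(.data$count * .data$dilution) / sum(.data$volume),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "medium", values_from = "conc",
                       values_fill = 0)
  for (m in c("inl", "pan", "none")) {
    if (!m %in% names(pooled)) pooled[[m]] <- 0
  }
  rows <- lapply(seq_len(nrow(pooled)), function(i) {
    dec <- deconvolve_genotypes(pooled$inl[i], pooled$pan[i],
                                pooled$none[i], method = method)
    dplyr::bind_cols(pooled[i, c("sample", "transfer")], dec)
  })
  dplyr::bind_rows(rows)
}
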