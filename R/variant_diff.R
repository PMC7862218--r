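#' Read per-clone variant calls from a VCF file
#'
#' Extracts the minimal call table the pairwise filter consumes: contig,
#' 1-based position, REF, ALT, site depth, and alternate-allele frequency.
#' Multi-allelic records are decomposed into one row per alternate allele
#' before any comparison.
#'
#' Depth is taken from the per-sample `DP` FORMAT field. The frequency comes
#' from `freq_field` when given (e.g. the `FREQ` percent string written by
#' common consensus callers); otherwise it is computed as alt-supporting
#' depth (`AD`) over `DP`. `AD` may hold either alt-only depths or the
#' VCF-standard ref-first layout; both are handled.
#'
#' @param path Path to a VCF 4.x file.
#' @param sample Sample column to read (index or name), default the first.
#' @param freq_field Optional FORMAT field holding the allele frequency;
#'   percent strings such as `"85.7%"` are parsed.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_frequency`.
#' @export
read_variant_calls <- function(path, sample = 1L, freq_field = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 500L, warn = FALSE)
  if (length(head_lines) == 0 || !grepl("^##fileformat=VCF", head_lines[1]) ||
      !any(startsWith(head_lines, "#CHROM"))) {
    stop("failed to parse VCF ", path,
         ": missing ##fileformat or #CHROM header line", call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = numeric(), alt_frequency = numeric()))
  }
  get_fmt <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el), error = function(e) NULL)
    if (is.null(m)) return(rep(NA_character_, n))
    as.character(m[, sample])
  }
  dp <- suppressWarnings(as.numeric(get_fmt("DP")))
  ad_raw <- get_fmt("AD")
  freq_raw <- if (!is.null(freq_field)) get_fmt(freq_field) else NULL

  rows <- lapply(seq_len(n), function(i) {
    line <- i  # data-line index within the VCF body, for error reporting
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    if (n_alt == 0 || anyNA(alts)) {
      stop("malformed VCF record (no ALT) at data line ", line, call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos)) {
      stop("malformed VCF record (bad POS) at data line ", line, call. = FALSE)
    }
    if (!is.null(freq_raw)) {
      fr <- strsplit(freq_raw[i], ",", fixed = TRUE)[[1]]
      fr <- suppressWarnings(as.numeric(sub("%$", "", fr)))
      if (any(fr > 1, na.rm = TRUE)) fr <- fr / 100
      if (length(fr) == 1 && n_alt > 1) fr <- rep(fr, n_alt)
    } else {
      ad <- strsplit(ad_raw[i], ",", fixed = TRUE)[[1]]
      ad <- suppressWarnings(as.numeric(ad))
      if (length(ad) == n_alt + 1) ad <- ad[-1]  # ref-first AD layout
      if (length(ad) != n_alt || anyNA(ad)) {
        stop("cannot derive allele frequency at data line ", line,
             ": AD field absent or inconsistent (supply `freq_field`?)",
             call. = FALSE)
      }
      fr <- if (is.na(dp[i]) || dp[i] == 0) rep(NA_real_, n_alt) else ad / dp[i]
    }
    tibble::tibble(contig = fix[i, "CHROM"], pos = pos,
                   ref = fix[i, "REF"], alt = alts,
                   depth = dp[i], alt_frequency = fr)
  })
  dplyr::bind_rows(rows)
}

#' Pairwise ancestor-versus-evolved variant difference filter
#'
#' Compares two per-clone call sets indexed by (contig, pos, ref, alt) and
#' keeps sites whose alternate-allele frequencies differ by at least
#' `min_freq_diff` with depth at least `min_cov`. A site absent from one
#' call set is treated as alt frequency 0 there, with depth taken from the
#' sample that does carry the record. Thresholds are inclusive.
#'
#' @param calls_ancestor,calls_evolved Call tibbles as returned by
#'   [read_variant_calls()].
#' @param min_cov Minimum site depth (default 10).
#' @param min_freq_diff Minimum absolute frequency difference (default 0.8).
#' @param coverage_scope Which sample(s) must meet `min_cov`: `"both"`
#'   (default), `"evolved"`, or `"carrier"` (only samples with non-zero
#'   frequency at the site).
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `freq_ancestor`,
#'   `freq_evolved`, `depth_ancestor`, `depth_evolved`, `direction`
#'   (`"gained"` when the evolved frequency is higher, else `"lost"`),
#'   ordered by contig then position.
#' @examples
#' anc <- tibble::tibble(contig = "chr1", pos = 100L, ref = "A", alt = "T",
#'                       depth = 30, alt_frequency = 0)
#' evo <- tibble::tibble(contig = "chr1", pos = 100L, ref = "A", alt = "T",
#'                       depth = 25, alt_frequency = 0.9)
#' pairwise_diff(anc, evo)
#' @export
pairwise_diff <- function(calls_ancestor, calls_evolved, min_cov = 10,
                          min_freq_diff = 0.8,
                          coverage_scope = c("both", "evolved", "carrier")) {
  coverage_scope <- match.arg(coverage_scope)
  key <- c("contig", "pos", "ref", "alt")
  check <- function(x, nm) {
    need <- c(key, "depth", "alt_frequency")
    if (!all(need %in% names(x))) {
      stop("`", nm, "` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(x$alt_frequency < 0 | x$alt_frequency > 1, na.rm = TRUE)) {
      stop("`", nm, "` has alt_frequency outside [0,1]", call. = FALSE)
    }
    x[c(key, "depth", "alt_frequency")]
  }
  a <- check(calls_ancestor, "calls_ancestor")
  e <- check(calls_evolved, "calls_evolved")
  shared_ctg <- union(a$contig, e$contig)
  if (nrow(a) > 0 && nrow(e) > 0 &&
      length(intersect(a$contig, e$contig)) == 0) {
    warning("the two call sets share no reference contig names",
            call. = FALSE)
  }
  m <- dplyr::full_join(
    dplyr::rename(a, depth_ancestor = "depth", freq_ancestor = "alt_frequency"),
    dplyr::rename(e, depth_evolved = "depth", freq_evolved = "alt_frequency"),
    by = key
  )
  # absent site: frequency 0, depth borrowed from the sample with the record
  m$freq_ancestor[is.na(m$freq_ancestor)] <- 0
  m$freq_evolved[is.na(m$freq_evolved)] <- 0
  m$depth_ancestor <- ifelse(is.na(m$depth_ancestor), m$depth_evolved,
                             m$depth_ancestor)
  m$depth_evolved <- ifelse(is.na(m$depth_evolved), m$depth_ancestor,
                            m$depth_evolved)
  depth_ok <- switch(
    coverage_scope,
    both = m$depth_ancestor >= min_cov & m$depth_evolved >= min_cov,
    evolved = m$depth_evolved >= min_cov,
    carrier = (m$freq_ancestor == 0 | m$depth_ancestor >= min_cov) &
      (m$freq_evolved == 0 | m$depth_evolved >= min_cov)
  )
  keep <- depth_ok & abs(m$freq_evolved - m$freq_ancestor) >= min_freq_diff
  out <- m[keep & !is.na(keep), , drop = FALSE]
  out$direction <- ifelse(out$freq_evolved > out$freq_ancestor,
                          "gained", "lost")
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  tibble::as_tibble(out[c(key, "freq_ancestor", "freq_evolved",
                          "depth_ancestor", "depth_evolved", "direction")])
}

#' Flag intermediate-frequency calls suggestive of a heterokaryotic sample
#'
#' Some clone samples are genetically mixed (two nuclear types in one
#' mycelium), so true variants sit at intermediate allele frequency and fail
#' the stringent pairwise filter. Rather than relaxing the main thresholds,
#' this helper reports such calls separately for manual review.
#'
#' @param calls Call tibble as returned by [read_variant_calls()].
#' @param lower,upper Frequency band treated as intermediate (defaults
#'   0.2 and 0.8).
#' @param min_cov Minimum depth (default 10).
#' @return Subset of `calls` within the band, ordered by contig, pos.
#' @export
intermediate_frequency_calls <- function(calls, lower = 0.2, upper = 0.8,
                                         min_cov = 10) {
  stopifnot(lower < upper)
  keep <- !is.na(calls$alt_frequency) &
    calls$alt_frequency >= lower & calls$alt_frequency <= upper &
    !is.na(calls$depth) & calls$depth >= min_cov
  out <- calls[keep, , drop = FALSE]
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' File-level ancestor/evolved variant difference
#'
#' Reads two VCF files and applies [pairwise_diff()].
#'
#' @param ancestor_vcf,evolved_vcf Paths to VCF files.
#' @param ... Passed to [pairwise_diff()].
#' @inheritParams read_variant_calls
#' @return See [pairwise_diff()].
#' @export
variant_diff <- function(ancestor_vcf, evolved_vcf, freq_field = NULL, ...) {
  a <- read_variant_calls(ancestor_vcf, freq_field = freq_field)
  e <- read_variant_calls(evolved_vcf, freq_field = freq_field)
  pairwise_diff(a, e, ...)
}
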