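#' SAM bitflags treated as discordant
#'
#' The twelve integer flag values that mark read pairs whose orientation,
#' pairing, or mate placement is consistent with a large indel, deletion, or
#' chromosomal rearrangement. Matching is exact set membership of the full
#' integer flag, not bit-level decomposition.
#'
#' @format Integer vector of length 12.
#' @export
DISCORDANT_FLAGS <- c(67L, 131L, 115L, 179L, 81L, 161L, 97L, 145L, 65L,
                      129L, 113L, 177L)

#' Test whether a SAM flag is in the discordant set
#'
#' @param flag Integer vector of SAM bitflags. Must be non-negative.
#' @return Logical vector: `TRUE` where the flag is exactly one of the
#'   twelve values in [DISCORDANT_FLAGS].
#' @examples
#' flag_is_discordant(81)   # TRUE
#' flag_is_discordant(99)   # FALSE (proper pair)
#' @export
flag_is_discordant <- function(flag) {
  if (!is.numeric(flag) || anyNA(flag)) {
    stop("`flag` must be a numeric vector without NAs", call. = FALSE)
  }
  if (any(flag < 0)) {
    stop("SAM flags must be non-negative", call. = FALSE)
  }
  as.integer(flag) %in% DISCORDANT_FLAGS
}

# CIGAR ops signalling a clipped or indel-bearing alignment
.ALT_CIGAR_PATTERN <- "[0-9]+[SHID]"
.CIGAR_VALID <- "^([0-9]+[MIDNSHP=X])+$"

#' Classify mapped alignments as alternate or normal
#'
#' An alignment belongs to the "alternate" set when its CIGAR string contains
#' a soft clip (S), hard clip (H), insertion (I) or deletion (D) operation,
#' or when its flag is one of the discordant values -- the union of the two
#' conditions. Everything else is "normal". Unmapped records (flag bit 0x4
#' set, or missing CIGAR) are not classified and raise an error; filter them
#' out first (see [read_alignments()]).
#'
#' @param obs A data frame of mapped alignments with at least columns
#'   `flag` (integer) and `cigar` (character).
#' @return Factor vector with levels `c("ALTERNATE", "NORMAL")`, one label
#'   per row of `obs`.
#' @examples
#' obs <- tibble::tibble(flag = c(99L, 99L, 177L),
#'                       cigar = c("50M10S", "100M", "100M"))
#' classify_alignments(obs)
#' @export
classify_alignments <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("flag", "cigar") %in% names(obs)))
  unmapped <- bitwAnd(as.integer(obs$flag), 4L) != 0L |
    is.na(obs$cigar) | obs$cigar == "*"
  if (any(unmapped)) {
    stop(sum(unmapped), " unmapped record(s) cannot be classified; ",
         "remove them before calling classify_alignments()", call. = FALSE)
  }
  bad <- !grepl(.CIGAR_VALID, obs$cigar)
  if (any(bad)) {
    stop("invalid CIGAR string(s): ",
         paste(utils::head(unique(obs$cigar[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  alt <- grepl(.ALT_CIGAR_PATTERN, obs$cigar) | flag_is_discordant(obs$flag)
  factor(ifelse(alt, "ALTERNATE", "NORMAL"),
         levels = c("ALTERNATE", "NORMAL"))
}

#' Tile a contig into fixed-width windows
#'
#' Windows are 0-based half-open intervals `[0,w), [w,2w), ...` tiled from
#' position 0; the final window is truncated at the contig end.
#'
#' @param contig_length Contig length in bp (positive).
#' @param window Window size in bp (positive), default 100.
#' @return Tibble with columns `window_start`, `window_end` (0-based,
#'   half-open), `ceiling(contig_length / window)` rows.
#' @examples
#' tile_windows(250, 100)
#' @export
tile_windows <- function(contig_length, window = 100) {
  if (!is.numeric(contig_length) || length(contig_length) != 1 ||
      contig_length <= 0) {
    stop("`contig_length` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop("`window` must be a single positive number", call. = FALSE)
  }
  starts <- seq(0, contig_length - 1, by = window)
  tibble::tibble(window_start = starts,
                 window_end = pmin(starts + window, contig_length))
}

# Reference-consuming width of an alignment (M, D, N, =, X ops).
.reference_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read alignments from a SAM or BAM file
#'
#' Loads the five columns the scan consults (flag, contig, position, mapping
#' quality, CIGAR) from a SAM text file or its binary equivalent. Unmapped
#' records are dropped; secondary and supplementary alignments are dropped by
#' default.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param include_secondary Keep secondary/supplementary alignments
#'   (default `FALSE`).
#' @return List with `alignments` (tibble: `contig`, `pos` 0-based, `flag`,
#'   `mapq`, `cigar`) and `contig_lengths` (named numeric vector from the
#'   header).
#' @export
read_alignments <- function(path, include_secondary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  contig_lengths <- hdr$targets
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (include_secondary) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("flag", "rname", "pos", "mapq", "cigar")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble::tibble(
    contig = as.character(rec$rname),
    pos = rec$pos - 1L,           # SAM is 1-based; internal convention 0-based
    flag = as.integer(rec$flag),
    mapq = as.integer(rec$mapq),
    cigar = rec$cigar
  ) -> aln
  list(alignments = aln, contig_lengths = contig_lengths)
}

#' Per-window alternate and total coverage profiles
#'
#' Quantifies per-base depth of the alternate read set (clipped/indel CIGAR
#' or discordant flag) in fixed windows, divided by the depth of all mapped
#' reads, yielding the per-window alternate fraction. A read contributes
#' depth over its reference-consuming span (M, D, N, =, X operations);
#' insertions and clips consume no reference. Windows with zero total
#' coverage get `NA` alternate fraction.
#'
#' @param obs Tibble of mapped alignments (`contig`, `pos` 0-based, `flag`,
#'   `cigar`, optionally `mapq`).
#' @param contig_lengths Named numeric vector of contig lengths. Every contig
#'   present in `obs` must appear here.
#' @param window Window size in bp, default 100.
#' @param min_mapq Optional mapping-quality floor applied to both read sets;
#'   default 0 (off).
#' @return Tibble with `contig`, `window_start`, `window_end`,
#'   `alt_coverage`, `total_coverage`, `alt_fraction`.
#' @export
window_profiles <- function(obs, contig_lengths, window = 100, min_mapq = 0) {
  stopifnot(is.data.frame(obs))
  need <- c("contig", "pos", "flag", "cigar")
  if (!all(need %in% names(obs))) {
    stop("`obs` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths)))) {
    stop("`contig_lengths` must be a named vector", call. = FALSE)
  }
  missing_ctg <- setdiff(unique(obs$contig), names(contig_lengths))
  if (length(missing_ctg) > 0) {
    stop("contig(s) not in `contig_lengths`: ",
         paste(missing_ctg, collapse = ", "), call. = FALSE)
  }
  if (min_mapq > 0 && "mapq" %in% names(obs)) {
    obs <- obs[obs$mapq >= min_mapq, , drop = FALSE]
  }
  if (any(obs$pos < 0)) stop("negative alignment position", call. = FALSE)
  label <- classify_alignments(obs)
  width <- .reference_width(obs$cigar)

  res <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    win <- tile_windows(len, window)
    on_ctg <- obs$contig == ctg
    sum_windows <- function(keep) {
      if (!any(keep)) return(numeric(nrow(win)))
      ir <- IRanges::IRanges(start = obs$pos[keep] + 1L, width = width[keep])
      cov <- IRanges::coverage(ir, width = len)
      v <- IRanges::Views(cov, start = win$window_start + 1L,
                          end = win$window_end)
      as.numeric(IRanges::viewSums(v))
    }
    win$contig <- ctg
    win$alt_coverage <- sum_windows(on_ctg & label == "ALTERNATE")
    win$total_coverage <- sum_windows(on_ctg)
    win
  })
  out <- dplyr::bind_rows(res)
  out$alt_fraction <- ifelse(out$total_coverage > 0,
                             out$alt_coverage / out$total_coverage, NA_real_)
  dplyr::select(out, "contig", "window_start", "window_end",
                "alt_coverage", "total_coverage", "alt_fraction")
}

#' Rank pairwise window-profile differences
#'
#' Joins two identically tiled window profiles, drops windows where either
#' sample's alternate fraction is undefined (zero total coverage), and ranks
#' the remaining windows by descending absolute difference of the alternate
#' fractions. No threshold is applied: the full ranked table is returned for
#' inspection. Ties are broken by (contig, window_start) ascending.
#'
#' @param profiles_a,profiles_b Window-profile tibbles from
#'   [window_profiles()], tiled identically.
#' @return Tibble with `contig`, `window_start`, `window_end`, `fraction_a`,
#'   `fraction_b`, `abs_difference`, `rank` (1-based, dense by row order).
#' @export
compare_profiles <- function(profiles_a, profiles_b) {
  key <- c("contig", "window_start", "window_end")
  a <- profiles_a[order(profiles_a$contig, profiles_a$window_start), ]
  b <- profiles_b[order(profiles_b$contig, profiles_b$window_start), ]
  if (nrow(a) != nrow(b) || !identical(a[key], b[key])) {
    stop("profiles are not tiled identically; recompute both with the same ",
         "windows and contigs", call. = FALSE)
  }
  out <- tibble::tibble(
    contig = a$contig,
    window_start = a$window_start,
    window_end = a$window_end,
    fraction_a = a$alt_fraction,
    fraction_b = b$alt_fraction
  )
  out <- out[!is.na(out$fraction_a) & !is.na(out$fraction_b), , drop = FALSE]
  out$abs_difference <- abs(out$fraction_a - out$fraction_b)
  out <- out[order(-out$abs_difference, out$contig, out$window_start), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Windowed structural-variant scan of two alignment files
#'
#' End-to-end convenience wrapper: reads two SAM/BAM files, profiles
#' alternate-read coverage in fixed windows, and returns the ranked pairwise
#' comparison table (BED-compatible first three columns).
#'
#' @param sample_a,sample_b Paths to SAM or BAM files aligned to the same
#'   reference.
#' @param window Window size in bp, default 100.
#' @param min_mapq Mapping-quality floor, default 0 (off).
#' @param include_secondary Keep secondary/supplementary alignments,
#'   default `FALSE`.
#' @return Tibble with `contig`, `start`, `end`, `alt_frac_a`, `alt_frac_b`,
#'   `abs_diff`, `rank`.
#' @export
sv_scan <- function(sample_a, sample_b, window = 100, min_mapq = 0,
                    include_secondary = FALSE) {
  a <- read_alignments(sample_a, include_secondary = include_secondary)
  b <- read_alignments(sample_b, include_secondary = include_secondary)
  if (!identical(a$contig_lengths, b$contig_lengths)) {
    stop("the two alignment files have different reference headers",
         call. = FALSE)
  }
  pa <- window_profiles(a$alignments, a$contig_lengths, window, min_mapq)
  pb <- window_profiles(b$alignments, b$contig_lengths, window, min_mapq)
  cmp <- compare_profiles(pa, pb)
  tibble::tibble(contig = cmp$contig, start = cmp$window_start,
                 end = cmp$window_end, alt_frac_a = cmp$fraction_a,
                 alt_frac_b = cmp$fraction_b, abs_diff = cmp$abs_difference,
                 rank = cmp$rank)
}
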