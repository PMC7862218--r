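# Independent oracles and fixture builders shared across tests.

# Reference-consuming span of a CIGAR string, by direct token parsing
# (independent of the package's GenomicAlignments-based path).
oracle_ref_span <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

# Per-base depth over a single contig by explicit looping.
oracle_depth <- function(obs, contig_length) {
  d <- numeric(contig_length)
  for (i in seq_len(nrow(obs))) {
    span <- oracle_ref_span(obs$cigar[i])
    if (span == 0) next
    from <- obs$pos[i] + 1
    to <- min(obs$pos[i] + span, contig_length)
    if (from <= to) d[from:to] <- d[from:to] + 1
  }
  d
}

# Binomial PMF for k = 0..n via the multiplicative recurrence
# pmf_{k+1} = pmf_k * (n-k)/(k+1) * p/q -- no dbinom, no log space.
oracle_binom_pmf <- function(n, p) {
  q <- 1 - p
  pmf <- numeric(n + 1)
  pmf[1] <- q^n
  for (k in 0:(n - 1)) {
    pmf[k + 2] <- pmf[k + 1] * (n - k) / (k + 1) * p / q
  }
  pmf
}

# Minimum-likelihood two-sided p-value from an enumerated PMF.
oracle_minlik_pvalue <- function(k, n, p) {
  pmf <- oracle_binom_pmf(n, p)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Minimal single-sample VCF with FORMAT DP:AD (AD = alt depths only).
write_toy_vcf <- function(path, calls) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=A,Type=Integer,Description=\"Alt depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "clone1", sep = "\t")
  )
  body <- vapply(seq_len(nrow(calls)), function(i) {
    paste(calls$contig[i], calls$pos[i], ".", calls$ref[i], calls$alt[i],
          ".", "PASS", ".", "DP:AD",
          sprintf("%d:%s", calls$dp[i], calls$ad[i]), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Random per-clone call set (tibble form) for property tests.
random_call_set <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      contig = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(10000, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      depth = sample(5:60, n, replace = TRUE),
      alt_frequency = round(stats::runif(n), 2)
    ) |> dplyr::distinct(contig, pos, ref, alt, .keep_all = TRUE)
  })
}
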