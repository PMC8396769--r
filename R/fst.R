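#' Weir-Cockerham FST variance components for two populations
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components of the
#' Weir & Cockerham (1984) estimator from per-variant genotype counts, using
#' the observed heterozygosity. Per-variant `fst = a / (a + b + c)`; negative
#' estimates are reported as computed.
#'
#' @param counts_pop1,counts_pop2 Data frames with columns `n_ref_hom`,
#'   `n_het`, `n_alt_hom` (one row per variant), e.g. from
#'   [allele_summary()].
#' @return Tibble with one row per variant: `a`, `b`, `c`, `fst`,
#'   `maf_pooled`, `n1`, `n2`, `defined` (`FALSE` where the variant is
#'   monomorphic across both populations or a population has no calls).
#' @export
wc_fst <- function(counts_pop1, counts_pop2) {
  c1 <- tibble::as_tibble(counts_pop1)
  c2 <- tibble::as_tibble(counts_pop2)
  assert_that(nrow(c1) == nrow(c2), "count tables must align by variant")
  n1 <- c1$n_ref_hom + c1$n_het + c1$n_alt_hom
  n2 <- c2$n_ref_hom + c2$n_het + c2$n_alt_hom
  p1 <- (c1$n_het + 2 * c1$n_alt_hom) / (2 * n1)
  p2 <- (c2$n_het + 2 * c2$n_alt_hom) / (2 * n2)
  h1 <- c1$n_het / n1
  h2 <- c2$n_het / n2
  r <- 2
  nbar <- (n1 + n2) / r
  pooled <- (n1 * p1 + n2 * p2) / (r * nbar)
  defined <- n1 > 0 & n2 > 0 & pooled > 0 & pooled < 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- pooled
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  out <- tibble::tibble(a = a, b = b, c = cc,
                        fst = ifelse(a + b + cc != 0, a / (a + b + cc),
                                     NA_real_),
                        maf_pooled = pmin(pooled, 1 - pooled),
                        n1 = n1, n2 = n2, defined = defined)
  out$a[!defined] <- NA_real_
  out$b[!defined] <- NA_real_
  out$c[!defined] <- NA_real_
  out$fst[!defined] <- NA_real_
  out
}

#' Per-variant Weir-Cockerham FST between two genotype panels
#'
#' @param G1,G2 [genotype_matrix()] objects over the same variants.
#' @return The [wc_fst()] tibble with `id`, `chrom`, `pos` prepended.
#' @export
wc_fst_genotypes <- function(G1, G2) {
  assert_that(identical(G1$variants$id, G2$variants$id),
              "panels must share the same variant set")
  s1 <- allele_summary(G1)
  s2 <- allele_summary(G2)
  dplyr::bind_cols(G1$variants[, c("id", "chrom", "pos")], wc_fst(s1, s2))
}

#' Windowed FST by the ratio of averages
#'
#' Aggregates per-variant Weir-Cockerham components over sliding windows as
#' `sum(a) / sum(a + b + c)` (ratio of averages), the recommended windowed
#' estimator; negative per-variant components are retained inside the sums.
#' Variants below the pooled-MAF cutoff are excluded before windowing.
#' Windows are defined either over a fixed number of consecutive variants
#' (default: 20-variant windows stepping by 5, a smoothing over adjacent
#' SNPs) or over physical distance in bp.
#'
#' @param per_variant Output of [wc_fst_genotypes()] (needs `pos`, `a`, `b`,
#'   `c`, `maf_pooled`, `defined`, and `chrom`).
#' @param window,step Window and step sizes, in `units`.
#' @param units `"variants"` or `"bp"`.
#' @param maf_min Pooled-MAF exclusion threshold.
#' @return Tibble: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_variants`, `value` (window FST), one row per non-empty window.
#' @export
windowed_fst <- function(per_variant, window = 20L, step = 5L,
                         units = c("variants", "bp"), maf_min = 0.05) {
  units <- match.arg(units)
  if (step > window) warn("step larger than window: windows will not overlap")
  d <- per_variant[per_variant$defined & per_variant$maf_pooled >= maf_min, ,
                   drop = FALSE]
  d <- d[order(d$pos), , drop = FALSE]
  if (nrow(d) == 0L)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_variants = integer(),
                          value = numeric()))
  win <- if (units == "variants") {
    starts <- seq(1L, nrow(d), by = step)
    purrr::map(starts, function(s) seq(s, min(s + window - 1L, nrow(d))))
  } else {
    starts <- seq(min(d$pos), max(d$pos), by = step)
    purrr::map(starts, function(s) which(d$pos >= s & d$pos <= s + window - 1L))
  }
  rows <- purrr::map_dfr(win, function(ii) {
    if (length(ii) == 0L) return(NULL)
    tibble::tibble(chrom = d$chrom[ii[1L]],
                   start = min(d$pos[ii]), end = max(d$pos[ii]),
                   n_variants = length(ii),
                   value = sum(d$a[ii]) / sum(d$a[ii] + d$b[ii] + d$c[ii]))
  })
  dplyr::distinct(rows, .data$start, .data$end, .keep_all = TRUE)
}

#' Empirical p-value of an observed scan statistic
#'
#' Rank-based empirical p against a genome-scan distribution:
#' `p = (1 + #(v > observed)) / (1 + N)` for the upper tail (the observed
#' value contributes the `1 +`, so the scan maximum gets `1 / (N + 1)` and a
#' value below the scan minimum gets 1), symmetric for the lower tail, and
#' twice the smaller tail (capped at 1) for two-sided. Invariant to monotone
#' transformations of the statistic.
#'
#' @param values Scan distribution (at least 100 values recommended; fewer
#'   triggers a warning). `NA`s dropped.
#' @param observed Observed value(s).
#' @param tail `"upper"`, `"lower"`, or `"two_sided"`.
#' @return Empirical p-value(s) in `(0, 1]`.
#' @export
empirical_p <- function(values, observed,
                        tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  if (length(values) < 100L)
    warn(sprintf("empirical_p on only %d scan values", length(values)))
  n <- length(values)
  vapply(observed, function(o) {
    if (is.na(o)) return(NA_real_)
    up <- (1 + sum(values > o)) / (1 + n)
    lo <- (1 + sum(values < o)) / (1 + n)
    switch(tail, upper = up, lower = lo,
           two_sided = min(1, 2 * min(up, lo)))
  }, numeric(1L))
}
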