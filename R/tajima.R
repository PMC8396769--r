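#' Tajima's (1989) normalization constants
#'
#' @param n Number of haplotypes (>= 3).
#' @return One-row tibble with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`,
#'   `e2`.
#' @export
tajima_constants <- function(n) {
  assert_that(n >= 3, "Tajima's D needs at least 3 haplotypes")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  tibble::tibble(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one haplotype window
#'
#' `D = (pi - S / a1) / sqrt(e1 S + e2 S (S - 1))`, where `S` is the number
#' of segregating sites in the window and `pi` the mean number of pairwise
#' differences. `S = 0` (or a zero variance term) gives an undefined-flagged
#' result.
#'
#' @param H A [haplotype_matrix()] restricted to the window, or a plain
#'   0/1 haplotype matrix.
#' @return One-row tibble: `n`, `S`, `pi`, `D`, `defined`, plus the
#'   normalization constants.
#' @export
tajimas_d <- function(H) {
  hap <- if (inherits(H, "haplotype_matrix")) H$hap else as.matrix(H)
  n <- nrow(hap)
  k <- colSums(hap)
  seg <- k > 0L & k < n
  S <- sum(seg)
  cst <- tajima_constants(n)
  # mean pairwise differences: per segregating site 2 k (n-k) / (n (n-1))
  pi <- sum(2 * k[seg] * (n - k[seg])) / (n * (n - 1))
  if (S == 0L) {
    return(dplyr::bind_cols(
      tibble::tibble(n = n, S = 0L, pi = 0, D = NA_real_, defined = FALSE),
      cst))
  }
  vr <- cst$e1 * S + cst$e2 * S * (S - 1)
  D <- if (vr > 0) (pi - S / cst$a1) / sqrt(vr) else NA_real_
  dplyr::bind_cols(
    tibble::tibble(n = n, S = S, pi = pi, D = D, defined = is.finite(D)),
    cst)
}

#' Windowed Tajima's D with empirical p-values
#'
#' Tiles the chromosome with non-overlapping windows of each requested size
#' (starting at position 1, last window partial) and computes Tajima's D per
#' window; the empirical p of each window is its rank within the scan
#' distribution of the same window size (two-sided by default; use the lower
#' tail to target sweeps, the upper for balancing selection).
#'
#' @param H A whole-chromosome [haplotype_matrix()].
#' @param sizes Window sizes in bp.
#' @param tail Passed to [empirical_p()].
#' @return Tibble: `window_size`, `chrom`, `start`, `end`, `n_variants`,
#'   `value` (D), `empirical_p`, `defined`.
#' @export
windowed_tajima <- function(H, sizes = c(100000L, 75000L, 50000L, 25000L),
                            tail = "two_sided") {
  stopifnot(inherits(H, "haplotype_matrix"))
  pos <- H$variants$pos
  chrom <- H$variants$chrom[1L]
  chr_len <- max(pos)
  purrr::map_dfr(sizes, function(w) {
    starts <- seq(1L, chr_len, by = w)
    rows <- purrr::map_dfr(starts, function(s) {
      e <- min(s + w - 1L, chr_len)
      ii <- which(pos >= s & pos <= e)
      if (length(ii) == 0L)
        return(tibble::tibble(window_size = w, chrom = chrom, start = s,
                              end = e, n_variants = 0L, value = NA_real_,
                              defined = FALSE))
      td <- tajimas_d(H$hap[, ii, drop = FALSE])
      tibble::tibble(window_size = w, chrom = chrom, start = s, end = e,
                     n_variants = length(ii), value = td$D,
                     defined = td$defined)
    })
    ok <- rows$defined
    rows$empirical_p <- NA_real_
    if (any(ok)) {
      suppressWarnings(
        rows$empirical_p[ok] <- empirical_p(rows$value[ok], rows$value[ok],
                                            tail = tail))
    }
    rows
  })
}
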