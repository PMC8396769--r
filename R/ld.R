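#' Pairwise linkage disequilibrium from haplotype frequencies
#'
#' @param p_ab Frequency of the haplotype carrying the alt allele at both
#'   loci.
#' @param p_a,p_b Alt-allele frequencies at the two loci.
#' @param n Number of haplotypes behind the estimate (carried through).
#' @return One-row tibble: `D = p_ab - p_a p_b`, `d_prime = D / Dmax`,
#'   `r2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`, `n_haplotypes`, `defined`.
#'   Monomorphic loci give an undefined-flagged row.
#' @export
ld_from_freqs <- function(p_ab, p_a, p_b, n = NA_integer_) {
  den <- p_a * (1 - p_a) * p_b * (1 - p_b)
  if (den <= 0) {
    return(tibble::tibble(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                          n_haplotypes = n, defined = FALSE))
  }
  D <- p_ab - p_a * p_b
  dmax <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
  else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  tibble::tibble(D = D,
                 d_prime = if (dmax > 0) D / dmax else 0,
                 r2 = D^2 / den,
                 n_haplotypes = n, defined = TRUE)
}

#' Pairwise LD between two loci of a phased panel
#'
#' Gametic disequilibrium computed from directly counted two-locus
#' haplotypes.
#'
#' @param H A [haplotype_matrix()].
#' @param i,j Variant ids or column indices of the two loci.
#' @return One-row tibble as in [ld_from_freqs()].
#' @export
ld_pair <- function(H, i, j) {
  stopifnot(inherits(H, "haplotype_matrix"))
  if (is.character(i)) i <- match(i, H$variants$id)
  if (is.character(j)) j <- match(j, H$variants$id)
  assert_that(!is.na(i) && !is.na(j), "unknown locus id")
  a <- H$hap[, i]; b <- H$hap[, j]
  n <- length(a)
  ld_from_freqs(mean(a == 1L & b == 1L), mean(a), mean(b), n)
}

#' Pairwise LD between two loci of unphased genotypes via two-locus EM
#'
#' Estimates the two-locus haplotype frequencies with [em_haplotypes()] and
#' derives D, D' and r2 from them; this is how r2 is obtained when only
#' unphased genotypes are available (e.g. for tag-SNP pruning).
#'
#' @param G A [genotype_matrix()].
#' @param i,j Variant ids or column indices.
#' @return One-row tibble as in [ld_from_freqs()].
#' @export
ld_pair_em <- function(G, i, j) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.character(i)) i <- match(i, G$variants$id)
  if (is.character(j)) j <- match(j, G$variants$id)
  assert_that(!is.na(i) && !is.na(j), "unknown locus id")
  d <- G$dosage[, c(i, j), drop = FALSE]
  ok <- stats::complete.cases(d)
  if (!any(ok)) {
    return(tibble::tibble(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                          n_haplotypes = 0L, defined = FALSE))
  }
  p_a <- mean(d[ok, 1L]) / 2
  p_b <- mean(d[ok, 2L]) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(tibble::tibble(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                          n_haplotypes = 2L * sum(ok), defined = FALSE))
  }
  fit <- em_haplotypes(G, loci = c(i, j))
  # haplotype carrying alt at both loci
  lab_ab <- paste0(G$variants$alt[i], G$variants$alt[j])
  p_ab <- unname(fit$p[match(lab_ab, fit$haplotypes)])
  if (is.na(p_ab)) p_ab <- 0
  ld_from_freqs(p_ab, sum(fit$p[fit$hap01[, 1L] == 1L]),
                sum(fit$p[fit$hap01[, 2L] == 1L]), 2L * sum(ok))
}

#' Pairwise r2 matrix over a set of loci
#'
#' @param x A [haplotype_matrix()] (direct counting) or [genotype_matrix()]
#'   (two-locus EM per pair).
#' @param loci Variant ids or indices (default: all).
#' @return A symmetric matrix of r2 values (diagonal 1, `NA` where
#'   undefined), with variant ids as dimnames.
#' @export
ld_r2_matrix <- function(x, loci = NULL) {
  v <- x$variants
  idx <- if (is.null(loci)) seq_len(nrow(v)) else {
    if (is.character(loci)) match(loci, v$id) else loci
  }
  m <- length(idx)
  out <- diag(1, m)
  dimnames(out) <- list(v$id[idx], v$id[idx])
  if (m < 2L) return(out)
  pair_fun <- if (inherits(x, "haplotype_matrix")) ld_pair else ld_pair_em
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      out[a, b] <- out[b, a] <- pair_fun(x, idx[a], idx[b])$r2
    }
  }
  out
}

#' Write a pairwise r2 matrix as square TSV
#'
#' @param r2 Matrix from [ld_r2_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r2, path) {
  utils::write.table(r2, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
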