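#' Patterson (EIGENSOFT-style) genotype normalization
#'
#' Centers each variant column by its mean dosage `mu_j` and scales by the
#' binomial standard deviation `sqrt((mu_j / 2)(1 - mu_j / 2))`. Missing
#' entries are set to 0 after centering (i.e. imputed at the mean);
#' monomorphic columns become all zero rather than dividing by zero.
#'
#' @param G A [genotype_matrix()] with no all-missing variant.
#' @return A numeric `n x m` matrix.
#' @export
patterson_normalize <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  assert_that(all(colSums(!is.na(d)) > 0), "all-missing variant in input")
  mu <- colMeans(d, na.rm = TRUE)
  sc <- sqrt((mu / 2) * (1 - mu / 2))
  x <- sweep(d, 2L, mu, `-`)
  x[is.na(x)] <- 0
  sc_safe <- ifelse(sc > 0, sc, 1)
  x <- sweep(x, 2L, sc_safe, `/`)
  x[, sc == 0] <- 0
  dimnames(x) <- dimnames(d)
  x
}

#' PCA with variant-space SNP weights
#'
#' Eigen-decomposition of the sample covariance of the Patterson-normalized
#' genotype matrix, via singular value decomposition. `snp_weights` are the
#' variant-space singular vectors (the per-SNP loadings on each principal
#' component, the quantity EIGENSOFT reports as snpweight); `pc_scores` are
#' the sample projections. Sign convention: the largest-|weight| entry of
#' each component is made positive.
#'
#' @param G A [genotype_matrix()] with at least 2 samples and 2 variants.
#' @param n_components Number of components to return (default
#'   `min(n, m)`).
#' @return Object of class `pca_weights`: list with `eigenvalues`
#'   (descending; variance explained, summing to the total variance of the
#'   normalized matrix when all components are kept), `pc_scores`
#'   (`n x n_components`), `snp_weights` (`m x n_components`, unit-norm
#'   columns), `variant_ids`, `samples`.
#' @export
pca_snp_weights <- function(G, n_components = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosage); m <- ncol(G$dosage)
  assert_that(n >= 2 && m >= 2, "need at least 2 samples and 2 variants")
  x <- patterson_normalize(G)
  full <- min(n, m)
  if (is.null(n_components)) n_components <- full
  n_components <- min(n_components, full)
  sv <- svd(x, nu = n_components, nv = n_components)
  assert_that(any(sv$d > 1e-12), "degenerate (rank 0) input")
  ev <- sv$d^2 / (n - 1)
  w <- sv$v
  u <- sv$u
  for (c_ in seq_len(n_components)) {
    top <- which.max(abs(w[, c_]))
    if (w[top, c_] < 0) { w[, c_] <- -w[, c_]; u[, c_] <- -u[, c_] }
  }
  scores <- u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(w) <- list(G$variants$id, paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(G$samples, paste0("PC", seq_len(n_components)))
  structure(list(eigenvalues = ev[seq_len(n_components)],
                 eigenvalues_all = ev,
                 pc_scores = scores, snp_weights = w,
                 variant_ids = G$variants$id, samples = G$samples),
            class = "pca_weights")
}

#' @export
print.pca_weights <- function(x, ...) {
  cat(sprintf("<pca_weights> %d components; top eigenvalues: %s\n",
              ncol(x$snp_weights),
              paste(signif(head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Tag-SNP selection from PC1 SNP weights
#'
#' Implements a PCA-guided tag-SNP shortlist over a gene region: variants
#' are ranked by `|PC1 weight|` (ties broken by ascending position), the top
#' `k` become candidate "top SNPs", and each is audited against four
#' auxiliary conditions: (maf) minor allele frequency above `maf_min`;
#' (ld) not in high LD (`r2 > r2_max`) with a higher-ranked kept SNP;
#' (annotation) located in a coding or regulatory region; (literature) prior
#' report in the phenotype's literature, consumed as a boolean input. SNPs
#' meeting at least `min_conditions` of the four are kept, subject to greedy
#' rank-ordered LD pruning so that no two kept SNPs exceed `r2_max`. In the
#' default `hard_maf` mode the MAF condition is additionally a hard filter.
#'
#' @param dec A `pca_weights` decomposition of `G`.
#' @param G The [genotype_matrix()] (for MAF and, when no phased panel is
#'   given, EM-based r2).
#' @param k Number of top-ranked SNPs to shortlist (capped at the number of
#'   variants, with a warning).
#' @param maf_min MAF threshold.
#' @param r2_max LD pruning threshold.
#' @param literature_flags Optional named logical vector (variant id ->
#'   prior-report flag).
#' @param annotations Optional named character vector overriding
#'   `G$variants$annotation`.
#' @param min_conditions Minimum auxiliary conditions met (default 3).
#' @param hard_maf Require the MAF condition unconditionally (default) in
#'   addition to the `min_conditions` rule.
#' @param H Optional [haplotype_matrix()] for direct r2 (otherwise two-locus
#'   EM on `G`).
#' @return Object of class `tag_selection`: list with `kept` (ids), `audit`
#'   (tibble: `id`, `rank`, `weight`, per-condition logicals, `n_met`,
#'   `kept`, `reason`), `r2` (matrix over the top SNPs), and the thresholds
#'   used.
#' @export
select_tag_snps <- function(dec, G, k = 30L, maf_min = 0.10, r2_max = 0.8,
                            literature_flags = NULL, annotations = NULL,
                            min_conditions = 3L, hard_maf = TRUE, H = NULL) {
  stopifnot(inherits(dec, "pca_weights"), inherits(G, "genotype_matrix"))
  assert_that(identical(dec$variant_ids, G$variants$id),
              "decomposition and genotypes must share the variant set")
  w1 <- abs(dec$snp_weights[, 1L])
  # ties (e.g. duplicated variants) resolved by ascending position; weights
  # are rounded so floating-point jitter cannot reorder exact ties
  ord <- order(-round(w1, 10L), G$variants$pos)
  if (k > length(ord)) {
    warn(sprintf("k = %d exceeds the %d variants; using all", k, length(ord)))
    k <- length(ord)
  }
  top <- ord[seq_len(k)]
  ids <- G$variants$id[top]

  summ <- allele_summary(subset_genotypes(G, variants = ids))
  cond_maf <- !is.na(summ$maf) & summ$maf > maf_min
  ann <- G$variants$annotation[top]
  if (!is.null(annotations)) ann <- unname(annotations[ids])
  cond_ann <- !is.na(ann) & ann %in% c("exonic", "regulatory")
  lit <- if (is.null(literature_flags)) rep(FALSE, k)
  else isTRUE_vec(literature_flags[ids])

  r2 <- if (!is.null(H)) ld_r2_matrix(H, ids) else ld_r2_matrix(G, ids)

  kept <- character()
  audit <- vector("list", k)
  for (i in seq_len(k)) {
    high_ld <- length(kept) > 0L &&
      any(r2[ids[i], kept] > r2_max, na.rm = TRUE)
    cond_ld <- !high_ld
    n_met <- cond_maf[i] + cond_ld + cond_ann[i] + lit[i]
    pass <- n_met >= min_conditions && (!hard_maf || cond_maf[i])
    keep_it <- pass && cond_ld
    reason <- if (keep_it) NA_character_
    else if (!pass && hard_maf && !cond_maf[i]) "maf"
    else if (!pass) "conditions"
    else "ld_prune"
    if (keep_it) kept <- c(kept, ids[i])
    audit[[i]] <- tibble::tibble(
      id = ids[i], rank = i, weight = w1[top[i]],
      cond_maf = cond_maf[i], cond_ld = cond_ld,
      cond_annotation = cond_ann[i], cond_literature = lit[i],
      n_met = as.integer(n_met), kept = keep_it, reason = reason)
  }
  structure(list(kept = kept, audit = dplyr::bind_rows(audit), r2 = r2,
                 k = k, maf_min = maf_min, r2_max = r2_max,
                 min_conditions = min_conditions, hard_maf = hard_maf),
            class = "tag_selection")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.tag_selection <- function(x, ...) {
  cat(sprintf("<tag_selection> kept %d of %d top SNPs: %s\n",
              length(x$kept), x$k, paste(x$kept, collapse = ", ")))
  invisible(x)
}

#' @method tidy tag_selection
#' @export
tidy.tag_selection <- function(x, ...) x$audit
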