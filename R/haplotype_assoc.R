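#' Haplotype case-control association on EM expected dosages
#'
#' Tests each haplotype against a chosen reference haplotype using the
#' posterior expected haplotype dosages of a [em_haplotypes()] fit,
#' restricted to carriers of the target or reference haplotype. Two
#' contrasts are available:
#'
#' * `"allelic"` (default): each individual contributes one pseudo-observation
#'   per haplotype copy, weighted by its expected dosage of the target
#'   (coded 1) and of the reference (coded 0); with no phase ambiguity and no
#'   covariates this is exactly the allelic 2x2 cross-ratio, the way crude
#'   haplotype odds ratios are reported against a reference haplotype.
#' * `"dosage"`: logistic regression of status on the target haplotype's
#'   expected dosage (haplo.stats-style); this is the consistent estimator of
#'   a per-copy log-OR generative effect.
#'
#' Haplotypes rarer than `report_min` in the fit are pooled into a `rare`
#' pseudo-haplotype before testing. BH-FDR is applied across the tested
#' haplotypes.
#'
#' @param fit A `haplotype_fit` from [em_haplotypes()].
#' @param samples Sample metadata aligned with the fit's samples (`sample_id`,
#'   `status`, plus covariate columns).
#' @param reference_haplotype Reference haplotype label; must be carried in
#'   both cases and controls.
#' @param covariates Character vector of covariate column names (or `NULL`).
#' @param contrast `"allelic"` or `"dosage"`.
#' @param report_min Pooling threshold for rare haplotypes (default 5%).
#' @return Tibble of class `assoc_scan`: one row per non-reference haplotype
#'   with `id`, `model`, `contrast`, `n_used`, `beta`, `se`, `or`, `or_l95`,
#'   `or_u95`, `p`, `q`, `covariates`, `note`.
#' @export
haplotype_assoc <- function(fit, samples, reference_haplotype,
                            covariates = NULL,
                            contrast = c("allelic", "dosage"),
                            report_min = 0.05) {
  stopifnot(inherits(fit, "haplotype_fit"))
  contrast <- match.arg(contrast)
  assert_that(reference_haplotype %in% fit$haplotypes,
              sprintf("reference haplotype '%s' not in fit",
                      reference_haplotype))
  samples <- samples[match(fit$samples, samples$sample_id), , drop = FALSE]
  y <- as.numeric(samples$status == "case")

  dos <- fit$dosage
  p <- fit$p
  rare <- p < report_min & fit$haplotypes != reference_haplotype
  if (any(rare)) {
    pooled <- rowSums(dos[, rare, drop = FALSE])
    dos <- cbind(dos[, !rare, drop = FALSE], rare = pooled)
    labels <- c(fit$haplotypes[!rare], "rare")
  } else {
    labels <- fit$haplotypes
  }
  ref <- dos[, match(reference_haplotype, labels)]
  ok0 <- !is.na(ref) & !is.na(y)
  assert_that(sum(ref[ok0 & y == 1], na.rm = TRUE) > 0 &&
                sum(ref[ok0 & y == 0], na.rm = TRUE) > 0,
              "reference haplotype absent in cases or controls")
  Xc <- covariate_matrix(samples, covariates)
  covs <- paste(covariates, collapse = ",")

  targets <- setdiff(labels, reference_haplotype)
  res <- purrr::map_dfr(targets, function(h) {
    dh <- dos[, match(h, labels)]
    use <- ok0 & (dh + ref) > 0
    if (!is.null(Xc)) use <- use & stats::complete.cases(Xc)
    note <- NA_character_
    est <- tryCatch({
      if (contrast == "allelic") {
        # one weighted pseudo-observation per target/reference copy
        idx <- which(use)
        X <- cbind(haplotype = c(rep(1, length(idx)), rep(0, length(idx))))
        if (!is.null(Xc)) X <- cbind(X, rbind(Xc[idx, , drop = FALSE],
                                              Xc[idx, , drop = FALSE]))
        w <- c(dh[idx], ref[idx])
        keepw <- w > 0
        logistic_fit(c(y[idx], y[idx])[keepw], X[keepw, , drop = FALSE],
                     weights = w[keepw])
      } else {
        X <- cbind(haplotype = dh[use])
        if (!is.null(Xc)) X <- cbind(X, Xc[use, , drop = FALSE])
        logistic_fit(y[use], X)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(est)) {
      return(tibble::tibble(id = h, model = "haplotype", contrast = contrast,
                            n_used = sum(use), beta = NA_real_, se = NA_real_,
                            or = NA_real_, or_l95 = NA_real_,
                            or_u95 = NA_real_, p = NA_real_, q = NA_real_,
                            covariates = covs, note = est))
    }
    r <- est[est$term == "haplotype", ]
    tibble::tibble(id = h, model = "haplotype", contrast = contrast,
                   n_used = sum(use), beta = r$beta, se = r$se,
                   or = exp(r$beta),
                   or_l95 = exp(r$beta - 1.96 * r$se),
                   or_u95 = exp(r$beta + 1.96 * r$se),
                   p = r$p, q = NA_real_, covariates = covs,
                   note = NA_character_)
  })
  res$q <- bh_fdr(res$p)
  class(res) <- c("assoc_scan", class(res))
  res
}

#' Crude haplotype odds ratio from published-style frequency tables
#'
#' Computes the crude odds ratio of a target haplotype against a reference
#' haplotype from group haplotype frequencies and sample sizes, by
#' reconstructing the implied allele-count 2x2 table (counts
#' `2 n x frequency`) with a Woolf confidence interval. This is the
#' arithmetic behind crude haplotype ORs quoted from frequency tables.
#'
#' @param freq_case,freq_ctrl Length-2 vectors: frequency of the target and
#'   of the reference haplotype in cases / controls.
#' @param n_case,n_ctrl Numbers of individuals per group.
#' @return One-row tibble: `or`, `beta`, `se`, `or_l95`, `or_u95`, `p`.
#' @export
crude_haplotype_or <- function(freq_case, freq_ctrl, n_case, n_ctrl) {
  a <- 2 * n_case * freq_case[1]   # target copies in cases
  b <- 2 * n_case * freq_case[2]   # reference copies in cases
  c_ <- 2 * n_ctrl * freq_ctrl[1]
  d <- 2 * n_ctrl * freq_ctrl[2]
  assert_that(all(c(a, b, c_, d) > 0),
              "all four haplotype-count cells must be positive")
  beta <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble::tibble(or = exp(beta), beta = beta, se = se,
                 or_l95 = exp(beta - 1.96 * se),
                 or_u95 = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)))
}
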