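#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts against
#' Hardy-Weinberg expectations computed from the sample allele frequency.
#'
#' @param n_ref_hom,n_het,n_alt_hom Genotype counts.
#' @return One-row tibble with `chi2`, `p`, `n`, and `defined` (`FALSE`, with
#'   `p = 1` by convention, for monomorphic counts).
#' @export
hwe_chi2 <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  assert_that(n > 0, "hwe_chi2 needs at least one genotype")
  p <- (n_het + 2 * n_alt_hom) / (2 * n)
  if (p == 0 || p == 1) {
    return(tibble::tibble(chi2 = 0, p = 1, n = n, defined = FALSE))
  }
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n_ref_hom, n_het, n_alt_hom)
  chi2 <- sum((o - e)^2 / e)
  tibble::tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 n = n, defined = TRUE)
}

#' Genotype and sample quality control
#'
#' Applies the standard pre-association filters: samples with missing or
#' inconsistent metadata are dropped; variants with call rate at or below
#' `call_rate_min` in cases or in controls are dropped; variants violating
#' Hardy-Weinberg equilibrium in controls (chi-square p < `hwe_alpha`) are
#' flagged and, by default, dropped. Every exclusion is reported with its
#' reason.
#'
#' @param G A [genotype_matrix()].
#' @param samples Sample metadata (needs `sample_id`, `status`; `sex`/`age`
#'   checked for missingness when present).
#' @param call_rate_min Minimum (exclusive) per-group call rate.
#' @param hwe_alpha HWE significance threshold applied in controls.
#' @param drop_hwe Drop HWE-violating variants (`TRUE`) or only flag them.
#' @return List with `genotypes` (filtered [genotype_matrix()]), `samples`
#'   (filtered metadata), and `report` (tibble: `item`, `type`, `reason`,
#'   `detail`).
#' @export
qc_filter <- function(G, samples, call_rate_min = 0.90, hwe_alpha = 0.05,
                      drop_hwe = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  report <- tibble::tibble(item = character(), type = character(),
                           reason = character(), detail = character())
  need <- intersect(c("status", "sex", "age"), names(samples))
  bad_meta <- !samples$sample_id %in% G$samples |
    Reduce(`|`, lapply(need, function(cl) is.na(samples[[cl]])), FALSE) |
    !samples$status %in% c("case", "control")
  if (any(bad_meta)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      item = samples$sample_id[bad_meta], type = "sample",
      reason = "metadata", detail = "missing or discordant metadata"))
  }
  samples <- samples[!bad_meta, , drop = FALSE]
  G <- subset_genotypes(G, samples = samples$sample_id)
  is_case <- samples$status == "case"
  if (!any(!is_case)) warn("no controls available; HWE step skipped")

  drop_var <- rep(FALSE, nrow(G$variants))
  for (grp in c("case", "control")) {
    idx <- if (grp == "case") is_case else !is_case
    if (!any(idx)) next
    cr <- colMeans(!is.na(G$dosage[idx, , drop = FALSE]))
    bad <- cr <= call_rate_min
    if (any(bad)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        item = G$variants$id[bad], type = "variant", reason = "call_rate",
        detail = sprintf("call rate %.3f in %ss", cr[bad], grp)))
      drop_var <- drop_var | bad
    }
  }
  if (any(!is_case)) {
    ctrl <- allele_summary(subset_genotypes(G, samples = samples$sample_id[!is_case]))
    hwe <- purrr::pmap_dfr(
      list(ctrl$n_ref_hom, ctrl$n_het, ctrl$n_alt_hom),
      function(a, b, c) {
        if (a + b + c == 0) tibble::tibble(chi2 = NA, p = 1, n = 0,
                                           defined = FALSE)
        else hwe_chi2(a, b, c)
      })
    viol <- hwe$defined & hwe$p < hwe_alpha & !drop_var
    if (any(viol)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        item = G$variants$id[viol], type = "variant", reason = "hwe",
        detail = sprintf("control HWE p = %.3g", hwe$p[viol])))
      if (drop_hwe) drop_var <- drop_var | viol
    }
  }
  keep <- G$variants$id[!drop_var]
  list(genotypes = subset_genotypes(G, variants = keep),
       samples = samples, report = report)
}

#' Logistic regression with Wald tests
#'
#' Maximum-likelihood logistic regression (via `stats::glm` with a tight
#' convergence tolerance), with explicit guards for the failure modes that
#' matter in sparse genetic tables: a rank-deficient design errors, and
#' quasi-separation (any |coefficient| diverging past 15 on the logit scale)
#' errors naming the offending column. An intercept is always included.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param X Design matrix or data frame of predictors (no intercept column).
#' @param weights Optional non-negative case weights.
#' @return Tibble with one row per coefficient (including the intercept):
#'   `term`, `beta`, `se`, `z`, `p`.
#' @export
logistic_fit <- function(y, X, weights = NULL) {
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "y must be binary 0/1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(.y = y, X, check.names = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    abort("design matrix is rank deficient")
  fit <- suppressWarnings(glm(
    .y ~ ., data = dat, family = binomial(),
    weights = weights,
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  b <- coef(fit)
  if (any(!is.finite(b)) || any(abs(b) > 15)) {
    bad <- names(b)[which(!is.finite(b) | abs(b) > 15)[1L]]
    abort(sprintf("separation detected: coefficient '%s' diverged", bad))
  }
  se <- sqrt(diag(vcov(fit)))
  tibble::tibble(term = c("(Intercept)", colnames(X)),
                 beta = unname(b), se = unname(se),
                 z = unname(b / se),
                 p = unname(2 * pnorm(-abs(b / se))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, passed through).
#' @return Vector of BH-adjusted values (q-values), same order as `p`.
#' @export
bh_fdr <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Automatic covariate selection for case-control adjustment
#'
#' Selects the covariates that differ between cases and controls at
#' `alpha`: chi-square tests for categorical covariates, Wilcoxon rank-sum
#' for numeric ones.
#'
#' @param samples Sample metadata with a `status` column.
#' @param candidates Covariate column names to consider.
#' @param alpha Selection threshold.
#' @return Tibble with `covariate`, `test`, `p`, `selected`.
#' @export
select_covariates <- function(samples,
                              candidates = intersect(
                                c("sex", "age", "ancestry_afr",
                                  "ancestry_eur"), names(samples)),
                              alpha = 0.05) {
  is_case <- samples$status == "case"
  purrr::map_dfr(candidates, function(cl) {
    x <- samples[[cl]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      p <- stats::wilcox.test(x[ok & is_case], x[ok & !is_case],
                              exact = FALSE)$p.value
      test <- "wilcoxon"
    } else {
      tb <- table(x[ok], is_case[ok])
      p <- if (nrow(tb) < 2L) 1 else
        suppressWarnings(stats::chisq.test(tb, correct = FALSE)$p.value)
      test <- "chisq"
    }
    tibble::tibble(covariate = cl, test = test, p = p, selected = p < alpha)
  })
}

model_codes <- function(dos, maf_flip) {
  # dos counts of minor allele (flip applied upstream)
  list(
    codominant_het = as.numeric(dos == 1L),
    codominant_hom = as.numeric(dos == 2L),
    dominant = as.numeric(dos >= 1L),
    recessive = as.numeric(dos == 2L),
    carrier = as.numeric(dos >= 1L)
  )
}

#' Per-variant genetic-model association scan
#'
#' Fits covariate-adjusted logistic regressions of case-control status on
#' each variant under the requested genetic models. The minor allele is
#' defined from the pooled sample. Codominant fits two indicator contrasts
#' (heterozygote and minor-homozygote vs major-homozygote) in one model;
#' dominant, recessive, and carrier fit one indicator; the allelic model
#' expands each individual into two allele-level observations. Covariates
#' default to those selected by [select_covariates()]; BH-FDR is applied per
#' model across variants (one family per scan invocation and model, the
#' `fdr_family` option pools across models instead).
#'
#' @param G QC'd [genotype_matrix()].
#' @param samples Sample metadata aligned with `G` (`sample_id`, `status`,
#'   plus any covariate columns).
#' @param models Subset of `c("codominant", "dominant", "recessive",
#'   "allelic", "carrier")`.
#' @param covariates `"auto"` (default), a character vector of column names,
#'   or `NULL` for crude models.
#' @param fdr_family `"per_model"` (default) or `"pooled"`.
#' @return Tibble of class `assoc_scan`: one row per variant x contrast with
#'   `id`, `model`, `contrast`, `n_used`, `beta`, `se`, `or`, `or_l95`,
#'   `or_u95`, `p`, `q`, `covariates`, `note` (`NA` beta rows carry the
#'   reason, e.g. an empty genotype class).
#' @export
model_scan <- function(G, samples,
                       models = c("codominant", "dominant", "recessive",
                                  "allelic", "carrier"),
                       covariates = "auto",
                       fdr_family = c("per_model", "pooled")) {
  stopifnot(inherits(G, "genotype_matrix"))
  fdr_family <- match.arg(fdr_family)
  models <- match.arg(models, several.ok = TRUE)
  samples <- samples[match(G$samples, samples$sample_id), , drop = FALSE]
  y <- as.numeric(samples$status == "case")

  if (identical(covariates, "auto")) {
    sel <- select_covariates(samples)
    covariates <- sel$covariate[sel$selected]
  }
  Xc <- covariate_matrix(samples, covariates)

  summ <- allele_summary(G)
  res <- purrr::map_dfr(seq_len(nrow(G$variants)), function(j) {
    dos <- G$dosage[, j]
    flip <- !is.na(summ$alt_freq[j]) && summ$alt_freq[j] > 0.5
    mdos <- if (flip) 2L - dos else dos           # minor-allele dosage
    purrr::map_dfr(models, function(mod)
      fit_one_model(G$variants$id[j], mod, y, mdos, Xc, covariates))
  })
  res$q <- NA_real_
  if (fdr_family == "per_model") {
    for (m in unique(res$model)) {
      i <- res$model == m
      res$q[i] <- bh_fdr(res$p[i])
    }
  } else {
    res$q <- bh_fdr(res$p)
  }
  class(res) <- c("assoc_scan", class(res))
  res
}

covariate_matrix <- function(samples, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- lapply(covariates, function(cl) {
    x <- samples[[cl]]
    if (is.numeric(x)) x else as.numeric(factor(x)) - 1
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

fit_one_model <- function(id, mod, y, mdos, Xc, covariates) {
  ok <- !is.na(mdos) & !is.na(y)
  if (!is.null(Xc)) ok <- ok & stats::complete.cases(Xc)
  covs <- paste(covariates, collapse = ",")
  empty_row <- function(contrast, note) tibble::tibble(
    id = id, model = mod, contrast = contrast, n_used = sum(ok),
    beta = NA_real_, se = NA_real_, or = NA_real_, or_l95 = NA_real_,
    or_u95 = NA_real_, p = NA_real_, q = NA_real_, covariates = covs,
    note = note)
  d <- mdos[ok]; yy <- y[ok]
  Xk <- if (is.null(Xc)) NULL else Xc[ok, , drop = FALSE]

  wrap_fit <- function(X, terms, contrasts, w = NULL, yv = yy) {
    ft <- tryCatch(logistic_fit(yv, X, weights = w),
                   error = function(e) conditionMessage(e))
    if (is.character(ft)) {
      return(purrr::map_dfr(contrasts, empty_row, note = ft))
    }
    purrr::map2_dfr(terms, contrasts, function(tm, ctr) {
      r <- ft[ft$term == tm, ]
      tibble::tibble(id = id, model = mod, contrast = ctr,
                     n_used = length(yv),
                     beta = r$beta, se = r$se, or = exp(r$beta),
                     or_l95 = exp(r$beta - 1.96 * r$se),
                     or_u95 = exp(r$beta + 1.96 * r$se),
                     p = r$p, q = NA_real_, covariates = covs,
                     note = NA_character_)
    })
  }

  if (mod == "codominant") {
    if (!all(c(0L, 1L, 2L) %in% d))
      return(dplyr::bind_rows(empty_row("het_vs_major", "empty genotype class"),
                              empty_row("hom_vs_major", "empty genotype class")))
    X <- cbind(het = as.numeric(d == 1L), hom = as.numeric(d == 2L), Xk)
    return(wrap_fit(X, c("het", "hom"), c("het_vs_major", "hom_vs_major")))
  }
  if (mod %in% c("dominant", "carrier")) {
    x <- as.numeric(d >= 1L)
    if (length(unique(x)) < 2L) return(empty_row(mod, "empty genotype class"))
    X <- cbind(x, Xk)
    colnames(X)[1L] <- mod
    return(wrap_fit(X, mod, mod))
  }
  if (mod == "recessive") {
    x <- as.numeric(d == 2L)
    if (length(unique(x)) < 2L) return(empty_row(mod, "empty genotype class"))
    return(wrap_fit(cbind(recessive = x, Xk), "recessive", "recessive"))
  }
  # allelic: per-allele expansion, two observations per individual
  a <- c(as.numeric(d >= 1L), as.numeric(d == 2L))
  if (length(unique(a)) < 2L) return(empty_row("allelic", "monomorphic"))
  Xa <- cbind(allelic = a, if (!is.null(Xk)) rbind(Xk, Xk))
  wrap_fit(Xa, "allelic", "allelic", yv = c(yy, yy))
}
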