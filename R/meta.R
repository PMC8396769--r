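#' DerSimonian-Laird random-effects meta-analysis of log odds ratios
#'
#' Pools per-site effect estimates with inverse-variance weights inflated by
#' the method-of-moments between-site variance: `Q` is the fixed-effect
#' heterogeneity statistic, `tau2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`, and the pooled estimate uses weights
#' `1 / (se^2 + tau2)`. Identical inputs across sites give `tau2 = 0` and
#' return the common estimate.
#'
#' @param site_results Data frame with columns `beta` and `se` (one row per
#'   site); an optional `site` column labels the sites.
#' @return Object of class `meta_result`: list with `beta`, `se`, `or`,
#'   `or_l95`, `or_u95`, `p`, `tau2`, `q_stat`, `df`, `i2`, `sites` (the
#'   input tibble), `method`.
#' @export
meta_random_effects <- function(site_results) {
  sr <- tibble::as_tibble(site_results)
  assert_that(all(c("beta", "se") %in% names(sr)),
              "site_results needs beta and se columns")
  sr <- sr[is.finite(sr$beta) & is.finite(sr$se) & sr$se > 0, , drop = FALSE]
  k <- nrow(sr)
  assert_that(k >= 1L, "no sites with finite estimates")
  if (!"site" %in% names(sr)) sr$site <- paste0("site", seq_len(k))
  if (k == 1L) {
    warn("single site: returning its estimate unpooled")
    b <- sr$beta[1]; s <- sr$se[1]
    return(new_meta_result(b, s, tau2 = 0, q_stat = 0, df = 0, sr))
  }
  w <- 1 / sr$se^2
  b_fe <- sum(w * sr$beta) / sum(w)
  q_stat <- sum(w * (sr$beta - b_fe)^2)
  df <- k - 1L
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q_stat - df) / cc)
  w_re <- 1 / (sr$se^2 + tau2)
  b <- sum(w_re * sr$beta) / sum(w_re)
  s <- sqrt(1 / sum(w_re))
  new_meta_result(b, s, tau2, q_stat, df, sr)
}

new_meta_result <- function(beta, se, tau2, q_stat, df, sites) {
  i2 <- if (q_stat > 0 && df > 0) max(0, (q_stat - df) / q_stat) else 0
  structure(list(
    beta = beta, se = se, or = exp(beta),
    or_l95 = exp(beta - 1.96 * se), or_u95 = exp(beta + 1.96 * se),
    p = 2 * pnorm(-abs(beta / se)),
    tau2 = tau2, q_stat = q_stat, df = df, i2 = i2,
    sites = sites, method = "DerSimonian-Laird"
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s: OR %.3f (%.3f-%.3f), p = %.3g, tau2 = %.4f over %d sites\n",
    x$method, x$or, x$or_l95, x$or_u95, x$p, x$tau2, nrow(x$sites)))
  invisible(x)
}

#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(term = "pooled", beta = x$beta, se = x$se, or = x$or,
                 or_l95 = x$or_l95, or_u95 = x$or_u95, p = x$p)
}

#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(tau2 = x$tau2, q_stat = x$q_stat, df = x$df, i2 = x$i2,
                 n_sites = nrow(x$sites), method = x$method)
}
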