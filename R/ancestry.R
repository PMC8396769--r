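#' Supervised maximum-likelihood admixture estimation
#'
#' Estimates each individual's admixture proportions `q` (length K) from an
#' ancestry-informative-marker panel, holding the ancestral-population allele
#' frequencies `f_kj` fixed. The per-individual log-likelihood
#' `sum_j [ g_j log(sum_k q_k f_kj) + (2 - g_j) log(sum_k q_k (1 - f_kj)) ]`
#' is maximized by EM: the responsibility of ancestry `k` for each allele
#' copy is proportional to `q_k f_kj` (alt copies) or `q_k (1 - f_kj)` (ref
#' copies), and `q` is updated as the mean responsibility. This is the
#' fixed-frequency special case of supervised model-based clustering: the
#' estimand matches a supervised STRUCTURE/ADMIXTURE run, without MCMC.
#'
#' Missing genotypes are skipped; individuals with all AIMs missing get an
#' undefined (all-`NA`) estimate, flagged in the output.
#'
#' @param G_aims [genotype_matrix()] of the AIM panel.
#' @param pool `ancestral_pool` with the fixed `K x J` frequencies (markers
#'   must line up with the columns of `G_aims`).
#' @param tol Convergence tolerance on `max |delta q|`.
#' @param max_iter Maximum EM iterations per individual.
#'
#' @return An object of class `ancestry_fit`: list with `q` (`n x K` matrix,
#'   rows summing to 1), `loglik`, `n_iter`, `converged`, `defined` (FALSE
#'   where every AIM was missing), `labels`, `samples`.
#' @export
supervised_admixture <- function(G_aims, pool, tol = 1e-7, max_iter = 5000L) {
  stopifnot(inherits(G_aims, "genotype_matrix"),
            inherits(pool, "ancestral_pool"))
  f <- pool$freqs
  assert_that(ncol(f) == ncol(G_aims$dosage),
              "pool must have one frequency column per AIM")
  K <- nrow(f)
  n <- length(G_aims$samples)
  q_out <- matrix(NA_real_, n, K, dimnames = list(G_aims$samples, pool$labels))
  ll <- rep(NA_real_, n)
  iters <- integer(n)
  conv <- rep(NA, n)
  for (i in seq_len(n)) {
    g <- G_aims$dosage[i, ]
    use <- !is.na(g)
    if (!any(use)) next
    fit <- admixture_em_one(g[use], f[, use, drop = FALSE], tol, max_iter)
    q_out[i, ] <- fit$q
    ll[i] <- fit$loglik
    iters[i] <- fit$n_iter
    conv[i] <- fit$converged
  }
  structure(list(q = q_out, loglik = ll, n_iter = iters, converged = conv,
                 defined = !is.na(ll), labels = pool$labels,
                 samples = G_aims$samples),
            class = "ancestry_fit")
}

# EM for one individual; g = dosages at the used AIMs, f = K x J frequencies
admixture_em_one <- function(g, f, tol, max_iter) {
  K <- nrow(f)
  if (K == 1L) {
    ll <- sum(g * log(f[1L, ]) + (2 - g) * log(1 - f[1L, ]))
    return(list(q = 1, loglik = ll, n_iter = 0L, converged = TRUE))
  }
  q <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    pa <- as.vector(crossprod(f, q))        # P(alt copy) per marker
    pr <- as.vector(crossprod(1 - f, q))    # P(ref copy) per marker
    # responsibilities: K x J, weighted by copy counts g and 2 - g
    r_alt <- f * q / rep(pa, each = K)
    r_ref <- (1 - f) * q / rep(pr, each = K)
    num <- as.vector(r_alt %*% g + r_ref %*% (2 - g))
    q_new <- num / sum(num)
    if (max(abs(q_new - q)) < tol) {
      q <- q_new
      return(list(q = q, loglik = admix_loglik(g, f, q), n_iter = it,
                  converged = TRUE))
    }
    q <- q_new
  }
  list(q = q, loglik = admix_loglik(g, f, q), n_iter = max_iter,
       converged = FALSE)
}

admix_loglik <- function(g, f, q) {
  pa <- as.vector(crossprod(f, q))
  pr <- as.vector(crossprod(1 - f, q))
  sum(g * log(pa) + (2 - g) * log(pr))
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("<ancestry_fit> %d individuals, K = %d (%s)\n",
              length(x$samples), ncol(x$q), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Tidy an admixture fit
#'
#' @param x An `ancestry_fit`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, one proportion column per ancestral
#'   population, `loglik`, and `converged`.
#' @method tidy ancestry_fit
#' @export
tidy.ancestry_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$samples),
    tibble::as_tibble(x$q),
    tibble::tibble(loglik = x$loglik, converged = x$converged)
  )
}

#' @method glance ancestry_fit
#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble::tibble(n = length(x$samples), k = ncol(x$q),
                 n_undefined = sum(!x$defined),
                 mean_iter = mean(x$n_iter[x$defined]))
}

#' Ancestry covariate columns for association models
#'
#' Returns K - 1 admixture proportions (dropping the last population) to
#' avoid the sum-to-one collinearity when used as regression covariates.
#'
#' @param x An `ancestry_fit`.
#' @return `n x (K-1)` matrix.
#' @export
ancestry_covariates <- function(x) {
  stopifnot(inherits(x, "ancestry_fit"))
  x$q[, -ncol(x$q), drop = FALSE]
}
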