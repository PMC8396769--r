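#' Simulate structured ancestral allele-frequency pools
#'
#' Draws per-population allele frequencies around shared base frequencies
#' under the Balding-Nichols model: for base frequency `p` and divergence
#' `F`, population frequencies are `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so their
#' mean is `p` and variance `F p (1-p)`. Draws are clamped to `[0.01, 0.99]`
#' to avoid degenerate fixed markers.
#'
#' @param p Base (ancestral) allele frequencies, each in (0, 1); length `J`.
#' @param F_k Divergence parameter per population, each in (0, 1); length `K`.
#' @param seed Optional integer seed (draws are reproducible given it).
#' @param labels Optional population labels (default `pop1..popK`).
#'
#' @return An object of class `ancestral_pool`: list with `K`, `freqs`
#'   (`K x J` matrix), `F_k`, and `base_freq`.
#' @export
balding_nichols_pools <- function(p, F_k, seed = NULL, labels = NULL) {
  assert_that(all(p > 0 & p < 1), "base frequencies must lie in (0, 1)")
  assert_that(all(F_k > 0 & F_k < 1), "divergence F must lie in (0, 1)")
  K <- length(F_k)
  J <- length(p)
  f <- with_seed(seed, {
    t(vapply(F_k, function(F) {
      lam <- (1 - F) / F
      rbeta(J, p * lam, (1 - p) * lam)
    }, numeric(J)))
  })
  f <- pmin(pmax(f, 0.01), 0.99)
  if (is.null(labels)) labels <- paste0("pop", seq_len(K))
  rownames(f) <- labels
  structure(list(K = K, freqs = f, F_k = F_k, base_freq = p,
                 labels = labels),
            class = "ancestral_pool")
}

#' Build an ancestral pool from explicit frequencies
#'
#' @param freqs `K x J` matrix of allele frequencies in (0, 1), one row per
#'   ancestral population.
#' @param labels Optional population labels.
#' @return An `ancestral_pool` object (see [balding_nichols_pools()]).
#' @export
ancestral_pool <- function(freqs, labels = rownames(freqs)) {
  freqs <- as.matrix(freqs)
  assert_that(all(freqs > 0 & freqs < 1),
              "pool frequencies must lie in (0, 1)")
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(freqs)))
  rownames(freqs) <- labels
  structure(list(K = nrow(freqs), freqs = freqs,
                 F_k = rep(NA_real_, nrow(freqs)),
                 base_freq = colMeans(freqs), labels = labels),
            class = "ancestral_pool")
}

#' @export
print.ancestral_pool <- function(x, ...) {
  cat(sprintf("<ancestral_pool> K = %d populations, %d markers\n",
              x$K, ncol(x$freqs)))
  invisible(x)
}
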