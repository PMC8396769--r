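#' EM estimation of multi-locus haplotype frequencies from unphased genotypes
#'
#' Classic expectation-maximization for haplotype frequencies: the E-step
#' assigns each individual's compatible diplotypes probabilities proportional
#' to `p_h1 * p_h2` (times 2 for heterozygous diplotypes), the M-step
#' re-estimates frequencies from the expected haplotype counts. Individuals
#' missing any of the block's loci are excluded (listwise deletion) and
#' counted. The run is initialized at linkage-equilibrium products of allele
#' frequencies plus `restarts` random Dirichlet initializations; the best
#' log-likelihood wins (the all-double-heterozygote dataset makes the LE
#' start a saddle point, which a random restart escapes). Haplotypes with
#' final frequency below `prune_tol` are pruned and the rest renormalized.
#'
#' @param G A [genotype_matrix()].
#' @param loci Variant ids or column indices of the block (at most 8).
#' @param tol Convergence tolerance on `max |delta p_h|`.
#' @param max_iter Maximum EM iterations per start.
#' @param restarts Number of additional random initializations.
#' @param prune_tol Frequencies below this are pruned after convergence.
#' @param seed Optional seed for the random restarts.
#'
#' @return An object of class `haplotype_fit`: list with `loci` (ids),
#'   `haplotypes` (allele-string labels), `hap01` (H x L 0/1 matrix), `p`
#'   (frequencies, summing to 1), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `n_used`, `n_excluded`, `dosage` (n x H posterior expected
#'   haplotype counts; `NA` rows for excluded individuals), `samples`.
#' @export
em_haplotypes <- function(G, loci, tol = 1e-6, max_iter = 1000L,
                          restarts = 3L, prune_tol = 1e-4, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.character(loci)) loci <- match(loci, G$variants$id)
  assert_that(!anyNA(loci), "unknown locus id in `loci`")
  L <- length(loci)
  assert_that(L >= 1L && L <= 8L, "em_haplotypes supports 1 to 8 loci")
  d <- G$dosage[, loci, drop = FALSE]
  ok <- stats::complete.cases(d)
  assert_that(any(ok), "no individuals with complete genotypes at the loci")
  dc <- d[ok, , drop = FALSE]
  n <- nrow(dc)

  nh <- 2L^L
  hap01 <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
  storage.mode(hap01) <- "integer"
  colnames(hap01) <- G$variants$id[loci]
  labels <- apply(hap01, 1L, function(b)
    paste0(ifelse(b == 1L, G$variants$alt[loci], G$variants$ref[loci]),
           collapse = ""))
  hap_index <- function(b) as.integer(b %*% 2L^((L - 1L):0)) + 1L

  # unique genotype patterns with their compatible diplotype pairs
  key <- apply(dc, 1L, paste, collapse = ",")
  upat <- !duplicated(key)
  pat <- dc[upat, , drop = FALSE]
  pat_of <- match(key, key[upat])
  cnt <- tabulate(pat_of, nbins = nrow(pat))
  pairs <- lapply(seq_len(nrow(pat)), function(i) {
    g <- pat[i, ]
    het <- which(g == 1L)
    base <- as.integer(g == 2L)
    if (length(het) == 0L) {
      h <- hap_index(matrix(base, 1L))
      return(cbind(h1 = h, h2 = h))
    }
    nfree <- length(het) - 1L
    combos <- as.matrix(expand.grid(rep(list(0:1), nfree)))
    if (nfree == 0L) combos <- matrix(numeric(0), 1L, 0L)
    t(apply(combos, 1L, function(bits) {
      h1 <- base; h1[het] <- c(0L, as.integer(bits))
      h2 <- base; h2[het] <- 1L - h1[het]
      c(hap_index(matrix(h1, 1L)), hap_index(matrix(h2, 1L)))
    }))
  })

  e_step <- function(p) {
    exp_counts <- numeric(nh)
    ll <- 0
    w_list <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      w <- p[pr[, 1L]] * p[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
      tw <- sum(w)
      if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw_ll <- -Inf }
      else { w <- w / tw; tw_ll <- log(tw) }
      ll <- ll + cnt[i] * tw_ll
      inc <- numeric(nh)
      for (r in seq_len(nrow(pr))) {
        inc[pr[r, 1L]] <- inc[pr[r, 1L]] + w[r]
        inc[pr[r, 2L]] <- inc[pr[r, 2L]] + w[r]
      }
      exp_counts <- exp_counts + cnt[i] * inc
      w_list[[i]] <- w
    }
    list(counts = exp_counts, loglik = ll, w = w_list)
  }

  run_em <- function(p0) {
    p <- p0
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      es <- e_step(p)
      trace <- c(trace, es$loglik)
      p_new <- es$counts / (2 * n)
      if (max(abs(p_new - p)) < tol) {
        return(list(p = p_new, loglik_trace = trace, n_iter = it,
                    converged = TRUE))
      }
      p <- p_new
    }
    list(p = p, loglik_trace = trace, n_iter = max_iter, converged = FALSE)
  }

  af <- colMeans(dc) / 2
  p_le <- apply(hap01, 1L, function(b) prod(ifelse(b == 1L, af, 1 - af)))
  starts <- list(p_le / sum(p_le))
  if (restarts > 0L) {
    starts <- c(starts, with_seed(seed, lapply(seq_len(restarts), function(i) {
      g <- stats::rgamma(nh, 1)
      g / sum(g)
    })))
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, function(f) tail(f$loglik_trace, 1L),
                                 numeric(1L)))]]

  p <- best$p
  keep <- p >= prune_tol
  p <- p[keep] / sum(p[keep])
  hap01_k <- hap01[keep, , drop = FALSE]
  labels_k <- labels[keep]
  # final E-step on the pruned set for posterior dosages and loglik
  pairs <- lapply(pairs, function(pr) {
    pr_new <- cbind(h1 = match(pr[, 1L], which(keep)),
                    h2 = match(pr[, 2L], which(keep)))
    pr_new[stats::complete.cases(pr_new), , drop = FALSE]
  })
  nh <- length(p)
  es <- e_step(p)
  dosage_c <- matrix(0, n, nh)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (nrow(pr) == 0L) next
    inc <- numeric(nh)
    w <- es$w[[i]]
    for (r in seq_len(nrow(pr))) {
      inc[pr[r, 1L]] <- inc[pr[r, 1L]] + w[r]
      inc[pr[r, 2L]] <- inc[pr[r, 2L]] + w[r]
    }
    dosage_c[pat_of == i, ] <- matrix(inc, sum(pat_of == i), nh, byrow = TRUE)
  }
  dosage <- matrix(NA_real_, nrow(d), nh)
  dosage[ok, ] <- dosage_c
  colnames(dosage) <- labels_k
  rownames(dosage) <- G$samples

  structure(list(
    loci = G$variants$id[loci], haplotypes = labels_k, hap01 = hap01_k,
    p = setNames(p, labels_k),
    loglik = es$loglik, loglik_trace = best$loglik_trace,
    n_iter = best$n_iter, converged = best$converged,
    n_used = n, n_excluded = sum(!ok),
    dosage = dosage, samples = G$samples
  ), class = "haplotype_fit")
}

#' Expected per-sample count of one haplotype
#'
#' @param fit A `haplotype_fit` from [em_haplotypes()].
#' @param haplotype Haplotype label (allele string) present in the fit.
#' @return Named numeric vector of posterior expected counts in `[0, 2]`
#'   (`NA` for individuals excluded for missingness).
#' @export
haplotype_dosage <- function(fit, haplotype) {
  stopifnot(inherits(fit, "haplotype_fit"))
  j <- match(haplotype, fit$haplotypes)
  assert_that(!is.na(j), sprintf("unknown haplotype label '%s'", haplotype))
  setNames(fit$dosage[, j], fit$samples)
}

#' @export
print.haplotype_fit <- function(x, ...) {
  cat(sprintf("<haplotype_fit> %d loci (%s), %d haplotypes, loglik %.3f (%d iter)\n",
              length(x$loci), paste(x$loci, collapse = "/"),
              length(x$p), x$loglik, x$n_iter))
  print(tidy(x))
  invisible(x)
}

#' Tidy a haplotype EM fit
#'
#' @param x A `haplotype_fit`.
#' @param report_min Haplotypes rarer than this in the table are collapsed
#'   into a `rare` row (all are retained in the fit itself); the conventional
#'   reporting cutoff is 5%. Use `0` to show all.
#' @param ... Unused.
#' @return Tibble with `haplotype` and `frequency`, frequency-sorted.
#' @method tidy haplotype_fit
#' @export
tidy.haplotype_fit <- function(x, report_min = 0, ...) {
  out <- tibble::tibble(haplotype = x$haplotypes, frequency = unname(x$p)) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  if (report_min > 0) {
    rare <- out$frequency < report_min
    if (any(rare)) {
      out <- dplyr::bind_rows(
        out[!rare, ],
        tibble::tibble(haplotype = "rare", frequency = sum(out$frequency[rare]))
      )
    }
  }
  out
}

#' @method glance haplotype_fit
#' @export
glance.haplotype_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_haplotypes = length(x$p),
                 n_used = x$n_used, n_excluded = x$n_excluded)
}

#' Write a haplotype frequency table as TSV
#'
#' @param fit A `haplotype_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(fit, path) {
  utils::write.table(tidy(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
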