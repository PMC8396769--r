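#' Parameters for the forward Wright-Fisher sweep simulator
#'
#' @param N Diploid population size (>= 2).
#' @param L Number of tracked biallelic sites.
#' @param span_bp Length of the simulated segment in bp.
#' @param mu Per-site, per-generation allele-flip mutation probability.
#' @param r Per-bp, per-generation recombination probability. The genetic map
#'   of the emitted panels uses the same rate (`cM/Mb = r * 1e8`).
#' @param s Selection coefficient at the focal site; diploid fitness is
#'   additive (`1`, `1 + s`, `1 + 2s`). `s = 0` runs a neutral pair.
#' @param burnin_gens Burn-in generations after the standing-variation
#'   initialization. The default (60) is chosen so the background
#'   haplotype-identity scale `~1/(2 r burnin_gens)` is a few tens of kb,
#'   i.e. a human-scale LD decay; running a small population to full
#'   coalescent equilibrium would instead produce unrealistically long
#'   background haplotypes that no outbred sample shows.
#' @param post_gens Cap on sweep generations (the sweep stops earlier if
#'   `target_freq` is reached).
#' @param target_freq Beneficial-allele frequency at which the sweep phase
#'   stops. The default runs the sweep essentially to completion: the
#'   cross-population haplotype statistics this simulator feeds are at their
#'   strongest for complete or near-complete sweeps, whereas partial sweeps
#'   are the within-population (iHS) regime.
#' @param null_gens Generations the focal copy drifts when `s = 0`, chosen to
#'   match the expected duration of a completed sweep under the default `s`
#'   (`~(1/s) log(2N target/(1-target))`), so the neutral pair is a matched
#'   control.
#' @param max_attempts Retries when the beneficial allele is lost to drift.
#'   A single introduced copy establishes with probability of roughly `2s`,
#'   so the default allows the retry loop to fail only with negligible
#'   probability; lost attempts die within a few generations and cost
#'   little.
#' @param seed Optional integer seed.
#' @return A list of class `sweep_params`.
#' @export
sweep_params <- function(N = 200, L = 1000L, span_bp = 400000L,
                         mu = 1e-6, r = 1e-6, s = 0.05,
                         burnin_gens = 60L, post_gens = 2000L,
                         target_freq = 0.99, null_gens = 210L,
                         max_attempts = 2000L, seed = NULL) {
  assert_that(N >= 2, "N must be >= 2")
  assert_that(s >= 0, "s must be >= 0")
  assert_that(mu >= 0 && mu < 1 && r >= 0 && r < 1,
              "mu and r must lie in [0, 1)")
  assert_that(span_bp >= L, "span_bp must be >= L")
  structure(as.list(environment()), class = "sweep_params")
}

# one Wright-Fisher generation: random mating with optional fitness weights,
# Poisson crossovers at rate r * span per gamete, allele-flip mutation
wf_generation <- function(H, pos, span_bp, r, mu, w = NULL) {
  n2 <- nrow(H)
  N <- n2 / 2L
  pid <- sample.int(N, n2, replace = TRUE, prob = w)
  s1 <- sample.int(2L, n2, replace = TRUE)
  ncx <- rpois(n2, r * span_bp)
  out <- H[2L * (pid - 1L) + s1, , drop = FALSE]
  for (g in which(ncx > 0L)) {
    bp <- sort(runif(ncx[g], 0, span_bp))
    take_other <- findInterval(pos, bp) %% 2L == 1L
    if (any(take_other))
      out[g, take_other] <- H[2L * (pid[g] - 1L) + (3L - s1[g]), take_other]
  }
  if (mu > 0) {
    nm <- rbinom(1L, n2 * ncol(H), mu)
    if (nm > 0L) {
      idx <- sample.int(n2 * ncol(H), nm)
      out[idx] <- 1L - out[idx]
    }
  }
  out
}

focal_dosage <- function(H, j, allele) {
  a <- H[, j] == allele
  a[seq(1L, nrow(H), 2L)] + a[seq(2L, nrow(H), 2L)]
}

#' Forward-simulate a selective sweep and a matched neutral panel
#'
#' Runs a discrete-generation Wright-Fisher population: standing variation is
#' initialized from the neutral site-frequency spectrum (allele count `k` with
#' probability proportional to `1/k`), followed by `burnin_gens` generations
#' of drift, mutation, and recombination to build linkage disequilibrium.
#' The population is then copied; in one copy a beneficial allele is
#' introduced by flipping the focal allele of a single haplotype (the focal
#' column is first set to its burn-in majority allele in both copies) and is
#' driven by additive selection until it reaches `target_freq` (or the
#' `post_gens` cap); the other copy is returned as the burn-in-final
#' population, the matched neutral control. If the beneficial allele is
#' lost, the sweep is retried up to `max_attempts` times. With `s = 0` no
#' allele is introduced and the focal copy drifts for `null_gens`
#' generations instead.
#'
#' Majority alleles at the end of burn-in are recorded as ancestral.
#'
#' @param params A [sweep_params()] object.
#' @return A list of class `sweep_sim`: `selected` and `neutral`
#'   ([haplotype_matrix()] panels over the same sites), `ancestral` (tibble
#'   `variant_id`, `allele`), `focal_id`, `focal_index`, `focal_freq`
#'   (beneficial-allele frequency in the selected panel), `sweep_gens`,
#'   `attempts`, and `params`.
#' @export
simulate_sweep <- function(params = sweep_params()) {
  stopifnot(inherits(params, "sweep_params"))
  with_seed(params$seed, simulate_sweep_impl(params))
}

simulate_sweep_impl <- function(p) {
  n2 <- 2L * p$N
  pos <- sort(sample.int(p$span_bp, p$L))
  # standing variation: neutral SFS, no initial LD (burn-in builds it)
  H <- matrix(0L, n2, p$L)
  counts <- sample.int(n2 - 1L, p$L, replace = TRUE,
                       prob = 1 / seq_len(n2 - 1L))
  for (j in seq_len(p$L)) H[sample.int(n2, counts[j]), j] <- 1L

  for (g in seq_len(p$burnin_gens))
    H <- wf_generation(H, pos, p$span_bp, p$r, p$mu)

  anc <- as.integer(colMeans(H) > 0.5)
  focal <- which.min(abs(pos - p$span_bp / 2))
  if (p$s == 0) {
    # null runs keep the standing focal variant: pick the mid-most site
    # polymorphic enough to be scored by the scan statistics
    fr <- colMeans(H)
    ok <- which(pmin(fr, 1 - fr) >= 0.05)
    if (length(ok) > 0L) focal <- ok[which.min(abs(pos[ok] - p$span_bp / 2))]
  }

  if (p$s > 0) {
    # hard sweep from a single introduced copy
    H[, focal] <- anc[focal]
    benef <- 1L - anc[focal]
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > p$max_attempts)
        abort(sprintf("beneficial allele lost in all %d attempts",
                      p$max_attempts))
      Hs <- H
      Hs[sample.int(n2, 1L), focal] <- benef
      gens <- 0L
      repeat {
        freq <- mean(Hs[, focal] == benef)
        if (freq == 0 || freq >= p$target_freq || gens >= p$post_gens) break
        w <- 1 + p$s * focal_dosage(Hs, focal, benef)
        Hs <- wf_generation(Hs, pos, p$span_bp, p$r, p$mu, w = w)
        gens <- gens + 1L
      }
      if (freq >= p$target_freq || (freq > 0 && gens >= p$post_gens)) break
    }
    Hn <- H
  } else {
    benef <- 1L - anc[focal]
    Hs <- H; Hn <- H
    gens <- p$null_gens
    attempt <- 1L
    for (g in seq_len(gens))
      Hs <- wf_generation(Hs, pos, p$span_bp, p$r, p$mu)
    freq <- mean(Hs[, focal] == benef)
  }

  ids <- sprintf("snp%04d", seq_len(p$L))
  vt <- variant_table(ids, "1", pos, "A", "G",
                      ancestral = ifelse(anc == 0L, "A", "G"),
                      cm_per_mb = p$r * 1e8)
  samples <- rep(sprintf("ind%04d", seq_len(p$N)), each = 2L)
  structure(list(
    selected = haplotype_matrix(Hs, vt, samples),
    neutral = haplotype_matrix(Hn, vt, samples),
    ancestral = tibble::tibble(variant_id = ids,
                               allele = ifelse(anc == 0L, "A", "G")),
    focal_id = ids[focal], focal_index = focal,
    focal_freq = freq, sweep_gens = gens, attempts = attempt,
    params = p
  ), class = "sweep_sim")
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat(sprintf(
    "<sweep_sim> 2N = %d haplotypes, %d sites over %.0f kb; s = %g, focal %s at freq %.2f (%d sweep gens)\n",
    nrow(x$selected$hap), x$params$L, x$params$span_bp / 1000,
    x$params$s, x$focal_id, x$focal_freq, x$sweep_gens))
  invisible(x)
}
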