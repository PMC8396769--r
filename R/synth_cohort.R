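#' Default per-ancestry focal-block haplotype frequencies
#'
#' Frequency profiles for a 3-SNP risk-haplotype block in each ancestral
#' population. The African and European columns follow published frequency
#' profiles for an African-ancestry candidate region (risk haplotype common
#' in Africans, rare reference haplotype); the Native-American column is a
#' plausible default chosen once for the generator. Drawing whole haplotypes
#' from these tables is what induces LD at the focal block.
#'
#' @return A tibble with columns `haplotype` (allele string over the three
#'   focal SNPs), `afr`, `eur`, `nam` (frequencies, each column summing to 1).
#' @export
default_focal_haplotypes <- function() {
  tibble::tibble(
    haplotype = c("TGG", "GGA", "GGG", "GAA"),
    afr = c(0.47, 0.32, 0.19, 0.02),
    eur = c(0.27, 0.04, 0.03, 0.66),
    nam = c(0.30, 0.05, 0.05, 0.60)
  )
}

#' Parameters for the admixed case-control cohort generator
#'
#' @param n_cases,n_controls Case and control quotas.
#' @param dirichlet_alpha Dirichlet concentration for individual admixture
#'   proportions `q` (length K). The default `c(3.5, 5, 1.5)` gives mean
#'   ancestry 35% / 50% / 15%, typical of an admixed Latin-American cohort.
#' @param focal_haplotype Risk haplotype allele string (must appear in
#'   `focal_haps$haplotype`).
#' @param beta0 Baseline log-odds of disease.
#' @param beta_hap Per-copy log-OR of the risk haplotype.
#' @param beta_age Log-OR per year of age (age centred at 40).
#' @param beta_sex Log-OR for male sex.
#' @param focal_haps Per-ancestry haplotype frequency table
#'   (see [default_focal_haplotypes()]).
#' @param n_null_snps Extra ancestry-structured SNPs with no phenotype effect
#'   (useful for type-I calibration).
#' @param ascertainment `"case_control"` (sample until both quotas are met,
#'   retrospective design) or `"population"` (take the first
#'   `n_cases + n_controls` individuals regardless of status).
#' @param max_draws Cap on candidate draws before the quota search errors.
#' @param seed Optional integer seed.
#'
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_cases = 500, n_controls = 500,
                          dirichlet_alpha = c(3.5, 5, 1.5),
                          focal_haplotype = "TGG",
                          beta0 = -1.1, beta_hap = log(1.64),
                          beta_age = 0.02, beta_sex = 0.3,
                          focal_haps = default_focal_haplotypes(),
                          n_null_snps = 0,
                          ascertainment = c("case_control", "population"),
                          max_draws = 60L * (n_cases + n_controls),
                          seed = NULL) {
  ascertainment <- match.arg(ascertainment)
  assert_that(all(dirichlet_alpha > 0), "dirichlet_alpha must be > 0")
  assert_that(is.finite(beta_hap), "beta_hap must be finite")
  assert_that(focal_haplotype %in% focal_haps$haplotype,
              "focal_haplotype must appear in focal_haps")
  structure(as.list(environment()), class = "cohort_params")
}

dirichlet_draw <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# one allele copy per (individual, marker): ancestry ~ Categorical(q),
# allele ~ Bernoulli(f[ancestry, marker])
draw_copy <- function(q, f) {
  n <- nrow(q); J <- ncol(f); K <- ncol(q)
  cq <- t(apply(q, 1L, cumsum))
  u <- matrix(runif(n * J), n, J)
  k <- matrix(1L, n, J)
  for (kk in seq_len(K - 1L)) k <- k + (u > cq[, kk])
  pf <- matrix(f[cbind(as.vector(k), rep(seq_len(J), each = n))], n, J)
  matrix(rbinom(n * J, 1L, as.vector(pf)), n, J)
}

#' Simulate an admixed case-control cohort with a planted risk haplotype
#'
#' Generates, per individual: admixture proportions `q ~ Dirichlet(alpha)`;
#' ancestry-informative-marker genotypes with each allele copy drawn by
#' ancestry `k ~ Categorical(q)` then `Bernoulli(f_kj)`; a pair of focal-block
#' haplotypes drawn from per-ancestry whole-haplotype frequency tables (so the
#' focal SNPs are in LD); covariates age and sex; and a binary phenotype from
#' the logistic model
#' `logit P(case) = beta0 + beta_hap * dosage(risk haplotype) +
#'  beta_age * (age - 40) + beta_sex * male`.
#' Under case-control ascertainment, candidates are drawn until both quotas
#' are filled.
#'
#' @param pool An `ancestral_pool` for the AIM panel (K rows; see
#'   [balding_nichols_pools()]). Its K must match `length(dirichlet_alpha)`.
#' @param params A [cohort_params()] object.
#' @param site Site (population) label stored in the sample table.
#'
#' @return An object of class `synthetic_cohort`: list with `genotypes`
#'   ([genotype_matrix()] over AIMs, focal SNPs, and any null SNPs), `samples`
#'   (tibble: `sample_id`, `status`, `sex`, `age`, `site`), `true_q`
#'   (`n x K`), `true_haplotypes` (`n x 2` character), `focal_ids`,
#'   `aim_ids`, `null_ids`, and `params`.
#' @export
simulate_admixed_cohort <- function(pool, params = cohort_params(),
                                    site = "site1") {
  stopifnot(inherits(pool, "ancestral_pool"), inherits(params, "cohort_params"))
  K <- pool$K
  assert_that(K == length(params$dirichlet_alpha),
              "pool K must match length(dirichlet_alpha)")
  with_seed(params$seed, simulate_admixed_cohort_impl(pool, params, site))
}

simulate_admixed_cohort_impl <- function(pool, params, site) {
  K <- pool$K
  J <- ncol(pool$freqs)
  hp <- params$focal_haps
  hap_freq <- t(as.matrix(hp[, -1L, drop = FALSE]))   # K x H
  assert_that(nrow(hap_freq) == K,
              "focal_haps must have one frequency column per ancestry")
  assert_that(all(abs(rowSums(hap_freq) - 1) < 1e-6),
              "per-ancestry haplotype frequencies must sum to 1")
  hap_alleles <- do.call(rbind, strsplit(hp$haplotype, ""))
  n_loci <- ncol(hap_alleles)
  # alt allele at each focal locus = allele of the risk haplotype where it
  # differs from the most common reference profile; encode as 0/1 per locus
  focal_ref <- apply(hap_alleles, 2L, function(a)
    names(sort(table(a), decreasing = TRUE))[1L])
  focal_alt <- vapply(seq_len(n_loci), function(j) {
    u <- unique(hap_alleles[, j])
    assert_that(length(u) == 2L, "each focal locus must be biallelic")
    u[u != focal_ref[j]]
  }, character(1L))
  hap01 <- matrix(as.integer(hap_alleles != matrix(focal_ref,
                                                   nrow(hap_alleles), n_loci,
                                                   byrow = TRUE)),
                  nrow(hap_alleles))

  n_needed <- params$n_cases + params$n_controls
  n_null <- params$n_null_snps
  # null-marker frequencies are drawn once: every sampling batch must share
  # one generating distribution or quota ascertainment would induce
  # spurious genotype-status association
  fnull <- if (n_null > 0L) null_pool_freqs(pool, n_null)
  batch <- max(1000L, n_needed)
  acc <- list()
  n_case_acc <- 0L; n_ctrl_acc <- 0L; n_drawn <- 0L
  repeat {
    n <- batch
    q <- dirichlet_draw(n, params$dirichlet_alpha)
    aims <- draw_copy(q, pool$freqs) + draw_copy(q, pool$freqs)
    cq <- t(apply(q, 1L, cumsum))
    chf <- t(apply(hap_freq, 1L, cumsum))
    h_idx <- vapply(1:2, function(copy) {
      k <- as.integer(rowSums(runif(n) > cq)) + 1L     # ancestry of this copy
      as.integer(rowSums(runif(n) > chf[k, , drop = FALSE])) + 1L
    }, integer(n))
    null_g <- NULL
    if (n_null > 0L) {
      null_g <- draw_copy(q, fnull) + draw_copy(q, fnull)
    }
    dos_risk <- rowSums(matrix(hp$haplotype[h_idx], n, 2L) ==
                          params$focal_haplotype)
    age <- rnorm(n, 40, 12)
    male <- rbinom(n, 1L, 0.5)
    eta <- params$beta0 + params$beta_hap * dos_risk +
      params$beta_age * (age - 40) + params$beta_sex * male
    y <- rbinom(n, 1L, expit(eta))
    acc[[length(acc) + 1L]] <- list(q = q, aims = aims, h_idx = h_idx,
                                    null_g = null_g, age = age, male = male,
                                    y = y)
    n_drawn <- n_drawn + n
    n_case_acc <- n_case_acc + sum(y == 1L)
    n_ctrl_acc <- n_ctrl_acc + sum(y == 0L)
    if (params$ascertainment == "population" && n_drawn >= n_needed) break
    if (n_case_acc >= params$n_cases && n_ctrl_acc >= params$n_controls) break
    if (n_drawn >= params$max_draws)
      abort(sprintf(paste0("case/control quota (%d/%d) not reached after %d ",
                           "draws; check beta0 against the quotas"),
                    params$n_cases, params$n_controls, n_drawn))
  }
  q <- do.call(rbind, lapply(acc, `[[`, "q"))
  aims <- do.call(rbind, lapply(acc, `[[`, "aims"))
  h_idx <- do.call(rbind, lapply(acc, `[[`, "h_idx"))
  null_g <- if (n_null > 0L) do.call(rbind, lapply(acc, `[[`, "null_g"))
  age <- unlist(lapply(acc, `[[`, "age"))
  male <- unlist(lapply(acc, `[[`, "male"))
  y <- unlist(lapply(acc, `[[`, "y"))

  keep <- if (params$ascertainment == "population") {
    seq_len(n_needed)
  } else {
    c(which(y == 1L)[seq_len(params$n_cases)],
      which(y == 0L)[seq_len(params$n_controls)])
  }
  q <- q[keep, , drop = FALSE]; aims <- aims[keep, , drop = FALSE]
  h_idx <- h_idx[keep, , drop = FALSE]
  if (n_null > 0L) null_g <- null_g[keep, , drop = FALSE]
  age <- age[keep]; male <- male[keep]; y <- y[keep]
  n <- length(y)

  focal_dos <- hap01[h_idx[, 1L], , drop = FALSE] +
    hap01[h_idx[, 2L], , drop = FALSE]
  aim_ids <- paste0("aim", seq_len(ncol(aims)))
  focal_ids <- paste0("focal", seq_len(ncol(focal_dos)))
  null_ids <- if (n_null > 0L) paste0("null", seq_len(n_null)) else character()
  dosage <- cbind(aims, focal_dos, null_g)

  variants <- variant_table(
    id = c(aim_ids, focal_ids, null_ids),
    chrom = "1",
    pos = c(seq_len(ncol(aims)) * 2000000L,
            155260000L + (seq_len(ncol(focal_dos)) - 1L) * 2000L,
            if (n_null > 0L) 200000000L + seq_len(n_null) * 10000L),
    ref = c(rep("A", ncol(aims)), focal_ref, rep("A", n_null)),
    alt = c(rep("G", ncol(aims)), focal_alt, rep("G", n_null))
  )
  samples <- tibble::tibble(
    sample_id = sprintf("ind%05d", seq_len(n)),
    status = ifelse(y == 1L, "case", "control"),
    sex = ifelse(male == 1L, "male", "female"),
    age = age, site = site
  )
  structure(list(
    genotypes = genotype_matrix(dosage, variants, samples$sample_id),
    samples = samples,
    true_q = q,
    true_haplotypes = matrix(hp$haplotype[h_idx], n, 2L),
    focal_ids = focal_ids, aim_ids = aim_ids, null_ids = null_ids,
    params = params
  ), class = "synthetic_cohort")
}

# ancestry-structured null markers: reuse the AIM pool's divergence by
# resampling Balding-Nichols frequencies around uniform base frequencies
null_pool_freqs <- function(pool, n_null) {
  Fk <- ifelse(is.na(pool$F_k), 0.15, pool$F_k)
  p <- runif(n_null, 0.1, 0.9)
  f <- t(vapply(Fk, function(F) {
    lam <- (1 - F) / F
    rbeta(n_null, p * lam, (1 - p) * lam)
  }, numeric(n_null)))
  pmin(pmax(f, 0.01), 0.99)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d cases / %d controls, %d AIMs + %d focal + %d null SNPs\n",
    sum(x$samples$status == "case"), sum(x$samples$status == "control"),
    length(x$aim_ids), length(x$focal_ids), length(x$null_ids)))
  invisible(x)
}
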