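test_that("HWE chi-square matches hand arithmetic", {
  h1 <- hwe_chi2(25, 50, 25)
  expect_equal(h1$chi2, 0)
  expect_equal(h1$p, 1)
  h2 <- hwe_chi2(50, 0, 50)
  expect_equal(h2$chi2, 100)  # (O-E)^2/E = 25 + 50 + 25
  h3 <- hwe_chi2(30, 0, 0)
  expect_false(h3$defined)
  expect_equal(h3$p, 1)
})

test_that("chi-square HWE rejections track the exact test under the null", {
  set.seed(19)
  n <- 150
  reps <- 1000
  rej_chi <- logical(reps); rej_ex <- logical(reps)
  for (i in seq_len(reps)) {
    p <- runif(1, 0.2, 0.8)
    g <- rbinom(n, 2, p)
    cnt <- tabulate(g + 1L, 3L)
    rej_chi[i] <- hwe_chi2(cnt[1], cnt[2], cnt[3])$p < 0.05
    rej_ex[i] <- oracle_hwe_exact(cnt[1], cnt[2], cnt[3]) < 0.05
  }
  expect_lt(abs(mean(rej_chi) - 0.05), 0.05)
  expect_lt(abs(mean(rej_chi) - mean(rej_ex)), 0.05)
  expect_gt(mean(rej_chi == rej_ex), 0.9)
})

test_that("QC drops low-call-rate variants and flags the HWE violator", {
  set.seed(23)
  n <- 200
  dos <- cbind(
    good = rbinom(n, 2, 0.4),
    lowcall = ifelse(runif(n) < 0.11, NA, rbinom(n, 2, 0.4)),
    violator = rep(c(0L, 2L), n / 2))
  G <- genotype_matrix(dos, variant_table(c("good", "lowcall", "violator"),
                                          "1", 1:3, "A", "G"))
  samples <- tibble::tibble(
    sample_id = G$samples, status = rep(c("case", "control"), each = n / 2),
    sex = "female", age = 30, site = "s")
  qc <- qc_filter(G, samples)
  expect_true("good" %in% qc$genotypes$variants$id)
  expect_false("violator" %in% qc$genotypes$variants$id)
  expect_true("hwe" %in% qc$report$reason[qc$report$item == "violator"])
  # samples with missing metadata are removed with a reason
  samples$age[1] <- NA
  qc2 <- qc_filter(G, samples)
  expect_equal(qc2$report$reason[qc2$report$type == "sample"], "metadata")
  expect_equal(length(qc2$samples$sample_id), n - 1L)
})

test_that("logistic_fit reproduces the closed-form 2x2 log odds ratio", {
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 40), rep(0, 60), rep(1, 20), rep(0, 80))
  fit <- logistic_fit(y, cbind(exposed = x))
  expect_equal(fit$beta[fit$term == "exposed"], log(40 * 80 / (60 * 20)),
               tolerance = 1e-8)
  expect_equal(fit$se[fit$term == "exposed"],
               sqrt(1 / 40 + 1 / 60 + 1 / 20 + 1 / 80), tolerance = 1e-6)
})

test_that("logistic_fit raises explicit separation and rank errors", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_error(logistic_fit(y, cbind(sep = y)), "separation")
  x <- rnorm(20)
  expect_error(logistic_fit(y, cbind(a = x, b = 2 * x)), "rank")
  expect_error(logistic_fit(rep(1, 10), cbind(x = rnorm(10))))
})

test_that("null logistic slopes follow asymptotic normality", {
  set.seed(29)
  inside <- vapply(1:300, function(i) {
    y <- rbinom(400, 1, 0.4)
    x <- rbinom(400, 1, 0.3)
    if (length(unique(x)) < 2) return(NA)
    f <- logistic_fit(y, cbind(x = x))
    abs(f$beta[2]) < 3 * f$se[2]
  }, logical(1))
  expect_gte(mean(inside, na.rm = TRUE), 0.985)
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(31)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p & q <= 1))
  # order-preserving: adjusted values are non-decreasing in the raw order
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("covariate auto-selection picks variables that differ by status", {
  set.seed(37)
  n <- 400
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    status = rep(c("case", "control"), each = n / 2),
    age = rnorm(n, mean = ifelse(rep(c(TRUE, FALSE), each = n / 2), 50, 40),
                sd = 5),
    sex = sample(c("male", "female"), n, TRUE))
  sel <- select_covariates(samples)
  expect_true(sel$selected[sel$covariate == "age"])
  expect_equal(sel$test[sel$covariate == "age"], "wilcoxon")
  expect_equal(sel$test[sel$covariate == "sex"], "chisq")
})

test_that("model scan encodes the genetic models consistently", {
  set.seed(41)
  pool <- balding_nichols_pools(runif(10, 0.3, 0.7), rep(0.2, 3), seed = 1)
  co <- simulate_admixed_cohort(pool, cohort_params(
    n_cases = 300, n_controls = 300, seed = 2))
  res <- model_scan(co$genotypes, co$samples, covariates = NULL)
  expect_s3_class(res, "assoc_scan")
  # carrier and dominant coincide exactly
  dom <- res[res$model == "dominant", ]
  car <- res[res$model == "carrier", ]
  expect_equal(dom$beta, car$beta)
  expect_equal(dom$p, car$p)
  # codominant returns two contrasts per variant, the others one each
  expect_equal(sum(res$model == "codominant"),
               2L * nrow(co$genotypes$variants))
  for (m in c("dominant", "recessive", "allelic", "carrier")) {
    expect_equal(sum(res$model == m), nrow(co$genotypes$variants))
  }
  expect_true(any(!is.na(res$beta[res$model == "allelic"])))
  # OR/CI identities hold
  ok <- !is.na(res$beta)
  expect_equal(res$or[ok], exp(res$beta[ok]))
  expect_equal(res$or_u95[ok], exp(res$beta[ok] + 1.96 * res$se[ok]))
  # q respects the per-model BH family
  for (m in unique(res$model)) {
    i <- res$model == m
    expect_equal(res$q[i], bh_fdr(res$p[i]))
  }
})

test_that("a planted additive effect is recovered by the dominant model", {
  set.seed(43)
  hits <- vapply(1:25, function(i) {
    n <- 600
    dos <- rbinom(n, 2, 0.3)
    eta <- -0.5 + log(2) * (dos >= 1)
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    G <- genotype_matrix(matrix(dos, ncol = 1),
                         variant_table("v", "1", 1L, "A", "G"))
    samples <- tibble::tibble(sample_id = G$samples,
                              status = ifelse(y == 1, "case", "control"))
    r <- model_scan(G, samples, models = "dominant", covariates = NULL)
    r$or_l95 <= 2 & 2 <= r$or_u95
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("empty genotype classes are reported, not fitted", {
  dos <- c(rep(0L, 30), rep(1L, 30))
  G <- genotype_matrix(matrix(dos, ncol = 1),
                       variant_table("v", "1", 1L, "A", "G"))
  samples <- tibble::tibble(sample_id = G$samples,
                            status = rep(c("case", "control"), 30))
  r <- model_scan(G, samples, models = c("codominant", "recessive"),
                  covariates = NULL)
  expect_true(all(is.na(r$beta[r$model == "codominant"])))
  expect_match(r$note[r$model == "recessive"], "empty")
})

test_that("DerSimonian-Laird pooling matches metafor and hand arithmetic", {
  # degenerate equal-study case
  eq <- meta_random_effects(data.frame(beta = c(0.4, 0.4, 0.4),
                                       se = c(0.1, 0.1, 0.1)))
  expect_equal(eq$tau2, 0)
  expect_equal(eq$beta, 0.4)
  # hand-computed two-study example
  m <- meta_random_effects(data.frame(beta = c(0.5, 0.1), se = c(0.2, 0.3)))
  w <- c(25, 1 / 0.09)
  b_fe <- sum(w * c(0.5, 0.1)) / sum(w)
  q <- sum(w * (c(0.5, 0.1) - b_fe)^2)
  tau2 <- max(0, (q - 1) / (sum(w) - sum(w^2) / sum(w)))
  w2 <- 1 / (c(0.04, 0.09) + tau2)
  expect_equal(m$tau2, tau2, tolerance = 1e-12)
  expect_equal(m$beta, sum(w2 * c(0.5, 0.1)) / sum(w2), tolerance = 1e-12)
  # metafor as independent oracle on random inputs
  set.seed(47)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0.3, 0.4)
    se <- runif(k, 0.05, 0.4)
    ours <- meta_random_effects(data.frame(beta = beta, se = se))
    ref <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(ours$se, ref$se, tolerance = 1e-8)
  }
  # fixed-effect containment when tau2 = 0: pooled CI inside site CI span
  if (m$tau2 == 0) {
    expect_gte(m$or_l95, exp(min(c(0.5, 0.1) - 1.96 * c(0.2, 0.3))))
  }
  expect_warning(meta_random_effects(data.frame(beta = 0.2, se = 0.1)),
                 "single")
  # simulated heterogeneity is detected most of the time
  set.seed(53)
  pos_tau <- vapply(1:50, function(i) {
    b <- rnorm(6, 0.3, sd = 0.2)          # true tau2 = 0.04
    bh <- b + rnorm(6, 0, 0.05)
    meta_random_effects(data.frame(beta = bh, se = rep(0.05, 6)))$tau2 > 0
  }, logical(1))
  expect_gte(mean(pos_tau), 0.8)
})

test_that("haplotype association reduces to the allelic 2x2 closed form", {
  # two-haplotype system, no phase ambiguity (single segregating block of
  # two loci in perfect LD)
  set.seed(59)
  n <- 300
  h <- matrix(rbinom(2 * n, 1, 0.4), ncol = 2) # per-copy carrier of GG
  dos <- cbind(h[, 1] + h[, 2], h[, 1] + h[, 2])
  G <- genotype_matrix(dos, variant_table(c("a", "b"), "1", 1:2, "A", "G"))
  risk <- rowSums(h)
  y <- rbinom(n, 1, 1 / (1 + exp(-(-0.4 + 0.6 * risk))))
  samples <- tibble::tibble(sample_id = G$samples,
                            status = ifelse(y == 1, "case", "control"))
  fit <- em_haplotypes(G, 1:2, restarts = 0)
  a <- haplotype_assoc(fit, samples, "AA", contrast = "allelic",
                       report_min = 0)
  # closed form from allele counts
  n_case_h <- sum(risk[y == 1]); n_case_r <- sum((2 - risk)[y == 1])
  n_ctrl_h <- sum(risk[y == 0]); n_ctrl_r <- sum((2 - risk)[y == 0])
  expect_equal(a$beta[a$id == "GG"],
               log(n_case_h * n_ctrl_r / (n_case_r * n_ctrl_h)),
               tolerance = 1e-6)
})

test_that("the published-style frequency table reproduces the crude OR", {
  tab <- read.delim(system.file("extdata", "cohort_haplotype_freqs.tsv",
                                package = "admixsel"))
  rio <- tab[tab$population == "southeast_br", ]
  or <- crude_haplotype_or(
    freq_case = c(rio$frequency[rio$group == "case" & rio$haplotype == "TGG"],
                  rio$frequency[rio$group == "case" & rio$haplotype == "GGA"]),
    freq_ctrl = c(rio$frequency[rio$group == "control" & rio$haplotype == "TGG"],
                  rio$frequency[rio$group == "control" & rio$haplotype == "GGA"]),
    n_case = rio$n[1], n_ctrl = rio$n[rio$group == "control"][1])
  expect_equal(or$or, (0.36 * 0.09) / (0.07 * 0.28), tolerance = 1e-10)
})

test_that("haplotype association errors when the reference is absent", {
  dos <- matrix(c(2L, 2L, 2L, 2L), 2, 2)
  G <- genotype_matrix(dos, variant_table(c("a", "b"), "1", 1:2, "A", "G"))
  samples <- tibble::tibble(sample_id = G$samples,
                            status = c("case", "control"))
  fit <- em_haplotypes(G, 1:2, restarts = 0)
  expect_error(haplotype_assoc(fit, samples, "ZZ"), "not in fit")
})
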