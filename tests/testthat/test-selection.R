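counts_df <- function(...) {
  m <- rbind(...)
  data.frame(n_ref_hom = m[, 1], n_het = m[, 2], n_alt_hom = m[, 3])
}

test_that("Weir-Cockerham FST handles fixation and no differentiation", {
  fix <- wc_fst(counts_df(c(0, 0, 50)), counts_df(c(50, 0, 0)))
  expect_equal(fix$fst, 1)
  same <- wc_fst(counts_df(c(30, 40, 30)), counts_df(c(30, 40, 30)))
  expect_lte(same$a, 0)
  expect_lt(abs(same$fst), 0.05)
  mono <- wc_fst(counts_df(c(50, 0, 0)), counts_df(c(50, 0, 0)))
  expect_false(mono$defined)
})

test_that("FST components match the independent transcription oracle", {
  ref <- oracle_wc_fst(list(c(30, 40, 30), c(10, 40, 50)))
  got <- wc_fst(counts_df(c(30, 40, 30)), counts_df(c(10, 40, 50)))
  expect_equal(c(got$a, got$b, got$c, got$fst), unname(ref),
               tolerance = 1e-10)
  set.seed(61)
  for (i in 1:100) {
    c1 <- rmultinom(1, sample(20:200, 1), runif(3, 0.05, 1))[, 1]
    c2 <- rmultinom(1, sample(20:200, 1), runif(3, 0.05, 1))[, 1]
    ref <- oracle_wc_fst(list(c1, c2))
    got <- wc_fst(counts_df(c1), counts_df(c2))
    if (got$defined) {
      expect_equal(c(got$a, got$b, got$c), unname(ref[1:3]),
                   tolerance = 1e-10)
    }
  }
})

test_that("windowed FST is the ratio of averages, not average of ratios", {
  pv <- tibble::tibble(chrom = "1", pos = c(100L, 200L),
                       a = c(0.2, 0.01), b = c(0.1, 0.2), c = c(0.1, 0.2),
                       maf_pooled = c(0.3, 0.3), defined = TRUE)
  w <- windowed_fst(pv, window = 2, step = 2, units = "variants")
  roa <- sum(pv$a) / sum(pv$a + pv$b + pv$c)
  aor <- mean(pv$a / (pv$a + pv$b + pv$c))
  expect_equal(w$value, roa)
  expect_false(isTRUE(all.equal(roa, aor)))  # regression guard
  # a single-variant window equals the per-variant value
  w1 <- windowed_fst(pv, window = 1, step = 1, units = "variants")
  expect_equal(w1$value, pv$a / (pv$a + pv$b + pv$c))
  # equal denominators: the window value is the mean of per-variant values
  pv2 <- tibble::tibble(chrom = "1", pos = c(1L, 2L), a = c(0.1, 0.3),
                        b = c(0.2, 0.1), c = c(0.2, 0.1),
                        maf_pooled = 0.4, defined = TRUE)
  w2 <- windowed_fst(pv2, window = 2, step = 2, units = "variants")
  expect_equal(w2$value, mean(pv2$a / 0.5))
  # MAF exclusion
  pv$maf_pooled[2] <- 0.01
  w3 <- windowed_fst(pv, window = 2, step = 2, units = "variants")
  expect_equal(w3$n_variants, 1L)
})

test_that("empirical p follows rank arithmetic and monotone invariance", {
  set.seed(67)
  vals <- rnorm(1000)
  expect_equal(empirical_p(vals, max(vals)), 1 / 1001)
  expect_equal(empirical_p(vals, min(vals) - 1), 1)
  obs <- quantile(vals, 0.98, type = 1)
  expect_lt(abs(empirical_p(vals, obs) - 0.02), 0.005)
  expect_equal(empirical_p(vals, obs), empirical_p(exp(vals), exp(obs)))
  expect_warning(empirical_p(rnorm(50), 0), "only")
})

test_that("Tajima's D matches the pairwise-enumeration oracle", {
  expect_false(tajimas_d(matrix(0L, 6, 4))$defined)
  set.seed(71)
  h5 <- matrix(rbinom(20, 1, 0.4), 5, 4)
  got <- tajimas_d(h5)
  if (got$defined) expect_equal(got$D, oracle_tajima(h5), tolerance = 1e-12)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    m <- sample(3:10, 1)
    h <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    got <- tajimas_d(h)
    ref <- oracle_tajima(h)
    if (got$defined) expect_equal(got$D, ref, tolerance = 1e-10)
    else expect_true(is.na(ref))
  }
})

test_that("windowed Tajima tiles the chromosome from position 1", {
  H <- rand_panel(20, 50, seed = 73)
  H$variants$pos <- sort(sample.int(250000L, 50))
  H$variants$pos[50] <- 250000L
  td <- windowed_tajima(H, sizes = 100000L)
  expect_equal(nrow(td), 3L)
  expect_equal(td$start, c(1L, 100001L, 200001L))
  expect_equal(td$end[3], 250000L)
  expect_true(all(td$empirical_p > 0 & td$empirical_p <= 1, na.rm = TRUE))
  # all-identical haplotypes: every window undefined
  H0 <- haplotype_matrix(matrix(1L, 10, 5),
                         variant_table(paste0("v", 1:5), "1",
                                       c(1, 2, 3, 4, 5) * 10000L, "A", "G"))
  td0 <- windowed_tajima(H0, sizes = 25000L)
  expect_true(all(!td0$defined))
})

test_that("EHH curves are 1 at the core, non-increasing, and match brute force", {
  set.seed(79)
  H <- rand_panel(40, 15, seed = 79)
  core <- 8L
  for (allele in c(1L, 0L)) {
    pr <- ehh_curve(H, core, allele = allele)
    expect_equal(pr$curve$ehh[pr$curve$position == H$variants$pos[core]],
                 c(1, 1))
    for (side in c("left", "right")) {
      v <- pr$curve$ehh[pr$curve$side == side]
      v <- if (side == "left") rev(v) else v
      expect_true(all(diff(v) <= 1e-12))
    }
    expect_true(all(pr$curve$ehh >= 0 & pr$curve$ehh <= 1))
    expect_gte(pr$ihh, 0)
    # brute-force enumeration at every visited marker
    rows <- which(H$hap[, core] == allele)
    for (k in seq_len(nrow(pr$curve))) {
      tgt <- match(pr$curve$position[k], H$variants$pos)
      if (tgt == core) next
      expect_equal(pr$curve$ehh[k], oracle_ehh_at(H$hap, rows, core, tgt),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical carrier haplotypes keep EHH at 1 with truncation", {
  hap <- rbind(matrix(1L, 4, 6), matrix(rep(c(0L, 1L), 18), 6, 6))
  H <- haplotype_matrix(hap, variant_table(paste0("v", 1:6), "1",
                                           1:6 * 100L, "A", "G"))
  # carriers of alt at column 3 include the 4 identical haplotypes only
  hap2 <- hap; hap2[5:10, 3] <- 0L
  H2 <- haplotype_matrix(hap2, variant_table(paste0("v", 1:6), "1",
                                             1:6 * 100L, "A", "G"))
  pr <- ehh_curve(H2, 3L, allele = 1L)
  expect_true(all(pr$curve$ehh == 1))
  expect_true(pr$truncated)
  expect_error(ehh_curve(H2, 3L, allele = 2L), "carried")
})

test_that("mirror-symmetric haplotype structure gives raw iHS of zero", {
  P <- diag(4L)  # four mutually distinct flank patterns
  hap <- rbind(cbind(P, 1L, P), cbind(P, 0L, P))
  H <- haplotype_matrix(hap, variant_table(
    paste0("v", 1:9), "1", 1:9 * 1000L, "A", "G",
    ancestral = c(rep(NA, 4), "A", rep(NA, 4))))
  # derived (alt) and ancestral (ref) carriers of the middle core have
  # identical flank structure, so their iHH integrals coincide
  sc <- ihs_scan(H, maf_min = 0.05, min_bin = 1)
  expect_equal(sc$raw[sc$id == "v5"], 0, tolerance = 1e-12)
})

test_that("standardized scan scores are centered and scaled", {
  sw <- simulate_sweep(sweep_params(s = 0, seed = 84))
  sc <- ihs_scan(sw$selected, ancestral = sw$ancestral)
  expect_gt(nrow(sc), 50)
  expect_lt(abs(mean(sc$score)), 0.05 + 3 / sqrt(nrow(sc)))
  expect_lt(abs(sd(sc$score) - 1), 0.1 + 3 / sqrt(nrow(sc)))
  xp <- xpehh_scan(sw$selected, sw$neutral)
  expect_lt(abs(mean(xp$score)), 1e-8)
  expect_equal(sd(xp$score), 1, tolerance = 1e-8)
})

test_that("identical panels give flagged, zeroed xpEHH scores", {
  H <- rand_panel(30, 20, seed = 89)
  xp <- xpehh_scan(H, H)
  expect_true(attr(xp, "constant_raw"))
  expect_true(all(xp$score == 0))
  expect_true(all(abs(xp$raw) < 1e-8))
})

test_that("score runs are detected from contiguous extreme stretches", {
  sc <- tibble::tibble(pos = 1:20 * 100L,
                       score = c(rep(0.5, 6), rep(2.5, 6), rep(-0.2, 4),
                                 rep(-2.4, 4)))
  runs <- score_runs(sc, threshold = 2, min_snps = 5L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 6L)
  expect_equal(runs$start, 700L)
  runs2 <- score_runs(sc, threshold = 2, min_snps = 4L)
  expect_equal(nrow(runs2), 2L)
})

test_that("an extended derived haplotype drives the raw iHS negative", {
  # derived carriers share one long haplotype; ancestral carriers are a
  # mosaic that decays quickly on both sides of the core
  set.seed(97)
  m <- 41; core <- 21L
  der <- matrix(rep(rbinom(m, 1, 0.5), each = 12), 12, m)
  anc <- matrix(rbinom(12 * m, 1, 0.5), 12, m)
  hap <- rbind(der, anc)
  hap[1:12, core] <- 1L
  hap[13:24, core] <- 0L
  H <- haplotype_matrix(hap, variant_table(
    paste0("v", 1:m), "1", 1:m * 1000L, "A", "G",
    ancestral = ifelse(seq_len(m) == core, "A", NA)))
  sc <- ihs_scan(H, min_bin = 1, keep_truncated = TRUE)
  expect_lt(sc$raw[sc$id == paste0("v", core)], -1)
  expect_gt(sc$ihh_der[sc$id == paste0("v", core)],
            sc$ihh_anc[sc$id == paste0("v", core)])
})
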