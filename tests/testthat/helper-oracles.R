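# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths / parameterizations than R/.

# Benjamini-Hochberg step-up, transcribed directly from the procedure
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranked <- p[ord] * m / (m:1)
  q <- cummin(ranked)
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Weir & Cockerham (1984) variance components, general-r transcription
# from genotype counts per population: list of c(n_AA, n_Aa, n_aa)
oracle_wc_fst <- function(pop_counts) {
  r <- length(pop_counts)
  n_i <- vapply(pop_counts, sum, numeric(1))
  p_i <- vapply(pop_counts, function(x) (x[2] + 2 * x[3]) / (2 * sum(x)),
                numeric(1))
  h_i <- vapply(pop_counts, function(x) x[2] / sum(x), numeric(1))
  nbar <- mean(n_i)
  C2 <- sum((n_i - nbar)^2) / ((r - 1) * nbar^2) # squared CV of sizes
  nc <- nbar * (1 - C2 / r * (r - 1))            # = (r*nbar - sum n^2/(r nbar))/(r-1)
  # use the direct definition to avoid algebra mistakes:
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Tajima's D by explicit pairwise-difference enumeration over haplotypes
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  diffs <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- diffs + sum(hap[i, ] != hap[j, ])
      npairs <- npairs + 1
    }
  }
  pi <- diffs / npairs
  k <- colSums(hap)
  S <- sum(k > 0 & k < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH by brute-force string enumeration of extended haplotypes
# (returns the EHH value at each marker index in `targets`, and the iHH by
# trapezoid over genetic positions from the core through all markers up to
# the stopping rule applied by the caller)
oracle_ehh_at <- function(hap, carrier_rows, core, target) {
  stopifnot(target != core)
  rng <- if (target > core) (core + 1):target else (core - 1):target
  strs <- apply(hap[carrier_rows, rng, drop = FALSE], 1, paste, collapse = "")
  counts <- table(strs)
  nc <- length(carrier_rows)
  sum(counts * (counts - 1)) / (nc * (nc - 1))
}

# 2-locus haplotype-frequency MLE by profile grid search over p_AB
# (allele-frequency margins are fixed at their observed values, which the
# multinomial MLE satisfies); g is an n x 2 dosage matrix
oracle_em_2locus <- function(g, step = 1e-5) {
  pA <- mean(g[, 1]) / 2
  pB <- mean(g[, 2]) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  tab <- table(factor(g[, 1], 0:2), factor(g[, 2], 0:2))
  ll <- vapply(grid, function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    cell <- matrix(c(
      pab^2, 2 * pab * paB, paB^2,
      2 * pab * pAb, 2 * pAB * pab + 2 * pAb * paB, 2 * paB * pAB,
      pAb^2, 2 * pAb * pAB, pAB^2), 3, 3, byrow = TRUE)
    cell[cell <= 0] <- NA
    s <- sum(tab * log(cell), na.rm = TRUE)
    if (any(tab > 0 & is.na(cell))) -Inf else s
  }, numeric(1))
  pAB <- grid[which.max(ll)]
  c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
}

# Wigginton et al. exact Hardy-Weinberg test
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * min(n_AA, n_aa) # rare allele copies (use minor)
  rare <- min(n_Aa + 2 * n_AA, n_Aa + 2 * n_aa)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # recurrence from the mid het count
  mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      het <- hets[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c /
        ((het + 2) * (het + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      het <- hets[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i - 1] <- probs[i] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- min(n_Aa, rare)
  sum(probs[probs <= probs[which(hets == n_Aa)] + 1e-12])
}

# random small genotype matrix fixture
rand_genotypes <- function(n, m, seed, miss = 0, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss > 0) dos[runif(n * m) < miss] <- NA
  genotype_matrix(dos, variant_table(paste0("v", seq_len(m)), "1",
                                     seq_len(m) * 1000L, "A", "G"))
}

# random small phased panel fixture
rand_panel <- function(n_hap, m, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  hap <- sapply(p, function(pp) rbinom(n_hap, 1, pp))
  haplotype_matrix(hap, variant_table(paste0("v", seq_len(m)), "1",
                                      sort(sample.int(m * 2000L, m)),
                                      "A", "G"))
}
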