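#' Extended haplotype homozygosity curve around a core variant
#'
#' EHH at marker `x` is the probability that two randomly drawn core-allele
#' carriers are identical at every marker from the core out to `x`:
#' `EHH(x) = sum_h n_h (n_h - 1) / (n_c (n_c - 1))` over the extended
#' haplotype classes `h` among the `n_c` carriers. The curve is computed
#' outward in both directions and stops once it decays below `cutoff`, at the
#' chromosome end, or at an inter-marker gap larger than `max_gap_bp`; a side
#' that ends before decaying below the cutoff sets the `truncated` flag.
#' iHH is the trapezoidal integral of the curve over genetic distance (cM),
#' summed over both sides.
#'
#' @param H A [haplotype_matrix()].
#' @param core Core variant id or column index.
#' @param allele Core allele defining the carrier set: `1`/`0` (alt/ref
#'   haplotype coding) or `NULL` for all haplotypes (whole-sample EHH, as
#'   used by the cross-population statistic).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap_bp Largest tolerated gap between adjacent markers.
#' @return Object of class `ehh_profile`: list with `core`, `allele`, `n_c`,
#'   `curve` (tibble `position`, `genetic_pos`, `side`, `ehh`, including the
#'   core point on both sides), `ihh`, `truncated`.
#' @export
ehh_curve <- function(H, core, allele = 1L, cutoff = 0.05,
                      max_gap_bp = 200000L) {
  stopifnot(inherits(H, "haplotype_matrix"))
  if (is.character(core)) core <- match(core, H$variants$id)
  assert_that(!is.na(core), "unknown core variant")
  rows <- if (is.null(allele)) seq_len(nrow(H$hap))
  else which(H$hap[, core] == allele)
  assert_that(length(rows) >= 2L,
              "core allele must be carried by at least 2 haplotypes")
  pos <- H$variants$pos
  gpos <- H$variants$genetic_pos
  left <- ehh_side(H$hap, rows, core, -1L, cutoff, max_gap_bp, pos)
  right <- ehh_side(H$hap, rows, core, 1L, cutoff, max_gap_bp, pos)
  curve <- dplyr::bind_rows(
    tibble::tibble(position = pos[rev(c(core, left$idx))],
                   genetic_pos = gpos[rev(c(core, left$idx))],
                   side = "left", ehh = rev(c(1, left$ehh))),
    tibble::tibble(position = pos[c(core, right$idx)],
                   genetic_pos = gpos[c(core, right$idx)],
                   side = "right", ehh = c(1, right$ehh))
  )
  ihh <- trapezoid_ihh(gpos[c(core, left$idx)], c(1, left$ehh)) +
    trapezoid_ihh(gpos[c(core, right$idx)], c(1, right$ehh))
  structure(list(core = H$variants$id[core], allele = allele,
                 n_c = length(rows), curve = curve, ihh = ihh,
                 truncated = left$truncated || right$truncated),
            class = "ehh_profile")
}

# walk outward from the core refining haplotype classes; returns visited
# marker indices, EHH values, and whether the walk hit an end/gap before
# decaying below the cutoff
ehh_side <- function(hap, rows, core, dir, cutoff, max_gap, pos) {
  idxs <- if (dir > 0L) {
    if (core < ncol(hap)) (core + 1L):ncol(hap) else integer()
  } else {
    if (core > 1L) (core - 1L):1L else integer()
  }
  nc <- length(rows)
  denom <- nc * (nc - 1)
  cls <- rep(1L, nc)
  out_idx <- integer(); out_ehh <- numeric()
  truncated <- TRUE
  prev <- pos[core]
  for (j in idxs) {
    if (abs(pos[j] - prev) > max_gap) break
    cls <- cls * 2L + hap[rows, j]
    cls <- match(cls, unique(cls))
    tab <- tabulate(cls)
    e <- sum(tab * (tab - 1)) / denom
    out_idx <- c(out_idx, j)
    out_ehh <- c(out_ehh, e)
    prev <- pos[j]
    if (e < cutoff) { truncated <- FALSE; break }
  }
  if (length(idxs) == 0L) truncated <- TRUE
  list(idx = out_idx, ehh = out_ehh, truncated = truncated)
}

trapezoid_ihh <- function(g, e) {
  if (length(g) < 2L) return(0)
  sum(0.5 * (e[-1L] + e[-length(e)]) * abs(diff(g)))
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat(sprintf("<ehh_profile> core %s (allele %s), %d carriers, iHH = %.4f cM%s\n",
              x$core, if (is.null(x$allele)) "all" else x$allele, x$n_c,
              x$ihh, if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

# fast iHH (no curve materialization) for the scan loops; returns
# c(ihh, truncated) with NA when the carrier set is degenerate
ihh_fast <- function(hap, rows, core, pos, gpos, cutoff, max_gap) {
  nc <- length(rows)
  if (nc < 2L) return(c(NA_real_, NA))
  denom <- nc * (nc - 1)
  ihh <- 0
  truncated <- FALSE
  for (dir in c(-1L, 1L)) {
    idxs <- if (dir > 0L) {
      if (core < ncol(hap)) (core + 1L):ncol(hap) else integer()
    } else {
      if (core > 1L) (core - 1L):1L else integer()
    }
    cls <- rep(1L, nc)
    n_cls <- 1L
    prev_pos <- pos[core]
    prev_g <- gpos[core]
    prev_e <- 1
    decayed <- FALSE
    for (j in idxs) {
      if (abs(pos[j] - prev_pos) > max_gap) break
      key <- 2L * cls + hap[rows, j]     # in 2..2*n_cls+1
      tab <- tabulate(key, nbins = 2L * n_cls + 1L)
      e <- sum(tab * (tab - 1L)) / denom
      ihh <- ihh + 0.5 * (prev_e + e) * abs(gpos[j] - prev_g)
      prev_pos <- pos[j]; prev_g <- gpos[j]; prev_e <- e
      if (e < cutoff) { decayed <- TRUE; break }
      # relabel classes 1..k for the next step
      map <- integer(2L * n_cls + 1L)
      nz <- which(tab > 0L)
      map[nz] <- seq_along(nz)
      cls <- map[key]
      n_cls <- length(nz)
    }
    if (!decayed) truncated <- TRUE
  }
  c(ihh, truncated)
}

#' Integrated haplotype score (iHS) scan
#'
#' For each scored SNP, computes the integrated EHH of the ancestral and of
#' the derived allele and their log-ratio `raw = ln(iHH_anc / iHH_der)`,
#' then standardizes within derived-allele-frequency bins (equal-width,
#' `n_bins` over `[0, 1]`; bins holding fewer than `min_bin` SNPs are merged
#' with their nearest neighbor). SNPs without ancestral-allele information
#' are skipped and counted; cores whose EHH never decays below the cutoff
#' before truncation are excluded unless `keep_truncated`.
#'
#' @param H A [haplotype_matrix()] with ancestral alleles in
#'   `H$variants$ancestral` (or supplied via `ancestral`).
#' @param ancestral Optional tibble (`variant_id`, `allele`) overriding the
#'   variant table's ancestral alleles.
#' @param maf_min Minor-allele-frequency cutoff for scored SNPs.
#' @param n_bins Number of equal-width derived-frequency bins.
#' @param min_bin Minimum SNPs per bin before merging.
#' @param cutoff,max_gap_bp Passed to [ehh_curve()].
#' @param keep_truncated Score cores truncated at a border/gap.
#' @return Tibble of class `scan_scores`: `id`, `pos`, `derived_freq`,
#'   `ihh_anc`, `ihh_der`, `raw`, `bin`, `score` (standardized iHS), with
#'   attributes `n_skipped_no_ancestral` and `n_skipped_truncated`.
#' @export
ihs_scan <- function(H, ancestral = NULL, maf_min = 0.05, n_bins = 20L,
                     min_bin = 10L, cutoff = 0.05, max_gap_bp = 200000L,
                     keep_truncated = FALSE) {
  stopifnot(inherits(H, "haplotype_matrix"))
  v <- H$variants
  anc_allele <- v$ancestral
  if (!is.null(ancestral)) {
    anc_allele <- ancestral$allele[match(v$id, ancestral$variant_id)]
  }
  anc01 <- ifelse(is.na(anc_allele), NA_integer_,
                  ifelse(anc_allele == v$alt, 1L, 0L))
  freq_alt <- unname(colMeans(H$hap))
  maf <- pmin(freq_alt, 1 - freq_alt)
  n_no_anc <- sum(is.na(anc01) & maf >= maf_min)
  cand <- which(!is.na(anc01) & maf >= maf_min)

  pos <- v$pos; gpos <- v$genetic_pos
  stats_m <- vapply(cand, function(j) {
    anc <- anc01[j]
    ia <- ihh_fast(H$hap, which(H$hap[, j] == anc), j, pos, gpos,
                   cutoff, max_gap_bp)
    id_ <- ihh_fast(H$hap, which(H$hap[, j] != anc), j, pos, gpos,
                    cutoff, max_gap_bp)
    c(ia[1L], id_[1L], ia[2L], id_[2L])
  }, numeric(4L))
  rows <- tibble::tibble(
    id = v$id[cand], pos = pos[cand],
    derived_freq = ifelse(anc01[cand] == 0L, freq_alt[cand],
                          1 - freq_alt[cand]),
    ihh_anc = stats_m[1L, ], ihh_der = stats_m[2L, ],
    truncated = stats_m[3L, ] > 0 | stats_m[4L, ] > 0)
  n_trunc <- 0L
  if (nrow(rows) > 0L && !keep_truncated) {
    n_trunc <- sum(rows$truncated, na.rm = TRUE)
    rows <- rows[!rows$truncated | is.na(rows$truncated), , drop = FALSE]
  }
  rows <- rows[!is.na(rows$ihh_anc) & !is.na(rows$ihh_der) &
                 rows$ihh_anc > 0 & rows$ihh_der > 0, , drop = FALSE]
  rows$raw <- log(rows$ihh_anc / rows$ihh_der)

  # equal-width derived-frequency bins with small-bin merging
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(rows$derived_freq, edges,
                                rightmost.closed = TRUE), 1L), n_bins)
  bin <- merge_small_bins(bin, min_bin)
  rows$bin <- bin
  rows$score <- NA_real_
  for (b in unique(bin)) {
    i <- bin == b
    m <- mean(rows$raw[i]); s <- sd(rows$raw[i])
    rows$score[i] <- if (is.na(s) || s == 0) 0 else (rows$raw[i] - m) / s
  }
  rows$truncated <- NULL
  attr(rows, "n_skipped_no_ancestral") <- n_no_anc
  attr(rows, "n_skipped_truncated") <- n_trunc
  class(rows) <- c("scan_scores", class(rows))
  rows
}

merge_small_bins <- function(bin, min_bin) {
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (length(small) == 0L || length(tab) == 1L) break
    b <- as.integer(small[1L])
    others <- as.integer(names(tab))[as.integer(names(tab)) != b]
    nb <- others[which.min(abs(others - b))]
    bin[bin == b] <- nb
  }
  bin
}

#' Cross-population EHH (xpEHH) scan
#'
#' For each SNP shared by the two phased panels, computes the whole-sample
#' integrated EHH in each population and the log-ratio
#' `raw = ln(iHH_A / iHH_B)`, standardized genome-wide by the scan mean and
#' standard deviation. Positive scores mean longer haplotypes (candidate
#' selection) in population A. Ancestral-allele information is not needed.
#' SNPs with an undefined iHH in either population are skipped and counted.
#' Scores beyond `|2|` are the conventional selection flag.
#'
#' @param H_popA,H_popB [haplotype_matrix()] panels over the same variants.
#' @param maf_min Minor-allele-frequency cutoff computed on the combined
#'   panels (shared policy).
#' @param cutoff,max_gap_bp Passed to [ehh_curve()].
#' @return Tibble of class `scan_scores`: `id`, `pos`, `ihh_a`, `ihh_b`,
#'   `raw`, `score` (standardized xpEHH), with attribute `n_skipped`. When
#'   the raw scores are constant (e.g. identical panels) standardization is
#'   degenerate: scores are set to 0 and the attribute
#'   `constant_raw = TRUE` is set.
#' @export
xpehh_scan <- function(H_popA, H_popB, maf_min = 0.05, cutoff = 0.05,
                       max_gap_bp = 200000L) {
  stopifnot(inherits(H_popA, "haplotype_matrix"),
            inherits(H_popB, "haplotype_matrix"))
  assert_that(identical(H_popA$variants$id, H_popB$variants$id),
              "panels must share the same variant set")
  v <- H_popA$variants
  freq <- unname(colSums(H_popA$hap) + colSums(H_popB$hap)) /
    (nrow(H_popA$hap) + nrow(H_popB$hap))
  maf <- pmin(freq, 1 - freq)
  cand <- which(maf >= maf_min)
  pos <- v$pos; gpos <- v$genetic_pos
  rowsA <- seq_len(nrow(H_popA$hap))
  rowsB <- seq_len(nrow(H_popB$hap))
  stats_m <- vapply(cand, function(j) {
    c(ihh_fast(H_popA$hap, rowsA, j, pos, gpos, cutoff, max_gap_bp)[1L],
      ihh_fast(H_popB$hap, rowsB, j, pos, gpos, cutoff, max_gap_bp)[1L])
  }, numeric(2L))
  rows <- tibble::tibble(id = v$id[cand], pos = pos[cand],
                         ihh_a = stats_m[1L, ], ihh_b = stats_m[2L, ])
  n_skip <- sum(is.na(rows$ihh_a) | is.na(rows$ihh_b) |
                  rows$ihh_a <= 0 | rows$ihh_b <= 0)
  rows <- rows[!is.na(rows$ihh_a) & !is.na(rows$ihh_b) &
                 rows$ihh_a > 0 & rows$ihh_b > 0, , drop = FALSE]
  rows$raw <- log(rows$ihh_a / rows$ihh_b)
  s <- sd(rows$raw)
  constant <- is.na(s) || s < 1e-12
  rows$score <- if (constant) 0 else (rows$raw - mean(rows$raw)) / s
  attr(rows, "n_skipped") <- n_skip
  attr(rows, "constant_raw") <- constant
  class(rows) <- c("scan_scores", class(rows))
  rows
}

#' Contiguous runs of extreme scan scores
#'
#' Finds runs of at least `min_snps` consecutive SNPs whose absolute
#' standardized score exceeds `threshold` — the way candidate regions are
#' called from an xpEHH scan.
#'
#' @param scores A `scan_scores` tibble (needs `pos` and `score`).
#' @param threshold Absolute score threshold (conventionally 2).
#' @param min_snps Minimum run length.
#' @return Tibble: `start`, `end`, `n_snps`, `max_abs_score`.
#' @export
score_runs <- function(scores, threshold = 2, min_snps = 5L) {
  s <- scores[order(scores$pos), , drop = FALSE]
  ext <- abs(s$score) > threshold
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_snps
  purrr::map_dfr(which(keep), function(i) {
    ii <- starts[i]:ends[i]
    tibble::tibble(start = s$pos[ii[1L]], end = s$pos[ii[length(ii)]],
                   n_snps = length(ii),
                   max_abs_score = max(abs(s$score[ii])))
  })
}
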