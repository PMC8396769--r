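#' Variant metadata table
#'
#' Builds the per-variant metadata tibble used by [genotype_matrix()] and
#' [haplotype_matrix()]. Coordinates are 1-based, as in VCF; any half-open
#' window arithmetic elsewhere in the package converts explicitly.
#'
#' @param id Variant identifiers (rsID or synthetic labels).
#' @param chrom Chromosome labels.
#' @param pos 1-based physical positions (integer, >= 1).
#' @param ref,alt Single-character reference / alternate alleles; `ref != alt`.
#' @param ancestral Optional ancestral alleles; each must equal `ref`, `alt`,
#'   or be `NA` (unknown).
#' @param annotation Optional functional category per variant
#'   (`"exonic"`, `"intronic"`, `"intergenic"`, `"regulatory"`, `"other"`).
#' @param genetic_pos Optional genetic-map positions in cM. Defaults to
#'   `pos * cm_per_mb / 1e6` (a flat map, the standard surrogate when no
#'   recombination map is available).
#' @param cm_per_mb Flat genetic-map rate used when `genetic_pos` is absent.
#'
#' @return A tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ancestral`, `annotation`, `genetic_pos`.
#' @export
variant_table <- function(id, chrom, pos, ref, alt,
                          ancestral = NA_character_,
                          annotation = NA_character_,
                          genetic_pos = NULL,
                          cm_per_mb = 1) {
  pos <- as.integer(pos)
  assert_that(all(pos >= 1L), "variant positions must be 1-based (>= 1)")
  assert_that(!any(ref == alt), "ref and alt alleles must differ")
  n <- length(id)
  ancestral <- rep_len(as.character(ancestral), n)
  bad_aa <- !is.na(ancestral) & ancestral != ref & ancestral != alt
  assert_that(!any(bad_aa), "ancestral allele must be ref, alt, or NA")
  if (is.null(genetic_pos)) genetic_pos <- pos * cm_per_mb / 1e6
  tibble::tibble(
    id = as.character(id), chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    ancestral = ancestral,
    annotation = rep_len(as.character(annotation), n),
    genetic_pos = as.numeric(genetic_pos)
  )
}

#' Diploid genotype container
#'
#' Holds alt-allele dosages (0/1/2, `NA` = missing) for `n` samples at `m`
#' biallelic SNPs, together with variant metadata.
#'
#' @param dosage `n x m` integer matrix of alt-allele counts; `NA` for missing
#'   calls. Row/column names are taken from `samples` / `variants$id`.
#' @param variants Variant metadata from [variant_table()] (one row per column
#'   of `dosage`).
#' @param samples Character vector of sample ids (one per row of `dosage`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  assert_that(nrow(variants) == ncol(dosage),
              "variants must have one row per dosage column")
  assert_that(length(samples) == nrow(dosage),
              "samples must have one id per dosage row")
  assert_that(all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)),
              "dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(samples, variants$id)
  structure(list(dosage = dosage, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' Phased haplotype container
#'
#' Holds a `2n x m` binary matrix of phased haplotypes (1 = alt allele), with
#' no missing entries, columns strictly increasing in position.
#'
#' @param hap `2n x m` 0/1 matrix; consecutive row pairs belong to one sample.
#' @param variants Variant metadata from [variant_table()].
#' @param sample_of_haplotype Sample id for each haplotype row (length `2n`).
#'
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(hap, variants,
                             sample_of_haplotype = NULL) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  assert_that(!anyNA(hap), "haplotype matrix must have no missing entries")
  assert_that(all(hap %in% c(0L, 1L)), "haplotype entries must be 0/1")
  assert_that(nrow(hap) %% 2L == 0L, "haplotype row count must be even")
  assert_that(nrow(variants) == ncol(hap),
              "variants must have one row per haplotype column")
  assert_that(all(diff(variants$pos) > 0) || ncol(hap) <= 1L,
              "variant positions must be strictly increasing")
  if (is.null(sample_of_haplotype)) {
    sample_of_haplotype <- rep(paste0("S", seq_len(nrow(hap) / 2L)), each = 2L)
  }
  assert_that(length(sample_of_haplotype) == nrow(hap),
              "sample_of_haplotype must have one entry per haplotype row")
  dimnames(hap) <- list(NULL, variants$id)
  structure(list(hap = hap, variants = variants,
                 sample_of_haplotype = as.character(sample_of_haplotype)),
            class = "haplotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.1f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes (%d samples) x %d variants\n",
              nrow(x$hap), nrow(x$hap) / 2L, nrow(x$variants)))
  invisible(x)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' @param H A [haplotype_matrix()].
#' @return A [genotype_matrix()] with dosage = sum of the two haplotypes per
#'   sample.
#' @export
as_genotype_matrix <- function(H) {
  stopifnot(inherits(H, "haplotype_matrix"))
  n <- nrow(H$hap) / 2L
  dos <- H$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(dos, H$variants,
                  samples = H$sample_of_haplotype[seq(1L, 2L * n, by = 2L)])
}

#' Subset a genotype matrix
#'
#' @param G A [genotype_matrix()].
#' @param variants Variant ids or column indices to keep (default all).
#' @param samples Sample ids or row indices to keep (default all).
#' @return A [genotype_matrix()] restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, variants = NULL, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_len(nrow(G$variants)) else {
    if (is.character(variants)) match(variants, G$variants$id) else variants
  }
  assert_that(!anyNA(vi), "unknown variant id in subset")
  si <- if (is.null(samples)) seq_along(G$samples) else {
    if (is.character(samples)) match(samples, G$samples) else samples
  }
  assert_that(!anyNA(si), "unknown sample id in subset")
  genotype_matrix(G$dosage[si, vi, drop = FALSE],
                  G$variants[vi, , drop = FALSE],
                  samples = G$samples[si])
}

#' Read a sample metadata table
#'
#' Reads the tab-separated metadata format used throughout the package:
#' columns `sample_id`, `status` (`case`/`control`), `sex`, `age`, `site`,
#' and optional `ancestry_afr`, `ancestry_eur`, `ancestry_nam` proportions.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble, with ancestry proportions checked to be non-negative and
#'   to sum to 1 (tolerance 1e-6) where present.
#' @export
read_sample_table <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  assert_that(all(c("sample_id", "status") %in% names(df)),
              "sample table needs at least sample_id and status columns")
  assert_that(all(df$status %in% c("case", "control")),
              "status must be 'case' or 'control'")
  qcols <- intersect(c("ancestry_afr", "ancestry_eur", "ancestry_nam"),
                     names(df))
  if (length(qcols) == 3L) {
    q <- as.matrix(df[qcols])
    ok <- apply(q, 1L, function(r) all(is.na(r)) ||
                  (all(r >= 0) && abs(sum(r) - 1) <= 1e-6))
    assert_that(all(ok), "ancestry proportions must be >= 0 and sum to 1")
  }
  df
}

#' Write a sample metadata table
#'
#' @param samples A data frame as produced by [read_sample_table()] or
#'   [simulate_admixed_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
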