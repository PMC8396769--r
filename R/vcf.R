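#' Read genotypes (and phased haplotypes) from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into the package's genotype
#' container. Only biallelic SNPs are used; multi-allelic or indel records are
#' skipped and counted, not split. If every GT entry in the file is phased
#' (`|` separator) and fully called, a phased [haplotype_matrix()] is returned
#' alongside the dosage matrix. The ancestral allele is read from the `AA`
#' INFO tag when present; values matching neither allele are treated as
#' unknown.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param region Optional `"chrom:start-end"` string restricting the variants
#'   kept (1-based, inclusive).
#' @param cm_per_mb Flat genetic-map rate used to fill `genetic_pos`.
#' @param verbose Emit a message with the number of skipped records.
#'
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `haplotypes` ([haplotype_matrix()] or `NULL` when the file is not fully
#'   phased), and `n_skipped` (records dropped as non-biallelic-SNP).
#' @export
read_vcf <- function(path, region = NULL, cm_per_mb = 1, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort(sprintf("no variant records in %s", path))
  gt_raw <- v@gt
  assert_that(!is.null(gt_raw) && ncol(gt_raw) >= 2L,
              sprintf("VCF %s has no genotype (GT) columns", path))

  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (verbose && n_skipped > 0L)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                    n_skipped))
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    assert_that(length(m) == 4L, "region must be 'chrom:start-end'")
    pos <- as.integer(fix$POS)
    in_r <- fix$CHROM == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    fix <- fix[in_r, , drop = FALSE]
    gt_raw <- gt_raw[in_r, , drop = FALSE]
  }
  assert_that(nrow(fix) > 0L, "no biallelic SNP records to read")

  aa <- sub(".*(?:^|;)AA=([^;]*).*", "\\1", fix$INFO)
  aa[!grepl("(^|;)AA=", fix$INFO)] <- NA_character_
  aa <- toupper(aa)
  aa[!is.na(aa) & aa != fix$REF & aa != fix$ALT] <- NA_character_

  ids <- fix$ID
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix$CHROM[miss_id], "_", fix$POS[miss_id])
  variants <- variant_table(ids, fix$CHROM, as.integer(fix$POS),
                            fix$REF, fix$ALT, ancestral = aa,
                            cm_per_mb = cm_per_mb)

  samples <- colnames(gt_raw)[-1L]
  # GT is the first colon-separated field (sub() drops dim; restore it)
  gt <- matrix(sub(":.*$", "", gt_raw[, -1L, drop = FALSE]),
               nrow = nrow(gt_raw))
  gt[is.na(gt)] <- "./."   # vcfR reads fully-missing GT as NA
  malformed <- matrix(!grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt),
                      nrow = nrow(gt))
  if (any(malformed)) {
    w <- which(malformed, arr.ind = TRUE)[1L, ]
    abort(sprintf("malformed GT '%s' at variant %s, sample %s",
                  gt[w[1], w[2]], variants$id[w[1]], samples[w[2]]))
  }
  haploid <- matrix(!grepl("[/|]", gt), nrow = nrow(gt))
  if (any(haploid)) {
    w <- which(haploid, arr.ind = TRUE)[1L, ]
    abort(sprintf("mixed/non-diploid GT '%s' at variant %s, sample %s",
                  gt[w[1], w[2]], variants$id[w[1]], samples[w[2]]))
  }
  a1 <- sub("^(\\.|[0-9]+)[/|].*$", "\\1", gt)
  a2 <- sub("^.*[/|](\\.|[0-9]+)$", "\\1", gt)
  missing <- a1 == "." | a2 == "."
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[!missing] <- as.integer(a1[!missing]) + as.integer(a2[!missing])
  bad <- !is.na(dos) & (dos < 0L | dos > 2L |
                          (!missing & (a1 > "1" | a2 > "1")))
  assert_that(!any(bad), "GT allele index other than 0/1 in biallelic record")

  G <- genotype_matrix(t(dos), variants, samples = samples)

  H <- NULL
  phased_all <- all(grepl("|", gt, fixed = TRUE)) && !any(missing)
  if (phased_all && all(diff(variants$pos) > 0)) {
    hap <- matrix(0L, 2L * length(samples), nrow(variants))
    hap[seq(1L, nrow(hap), 2L), ] <- t(matrix(as.integer(a1), nrow(gt)))
    hap[seq(2L, nrow(hap), 2L), ] <- t(matrix(as.integer(a2), nrow(gt)))
    H <- haplotype_matrix(hap, variants,
                          sample_of_haplotype = rep(samples, each = 2L))
  }
  list(genotypes = G, haplotypes = H, n_skipped = n_skipped)
}

#' Write genotypes or phased haplotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT column. Phased input uses
#' the `|` separator; unphased dosages use `/` (dosage 1 becomes `0/1`).
#' The `AA` INFO tag is written for variants whose ancestral allele is known.
#'
#' @param G A [genotype_matrix()] or [haplotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  phased <- inherits(G, "haplotype_matrix")
  assert_that(phased || inherits(G, "genotype_matrix"),
              "G must be a genotype_matrix or haplotype_matrix")
  v <- G$variants
  info <- ifelse(is.na(v$ancestral), ".", paste0("AA=", v$ancestral))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (phased) {
    samples <- unique(G$sample_of_haplotype)
    i1 <- seq(1L, nrow(G$hap), 2L)
    gt <- matrix(paste0(G$hap[i1, , drop = FALSE], "|",
                        G$hap[i1 + 1L, , drop = FALSE]),
                 nrow = length(i1))
    gt <- t(gt)
  } else {
    samples <- G$samples
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(code[as.character(t(G$dosage))], nrow = nrow(v))
    gt[is.na(gt)] <- "./."
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(v) > 0L) {
    body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info,
                  "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-variant allele and call-rate summary
#'
#' @param G A [genotype_matrix()].
#' @return A tibble with one row per variant: genotype counts (`n_ref_hom`,
#'   `n_het`, `n_alt_hom`), `n_called`, `call_rate`, `alt_freq` (alt alleles
#'   over `2 * n_called`), `maf = min(alt_freq, 1 - alt_freq)`, and a
#'   `defined` flag that is `FALSE` where every call is missing.
#' @export
allele_summary <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  n <- nrow(d)
  n0 <- unname(colSums(d == 0L, na.rm = TRUE))
  n1 <- unname(colSums(d == 1L, na.rm = TRUE))
  n2 <- unname(colSums(d == 2L, na.rm = TRUE))
  nc <- n0 + n1 + n2
  af <- ifelse(nc > 0L, (n1 + 2 * n2) / (2 * nc), NA_real_)
  tibble::tibble(
    id = G$variants$id, chrom = G$variants$chrom, pos = G$variants$pos,
    n_ref_hom = n0, n_het = n1, n_alt_hom = n2,
    n_called = nc, call_rate = nc / n,
    alt_freq = af, maf = pmin(af, 1 - af),
    defined = nc > 0L
  )
}
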