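#' Build a reference panel tibble
#'
#' A reference panel records, per SNP, the identifier, position, alleles and
#' minor allele frequency; heterozygosity \eqn{H_j = 2 p_j (1 - p_j)} is
#' derived and carried along because it scales per-allele effects into
#' per-genotype variance throughout the model.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chrom Chromosome labels (recycled if scalar).
#' @param pos Integer base-pair positions.
#' @param allele_eff,allele_oth Effect/other alleles (A, C, G, T).
#' @param maf Minor allele frequencies, in (0, 0.5].
#' @return A tibble of class `reference_panel` with columns `snp_id`,
#'   `chrom`, `pos`, `allele_eff`, `allele_oth`, `maf`, `het`.
#' @examples
#' reference_panel(c("rs1", "rs2"), 1, c(100L, 200L), c("A", "C"),
#'                 c("G", "T"), c(0.2, 0.5))
#' @export
reference_panel <- function(snp_id, chrom, pos, allele_eff, allele_oth, maf) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) abort("`snp_id` must be unique.")
  if (any(maf <= 0 | maf > 0.5)) abort("`maf` must lie in (0, 0.5].")
  out <- tibble(snp_id = snp_id,
                chrom = as.character(chrom),
                pos = as.integer(pos),
                allele_eff = toupper(allele_eff),
                allele_oth = toupper(allele_oth),
                maf = as.numeric(maf),
                het = 2 * maf * (1 - maf))
  class(out) <- c("reference_panel", class(out))
  out
}

#' Total heterozygosity of a reference panel
#'
#' \eqn{H_{total} = \sum_j 2 p_j (1 - p_j)}, the normalizing constant that
#' converts per-variant effect variance into SNP heritability.
#'
#' @param panel A [reference_panel()].
#' @return A single number.
#' @export
total_heterozygosity <- function(panel) sum(panel$het)

# ---- PLINK bed/bim/fam ------------------------------------------------------

#' Read a PLINK binary genotype fileset
#'
#' Reads `<prefix>.bed` / `.bim` / `.fam` (SNP-major binary format) and
#' returns 0/1/2 dosages of the *minor* allele (the bim A1 allele under the
#' usual PLINK convention), with missing genotypes as `NA`.
#'
#' @param prefix Path prefix of the fileset (no extension).
#' @return A list with `genotypes` (n x m integer matrix, column names =
#'   SNP ids), `panel` (a [reference_panel()] with MAF computed from the
#'   genotypes) and `fam` (a tibble of sample records).
#' @export
read_plink <- function(prefix) {
  bim <- readr::read_tsv(paste0(prefix, ".bim"),
                         col_names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                         col_types = "ccdicc", progress = FALSE)
  fam <- readr::read_table(paste0(prefix, ".fam"),
                           col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           col_types = "cccccc", progress = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    abort("not a SNP-major PLINK bed file (bad magic bytes).")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) abort("bed file truncated.")
  # 2-bit codes per sample: 00 = hom A1 (2), 01 = missing, 10 = het, 11 = hom A2 (0)
  lut <- matrix(NA_integer_, 256, 4)
  codes <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    lut[b + 1, ] <- codes[as.character(c(b %% 4, (b %/% 4) %% 4,
                                         (b %/% 16) %% 4, (b %/% 64) %% 4))]
  }
  bmat <- matrix(as.integer(raw), nrow = bytes_per_snp, ncol = m)
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    g <- as.vector(t(lut[bmat[, j] + 1L, , drop = FALSE]))
    geno[, j] <- g[seq_len(n)]
  }
  colnames(geno) <- bim$snp_id
  p_a1 <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(pmax(p_a1, 1e-9), 1 - 1e-9)
  maf <- pmin(maf, 1 - maf)
  panel <- reference_panel(bim$snp_id, bim$chrom, bim$pos, bim$a1, bim$a2, maf)
  list(genotypes = geno, panel = panel, fam = fam)
}

#' Write a PLINK binary genotype fileset
#'
#' Inverse of [read_plink()]; used to materialize synthetic panels for tools
#' and round-trip tests. `genotypes` holds 0/1/2 minor-allele dosages.
#'
#' @param genotypes n x m integer matrix (NA = missing).
#' @param panel A [reference_panel()] aligned to the columns.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, panel, prefix) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(m == nrow(panel))
  bim <- data.frame(panel$chrom, panel$snp_id, 0, panel$pos,
                    panel$allele_eff, panel$allele_oth)
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE, progress = FALSE)
  fam <- data.frame(paste0("F", seq_len(n)), paste0("I", seq_len(n)),
                    0, 0, 0, -9)
  readr::write_tsv(fam, paste0(prefix, ".fam"), col_names = FALSE, progress = FALSE)
  code <- function(g) { # dosage -> 2-bit code
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2L] <- 0L
    out[!is.na(g) & g == 1L] <- 2L
    out[!is.na(g) & g == 0L] <- 3L
    out
  }
  pad <- (-n) %% 4
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    cc <- c(code(genotypes[, j]), rep(3L, pad))
    quads <- matrix(cc, nrow = 4)
    bytes <- quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] + 64L * quads[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
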