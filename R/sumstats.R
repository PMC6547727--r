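#' Read GWAS summary statistics
#'
#' Reads LDSC-style whitespace/tab-delimited summary statistics and derives a
#' signed z-score for every row: a `Z` column is passed through; otherwise
#' `z = beta / se`; otherwise a signed p-value is inverted,
#' `z = sign(beta) * qnorm(p/2, lower.tail = FALSE)`. The provenance of each
#' derived z is recorded in `z_source`.
#'
#' @param path Path to the text file (any whitespace delimiter).
#' @param column_map Named list mapping the roles `snp_id`, `a1`, `a2`, `z`,
#'   `beta`, `se`, `p`, `n`, `info` to column names in the file. Roles absent
#'   from the map are auto-detected from common header names (SNP/RSID, A1,
#'   A2, Z, BETA/B, SE, P/PVAL, N, INFO).
#' @param n Scalar sample size used when the file has no N column.
#' @return A tibble with columns `snp_id`, `a1`, `a2`, `z`, `n`, `z_source`
#'   and, when present, `info`. Unparsable rows (missing/non-finite z inputs)
#'   are dropped; their count is stored in the `n_unparsable` attribute.
#' @export
read_sumstats <- function(path, column_map = list(), n = NULL) {
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  nm <- names(raw)
  pick <- function(role, candidates) {
    if (!is.null(column_map[[role]])) {
      if (!column_map[[role]] %in% nm)
        abort(sprintf("mapped column `%s` for role `%s` not in file.",
                      column_map[[role]], role))
      return(column_map[[role]])
    }
    hit <- nm[toupper(nm) %in% candidates]
    if (length(hit)) hit[1] else NULL
  }
  c_id <- pick("snp_id", c("SNP", "RSID", "ID", "MARKERNAME"))
  c_a1 <- pick("a1", c("A1", "EFFECT_ALLELE", "EA"))
  c_a2 <- pick("a2", c("A2", "OTHER_ALLELE", "OA", "NEA"))
  c_z  <- pick("z", "Z")
  c_b  <- pick("beta", c("BETA", "B", "EFFECT"))
  c_se <- pick("se", c("SE", "STDERR"))
  c_p  <- pick("p", c("P", "PVAL", "PVALUE", "P_VALUE"))
  c_n  <- pick("n", c("N", "NEFF", "N_EFF"))
  c_info <- pick("info", "INFO")
  if (is.null(c_id) || is.null(c_a1) || is.null(c_a2))
    abort("mandatory columns (snp id, effect allele, other allele) not found.")
  if (is.null(c_z) && is.null(c_b))
    abort("no usable association column: need Z, or BETA with SE or P.")
  num <- function(col) if (is.null(col)) NULL else suppressWarnings(as.numeric(raw[[col]]))
  z <- num(c_z); beta <- num(c_b); se <- num(c_se); p <- num(c_p)
  z_source <- rep(NA_character_, nrow(raw))
  out_z <- rep(NA_real_, nrow(raw))
  if (!is.null(z)) {
    ok <- is.finite(z)
    out_z[ok] <- z[ok]; z_source[ok] <- "z"
  }
  if (!is.null(beta) && !is.null(se)) {
    ok <- is.na(out_z) & is.finite(beta) & is.finite(se) & se > 0
    out_z[ok] <- beta[ok] / se[ok]; z_source[ok] <- "beta/se"
  }
  if (!is.null(beta) && !is.null(p)) {
    ok <- is.na(out_z) & is.finite(beta) & is.finite(p) & p > 0 & p <= 1
    out_z[ok] <- sign(beta[ok]) * qnorm(p[ok] / 2, lower.tail = FALSE)
    z_source[ok] <- "signed-p"
  }
  nn <- if (!is.null(c_n)) num(c_n) else {
    if (is.null(n)) abort("file has no N column and no scalar `n` was supplied.")
    rep(as.numeric(n), nrow(raw))
  }
  res <- tibble(snp_id = raw[[c_id]],
                a1 = toupper(raw[[c_a1]]), a2 = toupper(raw[[c_a2]]),
                z = out_z, n = nn, z_source = z_source)
  if (!is.null(c_info)) res$info <- num(c_info)
  bad <- !is.finite(res$z) | !is.finite(res$n) | res$n <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d unparsable row(s).", sum(bad)))
    res <- res[!bad, , drop = FALSE]
  }
  attr(res, "n_unparsable") <- sum(bad)
  res
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Effective sample size for case/control GWAS
#'
#' \eqn{N_{eff} = 4 / (1/N_{case} + 1/N_{control})}; equals the total sample
#' size for a balanced design and down-weights imbalanced designs.
#'
#' @param n_case,n_control Case and control counts, > 0.
#' @return The effective sample size.
#' @examples
#' effective_n(1000, 1000)  # 2000
#' effective_n(100, 300)    # 300
#' @export
effective_n <- function(n_case, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0))
    abort("case and control counts must be > 0.")
  4 / (1 / n_case + 1 / n_control)
}

#' Default exclusion regions (build GRCh37)
#'
#' The extended MHC, excluded by default because its extreme long-range LD
#' violates the sparse-window model. Intervals are 0-based half-open (BED
#' convention).
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
default_exclusion_regions <- function() {
  tibble(chrom = "6", start = 26e6, end = 34e6)
}

#' Harmonize summary statistics against a reference panel
#'
#' Aligns each record to the panel: z is negated when effect/other alleles
#' are swapped relative to the panel; strand flips are resolved via
#' complementary alleles; strand-ambiguous SNPs (A/T, C/G) are dropped;
#' records absent from the panel, or failing the MAF / INFO / region
#' filters, are dropped. The result is idempotent: harmonizing the output
#' again changes nothing.
#'
#' @param raw Tibble from [read_sumstats()] (columns `snp_id`, `a1`, `a2`,
#'   `z`, `n`, optionally `info`).
#' @param panel A [reference_panel()].
#' @param maf_min Panel MAF filter (default 0.05).
#' @param info_min INFO filter, applied only when an `info` column is
#'   present (default 0.9); most public files lack INFO, in which case the
#'   filter is skipped.
#' @param exclude Tibble of 0-based half-open intervals (`chrom`, `start`,
#'   `end`) to remove; defaults to [default_exclusion_regions()].
#' @return A tibble of class `sumstats` with columns `snp_id`,
#'   `aligned_index`, `z`, `n`, aligned to panel allele orientation; the
#'   `qc` attribute is a tibble of counts dropped per rule.
#' @export
harmonize <- function(raw, panel, maf_min = 0.05, info_min = 0.9,
                      exclude = default_exclusion_regions()) {
  qc <- list(input = nrow(raw))
  amb <- raw$a1 == unname(COMPLEMENT[raw$a2])
  amb[is.na(amb)] <- TRUE
  qc$ambiguous <- sum(amb)
  x <- raw[!amb, , drop = FALSE]
  idx <- match(x$snp_id, panel$snp_id)
  qc$not_in_panel <- sum(is.na(idx))
  x <- x[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  pe <- panel$allele_eff[idx]; po <- panel$allele_oth[idx]
  same <- x$a1 == pe & x$a2 == po
  swap <- x$a1 == po & x$a2 == pe
  flip_same <- unname(COMPLEMENT[x$a1]) == pe & unname(COMPLEMENT[x$a2]) == po
  flip_swap <- unname(COMPLEMENT[x$a1]) == po & unname(COMPLEMENT[x$a2]) == pe
  match_ok <- same | swap | flip_same | flip_swap
  qc$allele_mismatch <- sum(!match_ok)
  if (nrow(x) > 0 && sum(!match_ok) > 0.5 * nrow(x))
    abort(">50% of records fail allele matching: likely a genome-build or orientation problem.")
  x <- x[match_ok, , drop = FALSE]; idx <- idx[match_ok]
  negate <- (swap | flip_swap)[match_ok]
  z <- ifelse(negate, -x$z, x$z)
  maf_fail <- panel$maf[idx] < maf_min
  qc$maf <- sum(maf_fail)
  info_fail <- if ("info" %in% names(x)) !is.na(x$info) & x$info < info_min
               else rep(FALSE, nrow(x))
  qc$info <- sum(info_fail & !maf_fail)
  in_region <- rep(FALSE, nrow(x))
  if (!is.null(exclude) && nrow(exclude)) {
    for (k in seq_len(nrow(exclude))) {
      in_region <- in_region |
        (panel$chrom[idx] == as.character(exclude$chrom[k]) &
           panel$pos[idx] >= exclude$start[k] & panel$pos[idx] < exclude$end[k])
    }
  }
  qc$region <- sum(in_region & !maf_fail & !info_fail)
  keep <- !maf_fail & !info_fail & !in_region
  out <- tibble(snp_id = x$snp_id[keep],
                a1 = pe[keep], a2 = po[keep],
                aligned_index = idx[keep],
                z = z[keep], n = x$n[keep])
  if ("info" %in% names(x)) out$info <- x$info[keep]
  qc$output <- nrow(out)
  attr(out, "qc") <- tibble(rule = names(qc), count = unlist(qc, use.names = FALSE))
  class(out) <- c("sumstats", class(out))
  out
}

#' Write summary statistics in LDSC-style text
#'
#' @param sumstats Tibble with `snp_id`, `a1`, `a2`, `n`, `z` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp_id, A1 = sumstats$a1, A2 = sumstats$a2,
                    N = sumstats$n, Z = sumstats$z)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
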