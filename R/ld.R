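#' Sparse LD matrix constructor
#'
#' Stores allelic correlations as sparse triplets `(i, j, r)` with `i < j`
#' (the symmetric counterpart and the unit self-correlation are implicit).
#' Only pairs with \eqn{r^2 \ge} `r2_min` within `window_snps` positions of
#' each other are retained.
#'
#' @param pairs Tibble or data frame with integer columns `i`, `j` and
#'   numeric `r`.
#' @param n_snps Number of SNPs the indices refer to.
#' @param window_snps Fixed SNP-count window used when the pairs were
#'   computed.
#' @param r2_min Storage threshold on squared correlation.
#' @param snp_id Optional SNP identifiers for alignment checks.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(pairs, n_snps, window_snps, r2_min, snp_id = NULL) {
  pairs <- as_tibble(pairs)[c("i", "j", "r")]
  swap <- pairs$i > pairs$j
  if (any(swap)) {
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  }
  if (any(pairs$i == pairs$j)) abort("self-pairs must not be stored.")
  if (any(abs(pairs$r) > 1 + 1e-12)) abort("|r| must be <= 1.")
  structure(list(pairs = pairs, n_snps = as.integer(n_snps),
                 window_snps = as.integer(window_snps), r2_min = r2_min,
                 snp_id = snp_id),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<sparse LD matrix: %d SNPs, %d stored pairs, window %d SNPs, r2 >= %g>\n",
              x$n_snps, nrow(x$pairs), x$window_snps, x$r2_min))
  invisible(x)
}

#' Compute a sparse LD matrix from genotype dosages
#'
#' Pearson correlation of dosage columns for every pair within a fixed
#' SNP-count window; pairs with \eqn{r^2 <} `r2_min` are discarded.
#' Missing dosages are mean-imputed per SNP before correlation. Monomorphic
#' columns are dropped with a warning (their correlation is undefined).
#'
#' @param genotypes n x m numeric dosage matrix (columns = SNPs).
#' @param window_snps Fixed window size in SNP counts (default 50000,
#'   effectively genome-wide at desk scale).
#' @param r2_min Storage threshold on r^2 (default 0.05).
#' @return An [ld_matrix()]. Dropped monomorphic columns are recorded in the
#'   `dropped` attribute.
#' @examples
#' g <- cbind(a = c(0, 1, 2, 1, 0), b = c(0, 1, 2, 1, 1))
#' compute_ld(g, window_snps = 10, r2_min = 0.05)
#' @export
compute_ld <- function(genotypes, window_snps = 50000L, r2_min = 0.05) {
  if (window_snps < 1) abort("`window_snps` must be >= 1.")
  m <- ncol(genotypes)
  if (m < 2) abort("need at least 2 SNPs.")
  g <- apply(genotypes, 2, function(col) {
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  sds <- apply(g, 2, sd)
  mono <- which(sds == 0 | !is.finite(sds))
  if (length(mono)) {
    warn(sprintf("dropping %d monomorphic column(s): %s", length(mono),
                 paste(head(colnames(g)[mono] %||% mono, 5), collapse = ", ")))
  }
  keep <- setdiff(seq_len(m), mono)
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_r <- numeric(0)
  # correlate in banded chunks to stay within the window
  gz <- scale(g[, keep, drop = FALSE])
  mk <- length(keep)
  chunk <- 512L
  for (s in seq(1L, mk, by = chunk)) {
    e <- min(s + chunk - 1L, mk)
    upto <- min(e + window_snps, mk)
    cc <- crossprod(gz[, s:e, drop = FALSE], gz[, s:upto, drop = FALSE]) /
      (nrow(gz) - 1)
    for (a in s:e) {
      bs <- (a + 1):min(a + window_snps, mk)
      if (length(bs) == 0 || bs[1] > mk) next
      r <- cc[a - s + 1L, bs - s + 1L]
      sel <- which(r^2 >= r2_min)
      if (length(sel)) {
        pairs_i <- c(pairs_i, rep(a, length(sel)))
        pairs_j <- c(pairs_j, bs[sel])
        pairs_r <- c(pairs_r, unname(pmin(pmax(r[sel], -1), 1)))
      }
    }
  }
  out <- ld_matrix(tibble(i = keep[pairs_i], j = keep[pairs_j], r = pairs_r),
                   n_snps = m, window_snps = window_snps, r2_min = r2_min,
                   snp_id = colnames(genotypes))
  attr(out, "dropped") <- mono
  out
}

# symmetric edge list (both directions), optionally filtered on r^2
ld_edges <- function(ld, r2_thresh = NULL) {
  p <- ld$pairs
  if (!is.null(r2_thresh)) p <- p[p$r^2 >= r2_thresh, , drop = FALSE]
  tibble(i = c(p$i, p$j), j = c(p$j, p$i), r = c(p$r, p$r))
}

#' Heterozygosity-adjusted LD scores and fourth-moment sums
#'
#' For each SNP j computes \eqn{\ell_j = \sum_i H_i r_{ij}^2} (the LD score,
#' adjusted for heterozygosity) and the fourth-moment sum
#' \eqn{m4_j = \sum_i H_i^2 r_{ij}^4}, truncated at the stored sparse pairs.
#' The self term (\eqn{r_{jj} = 1}) is always included: a causal SNP tags
#' itself even when no off-diagonal pairs are stored.
#'
#' @param ld An [ld_matrix()].
#' @param panel A [reference_panel()] over the same SNPs (same order).
#' @return A tibble with columns `snp_id`, `ell`, `m4`, `ratio` (= m4/ell).
#' @export
ld_scores <- function(ld, panel) {
  if (nrow(panel) != ld$n_snps)
    abort(sprintf("panel has %d SNPs but LD matrix indexes %d.",
                  nrow(panel), ld$n_snps))
  if (!is.null(ld$snp_id) && !identical(as.character(ld$snp_id), panel$snp_id)) {
    bad <- head(which(ld$snp_id != panel$snp_id), 3)
    abort(paste0("LD matrix and panel are not aligned; first offending ids: ",
                 paste(ld$snp_id[bad], collapse = ", ")))
  }
  H <- panel$het
  ell <- H            # self term: H_j * 1
  m4 <- H^2           # self term: H_j^2 * 1
  e <- ld_edges(ld)
  if (nrow(e)) {
    # neighbor i contributes H_i r^2 to ell_j and H_i^2 r^4 to m4_j
    add1 <- tapply(panel$het[e$i] * e$r^2, e$j, sum)
    add2 <- tapply(panel$het[e$i]^2 * e$r^4, e$j, sum)
    idx <- as.integer(names(add1))
    ell[idx] <- ell[idx] + as.numeric(add1)
    m4[idx] <- m4[idx] + as.numeric(add2)
  }
  tibble(snp_id = panel$snp_id, ell = ell, m4 = m4, ratio = m4 / ell)
}

#' Per-SNP weights by random pruning
#'
#' Runs `T` iterations of random pruning: each iteration visits SNPs in an
#' independently shuffled order and retains a SNP unless it is in LD
#' (\eqn{r^2 \ge} `r2_thresh`) with an already-retained SNP, producing a
#' maximal independent-ish subset. The weight of SNP j is the fraction of
#' iterations in which it was retained. Averaging the log-likelihood with
#' these weights avoids overcounting evidence from large LD blocks.
#'
#' @param ld An [ld_matrix()].
#' @param r2_thresh Pruning threshold on r^2 (default 0.1).
#' @param T Number of pruning iterations (default 64).
#' @param seed Integer seed; the iteration streams are derived from it.
#' @return A tibble with columns `index` and `w`, carrying `r2_thresh`, `T`,
#'   `seed` and the per-iteration retained counts (`n_retained`) as
#'   attributes.
#' @export
random_pruning_weights <- function(ld, r2_thresh = 0.1, T = 64L, seed = 1L) {
  if (T < 1) abort("`T` must be >= 1.")
  m <- ld$n_snps
  e <- ld_edges(ld, r2_thresh = r2_thresh)
  nbr <- vector("list", m)
  if (nrow(e)) {
    sp <- split(e$j, e$i)
    nbr[as.integer(names(sp))] <- sp
  }
  counts <- integer(m)
  n_retained <- integer(T)
  rng <- rng_substream(seed, "pruning")
  withr_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(withr_seed))
  set.seed(rng)
  has_nbr <- lengths(nbr) > 0
  for (t in seq_len(T)) {
    ord <- sample.int(m)
    keep <- logical(m)
    for (j in ord) {
      nb <- nbr[[j]]
      if (is.null(nb) || !any(keep[nb])) keep[j] <- TRUE
    }
    counts <- counts + keep
    n_retained[t] <- sum(keep)
  }
  out <- tibble(index = seq_len(m), w = counts / T)
  attr(out, "r2_thresh") <- r2_thresh
  attr(out, "T") <- as.integer(T)
  attr(out, "seed") <- seed
  attr(out, "n_retained") <- n_retained
  out
}

# named substream seeds below 2^31, reproducibly derived from a master seed
rng_substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

# ---- on-disk sparse LD (quantized text triplets) ---------------------------

#' Write / read a sparse LD file
#'
#' Plain-text triplet storage with a versioned header recording the window,
#' threshold and quantization. Correlations are quantized to 16-bit signed
#' integers (`round(r * 32767)`), bounding the round-trip error by
#' 1/65534 per value.
#'
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @return `path` (write) or an [ld_matrix()] (read).
#' @export
write_ld <- function(ld, path) {
  hdr <- c("#causalmix_ld v1",
           sprintf("#n_snps=%d", ld$n_snps),
           sprintf("#window_snps=%d", ld$window_snps),
           sprintf("#r2_min=%.17g", ld$r2_min),
           "#quant=32767")
  writeLines(hdr, path)
  q <- data.frame(i = ld$pairs$i, j = ld$pairs$j,
                  rq = as.integer(round(ld$pairs$r * 32767)))
  readr::write_tsv(q, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  hdr <- readLines(path, n = 5)
  if (!identical(hdr[1], "#causalmix_ld v1")) abort("unrecognized LD file header.")
  get_val <- function(key) sub(paste0("#", key, "="), "",
                               grep(paste0("^#", key, "="), hdr, value = TRUE))
  q <- readr::read_tsv(path, comment = "#", col_names = c("i", "j", "rq"),
                       col_types = "iii", progress = FALSE)
  ld_matrix(tibble(i = q$i, j = q$j, r = q$rq / 32767),
            n_snps = as.integer(get_val("n_snps")),
            window_snps = as.integer(get_val("window_snps")),
            r2_min = as.numeric(get_val("r2_min")))
}
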