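# shared fixtures, built once per test run and memoized

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# integer dosage matrix with independent binomial SNPs
toy_genotypes <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  maf <- maf %||% runif(m, 0.1, 0.5)
  g <- sapply(maf, function(p) rbinom(n, 2, p))
  colnames(g) <- paste0("snp", seq_len(m))
  g
}

toy_panel <- function(maf, chrom = "1") {
  m <- length(maf)
  reference_panel(paste0("snp", seq_len(m)), chrom, seq_len(m) * 1000L,
                  rep("A", m), rep("G", m), maf)
}

# a small AR-block reference with contexts and weights (4K SNPs)
small_ref <- function() {
  memo("small_ref", {
    cond <- study_conditions(n_snps = 4000L)
    causalmix:::harness_reference(cond, seed = 42L)
  })
}

small_cond <- function() study_conditions(n_snps = 4000L)

# a 20-SNP AR block with dense correlation matrix for oracle loops
ar_block <- function(n = 20, phi = 0.8, seed = 5) {
  memo(sprintf("ar_%d_%g_%d", n, phi, seed), {
    pan <- make_panel(1, n, phi = phi, maf_spectrum = "uniform",
                      maf_range = c(0.1, 0.5), seed = seed)
    dense <- outer(seq_len(n), seq_len(n), function(i, j) phi^abs(i - j))
    list(panel = pan$panel, ld = pan$ld, dense = dense)
  })
}
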