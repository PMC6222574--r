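# Shared fixtures, built in code.

# VariantTable from an entries x variants matrix with evenly spaced positions
toy_table <- function(geno, chrom = NULL, pos = NULL, entry_id = NULL) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variant_table(geno, chrom, pos, entry_id = entry_id)
}

# small NAM-like study used by several test files (memoised per session)
.fix_env <- new.env()
small_study <- function() {
  if (is.null(.fix_env$study)) {
    cfg <- sim_config(n_founders = 4,
                      chrom_spec = list(c(5e7, 80), c(5e7, 80)),
                      n_variants = 500, n_ril_per_family = 60,
                      n_bc1_per_family = c(8, 4), h2 = 0.6, seed = 101)
    st <- simulate_study(cfg)
    rec <- simulate_phenotypes(st$truth$genetic_values, 0.6, 2, 2, 0.5, 15,
                               seed = 102)
    st$blues <- fit_blue(rec)
    st$records <- rec
    .fix_env$study <- st
  }
  .fix_env$study
}

# direct (oracle) partial-F p-value for adding x to covariates C, via two
# explicit least-squares fits
oracle_partial_f <- function(y, C, x) {
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  r0 <- rss(C); r1 <- rss(cbind(C, x))
  df <- length(y) - qr(cbind(C, x))$rank
  f <- (r0 - r1) / (r1 / df)
  stats::pf(f, 1, df, lower.tail = FALSE)
}
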