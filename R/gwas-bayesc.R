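#' Configuration for the BayesC multi-variant model
#'
#' @param pi prior exclusion probability of each marker, in `[0, 1)`.
#'   `NULL` (default) resolves at run time to `1 - 100/M` (expected ~100
#'   markers in the model), floored at 0.
#' @param chain_length,burn_in Gibbs chain settings (defaults 41,000 /
#'   1,000).
#' @param genetic_variance,residual_variance prior variances on the trait
#'   scale (defaults 1 and 1).
#' @param prior_df degrees of freedom of both scaled-inverse-chi-square
#'   variance priors (default 4); `Inf` freezes the variances at their
#'   configured values.
#' @param marker_variance optional direct prior marker-effect variance;
#'   when `NULL` it is derived as
#'   `genetic_variance / (sum(2 p (1-p)) * (1 - pi))`.
#' @param thin thinning factor for stored variance samples.
#' @param seed optional seed.
#' @return list of class `BayesCConfig`.
#' @export
bayesc_config <- function(pi = NULL, chain_length = 41000L, burn_in = 1000L,
                          genetic_variance = 1, residual_variance = 1,
                          prior_df = 4, marker_variance = NULL, thin = 10L,
                          seed = NULL) {
  if (!is.null(pi) && (pi < 0 || pi >= 1)) stop("pi must be in [0, 1)")
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  structure(list(pi = pi, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 genetic_variance = genetic_variance,
                 residual_variance = residual_variance,
                 prior_df = prior_df, marker_variance = marker_variance,
                 thin = as.integer(thin), seed = seed),
            class = "BayesCConfig")
}

#' BayesC mixture-model GWAS by Gibbs sampling
#'
#' Fits all variants simultaneously: each marker effect is zero with prior
#' probability `pi` and normal with a common variance otherwise, alongside
#' sampled population/subpopulation fixed effects. A single-site Gibbs
#' sampler (genome order, single chain) yields per-marker posterior model
#' frequencies (MF = fraction of post-burn-in samples including the
#' marker) and posterior mean effects. Missing dosages are mean-imputed;
#' marker columns are centered internally (effect scale is unchanged).
#'
#' @inheritParams sv_scan
#' @param config a [bayesc_config()].
#' @return list of class `BayesCResult`: `result` (`AssociationResult`
#'   data.frame with `model = "BMV"`, `effect`, `mf`, `score = mf`),
#'   `post_sigma2_c`, `post_sigma2_e`, `post_genetic_variance`, variance
#'   `traces`, `pi`, `config`.
#' @export
run_bayesc <- function(variants, y, design, config = bayesc_config()) {
  stopifnot(inherits(config, "BayesCConfig"))
  al <- align_response(y, variants)
  X <- mean_impute(variants$geno[al$entries, , drop = FALSE])
  m <- ncol(X)
  pi <- if (is.null(config$pi)) max(0, 1 - 100 / m) else config$pi
  p <- colMeans(X) / 2
  sumpq <- sum(2 * p * (1 - p))
  sigma2_c0 <- if (!is.null(config$marker_variance)) config$marker_variance
  else config$genetic_variance / max(sumpq * (1 - pi), 1e-12)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- design_matrix(design, al$entries)
  fix_var <- is.infinite(config$prior_df)
  nu <- if (fix_var) 4 else config$prior_df
  if (!is.null(config$seed)) set.seed(config$seed)
  fit <- bayesc_gibbs(al$y, W, X, pi, config$chain_length, config$burn_in,
                      sigma2_c0, config$residual_variance, nu, nu,
                      fix_var, config$thin)
  res <- data.frame(variant_id = variants$info$variant_id,
                    chrom = variants$info$chrom, pos = variants$info$pos,
                    model = "BMV", effect = fit$effect, mf = fit$mf,
                    score = fit$mf, n_used = length(al$y),
                    stringsAsFactors = FALSE)
  class(res) <- c("AssociationResult", "data.frame")
  structure(list(result = res,
                 post_sigma2_c = fit$post_sigma2_c,
                 post_sigma2_e = fit$post_sigma2_e,
                 post_genetic_variance = fit$post_genetic_variance,
                 fixed_effects = fit$fixed_effects,
                 traces = list(sigma2_c = fit$trace_sigma2_c,
                               sigma2_e = fit$trace_sigma2_e,
                               genetic_variance = fit$trace_genetic_variance),
                 n_samples = fit$n_samples, pi = pi,
                 marker_variance_prior = sigma2_c0, config = config),
            class = "BayesCResult")
}

#' @export
print.BayesCResult <- function(x, ...) {
  cat(sprintf(paste0("BayesCResult: %d markers, pi = %.4f, %d samples\n",
                     "  posterior sigma2_e = %.4f, genetic variance = %.4f\n"),
              nrow(x$result), x$pi, x$n_samples,
              x$post_sigma2_e, x$post_genetic_variance))
  invisible(x)
}

#' Two-step prior training for the BayesC model
#'
#' Step 1 runs a short chain (default 1,000 sweeps, 100 burn-in) with
#' default unit prior variances; step 2 replaces the prior genetic and
#' residual variances with step-1 posterior means and runs the long chain
#' configured in `config` (default 41,000 / 1,000).
#'
#' @inheritParams run_bayesc
#' @param config step-2 chain settings ([bayesc_config()]).
#' @param step1_chain,step1_burn_in step-1 chain settings.
#' @return the step-2 `BayesCResult`, with the step-1 result attached as
#'   `$step1`.
#' @export
two_step_train <- function(variants, y, design, config = bayesc_config(),
                           step1_chain = 1000L, step1_burn_in = 100L) {
  cfg1 <- config
  cfg1$chain_length <- as.integer(step1_chain)
  cfg1$burn_in <- as.integer(step1_burn_in)
  cfg1$genetic_variance <- 1
  cfg1$residual_variance <- 1
  cfg1$marker_variance <- NULL
  step1 <- run_bayesc(variants, y, design, cfg1)
  cfg2 <- config
  cfg2$genetic_variance <- step1$post_genetic_variance
  cfg2$residual_variance <- step1$post_sigma2_e
  cfg2$marker_variance <- NULL
  out <- run_bayesc(variants, y, design, cfg2)
  out$step1 <- step1
  out
}

#' Split-chain convergence diagnostic for variance traces
#'
#' A Geweke-style z-score comparing the first and second halves of each
#' stored variance trace, with batch-mean standard errors (batches of 10).
#' |z| beyond ~2-3 flags poor mixing.
#'
#' @param result a `BayesCResult`.
#' @return named numeric vector of z-scores, one per trace.
#' @export
bayesc_diagnostics <- function(result) {
  zs <- vapply(result$traces, function(tr) {
    n <- length(tr)
    if (n < 20) return(NA_real_)
    half <- function(v) {
      nb <- max(2, length(v) %/% 10)
      bm <- tapply(v, cut(seq_along(v), nb, labels = FALSE), mean)
      c(mean(v), stats::var(bm) / length(bm))
    }
    a <- half(tr[seq_len(n %/% 2)])
    b <- half(tr[(n %/% 2 + 1):n])
    (a[1] - b[1]) / sqrt(max(a[2] + b[2], 1e-300))
  }, numeric(1))
  zs
}
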