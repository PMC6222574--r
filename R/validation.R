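#' Informative-variant filter for validation panels
#'
#' A validation-panel variant is informative when it is polymorphic, has a
#' call rate strictly above `min_call_rate` and a minor allele frequency
#' strictly above `min_maf` (defaults 0.4 and 0.05).
#'
#' @inheritParams filter_variants
#' @return filtered `VariantTable`.
#' @export
informative_filter <- function(table, min_call_rate = 0.4, min_maf = 0.05) {
  filter_variants(table, min_call_rate, min_maf, strict = TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' Centered cross-product of the dosage matrix scaled by `sum(2 p (1-p))`
#' over the markers used; symmetric positive semi-definite with diagonal
#' near `1 + f` for inbreeding `f`. Monomorphic markers are excluded;
#' missing dosages are mean-imputed (which contributes zero after
#' centering).
#'
#' @param snps a `VariantTable` of genome-wide background SNPs (not the
#'   candidate variants themselves).
#' @return entries x entries numeric relationship matrix.
#' @export
vanraden_kinship <- function(snps) {
  stopifnot(n_entries(snps) >= 2, n_variants(snps) >= 10)
  X <- mean_impute(snps$geno)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / sum(2 * p * (1 - p))
  dimnames(K) <- list(entry_ids(snps), entry_ids(snps))
  K
}

#' Kinship mixed-model test of candidate variants
#'
#' Per candidate variant, fits `y = mu + x beta + u + e` with
#' `cov(u) = K sigma2_u`, estimating the variance ratio once on the null
#' (marker-free) model by REML via spectral decomposition of `K`
#' (population-parameters-previously-determined style), then testing
#' `beta = 0` with a Wald t-test under generalized least squares. With
#' `K = I` this reduces exactly to the ordinary least-squares test.
#'
#' @param kav a `VariantTable` of candidate variants on the validation
#'   entries.
#' @param y named phenotype vector (or `BlueTable`).
#' @param K kinship matrix with entry dimnames (positive semi-definite; a
#'   ridge of 1e-6 is added if numerically singular).
#' @return data.frame: `variant_id`, `effect`, `p`, `n_used`; attribute
#'   `"lambda"` holds the estimated variance ratio `sigma2_u / sigma2_e`.
#' @export
mlm_kav_test <- function(kav, y, K) {
  al <- align_response(y, kav)
  ids <- intersect(al$entries, rownames(K))
  yv <- al$y[match(ids, al$entries)]
  K <- K[ids, ids]
  n <- length(ids)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    message("mlm_kav_test: kinship not PSD; adding 1e-6 ridge")
    eg$values <- eg$values + 1e-6
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, yv))
  ones <- as.numeric(crossprod(U, rep(1, n)))
  # REML for V = sigma2_u K + sigma2_e I, parameterized by lam = s2u/s2e
  nll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    xwx <- sum(w * ones^2)
    b <- sum(w * ones * yt) / xwx
    rss <- sum(w * (yt - ones * b)^2)
    0.5 * ((n - 1) * log(rss) - sum(log(w)) + log(xwx))
  }
  opt <- stats::optimize(nll, c(-15, 15))
  lam <- exp(opt$minimum)
  if (nll(-25) <= opt$objective + 1e-10) lam <- 0
  w <- 1 / (lam * d + 1)
  out <- data.frame(variant_id = kav$info$variant_id, effect = NA_real_,
                    p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  G <- kav$geno[ids, , drop = FALSE]
  for (k in seq_len(ncol(G))) {
    use <- !is.na(G[, k])
    out$n_used[k] <- sum(use)
    if (sum(use) < 4) { out$p[k] <- 1; next }
    # rotate the complete-case subproblem with the global decomposition:
    # refit on the subset using the same lambda (P3D)
    Ks <- K[use, use]
    egs <- if (all(use)) list(values = d, vectors = U) else
      eigen(Ks, symmetric = TRUE)
    ws <- 1 / (lam * pmax(egs$values, 0) + 1)
    Us <- egs$vectors
    yts <- as.numeric(crossprod(Us, yv[use]))
    Xts <- crossprod(Us, cbind(1, G[use, k]))
    A <- crossprod(Xts, ws * Xts)
    if (abs(det(A)) < 1e-10 * max(diag(A))^2) { out$p[k] <- 1; next }
    Ai <- solve(A)
    b <- Ai %*% crossprod(Xts, ws * yts)
    rss <- sum(ws * (yts - Xts %*% b)^2)
    df <- sum(use) - 2L
    s2 <- rss / df
    se <- sqrt(s2 * Ai[2, 2])
    tt <- b[2] / se
    out$effect[k] <- b[2]
    out$p[k] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  attr(out, "lambda") <- lam
  out
}

#' Naive single-variant test without structure correction
#'
#' Per candidate variant, ordinary least-squares regression of the
#' phenotype on dosage with a Wald t-test; no population-structure
#' covariates.
#'
#' @inheritParams mlm_kav_test
#' @return data.frame: `variant_id`, `effect`, `p`, `n_used`.
#' @export
naive_kav_test <- function(kav, y) {
  al <- align_response(y, kav)
  G <- kav$geno[al$entries, , drop = FALSE]
  out <- data.frame(variant_id = kav$info$variant_id, effect = NA_real_,
                    p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(G))) {
    use <- !is.na(G[, k])
    out$n_used[k] <- sum(use)
    x <- G[use, k]; yy <- al$y[use]
    if (sum(use) < 4 || stats::var(x) == 0 || stats::var(yy) == 0) {
      out$p[k] <- 1
      next
    }
    xr <- x - mean(x); yr <- yy - mean(yy)
    ssx <- sum(xr^2)
    b <- sum(xr * yr) / ssx
    rss <- sum((yr - b * xr)^2)
    df <- sum(use) - 2L
    se <- sqrt(rss / df / ssx)
    out$effect[k] <- b
    out$p[k] <- 2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  }
  out
}

#' One-sided pooled allele-frequency test
#'
#' Tests whether the allele associated with a higher trait value in the
#' discovery GWAS is at higher frequency in the high-trait pools than in
#' the low-trait pools. Per-accession frequencies of the trait-increasing
#' allele are compared between groups with a one-sided Welch t-test
#' (default) or a binomial GLM on pooled counts.
#'
#' @param freq accessions x variants matrix of alternate-allele frequency
#'   estimates (from pooled genotyping).
#' @param label named vector of `"high"` / `"low"` pool assignments.
#' @param direction named vector of GWAS effect signs per variant
#'   (positive: the alternate allele increases the trait).
#' @param method `"welch"` or `"binomial"` (quasibinomial GLM on
#'   frequencies weighted by `2 * pool_size`).
#' @param pool_size plants per pool (used by the binomial method).
#' @return data.frame: `variant_id`, `delta` (high - low mean frequency of
#'   the trait-increasing allele), `p` (one-sided).
#' @export
pooled_freq_test <- function(freq, label, direction,
                             method = c("welch", "binomial"),
                             pool_size = 12) {
  method <- match.arg(method)
  hi <- names(label)[label == "high"]; lo <- names(label)[label == "low"]
  stopifnot(length(hi) >= 2, length(lo) >= 2)
  vids <- colnames(freq)
  out <- data.frame(variant_id = vids, delta = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(vids)) {
    f <- freq[, k]
    dir_k <- direction[vids[k]]
    if (is.na(dir_k) || dir_k == 0) dir_k <- 1
    if (dir_k < 0) f <- 1 - f          # frequency of the increasing allele
    fh <- f[hi]; fl <- f[lo]
    fh <- fh[!is.na(fh)]; fl <- fl[!is.na(fl)]
    if (length(fh) < 2 || length(fl) < 2) { out$p[k] <- 1; next }
    out$delta[k] <- mean(fh) - mean(fl)
    if (stats::var(fh) == 0 && stats::var(fl) == 0) {
      # degenerate: both groups fixed
      out$p[k] <- if (mean(fh) > mean(fl)) 0 else 1
      next
    }
    if (method == "welch") {
      out$p[k] <- stats::t.test(fh, fl, alternative = "greater")$p.value
    } else {
      g <- factor(c(rep("high", length(fh)), rep("low", length(fl))),
                  levels = c("low", "high"))
      fit <- stats::glm(c(fh, fl) ~ g, family = stats::quasibinomial(),
                        weights = rep(2 * pool_size, length(g)))
      sm <- summary(fit)$coefficients
      z <- sm[2, 1] / sm[2, 2]
      out$p[k] <- stats::pt(z, fit$df.residual, lower.tail = FALSE)
    }
  }
  out
}

#' Wright-Fisher drift null for divergent-selection frequency differences
#'
#' For each candidate variant, simulates `n_sim` pairs of independent
#' neutral Wright-Fisher lineages of `Ne` diploids from the base (cycle-0)
#' frequency for `generations` generations, and reports the empirical
#' probability (with the +1 correction, so never zero) that neutral drift
#' produces an absolute frequency difference between the two arms at least
#' as large as observed. Benjamini-Hochberg q-values are attached across
#' variants. Variants fixed in the base population are uninformative
#' (`p = 1`).
#'
#' @param freq_LE,freq_SE named observed frequencies in the two selected
#'   arms.
#' @param freq_C0 named base-population frequencies.
#' @param generations selection cycles separating the arms from the base
#'   (default 30).
#' @param Ne effective (diploid) size of each lineage.
#' @param n_sim neutral replicates per variant (>= 1000).
#' @param seed optional seed.
#' @return data.frame: `variant_id`, `delta_obs`, `p` (empirical), `q`
#'   (BH-adjusted).
#' @export
drift_null_test <- function(freq_LE, freq_SE, freq_C0, generations = 30,
                            Ne = 100, n_sim = 1000, seed = NULL) {
  stopifnot(n_sim >= 1000)
  if (!is.null(seed)) set.seed(seed)
  vids <- names(freq_C0)
  out <- data.frame(variant_id = vids,
                    delta_obs = abs(freq_LE[vids] - freq_SE[vids]),
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(vids)) {
    p0 <- freq_C0[k]
    if (is.na(p0) || p0 <= 0 || p0 >= 1) { out$p[k] <- 1; next }
    pA <- rep(p0, n_sim); pB <- rep(p0, n_sim)
    for (g in seq_len(generations)) {
      pA <- stats::rbinom(n_sim, 2 * Ne, pA) / (2 * Ne)
      pB <- stats::rbinom(n_sim, 2 * Ne, pB) / (2 * Ne)
    }
    out$p[k] <- (1 + sum(abs(pA - pB) >= out$delta_obs[k])) / (n_sim + 1)
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Share of between-population trait divergence explained by validated loci
#'
#' Predicted divergence is `sum(2 * delta_p_k * beta_k)` over the
#' validated variants (frequency difference times additive effect per
#' allele copy); the statistic is the squared ratio of predicted to
#' observed divergence, capped at 1.
#'
#' @param effects named additive effects (trait units per dosage unit) of
#'   the validated variants.
#' @param dfreq named allele-frequency differences between the two
#'   populations (same allele orientation as `effects`).
#' @param observed_divergence observed trait-mean difference (non-zero).
#' @return fraction in `[0, 1]`.
#' @export
between_pop_variance <- function(effects, dfreq, observed_divergence) {
  if (observed_divergence == 0) stop("observed divergence is zero")
  if (!length(effects)) return(0)
  ids <- intersect(names(effects), names(dfreq))
  pred <- sum(2 * dfreq[ids] * effects[ids])   # 2*dp = mean dosage change
  min(1, (pred / observed_divergence)^2)
}

#' Recombination-zone enrichment of validated variants
#'
#' Estimates local recombination rate (cM/Mb) in 10-cM windows of the
#' genetic map, classifies each candidate variant's window as cold
#' (`< cutoff`) or hot (`>= cutoff`, boundary counted hot), and tests the
#' 2x2 association between zone and validation status.
#'
#' @param kavs data.frame with `chrom`, `pos` and logical `validated`.
#' @param map a `GeneticMap`.
#' @param window_cM window size on the genetic scale (default 10).
#' @param cold_cutoff rate threshold in cM/Mb (default 1).
#' @return list: `kavs` (input plus `rate_cM_Mb`, `zone`), `table` (2x2),
#'   `odds_ratio`, `p` (chi-square).
#' @export
recombination_enrichment <- function(kavs, map, window_cM = 10,
                                     cold_cutoff = 1) {
  rate <- numeric(nrow(kavs))
  for (ch in unique(kavs$chrom)) {
    mm <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(mm) < 2) stop("map too sparse on ", ch)
    cm_max <- max(mm$pos_cM)
    breaks <- seq(0, cm_max + window_cM, by = window_cM)
    # bp at window boundaries by inverse interpolation
    bp_at <- stats::approx(mm$pos_cM, mm$pos_bp, xout = pmin(breaks, cm_max),
                           rule = 2, ties = "ordered")$y
    i <- which(kavs$chrom == ch)
    cm_k <- map_cM(map, kavs$chrom[i], kavs$pos[i])
    win <- pmin(findInterval(cm_k, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L)
    dcm <- pmin(breaks[win + 1L], cm_max) - breaks[win]
    dbp <- bp_at[win + 1L] - bp_at[win]
    rate[i] <- ifelse(dbp > 0, dcm / (dbp / 1e6), Inf)
  }
  zone <- ifelse(rate < cold_cutoff, "cold", "hot")
  tab <- table(factor(zone, levels = c("cold", "hot")),
               factor(kavs$validated, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(zone = c("cold", "hot"),
                        validated = c("yes", "no"))
  or <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], 1e-300)
  pv <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  kavs$rate_cM_Mb <- rate
  kavs$zone <- zone
  list(kavs = kavs, table = tab, odds_ratio = as.numeric(or), p = pv)
}

#' Summarize validation outcomes across populations and models
#'
#' Applies Benjamini-Hochberg FDR within each validation population's
#' informative candidates, flags a variant validated when `q < 0.05` in at
#' least one population (in the GWAS-consistent direction where the test
#' defines one), and tabulates validation rates per discovery model and
#' model combination.
#'
#' @param tests named list of per-population data.frames, each with
#'   `variant_id`, `p` and optionally `effect`/`delta` for a direction
#'   check plus `direction_ok` (logical) if directionality applies.
#' @param provenance data.frame from [select_validation_set()] (columns
#'   `variant_id`, `models`), optionally including control variants with
#'   `models == "control"`.
#' @param fdr q-value cutoff (default 0.05).
#' @return list of class `ValidationReport`: `per_variant` (q-values and
#'   flags per population), `rates` (named vector of validated/informative
#'   ratios overall, per model, and per combination), `counts`.
#' @export
summarize_validation <- function(tests, provenance, fdr = 0.05) {
  all_ids <- provenance$variant_id
  validated <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  informative <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  per_pop <- list()
  for (popn in names(tests)) {
    tt <- tests[[popn]]
    tt <- tt[tt$variant_id %in% all_ids, , drop = FALSE]
    inf <- if ("informative" %in% names(tt)) tt$informative else
      !is.na(tt$p) & tt$p < 1
    tt <- tt[inf, , drop = FALSE]
    if (!nrow(tt)) next
    tt$q <- stats::p.adjust(tt$p, method = "BH")
    ok <- tt$q < fdr
    if ("direction_ok" %in% names(tt)) ok <- ok & tt$direction_ok
    validated[tt$variant_id[ok]] <- TRUE
    informative[tt$variant_id] <- TRUE
    per_pop[[popn]] <- tt
  }
  pv <- data.frame(variant_id = all_ids,
                   models = provenance$models[match(all_ids,
                                                    provenance$variant_id)],
                   informative = informative, validated = validated,
                   stringsAsFactors = FALSE)
  rate <- function(sel) {
    i <- sel & pv$informative
    if (!sum(i)) NA_real_ else sum(pv$validated[i]) / sum(i)
  }
  has <- function(mod) grepl(mod, pv$models, fixed = TRUE)
  is_ctrl <- pv$models == "control"
  rates <- c(
    overall = rate(!is_ctrl),
    SV = rate(has("SV")), STR = rate(has("STR")), BMV = rate(has("BMV")),
    SV_only = rate(pv$models == "SV"),
    STR_only = rate(pv$models == "STR"),
    BMV_only = rate(pv$models == "BMV"),
    SV_and_BMV = rate(has("SV") & has("BMV")),
    control = rate(is_ctrl))
  counts <- c(candidates = nrow(pv),
              informative = sum(pv$informative & !is_ctrl),
              validated = sum(pv$validated & !is_ctrl))
  structure(list(per_variant = pv, per_population = per_pop,
                 rates = rates, counts = counts, fdr = fdr),
            class = "ValidationReport")
}
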