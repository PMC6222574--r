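#' Single-variant GWAS scan with off-chromosome QTL covariates
#'
#' For each variant `k` on chromosome `c`, fits ordinary least squares of
#' the adjusted phenotype on intercept + population + subpopulation +
#' the QTL peak markers located on chromosomes other than `c` + the variant
#' dosage, and tests the dosage effect with a two-sided partial F (df 1)
#' test. Entries missing the variant's dosage are dropped for that variant
#' only; variants collinear with the covariates get `p = 1` and an
#' undefined effect.
#'
#' @param variants a `VariantTable`.
#' @param y a `BlueTable` or named numeric phenotype vector.
#' @param design a `StudyDesign`.
#' @param qtl optional `QTLModel`; its peak markers supply the
#'   off-chromosome covariates (QTL covariate dosages are mean-imputed).
#' @return data.frame of class `AssociationResult` with columns
#'   `variant_id`, `chrom`, `pos`, `model` (`"SV"`), `effect` (rows per
#'   dosage unit), `p`, `score` (`-log10 p`), `n_used`.
#' @export
sv_scan <- function(variants, y, design, qtl = NULL) {
  al <- align_response(y, variants)
  n_all <- length(al$y)
  W <- design_matrix(design, al$entries)
  info <- variants$info
  G <- variants$geno[al$entries, , drop = FALSE]
  qtl_markers <- if (!is.null(qtl)) qtl$peaks$marker else character(0)
  qtl_chrom <- info$chrom[match(qtl_markers, info$variant_id)]
  Xq_all <- if (length(qtl_markers))
    mean_impute(G[, qtl_markers, drop = FALSE]) else NULL
  res <- data.frame(variant_id = info$variant_id, chrom = info$chrom,
                    pos = info$pos, model = "SV", effect = NA_real_,
                    p = NA_real_, score = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (ch in unique(info$chrom)) {
    jc <- which(info$chrom == ch)
    C <- cbind(W, Xq_all[, which(qtl_chrom != ch), drop = FALSE])
    Q <- ortho_basis(C)
    pcov <- ncol(Q)
    Gc <- G[, jc, drop = FALSE]
    complete <- !apply(is.na(Gc), 2, any)
    if (any(complete)) {
      Xr <- resid_vs(Gc[, complete, drop = FALSE], Q)
      yr <- as.numeric(resid_vs(matrix(al$y), Q))
      ssy <- sum(yr^2)
      ssx <- colSums(Xr^2)
      num <- as.numeric(crossprod(Xr, yr))
      df <- n_all - pcov - 1L
      ok <- ssx > 1e-10 * n_all
      r2 <- ifelse(ok, num^2 / (ssx * ssy), 0)
      Fst <- r2 / pmax(1 - r2, 1e-300) * df
      pv <- ifelse(ok, stats::pf(Fst, 1, df, lower.tail = FALSE), 1)
      eff <- ifelse(ok, num / ssx, NA_real_)
      jj <- jc[complete]
      res$effect[jj] <- eff
      res$p[jj] <- pv
      res$n_used[jj] <- n_all
    }
    for (k in jc[!complete]) {
      use <- !is.na(G[, k])
      n_k <- sum(use)
      res$n_used[k] <- n_k
      if (n_k < pcov + 3L) { res$p[k] <- 1; next }
      Qk <- ortho_basis(C[use, , drop = FALSE])
      yr <- as.numeric(resid_vs(matrix(al$y[use]), Qk))
      xr <- as.numeric(resid_vs(matrix(G[use, k]), Qk))
      ssx <- sum(xr^2); ssy <- sum(yr^2)
      if (ssx <= 1e-10 * n_k || ssy <= 0) { res$p[k] <- 1; next }
      r2 <- sum(xr * yr)^2 / (ssx * ssy)
      df <- n_k - ncol(Qk) - 1L
      Fst <- r2 / max(1 - r2, 1e-300) * df
      res$p[k] <- stats::pf(Fst, 1, df, lower.tail = FALSE)
      res$effect[k] <- sum(xr * yr) / ssx
    }
  }
  res$p[is.na(res$p)] <- 1
  res$score <- -log10(pmax(res$p, 1e-300))
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Stepwise-regression GWAS model
#'
#' Population and subpopulation effects are fitted first; markers are then
#' added by forward selection (smallest partial-F p-value below `alpha`,
#' ties to the lower chromosome/position) with backward elimination after
#' each addition (any included marker whose final-model p-value rises to
#' `alpha` or above is removed). Selection stops when no candidate
#' qualifies, when the cumulative model R-squared (computed on the
#' residual sum of squares after the fixed effects) reaches `max_r2`, or
#' when `max_markers` markers are included. Missing dosages are
#' mean-imputed so all markers share one entry set.
#'
#' @inheritParams sv_scan
#' @param max_r2 cumulative R-squared stop (default 0.8).
#' @param max_markers maximum markers retained (default 300).
#' @param alpha inclusion/retention significance level (default 0.05).
#' @return `AssociationResult` data.frame (`model = "STR"`), one row per
#'   retained marker in selection order: `effect` (final-model
#'   coefficient), `p` (final-model p), `inclusion_p` (p at first entry),
#'   `r2` (incremental sum of squares at entry / total sum of squares
#'   after fixed effects), `score = -log10(p)`. Attribute `"cum_r2"` gives
#'   the cumulative R-squared.
#' @export
str_select <- function(variants, y, design, max_r2 = 0.8, max_markers = 300L,
                       alpha = 0.05) {
  al <- align_response(y, variants)
  n <- length(al$y)
  X <- mean_impute(variants$geno[al$entries, , drop = FALSE])
  W <- design_matrix(design, al$entries)
  Q0 <- ortho_basis(W)
  yr0 <- as.numeric(resid_vs(matrix(al$y), Q0))
  tss <- sum(yr0^2)
  info <- variants$info
  selected <- character(0)
  entry_p <- entry_r2 <- numeric(0)
  state_basis <- function(sel) ortho_basis(cbind(W, X[, sel, drop = FALSE]))
  # residualized state, updated incrementally on additions (Gram-Schmidt)
  # and rebuilt from scratch after a backward removal
  Xr <- resid_vs(X, Q0)
  yr <- as.numeric(resid_vs(matrix(al$y), Q0))
  p_model <- ncol(Q0)
  repeat {
    if (length(selected) >= max_markers) break
    if (tss > 0 && (1 - sum(yr^2) / tss) >= max_r2) break
    ssx <- colSums(Xr^2)
    ssy <- sum(yr^2)
    ok <- ssx > 1e-8 * n & !(colnames(X) %in% selected)
    df <- n - p_model - 1L
    if (!any(ok) || ssy <= 0 || df < 1L) break
    num <- as.numeric(crossprod(Xr, yr))
    r2 <- ifelse(ok, num^2 / (ssx * ssy), -Inf)
    k <- which.max(r2)
    Fk <- r2[k] / max(1 - r2[k], 1e-300) * df
    pk <- stats::pf(Fk, 1, df, lower.tail = FALSE)
    if (!(pk < alpha)) break
    selected <- c(selected, colnames(X)[k])
    entry_p <- c(entry_p, pk)
    entry_r2 <- c(entry_r2, num[k]^2 / ssx[k] / tss)
    uk <- Xr[, k] / sqrt(ssx[k])
    Xr <- Xr - uk %*% crossprod(uk, Xr)
    yr <- yr - uk * sum(uk * yr)
    p_model <- p_model + 1L
    # backward elimination on the current model
    removed <- FALSE
    repeat {
      fit <- marker_tests(al$y, W, X[, selected, drop = FALSE])
      worst <- which.max(fit$p)
      if (length(selected) && fit$p[worst] >= alpha) {
        keep <- seq_along(selected) != worst
        selected <- selected[keep]
        entry_p <- entry_p[keep]
        entry_r2 <- entry_r2[keep]
        removed <- TRUE
      } else break
      if (!length(selected)) break
    }
    if (removed) {
      Q <- state_basis(selected)
      Xr <- resid_vs(X, Q)
      yr <- as.numeric(resid_vs(matrix(al$y), Q))
      p_model <- ncol(Q)
    }
  }
  if (!length(selected)) {
    out <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), model = character(0),
                      effect = numeric(0), p = numeric(0),
                      inclusion_p = numeric(0), r2 = numeric(0),
                      score = numeric(0), n_used = integer(0))
    class(out) <- c("AssociationResult", "data.frame")
    attr(out, "cum_r2") <- 0
    return(out)
  }
  fit <- marker_tests(al$y, W, X[, selected, drop = FALSE])
  idx <- match(selected, info$variant_id)
  out <- data.frame(variant_id = selected, chrom = info$chrom[idx],
                    pos = info$pos[idx], model = "STR",
                    effect = fit$coef, p = fit$p, inclusion_p = entry_p,
                    r2 = entry_r2, score = -log10(pmax(fit$p, 1e-300)),
                    n_used = n, stringsAsFactors = FALSE)
  class(out) <- c("AssociationResult", "data.frame")
  rss_final <- sum(resid_vs(matrix(al$y), state_basis(selected))^2)
  attr(out, "cum_r2") <- if (tss > 0) 1 - rss_final / tss else 0
  out
}

# final-model coefficient t-tests for the marker columns of [W, Xsel];
# aliased markers (NA coefficient under pivoted QR) receive p = 1 so the
# backward step removes them
marker_tests <- function(y, W, Xsel) {
  M <- cbind(W, Xsel)
  qrM <- qr(M)
  r <- qrM$rank
  piv <- qrM$pivot[seq_len(r)]
  cf <- qr.coef(qrM, y)
  rss <- sum(qr.resid(qrM, y)^2)
  df <- length(y) - r
  s2 <- rss / max(df, 1)
  vars <- rep(NA_real_, ncol(M))
  R <- qr.R(qrM)[seq_len(r), seq_len(r), drop = FALSE]
  vars[piv] <- diag(chol2inv(R)) * s2
  m_idx <- ncol(W) + seq_len(ncol(Xsel))
  co <- cf[m_idx]
  tt <- co / sqrt(vars[m_idx])
  p <- 2 * stats::pt(abs(tt), max(df, 1), lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  list(coef = co, p = p)
}

#' Joint variance explained by a set of variants
#'
#' Proportion of the phenotypic sum of squares remaining after the
#' population/subpopulation fixed effects that is explained by fitting the
#' selected variants simultaneously in an additive OLS model. If there are
#' more selected variants than residual degrees of freedom, a
#' ridge-penalized fit is used instead and flagged.
#'
#' @inheritParams sv_scan
#' @param selected character vector of variant ids.
#' @return fraction in `[0, 1]`; attribute `"ridge"` is `TRUE` when the
#'   ridge fallback was used.
#' @export
variance_explained <- function(variants, selected, y, design) {
  if (!length(selected)) return(structure(0, ridge = FALSE))
  al <- align_response(y, variants)
  n <- length(al$y)
  X <- mean_impute(variants$geno[al$entries, selected, drop = FALSE])
  W <- design_matrix(design, al$entries)
  Q0 <- ortho_basis(W)
  yr <- as.numeric(resid_vs(matrix(al$y), Q0))
  Xr <- resid_vs(X, Q0)
  tss <- sum(yr^2)
  if (tss <= 0) return(structure(0, ridge = FALSE))
  ridge <- ncol(X) >= n - ncol(Q0)
  if (!ridge) {
    rss <- sum(qr.resid(qr(Xr), yr)^2)
  } else {
    message("variance_explained: more variants than residual df; ridge fit")
    XtX <- crossprod(Xr)
    lam <- 1e-3 * mean(diag(XtX))
    b <- solve(XtX + diag(lam, ncol(Xr)), crossprod(Xr, yr))
    rss <- sum((yr - Xr %*% b)^2)
  }
  structure(max(0, min(1, 1 - rss / tss)), ridge = ridge)
}
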