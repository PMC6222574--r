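#' Best linear unbiased estimates of entry means
#'
#' Adjusts replicated trial records to one value per entry with the
#' two-factor mixed model `value = entry (fixed) + group (random) + error`,
#' where the grouping factor is typically the trial (multi-environment
#' RIL data) or the replication (single-season derived populations). The
#' single variance ratio `lambda = var(group) / var(error)` is estimated by
#' restricted maximum likelihood via a bounded one-dimensional profile
#' search; given `lambda`, entry effects are the generalized-least-squares
#' solution. Because the entry incidence matrix has orthogonal columns and
#' the grouping factor has few levels, all linear algebra reduces to
#' diagonal-plus-low-rank (Woodbury) operations.
#'
#' With a single grouping level (or `lambda` numerically zero) BLUEs reduce
#' to per-entry means. Entries whose records are all missing are excluded
#' with a message.
#'
#' @param records a `TrialRecords` data.frame (`entry_id`, `trial_id`,
#'   `replication_id`, `value`).
#' @param random name of the column used as the random grouping factor
#'   (`"trial_id"` or `"replication_id"`).
#' @param var_ratio optional fixed variance ratio; skips REML estimation
#'   (used for oracle comparisons and degenerate designs).
#' @return data.frame of class `BlueTable` with columns `entry_id`, `blue`,
#'   `se`; attributes `"varcomp"` (named vector: `sigma2_e`, `sigma2_g`,
#'   `lambda`) and `"n_records"`.
#' @export
fit_blue <- function(records, random = "trial_id", var_ratio = NULL) {
  stopifnot(is.data.frame(records), random %in% names(records))
  rec <- records[!is.na(records$value), , drop = FALSE]
  dropped <- setdiff(unique(records$entry_id), unique(rec$entry_id))
  if (length(dropped))
    message(sprintf("fit_blue: %d entr(ies) with no non-missing records excluded",
                    length(dropped)))
  entry <- factor(rec$entry_id)
  grp <- factor(rec[[random]])
  y <- rec$value
  n <- length(y)
  p <- nlevels(entry)
  q <- nlevels(grp)
  ei <- as.integer(entry); gi <- as.integer(grp)
  D <- as.numeric(tabulate(ei, p))             # records per entry
  if ((q < 2L || n - p < 2L) && is.null(var_ratio)) {
    bl <- tapply(y, entry, mean)
    sdv <- tapply(y, entry, stats::sd)
    se <- ifelse(is.na(sdv), NA_real_, sdv / sqrt(D))
    out <- data.frame(entry_id = levels(entry), blue = as.numeric(bl),
                      se = as.numeric(se), stringsAsFactors = FALSE)
    class(out) <- c("BlueTable", "data.frame")
    attr(out, "varcomp") <- c(sigma2_e = mean(sdv^2, na.rm = TRUE),
                              sigma2_g = 0, lambda = 0)
    attr(out, "n_records") <- n
    return(out)
  }
  U <- matrix(0, p, q)                          # entry x group counts
  for (i in seq_len(n)) U[ei[i], gi[i]] <- U[ei[i], gi[i]] + 1
  mj <- as.numeric(tabulate(gi, q))             # records per group
  Xty <- as.numeric(rowsum(y, ei))              # per-entry sums
  Zty <- as.numeric(rowsum(y, gi))              # per-group sums
  yty <- sum(y * y)

  gls <- function(lam) {
    if (lam <= 0) {
      b <- Xty / D
      rss <- yty - sum(b * Xty)
      return(list(b = b, rss = rss, ldV = 0, ldA = sum(log(D)),
                  Ainv_diag = 1 / D))
    }
    w <- lam / (1 + lam * mj)
    r <- Xty - U %*% (w * Zty)                  # X'V^-1 y
    DiU <- U / D
    M <- diag(1 / w, q) - crossprod(U, DiU)     # W^-1 - U'D^-1U
    Mi <- solve(M)
    solveA <- function(v) {
      dv <- v / D
      dv + DiU %*% (Mi %*% crossprod(DiU, v))
    }
    b <- as.numeric(solveA(r))
    yVy <- yty - sum(w * Zty^2)
    rss <- yVy - sum(b * r)
    ldV <- sum(log1p(lam * mj))
    ldA <- sum(log(D)) + determinant(diag(q) - (w * t(U)) %*% DiU)$modulus
    Ainv_diag <- 1 / D + rowSums((DiU %*% Mi) * DiU)
    list(b = b, rss = rss, ldV = ldV, ldA = as.numeric(ldA),
         Ainv_diag = Ainv_diag)
  }
  reml_nll <- function(loglam) {
    g <- gls(exp(loglam))
    0.5 * ((n - p) * log(max(g$rss, 1e-300)) + g$ldV + g$ldA)
  }
  if (is.null(var_ratio)) {
    opt <- stats::optimize(reml_nll, c(-20, 20))
    lam <- exp(opt$minimum)
    # accept the boundary at zero if it does at least as well
    if (reml_nll(-30) <= opt$objective + 1e-10) lam <- 0
  } else lam <- var_ratio
  g <- gls(lam)
  sigma2_e <- g$rss / max(n - p, 1)
  out <- data.frame(entry_id = levels(entry), blue = g$b,
                    se = sqrt(pmax(sigma2_e * g$Ainv_diag, 0)),
                    stringsAsFactors = FALSE)
  class(out) <- c("BlueTable", "data.frame")
  attr(out, "varcomp") <- c(sigma2_e = sigma2_e, sigma2_g = lam * sigma2_e,
                            lambda = lam)
  attr(out, "n_records") <- n
  out
}

#' Summarize a BLUE table
#'
#' @param blues a `BlueTable`.
#' @return named vector: `n`, `mean`, `min`, `max`, `sd`.
#' @export
blue_summary <- function(blues) {
  c(n = nrow(blues), mean = mean(blues$blue), min = min(blues$blue),
    max = max(blues$blue), sd = stats::sd(blues$blue))
}
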