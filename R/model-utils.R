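## Shared regression plumbing: design matrices, imputation, projections.

#' Fixed-effect design matrix for population structure
#'
#' Builds the intercept + population + subpopulation dummy matrix used by
#' all association models, restricted to `entries` and reduced to full
#' column rank (aliased columns, e.g. a subpopulation coextensive with a
#' population, are dropped via pivoted QR).
#'
#' @param design a `StudyDesign`.
#' @param entries entry ids, in the order of the response vector.
#' @return numeric matrix with `length(entries)` rows and full column rank.
#' @export
design_matrix <- function(design, entries) {
  i <- match(entries, design$entry_id)
  if (anyNA(i)) stop("entries missing from design: ",
                     paste(utils::head(entries[is.na(i)]), collapse = ", "))
  d <- design[i, , drop = FALSE]
  pop <- factor(d$population); sub <- factor(d$subpopulation)
  W <- cbind(`(Intercept)` = rep(1, nrow(d)),
             if (nlevels(pop) > 1) stats::model.matrix(~pop)[, -1, drop = FALSE],
             if (nlevels(sub) > 1) stats::model.matrix(~sub)[, -1, drop = FALSE])
  qrW <- qr(W)
  W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
}

# column-mean imputation of missing dosages (fixed entry set across markers)
mean_impute <- function(geno) {
  if (!anyNA(geno)) return(geno)
  cm <- colMeans(geno, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na <- which(is.na(geno))
  geno[na] <- cm[(na - 1) %/% nrow(geno) + 1]
  geno
}

# orthonormal basis of a covariate matrix
ortho_basis <- function(W) {
  qrW <- qr(W)
  qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
}

# residualize columns of M against the orthonormal basis Q
resid_vs <- function(M, Q) M - Q %*% crossprod(Q, M)

# align a BlueTable (or named vector) to a VariantTable's entries;
# returns list(y, entries) over the intersection, preserving table order
align_response <- function(y, table) {
  if (inherits(y, "BlueTable") || (is.data.frame(y) && "blue" %in% names(y))) {
    v <- stats::setNames(y$blue, y$entry_id)
  } else if (!is.null(names(y))) v <- y
  else stop("y must be a BlueTable or a named numeric vector")
  ids <- intersect(entry_ids(table), names(v))
  if (!length(ids)) stop("no entries shared between genotypes and phenotypes")
  list(y = as.numeric(v[ids]), entries = ids)
}
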