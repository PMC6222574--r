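#' Forward selection of QTL cofactor markers
#'
#' First step of two-step composite interval mapping: markers are added one
#' at a time by largest partial F (given the population/subpopulation
#' design and the markers already selected) while the inclusion p-value is
#' below `alpha`. Ties resolve to the lower (chrom, pos). Markers
#' numerically collinear with the current model are skipped.
#'
#' @param variants a `VariantTable` (missing dosages mean-imputed).
#' @param y a `BlueTable` or named numeric vector of adjusted phenotypes.
#' @param design a `StudyDesign`.
#' @param alpha inclusion significance level in `(0, 1)`.
#' @param max_cofactors safety cap on the number of selected markers.
#' @return character vector of selected variant ids, in selection order,
#'   with attribute `"inclusion_p"`.
#' @export
forward_select_cofactors <- function(variants, y, design, alpha = 0.05,
                                     max_cofactors = 50L) {
  stopifnot(alpha > 0, alpha < 1)
  al <- align_response(y, variants)
  X <- mean_impute(variants$geno[al$entries, , drop = FALSE])
  W <- design_matrix(design, al$entries)
  Q <- ortho_basis(W)
  n <- length(al$y)
  Xr <- resid_vs(X, Q)
  yr <- as.numeric(resid_vs(matrix(al$y), Q))
  ss0 <- colSums(Xr^2)
  tol <- 1e-8 * max(ss0, 1)
  selected <- character(0); incl_p <- numeric(0)
  p_base <- ncol(Q)
  # candidate order already (chrom, pos) sorted; which.min takes first on tie
  repeat {
    if (length(selected) >= max_cofactors) break
    ssx <- colSums(Xr^2)
    ssy <- sum(yr^2)
    ok <- ssx > tol & !(colnames(Xr) %in% selected)
    if (!any(ok) || ssy <= 0) break
    num <- as.numeric(crossprod(Xr, yr))
    r2 <- ifelse(ok, num^2 / (ssx * ssy), -Inf)
    df <- n - p_base - length(selected) - 1L
    if (df < 1L) break
    k <- which.max(r2)
    Fk <- r2[k] / (1 - min(r2[k], 1 - 1e-12)) * df
    pk <- stats::pf(Fk, 1, df, lower.tail = FALSE)
    if (!(pk < alpha)) break
    selected <- c(selected, colnames(Xr)[k])
    incl_p <- c(incl_p, pk)
    xk <- Xr[, k] / sqrt(ssx[k])
    Xr <- Xr - xk %*% crossprod(xk, Xr)
    yr <- yr - xk * sum(xk * yr)
  }
  attr(selected, "inclusion_p") <- incl_p
  selected
}

#' Composite-interval marker-regression scan
#'
#' Scans each chromosome on a physical grid of spacing `step_bp` (default
#' 1 Mb). At each grid position the test marker is the nearest marker
#' inside the half-open window of width `step_bp` centered on the grid
#' point; cofactors falling inside that window are dropped from the
#' covariates so a cofactor never shields its own neighborhood. The score
#' is `LOD = (n/2) * log10(RSS_reduced / RSS_full)` from nested
#' least-squares fits (reduced = design + out-of-window cofactors; full
#' adds the test marker).
#'
#' @inheritParams forward_select_cofactors
#' @param cofactors variant ids from [forward_select_cofactors()].
#' @param step_bp grid spacing and window size in bp.
#' @param map optional `GeneticMap`; when supplied together with
#'   `window_cM`, cofactors are excluded by genetic rather than physical
#'   distance from the tested position, so a cofactor in a
#'   recombinationally cold region cannot shield a linked test position.
#' @param window_cM half-width of the genetic exclusion window (used only
#'   with `map`).
#' @return data.frame (`chrom`, `pos`, `marker`, `lod`); grid positions
#'   with no marker in the window are skipped.
#' @export
cim_scan <- function(variants, y, design, cofactors = character(0),
                     step_bp = 1e6, map = NULL, window_cM = 10) {
  stopifnot(step_bp > 0)
  al <- align_response(y, variants)
  X <- mean_impute(variants$geno[al$entries, , drop = FALSE])
  W <- design_matrix(design, al$entries)
  n <- length(al$y)
  info <- variants$info
  cof_idx <- match(cofactors, info$variant_id)
  out <- list()
  basis_cache <- list()
  for (ch in unique(info$chrom)) {
    j <- which(info$chrom == ch)
    pos <- info$pos[j]
    grid <- seq(min(pos), max(pos), by = step_bp)
    for (g in grid) {
      win <- abs(pos - g) <= step_bp / 2
      if (!any(win)) next
      jm <- j[win][which.min(abs(pos[win] - g))]
      same_chr <- !is.na(cof_idx) & info$chrom[cof_idx] == ch
      drop_cof <- same_chr & abs(info$pos[cof_idx] - g) <= step_bp / 2
      if (!is.null(map) && any(same_chr)) {
        cm_cof <- map_cM(map, info$chrom[cof_idx[same_chr]],
                         info$pos[cof_idx[same_chr]])
        cm_g <- map_cM(map, ch, g)
        drop_cof[same_chr] <- drop_cof[same_chr] |
          abs(cm_cof - cm_g) <= window_cM
      }
      keep_cof <- cof_idx[!drop_cof]
      ckey <- paste0("c", paste(keep_cof, collapse = ","))
      if (is.null(basis_cache[[ckey]])) {
        Qc <- ortho_basis(cbind(W, X[, keep_cof, drop = FALSE]))
        basis_cache[[ckey]] <- list(Q = Qc,
                                    yr = as.numeric(resid_vs(matrix(al$y),
                                                             Qc)))
      }
      Qc <- basis_cache[[ckey]]$Q
      yr <- basis_cache[[ckey]]$yr
      xr <- as.numeric(resid_vs(X[, jm, drop = FALSE], Qc))
      rss_red <- sum(yr^2)
      ssx <- sum(xr^2)
      rss_full <- if (ssx > 1e-12) rss_red - sum(xr * yr)^2 / ssx else rss_red
      lod <- (n / 2) * log10(rss_red / max(rss_full, 1e-300))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = g, marker = info$variant_id[jm], lod = lod,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genome-wide permutation threshold for the CIM scan
#'
#' Phenotypes are permuted within subpopulation strata (preserving the
#' structure the design models under the null); each permutation's
#' genome-wide maximum LOD is recorded and the `(1 - alpha)` quantile is
#' returned. By default no cofactors are used under the permuted null; a
#' `cofactor_rule` function `(variants, y, design) -> ids` can be supplied
#' to re-select cofactors per permutation.
#'
#' @inheritParams cim_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide type-I error rate.
#' @param cofactor_rule `NULL` (no cofactors; fast vectorized path) or a
#'   function re-selecting cofactors for each permuted phenotype.
#' @param seed optional seed.
#' @return LOD threshold (numeric scalar) with attribute `"max_lods"`.
#' @export
permutation_threshold <- function(variants, y, design, n_perm = 1000,
                                  alpha = 0.05, cofactor_rule = NULL,
                                  step_bp = 1e6, seed = NULL) {
  stopifnot(n_perm >= 100 || alpha == 1)
  if (!is.null(seed)) set.seed(seed)
  al <- align_response(y, variants)
  strata <- design$subpopulation[match(al$entries, design$entry_id)]
  n <- length(al$y)
  perm_within <- function(v) {
    out <- v
    for (s in unique(strata)) {
      i <- which(strata == s)
      out[i] <- v[i[sample.int(length(i))]]
    }
    out
  }
  if (is.null(cofactor_rule)) {
    X <- mean_impute(variants$geno[al$entries, , drop = FALSE])
    W <- design_matrix(design, al$entries)
    Q <- ortho_basis(W)
    # unique test markers over the scan grid
    info <- variants$info
    jm <- integer(0)
    for (ch in unique(info$chrom)) {
      j <- which(info$chrom == ch)
      pos <- info$pos[j]
      for (g in seq(min(pos), max(pos), by = step_bp)) {
        win <- abs(pos - g) <= step_bp / 2
        if (any(win)) jm <- c(jm, j[win][which.min(abs(pos[win] - g))])
      }
    }
    jm <- unique(jm)
    Xr <- resid_vs(X[, jm, drop = FALSE], Q)
    ssx <- colSums(Xr^2)
    ok <- ssx > 1e-12
    Yp <- vapply(seq_len(n_perm), function(b) perm_within(al$y),
                 numeric(n))
    Yr <- resid_vs(Yp, Q)
    ssy <- colSums(Yr^2)
    num <- crossprod(Xr[, ok, drop = FALSE], Yr)          # markers x perms
    r2 <- sweep(num^2, 1, ssx[ok], "/")
    r2 <- sweep(r2, 2, ssy, "/")
    lod <- -(n / 2) * log10(pmax(1 - r2, 1e-300))
    max_lods <- apply(lod, 2, max)
  } else {
    max_lods <- vapply(seq_len(n_perm), function(b) {
      yp <- stats::setNames(perm_within(al$y), al$entries)
      cof <- cofactor_rule(variants, yp, design)
      max(cim_scan(variants, yp, design, cof, step_bp)$lod)
    }, numeric(1))
  }
  thr <- as.numeric(stats::quantile(max_lods, 1 - alpha))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' Call QTL peaks and 1.5-LOD support intervals
#'
#' Local maxima of the scan profile above the threshold become QTL peaks
#' (peaks closer than one grid step are merged into the higher one). Each
#' support interval extends to the nearest position on each side where the
#' profile drops to `peak - lod_drop`, with linear interpolation between
#' scan points; if the profile never drops that far the interval runs to
#' the end of the scanned chromosome.
#'
#' @param scan data.frame from [cim_scan()].
#' @param threshold LOD threshold from [permutation_threshold()].
#' @param lod_drop support-interval drop in LOD units (default 1.5).
#' @param merge_bp peaks closer than this are merged (default: the scan's
#'   grid spacing).
#' @param expand_to_scan if `TRUE`, interval endpoints are pushed outward
#'   to the nearest scan position beyond the drop crossing (the flanking
#'   marker convention of linkage mapping); if `FALSE` (default) the
#'   crossing itself, linearly interpolated, is the endpoint.
#' @return data.frame (`chrom`, `peak_pos`, `marker`, `lod`,
#'   `interval_start`, `interval_end`), one row per QTL.
#' @export
call_qtl <- function(scan, threshold, lod_drop = 1.5, merge_bp = NULL,
                     expand_to_scan = FALSE) {
  stopifnot(lod_drop > 0)
  if (is.null(merge_bp)) {
    d <- unlist(tapply(scan$pos, scan$chrom, function(p) diff(sort(p))))
    merge_bp <- if (length(d)) stats::median(d) else 1e6
  }
  peaks <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    l <- s$lod; np <- nrow(s)
    is_max <- l >= as.numeric(threshold) &
      l >= c(-Inf, l[-np]) & l >= c(l[-1], -Inf)
    cand <- which(is_max)
    cand <- cand[order(l[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) || all(abs(s$pos[kept] - s$pos[i]) > merge_bp))
        kept <- c(kept, i)
    }
    for (i in kept) {
      target <- l[i] - lod_drop
      left <- s$pos[1]
      for (jj in rev(seq_len(i - 1))) {
        if (l[jj] <= target) {
          left <- if (expand_to_scan) s$pos[jj] else
            s$pos[jj + 1] - (l[jj + 1] - target) / (l[jj + 1] - l[jj]) *
              (s$pos[jj + 1] - s$pos[jj])
          break
        }
      }
      right <- s$pos[np]
      for (jj in seq_len(np - i) + i) {
        if (l[jj] <= target) {
          right <- if (expand_to_scan) s$pos[jj] else
            s$pos[jj - 1] + (l[jj - 1] - target) / (l[jj - 1] - l[jj]) *
              (s$pos[jj] - s$pos[jj - 1])
          break
        }
      }
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, peak_pos = s$pos[i], marker = s$marker[i], lod = l[i],
        interval_start = left, interval_end = right, stringsAsFactors = FALSE)
    }
  }
  if (!length(peaks))
    return(data.frame(chrom = character(0), peak_pos = numeric(0),
                      marker = character(0), lod = numeric(0),
                      interval_start = numeric(0), interval_end = numeric(0)))
  out <- do.call(rbind, peaks)
  out[order(out$chrom, out$peak_pos), , drop = FALSE]
}

#' Two-step joint QTL analysis
#'
#' Convenience wrapper chaining [forward_select_cofactors()], [cim_scan()],
#' [permutation_threshold()] and [call_qtl()] into a `QTLModel`: the
#' cofactor set, the genome scan, the permutation threshold and the called
#' peaks with their support intervals. The peak markers (`peaks$marker`)
#' are the QTL covariates consumed by [sv_scan()].
#'
#' @inheritParams forward_select_cofactors
#' @param step_bp scan grid spacing (bp).
#' @param n_perm permutations for the threshold.
#' @param perm_alpha genome-wide error rate for the threshold.
#' @param lod_drop support-interval drop.
#' @param threshold optional fixed LOD threshold; skips permutations.
#' @param map optional `GeneticMap`; when given, the linkage analysis runs
#'   on a sparse map-resolution marker subset (the variant nearest each
#'   `marker_spacing_cM` grid point per chromosome) rather than on the
#'   full dense variant set, as linkage mapping pipelines do.
#' @param marker_spacing_cM spacing of the linkage-marker grid (default
#'   1 cM).
#' @param max_cofactors cap on forward-selected cofactors (default 10).
#' @param seed optional seed for the permutations.
#' @return list of class `QTLModel`: `cofactors`, `scan`, `threshold`,
#'   `peaks`, `markers` (the linkage-marker ids used).
#' @export
joint_qtl <- function(variants, y, design, alpha = 0.05, step_bp = 1e6,
                      n_perm = 1000, perm_alpha = 0.05, lod_drop = 1.5,
                      threshold = NULL, map = NULL, marker_spacing_cM = 1,
                      max_cofactors = 10L, seed = NULL) {
  vmap <- variants
  if (!is.null(map)) {
    keep <- integer(0)
    cm <- map_cM(map, variants$info$chrom, variants$info$pos)
    for (ch in unique(variants$info$chrom)) {
      j <- which(variants$info$chrom == ch)
      for (g in seq(min(cm[j]), max(cm[j]), by = marker_spacing_cM)) {
        keep <- c(keep, j[which.min(abs(cm[j] - g))])
      }
    }
    vmap <- variants[, sort(unique(keep))]
  }
  # both cofactor selection and the scan use the sparse linkage markers;
  # dense-variant profiles are noise-jagged under near-perfect linkage and
  # would produce spurious sharp local maxima
  cof <- forward_select_cofactors(vmap, y, design, alpha, max_cofactors)
  scan <- cim_scan(vmap, y, design, cof, step_bp, map = map)
  if (is.null(threshold))
    threshold <- permutation_threshold(vmap, y, design, n_perm,
                                       perm_alpha, step_bp = step_bp,
                                       seed = seed)
  peaks <- call_qtl(scan, threshold, lod_drop,
                    expand_to_scan = !is.null(map))
  structure(list(cofactors = cof, scan = scan,
                 threshold = as.numeric(threshold), peaks = peaks,
                 markers = vmap$info$variant_id),
            class = "QTLModel")
}

#' @export
print.QTLModel <- function(x, ...) {
  cat(sprintf("QTLModel: %d cofactor(s), threshold LOD %.2f, %d peak(s)\n",
              length(x$cofactors), x$threshold, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Serialize a QTL model
#'
#' Writes the scan profile as TSV, the peaks as BED (half-open, 0-based
#' starts) and the whole model as JSON.
#'
#' @param qtl a `QTLModel`.
#' @param prefix output path prefix; writes `<prefix>_scan.tsv`,
#'   `<prefix>_peaks.bed`, `<prefix>.json`.
#' @return invisibly, the paths written.
#' @export
write_qtl_model <- function(qtl, prefix) {
  p_scan <- paste0(prefix, "_scan.tsv")
  p_bed <- paste0(prefix, "_peaks.bed")
  p_json <- paste0(prefix, ".json")
  utils::write.table(qtl$scan, p_scan, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(qtl$peaks$chrom,
                    as.integer(floor(qtl$peaks$interval_start)) - 1L,
                    as.integer(ceiling(qtl$peaks$interval_end)),
                    qtl$peaks$marker)
  utils::write.table(bed, p_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(qtl), p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_scan, p_bed, p_json))
}
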