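#' QTL-guided variant thinning
#'
#' Dense association results from closely linked populations concentrate
#' significant variants in narrow regions; thinning keeps only the most
#' significant representatives. Two rules apply:
#'
#' * inside each QTL support interval extended by `flank_bp`: the top
#'   `cap` variants by score are kept (no score threshold);
#' * outside those regions: variants passing the model's score threshold
#'   are grouped per chromosome such that no pairwise distance within a
#'   group exceeds `cluster_bp` (complete linkage, built greedily seeded
#'   by descending score), and the top `cap` per group are kept.
#'
#' Score ties at a cap boundary resolve to the lower (chrom, pos).
#'
#' @param result an `AssociationResult` data.frame with columns
#'   `variant_id`, `chrom`, `pos` and `score` (larger = more significant;
#'   `-log10 p` for SV and STR, model frequency for BMV).
#' @param qtl a `QTLModel` (or `NULL` for no QTL regions).
#' @param threshold score threshold applied outside QTL regions (strict
#'   `>`): 20 for the SV `-log10 p`, 0.02 for BMV MF, `-log10(0.05)` for
#'   STR.
#' @param flank_bp flanking width added to each QTL interval (default
#'   1 Mb).
#' @param cluster_bp maximum pairwise span within a cluster (default
#'   10 Mb).
#' @param cap maximum variants kept per QTL region or cluster (default 10).
#' @return the selected subset of `result` rows (deduplicated, sorted by
#'   chrom/pos) with an added `in_qtl_region` flag and `cluster` id.
#' @export
thin_model_results <- function(result, qtl, threshold, flank_bp = 1e6,
                               cluster_bp = 1e7, cap = 10L) {
  stopifnot(all(c("variant_id", "chrom", "pos", "score") %in% names(result)))
  res <- result[is.finite(result$score), , drop = FALSE]
  intervals <- if (!is.null(qtl) && nrow(qtl$peaks))
    data.frame(chrom = qtl$peaks$chrom,
               start = qtl$peaks$interval_start - flank_bp,
               end = qtl$peaks$interval_end + flank_bp)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  in_region <- rep(FALSE, nrow(res))
  region_id <- rep(NA_integer_, nrow(res))
  for (r in seq_len(nrow(intervals))) {
    hit <- res$chrom == intervals$chrom[r] &
      res$pos >= intervals$start[r] & res$pos < intervals$end[r]
    region_id[hit & !in_region] <- r
    in_region <- in_region | hit
  }
  # rank helper: by descending score, ties to lower (chrom, pos)
  top_cap <- function(idx, k) {
    o <- idx[order(-res$score[idx], res$chrom[idx], res$pos[idx])]
    o[seq_len(min(k, length(o)))]
  }
  picked <- integer(0)
  for (r in seq_len(nrow(intervals))) {
    idx <- which(region_id == r)
    if (length(idx)) picked <- c(picked, top_cap(idx, cap))
  }
  # outside regions: threshold, then greedy complete-linkage clusters
  out_idx <- which(!in_region & res$score > threshold)
  cluster_id <- rep(NA_integer_, nrow(res))
  next_cl <- 1L
  for (ch in unique(res$chrom[out_idx])) {
    rem <- out_idx[res$chrom[out_idx] == ch]
    while (length(rem)) {
      seed <- rem[order(-res$score[rem], res$pos[rem])][1]
      grp <- seed
      cand <- setdiff(rem, seed)
      cand <- cand[order(abs(res$pos[cand] - res$pos[seed]))]
      for (i in cand) {
        if (all(abs(res$pos[grp] - res$pos[i]) <= cluster_bp))
          grp <- c(grp, i)
      }
      cluster_id[grp] <- next_cl
      next_cl <- next_cl + 1L
      picked <- c(picked, top_cap(grp, cap))
      rem <- setdiff(rem, grp)
    }
  }
  picked <- sort(unique(picked))
  out <- res[picked, , drop = FALSE]
  out$in_qtl_region <- in_region[picked]
  out$cluster <- cluster_id[picked]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 100-kb bin id of a 1-based position: half-open [start, end) windows
bin_id <- function(chrom, pos, bin_bp = 1e5) {
  paste0(chrom, ":", floor((pos - 1) / bin_bp))
}

#' Bin selected variants and compare models
#'
#' Maps each selected variant to its half-open physical bin
#' (`floor((pos - 1) / bin_bp)`, default 100 kb) and summarizes per-model
#' bin sets and their overlap.
#'
#' @param selections named list of thinned `AssociationResult` data.frames
#'   (typically `list(SV = ..., STR = ..., BMV = ...)`).
#' @param bin_bp bin width in bp (default 100 kb).
#' @return list of class `BinSummary`: `bins` (data.frame: bin, chrom,
#'   n_models, detected-by flags per model), `per_model` (bin id sets),
#'   `counts` (named vector: total bins, bins per model, bins detected by
#'   two or more models, by all models, and variants in multi-model bins).
#' @export
bin_and_compare <- function(selections, bin_bp = 1e5) {
  stopifnot(is.list(selections), length(selections) >= 1,
            !is.null(names(selections)))
  per_model <- lapply(selections, function(s)
    unique(bin_id(s$chrom, s$pos, bin_bp)))
  all_bins <- sort(unique(unlist(per_model)))
  flags <- vapply(per_model, function(b) all_bins %in% b,
                  logical(length(all_bins)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(all_bins))
  colnames(flags) <- names(selections)
  n_models <- rowSums(flags)
  bins <- data.frame(bin = all_bins,
                     chrom = sub(":.*$", "", all_bins),
                     n_models = n_models, stringsAsFactors = FALSE)
  bins <- cbind(bins, as.data.frame(flags))
  multi <- all_bins[n_models >= 2]
  n_var_multi <- sum(vapply(selections, function(s)
    sum(bin_id(s$chrom, s$pos, bin_bp) %in% multi), numeric(1)))
  # count unique variants (a variant may be selected by several models)
  vm <- unique(unlist(lapply(selections, function(s)
    s$variant_id[bin_id(s$chrom, s$pos, bin_bp) %in% multi])))
  counts <- c(total_bins = length(all_bins),
              stats::setNames(lengths(per_model),
                              paste0("bins_", names(per_model))),
              bins_ge2_models = length(multi),
              bins_all_models = sum(n_models == length(selections)),
              variants_in_multi_bins = length(vm))
  structure(list(bins = bins, per_model = per_model, counts = counts,
                 bin_bp = bin_bp), class = "BinSummary")
}

#' Select the validation candidate set
#'
#' All variants falling in bins detected by at least two models enter the
#' validation set; in addition, for each model, its top `n_private_bins`
#' private bins (ranked by the model's best score in the bin) contribute
#' their `per_bin_max` most significant variants.
#'
#' @param bin_summary a `BinSummary` from [bin_and_compare()].
#' @param selections the same named list of thinned results.
#' @param n_private_bins private bins taken per model (default 20; fewer
#'   if a model has fewer, with a message).
#' @param per_bin_max variants per private bin (default 2).
#' @return data.frame: `variant_id`, `chrom`, `pos`, `bin`, `n_models`,
#'   `models` (comma-joined provenance), `shared` (multi-model bin flag).
#' @export
select_validation_set <- function(bin_summary, selections,
                                  n_private_bins = 20L, per_bin_max = 2L) {
  stopifnot(inherits(bin_summary, "BinSummary"))
  bb <- bin_summary$bin_bp
  tagged <- lapply(names(selections), function(mod) {
    s <- selections[[mod]]
    if (!nrow(s)) return(NULL)
    data.frame(variant_id = s$variant_id, chrom = s$chrom, pos = s$pos,
               score = s$score, model = mod,
               bin = bin_id(s$chrom, s$pos, bb), stringsAsFactors = FALSE)
  })
  tagged <- do.call(rbind, tagged)
  multi <- bin_summary$bins$bin[bin_summary$bins$n_models >= 2]
  keep <- tagged[tagged$bin %in% multi, , drop = FALSE]
  for (mod in names(selections)) {
    priv <- setdiff(bin_summary$per_model[[mod]],
                    unlist(bin_summary$per_model[names(selections) != mod]))
    tm <- tagged[tagged$model == mod & tagged$bin %in% priv, , drop = FALSE]
    if (!nrow(tm)) next
    best <- tapply(tm$score, tm$bin, max)
    n_take <- min(n_private_bins, length(best))
    if (n_take < n_private_bins)
      message(sprintf("select_validation_set: %s has only %d private bin(s)",
                      mod, length(best)))
    top_bins <- names(sort(best, decreasing = TRUE))[seq_len(n_take)]
    for (b in top_bins) {
      tb <- tm[tm$bin == b, , drop = FALSE]
      tb <- tb[order(-tb$score, tb$chrom, tb$pos), , drop = FALSE]
      keep <- rbind(keep, tb[seq_len(min(per_bin_max, nrow(tb))), ])
    }
  }
  if (is.null(keep) || !nrow(keep))
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), bin = character(0),
                      n_models = integer(0), models = character(0),
                      shared = logical(0)))
  prov <- tapply(keep$model, keep$variant_id, function(m)
    paste(sort(unique(m)), collapse = ","))
  out <- keep[!duplicated(keep$variant_id), c("variant_id", "chrom", "pos",
                                              "bin"), drop = FALSE]
  out$n_models <- bin_summary$bins$n_models[match(out$bin,
                                                 bin_summary$bins$bin)]
  out$models <- as.character(prov[out$variant_id])
  out$shared <- out$bin %in% multi
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
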