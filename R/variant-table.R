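#' Genotype table of allele dosages
#'
#' A `VariantTable` couples a variant annotation table (chromosome, 1-based
#' physical position, ref/alt alleles) with an entries x variants matrix of
#' additive allele dosages: 0, 1 or 2 copies of the non-reference allele,
#' with `NA` marking missing calls. Variants are stored sorted by chromosome
#' and position; positions are strictly increasing within a chromosome.
#'
#' @param geno integer matrix, entries in rows, variants in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based physical positions (bp).
#' @param ref,alt allele strings; default `"A"`/`"B"` placeholders for
#'   simulated data.
#' @param variant_id optional variant identifiers; default `chrom_pos`.
#' @param entry_id optional entry identifiers; default taken from
#'   `rownames(geno)` or generated.
#' @return An object of class `VariantTable` with components `info`
#'   (data.frame: `variant_id`, `chrom`, `pos`, `ref`, `alt`) and `geno`
#'   (dosage matrix with entry/variant dimnames).
#' @export
variant_table <- function(geno, chrom, pos, ref = NULL, alt = NULL,
                          variant_id = NULL, entry_id = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  m <- ncol(geno)
  stopifnot(length(chrom) == m, length(pos) == m)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("B", m)
  if (is.null(variant_id)) variant_id <- paste(chrom, pos, sep = "_")
  if (is.null(entry_id)) {
    entry_id <- rownames(geno)
    if (is.null(entry_id)) entry_id <- sprintf("E%04d", seq_len(nrow(geno)))
  }
  info <- data.frame(variant_id = as.character(variant_id),
                     chrom = as.character(chrom),
                     pos = as.integer(pos),
                     ref = as.character(ref), alt = as.character(alt),
                     stringsAsFactors = FALSE)
  ord <- order(info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (anyDuplicated(info$variant_id))
    stop("duplicate variant ids")
  dup <- duplicated(paste(info$chrom, info$pos))
  if (any(dup))
    stop("duplicate (chrom, pos) coordinates")
  rownames(info) <- NULL
  dimnames(geno) <- list(entry_id, info$variant_id)
  structure(list(info = info, geno = geno), class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat(sprintf("VariantTable: %d entries x %d variants on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$info$chrom))))
  cat(sprintf("  mean call rate %.3f, mean MAF %.3f\n",
              mean(call_rate(x)), mean(maf(x), na.rm = TRUE)))
  invisible(x)
}

#' @rdname variant_table
#' @param x a `VariantTable`.
#' @export
n_variants <- function(x) ncol(x$geno)

#' @rdname variant_table
#' @export
n_entries <- function(x) nrow(x$geno)

#' @rdname variant_table
#' @export
entry_ids <- function(x) rownames(x$geno)

#' Per-variant call rate and minor allele frequency
#'
#' `call_rate()` is the fraction of non-missing calls per variant over all
#' entries of the table. `maf()` is the minor allele frequency computed from
#' non-missing calls only (`NaN` for fully missing variants); it always lies
#' in `[0, 0.5]`.
#'
#' @param x a `VariantTable`.
#' @param entries optional subset of entry ids over which to compute the
#'   frequency (e.g. founders only).
#' @return numeric vector, one value per variant.
#' @export
call_rate <- function(x, entries = NULL) {
  g <- if (is.null(entries)) x$geno else x$geno[entries, , drop = FALSE]
  colMeans(!is.na(g))
}

#' @rdname call_rate
#' @export
maf <- function(x, entries = NULL) {
  p <- alt_freq(x, entries)
  pmin(p, 1 - p)
}

#' @rdname call_rate
#' @export
alt_freq <- function(x, entries = NULL) {
  g <- if (is.null(entries)) x$geno else x$geno[entries, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Subset a VariantTable
#'
#' @param x a `VariantTable`.
#' @param i entry selector (ids, indices or logical).
#' @param j variant selector (ids, indices or logical).
#' @param ... ignored.
#' @export
`[.VariantTable` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(j)) j <- match(j, x$info$variant_id)
  g <- x$geno[i, j, drop = FALSE]
  info <- x$info[j, , drop = FALSE]
  variant_table(g, info$chrom, info$pos, info$ref, info$alt,
                info$variant_id, rownames(g))
}

#' Filter variants on call rate, frequency and polymorphism
#'
#' Retains variants whose call rate and minor allele frequency meet the
#' thresholds and that are polymorphic (at least two distinct observed
#' dosage values). Defaults mirror the processing used for multi-parent GWAS
#' panels: call rate >= 0.4 and MAF >= 0.1. Variant order is preserved.
#'
#' @param table a `VariantTable`.
#' @param min_call_rate,min_maf thresholds in `[0, 1]`.
#' @param strict if `TRUE`, use strict inequalities (`>` rather than `>=`),
#'   as in the informative-variant definition for validation panels.
#' @param maf_entries optional entry ids over which MAF is computed (e.g.
#'   founder lines rather than the full derived panel); call rate is always
#'   computed over all entries of `table`.
#' @return the filtered `VariantTable`; an attribute `"filter_counts"`
#'   records how many variants each rule removed.
#' @export
filter_variants <- function(table, min_call_rate = 0.4, min_maf = 0.1,
                            strict = FALSE, maf_entries = NULL) {
  if (!is.finite(min_call_rate) || !is.finite(min_maf) ||
      min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1)
    stop("thresholds must be finite fractions in [0, 1]")
  if (n_variants(table) == 0L) return(table)
  cr <- call_rate(table)
  mf <- maf(table, maf_entries)
  poly <- vapply(seq_len(ncol(table$geno)), function(k) {
    v <- table$geno[, k]
    length(unique(v[!is.na(v)])) >= 2L
  }, logical(1))
  cmp <- if (strict) `>` else `>=`
  keep_cr <- cmp(cr, min_call_rate)
  keep_mf <- !is.na(mf) & cmp(mf, min_maf)
  keep <- keep_cr & keep_mf & poly
  out <- table[, which(keep)]
  attr(out, "filter_counts") <- c(
    input = n_variants(table),
    low_call_rate = sum(!keep_cr),
    low_maf = sum(keep_cr & !keep_mf),
    monomorphic = sum(keep_cr & keep_mf & !poly),
    kept = sum(keep))
  out
}

#' Merge genotype tables in consensus mode
#'
#' Variants are matched across tables by (chrom, pos); the union of variants
#' and the union of entries are returned. Where two sources give the same
#' entry a call, agreeing calls are kept and conflicting non-missing calls
#' are set to missing. Variants whose ref/alt labels disagree between
#' sources are dropped with a warning.
#'
#' @param tables a list of `VariantTable` objects on one coordinate system.
#' @return merged `VariantTable`; attribute `"consensus_counts"` reports the
#'   number of conflicting cells blanked and allele-mismatched variants
#'   dropped.
#' @export
merge_consensus <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1L]])
  key <- function(t) paste(t$info$chrom, t$info$pos, sep = ":")
  all_keys <- unique(unlist(lapply(tables, key)))
  all_entries <- unique(unlist(lapply(tables, entry_ids)))
  # detect allele-label mismatches
  allele_tab <- list()
  drop_keys <- character(0)
  for (t in tables) {
    k <- key(t)
    al <- paste(t$info$ref, t$info$alt, sep = "/")
    for (i in seq_along(k)) {
      prev <- allele_tab[[k[i]]]
      if (is.null(prev)) allele_tab[[k[i]]] <- al[i]
      else if (prev != al[i]) drop_keys <- c(drop_keys, k[i])
    }
  }
  drop_keys <- unique(drop_keys)
  if (length(drop_keys))
    warning(sprintf("dropping %d variant(s) with conflicting allele labels",
                    length(drop_keys)))
  keep_keys <- setdiff(all_keys, drop_keys)
  geno <- matrix(NA_real_, length(all_entries), length(keep_keys),
                 dimnames = list(all_entries, keep_keys))
  conflict <- matrix(FALSE, length(all_entries), length(keep_keys))
  for (t in tables) {
    k <- key(t)
    jj <- match(k, keep_keys)
    sel <- !is.na(jj)
    ii <- match(entry_ids(t), all_entries)
    g <- t$geno[, sel, drop = FALSE]
    jj <- jj[sel]
    cur <- geno[ii, jj, drop = FALSE]
    clash <- !is.na(cur) & !is.na(g) & cur != g
    conflict[ii, jj] <- conflict[ii, jj] | clash
    take <- is.na(cur) & !is.na(g)
    cur[take] <- g[take]
    geno[ii, jj] <- cur
  }
  geno[conflict] <- NA_real_
  n_conflict <- sum(conflict)
  if (n_conflict > 0)
    message(sprintf("consensus merge: %d conflicting call(s) set to missing",
                    n_conflict))
  # recover info rows from the first table providing each key
  info <- do.call(rbind, lapply(tables, function(t) t$info))
  info$key <- paste(info$chrom, info$pos, sep = ":")
  info <- info[!duplicated(info$key), , drop = FALSE]
  info <- info[match(keep_keys, info$key), , drop = FALSE]
  out <- variant_table(geno, info$chrom, info$pos, info$ref, info$alt,
                       info$variant_id, all_entries)
  attr(out, "consensus_counts") <- c(conflicting_calls = n_conflict,
                                     allele_mismatch_dropped = length(drop_keys))
  out
}
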