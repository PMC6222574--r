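#' Project founder genotypes onto F1 and BC1 derivatives
#'
#' For entries whose genomes are deterministic combinations of two known
#' homozygous haplotypes, dosages follow from Mendelian sums: an F1 of
#' parents with dosages `a` and `b` (each 0 or 2) carries `a/2 + b/2`
#' copies; a BC1 of a homozygous RIL by a homozygous recurrent parent
#' likewise carries one allele from each. Heterozygous parental calls are
#' not phase-resolvable and are treated as missing (with a warning);
#' missing parental calls propagate to missing projected calls.
#'
#' @param founders `VariantTable` holding the parental genotypes (founder
#'   lines, and RIL genotypes for BC1 projection).
#' @param pedigree a [pedigree()] with `cross_type` `"F1"` or `"BC1"`.
#' @return `VariantTable` of projected entries over the founder variants.
#' @export
project_from_parents <- function(founders, pedigree) {
  stopifnot(inherits(founders, "VariantTable"), inherits(pedigree, "Pedigree"))
  ped <- pedigree[pedigree$cross_type %in% c("F1", "BC1"), , drop = FALSE]
  miss_par <- setdiff(unique(c(ped$parent_a, ped$parent_b)), entry_ids(founders))
  if (length(miss_par))
    stop("parents absent from founder table: ", paste(miss_par, collapse = ", "))
  hap <- founders$geno / 2          # allele contribution per parent
  het <- !is.na(founders$geno) & founders$geno == 1
  if (any(het)) {
    warning(sprintf("%d heterozygous parental call(s) treated as missing",
                    sum(het)))
    hap[het] <- NA_real_
  }
  g <- hap[ped$parent_a, , drop = FALSE] + hap[ped$parent_b, , drop = FALSE]
  rownames(g) <- ped$entry_id
  variant_table(g, founders$info$chrom, founders$info$pos,
                founders$info$ref, founders$info$alt,
                founders$info$variant_id, ped$entry_id)
}

#' Impute dense founder variants onto RILs from a sparse scaffold
#'
#' Each RIL chromosome is treated as a mosaic of founder-of-origin blocks.
#' Scaffold markers that are informative between the family's two founders
#' (both parents called, homozygous, and different) and called homozygous in
#' the RIL vote for one parent; maximal runs of concordant votes define
#' blocks, with block boundaries placed at the midpoint between the flanking
#' discordant scaffold markers. Dense founder variants inside a block
#' receive that founder's allele; variants outside any block (no informative
#' scaffold evidence on the chromosome) and heterozygous or unmatched
#' scaffold calls yield missing dense calls. Dense variants where both
#' parents carry the same allele receive it regardless of block structure,
#' and markers directly observed in the scaffold keep their observed calls.
#'
#' @param scaffold `VariantTable` of sparse genotyped markers on the RILs
#'   (e.g. GBS calls).
#' @param founders `VariantTable` of dense founder genotypes.
#' @param pedigree a [pedigree()] with `cross_type == "RIL"` mapping each
#'   RIL to its two family founders.
#' @return `VariantTable` of dense imputed RIL genotypes; attribute
#'   `"impute_log"` counts RILs with no scaffold evidence.
#' @export
impute_ril_dense <- function(scaffold, founders, pedigree) {
  stopifnot(inherits(scaffold, "VariantTable"),
            inherits(founders, "VariantTable"), inherits(pedigree, "Pedigree"))
  ped <- pedigree[pedigree$cross_type == "RIL", , drop = FALSE]
  dense_info <- founders$info
  chroms <- unique(dense_info$chrom)
  out <- matrix(NA_real_, nrow(ped), nrow(dense_info),
                dimnames = list(ped$entry_id, dense_info$variant_id))
  # scaffold columns indexed into the dense coordinate system by (chrom,pos)
  sc_key <- paste(scaffold$info$chrom, scaffold$info$pos)
  no_evidence <- character(0)
  for (r in seq_len(nrow(ped))) {
    pa <- ped$parent_a[r]; pb <- ped$parent_b[r]
    fa <- founders$geno[pa, ]; fb <- founders$geno[pb, ]
    ril_id <- ped$entry_id[r]
    has_sc <- ril_id %in% entry_ids(scaffold)
    row_has_block <- FALSE
    for (ch in chroms) {
      jd <- which(dense_info$chrom == ch)
      pos_d <- dense_info$pos[jd]
      a <- fa[jd]; b <- fb[jd]
      same <- !is.na(a) & !is.na(b) & a == b
      # blocks from scaffold votes
      if (has_sc) {
        js <- which(scaffold$info$chrom == ch)
        if (length(js)) {
          spos <- scaffold$info$pos[js]
          sg <- scaffold$geno[ril_id, js]
          # parental dosages at scaffold positions (match by coordinate)
          jmatch <- match(paste(ch, spos), paste(ch, pos_d))
          pa_s <- a[jmatch]; pb_s <- b[jmatch]
          informative <- !is.na(pa_s) & !is.na(pb_s) &
            pa_s != pb_s & pa_s %in% c(0, 2) & pb_s %in% c(0, 2) &
            !is.na(sg) & sg %in% c(0, 2)
          vote <- rep(NA_integer_, length(js))
          vote[informative & sg == pa_s] <- 1L   # parent a
          vote[informative & sg == pb_s] <- 2L   # parent b
          ok <- !is.na(vote)
          if (any(ok)) {
            vpos <- spos[ok]; v <- vote[ok]
            # run-length blocks with midpoint boundaries
            runs <- rle(v)
            ends_idx <- cumsum(runs$lengths)
            starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
            b_start <- c(-Inf, (vpos[ends_idx[-length(ends_idx)]] +
                                  vpos[starts_idx[-1L]]) / 2)
            b_end <- c(b_start[-1L], Inf)
            assign_f <- runs$values
            blk <- findInterval(pos_d, b_start)  # which block each dense pos
            src <- assign_f[blk]
            imp <- ifelse(src == 1L, a, b)
            out[r, jd] <- imp
            row_has_block <- TRUE
          }
        }
      }
      if (any(same)) out[r, jd[same]] <- a[same]
      # observed scaffold calls take precedence over block inference
      if (has_sc) {
        js <- which(scaffold$info$chrom == ch)
        if (length(js)) {
          jmatch <- match(paste(ch, scaffold$info$pos[js]), paste(ch, pos_d))
          sg <- scaffold$geno[ril_id, js]
          keep <- !is.na(jmatch) & !is.na(sg)
          out[r, jd[jmatch[keep]]] <- sg[keep]
        }
      }
    }
    if (!row_has_block) no_evidence <- c(no_evidence, ril_id)
  }
  if (length(no_evidence))
    message(sprintf("impute_ril_dense: %d RIL(s) without scaffold evidence",
                    length(no_evidence)))
  res <- variant_table(out, dense_info$chrom, dense_info$pos,
                       dense_info$ref, dense_info$alt,
                       dense_info$variant_id, ped$entry_id)
  attr(res, "impute_log") <- list(no_scaffold = no_evidence)
  res
}
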