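#' Read and write genotype and metadata tables
#'
#' Plain-text interchange formats used across the pipeline. The dosage TSV
#' is a transposed matrix layout: one row per variant with columns
#' `variant_id`, `chrom`, `pos`, `ref`, `alt` followed by one dosage column
#' per entry (missing coded `NA`). Writers emit a deterministic column
#' order.
#'
#' @param table a `VariantTable`.
#' @param file path.
#' @return `read_dosage_tsv()` returns a `VariantTable`; writers return the
#'   file path invisibly.
#' @export
write_dosage_tsv <- function(table, file) {
  d <- cbind(table$info, as.data.frame(t(table$geno), check.names = FALSE))
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(variant_id = "character",
                                        chrom = "character",
                                        ref = "character",
                                        alt = "character"))
  meta <- c("variant_id", "chrom", "pos", "ref", "alt")
  g <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  variant_table(g, d$chrom, d$pos, d$ref, d$alt, d$variant_id, rownames(g))
}

#' @rdname write_dosage_tsv
#' @export
write_vcf <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", entry_ids(table)), collapse = "\t")),
             con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (k in seq_len(n_variants(table))) {
    g <- table$geno[, k]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(table$info$chrom[k], table$info$pos[k],
                       table$info$variant_id[k], table$info$ref[k],
                       table$info$alt[k], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- function(a) {
    out <- suppressWarnings(as.numeric(a))
    out[!a %in% c("0", "1")] <- NA_real_
    matrix(out, nrow(gt), ncol(gt))
  }
  dos <- num(substr(gt, 1, 1)) + num(substr(gt, 3, 3))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste(fix$CHROM, fix$POS, sep = "_")[
    is.na(ids) | ids == "."]
  variant_table(t(dos), fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT,
                ids, colnames(gt))
}

#' @rdname write_dosage_tsv
#' @param map a `GeneticMap`.
#' @export
write_map_tsv <- function(map, file) {
  utils::write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_map_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  genetic_map(d$chrom, d$pos_bp, d$pos_cM)
}

#' @rdname write_dosage_tsv
#' @param ped a `Pedigree`.
#' @export
write_pedigree_tsv <- function(ped, file) {
  utils::write.table(as.data.frame(ped), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_pedigree_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  pedigree(d$entry_id, d$parent_a, d$parent_b, d$cross_type)
}

#' @rdname write_dosage_tsv
#' @param records a `TrialRecords` data.frame.
#' @export
write_trials_tsv <- function(records, file) {
  utils::write.table(as.data.frame(records), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_trials_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  trial_records(d$entry_id, d$trial_id, d$replication_id, d$value)
}
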