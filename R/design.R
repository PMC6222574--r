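#' Study design, pedigree and genetic-map tables
#'
#' Light validated data.frame wrappers used throughout the pipeline.
#'
#' `study_design()` maps each entry to exactly one GWAS population (e.g.
#' RIL, BC1-to-parent-A, BC1-to-parent-B, diallel F1) and one subpopulation
#' (typically the RIL family of the non-common parent). These labels become
#' the fixed population/subpopulation effects of all association models.
#'
#' @param entry_id character entry identifiers.
#' @param population,subpopulation categorical labels, one per entry.
#' @return a data.frame of class `StudyDesign`.
#' @export
study_design <- function(entry_id, population, subpopulation) {
  population <- rep_len(population, length(entry_id))
  subpopulation <- rep_len(subpopulation, length(entry_id))
  if (anyDuplicated(entry_id)) stop("duplicate entry ids in design")
  d <- data.frame(entry_id = as.character(entry_id),
                  population = as.character(population),
                  subpopulation = as.character(subpopulation),
                  stringsAsFactors = FALSE)
  class(d) <- c("StudyDesign", "data.frame")
  d
}

#' @rdname study_design
#' @param parent_a,parent_b parental line identifiers.
#' @param cross_type one of `"RIL"`, `"BC1"`, `"F1"` per entry.
#' @export
pedigree <- function(entry_id, parent_a, parent_b, cross_type) {
  stopifnot(all(cross_type %in% c("RIL", "BC1", "F1")))
  d <- data.frame(entry_id = as.character(entry_id),
                  parent_a = as.character(parent_a),
                  parent_b = as.character(parent_b),
                  cross_type = as.character(cross_type),
                  stringsAsFactors = FALSE)
  class(d) <- c("Pedigree", "data.frame")
  d
}

#' @rdname study_design
#' @param chrom chromosome of each map anchor.
#' @param pos_bp physical position (bp, 1-based).
#' @param pos_cM genetic position (cM), non-decreasing within chromosome.
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM) {
  d <- data.frame(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                  pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos_bp), , drop = FALSE]
  for (ch in unique(d$chrom)) {
    cm <- d$pos_cM[d$chrom == ch]
    if (is.unsorted(cm)) stop("pos_cM must be non-decreasing within chromosome")
  }
  rownames(d) <- NULL
  class(d) <- c("GeneticMap", "data.frame")
  d
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation within each chromosome of the map; positions beyond
#' the mapped span take the boundary cM value (constant extrapolation).
#'
#' @param map a `GeneticMap`.
#' @param chrom,pos_bp vectors of query coordinates.
#' @return numeric cM positions.
#' @export
map_cM <- function(map, chrom, pos_bp) {
  out <- numeric(length(pos_bp))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) stop("chromosome absent from map: ", ch)
    if (nrow(m) == 1L) out[i] <- m$pos_cM
    else out[i] <- stats::approx(m$pos_bp, m$pos_cM, xout = pos_bp[i],
                                 rule = 2, ties = "ordered")$y
  }
  out
}

#' @rdname study_design
#' @param trial_id,replication_id trial and replication labels.
#' @param value observed trait value (e.g. kernel row number).
#' @export
trial_records <- function(entry_id, trial_id, replication_id, value) {
  d <- data.frame(entry_id = as.character(entry_id),
                  trial_id = as.character(trial_id),
                  replication_id = as.character(replication_id),
                  value = as.numeric(value), stringsAsFactors = FALSE)
  class(d) <- c("TrialRecords", "data.frame")
  d
}
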