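#' Configuration for a synthetic multi-parent study
#'
#' Describes a NAM-like design: one common parent crossed to each of the
#' other founders, recombinant inbred families derived by repeated selfing,
#' BC1 subsets backcrossed to two recurrent parents, and a partial diallel
#' among the founders. The trait is purely additive: each QTL contributes
#' `effect * dosage / 2` rows (so `effect` is the difference between the
#' two homozygous classes).
#'
#' @param n_founders number of founder lines (>= 2); founder 1 plays the
#'   common-parent role.
#' @param chrom_spec list of per-chromosome `c(length_bp, length_cM)`.
#' @param n_variants total variant count, allocated to chromosomes in
#'   proportion to physical length.
#' @param qtl_spec data.frame with columns `chrom`, `pos`, `effect` (rows);
#'   `NULL` places 5 default QTL with row-scale effects.
#' @param h2 narrow-sense heritability of entry means in `(0, 1]`.
#' @param n_ril_per_family RILs per family.
#' @param n_self_generations selfing generations after the F1 (single-seed
#'   descent).
#' @param n_bc1_per_family length-2 vector: BC1 entries per family to the
#'   common parent and to the second recurrent parent.
#' @param trait_mean trait intercept in rows (kernel-row-number-like).
#' @param founder_freq_range range of the uniform founder allele-frequency
#'   spectrum.
#' @param n_trials,n_reps,trial_sd replication structure and trial-effect
#'   standard deviation used by [simulate_phenotypes()].
#' @param seed integer master seed.
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(n_founders = 5,
                       chrom_spec = list(c(2e8, 150), c(2e8, 150)),
                       n_variants = 5000,
                       qtl_spec = NULL,
                       h2 = 0.6,
                       n_ril_per_family = 200,
                       n_self_generations = 6,
                       n_bc1_per_family = c(20, 8),
                       trait_mean = 15,
                       founder_freq_range = c(0.1, 0.5),
                       n_trials = 2, n_reps = 2, trial_sd = 0.5,
                       seed = 1) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (is.null(qtl_spec)) {
    n_chr <- length(chrom_spec)
    chr <- paste0("chr", rep_len(seq_len(n_chr), 5))
    len <- vapply(chrom_spec, `[`, numeric(1), 1)[rep_len(seq_len(n_chr), 5)]
    frac <- c(0.25, 0.6, 0.8, 0.4, 0.15)
    qtl_spec <- data.frame(chrom = chr, pos = round(len * frac),
                           effect = c(1.2, -1.0, 0.8, 0.7, -0.6))
  }
  if (!all(is.finite(qtl_spec$effect))) stop("QTL effects must be finite")
  cfg <- list(n_founders = n_founders, chrom_spec = chrom_spec,
              n_variants = n_variants, qtl_spec = qtl_spec, h2 = h2,
              n_ril_per_family = n_ril_per_family,
              n_self_generations = n_self_generations,
              n_bc1_per_family = n_bc1_per_family,
              trait_mean = trait_mean,
              founder_freq_range = founder_freq_range,
              n_trials = n_trials, n_reps = n_reps, trial_sd = trial_sd,
              seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

chrom_names <- function(config) paste0("chr", seq_along(config$chrom_spec))

#' Physical and genetic coordinates of a simulated variant set
#'
#' Variant physical positions are drawn uniformly per chromosome; genetic
#' positions follow a linear bp-to-cM map per chromosome (constant local
#' recombination rate), anchored at both chromosome ends.
#'
#' @param config a [sim_config()].
#' @return list with `info` (chrom, pos) and `map` (a `GeneticMap` with
#'   anchors at chromosome ends).
#' @keywords internal
sim_coords <- function(config) {
  lens_bp <- vapply(config$chrom_spec, `[`, numeric(1), 1)
  lens_cM <- vapply(config$chrom_spec, `[`, numeric(1), 2)
  alloc <- pmax(1L, round(config$n_variants * lens_bp / sum(lens_bp)))
  alloc[1] <- alloc[1] + (config$n_variants - sum(alloc))
  chrom <- rep(chrom_names(config), alloc)
  pos <- unlist(lapply(seq_along(alloc), function(c)
    sort(sample.int(lens_bp[c], alloc[c]))))
  # U-shaped recombination profile (pericentromeric suppression): cM mass
  # per physical decile is highest at the chromosome ends
  w <- c(3, 2, 1, 0.5, 0.25, 0.25, 0.5, 1, 2, 3)
  w <- w / sum(w)
  anchor_bp <- lapply(lens_bp, function(L) as.integer(round(seq(1, L, length.out = 11))))
  anchor_cM <- lapply(lens_cM, function(L) c(0, cumsum(w)) * L)
  map <- genetic_map(rep(chrom_names(config), each = 11),
                     unlist(anchor_bp), unlist(anchor_cM))
  list(info = data.frame(chrom = chrom, pos = as.integer(pos),
                         stringsAsFactors = FALSE),
       map = map, lens_bp = lens_bp, lens_cM = lens_cM)
}

#' Simulate homozygous founder genotypes
#'
#' Per-variant founder allele frequencies are drawn from a uniform spectrum
#' (default U(0.1, 0.5)); each founder carries the alternate allele in
#' homozygous state with that probability, so all calls are 0 or 2.
#'
#' @param config a [sim_config()].
#' @return a `VariantTable` of founders (`FND01`, ...) with attributes
#'   `"map"` (the `GeneticMap`) and `"coords"`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  co <- sim_coords(config)
  m <- nrow(co$info)
  p <- stats::runif(m, config$founder_freq_range[1], config$founder_freq_range[2])
  alle <- matrix(stats::rbinom(config$n_founders * m, 1, rep(p, each = config$n_founders)),
                 nrow = config$n_founders)
  ids <- sprintf("FND%02d", seq_len(config$n_founders))
  vt <- variant_table(2 * alle, co$info$chrom, co$info$pos, entry_id = ids)
  attr(vt, "map") <- co$map
  attr(vt, "coords") <- co
  vt
}

## internal fast meiosis: haplotypes as 0/1 integer matrix (2 x M),
## marker_cM list-indexed per chromosome via chrom_index
meiosis_ <- function(h1, h2, cm_by_chr, idx_by_chr, len_cM) {
  gam <- h1
  for (c in seq_along(idx_by_chr)) {
    idx <- idx_by_chr[[c]]
    L <- len_cM[c]
    nxo <- stats::rpois(1, L / 100)
    start <- stats::runif(1) < 0.5
    if (nxo == 0L) {
      if (start) gam[idx] <- h2[idx]
      next
    }
    xo <- sort(stats::runif(nxo, 0, L))
    seg <- findInterval(cm_by_chr[[c]], xo)
    use2 <- xor(start, seg %% 2 == 1)
    gam[idx[use2]] <- h2[idx[use2]]
  }
  gam
}

#' Simulate one meiosis
#'
#' Crossovers are placed under the Haldane (no-interference) model: the
#' count per chromosome is Poisson with mean `length_cM / 100` and
#' positions are uniform on the genetic scale. The returned gamete is a
#' mosaic of the two parental haplotypes.
#'
#' @param parent_haplotypes 2 x M matrix of alleles (0/1), one row per
#'   parental haplotype, columns in map order.
#' @param map a `GeneticMap` covering all markers.
#' @param chrom,pos_bp marker coordinates (length M, sorted as in
#'   `parent_haplotypes` columns).
#' @param seed optional seed.
#' @return integer vector of gamete alleles, length M.
#' @export
meiosis <- function(parent_haplotypes, map, chrom, pos_bp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cm <- map_cM(map, chrom, pos_bp)
  chrs <- unique(chrom)
  idx_by_chr <- lapply(chrs, function(ch) which(chrom == ch))
  cm_by_chr <- lapply(idx_by_chr, function(i) cm[i])
  len_cM <- vapply(seq_along(chrs), function(c) {
    m <- map[map$chrom == chrs[c], ]
    max(m$pos_cM)
  }, numeric(1))
  meiosis_(parent_haplotypes[1, ], parent_haplotypes[2, ],
           cm_by_chr, idx_by_chr, len_cM)
}

#' Simulate a complete multi-parent study
#'
#' Builds, from one [sim_config()]: RIL families (common parent x each
#' other founder, selfed by single-seed descent), BC1 subsets of the RILs
#' backcrossed to the common parent and to founder 2, and a partial diallel
#' of F1s among all founder pairs. Returns genotypes for all phenotyped
#' entries, the population/subpopulation design, the pedigree, the genetic
#' map, and a truth record with QTL assignments and per-entry additive
#' genetic values (`sum(effect * dosage) / 2`).
#'
#' @param config a [sim_config()].
#' @return list with components `geno` (`VariantTable`), `design`
#'   (`StudyDesign`), `pedigree`, `map`, `founders`, and `truth` (list:
#'   `qtl` data.frame with the causal `variant_id`s, `genetic_values`,
#'   `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  founders <- simulate_founders(config)   # seeds the RNG
  co <- attr(founders, "coords")
  map <- co$map
  chrom <- founders$info$chrom
  chrs <- chrom_names(config)
  idx_by_chr <- lapply(chrs, function(ch) which(chrom == ch))
  cm <- map_cM(map, chrom, founders$info$pos)
  cm_by_chr <- lapply(idx_by_chr, function(i) cm[i])
  len_cM <- co$lens_cM
  fhap <- founders$geno / 2               # founder haplotypes (0/1)

  self_down <- function(h1, h2, gens) {
    for (g in seq_len(gens)) {
      g1 <- meiosis_(h1, h2, cm_by_chr, idx_by_chr, len_cM)
      g2 <- meiosis_(h1, h2, cm_by_chr, idx_by_chr, len_cM)
      h1 <- g1; h2 <- g2
    }
    list(h1, h2)
  }

  entries <- list(); design_rows <- list(); ped_rows <- list()
  ril_haps <- list()
  nb <- config$n_bc1_per_family
  for (f in 2:config$n_founders) {
    fam <- sprintf("fam%02d", f)
    for (i in seq_len(config$n_ril_per_family)) {
      id <- sprintf("RIL_%02d_%03d", f, i)
      hp <- self_down(fhap[1, ], fhap[f, ], config$n_self_generations)
      ril_haps[[id]] <- hp
      entries[[id]] <- hp[[1]] + hp[[2]]
      design_rows[[id]] <- c(id, "NAM", fam)
      ped_rows[[id]] <- c(id, "FND01", sprintf("FND%02d", f), "RIL")
    }
    # BC1 to the common parent (recurrent FND01) and to founder 2
    bc_specs <- list(c(nb[1], 1L, "BC1A"), c(nb[2], 2L, "BC1B"))
    for (s in bc_specs) {
      n_bc <- as.integer(s[1]); rec <- as.integer(s[2]); popl <- s[3]
      n_bc <- min(n_bc, config$n_ril_per_family)
      for (i in seq_len(n_bc)) {
        rid <- sprintf("RIL_%02d_%03d", f, i)
        id <- sprintf("%s_%02d_%03d", popl, f, i)
        hp <- ril_haps[[rid]]
        gam <- meiosis_(hp[[1]], hp[[2]], cm_by_chr, idx_by_chr, len_cM)
        entries[[id]] <- gam + fhap[rec, ]
        design_rows[[id]] <- c(id, popl, fam)
        ped_rows[[id]] <- c(id, rid, sprintf("FND%02d", rec), "BC1")
      }
    }
  }
  # partial diallel F1s among all founder pairs
  pairs <- utils::combn(config$n_founders, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    id <- sprintf("DIA_%02dx%02d", i, j)
    entries[[id]] <- fhap[i, ] + fhap[j, ]
    design_rows[[id]] <- c(id, "DIA", "dia")
    ped_rows[[id]] <- c(id, sprintf("FND%02d", i), sprintf("FND%02d", j), "F1")
  }

  geno <- do.call(rbind, entries)
  vt <- variant_table(geno, founders$info$chrom, founders$info$pos,
                      founders$info$ref, founders$info$alt,
                      founders$info$variant_id, names(entries))
  dm <- do.call(rbind, design_rows)
  design <- study_design(dm[, 1], dm[, 2], dm[, 3])
  pm <- do.call(rbind, ped_rows)
  ped <- pedigree(pm[, 1], pm[, 2], pm[, 3], pm[, 4])

  # assign each configured QTL to the nearest variant that segregates among
  # the founders (a founder-monomorphic causal locus would carry no signal)
  qs <- config$qtl_spec
  fmaf <- maf(founders)
  qid <- character(nrow(qs))
  for (q in seq_len(nrow(qs))) {
    jc <- which(vt$info$chrom == qs$chrom[q] & fmaf > 0)
    qid[q] <- vt$info$variant_id[jc[which.min(abs(vt$info$pos[jc] - qs$pos[q]))]]
  }
  qtl <- data.frame(variant_id = qid,
                    chrom = vt$info$chrom[match(qid, vt$info$variant_id)],
                    pos = vt$info$pos[match(qid, vt$info$variant_id)],
                    effect = qs$effect, stringsAsFactors = FALSE)
  gv <- as.vector(vt$geno[, qid, drop = FALSE] %*% qtl$effect) / 2
  names(gv) <- entry_ids(vt)
  list(geno = vt, design = design, pedigree = ped, map = map,
       founders = founders,
       truth = list(qtl = qtl, genetic_values = gv, config = config))
}

#' Simulate replicated trial phenotypes
#'
#' Records follow `value = trait_mean + genetic_value + trial_effect +
#' residual`. Trial effects are common to all entries within a trial
#' (normal, sd `trial_sd`). The residual standard deviation is chosen so
#' that, at the configured replication (`n_trials * n_reps` records per
#' entry), the
#' variance of entry means decomposes as var(genetic) / var(entry mean)
#' close to `h2`.
#'
#' @param genetic_values named numeric vector of per-entry genetic values.
#' @param h2 target heritability of entry means, in `(0, 1]`.
#' @param n_trials,n_reps number of trials and replications per trial.
#' @param trial_sd trial-effect standard deviation (rows).
#' @param trait_mean trait intercept (rows).
#' @param seed optional seed.
#' @return a `TrialRecords` data.frame.
#' @export
simulate_phenotypes <- function(genetic_values, h2, n_trials = 2, n_reps = 2,
                                trial_sd = 0.5, trait_mean = 15, seed = NULL) {
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(genetic_values)
  r <- n_trials * n_reps
  varg <- stats::var(genetic_values)
  sd_e <- if (h2 == 1) 0 else sqrt(r * varg * (1 - h2) / h2)
  trial_eff <- stats::rnorm(n_trials, 0, trial_sd)
  rec <- expand.grid(entry = seq_len(n), trial = seq_len(n_trials),
                     rep = seq_len(n_reps))
  value <- trait_mean + genetic_values[rec$entry] + trial_eff[rec$trial] +
    stats::rnorm(nrow(rec), 0, sd_e)
  trial_records(names(genetic_values)[rec$entry],
                sprintf("T%02d", rec$trial), sprintf("R%02d", rec$rep), value)
}

#' Degrade a genotype table to a GBS-like scaffold
#'
#' Keeps a random subset of variants and masks random cells so the
#' expected call rate matches `call_rate`.
#'
#' @param table a `VariantTable`.
#' @param scaffold_fraction fraction of variants retained, in `(0, 1]`.
#' @param call_rate target per-cell call rate, in `(0, 1]`.
#' @param seed optional seed.
#' @return a sparser `VariantTable`.
#' @export
simulate_gbs <- function(table, scaffold_fraction, call_rate, seed = NULL) {
  stopifnot(scaffold_fraction > 0, scaffold_fraction <= 1,
            call_rate > 0, call_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_variants(table)
  keep <- sort(sample.int(m, max(1L, round(scaffold_fraction * m))))
  out <- table[, keep]
  if (call_rate < 1) {
    mask <- stats::runif(length(out$geno)) > call_rate
    out$geno[mask] <- NA_real_
  }
  out
}

#' Realized heritability of entry means
#'
#' Regression-based check of the phenotype generator: the squared
#' correlation between per-entry record means and true genetic values.
#'
#' @param records a `TrialRecords` data.frame.
#' @param genetic_values named truth vector.
#' @return list with `r2` (realized h2) and `slope` of the regression of
#'   entry means on genetic values.
#' @export
realized_h2 <- function(records, genetic_values) {
  em <- tapply(records$value, records$entry_id, mean)
  gv <- genetic_values[names(em)]
  fit <- stats::lm(em ~ gv)
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Serialize simulation truth and configuration
#'
#' The truth record (QTL assignments, per-entry genetic values, the
#' generating configuration) is written as JSON; the configuration alone
#' round-trips through a YAML key-value file.
#'
#' @param truth truth record from [simulate_study()].
#' @param config a [sim_config()].
#' @param file output path.
#' @return the path, invisibly (`read_sim_config()` returns a `SimConfig`).
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(list(qtl = truth$qtl,
                            genetic_values = as.list(truth$genetic_values),
                            config = unclass(truth$config)),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_truth_json
#' @export
write_sim_config <- function(config, file) {
  stopifnot(inherits(config, "SimConfig"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the yaml package")
  cfg <- unclass(config)
  cfg$qtl_spec <- as.list(cfg$qtl_spec)
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' @rdname write_truth_json
#' @export
read_sim_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the yaml package")
  cfg <- yaml::read_yaml(file)
  cfg$qtl_spec <- as.data.frame(cfg$qtl_spec, stringsAsFactors = FALSE)
  cfg$chrom_spec <- lapply(cfg$chrom_spec, unlist)
  do.call(sim_config, cfg)
}
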