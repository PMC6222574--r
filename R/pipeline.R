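#' Configuration of the end-to-end synthetic study
#'
#' Bundles every stage's parameters with defaults mirroring the analysis
#' as run on real multi-parent data (call-rate/MAF filters 0.4/0.1, 1-Mb
#' CIM grid, 1.5-LOD intervals, thinning thresholds 20 / 0.02 / 0.05,
#' 100-kb bins, 1-Mb flanks, 10-Mb clusters, caps of 10) at problem sizes
#' a single workstation handles in minutes. A single master seed fans out
#' to per-stage seeds.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param seed master seed.
#' @param out_dir optional artifact directory (created if needed); `NULL`
#'   keeps everything in memory.
#' @param stages named logical toggles: `gbs_impute`, `bayesc`,
#'   `validation`.
#' @param filter,gbs,qtl,str,bayesc,thin,validation_set,validation
#'   per-stage parameter lists; see the implementation for fields.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(sim = sim_config(),
                       seed = 1,
                       out_dir = NULL,
                       stages = c(gbs_impute = TRUE, bayesc = TRUE,
                                  validation = TRUE),
                       filter = list(min_call_rate = 0.4, min_maf = 0.1),
                       gbs = list(scaffold_fraction = 0.3, call_rate = 0.8),
                       qtl = list(cofactor_alpha = 0.05, max_cofactors = 10,
                                  step_bp = 1e6, n_perm = 200,
                                  perm_alpha = 0.05, lod_drop = 1.5),
                       str = list(max_r2 = 0.8, max_markers = 100,
                                  alpha = 0.05),
                       bayesc = list(expected_markers = 20,
                                     chain_length = 6000, burn_in = 500,
                                     step1_chain = 1000, step1_burn = 100),
                       thin = list(sv_threshold = 20,
                                   str_threshold = -log10(0.05),
                                   bmv_threshold = 0.02, flank_bp = 1e6,
                                   cluster_bp = 1e7, cap = 10),
                       validation_set = list(n_private_bins = 20,
                                             per_bin_max = 2,
                                             n_controls = 9),
                       validation = list(n_elite = 200,
                                         elite_generations = 10,
                                         elite_Ne = 80,
                                         elite_self_generations = 3,
                                         n_bg_snps = 600,
                                         n_accessions = 200, pool_size = 12,
                                         pool_tails = c(0.25, 0.25),
                                         fst = 0.2,
                                         bsle_generations = 30,
                                         bsle_Ne = 100,
                                         bsle_selected_fraction = 0.2,
                                         genetic_correlation = -0.6,
                                         h2_validation = 0.5,
                                         drift_n_sim = 1000)) {
  structure(list(sim = sim, seed = seed, out_dir = out_dir, stages = stages,
                 filter = filter, gbs = gbs, qtl = qtl, str = str,
                 bayesc = bayesc, thin = thin,
                 validation_set = validation_set, validation = validation),
            class = "RunConfig")
}

#' Run the complete synthetic comparative-GWAS study
#'
#' Executes, in order: study simulation; GBS degradation and
#' pedigree-based re-imputation of the RIL genotypes (optional stage);
#' variant filtering; BLUE adjustment of replicated phenotypes; joint QTL
#' analysis; the three association models (single-variant scan, stepwise
#' regression, BayesC); QTL-guided thinning, 100-kb binning and
#' cross-model comparison; validation-set selection with negative
#' controls; and the three-population genetic-validation suite. Every
#' stage is seeded from the master seed, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @return list of class `StudyArtifacts` holding all stage outputs and a
#'   `report` list (see [write_report()]).
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  sd <- sample.int(2^30, 12)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  ## 1. simulate the study
  simc <- config$sim
  simc$seed <- sd[1]
  study <- simulate_study(simc)
  say("simulated %d entries x %d variants, %d QTL",
      n_entries(study$geno), n_variants(study$geno), nrow(study$truth$qtl))

  ## 2. GBS scaffold + imputation of the RIL genotypes
  geno <- study$geno
  impute_err <- NA_real_
  if (isTRUE(config$stages[["gbs_impute"]])) {
    rils <- study$pedigree$entry_id[study$pedigree$cross_type == "RIL"]
    scaffold <- simulate_gbs(geno[rils, ], config$gbs$scaffold_fraction,
                             config$gbs$call_rate, seed = sd[2])
    imputed <- impute_ril_dense(scaffold, study$founders, study$pedigree)
    truth_g <- geno$geno[rils, ]
    ok <- !is.na(imputed$geno)
    impute_err <- mean(imputed$geno[ok] != truth_g[ok])
    geno$geno[rils, ] <- imputed$geno[rils, ]
    say("imputed RILs from %.0f%%-density scaffold: error %.4f, coverage %.3f",
        100 * config$gbs$scaffold_fraction, impute_err, mean(ok))
  }

  ## 3. filter
  geno_f <- filter_variants(geno, config$filter$min_call_rate,
                            config$filter$min_maf)
  say("filter: %d -> %d variants", n_variants(geno), n_variants(geno_f))

  ## 4. phenotypes and BLUEs
  records <- simulate_phenotypes(study$truth$genetic_values, simc$h2,
                                 simc$n_trials, simc$n_reps, simc$trial_sd,
                                 simc$trait_mean, seed = sd[3])
  blues <- fit_blue(records)
  h2r <- realized_h2(records, study$truth$genetic_values)
  bs <- blue_summary(blues)
  say("BLUEs: n %d, mean %.2f, range %.1f-%.1f, realized h2 %.3f",
      bs["n"], bs["mean"], bs["min"], bs["max"], h2r$r2)

  ## 5. joint QTL analysis
  qtl <- joint_qtl(geno_f, blues, study$design,
                   alpha = config$qtl$cofactor_alpha,
                   step_bp = config$qtl$step_bp, n_perm = config$qtl$n_perm,
                   perm_alpha = config$qtl$perm_alpha,
                   lod_drop = config$qtl$lod_drop, map = study$map,
                   max_cofactors = config$qtl$max_cofactors, seed = sd[4])
  say("joint QTL: %d cofactors, threshold %.2f, %d peaks",
      length(qtl$cofactors), qtl$threshold, nrow(qtl$peaks))

  ## 6. the three GWAS models
  sv <- sv_scan(geno_f, blues, study$design, qtl)
  say("SV scan: max -log10 p = %.1f", max(sv$score))
  str_res <- str_select(geno_f, blues, study$design,
                        max_r2 = config$str$max_r2,
                        max_markers = config$str$max_markers,
                        alpha = config$str$alpha)
  say("STR: %d markers, cumulative R2 %.3f", nrow(str_res),
      attr(str_res, "cum_r2"))
  bmv <- NULL
  if (isTRUE(config$stages[["bayesc"]])) {
    m <- n_variants(geno_f)
    bcfg <- bayesc_config(pi = max(0, 1 - config$bayesc$expected_markers / m),
                          chain_length = config$bayesc$chain_length,
                          burn_in = config$bayesc$burn_in, seed = sd[5])
    bmv <- two_step_train(geno_f, blues, study$design, bcfg,
                          step1_chain = config$bayesc$step1_chain,
                          step1_burn_in = config$bayesc$step1_burn)
    say("BayesC: pi %.4f, posterior genetic variance %.3f, max MF %.3f",
        bmv$pi, bmv$post_genetic_variance, max(bmv$result$mf))
  }

  ## 7. thinning, binning, validation-set selection
  selections <- list(
    SV = thin_model_results(sv, qtl, config$thin$sv_threshold,
                            config$thin$flank_bp, config$thin$cluster_bp,
                            config$thin$cap),
    STR = thin_model_results(str_res, qtl, config$thin$str_threshold,
                             config$thin$flank_bp, config$thin$cluster_bp,
                             config$thin$cap))
  if (!is.null(bmv))
    selections$BMV <- thin_model_results(bmv$result, qtl,
                                         config$thin$bmv_threshold,
                                         config$thin$flank_bp,
                                         config$thin$cluster_bp,
                                         config$thin$cap)
  say("KAVs after thinning: %s",
      paste(sprintf("%s=%d", names(selections),
                    vapply(selections, nrow, integer(1))), collapse = ", "))
  bins <- bin_and_compare(selections)
  vset <- select_validation_set(bins, selections,
                                config$validation_set$n_private_bins,
                                config$validation_set$per_bin_max)
  say("bins: %d total, %d multi-model; validation set: %d variants",
      bins$counts["total_bins"], bins$counts["bins_ge2_models"], nrow(vset))
  ve <- lapply(names(selections), function(mod)
    variance_explained(geno_f, selections[[mod]]$variant_id, blues,
                       study$design))
  names(ve) <- names(selections)
  ve_set <- variance_explained(geno_f, vset$variant_id, blues, study$design)

  ## negative controls: non-associated variants through the same pipeline
  set.seed(sd[6])
  pool_ctrl <- sv$variant_id[sv$p > 0.5 &
                               !(sv$variant_id %in% vset$variant_id)]
  controls <- sample(pool_ctrl, min(config$validation_set$n_controls,
                                    length(pool_ctrl)))
  provenance <- rbind(
    vset[, c("variant_id", "chrom", "pos", "models")],
    data.frame(variant_id = controls,
               chrom = sv$chrom[match(controls, sv$variant_id)],
               pos = sv$pos[match(controls, sv$variant_id)],
               models = "control", stringsAsFactors = FALSE))

  ## 8. genetic validation in three unrelated population types
  validation <- NULL
  if (isTRUE(config$stages[["validation"]])) {
    validation <- run_validation_suite(study, sv, provenance, config,
                                       sd[7:12])
    say("validation: overall rate %.2f (%d/%d informative)",
        validation$summary$rates["overall"],
        validation$summary$counts["validated"],
        validation$summary$counts["informative"])
  }

  report <- build_report(study, geno_f, blues, h2r, impute_err, qtl,
                         selections, bins, vset, ve, ve_set, validation,
                         config)
  art <- structure(list(study = study, geno = geno_f, records = records,
                        blues = blues, qtl = qtl, sv = sv, str = str_res,
                        bmv = bmv, selections = selections, bins = bins,
                        validation_set = vset, provenance = provenance,
                        validation = validation, report = report,
                        log = log_lines, config = config),
                   class = "StudyArtifacts")
  if (!is.null(config$out_dir)) write_report(art, config$out_dir)
  art
}

# the three-population validation suite on simulated unrelated material
run_validation_suite <- function(study, sv, provenance, config, seeds) {
  vc <- config$validation
  truth <- study$truth
  map <- study$map
  founders <- study$founders
  kav_ids <- provenance$variant_id
  effect_sign <- stats::setNames(sign(sv$effect), sv$variant_id)[kav_ids]
  effect_sign[is.na(effect_sign)] <- 1

  ## population 1: elite-like inbred panel (kinship MLM + naive tests)
  elite <- random_mating_panel(founders, map, vc$n_elite,
                               vc$elite_generations, vc$elite_Ne,
                               vc$elite_self_generations, "ELITE",
                               seed = seeds[1])
  gv_e <- as.vector(elite$geno[, truth$qtl$variant_id, drop = FALSE] %*%
                      truth$qtl$effect) / 2
  h2v <- vc$h2_validation
  y_e <- truth$config$trait_mean + gv_e +
    stats::rnorm(length(gv_e), 0, sqrt(stats::var(gv_e) * (1 - h2v) / h2v))
  names(y_e) <- entry_ids(elite)
  elite_kav <- elite[, intersect(kav_ids, elite$info$variant_id)]
  elite_inf <- informative_filter(elite_kav)
  bg_pool <- setdiff(elite$info$variant_id, kav_ids)
  bg <- sample(bg_pool, min(vc$n_bg_snps, length(bg_pool)))
  K <- vanraden_kinship(elite[, bg])
  mlm <- if (n_variants(elite_inf)) mlm_kav_test(elite_inf, y_e, K) else NULL
  naive <- if (n_variants(elite_inf)) naive_kav_test(elite_inf, y_e) else NULL
  if (!is.null(naive)) naive$informative <- TRUE

  ## population 2: pooled heterogeneous accessions (frequency test)
  acc <- simulate_accessions(stats::setNames(alt_freq(founders),
                                             founders$info$variant_id),
                             truth, variant_ids = kav_ids,
                             n_accessions = vc$n_accessions, fst = vc$fst,
                             seed = seeds[2])
  pools <- simulate_pools(acc, vc$pool_size, vc$pool_tails, seed = seeds[3])
  pooled <- pooled_freq_test(pools$freq, pools$label, effect_sign)
  pf <- colMeans(pools$freq, na.rm = TRUE)
  pooled$informative <- pmin(pf, 1 - pf)[pooled$variant_id] > 0.05

  ## population 3: divergently selected population (drift-null test)
  bsle_base <- random_mating_panel(founders, map, 60, 5, 60, 0, "BSLE",
                                   seed = seeds[4])
  bsle <- simulate_divergent_selection(
    bsle_base, truth, map, generations = vc$bsle_generations,
    selected_fraction = vc$bsle_selected_fraction,
    genetic_correlation = vc$genetic_correlation, Ne = vc$bsle_Ne,
    seed = seeds[5])
  last <- vc$bsle_generations + 1
  f_le <- bsle$freq_LE[kav_ids, last]
  f_se <- bsle$freq_SE[kav_ids, last]
  f_c0 <- bsle$freq_C0[kav_ids]
  drift <- drift_null_test(f_le, f_se, f_c0, vc$bsle_generations,
                           vc$bsle_Ne, vc$drift_n_sim, seed = seeds[6])
  drift$informative <- pmin(f_c0, 1 - f_c0)[drift$variant_id] > 0.05
  # direction: the arm selected toward the higher focal trait should carry
  # more of the trait-increasing allele
  hi_arm <- if (vc$genetic_correlation < 0) f_se else f_le
  lo_arm <- if (vc$genetic_correlation < 0) f_le else f_se
  drift$direction_ok <- (hi_arm - lo_arm)[drift$variant_id] *
    effect_sign[drift$variant_id] > 0

  summary <- summarize_validation(
    list(elite = naive, pools = pooled, bsle = drift), provenance)

  ## recombination-zone enrichment over informative, non-control KAVs
  pv <- summary$per_variant
  keep <- pv$informative & pv$models != "control"
  enr <- NULL
  if (sum(keep) >= 4 && length(unique(pv$validated[keep])) > 0) {
    kdf <- data.frame(
      variant_id = pv$variant_id[keep],
      chrom = provenance$chrom[match(pv$variant_id[keep],
                                     provenance$variant_id)],
      pos = provenance$pos[match(pv$variant_id[keep],
                                 provenance$variant_id)],
      validated = pv$validated[keep], stringsAsFactors = FALSE)
    enr <- recombination_enrichment(kdf, map)
  }

  ## share of between-arm trait divergence explained by validated KAVs
  tr <- bsle$trait
  d_obs <- tr$focal[tr$arm == "LE" & tr$generation == vc$bsle_generations] -
    tr$focal[tr$arm == "SE" & tr$generation == vc$bsle_generations]
  val_bsle <- drift$variant_id[drift$variant_id %in%
                                 pv$variant_id[pv$validated] &
                                 drift$q < summary$fdr & drift$direction_ok]
  bpv <- if (length(val_bsle) && d_obs != 0) {
    eff <- stats::setNames(sv$effect, sv$variant_id)[val_bsle]
    between_pop_variance(eff[!is.na(eff)],
                         (f_le - f_se)[val_bsle][!is.na(eff)], d_obs)
  } else 0
  list(elite = list(panel_n = n_entries(elite),
                    informative = n_variants(elite_inf),
                    mlm = mlm, naive = naive, kinship_lambda =
                      if (!is.null(mlm)) attr(mlm, "lambda") else NA),
       pools = pooled, bsle = drift, summary = summary, enrichment = enr,
       between_pop_variance = as.numeric(bpv),
       bsle_divergence = d_obs)
}

build_report <- function(study, geno_f, blues, h2r, impute_err, qtl,
                         selections, bins, vset, ve, ve_set, validation,
                         config) {
  bs <- blue_summary(blues)
  rep <- list(
    n_entries = n_entries(study$geno),
    n_variants_simulated = n_variants(study$geno),
    n_variants_filtered = n_variants(geno_f),
    imputation_error = impute_err,
    blue_mean = unname(bs["mean"]),
    blue_min = unname(bs["min"]), blue_max = unname(bs["max"]),
    realized_h2 = h2r$r2,
    qtl_n_cofactors = length(qtl$cofactors),
    qtl_threshold = qtl$threshold,
    qtl_n_peaks = nrow(qtl$peaks),
    kav_counts = vapply(selections, nrow, integer(1)),
    variance_explained = vapply(ve, as.numeric, numeric(1)),
    variance_explained_validation_set = as.numeric(ve_set),
    bin_counts = bins$counts,
    validation_set_size = nrow(vset))
  if (!is.null(validation)) {
    s <- validation$summary
    rep$validation_rates <- s$rates
    rep$validation_counts <- s$counts
    rep$elite_mlm_informative <- validation$elite$informative
    rep$recombination_odds_ratio <-
      if (!is.null(validation$enrichment))
        validation$enrichment$odds_ratio else NA_real_
    rep$between_pop_variance <- validation$between_pop_variance
    rep$bsle_divergence <- validation$bsle_divergence
  }
  rep
}

#' Write study artifacts and the machine-readable report
#'
#' Writes per-stage TSVs (genotypes are omitted for size; association
#' results, thinned selections, validation set and per-population
#' validation tables are written), the run log, and `report.json` with
#' every count and rate of the run.
#'
#' @param artifacts a `StudyArtifacts` from [run_full_study()].
#' @param out_dir output directory.
#' @return invisibly, the report list.
#' @export
write_report <- function(artifacts, out_dir) {
  stopifnot(inherits(artifacts, "StudyArtifacts"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f)
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(as.data.frame(artifacts$blues), "blues.tsv")
  wt(artifacts$sv, "gwas_sv.tsv")
  wt(artifacts$str, "gwas_str.tsv")
  if (!is.null(artifacts$bmv)) {
    wt(artifacts$bmv$result, "gwas_bmv.tsv")
    jsonlite::write_json(
      list(split_chain_z = as.list(bayesc_diagnostics(artifacts$bmv)),
           pi = artifacts$bmv$pi,
           n_samples = artifacts$bmv$n_samples,
           post_sigma2_e = artifacts$bmv$post_sigma2_e,
           post_genetic_variance = artifacts$bmv$post_genetic_variance),
      file.path(out_dir, "bmv_diagnostics.json"), auto_unbox = TRUE,
      digits = NA)
  }
  for (mod in names(artifacts$selections))
    wt(artifacts$selections[[mod]], sprintf("kav_%s.tsv", tolower(mod)))
  wt(artifacts$validation_set, "validation_set.tsv")
  wt(artifacts$bins$bins, "bins.tsv")
  write_qtl_model(artifacts$qtl, file.path(out_dir, "qtl"))
  if (!is.null(artifacts$validation)) {
    wt(artifacts$validation$summary$per_variant, "validation_per_variant.tsv")
    for (popn in names(artifacts$validation$summary$per_population))
      wt(artifacts$validation$summary$per_population[[popn]],
         sprintf("validation_%s.tsv", popn))
  }
  writeLines(artifacts$log, file.path(out_dir, "run.log"))
  jsonlite::write_json(artifacts$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(artifacts$report)
}
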