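test_that("founder simulation is reproducible, homozygous, spectrum-bounded", {
  cfg <- sim_config(n_founders = 2, n_variants = 100, seed = 5)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1$geno, f2$geno)
  expect_equal(n_variants(f1), 100L)
  expect_true(all(f1$geno %in% c(0, 2)))
  expect_error(simulate_founders(sim_config(n_founders = 1)), "n_founders")

  # allele-frequency spectrum: empirical founder frequency tracks U(0.1, 0.5)
  cfg_big <- sim_config(n_founders = 40, n_variants = 5000, seed = 6)
  fb <- simulate_founders(cfg_big)
  p <- alt_freq(fb)
  expect_gt(mean(p), 0.25)
  expect_lt(mean(p), 0.35)            # E[U(0.1, 0.5)] = 0.3
  # spread = uniform spectrum variance plus binomial sampling over founders
  expect_equal(sd(p), sqrt(1 / 75 + 0.21 / 40), tolerance = 0.12)
})

test_that("meiosis reproduces Haldane recombination fractions", {
  # two markers 10 cM apart: recombinant fraction (1 - exp(-0.2)) / 2
  map <- genetic_map(c("c1", "c1"), c(1L, 1000000L), c(0, 10))
  hap <- rbind(c(0, 0), c(1, 1))
  set.seed(7)
  n <- 40000
  rec <- 0
  for (i in seq_len(n)) {
    g <- meiosis(hap, map, c("c1", "c1"), c(1, 1000000))
    if (g[1] != g[2]) rec <- rec + 1
  }
  expect_equal(rec / n, (1 - exp(-0.2)) / 2, tolerance = 0.06)

  # 0 cM chromosome: gamete equals one parent intact
  map0 <- genetic_map(c("c1", "c1"), c(1L, 1000000L), c(0, 0))
  for (i in 1:20) {
    g <- meiosis(hap, map0, c("c1", "c1"), c(1, 1000000))
    expect_true(all(g == 0) || all(g == 1))
  }
})

test_that("study simulation yields inbred RILs, diallel sums, exact truth", {
  cfg <- sim_config(n_founders = 3, chrom_spec = list(c(2e7, 60)),
                    n_variants = 300, n_ril_per_family = 40,
                    n_self_generations = 10, n_bc1_per_family = c(5, 3),
                    seed = 9)
  st <- simulate_study(cfg)
  rils <- st$design$entry_id[st$design$population == "NAM"]
  het <- mean(st$geno$geno[rils, ] == 1)
  expect_lt(het, 0.01)                    # ~2^-10 per locus after 10 selfs

  # diallel F1 dosage equals the Mendelian sum of its homozygous parents
  f <- st$founders$geno
  expect_equal(unname(st$geno$geno["DIA_01x02", ]),
               unname(f["FND01", ] / 2 + f["FND02", ] / 2))

  # truth bookkeeping: genetic value recomputable exactly from the table
  gv <- as.vector(st$geno$geno[, st$truth$qtl$variant_id] %*%
                    st$truth$qtl$effect) / 2
  expect_equal(unname(st$truth$genetic_values), gv)

  # determinism and allele-frequency bookkeeping
  st2 <- simulate_study(cfg)
  expect_identical(st$geno$geno, st2$geno$geno)
  expect_equal(alt_freq(st$geno), colMeans(st$geno$geno) / 2)

  # every phenotyped entry has exactly one population and subpopulation
  expect_equal(anyDuplicated(st$design$entry_id), 0L)
  expect_false(any(is.na(st$design$population) |
                     is.na(st$design$subpopulation)))
})

test_that("phenotype generator hits configured heritability and structure", {
  # noiseless limit: phenotype = mean + genetic value exactly
  gv <- stats::setNames(rnorm(50), sprintf("E%02d", 1:50))
  rec <- simulate_phenotypes(gv, h2 = 1, n_trials = 1, n_reps = 1,
                             trial_sd = 0, trait_mean = 15, seed = 1)
  expect_equal(rec$value, unname(15 + gv[rec$entry_id]))

  # h2 = 0.5 at large n: regression of entry means on truth has slope ~ 1
  # and R^2 ~ 0.5
  set.seed(2)
  gv_big <- stats::setNames(rnorm(8000), sprintf("E%04d", 1:8000))
  rec_big <- simulate_phenotypes(gv_big, h2 = 0.5, n_trials = 2, n_reps = 2,
                                 trial_sd = 0.5, seed = 3)
  h <- realized_h2(rec_big, gv_big)
  expect_equal(h$r2, 0.5, tolerance = 0.04)
  expect_equal(h$slope, 1, tolerance = 0.05)

  # distinct trial effects shift within-trial means by their difference
  rec_tr <- simulate_phenotypes(gv_big, h2 = 0.99, n_trials = 2, n_reps = 1,
                                trial_sd = 3, seed = 4)
  tm <- tapply(rec_tr$value, rec_tr$trial_id, mean)
  expect_gt(abs(tm[1] - tm[2]), 0.05)   # trial effects present
})

test_that("GBS degradation hits its masking targets and is seeded", {
  st <- small_study()
  tab <- st$geno[1:50, ]
  expect_equal(simulate_gbs(tab, 1, 1, seed = 1)$geno, tab$geno)
  g1 <- simulate_gbs(tab, 0.5, 0.6, seed = 2)
  g2 <- simulate_gbs(tab, 0.5, 0.6, seed = 2)
  expect_identical(g1$geno, g2$geno)
  expect_equal(mean(!is.na(g1$geno)), 0.6, tolerance = 0.01)
  expect_equal(n_variants(g1), 250L)
})

test_that("divergent selection: trivial identity, drift variance, response sign", {
  st <- small_study()
  set.seed(42)
  base <- st$geno[sample(which(st$design$population == "NAM"), 40), ]

  # generations = 0: both arms equal C0 exactly
  d0 <- simulate_divergent_selection(base, st$truth, st$map, generations = 0,
                                     selected_fraction = 0.5, Ne = 30,
                                     seed = 1)
  expect_equal(d0$freq_LE[, 1], d0$freq_C0)
  expect_equal(d0$freq_SE[, 1], d0$freq_C0)

  # selected_fraction = 1: pure drift; Var of freq change matches the
  # Wright-Fisher closed form p(1-p)(1 - (1 - 1/(2Ne))^t) across loci
  t_g <- 12; ne <- 40
  expfac <- 1 - (1 - 1 / (2 * ne))^t_g
  # linkage makes single-run averages noisy; average both arms over seeds
  devs <- drifts <- numeric(0)
  for (s in 2:4) {
    dd <- simulate_divergent_selection(base, st$truth, st$map,
                                       generations = t_g,
                                       selected_fraction = 1, Ne = ne,
                                       seed = s)
    p0 <- dd$freq_C0
    use <- p0 > 0.2 & p0 < 0.8
    for (arm in list(dd$freq_LE, dd$freq_SE)) {
      devs <- c(devs, mean((arm[use, t_g + 1] - p0[use])^2 /
                             (p0[use] * (1 - p0[use]))))
      drifts <- c(drifts, mean(arm[use, t_g + 1] - p0[use]))
    }
  }
  expect_lt(abs(mean(devs) - expfac), 0.35 * expfac)
  # no systematic direction under drift
  expect_lt(abs(mean(drifts)), 0.02)

  # negatively correlated large-effect focal QTL diverges with LE < SE for
  # its trait-increasing allele (sign check over the arms)
  ds <- simulate_divergent_selection(base, st$truth, st$map, generations = 15,
                                     selected_fraction = 0.25, Ne = 50,
                                     genetic_correlation = -0.9, seed = 3)
  qtl <- st$truth$qtl
  last <- 16
  inc_freq_le <- ifelse(qtl$effect > 0, ds$freq_LE[qtl$variant_id, last],
                        1 - ds$freq_LE[qtl$variant_id, last])
  inc_freq_se <- ifelse(qtl$effect > 0, ds$freq_SE[qtl$variant_id, last],
                        1 - ds$freq_SE[qtl$variant_id, last])
  # focal trait responds opposite to the primary in LE vs SE arms
  tr <- ds$trait
  foc_le <- tr$focal[tr$arm == "LE" & tr$generation == 15]
  foc_se <- tr$focal[tr$arm == "SE" & tr$generation == 15]
  expect_lt(foc_le, foc_se)
  expect_lt(mean(inc_freq_le), mean(inc_freq_se))
})

test_that("pooled accession genotyping behaves at its limits", {
  st <- small_study()
  bf <- stats::setNames(alt_freq(st$founders), st$founders$info$variant_id)
  acc <- simulate_accessions(bf, st$truth, n_accessions = 80, fst = 0.2,
                             seed = 4)
  # monomorphic accession frequencies stay exactly 0 or 1 in pools
  acc0 <- acc
  acc0$freq[1, ] <- round(acc0$freq[1, ])
  p0 <- simulate_pools(acc0, pool_size = 8, seed = 5)
  a1 <- rownames(acc0$freq)[1]
  if (a1 %in% rownames(p0$freq))
    expect_true(all(p0$freq[a1, ] %in% c(0, 1)))

  # large pools converge to the true accession frequency
  pbig <- simulate_pools(acc, pool_size = 5000, seed = 6)
  expect_lt(max(abs(pbig$freq - pbig$true_freq)), 0.03)

  # high and low labels split the trait tails
  p <- simulate_pools(acc, pool_size = 12, tails = c(0.25, 0.25), seed = 7)
  expect_gt(min(p$trait[p$label == "high"]), max(p$trait[p$label == "low"]))

  # a neutral variant shows no mean frequency difference between pools
  neutral <- setdiff(colnames(p$freq), st$truth$qtl$variant_id)[1:20]
  dif <- colMeans(p$true_freq[p$label == "high", neutral]) -
    colMeans(p$true_freq[p$label == "low", neutral])
  expect_lt(abs(mean(dif)), 0.05)
})
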