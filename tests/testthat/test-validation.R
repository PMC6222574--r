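test_that("informative filter uses strict boundaries", {
  # MAF exactly 0.05: excluded under the strict rule
  g <- cbind(c(2, rep(0, 19)),              # MAF 0.05 exactly
             c(2, 2, 2, rep(0, 17)),        # MAF 0.15
             rep(0, 20),                    # monomorphic
             c(rep(NA, 13), 2, 2, rep(0, 5)),  # call rate 0.35
             rep(NA, 20),                   # fully missing
             c(rep(2, 6), rep(0, 14)))      # MAF 0.3
  tab <- toy_table(g, entry_id = sprintf("E%02d", 1:20))
  out <- informative_filter(tab)
  expect_equal(n_variants(out), 2L)
  expect_setequal(out$info$pos, c(2000L, 6000L))
})

test_that("VanRaden kinship has Gram-matrix structure", {
  set.seed(71)
  g <- matrix(sample(c(0, 2), 12 * 200, replace = TRUE, prob = c(0.6, 0.4)),
              12, 200, dimnames = list(sprintf("E%02d", 1:12), NULL))
  g[2, ] <- g[1, ]                     # duplicated entry
  tab <- toy_table(g, entry_id = rownames(g))
  K <- vanraden_kinship(tab)
  expect_equal(K, t(K))
  expect_equal(K[1, 2], K[1, 1])       # duplicate: off-diagonal = diagonal
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # unrelated entries: small off-diagonals relative to the diagonal
  off <- K[upper.tri(K)][-1]           # drop the duplicate pair
  expect_lt(stats::median(abs(off)), 0.25 * mean(diag(K)))
})

test_that("kinship MLM reduces exactly to OLS when K is the identity", {
  set.seed(72)
  n <- 40
  g <- matrix(sample(0:2, n * 5, replace = TRUE), n, 5,
              dimnames = list(sprintf("E%02d", 1:n), NULL))
  tab <- toy_table(g, entry_id = rownames(g))
  y <- stats::setNames(0.5 * g[, 2] + rnorm(n), rownames(g))
  K <- diag(n); dimnames(K) <- list(rownames(g), rownames(g))
  mlm <- mlm_kav_test(tab, y, K)
  ols <- naive_kav_test(tab, y)
  expect_equal(mlm$p, ols$p, tolerance = 1e-8)
  expect_equal(mlm$effect, ols$effect, tolerance = 1e-8)
})

test_that("kinship correction deflates structure-confounded signals", {
  set.seed(73)
  n <- 60
  cluster <- rep(c(0, 1), each = n / 2)
  # background SNPs differentiated by cluster -> structured kinship
  p_by_cluster <- cbind(runif(300, 0.1, 0.4), runif(300, 0.6, 0.9))
  bg <- sapply(1:300, function(k)
    2 * rbinom(n, 1, p_by_cluster[k, cluster + 1]))
  rownames(bg) <- sprintf("E%02d", 1:n)
  K <- vanraden_kinship(toy_table(bg, entry_id = rownames(bg)))
  # candidate variant perfectly confounded with the cluster split
  kav <- toy_table(matrix(2 * cluster, n, 1), entry_id = rownames(bg))
  y <- stats::setNames(2 * cluster + rnorm(n, 0, 0.5), rownames(bg))
  p_mlm <- mlm_kav_test(kav, y, K)$p
  p_ols <- naive_kav_test(kav, y)$p
  expect_gt(p_mlm, p_ols)
})

test_that("naive test matches the textbook two-sided t-test", {
  g <- matrix(c(0, 0, 0, 2, 2, 2, 0, 2), 8, 1,
              dimnames = list(sprintf("E%02d", 1:8), NULL))
  tab <- toy_table(g, entry_id = rownames(g))
  y <- stats::setNames(c(10, 11, 10.5, 14, 13, 15, 9.5, 14.5), rownames(g))
  res <- naive_kav_test(tab, y)
  oracle <- summary(lm(y ~ g[, 1]))$coefficients[2, 4]
  expect_equal(res$p[1], oracle, tolerance = 1e-12)

  # constant phenotype: p = 1
  yc <- stats::setNames(rep(15, 8), rownames(g))
  expect_equal(naive_kav_test(tab, yc)$p, 1)
})

test_that("pooled frequency test is one-sided with degenerate handling", {
  set.seed(74)
  n_acc <- 30
  lab <- stats::setNames(rep(c("high", "low"), each = n_acc / 2),
                         sprintf("A%02d", 1:n_acc))
  # null variant: identical distributions -> p near 0.5 on average
  ps <- replicate(120, {
    f <- matrix(runif(n_acc, 0.2, 0.8), n_acc, 1,
                dimnames = list(names(lab), "v1"))
    pooled_freq_test(f, lab, c(v1 = 1))$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)

  # separation: increasing allele fixed in high pools, absent in low
  f_sep <- matrix(c(rep(1, 15), rep(0, 15)), n_acc, 1,
                  dimnames = list(names(lab), "v1"))
  expect_equal(pooled_freq_test(f_sep, lab, c(v1 = 1))$p, 0)

  # flipping the direction complements the one-sided p
  f <- matrix(runif(n_acc, 0.2, 0.8), n_acc, 1,
              dimnames = list(names(lab), "v1"))
  p_pos <- pooled_freq_test(f, lab, c(v1 = 1))$p
  p_neg <- pooled_freq_test(f, lab, c(v1 = -1))$p
  expect_equal(p_pos + p_neg, 1, tolerance = 1e-9)

  # binomial GLM route agrees in direction
  p_glm <- pooled_freq_test(f_sep, lab, c(v1 = 1), method = "binomial")$p
  expect_lt(p_glm, 0.01)
})

test_that("drift null test covers its trivial and closed-form cases", {
  # observed difference of zero: p = 1
  r0 <- drift_null_test(c(v = 0.5), c(v = 0.5), c(v = 0.5), 30, 100,
                        n_sim = 1000, seed = 1)
  expect_equal(r0$p, 1)

  # base fixed: uninformative, p = 1
  rf <- drift_null_test(c(v = 0.4), c(v = 0.9), c(v = 1), 30, 100,
                        n_sim = 1000, seed = 2)
  expect_equal(rf$p, 1)

  # p0 = 0.5, Ne = 100, t = 30: null sd of the difference ~ 0.264, so an
  # observed difference of 0.9 is extreme
  r <- drift_null_test(c(v = 0.95), c(v = 0.05), c(v = 0.5), 30, 100,
                       n_sim = 1000, seed = 3)
  expect_lt(r$p, 0.01)

  # huge Ne: drift freezes, any difference becomes maximally significant
  rinf <- drift_null_test(c(v = 0.6), c(v = 0.4), c(v = 0.5), 30, 1e7,
                          n_sim = 1000, seed = 4)
  expect_equal(rinf$p, 1 / 1001)

  # q-values dominate p-values (BH step-up)
  many <- drift_null_test(stats::setNames(runif(20, 0.3, 0.9), paste0("v", 1:20)),
                          stats::setNames(runif(20, 0.1, 0.7), paste0("v", 1:20)),
                          stats::setNames(rep(0.5, 20), paste0("v", 1:20)),
                          10, 50, n_sim = 1000, seed = 5)
  expect_true(all(many$q >= many$p - 1e-12))
})

test_that("between-population variance statistic covers its limit cases", {
  # a single variant fully explaining the divergence
  expect_equal(between_pop_variance(c(v = 2), c(v = 0.25), 1), 1)
  # no validated variants
  expect_equal(between_pop_variance(numeric(0), numeric(0), 1), 0)
  # capped at 1
  expect_equal(between_pop_variance(c(v = 10), c(v = 0.5), 1), 1)
  expect_error(between_pop_variance(c(v = 1), c(v = 0.1), 0), "zero")
})

test_that("recombination enrichment reproduces the hand 2x2 arithmetic", {
  # map: first half of the chromosome cold (0.5 cM/Mb), second half hot
  # (4 cM/Mb): 100 Mb -> 25 + 200 cM
  map <- genetic_map(rep("chr1", 3), c(1L, 50000000L, 100000000L),
                     c(0, 25, 225))
  set.seed(75)
  # 20 cold KAVs (10 validated), 28 hot KAVs (4 validated)
  kavs <- data.frame(
    chrom = "chr1",
    pos = c(seq(2e6, 48e6, length.out = 20),
            seq(52e6, 98e6, length.out = 28)),
    validated = c(rep(c(TRUE, FALSE), 10), rep(c(TRUE, rep(FALSE, 6)), 4)))
  enr <- recombination_enrichment(kavs, map)
  expect_equal(unname(enr$table["cold", "yes"]), 10)
  expect_equal(unname(enr$table["hot", "yes"]), 4)
  expect_equal(enr$odds_ratio, (10 * 24) / (10 * 4))
  expect_true(all(enr$kavs$zone[enr$kavs$pos < 50e6] == "cold"))

  # permuting the validated flags centers the odds ratio at 1
  ors <- replicate(60, {
    k2 <- kavs; k2$validated <- sample(k2$validated)
    suppressWarnings(recombination_enrichment(k2, map)$odds_ratio)
  })
  expect_equal(median(log(ors[is.finite(ors) & ors > 0])), 0,
               tolerance = 0.8)

  # a uniform map at the cutoff classifies everything hot (boundary rule)
  map_u <- genetic_map(rep("chr1", 2), c(1L, 100000000L), c(0, 100))
  enr_u <- recombination_enrichment(kavs, map_u, cold_cutoff = 1)
  expect_true(all(enr_u$kavs$zone == "hot"))
})

test_that("validation summary rates match hand arithmetic", {
  prov <- data.frame(variant_id = paste0("v", 1:8),
                     models = c("SV", "SV", "STR", "BMV", "SV,BMV",
                                "SV,BMV", "control", "control"),
                     stringsAsFactors = FALSE)
  tests <- list(
    popA = data.frame(variant_id = paste0("v", 1:8),
                      p = c(1e-5, 0.5, 1e-4, 0.9, 1e-6, 0.8, 0.9, 1e-5),
                      informative = c(rep(TRUE, 7), FALSE)),
    popB = data.frame(variant_id = paste0("v", 1:8),
                      p = c(0.9, 0.9, 0.9, 1e-3, 0.9, 0.9, 0.9, 0.9),
                      informative = rep(TRUE, 8)))
  s <- summarize_validation(tests, prov, fdr = 0.05)
  pv <- s$per_variant
  expect_true(all(pv$validated[c(1, 3, 4, 5)]))
  expect_false(any(pv$validated[c(2, 6)]))
  expect_true(all(pv$validated <= pv$informative))  # validated => informative
  expect_equal(unname(s$rates["SV_only"]), 1 / 2)   # v1 yes, v2 no
  expect_equal(unname(s$rates["STR_only"]), 1)      # v3
  expect_equal(unname(s$rates["SV_and_BMV"]), 1 / 2)

  # degenerate summaries: nothing validated, everything validated
  t_none <- list(popA = data.frame(variant_id = paste0("v", 1:8),
                                   p = rep(0.9, 8),
                                   informative = rep(TRUE, 8)))
  expect_equal(unname(summarize_validation(t_none, prov)$rates["overall"]), 0)
  t_all <- list(popA = data.frame(variant_id = paste0("v", 1:8),
                                  p = rep(1e-9, 8),
                                  informative = rep(TRUE, 8)))
  expect_equal(unname(summarize_validation(t_all, prov)$rates["overall"]), 1)
})
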