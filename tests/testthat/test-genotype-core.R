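test_that("filter_variants applies call-rate, MAF and polymorphism rules", {
  # one monomorphic variant: removed regardless of thresholds
  mono <- toy_table(matrix(0, 5, 1))
  expect_equal(n_variants(filter_variants(mono, 0, 0)), 0L)

  # 10 variants: 3 with call rate 0.3, 7 fully called with MAF 0.2
  set.seed(1)
  n <- 10
  g_good <- sapply(1:7, function(k) c(rep(2, 2), rep(0, 8)))   # MAF 0.2
  g_bad <- sapply(1:3, function(k) c(0, 2, 0, rep(NA, 7)))     # call rate 0.3
  tab <- toy_table(cbind(g_good, g_bad))
  out <- filter_variants(tab, 0.4, 0.1)
  expect_equal(n_variants(out), 7L)

  # zero thresholds on a fully called polymorphic table: identity
  poly <- toy_table(matrix(c(0, 1, 2, 0, 2, 0), 3, 2))
  expect_equal(filter_variants(poly, 0, 0)$geno, poly$geno)

  # idempotence
  once <- filter_variants(tab, 0.4, 0.1)
  twice <- filter_variants(once, 0.4, 0.1)
  expect_equal(twice$info, once$info)
  expect_equal(twice$geno, once$geno)

  expect_error(filter_variants(tab, NaN, 0.1), "finite")
  expect_equal(n_variants(filter_variants(tab[, 0], 0.4, 0.1)), 0L)
})

test_that("call rate and MAF respect their ranges and missing-data rules", {
  g <- matrix(c(0, 2, NA, 2,
                1, 1, 1, NA), 4, 2)
  tab <- toy_table(g)
  expect_equal(call_rate(tab), c(chr1_1000 = 0.75, chr1_2000 = 0.75))
  expect_true(all(maf(tab) >= 0 & maf(tab) <= 0.5))
  expect_equal(unname(maf(tab)[1]), 1 / 3)  # freq 4/6 -> minor 1/3
})

test_that("merge_consensus keeps agreement, blanks conflicts, unions variants", {
  g <- matrix(c(0, 2, 1, 0), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  t1 <- toy_table(g, entry_id = c("a", "b"))
  t2 <- toy_table(g, entry_id = c("a", "b"))
  expect_equal(merge_consensus(list(t1, t2))$geno, t1$geno)

  # conflicting non-missing calls become missing
  g2 <- g; g2[1, 1] <- 2
  t3 <- toy_table(g2, entry_id = c("a", "b"))
  suppressMessages(m <- merge_consensus(list(t1, t3)))
  expect_true(is.na(m$geno["a", 1]))
  expect_equal(m$geno["b", 1], 2)

  # disjoint variant sets: concatenated union with per-source missingness
  t4 <- toy_table(matrix(c(2, 0), 2, 1), pos = 9000L, entry_id = c("a", "c"))
  u <- merge_consensus(list(t1, t4))
  expect_equal(n_variants(u), 3L)
  expect_true(all(is.na(u$geno["c", c("chr1_1000", "chr1_2000")])))
  expect_true(is.na(u$geno["b", "chr1_9000"]))

  # allele-label mismatch drops the variant with a warning
  t5 <- variant_table(matrix(c(0, 2), 2, 1), "chr1", 1000L, ref = "C",
                      alt = "G", entry_id = c("a", "b"))
  expect_warning(m5 <- merge_consensus(list(t1, t5)), "allele")
  expect_false("chr1:1000" %in% paste(m5$info$chrom, m5$info$pos, sep = ":"))
})

test_that("project_from_parents performs Mendelian sums with missing rules", {
  founders <- toy_table(rbind(P1 = c(0, 2, 0, NA),
                              P2 = c(2, 2, 0, 2)),
                        entry_id = c("P1", "P2"))
  ped <- pedigree("F1_1", "P1", "P2", "F1")
  f1 <- project_from_parents(founders, ped)
  expect_equal(unname(f1$geno["F1_1", ]), c(1, 2, 0, NA))

  # BC1 of homozygous RIL x recurrent parent
  founders2 <- toy_table(rbind(RIL = c(2, 0), P = c(0, 0)),
                         entry_id = c("RIL", "P"))
  bc <- project_from_parents(founders2, pedigree("B1", "RIL", "P", "BC1"))
  expect_equal(unname(bc$geno["B1", ]), c(1, 0))

  # heterozygous parental call: missing with warning
  founders3 <- toy_table(rbind(P1 = c(1, 0), P2 = c(0, 0)),
                         entry_id = c("P1", "P2"))
  expect_warning(h <- project_from_parents(founders3,
                                           pedigree("X", "P1", "P2", "F1")),
                 "heterozygous")
  expect_true(is.na(h$geno["X", 1]))
  expect_equal(h$geno["X", 2], 0)
})

test_that("F1 projection matches brute-force per-cell Mendelian sums", {
  set.seed(11)
  founders <- toy_table(matrix(2 * rbinom(5 * 40, 1, 0.4), 5, 40),
                        entry_id = paste0("P", 1:5))
  ped <- pedigree(paste0("F", 1:4), paste0("P", 1:4), paste0("P", 2:5), "F1")
  pr <- project_from_parents(founders, ped)
  for (i in 1:4) {
    expected <- founders$geno[paste0("P", i), ] / 2 +
      founders$geno[paste0("P", i + 1), ] / 2
    expect_equal(unname(pr$geno[paste0("F", i), ]), unname(expected))
  }
})

test_that("impute_ril_dense recovers blocks with midpoint breakpoints", {
  # dense founder variants every 1 Mb on one 20-Mb chromosome
  pos <- seq(1e6, 2e7, by = 1e6)
  pa <- rep(0, length(pos)); pb <- rep(2, length(pos))
  pb[5] <- 0                      # both parents share the allele at 5 Mb
  founders <- variant_table(rbind(A = pa, B = pb), rep("chr1", length(pos)),
                            pos, entry_id = c("A", "B"))
  ped <- pedigree("R1", "A", "B", "RIL")

  # scaffold: matches parent A at 10 Mb and earlier, parent B at 12 Mb on
  scaf_pos <- c(2e6, 10e6, 12e6, 18e6)
  scaf <- variant_table(matrix(c(0, 0, 2, 2), 1, 4,
                               dimnames = list("R1", NULL)),
                        rep("chr1", 4), scaf_pos, entry_id = "R1")
  imp <- impute_ril_dense(scaf, founders, ped)
  got <- imp$geno["R1", ]
  # breakpoint at (10 + 12)/2 = 11 Mb: 10.5 Mb -> A allele, 11.5 Mb -> B
  expect_equal(unname(got[pos <= 10e6 & pb != pa]),
               rep(0, sum(pos <= 10e6 & pb != pa)))
  expect_equal(unname(got[pos >= 12e6]), rep(2, sum(pos >= 12e6)))
  expect_equal(unname(got[pos == 11e6]), 2)  # 11 Mb falls in the B block
  expect_equal(unname(got[5]), 0)            # shared allele regardless

  # scaffold entirely matching parent A: single block, all A
  scaf_a <- variant_table(matrix(c(0, 0, 0, 0), 1, 4,
                                 dimnames = list("R1", NULL)),
                          rep("chr1", 4), scaf_pos, entry_id = "R1")
  imp_a <- impute_ril_dense(scaf_a, founders, ped)
  expect_equal(unname(imp_a$geno["R1", ]), ifelse(pb == pa, pa, pa))

  # RIL with no scaffold data: everything missing except shared alleles
  scaf_none <- variant_table(matrix(NA_real_, 1, 4,
                                    dimnames = list("R1", NULL)),
                             rep("chr1", 4), scaf_pos, entry_id = "R1")
  suppressMessages(imp_n <- impute_ril_dense(scaf_none, founders, ped))
  expect_true(all(is.na(imp_n$geno["R1", pb != pa])))
  expect_equal(unname(imp_n$geno["R1", 5]), 0)
})

test_that("imputation from a fully dense scaffold recovers truth exactly", {
  st <- small_study()
  rils <- st$pedigree$entry_id[st$pedigree$cross_type == "RIL"][1:10]
  truth <- st$geno[rils, ]
  imp <- impute_ril_dense(truth, st$founders,
                          st$pedigree[st$pedigree$entry_id %in% rils, ])
  ok <- !is.na(imp$geno)
  expect_gt(mean(ok), 0.97)
  expect_equal(sum(imp$geno[ok] != truth$geno[rils, ][ok]), 0L)
})

test_that("imputation error decreases as scaffold density increases", {
  st <- small_study()
  rils <- st$pedigree$entry_id[st$pedigree$cross_type == "RIL"][1:25]
  truth <- st$geno[rils, ]
  ped <- st$pedigree[st$pedigree$entry_id %in% rils, ]
  err_at <- function(frac, seed) {
    scaf <- simulate_gbs(truth, frac, 0.8, seed = seed)
    imp <- suppressMessages(impute_ril_dense(scaf, st$founders, ped))
    ok <- !is.na(imp$geno)
    mean(imp$geno[ok] != truth$geno[, ][ok])
  }
  errs_sparse <- sapply(1:3, function(s) err_at(0.05, s))
  errs_dense <- sapply(1:3, function(s) err_at(0.5, s + 10))
  expect_lt(mean(errs_dense), mean(errs_sparse))
})
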