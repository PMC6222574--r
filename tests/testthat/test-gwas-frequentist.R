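test_that("sv_scan equals brute-force partial-F OLS on a hand fixture", {
  # 12 entries, 1 population, 2 subpopulations, 1 QTL covariate on chr2
  set.seed(41)
  g <- matrix(sample(0:2, 12 * 6, replace = TRUE), 12, 6,
              dimnames = list(sprintf("E%02d", 1:12), NULL))
  tab <- variant_table(g, rep(c("chr1", "chr2"), each = 3),
                       c(1e6, 5e6, 9e6, 1e6, 5e6, 9e6),
                       entry_id = rownames(g))
  des <- study_design(rownames(g), rep("P1", 12), rep(c("S1", "S2"), 6))
  y <- stats::setNames(rnorm(12, 15), rownames(g))
  qtl <- structure(list(cofactors = character(0), scan = NULL, threshold = 3,
                        peaks = data.frame(chrom = "chr2", peak_pos = 5e6,
                                           marker = tab$info$variant_id[5],
                                           lod = 5, interval_start = 4e6,
                                           interval_end = 6e6)),
                   class = "QTLModel")
  res <- sv_scan(tab, y, des, qtl)
  sub <- as.numeric(des$subpopulation == "S2")
  for (k in which(tab$info$chrom == "chr1")) {
    C <- cbind(1, sub, g[, 5])
    p_oracle <- oracle_partial_f(unname(y), C, g[, k])
    expect_equal(res$p[k], p_oracle, tolerance = 1e-10)
  }
  # on the QTL's own chromosome the covariate is dropped
  for (k in which(tab$info$chrom == "chr2")) {
    C <- cbind(1, sub)
    expect_equal(res$p[k], oracle_partial_f(unname(y), C, g[, k]),
                 tolerance = 1e-10)
  }
})

test_that("sv_scan handles orthogonal, missing and collinear dosages", {
  # orthogonal noiseless fixture: effect 0, p = 1
  g <- matrix(c(0, 0, 2, 2, 2, 2, 0, 0), 4, 2,
              dimnames = list(paste0("E", 1:4), NULL))
  tab <- toy_table(g, entry_id = rownames(g))
  des <- study_design(rownames(g), "P1", "S1")
  y <- stats::setNames(c(-1, 1, -1, 1), rownames(g))  # orthogonal to both
  res <- sv_scan(tab, y, des)
  expect_equal(res$p, c(1, 1))
  expect_equal(res$effect, c(0, 0))

  # missing dosages: per-variant entry dropping changes n_used
  g2 <- cbind(g, c(NA, 0, 1, 2))
  tab2 <- toy_table(g2, entry_id = rownames(g))
  res2 <- sv_scan(tab2, y, des)
  expect_equal(res2$n_used, c(4L, 4L, 3L))

  # constant dosage: collinear with intercept, p = 1
  g3 <- cbind(g, rep(2, 4))
  res3 <- sv_scan(toy_table(g3, entry_id = rownames(g)), y, des)
  expect_equal(res3$p[3], 1)
})

test_that("sv_scan p-values are invariant under affine rescaling of y", {
  st <- small_study()
  gf <- filter_variants(st$geno, 0.4, 0.1)[, 1:50]
  y1 <- stats::setNames(st$blues$blue, st$blues$entry_id)
  y2 <- 3.2 * y1 - 40
  r1 <- sv_scan(gf, y1, st$design)
  r2 <- sv_scan(gf, y2, st$design)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("stepwise regression recovers exact signals and obeys stop rules", {
  set.seed(43)
  n <- 60
  g <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10,
              dimnames = list(sprintf("E%02d", 1:n), NULL))
  tab <- toy_table(g, pos = seq_len(10) * 1e6, entry_id = rownames(g))
  des <- study_design(rownames(g), "P1", "S1")
  # phenotype an exact linear function of markers 2, 5, 9
  y <- stats::setNames(2 * g[, 2] - 1.5 * g[, 5] + g[, 9], rownames(g))
  res <- str_select(tab, y, des, max_r2 = 0.9999, alpha = 0.05)
  expect_setequal(res$variant_id, tab$info$variant_id[c(2, 5, 9)])
  expect_gte(attr(res, "cum_r2"), 0.9999)

  # brute-force check: no 3-subset of the 10 markers fits better
  rss3 <- function(idx) sum(lm.fit(cbind(1, g[, idx]), unname(y))$residuals^2)
  best <- min(apply(utils::combn(10, 3), 2, rss3))
  expect_equal(rss3(c(2, 5, 9)), best, tolerance = 1e-9)

  # max_r2 stop: the cap truncates selection
  res_cap <- str_select(tab, y, des, max_r2 = 0.5, alpha = 0.05)
  expect_lt(nrow(res_cap), 3)

  # alpha -> 0: empty selection
  expect_equal(nrow(str_select(tab, y, des, alpha = 1e-14)), 0L)

  # max_markers = 1 with two signals: only the stronger one
  y2 <- stats::setNames(3 * g[, 2] + 0.8 * g[, 5] + rnorm(n, 0, 0.1),
                        rownames(g))
  res1 <- str_select(tab, y2, des, max_markers = 1)
  expect_equal(res1$variant_id, tab$info$variant_id[2])
})

test_that("stepwise never keeps a marker whose final p exceeds alpha", {
  st <- small_study()
  gf <- filter_variants(st$geno, 0.4, 0.1)
  res <- str_select(gf, st$blues, st$design, max_markers = 25, alpha = 0.05)
  expect_true(all(res$p < 0.05))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
})

test_that("first stepwise inclusion p equals the single-variant p", {
  st <- small_study()
  gf <- filter_variants(st$geno, 0.4, 0.1)[, 1:40]
  y <- stats::setNames(st$blues$blue, st$blues$entry_id)
  sv <- sv_scan(gf, y, st$design)
  res <- str_select(gf, y, st$design, max_markers = 1)
  k <- match(res$variant_id[1], sv$variant_id)
  expect_equal(res$inclusion_p[1], sv$p[k], tolerance = 1e-9)
  expect_equal(sv$p[k], min(sv$p), tolerance = 1e-12)
})

test_that("variance_explained covers exact, null and single-variant cases", {
  set.seed(44)
  n <- 80
  g <- matrix(sample(0:2, n * 12, replace = TRUE), n, 12,
              dimnames = list(sprintf("E%02d", 1:n), NULL))
  tab <- toy_table(g, entry_id = rownames(g))
  des <- study_design(rownames(g), "P1", "S1")
  sel <- tab$info$variant_id[c(1, 4, 7)]
  y_exact <- stats::setNames(rowSums(g[, c(1, 4, 7)]), rownames(g))
  expect_equal(as.numeric(variance_explained(tab, sel, y_exact, des)), 1)

  y_null <- stats::setNames(rnorm(n), rownames(g))
  r2_null <- as.numeric(variance_explained(tab, sel, y_null, des))
  expect_lt(r2_null, 3 * 3 / n + 0.1)   # overfit bound ~ p/n

  # single variant: equals the squared partial correlation
  r2_1 <- as.numeric(variance_explained(tab, sel[1], y_null, des))
  expect_equal(r2_1, cor(g[, 1], y_null)^2, tolerance = 1e-9)

  expect_equal(as.numeric(variance_explained(tab, character(0), y_null, des)),
               0)
  # ridge fallback flagged when variants outnumber entries
  small <- tab[1:10, ]
  ys <- stats::setNames(rnorm(10), entry_ids(small))
  dsmall <- study_design(entry_ids(small), "P1", "S1")
  expect_message(
    vr <- variance_explained(small, small$info$variant_id, ys, dsmall),
    "ridge")
  expect_true(attr(vr, "ridge"))
})
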