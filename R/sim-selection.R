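## Helpers shared by the selection and pool simulators.

# derive two haplotypes per entry from a (near-)homozygous dosage matrix;
# het calls split at random, missing calls drawn from the column frequency
entry_haplotypes <- function(table) {
  g <- table$geno
  p <- alt_freq(table)
  na <- which(is.na(g))
  if (length(na)) {
    pc <- p[(na - 1) %/% nrow(g) + 1]
    g[na] <- 2 * stats::rbinom(length(na), 1, pc)
  }
  h1 <- h2 <- g / 2
  het <- which(g == 1)
  if (length(het)) {
    coin <- stats::rbinom(length(het), 1, 0.5)
    h1[het] <- coin
    h2[het] <- 1 - coin
  }
  list(h1 = h1, h2 = h2)   # entries x variants matrices of 0/1
}

#' Simulate long-term divergent selection with a correlated focal trait
#'
#' Emulates a recurrent-selection experiment: from a base population, two
#' arms are propagated for `generations` cycles of truncation selection on
#' a primary trait (ear-length-like) that is genetically correlated with
#' the focal trait (kernel-row-number-like) carried by `truth`. The
#' long-arm (LE) selects high, the short-arm (SE) selects low. Each cycle,
#' `round(Ne / selected_fraction)` offspring are produced by random mating
#' (with replacement) among the `Ne` selected parents, so an unselected
#' variant drifts as a Wright-Fisher population of size `Ne`.
#'
#' The primary trait's genetic values are constructed by pleiotropy: a
#' scaled copy of the focal genetic values plus an independent polygenic
#' component on background loci, giving genetic correlation
#' `genetic_correlation` in the base population.
#'
#' @param base a `VariantTable` for the base population (entries are used
#'   as the founding gene pool).
#' @param truth truth record from [simulate_study()] (for focal QTL ids and
#'   effects).
#' @param map a `GeneticMap` covering the variants.
#' @param generations number of selection cycles (default 30).
#' @param selected_fraction fraction selected each cycle; `1` gives pure
#'   drift.
#' @param genetic_correlation correlation between primary and focal genetic
#'   values in the base (default -0.6: longer ears, fewer kernel rows).
#' @param Ne number of selected parents per cycle.
#' @param h2_primary heritability of the primary trait used for selection.
#' @param n_background number of background loci for the independent
#'   polygenic component.
#' @param seed optional seed.
#' @return list: `freq_C0` (base allele frequencies), `freq_LE`/`freq_SE`
#'   (variants x generations+1 frequency trajectories), `trait`
#'   (per-generation mean genetic values of both traits per arm).
#' @export
simulate_divergent_selection <- function(base, truth, map, generations = 30,
                                         selected_fraction = 0.2,
                                         genetic_correlation = -0.6,
                                         Ne = 100, h2_primary = 0.5,
                                         n_background = 100, seed = NULL) {
  stopifnot(generations >= 0, selected_fraction > 0, selected_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_variants(base)
  chrom <- base$info$chrom
  cm <- map_cM(map, chrom, base$info$pos)
  chrs <- unique(chrom)
  idx_by_chr <- lapply(chrs, function(ch) which(chrom == ch))
  cm_by_chr <- lapply(idx_by_chr, function(i) cm[i])
  len_cM <- vapply(chrs, function(ch) max(map$pos_cM[map$chrom == ch]),
                   numeric(1))

  # focal and primary effect vectors over all variants
  beta_f <- numeric(m)
  jq <- match(truth$qtl$variant_id, base$info$variant_id)
  beta_f[jq] <- truth$qtl$effect
  bg <- sample(setdiff(seq_len(m), jq), min(n_background, m - length(jq)))
  beta_bg <- numeric(m)
  beta_bg[bg] <- stats::rnorm(length(bg))

  hap <- entry_haplotypes(base)
  census <- max(2L, round(Ne / selected_fraction))

  gv <- function(H) as.vector((H$h1 + H$h2) %*% cbind(beta_f, beta_bg)) # 2 cols
  g0 <- matrix(gv(hap), ncol = 2)
  sd_f <- stats::sd(g0[, 1]); sd_b <- stats::sd(g0[, 2])
  if (sd_b == 0) sd_b <- 1
  rho <- genetic_correlation
  w_f <- rho / max(sd_f, 1e-12)
  w_b <- sqrt(1 - rho^2) / sd_b

  freqs <- function(H) colMeans(H$h1 + H$h2) / 2

  advance <- function(H, direction) {
    traj <- matrix(NA_real_, m, generations + 1)
    tr <- data.frame(generation = 0:generations, focal = NA_real_,
                     primary = NA_real_)
    cur <- H
    for (t in 0:generations) {
      g <- matrix(gv(cur), ncol = 2)
      gp <- w_f * g[, 1] + w_b * g[, 2]
      traj[, t + 1] <- freqs(cur)
      tr$focal[t + 1] <- mean(g[, 1]) / 2     # dosage/2 scale
      tr$primary[t + 1] <- mean(gp)
      if (t == generations) break
      pheno <- gp + stats::rnorm(length(gp),
                                 0, sqrt(stats::var(gp) * (1 - h2_primary) /
                                           max(h2_primary, 1e-12)))
      n_sel <- max(1L, round(selected_fraction * nrow(cur$h1)))
      sel <- order(pheno, decreasing = direction > 0)[seq_len(n_sel)]
      if (n_sel < 2 && selected_fraction < 1)
        stop("population extinct: fewer than 2 selected parents")
      p1 <- sel[sample.int(n_sel, census, replace = TRUE)]
      p2 <- sel[sample.int(n_sel, census, replace = TRUE)]
      h1 <- matrix(0L, census, m); h2 <- matrix(0L, census, m)
      for (i in seq_len(census)) {
        h1[i, ] <- meiosis_(cur$h1[p1[i], ], cur$h2[p1[i], ],
                            cm_by_chr, idx_by_chr, len_cM)
        h2[i, ] <- meiosis_(cur$h1[p2[i], ], cur$h2[p2[i], ],
                            cm_by_chr, idx_by_chr, len_cM)
      }
      cur <- list(h1 = h1, h2 = h2)
    }
    list(traj = traj, trait = tr)
  }

  ## bring the base up to census size by one round of random mating
  expand <- function(H) {
    nb <- nrow(H$h1)
    p1 <- sample.int(nb, census, replace = TRUE)
    p2 <- sample.int(nb, census, replace = TRUE)
    h1 <- matrix(0L, census, m); h2 <- matrix(0L, census, m)
    for (i in seq_len(census)) {
      h1[i, ] <- meiosis_(H$h1[p1[i], ], H$h2[p1[i], ],
                          cm_by_chr, idx_by_chr, len_cM)
      h2[i, ] <- meiosis_(H$h1[p2[i], ], H$h2[p2[i], ],
                          cm_by_chr, idx_by_chr, len_cM)
    }
    list(h1 = h1, h2 = h2)
  }
  c0 <- expand(hap)
  freq_C0 <- freqs(c0)
  le <- advance(c0, +1)
  se <- advance(c0, -1)
  rownames(le$traj) <- rownames(se$traj) <- base$info$variant_id
  names(freq_C0) <- base$info$variant_id
  list(freq_C0 = freq_C0, freq_LE = le$traj, freq_SE = se$traj,
       trait = rbind(cbind(arm = "LE", le$trait), cbind(arm = "SE", se$trait)),
       generations = generations, Ne = Ne,
       selected_fraction = selected_fraction)
}

#' Simulate a panel of heterogeneous accessions
#'
#' Each accession is an open-pollinated population characterized by its own
#' allele frequencies, drawn around the base frequencies with a
#' Balding-Nichols Beta model at divergence `fst`. The accession's true
#' trait value is its expected genetic value under the focal additive
#' effects.
#'
#' @param base_freq per-variant base alternate-allele frequencies (named).
#' @param truth truth record from [simulate_study()].
#' @param variant_ids variant ids for the panel columns (default all of
#'   `names(base_freq)`).
#' @param n_accessions number of accessions.
#' @param fst divergence parameter in `(0, 1)`.
#' @param seed optional seed.
#' @return list of class `AccessionPanel`: `freq` (accessions x variants
#'   true allele frequencies), `trait` (true trait values), `variant_id`.
#' @export
simulate_accessions <- function(base_freq, truth, variant_ids = names(base_freq),
                                n_accessions = 200, fst = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- base_freq[variant_ids]
  k <- (1 - fst) / fst
  m <- length(p)
  fr <- matrix(stats::rbeta(n_accessions * m,
                            rep(p * k, each = n_accessions),
                            rep((1 - p) * k, each = n_accessions)),
               nrow = n_accessions,
               dimnames = list(sprintf("ACC%04d", seq_len(n_accessions)),
                               variant_ids))
  beta <- numeric(m)
  jq <- match(truth$qtl$variant_id, variant_ids)
  beta[jq[!is.na(jq)]] <- truth$qtl$effect[!is.na(jq)]
  trait <- as.vector(fr %*% beta)   # E[dosage/2 * effect] = p * effect
  names(trait) <- rownames(fr)
  structure(list(freq = fr, trait = trait, variant_id = variant_ids),
            class = "AccessionPanel")
}

#' Pool-genotype an accession panel at its trait tails
#'
#' Accessions in the high and low tails of the true trait distribution are
#' retained and "genotyped" as pools: for each accession, `pool_size`
#' plants are drawn (dosage ~ Binomial(2, p)) and the pooled allele
#' frequency estimate is the mean dosage / 2.
#'
#' @param accessions an `AccessionPanel` from [simulate_accessions()].
#' @param pool_size plants pooled per accession (<= 12 in practice).
#' @param tails length-2 vector: high and low tail fractions.
#' @param seed optional seed.
#' @return list: `freq` (estimated pooled frequencies, accessions x
#'   variants), `label` ("high"/"low" per retained accession), `true_freq`,
#'   `trait`.
#' @export
simulate_pools <- function(accessions, pool_size = 12, tails = c(0.25, 0.25),
                           seed = NULL) {
  stopifnot(inherits(accessions, "AccessionPanel"), pool_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(accessions$freq)
  ord <- order(accessions$trait, decreasing = TRUE)
  n_hi <- max(1L, round(tails[1] * n)); n_lo <- max(1L, round(tails[2] * n))
  hi <- ord[seq_len(n_hi)]; lo <- rev(ord)[seq_len(n_lo)]
  keep <- c(hi, lo)
  label <- c(rep("high", n_hi), rep("low", n_lo))
  p <- accessions$freq[keep, , drop = FALSE]
  est <- matrix(stats::rbinom(length(p), 2L * pool_size, p) / (2 * pool_size),
                nrow = nrow(p), dimnames = dimnames(p))
  list(freq = est, label = stats::setNames(label, rownames(p)),
       true_freq = p, trait = accessions$trait[keep],
       pool_size = pool_size)
}

#' Derive an unrelated panel by generations of random mating
#'
#' Produces a validation panel that shares ancestral haplotypes (hence
#' short-range linkage disequilibrium) with the base material but none of
#' the family structure of the mapping populations: `generations` cycles
#' of random mating at size `Ne`, followed by optional selfing of each
#' final individual to emulate inbred lines.
#'
#' @param base a `VariantTable` founding gene pool.
#' @param map a `GeneticMap` covering the variants.
#' @param n_out number of panel entries returned.
#' @param generations random-mating generations.
#' @param Ne population size during random mating.
#' @param self_generations selfing generations applied to each final
#'   individual (0 keeps them outbred).
#' @param prefix entry-id prefix.
#' @param seed optional seed.
#' @return a `VariantTable` of `n_out` entries.
#' @export
random_mating_panel <- function(base, map, n_out, generations = 10, Ne = 80,
                                self_generations = 0, prefix = "PANEL",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_variants(base)
  chrom <- base$info$chrom
  cm <- map_cM(map, chrom, base$info$pos)
  chrs <- unique(chrom)
  idx_by_chr <- lapply(chrs, function(ch) which(chrom == ch))
  cm_by_chr <- lapply(idx_by_chr, function(i) cm[i])
  len_cM <- vapply(chrs, function(ch) max(map$pos_cM[map$chrom == ch]),
                   numeric(1))
  cur <- entry_haplotypes(base)
  sizes <- c(rep(Ne, max(generations, 1) - 1), n_out)
  if (generations == 0) sizes <- integer(0)
  for (sz in sizes) {
    nb <- nrow(cur$h1)
    p1 <- sample.int(nb, sz, replace = TRUE)
    p2 <- sample.int(nb, sz, replace = TRUE)
    h1 <- matrix(0L, sz, m); h2 <- matrix(0L, sz, m)
    for (i in seq_len(sz)) {
      h1[i, ] <- meiosis_(cur$h1[p1[i], ], cur$h2[p1[i], ],
                          cm_by_chr, idx_by_chr, len_cM)
      h2[i, ] <- meiosis_(cur$h1[p2[i], ], cur$h2[p2[i], ],
                          cm_by_chr, idx_by_chr, len_cM)
    }
    cur <- list(h1 = h1, h2 = h2)
  }
  for (g in seq_len(self_generations)) {
    for (i in seq_len(nrow(cur$h1))) {
      a <- meiosis_(cur$h1[i, ], cur$h2[i, ], cm_by_chr, idx_by_chr, len_cM)
      b <- meiosis_(cur$h1[i, ], cur$h2[i, ], cm_by_chr, idx_by_chr, len_cM)
      cur$h1[i, ] <- a; cur$h2[i, ] <- b
    }
  }
  g <- cur$h1 + cur$h2
  rownames(g) <- sprintf("%s_%04d", prefix, seq_len(nrow(g)))
  variant_table(g, base$info$chrom, base$info$pos, base$info$ref,
                base$info$alt, base$info$variant_id, rownames(g))
}
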