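test_that("simple-matching kinship handles identity, opposition, missing", {
  a <- c(0, 1, 2, 0, 1, 2)
  gm <- toy_gm(rbind(a, a, 2 - a))
  K <- kinship_simple_matching(gm)
  expect_equal(unname(K[1, 2]), 1)
  expect_equal(unname(K[1, 3]), 1 / 3)  # dosage-1 sites still match
  gm2 <- toy_gm(rbind(c(0, 0, 0), c(2, 2, 2)))
  K2 <- kinship_simple_matching(gm2)
  expect_equal(unname(K2[1, 2]), 0)
  expect_equal(unname(diag(K2)), c(1, 1))
})

test_that("kinship equals an exhaustive pairwise counting oracle", {
  dos <- rbind(
    c(0, 1, 2, NA, 1, 0),
    c(0, 1, 1, 2, NA, 0),
    c(2, 1, 2, 2, 1, 1),
    c(0, NA, 2, 2, 1, 0)
  )
  gm <- toy_gm(dos)
  K <- kinship_simple_matching(gm)
  for (i in 1:4) {
    for (j in 1:4) {
      both <- !is.na(dos[i, ]) & !is.na(dos[j, ])
      expect_equal(unname(K[i, j]),
                   sum(dos[i, both] == dos[j, both]) / sum(both))
    }
  }
  expect_true(isSymmetric(unclass(K)))
  expect_true(all(K >= 0 & K <= 1))
})

test_that("kinship errors when a pair shares no genotyped locus", {
  dos <- rbind(c(0, NA), c(NA, 2))
  expect_error(kinship_simple_matching(toy_gm(dos)), "zero jointly")
})

test_that("PCA separates simulated subpopulations", {
  cfg <- sim_config(n_accessions = 80, n_subpops = 2, n_chroms = 2,
                    snps_per_chrom = 150, fst = 0.3, missing_rate = 0,
                    n_qtl = 0, seed = 21)
  gm <- simulate_genotypes(cfg)
  pca <- pca_genotypes(gm, n_components = 3)
  sp <- attr(gm, "subpop")
  pc1 <- pca$scores$PC1
  # silhouette of the subpopulation labels along PC1
  sil <- vapply(seq_along(pc1), function(i) {
    d <- abs(pc1 - pc1[i])
    a <- mean(d[sp == sp[i]][-which(which(sp == sp[i]) == i)])
    a <- mean(d[setdiff(which(sp == sp[i]), i)])
    b <- mean(d[sp != sp[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  # variance fractions are non-increasing and sum below 1
  expect_true(all(diff(pca$var_frac) <= 1e-12))
  expect_lt(sum(pca$var_frac), 1 + 1e-12)
})

test_that("duplicated accessions coincide on all PCs", {
  cfg <- small_cfg(missing_rate = 0)
  gm <- simulate_genotypes(cfg)
  dup <- gm$dosages[c(seq_len(20), seq_len(20)), ]
  rownames(dup) <- sprintf("ACC%03d", seq_len(40))
  gmd <- genotype_matrix(dup, gm$variants)
  pca <- pca_genotypes(gmd, n_components = 2, prune = FALSE)
  s <- as.matrix(pca$scores[, c("PC1", "PC2")])
  expect_equal(s[1:20, ], s[21:40, ], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("ld_r2 equals direct correlation and is label-swap invariant", {
  withr::with_seed(4, {
    x <- sample(0:2, 8, replace = TRUE)
    y <- pmin(2, pmax(0, x + sample(c(-1, 0, 1), 8, replace = TRUE)))
  })
  gm <- toy_gm(cbind(x, y, 2 - x))
  expect_equal(ld_r2(gm, "chr1_1000", "chr1_2000"),
               cor(x, y)^2, tolerance = 1e-12)
  expect_equal(ld_r2(gm, "chr1_1000", "chr1_1000"), 1)
  expect_equal(ld_r2(gm, "chr1_1000", "chr1_3000"), 1, tolerance = 1e-12)
  gm_mono <- toy_gm(cbind(x, rep(1, 8)))
  expect_error(ld_r2(gm_mono, "chr1_1000", "chr1_2000"), "monomorphic")
})

test_that("ld_decay matches a brute-force pair enumeration", {
  cfg <- sim_config(n_accessions = 100, n_chroms = 1, snps_per_chrom = 200,
                    chrom_length_bp = 5e6, ld_block_size_bp = 2.5e5,
                    within_block_r2 = 0.8, missing_rate = 0, n_qtl = 0,
                    seed = 2)
  gm <- simulate_genotypes(cfg)
  dec <- ld_decay(gm, max_dist = 2e6, bin_width = 1e5)
  # brute force: every pair, squared correlation, same binning
  pos <- gm$variants$pos
  d <- gm$dosages
  recs <- list()
  for (i in 1:(length(pos) - 1)) {
    for (j in (i + 1):length(pos)) {
      dist <- abs(pos[j] - pos[i])
      if (dist > 2e6) next
      r2 <- suppressWarnings(cor(d[, i], d[, j]))^2
      if (is.na(r2)) next
      recs[[length(recs) + 1]] <- c(min(dist %/% 1e5, 19), r2)
    }
  }
  mat <- do.call(rbind, recs)
  oracle <- tapply(mat[, 2], mat[, 1], mean)
  got <- setNames(dec$curve$mean_r2, dec$curve$bin_start / 1e5)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(dec$curve$mean_r2 >= 0 & dec$curve$mean_r2 <= 1))
})

test_that("perfect within-block LD and no-LD limits behave as expected", {
  # one perfect-LD block spanning the chromosome: curve pinned at 1, no decay
  cfg1 <- sim_config(n_accessions = 60, n_chroms = 1, snps_per_chrom = 60,
                     chrom_length_bp = 2e6, ld_block_size_bp = 2e6,
                     within_block_r2 = 1, missing_rate = 0, n_qtl = 0,
                     seed = 3)
  gm1 <- simulate_genotypes(cfg1)
  dec1 <- ld_decay(gm1, max_dist = 2e6, bin_width = 2e5)
  expect_true(all(abs(dec1$curve$mean_r2 - 1) < 1e-12))
  expect_true(is.na(dec1$half_max_dist))  # never falls to half max

  # two-tier structure: high LD inside 200 kb blocks, chance level beyond,
  # so the half-max distance lands in the first cross-block bin
  cfg2 <- sim_config(n_accessions = 200, n_chroms = 1, snps_per_chrom = 400,
                     chrom_length_bp = 8e6, ld_block_size_bp = 2e5,
                     within_block_r2 = 0.9, missing_rate = 0, n_qtl = 0,
                     seed = 4)
  gm2 <- simulate_genotypes(cfg2)
  dec2 <- ld_decay(gm2, max_dist = 2e6, bin_width = 2e5)
  expect_equal(dec2$half_max_dist, dec2$curve$bin_mid[2])
  expect_lt(dec2$dist_r2_50, 4e5)
})

test_that("Tajima's D matches an independently coded oracle", {
  # 5 diploid accessions = 10 chromosomes, 16 sites
  withr::with_seed(9, {
    dos <- matrix(sample(0:2, 5 * 16, replace = TRUE,
                         prob = c(0.45, 0.2, 0.35)), 5, 16)
  })
  gm <- toy_gm(dos)
  got <- tajimas_d(gm)

  # oracle written separately from the package formulas
  n <- 10
  counts <- colSums(dos)
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  pi_hat <- 0
  for (c_alt in counts[seg]) {
    pi_hat <- pi_hat + (c_alt * (n - c_alt)) / (n * (n - 1) / 2)
  }
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_oracle <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got$D, D_oracle, tolerance = 1e-9)
  expect_equal(got$S, S)
})

test_that("Tajima's D sign tracks the site frequency spectrum", {
  # singletons only -> negative D
  n_acc <- 12
  dos_rare <- matrix(0, n_acc, 10)
  for (j in 1:10) dos_rare[((j - 1) %% n_acc) + 1, j] <- 1
  expect_lt(tajimas_d(toy_gm(dos_rare))$D, 0)
  # intermediate-frequency sites -> positive D
  dos_common <- matrix(0, n_acc, 6)
  for (j in 1:6) dos_common[1:(n_acc / 2), j] <- 2
  expect_gt(tajimas_d(toy_gm(dos_common))$D, 0)
  # no segregating sites -> error
  expect_error(tajimas_d(toy_gm(matrix(0, 4, 5))), "no segregating")
})

test_that("neutral exchangeable-frequency regions give mean D near zero", {
  n_acc <- 40
  n <- 2 * n_acc
  sfs_prob <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  ds <- withr::with_seed(11, replicate(200, {
    S <- 25
    dos <- matrix(0, n_acc, S)
    for (j in seq_len(S)) {
      cnt <- sample(n - 1, 1, prob = sfs_prob)
      chroms <- sample(n, cnt)
      for (ch in chroms) {
        dos[(ch - 1) %/% 2 + 1, j] <- dos[(ch - 1) %/% 2 + 1, j] + 1
      }
    }
    tajimas_d(toy_gm(dos))$D
  }))
  expect_lt(abs(mean(ds)), 0.3)
})

test_that("LD pruning collapses perfect blocks and spares independence", {
  # blocks of 5 SNPs in perfect LD within a 50 kb window
  cfg <- sim_config(n_accessions = 80, n_chroms = 1, snps_per_chrom = 50,
                    chrom_length_bp = 5e5, ld_block_size_bp = 5e4,
                    within_block_r2 = 1, missing_rate = 0, n_qtl = 0,
                    seed = 6)
  gm <- simulate_genotypes(cfg)
  pr <- ld_prune(gm, window_bp = 6e4, step = 1, r2_max = 0.2)
  blocks <- unique((gm$variants$pos - 1) %/% 5e4)
  kept_blocks <- (gm$variants$pos[match(pr$kept_ids, gm$variants$id)] - 1) %/% 5e4
  expect_equal(pr$n_independent, length(blocks))
  expect_equal(anyDuplicated(kept_blocks), 0L)

  # independent SNPs survive intact
  cfg2 <- sim_config(n_accessions = 100, n_chroms = 1, snps_per_chrom = 80,
                     chrom_length_bp = 8e6, ld_block_size_bp = 1,
                     missing_rate = 0, n_qtl = 0, seed = 7)
  gm2 <- simulate_genotypes(cfg2)
  pr2 <- ld_prune(gm2, window_bp = 5e4, step = 5, r2_max = 0.6)
  expect_equal(pr2$n_independent, 80)
})

test_that("no surviving pair in any visited window exceeds the threshold", {
  cfg <- sim_config(n_accessions = 100, n_chroms = 1, snps_per_chrom = 200,
                    chrom_length_bp = 4e6, ld_block_size_bp = 2e5,
                    within_block_r2 = 0.9, missing_rate = 0, n_qtl = 0,
                    seed = 8)
  gm <- simulate_genotypes(cfg)
  pr <- ld_prune(gm, window_bp = 3e5, step = 1, r2_max = 0.2)
  kept <- subset_genotypes(gm, snp_ids = pr$kept_ids)
  pos <- kept$variants$pos
  # exhaustive post-hoc re-check over every kept pair closer than the window
  r2 <- suppressWarnings(cor(kept$dosages))^2
  for (i in seq_len(length(pos) - 1)) {
    for (j in (i + 1):length(pos)) {
      if (pos[j] - pos[i] <= 3e5) {
        expect_lte(r2[i, j], 0.2 + 1e-12)
      }
    }
  }
})
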