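obs_row <- function(vals) {
  tibble::tibble(accession = "A1", trait = names(vals), year = 1, rep = 1,
                 value = unname(vals))
}

test_that("ratio traits follow their defining formulas", {
  vals <- c(spike_length = 10, spike_weight = 5, grain_weight = 3,
            awn_weight = 0.4, chaff_weight = 1.5, grain_number = 60,
            spikelet_number = 20, rachis_weight = 0.3,
            spikelet_weight = 0.25, grain_number_spikelet = 3,
            chaff_weight_spikelet = 0.08, grain_weight_spikelet = 0.15)
  out <- derive_traits(obs_row(vals))
  got <- setNames(out$value, out$trait)
  # thousand kernel weight: (grain weight / grain number) x 1000
  expect_equal(got[["tkw"]], 3 / 60 * 1000)  # = 50
  # spikelet density: spikelet number / spike length
  expect_equal(got[["spikelet_density"]], 20 / 10)  # = 2
  # every ratio equals an independent hand computation
  hand <- c(
    tkw = 50, grain_number_per_chaff = 60 / 1.5,
    grain_weight_per_chaff = 3 / 1.5, grain_weight_per_spike = 3 / 5,
    grain_weight_per_rachis = 3 / 0.3, spikelet_density = 2,
    chaff_per_spike_weight = 1.5 / 5, awn_per_spike_weight = 0.4 / 5,
    awn_per_grain_weight = 0.4 / 3, awn_per_chaff_weight = 0.4 / 1.5,
    grain_weight_per_chaff_spikelet = 0.15 / 0.08,
    tkw_spikelet = 0.15 / 3 * 1000,
    fruiting_efficiency_spikelet = 3 / 0.08,
    grain_weight_per_spikelet_weight = 0.15 / 0.25,
    chaff_per_spikelet_weight = 0.08 / 0.25
  )
  expect_equal(got[names(hand)], hand, ignore_attr = TRUE)
  expect_equal(length(got), 27L)
})

test_that("ratios are computed per replicate, not on averages", {
  # two replicates chosen so mean-of-ratios != ratio-of-means
  obs <- tibble::tibble(
    accession = "A1",
    trait = rep(c("grain_weight", "grain_number"), each = 2),
    year = 1, rep = rep(1:2, 2),
    value = c(2, 4, 40, 100)
  )
  out <- suppressWarnings(derive_traits(obs))
  tkw <- dplyr::filter(out, trait == "tkw")
  expect_equal(sort(tkw$value), sort(c(2 / 40, 4 / 100) * 1000))
  per_rep_mean <- mean(c(2 / 40, 4 / 100) * 1000)
  of_means <- mean(c(2, 4)) / mean(c(40, 100)) * 1000
  expect_false(isTRUE(all.equal(per_rep_mean, of_means)))
  expect_equal(mean(tkw$value), per_rep_mean)
})

test_that("zero or missing denominators drop the record with a count", {
  obs <- tibble::tibble(
    accession = c("A1", "A2", "A2"),
    trait = c("spikelet_number", "spikelet_number", "spike_length"),
    year = 1, rep = 1,
    value = c(20, 18, 0)
  )
  out <- suppressWarnings(derive_traits(obs))
  expect_false("spikelet_density" %in% out$trait[out$accession == "A2"])
  expect_gte(attr(out, "dropped"), 1L)
})

test_that("variance components are zero for constant data", {
  obs <- balanced_obs(rep(5, 4), rep(0, 2), reps = 3)
  vc <- anova_components(obs)
  expect_equal(vc$var_G, 0)
  expect_equal(vc$var_GxE, 0)
  expect_equal(vc$var_e, 0)
})

test_that("noise-free genotype effects are recovered exactly", {
  geno <- c(1, 3, 7, 10, 2)
  obs <- balanced_obs(geno, c(0, 0), reps = 3)
  vc <- anova_components(obs)
  expect_equal(vc$var_e, 0)
  expect_equal(vc$var_GxE, 0)
  # MS_G/(r*y) with MS_GxE = 0: empirical genotype variance
  expect_equal(vc$var_G, var(geno) * 6 / 6)
})

test_that("balanced closed-form sums of squares equal aov()", {
  obs <- balanced_obs(c(1, 4, 2, 8), c(0, 3), reps = 3, noise_sd = 2,
                      seed = 7)
  vc <- anova_components(obs)
  fit <- aov(value ~ factor(accession) * factor(year), data = obs)
  s <- summary(fit)[[1]]
  expect_equal(vc$anova$sumsq, unname(s$`Sum Sq`), tolerance = 1e-10)
  expect_equal(vc$anova$df, unname(s$Df))
  # conservation: stratum sums of squares add to the total
  expect_equal(sum(vc$anova$sumsq), sum((obs$value - mean(obs$value))^2),
               tolerance = 1e-10)
})

test_that("components are inestimable with one year or one replicate", {
  one_year <- balanced_obs(c(1, 2, 3), 0, reps = 3, noise_sd = 1)
  expect_error(anova_components(one_year), ">= 2")
  one_rep <- balanced_obs(c(1, 2, 3), c(0, 1), reps = 1, noise_sd = 1)
  expect_error(anova_components(one_rep), ">= 2")
})

test_that("negative moment estimates are clamped and flagged", {
  # pure noise with tiny genotype signal often gives negative var_G
  found <- FALSE
  for (seed in 1:10) {
    obs <- balanced_obs(rep(0, 5), c(0, 0), reps = 2, noise_sd = 1,
                        seed = seed)
    vc <- anova_components(obs)
    if (any(vc$clamped)) { found <- TRUE; break }
  }
  expect_true(found)
  expect_gte(vc$var_G, 0)
  expect_gte(vc$var_GxE, 0)
})

test_that("heritability follows the entry-mean formula", {
  vc <- list(var_G = 4, var_GxE = 2, var_e = 5)
  expect_equal(heritability(vc, n_years = 2, r = 5), 4 / (4 + 1 + 0.5))
  expect_equal(round(heritability(vc, n_years = 2, r = 5), 4), 0.7273)
  expect_equal(heritability(list(var_G = 3, var_GxE = 0, var_e = 0),
                            n_years = 2, r = 5), 1)
  expect_equal(heritability(list(var_G = 0, var_GxE = 2, var_e = 5),
                            n_years = 2, r = 5), 0)
  expect_error(heritability(list(var_G = 0, var_GxE = 0, var_e = 0),
                            n_years = 2, r = 5), "undefined")
})

test_that("H2 is invariant to rescaling all observations", {
  obs <- balanced_obs(c(1, 5, 3, 9), c(0, 2),
                      gxe = matrix(rnorm(8, 0, 0.5), 4, 2),
                      reps = 3, noise_sd = 1, seed = 3)
  h1 <- heritability(anova_components(obs))
  obs2 <- dplyr::mutate(obs, value = value * 7.3)
  h2 <- heritability(anova_components(obs2))
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("balanced BLUEs equal genotype means and translate with the data", {
  obs <- balanced_obs(c(2, 4, 9), c(0, 1), reps = 2, noise_sd = 1, seed = 2)
  b <- compute_blues(obs)
  expect_equal(attr(b, "method"), "balanced_mean")
  means <- tapply(obs$value, obs$accession, mean)
  expect_equal(b$blue, as.numeric(means[b$accession]))
  b2 <- compute_blues(dplyr::mutate(obs, value = value + 11))
  expect_equal(b2$blue, b$blue + 11)
})

test_that("unbalanced BLUEs match an explicit GLS oracle", {
  obs <- balanced_obs(c(2, 4, 9, 5, 7), c(0, 1), reps = 3, noise_sd = 1,
                      seed = 8)
  obs <- obs[!(obs$accession == "G02" & obs$year == 2), ]  # unbalance
  b <- compute_blues(obs)
  expect_equal(attr(b, "method"), "reml")
  fit <- attr(b, "fit")
  # GLS at the REML variance estimates, by explicit matrix inversion
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_gy <- vc$vcov[vc$grp == "accession:year"]
  s2_y <- vc$vcov[vc$grp == "year"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  X <- model.matrix(~ 0 + factor(accession), data = obs)
  Zy <- model.matrix(~ 0 + factor(year), data = obs)
  Zgy <- model.matrix(~ 0 + factor(accession):factor(year), data = obs)
  V <- s2_y * tcrossprod(Zy) + s2_gy * tcrossprod(Zgy) +
    s2_e * diag(nrow(obs))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% obs$value)
  expect_equal(b$blue, as.numeric(beta), tolerance = 1e-6)
})

test_that("all-random mode returns shrunken genotype predictions", {
  obs <- balanced_obs(c(0, 10), c(0, 1), reps = 3, noise_sd = 2, seed = 4)
  blup <- compute_blues(obs, genotype_random = TRUE)
  blue <- compute_blues(obs)
  expect_equal(attr(blup, "method"), "blup")
  # BLUPs shrink toward the grand mean
  expect_lt(diff(range(blup$blue)), diff(range(blue$blue)) + 1e-9)
})

test_that("LSD letters separate obvious groups and join identical ones", {
  same <- lsd_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$letters[1], same$letters[2])
  far <- lsd_groups(c(0.1, 0.2, 0.15, 100.1, 100.2, 100.15),
                    rep(c("lo", "hi"), each = 3))
  expect_false(far$letters[1] == far$letters[2])
})

test_that("LSD letters agree with exhaustive pairwise t comparisons", {
  withr::with_seed(10, {
    vals <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 5))
    grp <- rep(c("g1", "g2", "g3"), each = 6)
  })
  out <- lsd_groups(vals, grp, alpha = 0.05)
  # brute-force oracle: pooled-variance pairwise comparisons
  fit <- aov(vals ~ factor(grp))
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfe <- summary(fit)[[1]]$Df[2]
  means <- tapply(vals, grp, mean)
  share_letter <- function(i, j) {
    any(strsplit(out$letters[out$group == i], "")[[1]] %in%
          strsplit(out$letters[out$group == j], "")[[1]])
  }
  for (i in c("g1", "g2")) {
    for (j in setdiff(c("g2", "g3"), i)) {
      sig <- abs(means[i] - means[j]) >
        qt(0.975, dfe) * sqrt(mse * (1 / 6 + 1 / 6))
      expect_equal(!share_letter(i, j), unname(sig))
    }
  }
})

test_that("groups with fewer than two observations are excluded", {
  expect_warning(
    out <- lsd_groups(c(1, 2, 1.5, 2.5, 9), c("a", "a", "b", "b", "c")),
    "excluding"
  )
  expect_false("c" %in% out$group)
})
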