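test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(dispersion = 0.5), "dispersion")
  bad <- anole_trait_correlation()
  bad[1, 2] <- 0.99; bad[2, 1] <- 0.99; bad[2, 3] <- -0.99; bad[3, 2] <- -0.99
  bad[1, 3] <- 0.99; bad[3, 1] <- 0.99
  expect_error(sim_config(trait_correlation = bad), "positive definite")
  g <- matrix(0, 6, 6); g[1, 2] <- 1
  expect_error(sim_config(gamma_true = g), "symmetric")
})

test_that("phenotypes reproduce the configured correlation structure", {
  # means far from zero so the sperm-count floor never triggers
  base <- list(n_males = 1e5, trait_means = rep(100, 6),
               trait_sds = rep(1, 6), seed = 42)
  ph_id <- simulate_phenotypes(do.call(sim_config,
    c(base, list(trait_correlation = diag(6)))))
  r_id <- cor(as.matrix(ph_id[sperm_traits()]))
  expect_lt(max(abs(r_id[upper.tri(r_id)])), 0.02)

  target <- anole_trait_correlation()
  ph <- simulate_phenotypes(do.call(sim_config,
    c(base, list(trait_correlation = target))))
  r <- cor(as.matrix(ph[sperm_traits()]))
  expect_lt(max(abs(r - target)), 0.01)
  expect_equal(unname(r["velocity", "linearity"]), 0.638, tolerance = 0.02)
  expect_equal(unname(r["sperm_count", "midpiece_length"]), -0.249,
               tolerance = 0.05)
  # moment matching for means and SDs
  x <- as.matrix(ph[sperm_traits()])
  expect_lt(max(abs(colMeans(x) - 100)), 3 / sqrt(1e5) * 1.5)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 0.02)
})

test_that("the generator is deterministic given the config", {
  cfg <- sim_config(n_males = 50, n_females = 80, n_loci = 40, seed = 9)
  s1 <- simulate_study(cfg, tracks = TRUE, cells_per_male = 2)
  s2 <- simulate_study(cfg, tracks = TRUE, cells_per_male = 2)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$offspring_counts, s2$offspring_counts)
  expect_identical(s1$adults$genotypes, s2$adults$genotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$tracks, s2$tracks)
})

test_that("offspring counts match the null moments and dispersion", {
  z <- matrix(rnorm(1e5 * 6), ncol = 6)
  z <- scale(z)
  cnt <- simulate_fitness(z, rep(0, 6), matrix(0, 6, 6),
                          mean_offspring = 7, dispersion = 1, seed = 2)
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_equal(mean(cnt), 7, tolerance = 0.05)
  expect_equal(var(cnt), 7, tolerance = 0.05)
  cnt3 <- simulate_fitness(z, rep(0, 6), matrix(0, 6, 6),
                           mean_offspring = 7, dispersion = 3, seed = 2)
  expect_equal(var(cnt3) / mean(cnt3), 3, tolerance = 0.1)
  expect_error(simulate_fitness(z, rep(0, 6), matrix(0, 6, 6),
                                dispersion = 0.9), "dispersion")
  expect_identical(cnt, simulate_fitness(z, rep(0, 6), matrix(0, 6, 6),
                                         mean_offspring = 7,
                                         dispersion = 1, seed = 2))
})

test_that("linear selection written into fitness is recovered by regression", {
  # oracle: for Gaussian standardized traits and a pure log-linear surface,
  # cov(w, z_count) equals the generative gradient
  set.seed(31)
  z <- scale(matrix(rnorm(1e5 * 6), ncol = 6))
  beta <- c(-0.17, 0, 0, 0, 0, 0)
  cnt <- simulate_fitness(z, beta, matrix(0, 6, 6), mean_offspring = 7,
                          dispersion = 1, seed = 8)
  w <- relative_fitness(cnt)
  slope <- coef(lm(w ~ z[, 1]))[2]
  expect_equal(unname(slope), -0.17, tolerance = 0.01)
})

test_that("true trios are Mendelian-consistent when error and missingness are off", {
  cfg <- sim_config(n_males = 20, n_females = 40, n_loci = 50,
                    per_allele_error = 0, missing_rate = 0, seed = 5)
  st <- simulate_study(cfg)
  ped <- st$pedigree
  skip_if(nrow(ped) == 0)
  g_o <- st$offspring$genotypes
  g_a <- st$adults$genotypes
  for (i in seq_len(min(nrow(ped), 50))) {
    tr <- trio_log_likelihood(g_o[ped$offspring_id[i], ],
                              g_a[ped$dam_id[i], ],
                              g_a[ped$sire_id[i], ],
                              st$allele_freqs, per_allele_error = 0)
    expect_identical(tr$n_incompatible, 0L)
    expect_gt(tr$lod, 0)
  }
})

test_that("non-parent trio incompatibility rate matches exhaustive enumeration", {
  # oracle: enumerate all 27 genotype combinations of an unrelated trio at
  # p = 0.5 and sum the Hardy-Weinberg probability of the Mendelian-
  # impossible ones
  hw <- c(0.25, 0.5, 0.25)
  M <- spermsel:::mendel_table()
  expected <- 0
  for (o in 0:2) for (d in 0:2) for (s in 0:2) {
    if (M[d + 1, s + 1, o + 1] == 0) {
      expected <- expected + hw[o + 1] * hw[d + 1] * hw[s + 1]
    }
  }
  n_trio <- 400; L <- 215
  frac <- spermsel:::with_seed(77, {
    draw <- function() matrix(rbinom(n_trio * L, 2, 0.5), n_trio, L)
    go <- draw(); gd <- draw(); gs <- draw()
    inc <- M[cbind(c(gd) + 1, c(gs) + 1, c(go) + 1)] == 0
    mean(inc)
  })
  se <- sqrt(expected * (1 - expected) / (n_trio * L))
  expect_equal(frac, expected, tolerance = 4 * se / expected)
})

test_that("missingness at 30% pushes adults past the 50-locus exclusion threshold", {
  cfg <- sim_config(n_males = 60, n_females = 60, n_loci = 215,
                    missing_rate = 0.3, seed = 13)
  st <- simulate_study(cfg)
  miss <- rowSums(is.na(st$adults$genotypes))
  expect_equal(mean(miss), 0.3 * 215, tolerance = 0.05)
  expect_gt(mean(miss > 50), 0.9)
})

test_that("simulated tracks honour the straight-line limit and determinism", {
  tr <- simulate_tracks(50, 100, fps = 25, duration_s = 2, noise_sd = 0,
                        seed = 4)
  expect_equal(as.numeric(compute_vapi(tr)), 50, tolerance = 1e-8)
  expect_equal(compute_linearity(tr), 100, tolerance = 1e-8)
  t1 <- simulate_tracks(40, 70, seed = 6)
  t2 <- simulate_tracks(40, 70, seed = 6)
  expect_identical(t1, t2)
  expect_error(simulate_tracks(40, 70, fps = 0), "positive")
  expect_error(simulate_tracks(40, 70, duration_s = 0.5), "45 frames")
})

test_that("track straightness tracks the requested linearity", {
  lin <- vapply(1:15, function(i) {
    compute_linearity(simulate_tracks(50, 60, duration_s = 2.2, seed = i))
  }, numeric(1))
  # the correlated-random-walk calibration is approximate (it matches the
  # root-mean-square displacement); demand the right neighbourhood
  expect_gt(mean(lin), 40)
  expect_lt(mean(lin), 75)
})
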