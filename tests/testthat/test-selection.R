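test_that("standardization uses the sample SD and reports exclusions", {
  df <- data.frame(male_id = c("a", "b", "c"), tr = c(1, 2, 3))
  z <- standardize(df, "tr")
  # sample-SD (n - 1) convention: sd(1,2,3) = 1, so z is exactly (-1, 0, 1)
  expect_equal(z$tr, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(sd(z$tr), 1, tolerance = 1e-12)
  expect_equal(unname(attr(z, "scale")), 1)
  # idempotence
  z2 <- standardize(z, "tr")
  expect_equal(z2$tr, z$tr, tolerance = 1e-12)
  # complete-case handling with a report
  df2 <- data.frame(male_id = c("a", "b", "c", "d"),
                    t1 = c(1, 2, NA, 4), t2 = c(5, 1, 2, 9))
  z3 <- standardize(df2, c("t1", "t2"))
  expect_equal(attr(z3, "dropped"), "c")
  expect_equal(unname(colMeans(as.matrix(z3[c("t1", "t2")]))), c(0, 0),
               tolerance = 1e-10)
  expect_error(standardize(data.frame(t = rep(1, 5)), "t"),
               "zero-variance")
})

test_that("relative fitness normalizes to mean one", {
  expect_equal(relative_fitness(c(0, 2, 4)), c(0, 1, 2))
  expect_equal(relative_fitness(rep(3, 7)), rep(1, 7))
  set.seed(2); cnt <- rpois(50, 4)
  expect_equal(mean(relative_fitness(cnt)), 1, tolerance = 1e-12)
  expect_error(relative_fitness(rep(0, 4)), "zero")
  expect_error(relative_fitness(c(-1, 2)), "non-negative")
})

test_that("the linear differential equals cov(w, z) on standardized traits", {
  set.seed(5)
  for (rep in 1:3) {
    x <- matrix(rnorm(60 * 4), 60, 4)
    colnames(x) <- paste0("t", 1:4)
    z <- z_std <- standardize(as.data.frame(x))
    w <- relative_fitness(rpois(60, exp(0.3 * as.matrix(z)[, 1] + 1)))
    uni <- univariate_differentials(z, w)
    for (j in 1:4) {
      expect_equal(uni$s[j], cov(w, as.matrix(z)[, j]),
                   tolerance = 1e-10)
    }
  }
})

test_that("gradients equal the brute-force normal-equations solution", {
  set.seed(12)
  z <- scale(matrix(rnorm(12 * 2), 12, 2))
  colnames(z) <- c("t1", "t2")
  w <- relative_fitness(rpois(12, 3) + 1)
  mg <- multivariate_gradients(z, w)
  # linear model
  bo <- normal_equations(z, w)
  expect_equal(mg$beta$beta, unname(bo[2:3]), tolerance = 1e-10)
  # full quadratic model
  X <- cbind(z, z[, 1]^2, z[, 2]^2, z[, 1] * z[, 2])
  qo <- normal_equations(X, w)
  expect_equal(unname(diag(mg$gamma)), unname(2 * qo[4:5]),
               tolerance = 1e-10)
  expect_equal(mg$gamma[1, 2], unname(qo[6]), tolerance = 1e-10)
  # univariate differentials against the same oracle
  uni <- univariate_differentials(z, w)
  so <- normal_equations(z[, 1, drop = FALSE], w)
  expect_equal(uni$s[1], unname(so[2]), tolerance = 1e-10)
  co <- normal_equations(cbind(z[, 1], z[, 1]^2), w)
  expect_equal(uni$c[1], unname(2 * co[3]), tolerance = 1e-10)
})

test_that("doubling applies to quadratic terms and their SEs, never to cross-products", {
  set.seed(31)
  z <- scale(matrix(rnorm(40 * 3), 40, 3))
  colnames(z) <- c("a", "b", "c")
  w <- relative_fitness(rpois(40, 4) + 1)
  mg <- multivariate_gradients(z, w)
  raw <- summary(mg$fit_quadratic)$coefficients
  for (tr in colnames(z)) {
    expect_identical(mg$gamma[tr, tr],
                     2 * raw[paste0(tr, ".sq"), "Estimate"])
    expect_identical(mg$gamma_se[tr, tr],
                     2 * raw[paste0(tr, ".sq"), "Std. Error"])
  }
  expect_identical(mg$gamma["a", "b"], raw["a.x.b", "Estimate"])
  expect_identical(mg$gamma_se["a", "b"], raw["a.x.b", "Std. Error"])
  expect_equal(mg$gamma, t(mg$gamma))
  uni <- univariate_differentials(z, w)
  f2 <- lm(w ~ z[, "a"] + I(z[, "a"]^2))
  expect_equal(uni$c[1], 2 * coef(f2)[3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("beta equals s when the sample correlations are exactly zero", {
  set.seed(8)
  raw <- matrix(rnorm(50 * 3), 50, 3)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:4]   # exactly orthogonal, mean zero
  z <- scale(q)
  colnames(z) <- paste0("t", 1:3)
  w <- relative_fitness(rpois(50, 5) + 1)
  s <- univariate_differentials(z, w)$s
  b <- multivariate_gradients(z, w)$beta$beta
  expect_equal(b, s, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly with the collinear columns named", {
  z <- scale(matrix(rnorm(30), 30, 1))
  z <- cbind(z, z)
  colnames(z) <- c("t1", "t2")
  w <- rep(1, 30)
  expect_error(multivariate_gradients(z, w), "collinear")
})

test_that("quasi-Poisson tests estimate dispersion and scale SEs as sqrt(phi)", {
  set.seed(41)
  z <- scale(matrix(rnorm(2000 * 2), 2000, 2))
  colnames(z) <- c("t1", "t2")
  cnt1 <- simulate_fitness(z, c(0, 0), matrix(0, 2, 2), mean_offspring = 5,
                           dispersion = 1, seed = 1)
  p1 <- significance_glm(z, cnt1, "linear")
  expect_equal(attr(p1, "dispersion"), 1, tolerance = 0.1)
  cnt3 <- simulate_fitness(z, c(0, 0), matrix(0, 2, 2), mean_offspring = 5,
                           dispersion = 3, seed = 1)
  p3 <- significance_glm(z, cnt3, "linear")
  expect_equal(attr(p3, "dispersion"), 3, tolerance = 0.35)
  # quasi-likelihood scaling: SEs inflate by ~sqrt(3), estimates unbiased
  expect_equal(mean(p3$se / p1$se), sqrt(3), tolerance = 0.15)
  expect_lt(max(abs(p3$estimate)), 0.1)
  expect_error(significance_glm(z, cnt1 + 0.5), "integers")
})

test_that("quasi-Poisson p-values match the matching design and glm oracle", {
  set.seed(4)
  z <- scale(matrix(rnorm(120 * 2), 120, 2))
  colnames(z) <- c("t1", "t2")
  cnt <- rpois(120, exp(1 - 0.3 * z[, 1]))
  got <- significance_glm(z, cnt, "quadratic_full")
  X <- as.data.frame(spermsel:::quadratic_design(z))
  oracle <- summary(glm(cnt ~ ., data = X, family = quasipoisson()))
  expect_equal(got$p, unname(oracle$coefficients[-1, "Pr(>|t|)"]),
               tolerance = 1e-12)
})

test_that("variance inflation factors follow the closed form", {
  set.seed(19)
  # orthogonal design -> all VIF = 1
  q <- scale(qr.Q(qr(cbind(1, matrix(rnorm(200 * 4), 200, 4))))[, 2:5])
  colnames(q) <- paste0("t", 1:4)
  expect_equal(unname(variance_inflation(q, "linear")), rep(1, 4),
               tolerance = 1e-8)
  # two correlated columns: VIF = 1 / (1 - r^2)
  x1 <- rnorm(500)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(500)
  z <- scale(cbind(a = x1, b = x2))
  r <- cor(z)[1, 2]
  got <- variance_inflation(z, "linear")
  expect_equal(unname(got), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  skip_if_not_installed("car")
  w <- rnorm(500)
  oracle <- car::vif(lm(w ~ z[, 1] + z[, 2]))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-6)
})

test_that("partial correlations match the residualization oracle", {
  set.seed(23)
  n <- 150
  x3 <- rnorm(n)
  x1 <- 0.6 * x3 + rnorm(n)
  x2 <- -0.4 * x3 + rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  pc <- partial_correlations(X)
  oracle <- cor(resid(lm(x1 ~ x3)), resid(lm(x2 ~ x3)))
  expect_equal(pc$r["a", "b"], oracle, tolerance = 1e-10)
  expect_equal(pc$r, t(pc$r))
  expect_equal(pc$df, n - 3)
  # independent traits -> partial r near zero
  Y <- matrix(rnorm(n * 4), n, 4)
  colnames(Y) <- paste0("t", 1:4)
  pr <- partial_correlations(Y)$r
  expect_lt(max(abs(pr[upper.tri(pr)])), 3 / sqrt(n))
  expect_error(partial_correlations(X[1:5, ]), "8 complete cases")
})

test_that("the wrapped analysis returns a coherent set of estimates", {
  cfg <- sim_config(n_males = 120, seed = 3)
  st <- simulate_study(cfg)
  est <- selection_analysis(st$phenotypes, st$offspring_counts)
  expect_s3_class(est, "selection_estimates")
  expect_equal(est$n, 120)
  expect_equal(mean(est$w), 1, tolerance = 1e-12)
  expect_equal(est$gamma, t(est$gamma))
  expect_true(all(est$vif_linear >= 1))
  expect_equal(nrow(est$univariate), 6)
  expect_equal(nrow(est$p_linear), 6)
  expect_equal(nrow(est$p_quadratic_full), 6 + 6 + 15)
})

test_that("adding an irrelevant body-size covariate leaves sperm-count selection intact", {
  set.seed(7)
  cfg <- sim_config(n_males = 400, seed = 17)
  ph <- simulate_phenotypes(cfg)
  ph$svl <- rnorm(400, 60, 4)  # independent of fitness by construction
  z <- scale(as.matrix(ph[sperm_traits()]))
  cnt <- simulate_fitness(z, cfg$beta_true, cfg$gamma_true,
                          cfg$mean_offspring, cfg$dispersion, seed = 9)
  two <- svl_robustness(ph, cnt)
  expect_setequal(two$beta$trait, c("sperm_count", "svl"))
  svl_beta <- two$beta$beta[two$beta$trait == "svl"]
  expect_lt(abs(svl_beta), 3 * two$beta$beta_se[two$beta$trait == "svl"])
  # sperm-count estimate agrees with the svl-free univariate differential
  uni <- univariate_differentials(z[, "sperm_count", drop = FALSE],
                                  relative_fitness(cnt))
  cnt_beta <- two$beta$beta[two$beta$trait == "sperm_count"]
  expect_equal(cnt_beta, uni$s[1], tolerance = 3 * uni$s_se[1])
})
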