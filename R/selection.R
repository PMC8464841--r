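#' Standardize traits to mean 0, SD 1
#'
#' Variance-standardizes each trait column with the sample SD (n - 1
#' denominator). Rows with any missing trait are dropped (complete-case
#' analysis) and listed in the attached report.
#'
#' @param traits Data frame with `male_id` (optional) and trait columns.
#' @param trait_cols Character vector of columns to standardize (default:
#'   every non-id numeric column).
#' @return Data frame of standardized traits (plus `male_id` if present),
#'   with attributes `center`, `scale` and `dropped` (ids or row indices of
#'   incomplete rows).
#' @export
standardize <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))], "male_id")
  }
  stopifnot(length(trait_cols) >= 1, all(trait_cols %in% names(traits)))
  cc <- complete.cases(traits[trait_cols])
  if (sum(cc) < 2) stop("fewer than 2 complete cases")
  dropped <- if ("male_id" %in% names(traits)) traits$male_id[!cc]
             else which(!cc)
  x <- as.matrix(traits[cc, trait_cols, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    stop("zero-variance trait: ",
         paste(trait_cols[scl == 0], collapse = ", "))
  }
  z <- scale(x, center = ctr, scale = scl)
  out <- as.data.frame(z)
  if ("male_id" %in% names(traits)) {
    out <- cbind(male_id = traits$male_id[cc], out,
                 stringsAsFactors = FALSE)
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "dropped") <- dropped
  out
}

#' Relative fitness
#'
#' Each male's offspring count divided by the mean count across males, so
#' that mean relative fitness is exactly 1.
#'
#' @param offspring_counts Non-negative counts.
#' @return Numeric vector `w` with `mean(w) == 1`.
#' @export
relative_fitness <- function(offspring_counts) {
  if (any(offspring_counts < 0)) stop("counts must be non-negative")
  m <- mean(offspring_counts)
  if (m == 0) stop("all offspring counts are zero")
  offspring_counts / m
}

z_matrix <- function(z) {
  if (is.data.frame(z)) z <- z[setdiff(names(z), "male_id")]
  as.matrix(z)
}

#' Univariate selection differentials
#'
#' Per trait, the linear differential s is the slope of the OLS regression
#' of relative fitness on that standardized trait alone; the quadratic
#' differential c is twice the quadratic coefficient of the OLS regression
#' on the trait plus its square, with the standard error doubled likewise.
#'
#' @param z Standardized trait matrix or data frame.
#' @param w Relative fitness.
#' @return Data frame: trait, s, s_se, c, c_se.
#' @export
univariate_differentials <- function(z, w) {
  z <- z_matrix(z)
  if (nrow(z) <= 3) stop("too few observations (n <= 3)")
  stopifnot(length(w) == nrow(z))
  out <- lapply(colnames(z), function(tr) {
    zi <- z[, tr]
    f1 <- lm(w ~ zi)
    f2 <- lm(w ~ zi + I(zi^2))
    s1 <- summary(f1)$coefficients
    s2 <- summary(f2)$coefficients
    data.frame(trait = tr,
               s = s1["zi", "Estimate"], s_se = s1["zi", "Std. Error"],
               c = 2 * s2["I(zi^2)", "Estimate"],
               c_se = 2 * s2["I(zi^2)", "Std. Error"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Design matrix of the full second-order model: all linear terms, all
# squares (named <trait>.sq) and all pairwise cross-products (<a>.x.<b>).
quadratic_design <- function(z) {
  z <- z_matrix(z)
  tr <- colnames(z)
  X <- z
  for (j in seq_along(tr)) {
    q <- z[, j]^2
    X <- cbind(X, q)
    colnames(X)[ncol(X)] <- paste0(tr[j], ".sq")
  }
  if (length(tr) > 1) {
    for (i in seq_len(length(tr) - 1)) for (j in (i + 1):length(tr)) {
      X <- cbind(X, z[, i] * z[, j])
      colnames(X)[ncol(X)] <- paste0(tr[i], ".x.", tr[j])
    }
  }
  X
}

#' Multivariate selection gradients
#'
#' Linear gradients beta are the coefficients of the OLS multiple
#' regression of relative fitness on all standardized traits. Quadratic and
#' correlational gradients come from the full second-order OLS fit (all
#' linear, squared and pairwise cross-product terms): diagonal gamma_ii is
#' twice the squared-term coefficient (SE doubled), off-diagonal gamma_ij
#' is the cross-product coefficient, not doubled. The gamma matrix is
#' returned symmetric.
#'
#' @param z Standardized trait matrix or data frame.
#' @param w Relative fitness.
#' @return List: `beta` (data frame trait/beta/beta_se), `gamma` and
#'   `gamma_se` (symmetric matrices), plus the underlying `fit_linear` and
#'   `fit_quadratic` lm objects.
#' @export
multivariate_gradients <- function(z, w) {
  z <- z_matrix(z)
  tr <- colnames(z)
  stopifnot(length(w) == nrow(z))
  Xl <- as.data.frame(z)
  fit_l <- lm(w ~ ., data = Xl)
  if (fit_l$rank < ncol(z) + 1) {
    stop("rank-deficient linear design; collinear columns: ",
         paste(tr[is.na(coef(fit_l)[-1])], collapse = ", "))
  }
  Xq <- as.data.frame(quadratic_design(z))
  fit_q <- lm(w ~ ., data = Xq)
  if (fit_q$rank < ncol(Xq) + 1) {
    bad <- names(coef(fit_q))[is.na(coef(fit_q))]
    stop("rank-deficient quadratic design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sl <- summary(fit_l)$coefficients
  sq <- summary(fit_q)$coefficients
  beta <- data.frame(trait = tr, beta = sl[tr, "Estimate"],
                     beta_se = sl[tr, "Std. Error"],
                     stringsAsFactors = FALSE, row.names = NULL)
  k <- length(tr)
  gamma <- gamma_se <- matrix(NA_real_, k, k, dimnames = list(tr, tr))
  for (j in seq_len(k)) {
    nm <- paste0(tr[j], ".sq")
    gamma[j, j] <- 2 * sq[nm, "Estimate"]
    gamma_se[j, j] <- 2 * sq[nm, "Std. Error"]
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      nm <- paste0(tr[i], ".x.", tr[j])
      gamma[i, j] <- gamma[j, i] <- sq[nm, "Estimate"]
      gamma_se[i, j] <- gamma_se[j, i] <- sq[nm, "Std. Error"]
    }
  }
  list(beta = beta, gamma = gamma, gamma_se = gamma_se,
       fit_linear = fit_l, fit_quadratic = fit_q)
}

#' Quasi-Poisson significance tests for selection terms
#'
#' Because relative fitness is typically highly skewed, significance is
#' assessed on the raw offspring counts with a log-link Poisson fit whose
#' dispersion is estimated by the Pearson chi-square over residual degrees
#' of freedom (the quasi-Poisson model). Estimates still come from the OLS
#' models; this function supplies the per-term p-values for the matching
#' design.
#'
#' @param z Standardized trait matrix or data frame.
#' @param offspring_counts Integer counts (the GLM response).
#' @param model `"linear"` (all traits), `"quadratic"` (per-trait linear +
#'   square, univariate designs) or `"quadratic_full"` (all linear, squared
#'   and cross-product terms).
#' @return Data frame: term, estimate (GLM scale), se, t, p; attribute
#'   `dispersion`.
#' @export
significance_glm <- function(z, offspring_counts,
                             model = c("linear", "quadratic",
                                       "quadratic_full")) {
  model <- match.arg(model)
  z <- z_matrix(z)
  if (any(offspring_counts != round(offspring_counts)) ||
      any(offspring_counts < 0)) {
    stop("offspring counts must be non-negative integers")
  }
  stopifnot(length(offspring_counts) == nrow(z))
  if (model == "quadratic") {
    out <- lapply(colnames(z), function(tr) {
      zi <- z[, tr]
      fit <- glm(offspring_counts ~ zi + I(zi^2),
                 family = quasipoisson())
      sm <- summary(fit)$coefficients
      data.frame(term = c(tr, paste0(tr, ".sq")),
                 estimate = sm[2:3, "Estimate"], se = sm[2:3, "Std. Error"],
                 t = sm[2:3, "t value"], p = sm[2:3, "Pr(>|t|)"],
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    return(do.call(rbind, out))
  }
  X <- if (model == "linear") z else quadratic_design(z)
  dat <- data.frame(..y = offspring_counts, as.data.frame(X),
                    check.names = FALSE)
  fit <- glm(..y ~ ., data = dat, family = quasipoisson())
  if (!fit$converged) warning("quasi-Poisson fit did not converge")
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], t = co[, "t value"],
                    p = co[, "Pr(>|t|)"], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dispersion") <- sm$dispersion
  out
}

#' Variance inflation factors
#'
#' VIF for each term of the linear or full second-order design:
#' 1 / (1 - R^2) from the regression of that column on all the others
#' (computed via inversion of the design correlation matrix). Perfectly
#' collinear columns get an infinite VIF.
#'
#' @param z Standardized trait matrix or data frame.
#' @param model `"linear"` or `"quadratic_full"`.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
variance_inflation <- function(z, model = c("linear", "quadratic_full")) {
  model <- match.arg(model)
  z <- z_matrix(z)
  X <- if (model == "linear") z else quadratic_design(z)
  R <- cor(X)
  vif <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(vif) || any(vif < 0)) {
    # near-singular: fall back to column-wise R^2
    vif <- vapply(seq_len(ncol(X)), function(k) {
      r2 <- summary(lm(X[, k] ~ X[, -k]))$r.squared
      if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  setNames(pmax(vif, 1), colnames(X))
}

#' Pairwise partial correlations among traits
#'
#' Partial correlation of each trait pair controlling for all remaining
#' traits, via inversion of the trait correlation matrix
#' (r_ij = -P_ij / sqrt(P_ii P_jj)). Two-sided p-values use the
#' t-transform with n - 2 - (k - 2) = n - k degrees of freedom, where k is
#' the number of traits.
#'
#' @param traits Trait matrix or data frame (need not be standardized; at
#'   least 8 complete cases).
#' @return List: `r` (partial correlation matrix), `p` (p-value matrix),
#'   `df`.
#' @export
partial_correlations <- function(traits) {
  x <- z_matrix(traits)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 8) stop("need at least 8 complete cases")
  R <- cor(x)
  P <- tryCatch(solve(R), error = function(e)
    stop("singular trait correlation matrix"))
  d <- sqrt(diag(P))
  pr <- -P / outer(d, d)
  diag(pr) <- 1
  df <- n - k
  tstat <- pr * sqrt(df / pmax(1 - pr^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  diag(p) <- NA
  list(r = pr, p = p, df = df)
}

#' Full selection analysis on a trait table
#'
#' Convenience wrapper running the complete Lande-Arnold analysis:
#' standardization, relative fitness, univariate differentials,
#' multivariate gradients, quasi-Poisson significance for every term, VIFs
#' for both designs and partial trait correlations.
#'
#' @param traits Data frame with `male_id` and trait columns.
#' @param offspring_counts Integer counts aligned with `traits` rows.
#' @param trait_cols Trait columns (default [sperm_traits()] intersected
#'   with the table).
#' @return List of class `selection_estimates` with elements `n`, `z`, `w`,
#'   `univariate`, `beta`, `gamma`, `gamma_se`, `p_linear`, `p_univariate`,
#'   `p_quadratic_full`, `vif_linear`, `vif_nonlinear`, `partial`,
#'   `dropped`.
#' @export
selection_analysis <- function(traits, offspring_counts,
                               trait_cols = intersect(sperm_traits(),
                                                      names(traits))) {
  stopifnot(length(offspring_counts) == nrow(traits))
  traits$..counts <- offspring_counts
  zs <- standardize(traits, trait_cols)
  kept <- if ("male_id" %in% names(traits)) {
    traits$male_id %in% zs$male_id
  } else complete.cases(traits[trait_cols])
  counts <- traits$..counts[kept]
  z <- z_matrix(zs[trait_cols])
  w <- relative_fitness(counts)
  out <- list(
    n = nrow(z), z = z, w = w, counts = counts,
    univariate = univariate_differentials(z, w),
    multivariate = multivariate_gradients(z, w),
    p_linear = significance_glm(z, counts, "linear"),
    p_univariate = significance_glm(z, counts, "quadratic"),
    p_quadratic_full = significance_glm(z, counts, "quadratic_full"),
    vif_linear = variance_inflation(z, "linear"),
    vif_nonlinear = variance_inflation(z, "quadratic_full"),
    partial = partial_correlations(z),
    dropped = attr(zs, "dropped"))
  out$beta <- out$multivariate$beta
  out$gamma <- out$multivariate$gamma
  out$gamma_se <- out$multivariate$gamma_se
  class(out) <- "selection_estimates"
  out
}

#' @export
print.selection_estimates <- function(x, ...) {
  cat(sprintf("Selection analysis on %d males, %d traits\n", x$n,
              ncol(x$z)))
  tab <- merge(x$univariate, x$beta, by = "trait", sort = FALSE)
  print(tab, digits = 3)
  cat("\ngamma (quadratic on diagonal, correlational above):\n")
  print(round(x$gamma, 3))
  invisible(x)
}

#' Body-size robustness analysis
#'
#' Re-runs the univariate and multivariate selection analysis on the
#' two-trait design (sperm count, snout-vent length) to check that
#' selection on sperm count is not an artefact of body size.
#'
#' @param traits Data frame with `sperm_count` and `svl` columns (plus
#'   optional `male_id`).
#' @param offspring_counts Integer counts aligned with `traits`.
#' @return A `selection_estimates` list for the two-trait design.
#' @export
svl_robustness <- function(traits, offspring_counts) {
  stopifnot(all(c("sperm_count", "svl") %in% names(traits)))
  keep <- intersect(c("male_id", "sperm_count", "svl"), names(traits))
  selection_analysis(traits[keep], offspring_counts,
                     trait_cols = c("sperm_count", "svl"))
}
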