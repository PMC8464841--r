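#' Fit a penalized cubic regression spline with GCV-optimal smoothing
#'
#' Builds a B-spline basis of dimension `k` on equally spaced knots
#' (cubic for `k >= 4`; `k = 3` falls back to a quadratic basis), penalizes
#' second differences of the coefficients, and chooses the smoothing
#' intensity lambda minimizing the generalized cross-validation score
#' `GCV(lambda) = n * RSS / (n - tr(H))^2` by golden-section search on
#' log10(lambda). At large lambda the fit degenerates to the ordinary
#' least-squares straight line; at lambda near 0 it approaches the
#' unpenalized regression spline.
#'
#' @param x Predictor (e.g. standardized sperm count).
#' @param w Response (relative fitness).
#' @param k Basis dimension (3 <= k < n).
#' @param lambda Optional fixed smoothing parameter; when `NULL` (default)
#'   lambda is selected by GCV.
#' @param lambda_range log10(lambda) search interval.
#' @return Object of class `pspline_fit`: coefficients, knots, `lambda`,
#'   `gcv`, `edf` (trace of the hat matrix), `sigma2`, and what
#'   [predict.pspline_fit()] needs for pointwise standard errors.
#' @export
fit_penalized_spline <- function(x, w, k, lambda = NULL,
                                 lambda_range = c(-8, 8)) {
  stopifnot(is.numeric(x), is.numeric(w), length(x) == length(w))
  if (any(!is.finite(x)) || any(!is.finite(w))) {
    stop("non-finite inputs")
  }
  n <- length(x)
  if (k < 3) stop("basis dimension k must be >= 3")
  if (k >= n) stop("basis dimension k must be smaller than n")
  degree <- if (k >= 4) 3L else 2L
  knots <- pspline_knots(range(x), k, degree)
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  D <- diff(diag(k), differences = 2)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Btw <- crossprod(B, w)

  gcv_of <- function(log10_lambda) {
    lam <- 10^log10_lambda
    A <- BtB + lam * P
    cf <- tryCatch(solve(A, Btw), error = function(e) NULL)
    if (is.null(cf)) return(list(gcv = Inf))
    fitv <- drop(B %*% cf)
    rss <- sum((w - fitv)^2)
    edf <- sum(diag(solve(A, BtB)))
    list(gcv = n * rss / (n - edf)^2, coef = drop(cf), edf = edf,
         rss = rss, lambda = lam)
  }

  if (is.null(lambda)) {
    opt_log <- golden_section(function(l) gcv_of(l)$gcv,
                              lambda_range[1], lambda_range[2],
                              tol = 1e-6)
    sol <- gcv_of(opt_log)
  } else {
    sol <- gcv_of(log10(lambda))
  }
  structure(list(coef = sol$coef, knots = knots, degree = degree, k = k,
                 lambda = sol$lambda, gcv = sol$gcv, edf = sol$edf,
                 sigma2 = sol$rss / (n - sol$edf),
                 BtB = BtB, P = P, n = n, x_range = range(x)),
            class = "pspline_fit")
}

# Equally spaced knot sequence giving exactly k B-spline basis functions of
# the given degree over [a, b] (with the usual degree extra knots on each
# side).
pspline_knots <- function(xr, k, degree) {
  nseg <- k - degree
  stopifnot(nseg >= 1)
  pad <- 1e-8 * max(1, diff(xr))
  a <- xr[1] - pad; b <- xr[2] + pad
  h <- (b - a) / nseg
  seq(a - degree * h, b + degree * h, by = h)
}

# Plain golden-section minimization on [lo, hi].
golden_section <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Predict from a penalized spline fit
#'
#' @param object A `pspline_fit`.
#' @param newdata Numeric vector of predictor values (clamped to the fitted
#'   range).
#' @param se.fit If `TRUE`, also return pointwise standard errors from the
#'   penalized-fit covariance `(B'B + lambda P)^-1 B'B (B'B + lambda P)^-1
#'   sigma^2`.
#' @param ... Unused.
#' @return Vector of fitted values, or a list `fit`/`se.fit`.
#' @export
predict.pspline_fit <- function(object, newdata, se.fit = FALSE, ...) {
  x <- pmin(pmax(newdata, object$x_range[1]), object$x_range[2])
  B <- splines::splineDesign(object$knots, x, ord = object$degree + 1L)
  fit <- drop(B %*% object$coef)
  if (!se.fit) return(fit)
  A <- object$BtB + object$lambda * object$P
  V <- solve(A, object$BtB) %*% solve(A) * object$sigma2
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  list(fit = fit, se.fit = se)
}

#' Select the spline basis dimension by GCV
#'
#' Fits [fit_penalized_spline()] for every candidate basis dimension K and
#' keeps the K with the smallest GCV score (ties go to the smaller K).
#' Also assembles the fitness-surface outputs: a prediction grid with a
#' pointwise 95% band and the equal-size binned means.
#'
#' @param x Standardized sperm count (or any single predictor).
#' @param w Relative fitness.
#' @param k_candidates Candidate basis dimensions (default 3:10).
#' @param n_grid Grid size for predictions.
#' @param n_bins Number of bins for [binned_means()].
#' @return Object of class `surface_fit`: `k_candidates`, `gcv_scores`,
#'   `k_best`, `fit`, `grid`, `predicted_w`, `ci_lower`, `ci_upper`,
#'   `binned`.
#' @export
select_k <- function(x, w, k_candidates = 3:10, n_grid = 200,
                     n_bins = 10) {
  if (length(k_candidates) == 0) stop("empty candidate list")
  fits <- lapply(k_candidates, function(k)
    fit_penalized_spline(x, w, k))
  gcv <- vapply(fits, `[[`, numeric(1), "gcv")
  best <- which(gcv <= min(gcv) + 0)[1]  # ties -> smaller K (list order)
  fit <- fits[[best]]
  grid <- seq(min(x), max(x), length.out = n_grid)
  pr <- predict(fit, grid, se.fit = TRUE)
  structure(list(k_candidates = k_candidates, gcv_scores = gcv,
                 k_best = k_candidates[best], fit = fit, grid = grid,
                 predicted_w = pr$fit,
                 ci_lower = pr$fit - 1.96 * pr$se.fit,
                 ci_upper = pr$fit + 1.96 * pr$se.fit,
                 binned = binned_means(x, w, n_bins)),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit: K = %d chosen by GCV from {%s}, edf = %.2f>\n",
              x$k_best, paste(x$k_candidates, collapse = ","),
              x$fit$edf))
  invisible(x)
}

#' Rank-based binned means of fitness
#'
#' Partitions the sample into `n_bins` rank-based bins of near-equal size
#' (sizes differing by at most one before tie handling; tied predictor
#' values are kept together in the lower bin) and reports the mean
#' predictor, mean response, its standard error and the bin size.
#'
#' @param x Predictor.
#' @param w Response.
#' @param n_bins Number of bins (default 10; requires `n >= n_bins`).
#' @return Data frame: bin, mean_z, mean_w, se_w, n.
#' @export
binned_means <- function(x, w, n_bins = 10) {
  n <- length(x)
  stopifnot(length(w) == n)
  if (n < n_bins) stop("fewer observations than bins")
  ord <- order(x)
  cuts <- floor(seq(0, n, length.out = n_bins + 1))
  bin <- rep(seq_len(n_bins), times = diff(cuts))[order(ord)]
  # keep tied x values together, in the lower of the bins they straddle
  bin <- stats::ave(bin, x, FUN = min)
  agg <- lapply(sort(unique(bin)), function(b) {
    wi <- w[bin == b]
    data.frame(bin = b, mean_z = mean(x[bin == b]), mean_w = mean(wi),
               se_w = if (length(wi) > 1) sd(wi) / sqrt(length(wi)) else 0,
               n = length(wi))
  })
  do.call(rbind, agg)
}

#' Plot the fitness surface
#'
#' Two panels in the style of a selection-surface figure: (A) individual
#' males as points with the fitted spline and its 95% band; (B) the binned
#' means with standard-error bars over the same curve.
#'
#' @param surface A [select_k()] result.
#' @param x,w The data used for the fit (points in panel A).
#' @return A list of two ggplot objects, `points` and `binned`.
#' @export
plot_fitness_surface <- function(surface, x, w) {
  stopifnot(inherits(surface, "surface_fit"))
  curve_df <- data.frame(z = surface$grid, fit = surface$predicted_w,
                         lo = surface$ci_lower, hi = surface$ci_upper)
  base <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "Standardized sperm count",
                  y = "Relative fitness") +
    ggplot2::theme_classic()
  pts <- base +
    ggplot2::geom_point(data = data.frame(z = x, w = w),
                        ggplot2::aes(y = .data$w), alpha = 0.5)
  bn <- base +
    ggplot2::geom_pointrange(
      data = surface$binned,
      ggplot2::aes(x = .data$mean_z, y = .data$mean_w,
                   ymin = .data$mean_w - .data$se_w,
                   ymax = .data$mean_w + .data$se_w))
  list(points = pts, binned = bn)
}
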