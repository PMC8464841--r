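#' Canonical ejaculate trait names
#'
#' The six sperm traits analysed throughout the package, in their fixed
#' order: total sperm count, average path velocity (VAPi, um/s), linearity
#' (percent), and the lengths (um) of the sperm head, midpiece and flagellum.
#'
#' @return Character vector of length 6.
#' @export
sperm_traits <- function() {
  c("sperm_count", "velocity", "linearity",
    "head_length", "midpiece_length", "flagellum_length")
}

#' Phenotypic correlation structure of the wild study population
#'
#' The pairwise phenotypic correlation matrix among the six ejaculate traits
#' measured in the wild brown anole population (e.g. velocity-linearity
#' r = 0.638, count-midpiece r = -0.249). Used as the default generative
#' correlation structure for synthetic phenotypes.
#'
#' @return A symmetric positive-definite 6 x 6 correlation matrix with
#'   dimnames [sperm_traits()].
#' @export
anole_trait_correlation <- function() {
  tr <- sperm_traits()
  R <- diag(6)
  dimnames(R) <- list(tr, tr)
  up <- rbind(
    c(1, 2,  0.241), c(1, 3, 0.041), c(1, 4, 0.120), c(1, 5, -0.249),
    c(1, 6,  0.039),
    c(2, 3,  0.638), c(2, 4, 0.123), c(2, 5, -0.130), c(2, 6, 0.135),
    c(3, 4,  0.121), c(3, 5, -0.118), c(3, 6, 0.101),
    c(4, 5, -0.287), c(4, 6, 0.174),
    c(5, 6, -0.231))
  for (k in seq_len(nrow(up))) {
    R[up[k, 1], up[k, 2]] <- R[up[k, 2], up[k, 1]] <- up[k, 3]
  }
  R
}

#' Configuration for the synthetic-population generator
#'
#' Bundles every generative parameter of the synthetic study: the trait
#' distribution, the true selection surface acting on standardized traits
#' (log link), the mating/offspring regime, and the SNP panel properties.
#' Defaults reproduce the study conditions: 171 phenotyped males, a 215-SNP
#' panel with a 0.5% per-allele genotyping error rate, the population's
#' trait correlation structure, and negative linear (-0.17) plus negative
#' quadratic (-0.16) selection on sperm count only.
#'
#' @param n_males,n_females Number of adult males / females.
#' @param n_loci Number of biallelic SNP loci in the panel.
#' @param trait_means,trait_sds Length-6 vectors of trait means and SDs on
#'   the raw measurement scale (count in cells, velocity in um/s, linearity
#'   in percent, lengths in um).
#' @param trait_correlation 6 x 6 symmetric positive-definite correlation
#'   matrix with unit diagonal.
#' @param beta_true Length-6 vector of generative linear selection gradients
#'   on the standardized scale.
#' @param gamma_true 6 x 6 symmetric matrix of generative quadratic
#'   (diagonal) and correlational (off-diagonal) gradients.
#' @param mean_offspring Expected offspring per male at the trait mean.
#' @param dispersion Variance-to-mean ratio of offspring counts (>= 1;
#'   1 = Poisson).
#' @param allele_freq_range Interval in (0, 1) from which per-locus
#'   alternate-allele frequencies are drawn.
#' @param per_allele_error Probability that a single allele is misread.
#' @param missing_rate Probability that a genotype call is missing.
#' @param mate_mean,mate_size Mean and negative-binomial size of the
#'   dams-per-sire distribution (defaults reproduce the observed mean of
#'   3.85 mates with a maximum near 16 in a population of ~300 males).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_males = 171, n_females = 465, n_loci = 215,
                       trait_means = c(1.5e6, 45, 75, 12, 4, 70),
                       trait_sds = c(6e5, 10, 10, 0.8, 0.5, 4),
                       trait_correlation = anole_trait_correlation(),
                       beta_true = c(-0.17, 0, 0, 0, 0, 0),
                       gamma_true = {
                         g <- matrix(0, 6, 6); g[1, 1] <- -0.16; g
                       },
                       mean_offspring = 3.86, dispersion = 3,
                       allele_freq_range = c(0.2, 0.8),
                       per_allele_error = 0.005, missing_rate = 0.1,
                       mate_mean = 3.85, mate_size = 2,
                       seed = 1L) {
  stopifnot(is_count(n_males), n_males > 0, is_count(n_females),
            n_females > 0, is_count(n_loci), n_loci > 0,
            length(trait_means) == 6, length(trait_sds) == 6,
            all(trait_sds > 0),
            is.matrix(trait_correlation),
            all(dim(trait_correlation) == c(6, 6)))
  if (max(abs(trait_correlation - t(trait_correlation))) > 1e-8 ||
      max(abs(diag(trait_correlation) - 1)) > 1e-8) {
    stop("trait_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(trait_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("trait_correlation is not positive definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  stopifnot(length(beta_true) == 6, is.matrix(gamma_true),
            all(dim(gamma_true) == c(6, 6)))
  if (max(abs(gamma_true - t(gamma_true))) > 1e-8) {
    stop("gamma_true must be symmetric")
  }
  if (dispersion < 1) stop("dispersion must be >= 1")
  stopifnot(length(allele_freq_range) == 2,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            allele_freq_range[1] <= allele_freq_range[2],
            per_allele_error >= 0, per_allele_error <= 1,
            missing_rate >= 0, missing_rate <= 1,
            mean_offspring > 0, mate_mean > 0, mate_size > 0)
  cfg <- list(n_males = as.integer(n_males),
              n_females = as.integer(n_females),
              n_loci = as.integer(n_loci),
              trait_means = as.numeric(trait_means),
              trait_sds = as.numeric(trait_sds),
              trait_correlation = trait_correlation,
              beta_true = as.numeric(beta_true),
              gamma_true = gamma_true,
              mean_offspring = mean_offspring,
              dispersion = dispersion,
              allele_freq_range = as.numeric(allele_freq_range),
              per_allele_error = per_allele_error,
              missing_rate = missing_rate,
              mate_mean = mate_mean, mate_size = mate_size,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate per-male ejaculate phenotypes
#'
#' Draws the six sperm traits from a multivariate normal with the configured
#' correlation structure, then shifts/scales each trait to its configured
#' mean and SD. Sperm counts are floored at zero (a count cannot be
#' negative).
#'
#' @param config A [sim_config()].
#' @return A data frame with `male_id` and one column per trait in
#'   [sperm_traits()] order.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "phenotypes"), {
    n <- config$n_males
    L <- chol(config$trait_correlation)
    z <- matrix(rnorm(n * 6), n, 6) %*% L
    x <- sweep(sweep(z, 2, config$trait_sds, `*`), 2, config$trait_means, `+`)
    colnames(x) <- sperm_traits()
    x[, "sperm_count"] <- pmax(x[, "sperm_count"], 0)
    data.frame(male_id = sprintf("M%04d", seq_len(n)), x,
               stringsAsFactors = FALSE)
  })
}

#' Simulate offspring counts under a log-link selection surface
#'
#' Offspring counts are drawn with
#' `log(mean) = log(mean_offspring) + beta' z + z' gamma z / 2` and variance
#' `dispersion * mean`: Poisson when `dispersion = 1`, negative binomial
#' (size = mean / (dispersion - 1)) when `dispersion > 1`.
#'
#' @param z Column-standardized trait matrix (n x 6).
#' @param beta_true,gamma_true Generative gradients as in [sim_config()].
#' @param mean_offspring Expected offspring at z = 0.
#' @param dispersion Variance-to-mean ratio, >= 1.
#' @param seed Integer seed.
#' @return Integer vector of offspring counts, one per row of `z`.
#' @export
simulate_fitness <- function(z, beta_true, gamma_true,
                             mean_offspring = 3.86, dispersion = 3,
                             seed = 1L) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(beta_true),
            all(dim(gamma_true) == ncol(z)))
  if (dispersion < 1) stop("dispersion must be >= 1")
  with_seed(seed, {
    lmu <- log(mean_offspring) + drop(z %*% beta_true) +
      0.5 * rowSums((z %*% gamma_true) * z)
    mu <- exp(lmu)
    if (dispersion == 1) {
      rpois(nrow(z), mu)
    } else {
      rnbinom(nrow(z), mu = mu, size = mu / (dispersion - 1))
    }
  })
}

# Per-allele misread: transition matrix P(observed genotype | true genotype)
# for a symmetric allele flip at rate e, applied independently to the two
# alleles. Rows = true genotype 0/1/2, columns = observed.
genotype_error_matrix <- function(e) {
  rbind(c((1 - e)^2, 2 * e * (1 - e), e^2),
        c(e * (1 - e), (1 - e)^2 + e^2, e * (1 - e)),
        c(e^2, 2 * e * (1 - e), (1 - e)^2))
}

# Apply the per-allele error model and missingness to a true genotype
# matrix (individuals x loci, codes 0/1/2).
observe_genotypes <- function(g, per_allele_error, missing_rate) {
  n <- length(g)
  if (per_allele_error > 0) {
    E <- genotype_error_matrix(per_allele_error)
    u <- runif(n)
    cum1 <- E[g + 1L, 1L]
    cum2 <- cum1 + E[g + 1L, 2L]
    obs <- ifelse(u < cum1, 0L, ifelse(u < cum2, 1L, 2L))
  } else obs <- g
  if (missing_rate > 0) obs[runif(n) < missing_rate] <- NA_integer_
  out <- matrix(as.integer(obs), nrow(g), ncol(g), dimnames = dimnames(g))
  out
}

#' Simulate a pedigree and SNP genotypes for parentage analysis
#'
#' Given per-male offspring counts, draws dams for each sire so that
#' dams-per-sire follow a negative-binomial mating regime, simulates
#' parental genotypes under Hardy-Weinberg equilibrium at per-locus allele
#' frequencies, forms each offspring genotype by Mendelian transmission from
#' its true dam and sire, and finally applies per-allele genotyping errors
#' and missingness.
#'
#' @param config A [sim_config()].
#' @param offspring_counts Integer vector of offspring per male (length
#'   `n_males`), e.g. from [simulate_fitness()].
#' @return A list with `adults` and `offspring` (both [genotype_panel()]
#'   objects), `pedigree` (data frame: offspring_id, dam_id, sire_id) and
#'   `allele_freqs` (the true per-locus frequencies).
#' @export
simulate_pedigree_and_genotypes <- function(config, offspring_counts) {
  stopifnot(inherits(config, "sim_config"),
            length(offspring_counts) == config$n_males,
            all(offspring_counts >= 0))
  if (config$n_loci <= 0) stop("n_loci must be positive")
  with_seed(derive_seed(config$seed, "genotypes"), {
    nm <- config$n_males; nf <- config$n_females; L <- config$n_loci
    male_ids <- sprintf("M%04d", seq_len(nm))
    female_ids <- sprintf("F%04d", seq_len(nf))
    p <- runif(L, config$allele_freq_range[1], config$allele_freq_range[2])
    loci <- sprintf("L%03d", seq_len(L))

    draw_hw <- function(ids) {
      g <- matrix(rbinom(length(ids) * L, 2, rep(p, each = length(ids))),
                  length(ids), L, dimnames = list(ids, loci))
      g
    }
    g_m <- draw_hw(male_ids)
    g_f <- draw_hw(female_ids)

    # Mating: each sire with k offspring mates m dams, m ~ NB(mate_mean,
    # mate_size) truncated to [1, k]; offspring are spread over those dams.
    ped <- NULL
    off_rows <- sum(offspring_counts)
    if (off_rows > 0) {
      dam_of <- character(off_rows)
      sire_of <- character(off_rows)
      pos <- 0L
      for (i in seq_len(nm)) {
        k <- offspring_counts[i]
        if (k == 0) next
        m <- rnbinom(1, mu = config$mate_mean, size = config$mate_size)
        m <- max(1L, min(as.integer(m), k, nf))
        dams <- sample(female_ids, m)
        dam_assign <- dams[sample.int(m, k, replace = TRUE)]
        dam_of[pos + seq_len(k)] <- dam_assign
        sire_of[pos + seq_len(k)] <- male_ids[i]
        pos <- pos + k
      }
      ped <- data.frame(offspring_id = sprintf("O%05d", seq_len(off_rows)),
                        dam_id = dam_of, sire_id = sire_of,
                        stringsAsFactors = FALSE)
    } else {
      ped <- data.frame(offspring_id = character(), dam_id = character(),
                        sire_id = character(), stringsAsFactors = FALSE)
    }

    # Mendelian transmission: each parent passes one allele; for a
    # heterozygote the transmitted allele is a fair coin.
    transmit <- function(gp) {
      n <- length(gp)
      (gp == 2L) + (gp == 1L) * rbinom(n, 1, 0.5)
    }
    g_o <- matrix(0L, nrow(ped), L,
                  dimnames = list(ped$offspring_id, loci))
    if (nrow(ped) > 0) {
      gd <- g_f[ped$dam_id, , drop = FALSE]
      gs <- g_m[ped$sire_id, , drop = FALSE]
      g_o[] <- transmit(gd) + transmit(gs)
    }

    adults <- genotype_panel(
      rbind(observe_genotypes(g_m, config$per_allele_error,
                              config$missing_rate),
            observe_genotypes(g_f, config$per_allele_error,
                              config$missing_rate)),
      stage = c(rep("adult_male", nm), rep("adult_female", nf)))
    offspring <- genotype_panel(
      observe_genotypes(g_o, config$per_allele_error, config$missing_rate),
      stage = rep("offspring", nrow(g_o)))
    list(adults = adults, offspring = offspring, pedigree = ped,
         allele_freqs = setNames(p, loci))
  })
}

#' Simulate a sperm-cell track as a correlated random walk
#'
#' Generates a 2-D path with fixed step length `true_velocity / fps` and
#' von-Mises turning angles whose concentration is calibrated so that the
#' expected linearity (net displacement over path length) approximates
#' `true_linearity`. Optional Gaussian positional jitter of scale `noise_sd`
#' emulates tracking error.
#'
#' @param true_velocity Path velocity in um/s.
#' @param true_linearity Target linearity in percent (0-100]; 100 gives an
#'   exactly straight path.
#' @param fps Frame rate (frames/s), supported range 5-30.
#' @param duration_s Track duration in seconds (>= 45/fps).
#' @param noise_sd SD of additive coordinate jitter, um.
#' @param um_per_px Spatial calibration; coordinates are stored in pixels.
#' @param seed Integer seed.
#' @param cell_id Identifier stored on the track.
#' @return A [cell_track()] object.
#' @export
simulate_tracks <- function(true_velocity, true_linearity, fps = 25,
                            duration_s = 2.2, noise_sd = 0, um_per_px = 1,
                            seed = 1L, cell_id = "cell1") {
  if (fps <= 0 || duration_s <= 0) stop("fps and duration must be positive")
  if (fps < 5 || fps > 30) stop("fps outside the supported 5-30 range")
  n_steps <- max(2L, round(fps * duration_s))
  if (n_steps + 1 < 45) stop("duration too short: fewer than 45 frames")
  stopifnot(true_velocity > 0, true_linearity > 0, true_linearity <= 100)
  l <- true_velocity / fps  # um per frame
  with_seed(seed, {
    if (true_linearity >= 99.95) {
      ang <- rep(0, n_steps - 1)
    } else {
      rho <- crw_rho_for_linearity(true_linearity / 100, n_steps)
      kappa <- uniroot(function(k) vm_mean_resultant(k) - rho,
                       c(1e-8, 5e5), tol = 1e-10)$root
      ang <- rvonmises(n_steps - 1, kappa)
    }
    heading <- cumsum(c(runif(1, -pi, pi), ang))
    x <- c(0, cumsum(l * cos(heading)))
    y <- c(0, cumsum(l * sin(heading)))
    if (noise_sd > 0) {
      x <- x + rnorm(length(x), 0, noise_sd)
      y <- y + rnorm(length(y), 0, noise_sd)
    }
    cell_track(x / um_per_px, y / um_per_px, fps = fps,
               um_per_px = um_per_px, cell_id = cell_id)
  })
}

# Invert the Kareiva-Shigesada mean-squared-displacement formula for a
# correlated random walk: find the turning-angle mean resultant length rho
# such that sqrt(E[R^2]) / (N l) matches the target straightness.
crw_rho_for_linearity <- function(target, n_steps) {
  stopifnot(target > 0, target < 1)
  straightness <- function(rho) {
    if (rho >= 1) return(1)
    er2 <- n_steps * (1 + rho) / (1 - rho) -
      2 * rho * (1 - rho^n_steps) / (1 - rho)^2
    sqrt(max(er2, 0)) / n_steps
  }
  lo <- straightness(1e-9)
  hi <- 1 - 1e-4  # the MSD formula cancels catastrophically nearer 1
  if (target <= lo) return(1e-9)
  if (target >= straightness(hi)) return(hi)
  uniroot(function(r) straightness(r) - target,
          c(1e-9, hi), tol = 1e-10)$root
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: phenotypes, offspring counts under the
#' configured selection surface, pedigree + genotypes, and (optionally)
#' per-male cell tracks matching each male's generative velocity and
#' linearity.
#'
#' @param config A [sim_config()].
#' @param tracks If `TRUE`, simulate `cells_per_male` tracks per male.
#' @param cells_per_male Number of tracks per male.
#' @return A list: `config`, `phenotypes`, `z` (standardized generative
#'   traits), `offspring_counts`, `adults`, `offspring`, `pedigree`,
#'   `allele_freqs`, and `tracks` (named list of track lists, or NULL).
#' @export
simulate_study <- function(config = sim_config(), tracks = FALSE,
                           cells_per_male = 15) {
  ph <- simulate_phenotypes(config)
  z <- scale(as.matrix(ph[sperm_traits()]))
  counts <- simulate_fitness(z, config$beta_true, config$gamma_true,
                             config$mean_offspring, config$dispersion,
                             seed = derive_seed(config$seed, "fitness"))
  gen <- simulate_pedigree_and_genotypes(config, counts)
  trk <- NULL
  if (tracks) {
    trk <- lapply(seq_len(config$n_males), function(i) {
      lapply(seq_len(cells_per_male), function(j) {
        simulate_tracks(
          true_velocity = max(ph$velocity[i], 5),
          true_linearity = min(max(ph$linearity[i], 5), 100),
          fps = 25, duration_s = 2.2, noise_sd = 0.3, um_per_px = 1,
          seed = derive_seed(config$seed, paste0("track", i, "_", j)),
          cell_id = sprintf("%s_c%02d", ph$male_id[i], j))
      })
    })
    names(trk) <- ph$male_id
  }
  c(list(config = config, phenotypes = ph, z = z,
         offspring_counts = counts), gen, list(tracks = trk))
}
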