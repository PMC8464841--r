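#' Pipeline run configuration
#'
#' All stage toggles and parameters for an end-to-end run, serializable to
#' YAML and back without loss. Every stochastic stage draws its own seed
#' deterministically from the master seed, so stages are individually
#' reproducible.
#'
#' @param sim A [sim_config()] describing the synthetic population (its
#'   `seed` is overridden by `master_seed`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "kinematics", "parentage", "selection", "surface")` in
#'   dependency order.
#' @param master_seed Integer master seed.
#' @param fitness_csv Optional path to a pre-computed fitness CSV
#'   (`adult_id`, `n_offspring`); lets the selection stage run with the
#'   parentage stage disabled.
#' @param window_vap,window_extra Kinematics smoothing windows.
#' @param cells_per_male Tracks simulated/required per male.
#' @param per_allele_error,fdr_threshold,n_null Parentage parameters.
#' @param k_candidates Spline basis dimensions searched.
#' @param n_bins Fitness-surface bins.
#' @return Object of class `run_config` (a plain list).
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "kinematics", "parentage",
                                  "selection", "surface"),
                       master_seed = 1L,
                       fitness_csv = NULL,
                       window_vap = 5, window_extra = 5,
                       cells_per_male = 15,
                       per_allele_error = 0.005, fdr_threshold = 0.005,
                       n_null = 10000,
                       k_candidates = 3:10, n_bins = 10) {
  stopifnot(all(stages %in% c("simulate", "kinematics", "parentage",
                              "selection", "surface")))
  sim$seed <- as.integer(master_seed)
  structure(list(sim = sim, stages = stages,
                 master_seed = as.integer(master_seed),
                 fitness_csv = fitness_csv,
                 window_vap = window_vap, window_extra = window_extra,
                 cells_per_male = cells_per_male,
                 per_allele_error = per_allele_error,
                 fdr_threshold = fdr_threshold, n_null = n_null,
                 k_candidates = k_candidates, n_bins = n_bins),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The round trip `read_run_config(write_run_config(cfg, f))` reproduces
#' the configuration exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$trait_correlation <- as.vector(x$sim$trait_correlation)
  x$sim$gamma_true <- as.vector(x$sim$gamma_true)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$trait_correlation <- matrix(x$sim$trait_correlation, 6, 6,
                                    dimnames = list(sperm_traits(),
                                                    sperm_traits()))
  x$sim$gamma_true <- matrix(x$sim$gamma_true, 6, 6)
  sim <- do.call(sim_config, x$sim)
  do.call(run_config, c(list(sim = sim),
                        x[setdiff(names(x), c("sim", "master_seed"))],
                        list(master_seed = x$master_seed)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order - simulate the
#' population, measure kinematics from simulated tracks, assign parentage
#' and tally fitness, run the selection analysis, fit the fitness surface -
#' writing each stage's tables as CSV under `dir` and a JSON manifest
#' recording seeds, row counts and md5 checksums of every output. When
#' `reuse = TRUE`, stages whose outputs already exist are skipped and their
#' cached files are used downstream.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @param reuse Reuse cached stage outputs when present (default FALSE).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, dir, reuse = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  manifest <- list(package_version = as.character(
    utils::packageVersion("spermsel")),
    master_seed = config$master_seed, stages = list())
  results <- list(config = config)
  log_stage <- function(name, files, info = list()) {
    manifest$stages[[name]] <<- c(list(
      seed = derive_seed(config$master_seed, name),
      files = lapply(setNames(files, basename(files)), function(f)
        list(md5 = unname(tools::md5sum(f)),
             rows = length(readLines(f)) - 1L))), info)
    message(sprintf("[%s] wrote %s", name,
                    paste(basename(files), collapse = ", ")))
  }

  want <- function(s) s %in% config$stages

  ## -- simulate ----------------------------------------------------------
  if (want("simulate") &&
      !(reuse && file.exists(pth("phenotypes.csv")))) {
    study <- simulate_study(config$sim, tracks = config$cells_per_male > 0,
                            cells_per_male = config$cells_per_male)
    results$study <- study
    write.csv(study$phenotypes, pth("phenotypes.csv"), row.names = FALSE)
    truth <- cbind(study$pedigree)
    write.csv(truth, pth("pedigree_truth.csv"), row.names = FALSE)
    write.csv(data.frame(male_id = study$phenotypes$male_id,
                         n_offspring_true = study$offspring_counts),
              pth("offspring_truth.csv"), row.names = FALSE)
    write_genotypes_csv(study$adults, pth("genotypes_adults.csv"))
    write_genotypes_csv(study$offspring, pth("genotypes_offspring.csv"))
    if (!is.null(study$tracks)) {
      write_tracks_csv(unlist(study$tracks, recursive = FALSE),
                       pth("tracks.csv"))
    }
    write_run_config(config, pth("config.yaml"))
    log_stage("simulate",
              c(pth("phenotypes.csv"), pth("pedigree_truth.csv"),
                pth("offspring_truth.csv"), pth("genotypes_adults.csv"),
                pth("genotypes_offspring.csv"),
                if (!is.null(study$tracks)) pth("tracks.csv"),
                pth("config.yaml")))
  } else if (file.exists(pth("phenotypes.csv"))) {
    results$study <- list(
      phenotypes = read.csv(pth("phenotypes.csv"),
                            stringsAsFactors = FALSE))
  }

  ## -- kinematics --------------------------------------------------------
  if (want("kinematics") &&
      !(reuse && file.exists(pth("kinematics.csv")))) {
    tracks <- read_tracks_csv(pth("tracks.csv"), fps = 25, um_per_px = 1)
    male_of <- sub("_c[0-9]+$", "", names(tracks))
    by_male <- split(tracks, male_of)
    kin <- do.call(rbind, lapply(names(by_male), function(m) {
      s <- summarize_male(by_male[[m]], male_id = m,
                          required_cells = config$cells_per_male,
                          window_vap = config$window_vap,
                          window_extra = config$window_extra)
      data.frame(male_id = m, mean_vapi = s$mean_vapi,
                 mean_linearity = s$mean_linearity, n_cells = s$n_cells,
                 excluded = s$excluded, stringsAsFactors = FALSE)
    }))
    write.csv(kin, pth("kinematics.csv"), row.names = FALSE)
    results$kinematics <- kin
    log_stage("kinematics", pth("kinematics.csv"))
  } else if (file.exists(pth("kinematics.csv"))) {
    results$kinematics <- read.csv(pth("kinematics.csv"),
                                   stringsAsFactors = FALSE)
  }

  ## -- parentage ---------------------------------------------------------
  if (want("parentage") &&
      !(reuse && file.exists(pth("fitness.csv")))) {
    adults <- read_genotypes_csv(pth("genotypes_adults.csv"))
    offspring <- read_genotypes_csv(pth("genotypes_offspring.csv"))
    panel <- filter_individuals(combine_panels(adults, offspring))
    asg <- assign_parentage(panel,
                            per_allele_error = config$per_allele_error,
                            fdr_threshold = config$fdr_threshold,
                            n_null = config$n_null,
                            seed = derive_seed(config$master_seed,
                                               "parentage"))
    write.csv(asg, pth("assignments.csv"), row.names = FALSE)
    fit <- tally_fitness(asg, panel)
    write.csv(fit, pth("fitness.csv"), row.names = FALSE)
    results$assignments <- asg
    results$fitness <- fit
    log_stage("parentage", c(pth("assignments.csv"), pth("fitness.csv")),
              info = list(n_offspring = sum(panel$stage == "offspring"),
                          n_assigned = sum(asg$accepted),
                          excluded = nrow(attr(panel, "exclusions"))))
  } else if (want("selection")) {
    src <- if (!is.null(config$fitness_csv)) config$fitness_csv
           else pth("fitness.csv")
    if (file.exists(src)) {
      results$fitness <- read.csv(src, stringsAsFactors = FALSE)
    }
  }

  ## -- selection ---------------------------------------------------------
  if (want("selection")) {
    ph <- results$study$phenotypes
    if (!is.null(results$kinematics)) {
      # use track-measured velocity and linearity, as the field study does
      m <- match(ph$male_id, results$kinematics$male_id)
      ok <- !is.na(m)
      ph$velocity[ok] <- results$kinematics$mean_vapi[m[ok]]
      ph$linearity[ok] <- results$kinematics$mean_linearity[m[ok]]
    }
    fitrec <- results$fitness
    stopifnot(!is.null(fitrec))
    idc <- if ("adult_id" %in% names(fitrec)) "adult_id" else "male_id"
    counts <- fitrec$n_offspring[match(ph$male_id, fitrec[[idc]])]
    keep <- !is.na(counts)
    est <- selection_analysis(ph[keep, ], counts[keep])
    results$selection <- est
    uni <- est$univariate
    tab1 <- merge(uni, est$beta, by = "trait", sort = FALSE)
    write.csv(tab1, pth("selection_differentials.csv"),
              row.names = FALSE)
    gm <- data.frame(trait = rownames(est$gamma), est$gamma,
                     check.names = FALSE)
    write.csv(gm, pth("selection_gamma.csv"), row.names = FALSE)
    pv <- rbind(cbind(model = "linear", est$p_linear),
                cbind(model = "univariate_quadratic", est$p_univariate),
                cbind(model = "quadratic_full", est$p_quadratic_full))
    write.csv(pv, pth("selection_pvalues.csv"), row.names = FALSE)
    viftab <- data.frame(
      term = c(names(est$vif_linear), names(est$vif_nonlinear)),
      model = c(rep("linear", length(est$vif_linear)),
                rep("quadratic_full", length(est$vif_nonlinear))),
      vif = c(est$vif_linear, est$vif_nonlinear))
    write.csv(viftab, pth("vif.csv"), row.names = FALSE)
    pc <- data.frame(trait = rownames(est$partial$r), est$partial$r,
                     check.names = FALSE)
    write.csv(pc, pth("partial_correlations.csv"), row.names = FALSE)
    log_stage("selection",
              c(pth("selection_differentials.csv"),
                pth("selection_gamma.csv"), pth("selection_pvalues.csv"),
                pth("vif.csv"), pth("partial_correlations.csv")),
              info = list(n_males = est$n))
  }

  ## -- surface -----------------------------------------------------------
  if (want("surface")) {
    est <- results$selection
    stopifnot(!is.null(est))
    sf <- select_k(est$z[, "sperm_count"], est$w,
                   k_candidates = config$k_candidates,
                   n_bins = config$n_bins)
    results$surface <- sf
    write.csv(data.frame(z = sf$grid, fit = sf$predicted_w,
                         ci_lower = sf$ci_lower, ci_upper = sf$ci_upper),
              pth("surface_curve.csv"), row.names = FALSE)
    write.csv(sf$binned, pth("surface_bins.csv"), row.names = FALSE)
    write.csv(data.frame(k = sf$k_candidates, gcv = sf$gcv_scores),
              pth("surface_gcv.csv"), row.names = FALSE)
    log_stage("surface",
              c(pth("surface_curve.csv"), pth("surface_bins.csv"),
                pth("surface_gcv.csv")),
              info = list(k_best = sf$k_best))
  }

  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE)
  writeLines(manifest_json, pth("manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

#' Render a human-readable run report
#'
#' Aggregates a completed run directory into one markdown document: the
#' selection differential/gradient table (s, beta, c), the gamma triangle,
#' VIFs and partial correlations, the GCV scores and chosen K, and the
#' parentage accounting. Entries with p < 0.05 in the quasi-Poisson tests
#' are bolded. Regeneration from unchanged outputs is byte-identical.
#'
#' @param dir A directory written by [run_pipeline()].
#' @param path Output file (default `report.md` inside `dir`).
#' @return The report path, invisibly.
#' @export
make_report <- function(dir, path = file.path(dir, "report.md")) {
  need <- c("selection_differentials.csv", "selection_gamma.csv",
            "selection_pvalues.csv", "vif.csv",
            "partial_correlations.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  }
  tab1 <- read.csv(file.path(dir, "selection_differentials.csv"))
  gm <- read.csv(file.path(dir, "selection_gamma.csv"),
                 check.names = FALSE)
  pv <- read.csv(file.path(dir, "selection_pvalues.csv"))
  vif <- read.csv(file.path(dir, "vif.csv"))
  pc <- read.csv(file.path(dir, "partial_correlations.csv"),
                 check.names = FALSE)
  p_of <- function(model, term) {
    hit <- pv$p[pv$model == model & pv$term == term]
    if (length(hit)) hit[1] else NA_real_
  }
  bold <- function(txt, p) {
    ifelse(!is.na(p) & p < 0.05, paste0("**", txt, "**"), txt)
  }
  fmt <- function(est, se) sprintf("%.3f (+/-%.3f)", est, se)
  lines <- c("# Selection analysis run report", "",
             "## Selection differentials and gradients", "",
             "| Trait | s (univariate) | beta (multivariate) | c (univariate) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(tab1))) {
    tr <- tab1$trait[i]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |", tr,
      bold(fmt(tab1$s[i], tab1$s_se[i]), p_of("linear", tr)),
      bold(fmt(tab1$beta[i], tab1$beta_se[i]), p_of("linear", tr)),
      bold(fmt(tab1$c[i], tab1$c_se[i]),
           p_of("univariate_quadratic", paste0(tr, ".sq")))))
  }
  traits <- gm$trait
  lines <- c(lines, "", "## gamma (quadratic diagonal, correlational above)",
             "", paste0("| |", paste(traits, collapse = "|"), "|"),
             paste0("|", paste(rep("---", length(traits) + 1),
                               collapse = "|"), "|"))
  for (i in seq_along(traits)) {
    row <- vapply(seq_along(traits), function(j) {
      if (j < i) return("")
      term <- if (i == j) paste0(traits[i], ".sq")
              else paste0(traits[i], ".x.", traits[j])
      bold(sprintf("%.3f", gm[i, j + 1]), p_of("quadratic_full", term))
    }, character(1))
    lines <- c(lines, paste0("| ", traits[i], " |",
                             paste(row, collapse = "|"), "|"))
  }
  lines <- c(lines, "", "## Variance inflation factors", "",
             sprintf("- linear model: max VIF %.3f",
                     max(vif$vif[vif$model == "linear"])),
             sprintf("- full quadratic model: max VIF %.3f",
                     max(vif$vif[vif$model == "quadratic_full"])))
  lines <- c(lines, "", "## Partial correlations", "", "```",
             utils::capture.output(print(pc, digits = 3)), "```")
  if (file.exists(file.path(dir, "surface_gcv.csv"))) {
    gcv <- read.csv(file.path(dir, "surface_gcv.csv"))
    lines <- c(lines, "", "## Fitness surface", "",
               sprintf("Chosen basis dimension K = %d (GCV %.5f).",
                       gcv$k[which.min(gcv$gcv)], min(gcv$gcv)),
               "", "| K | GCV |", "|---|---|",
               sprintf("| %d | %.6f |", gcv$k, gcv$gcv))
  }
  if (file.exists(file.path(dir, "manifest.json"))) {
    mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
    if (!is.null(mf$stages$parentage)) {
      lines <- c(lines, "", "## Parentage accounting", "",
                 sprintf("- offspring genotyped: %d",
                         mf$stages$parentage$n_offspring),
                 sprintf("- offspring assigned at FDR control: %d",
                         mf$stages$parentage$n_assigned),
                 sprintf("- individuals excluded for missing data: %d",
                         mf$stages$parentage$excluded))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
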