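#' A panel of biallelic SNP genotypes
#'
#' Individuals x loci matrix of alternate-allele counts (0/1/2, `NA` =
#' missing call) together with a life-stage label per individual
#' (`adult_male`, `adult_female`, `offspring`).
#'
#' @param genotypes Integer matrix with individual IDs as rownames and
#'   locus IDs as colnames; entries in {0, 1, 2, NA}.
#' @param stage Character vector, one label per row.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes,
                           stage = rep("offspring", nrow(genotypes))) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  stopifnot(length(stage) == nrow(genotypes),
            all(stage %in% c("adult_male", "adult_female", "offspring")))
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("ind%05d", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("L%03d", seq_len(ncol(genotypes)))
  }
  structure(list(genotypes = genotypes, stage = as.character(stage)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel: %d individuals x %d loci (%s)>\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(sprintf("%s: %d", names(table(x$stage)),
                            table(x$stage)), collapse = ", ")))
  invisible(x)
}

#' Combine genotype panels
#'
#' Row-binds panels sharing the same loci (e.g. adults + offspring) into a
#' single panel for filtering and parentage assignment.
#'
#' @param ... `genotype_panel` objects with identical locus sets.
#' @return A `genotype_panel`.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  loci <- colnames(panels[[1]]$genotypes)
  stopifnot(all(vapply(panels, function(p)
    identical(colnames(p$genotypes), loci), logical(1))))
  genotype_panel(do.call(rbind, lapply(panels, `[[`, "genotypes")),
                 stage = unlist(lapply(panels, `[[`, "stage")))
}

#' Estimate per-locus allele frequencies from adults
#'
#' Alternate-allele frequency per locus, computed from adult genotypes with
#' missing entries ignored.
#'
#' @param panel A [genotype_panel()].
#' @return Named numeric vector of frequencies.
#' @export
estimate_allele_freqs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  adults <- panel$genotypes[panel$stage != "offspring", , drop = FALSE]
  if (nrow(adults) == 0) adults <- panel$genotypes
  colMeans(adults, na.rm = TRUE) / 2
}

#' Filter individuals by genotype completeness
#'
#' Offspring with more than `offspring_max_missing_frac` of loci missing
#' are removed outright; adults with more than `adult_max_missing_loci`
#' missing loci are removed from the candidate-parent pool. Every exclusion
#' is listed in the attached report.
#'
#' @param panel A [genotype_panel()].
#' @param offspring_max_missing_frac Maximum tolerated missing fraction for
#'   offspring (default 0.5).
#' @param adult_max_missing_loci Maximum tolerated missing loci for adults
#'   (default 50).
#' @return The filtered `genotype_panel`, with attribute `exclusions`: a
#'   data frame (id, stage, n_missing).
#' @export
filter_individuals <- function(panel, offspring_max_missing_frac = 0.5,
                               adult_max_missing_loci = 50) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  if (nrow(g) == 0) stop("empty panel")
  miss <- rowSums(is.na(g))
  L <- ncol(g)
  is_off <- panel$stage == "offspring"
  drop <- (is_off & miss > offspring_max_missing_frac * L) |
    (!is_off & miss > adult_max_missing_loci)
  if (all(drop)) stop("all individuals excluded by missing-data filters")
  excl <- data.frame(id = rownames(g)[drop], stage = panel$stage[drop],
                     n_missing = unname(miss[drop]),
                     stringsAsFactors = FALSE)
  out <- genotype_panel(g[!drop, , drop = FALSE],
                        stage = panel$stage[!drop])
  attr(out, "exclusions") <- excl
  out
}

# Mendelian transmission table: M[d+1, s+1, o+1] = P(offspring genotype o |
# dam genotype d, sire genotype s), each parent transmitting one allele
# (heterozygotes a fair coin).
mendel_table <- function() {
  M <- array(0, c(3, 3, 3))
  for (d in 0:2) for (s in 0:2) {
    pd <- d / 2; ps <- s / 2
    M[d + 1, s + 1, 1] <- (1 - pd) * (1 - ps)
    M[d + 1, s + 1, 2] <- pd * (1 - ps) + (1 - pd) * ps
    M[d + 1, s + 1, 3] <- pd * ps
  }
  M
}

# Per-locus lookup tables for trio evaluation. Genotypes are coded
# 0/1/2/3(=missing); the combined state of a trio at one locus is
# 1 + o + 4*d + 16*s in 1..64. Returns, for each locus:
#   lr[state, locus]      log10 likelihood ratio (trio vs unrelated);
#                         0 for any state involving a missing call
#   inc[state, locus]     TRUE where the observed trio is impossible under
#                         error-free Mendelian transmission
trio_tables <- function(allele_freqs, per_allele_error) {
  stopifnot(per_allele_error >= 0, per_allele_error < 0.5)
  keep <- allele_freqs > 0 & allele_freqs < 1
  p <- allele_freqs
  L <- length(p)
  E <- genotype_error_matrix(per_allele_error)
  M <- mendel_table()
  # Hardy-Weinberg genotype frequencies per locus: 3 x L
  hw <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  # marginal P(observed g) under HW + error: 3 x L
  marg <- t(E) %*% hw
  lr <- matrix(0, 64, L)
  inc <- matrix(FALSE, 64, L)
  for (o in 0:2) for (d in 0:2) for (s in 0:2) {
    st <- 1 + o + 4 * d + 16 * s
    # P(obs o,d,s | true trio): sum over true genotypes
    num <- 0
    for (td in 0:2) for (ts in 0:2) {
      po_true <- M[td + 1, ts + 1, ] # P(true offspring gt | td, ts)
      num <- num + hw[td + 1, ] * hw[ts + 1, ] * E[td + 1, d + 1] *
        E[ts + 1, s + 1] * drop(po_true %*% E[, o + 1])
    }
    den <- marg[o + 1, ] * marg[d + 1, ] * marg[s + 1, ]
    lr[st, ] <- log10(num) - log10(den)
    inc[st, ] <- rep(M[d + 1, s + 1, o + 1] == 0, L)
  }
  lr[, !keep] <- 0
  inc[, !keep] <- FALSE
  list(lr = lr, inc = inc, dropped = which(!keep))
}

trio_state <- function(o, d, s) {
  o <- ifelse(is.na(o), 3L, o); d <- ifelse(is.na(d), 3L, d)
  s <- ifelse(is.na(s), 3L, s)
  1L + o + 4L * d + 16L * s
}

#' Trio parentage log-likelihood ratio
#'
#' Per-locus likelihood of the observed offspring/dam/sire genotypes under
#' (i) true parentage with Mendelian transmission and a symmetric
#' per-allele genotyping error versus (ii) three unrelated Hardy-Weinberg
#' draws under the same error model. The LOD is the sum of log10 ratios
#' over loci at which all three calls are present; loci with allele
#' frequency 0 or 1 are dropped with a warning. `n_incompatible` counts
#' loci at which the observed trio is impossible under error-free
#' transmission.
#'
#' @param offspring_gt,dam_gt,sire_gt Integer genotype vectors (0/1/2/NA)
#'   over the same loci.
#' @param allele_freqs Per-locus alternate-allele frequencies.
#' @param per_allele_error Per-allele error rate in [0, 0.5).
#' @return List with `lod` and `n_incompatible`.
#' @export
trio_log_likelihood <- function(offspring_gt, dam_gt, sire_gt,
                                allele_freqs, per_allele_error = 0.005) {
  L <- length(allele_freqs)
  stopifnot(length(offspring_gt) == L, length(dam_gt) == L,
            length(sire_gt) == L)
  tabs <- trio_tables(allele_freqs, per_allele_error)
  if (length(tabs$dropped)) {
    warning(length(tabs$dropped),
            " monomorphic loci (allele frequency 0 or 1) dropped")
  }
  st <- trio_state(offspring_gt, dam_gt, sire_gt)
  idx <- cbind(st, seq_len(L))
  complete <- !(is.na(offspring_gt) | is.na(dam_gt) | is.na(sire_gt))
  list(lod = sum(tabs$lr[idx]),
       n_incompatible = sum(tabs$inc[idx] & complete))
}

# Counts of opposing homozygotes (offspring 0 vs adult 2 or vice versa)
# between every offspring and every adult; a fast exclusion screen for
# candidate parents. Returns an offspring x adults integer matrix.
opposing_homozygotes <- function(off_g, adult_g) {
  o0 <- (!is.na(off_g)) & off_g == 0L
  o2 <- (!is.na(off_g)) & off_g == 2L
  a0 <- (!is.na(adult_g)) & adult_g == 0L
  a2 <- (!is.na(adult_g)) & adult_g == 2L
  storage.mode(o0) <- storage.mode(o2) <- "double"
  storage.mode(a0) <- storage.mode(a2) <- "double"
  o0 %*% t(a2) + o2 %*% t(a0)
}

#' Assign offspring to dam-sire trios with FDR control
#'
#' For every offspring, the dam-sire pair with the maximal trio LOD is
#' located by exhaustive search over candidate pairs (pre-filtered by a cap
#' on pairwise opposing-homozygote counts). A null LOD distribution is
#' built from `n_null` simulated unrelated trios drawn from the adult
#' allele frequencies under the same error and missingness regime, and the
#' LOD acceptance cutoff is chosen (step-up) so the estimated false
#' discovery rate - expected null exceedances relative to accepted calls -
#' stays below `fdr_threshold`. The null tail probability uses the add-one
#' convention (k+1)/(n+1), so an FDR threshold of 0 accepts nothing.
#' Offspring whose best trio fails the cutoff, or whose best LOD is tied
#' between distinct pairs, remain unassigned.
#'
#' @param panel A filtered [genotype_panel()] containing offspring and
#'   candidate adults of both sexes.
#' @param per_allele_error Per-allele genotyping error rate.
#' @param fdr_threshold Acceptance FDR (default 0.005).
#' @param n_null Simulated unrelated trios for the null (default 10000).
#' @param incompat_cap Pairwise opposing-homozygote cap for the candidate
#'   pre-filter (default 10).
#' @param seed Integer seed for the null simulation.
#' @return A data frame of class `trio_assignments` with one row per
#'   offspring: `offspring_id`, `dam_id`, `sire_id`, `lod`,
#'   `n_incompatible`, `accepted`; attributes `lod_cutoff`,
#'   `fdr_at_acceptance` and `null_lods`.
#' @export
assign_parentage <- function(panel, per_allele_error = 0.005,
                             fdr_threshold = 0.005, n_null = 10000,
                             incompat_cap = 10, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  off <- g[panel$stage == "offspring", , drop = FALSE]
  dams <- g[panel$stage == "adult_female", , drop = FALSE]
  sires <- g[panel$stage == "adult_male", , drop = FALSE]
  empty <- data.frame(offspring_id = rownames(off),
                      dam_id = NA_character_, sire_id = NA_character_,
                      lod = NA_real_, n_incompatible = NA_integer_,
                      accepted = FALSE, stringsAsFactors = FALSE)
  if (nrow(dams) == 0 || nrow(sires) == 0) {
    warning("no candidate parents of one sex; all offspring unassigned")
    class(empty) <- c("trio_assignments", "data.frame")
    return(empty)
  }
  p <- estimate_allele_freqs(panel)
  tabs <- trio_tables(p, per_allele_error)
  L <- ncol(g)
  loci_idx <- seq_len(L)

  oh_dam <- opposing_homozygotes(off, dams)
  oh_sire <- opposing_homozygotes(off, sires)

  # pre-encoded genotype states (missing -> 3) for fast table lookups
  enc <- function(m) { m[is.na(m)] <- 3L; m }
  e_off <- enc(off); e_dam <- 4L * enc(dams); e_sire <- 16L * enc(sires)

  res <- empty
  for (i in seq_len(nrow(off))) {
    dc <- which(oh_dam[i, ] <= incompat_cap)
    sc <- which(oh_sire[i, ] <= incompat_cap)
    if (length(dc) == 0 || length(sc) == 0) next
    best_lod <- -Inf; best <- NULL; tied <- FALSE
    for (d in dc) {
      ostate <- 1L + e_off[i, ] + e_dam[d, ]
      for (s in sc) {
        lod <- sum(tabs$lr[cbind(ostate + e_sire[s, ], loci_idx)])
        # -Inf arises under a zero error rate for Mendelian-impossible
        # pairs; such pairs can never be the best trio
        if (!is.finite(lod)) next
        if (lod > best_lod + 1e-12) {
          best_lod <- lod; best <- c(d, s); tied <- FALSE
        } else if (abs(lod - best_lod) <= 1e-12) {
          tied <- TRUE
        }
      }
    }
    if (is.null(best) || tied) next
    st <- 1L + e_off[i, ] + e_dam[best[1], ] + e_sire[best[2], ]
    complete <- !(is.na(off[i, ]) | is.na(dams[best[1], ]) |
                    is.na(sires[best[2], ]))
    res$dam_id[i] <- rownames(dams)[best[1]]
    res$sire_id[i] <- rownames(sires)[best[2]]
    res$lod[i] <- best_lod
    res$n_incompatible[i] <- sum(tabs$inc[cbind(st, loci_idx)] & complete)
  }

  # Null LOD distribution from unrelated trios simulated at the estimated
  # allele frequencies, with the same error model and the panel's observed
  # missingness.
  miss_rate <- mean(is.na(g))
  null_lods <- with_seed(seed, {
    draw <- function() {
      tg <- matrix(rbinom(n_null * L, 2, rep(p, each = n_null)), n_null, L)
      observe_genotypes(tg, per_allele_error, miss_rate)
    }
    no <- draw(); nd <- draw(); ns <- draw()
    st <- trio_state(no, nd, ns)
    rowSums(matrix(tabs$lr[cbind(c(st), rep(loci_idx, each = n_null))],
                   n_null, L))
  })

  cand <- which(!is.na(res$lod))
  accepted_cut <- Inf
  fdr_at <- NA_real_
  if (length(cand)) {
    lods <- sort(res$lod[cand], decreasing = TRUE)
    n_off <- nrow(off)
    # step-up: largest k whose cutoff keeps the estimated FDR under control
    fdr_k <- vapply(seq_along(lods), function(k) {
      tail_p <- (sum(null_lods >= lods[k]) + 1) / (n_null + 1)
      n_off * tail_p / k
    }, numeric(1))
    ok <- which(fdr_k <= fdr_threshold)
    if (length(ok)) {
      k <- max(ok)
      accepted_cut <- lods[k]
      fdr_at <- fdr_k[k]
      res$accepted <- !is.na(res$lod) & res$lod >= accepted_cut
    }
  }
  attr(res, "lod_cutoff") <- accepted_cut
  attr(res, "fdr_at_acceptance") <- fdr_at
  attr(res, "null_lods") <- null_lods
  class(res) <- c("trio_assignments", "data.frame")
  res
}

#' Tally offspring and unique mates per adult
#'
#' Counts, for each genotyped adult, the number of accepted offspring
#' assignments and the number of distinct co-parents. Adults present in the
#' panel but never assigned get (0, 0). Summary statistics of mate counts
#' (overall and for the subset with at least two progeny) are attached.
#'
#' @param assignments A `trio_assignments` data frame (only accepted rows
#'   are used).
#' @param panel The [genotype_panel()] of genotyped individuals (adults
#'   provide the roster; offspring rows are ignored).
#' @return Data frame: `adult_id`, `stage`, `n_offspring`, `n_mates`;
#'   attribute `mate_summary`.
#' @export
tally_fitness <- function(assignments, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  acc <- assignments[assignments$accepted %in% TRUE, , drop = FALSE]
  adults <- rownames(panel$genotypes)[panel$stage != "offspring"]
  stage <- panel$stage[panel$stage != "offspring"]
  bad <- setdiff(c(acc$dam_id, acc$sire_id), adults)
  if (length(bad)) {
    stop("assignments reference unknown adults: ",
         paste(head(bad), collapse = ", "))
  }
  n_off <- n_mates <- setNames(integer(length(adults)), adults)
  if (nrow(acc)) {
    ts <- table(acc$sire_id); td <- table(acc$dam_id)
    n_off[names(ts)] <- as.integer(ts)
    n_off[names(td)] <- as.integer(td)
    ms <- tapply(acc$dam_id, acc$sire_id, function(x) length(unique(x)))
    md <- tapply(acc$sire_id, acc$dam_id, function(x) length(unique(x)))
    n_mates[names(ms)] <- as.integer(ms)
    n_mates[names(md)] <- as.integer(md)
  }
  out <- data.frame(adult_id = adults, stage = stage,
                    n_offspring = unname(n_off),
                    n_mates = unname(n_mates), stringsAsFactors = FALSE)
  summ <- function(d) {
    c(mean_mates = mean(d$n_mates), min_mates = min(d$n_mates),
      max_mates = max(d$n_mates))
  }
  males <- out[out$stage == "adult_male", ]
  females <- out[out$stage == "adult_female", ]
  attr(out, "mate_summary") <- list(
    males = summ(males), females = summ(females),
    males_2plus = if (any(males$n_offspring >= 2))
      summ(males[males$n_offspring >= 2, ]) else NULL,
    females_2plus = if (any(females$n_offspring >= 2))
      summ(females[females$n_offspring >= 2, ]) else NULL)
  out
}
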