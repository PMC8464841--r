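test_that("missing-data filters apply the adult and offspring thresholds", {
  g <- matrix(1L, 4, 215)
  g[1, 1:51] <- NA      # adult, 51 missing -> excluded as candidate
  g[2, 1:50] <- NA      # adult, exactly 50 missing -> kept
  g[3, 1:108] <- NA     # offspring, >50% missing -> excluded
  rownames(g) <- c("A1", "A2", "O1", "O2")
  panel <- genotype_panel(g, stage = c("adult_male", "adult_female",
                                       "offspring", "offspring"))
  flt <- filter_individuals(panel)
  excl <- attr(flt, "exclusions")
  expect_setequal(excl$id, c("A1", "O1"))
  expect_equal(excl$n_missing[excl$id == "A1"], 51)
  expect_setequal(rownames(flt$genotypes), c("A2", "O2"))
  # no missing data -> identity
  clean <- genotype_panel(matrix(1L, 3, 10),
                          stage = c("adult_male", "adult_female",
                                    "offspring"))
  expect_equal(filter_individuals(clean)$genotypes, clean$genotypes)
  all_bad <- genotype_panel(matrix(NA_integer_, 2, 10),
                            stage = rep("offspring", 2))
  expect_error(filter_individuals(all_bad), "excluded")
})

test_that("trio LOD is positive and incompatibility-free for a true trio", {
  panel <- tiny_trio_panel()
  g <- panel$genotypes
  p <- rep(0.5, ncol(g))
  tr <- trio_log_likelihood(g["O1", ], g["F1", ], g["M1", ], p,
                            per_allele_error = 0)
  expect_identical(tr$n_incompatible, 0L)
  expect_gt(tr$lod, 0)
  # an unrelated pairing typically carries incompatibilities and lower LOD
  tr2 <- trio_log_likelihood(g["O1", ], g["F3", ], g["M4", ], p,
                             per_allele_error = 0)
  expect_gt(tr2$n_incompatible, 0)
  expect_lt(tr2$lod, tr$lod)
})

test_that("Mendelian-impossible loci are counted", {
  p <- c(0.5, 0.5)
  tr <- trio_log_likelihood(c(2L, 1L), c(0L, 1L), c(0L, 1L), p,
                            per_allele_error = 0.005)
  expect_identical(tr$n_incompatible, 1L)  # offspring 2 from 0 x 0
  # with error = 0 the impossible locus zeroes the likelihood
  tr0 <- trio_log_likelihood(c(2L), c(0L), c(0L), 0.5,
                             per_allele_error = 0)
  expect_identical(tr0$n_incompatible, 1L)
  expect_equal(tr0$lod, -Inf)
})

test_that("single-locus likelihood ratio matches exhaustive enumeration", {
  # all three heterozygous at p = 0.5, no error: enumerate the transmission
  # probabilities by brute force
  hw <- c(0.25, 0.5, 0.25)
  M <- spermsel:::mendel_table()
  num <- hw[2] * hw[2] * M[2, 2, 2]
  den <- hw[2]^3
  oracle <- log10(num / den)
  got <- trio_log_likelihood(1L, 1L, 1L, 0.5, per_allele_error = 0)
  expect_equal(got$lod, oracle, tolerance = 1e-12)

  # same check with error, at an asymmetric frequency, all 27 states
  p <- 0.3; e <- 0.01
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  E <- spermsel:::genotype_error_matrix(e)
  marg <- as.vector(t(E) %*% hw)
  for (o in 0:2) for (d in 0:2) for (s in 0:2) {
    num <- 0
    for (td in 0:2) for (ts in 0:2) for (to in 0:2) {
      num <- num + hw[td + 1] * hw[ts + 1] * M[td + 1, ts + 1, to + 1] *
        E[to + 1, o + 1] * E[td + 1, d + 1] * E[ts + 1, s + 1]
    }
    oracle <- log10(num) - log10(marg[o + 1] * marg[d + 1] * marg[s + 1])
    got <- trio_log_likelihood(as.integer(o), as.integer(d),
                               as.integer(s), p, per_allele_error = e)
    expect_equal(got$lod, oracle, tolerance = 1e-10)
  }
})

test_that("LOD is additive over loci and invariant to locus order", {
  panel <- tiny_trio_panel(n_loci = 40)
  g <- panel$genotypes
  set.seed(14)
  p <- runif(40, 0.2, 0.8)
  whole <- trio_log_likelihood(g["O1", ], g["F1", ], g["M1", ], p, 0.01)
  parts <- trio_log_likelihood(g["O1", 1:15], g["F1", 1:15],
                               g["M1", 1:15], p[1:15], 0.01)$lod +
    trio_log_likelihood(g["O1", 16:40], g["F1", 16:40], g["M1", 16:40],
                        p[16:40], 0.01)$lod
  expect_equal(whole$lod, parts, tolerance = 1e-10)
  perm <- sample(40)
  shuffled <- trio_log_likelihood(g["O1", perm], g["F1", perm],
                                  g["M1", perm], p[perm], 0.01)
  expect_equal(shuffled$lod, whole$lod, tolerance = 1e-10)
})

test_that("monomorphic loci are dropped with a warning", {
  expect_warning(
    trio_log_likelihood(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(0.5, 0),
                        0.005),
    "monomorphic")
})

test_that("an error-free Mendelian child is assigned to its true trio", {
  panel <- tiny_trio_panel(n_loci = 80, n_extra = 10)
  asg <- assign_parentage(panel, per_allele_error = 0.005, n_null = 2000,
                          seed = 3)
  expect_equal(asg$dam_id, "F1")
  expect_equal(asg$sire_id, "M1")
  expect_true(asg$accepted)
  expect_identical(asg$n_incompatible, 0L)
})

test_that("an FDR threshold of zero accepts nothing", {
  panel <- tiny_trio_panel(n_loci = 80)
  asg <- assign_parentage(panel, fdr_threshold = 0, n_null = 500,
                          seed = 3)
  expect_false(any(asg$accepted))
})

test_that("missing candidates of one sex leaves offspring unassigned", {
  panel <- tiny_trio_panel(n_loci = 30)
  keep <- panel$stage != "adult_female"
  males_only <- genotype_panel(panel$genotypes[keep, ],
                               stage = panel$stage[keep])
  expect_warning(asg <- assign_parentage(males_only, n_null = 100,
                                         seed = 1), "one sex")
  expect_false(any(asg$accepted))
})

test_that("parentage recovery on a synthetic population is accurate and FDR-controlled", {
  cfg <- sim_config(n_males = 25, n_females = 40, n_loci = 215,
                    per_allele_error = 0.005, missing_rate = 0.1,
                    mean_offspring = 6, seed = 21)
  st <- simulate_study(cfg)
  panel <- filter_individuals(combine_panels(st$adults, st$offspring))
  asg <- assign_parentage(panel, per_allele_error = 0.005,
                          fdr_threshold = 0.005, n_null = 5000, seed = 2)
  acc <- asg[asg$accepted, ]
  truth <- st$pedigree[match(acc$offspring_id, st$pedigree$offspring_id), ]
  correct <- acc$dam_id == truth$dam_id & acc$sire_id == truth$sire_id
  expect_gt(sum(correct) / nrow(st$pedigree), 0.9)
  expect_lte(mean(!correct), 0.005 + 3 * sqrt(0.005 / nrow(acc)))
  # accepted-with-zero-error invariant: rerun without genotyping error
  cfg0 <- sim_config(n_males = 10, n_females = 15, n_loci = 100,
                     per_allele_error = 0, missing_rate = 0,
                     mean_offspring = 4, seed = 22)
  st0 <- simulate_study(cfg0)
  p0 <- combine_panels(st0$adults, st0$offspring)
  asg0 <- assign_parentage(p0, per_allele_error = 0, n_null = 2000,
                           seed = 4)
  expect_true(all(asg0$n_incompatible[asg0$accepted] == 0L))
})

test_that("fitness tallies count offspring and unique mates", {
  asg <- data.frame(
    offspring_id = paste0("O", 1:5),
    dam_id = c("F1", "F1", "F2", "F2", "F3"),
    sire_id = c("M1", "M1", "M1", "M2", "M2"),
    lod = 10, n_incompatible = 0L, accepted = TRUE,
    stringsAsFactors = FALSE)
  g <- matrix(1L, 6, 4)
  rownames(g) <- c("M1", "M2", "M3", "F1", "F2", "F3")
  panel <- genotype_panel(g, stage = c(rep("adult_male", 3),
                                       rep("adult_female", 3)))
  tal <- tally_fitness(asg, panel)
  expect_equal(tal$n_offspring[tal$adult_id == "M1"], 3)
  expect_equal(tal$n_mates[tal$adult_id == "M1"], 2)
  expect_equal(tal$n_offspring[tal$adult_id == "M3"], 0)
  expect_equal(tal$n_mates[tal$adult_id == "M3"], 0)
  # brute-force recount
  for (id in tal$adult_id) {
    rows <- asg[asg$dam_id == id | asg$sire_id == id, ]
    expect_equal(tal$n_offspring[tal$adult_id == id], nrow(rows))
  }
  # conservation: sire totals equal number of accepted assignments
  expect_equal(sum(tal$n_offspring[tal$stage == "adult_male"]), nrow(asg))
  expect_equal(sum(tal$n_offspring[tal$stage == "adult_female"]),
               nrow(asg))
  bad <- asg; bad$sire_id[1] <- "MX"
  expect_error(tally_fitness(bad, panel), "unknown")
})

test_that("genotype CSV and VCF round trips preserve the panel", {
  panel <- tiny_trio_panel(n_loci = 12)
  f <- tempfile(fileext = ".csv")
  write_genotypes_csv(panel, f)
  back <- read_genotypes_csv(f)
  expect_equal(back$genotypes, panel$genotypes)
  expect_equal(back$stage, panel$stage)
  skip_if_not_installed("vcfR")
  # minimal VCF with GT fields for the same individuals
  g <- panel$genotypes
  vcf <- tempfile(fileext = ".vcf")
  gt_str <- apply(g, 1, function(row) c("0/0", "0/1", "1/1")[row + 1])
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  for (j in seq_len(ncol(g))) {
    lines <- c(lines, paste(c("1", j, colnames(g)[j], "A", "T", ".",
                              "PASS", ".", "GT", gt_str[j, ]),
                            collapse = "\t"))
  }
  writeLines(lines, vcf)
  pv <- read_genotypes_vcf(vcf)
  expect_equal(unname(pv$genotypes[rownames(g), colnames(g)]), unname(g))
})
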