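#' Write cell tracks to CSV
#'
#' One row per frame with columns `cell_id`, `frame`, `x_px`, `y_px`.
#' Acquisition metadata (fps, um/px) travels separately, e.g. in the run
#' config.
#'
#' @param tracks List of [cell_track()] objects.
#' @param path Output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(cell_id = tr$cell_id, frame = seq_along(tr$x) - 1L,
               x_px = tr$x, y_px = tr$y, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cell tracks from CSV
#'
#' Expects columns `cell_id`, `frame`, `x_px`, `y_px`; frames are ordered
#' within cell and converted to time via `fps`.
#'
#' @param path CSV path.
#' @param fps Frame rate of the source video.
#' @param um_per_px Spatial calibration.
#' @return Named list of [cell_track()] objects.
#' @export
read_tracks_csv <- function(path, fps, um_per_px) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "frame", "x_px", "y_px") %in% names(df)))
  split_df <- split(df, df$cell_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$frame), ]
    cell_track(d$x_px, d$y_px, fps = fps, um_per_px = um_per_px,
               cell_id = d$cell_id[1], t = d$frame / fps)
  })
  out[order(names(out))]
}

#' Write a genotype panel to CSV
#'
#' Rows are individuals (first columns `id`, `stage`), remaining columns
#' are loci with codes 0/1/2 and missing written as `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output CSV path.
#' @export
write_genotypes_csv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(id = rownames(panel$genotypes), stage = panel$stage,
                   panel$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from CSV
#'
#' @param path CSV written by [write_genotypes_csv()] (columns `id`,
#'   `stage`, then one column per locus).
#' @return A [genotype_panel()].
#' @export
read_genotypes_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "stage") %in% names(df)))
  g <- as.matrix(df[setdiff(names(df), c("id", "stage"))])
  rownames(g) <- df$id
  genotype_panel(g, stage = df$stage)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Minimal VCF support for parentage input: reads the GT field of biallelic
#' SNP records and converts to alternate-allele counts (0/1/2, missing =
#' NA). Multi-allelic records are dropped with a warning.
#'
#' @param path VCF path (plain or gzipped).
#' @param stage Stage label per sample, recycled if length 1.
#' @return A [genotype_panel()] (individuals x loci).
#' @export
read_genotypes_vcf <- function(path, stage = "offspring") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  if (!all(biallelic)) {
    warning(sum(!biallelic), " multi-allelic records dropped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", s), "/"), function(a)
             sum(a == "1"), integer(1)))
  }
  g <- apply(gt, 2, count_alt)
  g <- t(g)  # individuals x loci
  colnames(g) <- rownames(gt)
  if (length(stage) == 1) stage <- rep(stage, nrow(g))
  genotype_panel(g, stage = stage)
}
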