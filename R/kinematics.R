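#' A single sperm-cell track
#'
#' Time-ordered 2-D coordinates of one tracked cell, with the acquisition
#' metadata needed to convert to physical units: frame rate and the
#' micrometres-per-pixel calibration.
#'
#' @param x_px,y_px Numeric coordinate vectors (pixels), equal length.
#' @param fps Frame rate, frames/s (> 0).
#' @param um_per_px Spatial calibration, um/pixel (> 0).
#' @param cell_id Identifier.
#' @param t Optional absolute time stamps (s), strictly increasing; derived
#'   from the frame index and `fps` when absent.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(x_px, y_px, fps, um_per_px, cell_id = "cell",
                       t = NULL) {
  stopifnot(length(x_px) == length(y_px), length(x_px) >= 2,
            fps > 0, um_per_px > 0)
  if (is.null(t)) t <- (seq_along(x_px) - 1) / fps
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  structure(list(cell_id = cell_id, t = as.numeric(t),
                 x = as.numeric(x_px), y = as.numeric(y_px),
                 fps = fps, um_per_px = um_per_px),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track %s: %d frames @ %g fps, %g um/px>\n",
              x$cell_id, length(x$x), x$fps, x$um_per_px))
  invisible(x)
}

n_frames <- function(track) length(track$x)

#' Smooth a track with a centered moving average
#'
#' Applies a centered moving average of odd width to the x and y
#' coordinates. Endpoints use shrinking (still centered) windows, so no
#' data are invented beyond the track; `window = 1` is the identity.
#'
#' @param track A [cell_track()] or a 2-column coordinate matrix.
#' @param window Odd window width, `1 <= window <=` track length.
#' @return Object of the same kind with smoothed coordinates.
#' @export
smooth_path <- function(track, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  xy <- if (inherits(track, "cell_track")) cbind(track$x, track$y)
        else as.matrix(track)
  n <- nrow(xy)
  if (window > n) stop("window longer than track")
  if (window > 1) {
    half <- (window - 1) / 2
    cx <- rbind(0, apply(xy, 2, cumsum))
    sm <- xy
    for (i in seq_len(n)) {
      h <- min(half, i - 1, n - i)  # shrink at endpoints, stay centered
      sm[i, ] <- (cx[i + h + 1, ] - cx[i - h, ]) / (2 * h + 1)
    }
    xy <- sm
  }
  if (inherits(track, "cell_track")) {
    out <- track; out$x <- xy[, 1]; out$y <- xy[, 2]; out
  } else xy
}

path_length_px <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Smoothed average path velocity (VAPi)
#'
#' The classical average path velocity smooths the raw track once and
#' divides the smoothed path length by elapsed time; the VAPi variant for
#' low-framerate video adds a second smoothing pass. Both window widths are
#' configurable and reported in the result attributes.
#'
#' @param track A [cell_track()].
#' @param window_vap Odd window for the classical VAP smoothing pass.
#' @param window_extra Odd window for the extra VAPi pass.
#' @return VAPi in um/s, with attributes `window_vap`/`window_extra`.
#' @export
compute_vapi <- function(track, window_vap = 5, window_extra = 5) {
  stopifnot(inherits(track, "cell_track"))
  if (n_frames(track) < 2) stop("degenerate track: fewer than 2 frames")
  sm <- smooth_path(smooth_path(track, window_vap), window_extra)
  elapsed <- sm$t[length(sm$t)] - sm$t[1]
  v <- path_length_px(sm$x, sm$y) * track$um_per_px / elapsed
  structure(v, window_vap = window_vap, window_extra = window_extra)
}

#' Raw curvilinear velocity (VCL)
#'
#' Point-to-point path length over elapsed time, without smoothing; the
#' upper bound on any smoothed path velocity.
#'
#' @param track A [cell_track()].
#' @return VCL in um/s.
#' @export
compute_vcl <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  elapsed <- track$t[length(track$t)] - track$t[1]
  path_length_px(track$x, track$y) * track$um_per_px / elapsed
}

#' Track linearity (percent forward progression)
#'
#' The default definition is the standard CASA linearity LIN:
#' 100 x (straight-line distance from first to last point) / (total
#' point-to-point path length). `method = "STR"` instead reports
#' straightness, net displacement velocity over the smoothed path velocity.
#'
#' @param track A [cell_track()].
#' @param method `"LIN"` (default) or `"STR"`.
#' @param ... Passed to [compute_vapi()] when `method = "STR"`.
#' @return Percentage in [0, 100].
#' @export
compute_linearity <- function(track, method = c("LIN", "STR"), ...) {
  stopifnot(inherits(track, "cell_track"))
  method <- match.arg(method)
  n <- n_frames(track)
  if (n < 2) stop("need at least 2 frames")
  path <- path_length_px(track$x, track$y)
  if (path == 0) stop("zero path length: immobile cell")
  net <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  if (method == "LIN") {
    100 * net / path
  } else {
    elapsed <- track$t[n] - track$t[1]
    vsl <- net * track$um_per_px / elapsed
    min(100, 100 * vsl / compute_vapi(track, ...))
  }
}

#' Motility screen
#'
#' A cell is flagged immobile when its total path length falls below a
#' distance threshold (default 5 um).
#'
#' @param track A [cell_track()].
#' @param min_path_um Threshold, um.
#' @return Logical.
#' @export
is_motile <- function(track, min_path_um = 5) {
  path_length_px(track$x, track$y) * track$um_per_px >= min_path_um
}

#' Per-male kinematics summary
#'
#' Screens tracks for minimum length and motility, computes VAPi and
#' linearity per cell, and averages across cells. Males with fewer than
#' `required_cells` usable tracks are flagged for exclusion from downstream
#' selection analysis.
#'
#' @param tracks List of [cell_track()] objects from one male.
#' @param male_id Identifier.
#' @param required_cells Number of usable cells required (default 15).
#' @param min_frames Minimum frames per track (default 45).
#' @param window_vap,window_extra Smoothing windows for [compute_vapi()].
#' @param min_path_um Motility threshold for [is_motile()].
#' @param linearity_method Passed to [compute_linearity()].
#' @return A list of class `kinematics_summary`: `male_id`, `mean_vapi`,
#'   `mean_linearity`, `n_cells`, `excluded` flag and the `per_cell` table.
#' @export
summarize_male <- function(tracks, male_id = "male", required_cells = 15,
                           min_frames = 45, window_vap = 5,
                           window_extra = 5, min_path_um = 5,
                           linearity_method = "LIN") {
  if (length(tracks) == 0) stop("empty track list")
  ok <- vapply(tracks, function(tr) {
    n_frames(tr) >= min_frames && is_motile(tr, min_path_um)
  }, logical(1))
  kept <- tracks[ok]
  per_cell <- data.frame(
    cell_id = vapply(kept, `[[`, "", "cell_id"),
    vapi = vapply(kept, function(tr)
      as.numeric(compute_vapi(tr, window_vap, window_extra)), numeric(1)),
    linearity = vapply(kept, function(tr)
      compute_linearity(tr, method = linearity_method), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(
    male_id = male_id,
    mean_vapi = mean(per_cell$vapi),
    mean_linearity = mean(per_cell$linearity),
    n_cells = nrow(per_cell),
    excluded = nrow(per_cell) < required_cells,
    per_cell = per_cell,
    window_vap = window_vap, window_extra = window_extra),
    class = "kinematics_summary")
}

#' Scale a hemocytometer chamber count to a total sperm count
#'
#' @param chamber_count Cells counted in the chamber aliquot (>= 0).
#' @param chamber_volume Aliquot volume, uL.
#' @param total_volume Total suspension volume, uL.
#' @return Estimated total cells, `chamber_count * total_volume /
#'   chamber_volume`.
#' @export
scale_sperm_count <- function(chamber_count, chamber_volume = 10,
                              total_volume = 1000) {
  if (any(chamber_count < 0)) stop("negative count")
  if (chamber_volume <= 0 || total_volume <= 0) stop("volumes must be > 0")
  if (chamber_volume > total_volume) {
    stop("chamber volume exceeds total volume")
  }
  chamber_count * total_volume / chamber_volume
}

#' Bootstrap precision of per-male means at increasing cell numbers
#'
#' For each subsample size k, resamples k per-cell values with replacement
#' `n_sim` times per male, takes the SD of the bootstrap means, and averages
#' those SDs across males. Used to confirm that the number of cells measured
#' per male is enough to approach asymptotically low sampling variance.
#'
#' @param per_cell_values Named list; one numeric vector of per-cell values
#'   per male (each of length >= 2).
#' @param sizes Subsample sizes (default 2:15).
#' @param n_sim Bootstrap replicates per size (default 10000).
#' @param seed Integer seed.
#' @return Data frame with `size` and `mean_sd` (average bootstrap SD
#'   across males).
#' @export
resampling_precision <- function(per_cell_values, sizes = 2:15,
                                 n_sim = 10000, seed = 1L) {
  stopifnot(length(per_cell_values) >= 1,
            all(vapply(per_cell_values, length, 0L) >= 2))
  with_seed(seed, {
    out <- vapply(sizes, function(k) {
      sds <- vapply(per_cell_values, function(v) {
        bm <- colMeans(matrix(sample(v, k * n_sim, replace = TRUE),
                              nrow = k))
        sd(bm)
      }, numeric(1))
      mean(sds)
    }, numeric(1))
    data.frame(size = sizes, mean_sd = out)
  })
}
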