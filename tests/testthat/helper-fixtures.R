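# Small deterministic fixtures used across the test files.

straight_track <- function(v_px_s = 50, fps = 25, n = 51, um_per_px = 1,
                           angle = 0) {
  d <- (seq_len(n) - 1) * v_px_s / fps
  cell_track(d * cos(angle), d * sin(angle), fps = fps,
             um_per_px = um_per_px, cell_id = "straight")
}

circle_track <- function(radius = 20, fps = 25, n = 51, um_per_px = 1) {
  th <- seq(0, 2 * pi, length.out = n)  # returns exactly to the origin
  cell_track(radius * cos(th), radius * sin(th), fps = fps,
             um_per_px = um_per_px, cell_id = "circle")
}

right_angle_track <- function(leg = 30, fps = 25, per_leg = 25) {
  x <- c(seq(0, leg, length.out = per_leg + 1),
         rep(leg, per_leg))
  y <- c(rep(0, per_leg + 1), seq(0, leg, length.out = per_leg + 1)[-1])
  cell_track(x, y, fps = fps, um_per_px = 1, cell_id = "right_angle")
}

# A small genotype panel containing one true trio (error-free Mendelian
# child of dam F1 and sire M1) plus unrelated adults, at allele freq 0.5.
tiny_trio_panel <- function(n_loci = 60, n_extra = 8, seed = 11) {
  spermsel:::with_seed(seed, {
    p <- rep(0.5, n_loci)
    draw <- function(k) matrix(rbinom(k * n_loci, 2, 0.5), k, n_loci)
    sires <- draw(n_extra); dams <- draw(n_extra)
    transmit <- function(g) (g == 2) + (g == 1) * rbinom(length(g), 1, 0.5)
    off <- transmit(dams[1, ]) + transmit(sires[1, ])
    g <- rbind(sires, dams, off)
    rownames(g) <- c(paste0("M", seq_len(n_extra)),
                     paste0("F", seq_len(n_extra)), "O1")
    genotype_panel(g, stage = c(rep("adult_male", n_extra),
                                rep("adult_female", n_extra),
                                "offspring"))
  })
}

# Exact OLS solution through the normal equations; the independent oracle
# for every regression-based estimate.
normal_equations <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}
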