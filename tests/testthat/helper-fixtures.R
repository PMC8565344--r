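# shared fixtures, all built in code

# a track_set from a list of coordinate matrices (frames consecutive)
make_ts <- function(coords, dt = 0.04) {
  rows <- do.call(rbind, lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    data.frame(track_id = sprintf("t%02d", i), frame = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2])
  }))
  track_set(rows, dt = dt)
}

# analytic displacement sample: exact Rayleigh quantiles for one population
# (u = r^2 is Exp(4 D tau); deterministic plotting-position sample)
rayleigh_sample <- function(n, D, tau, seed = NULL) {
  p <- (seq_len(n) - 0.5) / n
  u <- -4 * D * tau * log(1 - p)
  r <- sqrt(u)
  th <- 2 * pi * p * 7.13 %% (2 * pi)  # deterministic spread of angles
  displacement_sample(r * cos(th), r * sin(th), tau)
}

# random two-population displacement sample drawn directly from the model
mixture_sample <- function(n, D, f, tau, seed, sigma = 0) {
  set.seed(seed)
  comp <- sample.int(length(D), n, replace = TRUE, prob = f)
  sd_ax <- sqrt(2 * D[comp] * tau + 2 * sigma^2)
  displacement_sample(rnorm(n, 0, sd_ax), rnorm(n, 0, sd_ax), tau)
}

# rectangular cell outline polygon (micrometre)
rect_cell <- function(cx = 0, cy = 0, length = 3, width = 1, id = "cell1") {
  cell_geometry(cbind(cx + c(-1, 1, 1, -1) * length / 2,
                      cy + c(-1, -1, 1, 1) * width / 2), cell_id = id)
}

# standardized uniform points in the 3 x 1 cell
uniform_std_points <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(x = runif(n, -1.5, 1.5), y = runif(n, -0.5, 0.5))
}

flat_profile <- function(n = 48) matrix(1, n, n)

# well-separated interior constellation in the centered 3 x 1 um cell:
# jittered 5 x 2 grid (spacing ~0.45 x 0.3 um), N <= 10
interior_constellation <- function(N, seed = 1) {
  stopifnot(N <= 10)
  g <- expand.grid(x = seq(1.65, 3.45, length.out = 5),
                   y = c(2.39, 2.69))
  set.seed(seed)
  idx <- sample.int(10, N)
  data.frame(x = g$x[idx] + runif(N, -0.04, 0.04),
             y = g$y[idx] + runif(N, -0.04, 0.04))
}
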