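# Synthetic generators: patchy marsh/water landscapes with a chlorophyll
# gradient, consumer isotope samples from a known mixing simplex, and GPS
# tracks from a known covariate-dependent 3-state HMM. Every downstream
# stage gets a parameter-recovery test from these, with no download.

HAB_LEVELS <- c("marsh", "water", "other")
HAB_MARSH <- 1L
HAB_WATER <- 2L
HAB_OTHER <- 3L

#' Synthetic landscape configuration
#'
#' @param width,height raster dimensions in cells (> 0).
#' @param cell_size cell edge (m); 10 m mirrors high-resolution coastal
#'   cover maps, coarser cells are used for movement-scale arenas.
#' @param marsh_fraction proportion of cells classed marsh, in `[0, 1]`.
#' @param other_fraction proportion classed "other" (upland cores carved
#'   from the highest ground of the same random field); default 0.
#' @param patch_scale Gaussian smoothing scale of the patch field, in
#'   cells; larger values give larger, smoother marsh patches.
#' @param chl_gradient range `(min, max)` of relative chlorophyll over
#'   the west-east axis, values in `(0, 1]`.
#' @param seed integer RNG seed; identical seeds give identical rasters.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(width = 200, height = 200, cell_size = 10,
                             marsh_fraction = 0.35, other_fraction = 0,
                             patch_scale = 6,
                             chl_gradient = c(0.25, 1), seed = 1L) {
  if (width < 1 || height < 1) stop("landscape dimensions must be positive")
  if (marsh_fraction < 0 || marsh_fraction > 1)
    stop("marsh_fraction must be in [0, 1]")
  if (other_fraction < 0 || marsh_fraction + other_fraction > 1)
    stop("marsh_fraction + other_fraction must be <= 1")
  if (any(chl_gradient <= 0) || any(chl_gradient > 1))
    stop("chl_gradient values must be in (0, 1]")
  if (is.null(seed)) stop("seed must be supplied")
  structure(list(width = as.integer(width), height = as.integer(height),
                 cell_size = cell_size, marsh_fraction = marsh_fraction,
                 other_fraction = other_fraction, patch_scale = patch_scale,
                 chl_gradient = chl_gradient, seed = as.integer(seed)),
            class = "landscape_config")
}

# separable Gaussian smoothing with edge replication
conv1d_rows <- function(m, k) {
  half <- (length(k) - 1L) / 2L
  nc <- ncol(m)
  padded <- cbind(m[, rep(1L, half), drop = FALSE], m,
                  m[, rep(nc, half), drop = FALSE])
  out <- matrix(0, nrow(m), nc)
  for (o in seq_along(k))
    out <- out + k[o] * padded[, o:(o + nc - 1L), drop = FALSE]
  out
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  t(conv1d_rows(t(conv1d_rows(m, k)), k))
}

#' Generate a synthetic habitat + chlorophyll landscape
#'
#' Marsh patches are the upper tail of a smoothed Gaussian random field
#' (thresholded by rank so class fractions are hit exactly); "other"
#' (upland) occupies the very highest ground inside marsh cores. Water
#' cells carry relative chlorophyll following a west-east gradient plus
#' smooth noise; non-water cells have missing chlorophyll.
#'
#' @param config a [landscape_config()].
#' @return list with `habitat` (integer-coded [grid_raster()], levels
#'   marsh/water/other) and `chl` (numeric [grid_raster()] in `(0, 1]`
#'   on water, `NA` elsewhere).
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width
  field <- gauss_smooth(matrix(stats::rnorm(h * w), h, w),
                        config$patch_scale)
  n <- h * w
  n_other <- round(config$other_fraction * n)
  n_marsh <- round(config$marsh_fraction * n)
  codes <- matrix(HAB_WATER, h, w)
  ord <- order(field, decreasing = TRUE)
  if (n_other > 0) codes[ord[seq_len(n_other)]] <- HAB_OTHER
  if (n_marsh > 0) codes[ord[n_other + seq_len(n_marsh)]] <- HAB_MARSH
  attr(codes, "levels") <- HAB_LEVELS
  habitat <- grid_raster(codes, cellsize = config$cell_size)

  g <- config$chl_gradient
  grad <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
  noise <- gauss_smooth(matrix(stats::rnorm(h * w, sd = 1), h, w),
                        config$patch_scale)
  noise <- noise / max(stats::sd(noise), 1e-12) * 0.08
  chl <- g[1] + (g[2] - g[1]) * grad + noise
  chl <- pmin(pmax(chl, 1e-3), 1)
  chl[codes != HAB_WATER] <- NA_real_
  list(habitat = habitat,
       chl = grid_raster(chl, cellsize = config$cell_size))
}

#' Ground-truth parameters for synthetic data
#'
#' Defaults mirror the study system: basal-source contributions
#' phytoplankton 0.68 / benthic algae 0.23 / marsh 0.09; selection
#' coefficient 1.0 on log(HRI); three movement states ordered by mean
#' step length — stationary (5.41 +- 5.05 m), foraging (1176 +- 1353 m),
#' traveling (5203 +- 2903 m) with von Mises turns (mu 0.42/-0.05/0.03,
#' kappa 0.07/0.89/1.62); transition slopes on log(HRI) of 0.41
#' (stationary -> foraging) and 1.02 (traveling -> foraging), others 0.
#'
#' @param source_props 3-simplex (phytoplankton, benthic, marsh).
#' @param ssf_beta selection coefficient on log(HRI).
#' @param step_mean,step_sd per-state gamma step-length mean/SD (m).
#' @param turn_mu,turn_kappa per-state von Mises parameters (rad).
#' @param trans_alpha,trans_beta 3x3 matrices of off-diagonal transition
#'   intercepts/slopes on log(HRI) (diagonal entries ignored).
#' @param colony_xy colony coordinates (m).
#' @return a `truth_params` list.
#' @export
truth_params <- function(source_props = c(phytoplankton = 0.68,
                                          benthic = 0.23, marsh = 0.09),
                         ssf_beta = 1.0,
                         step_mean = c(5.41, 1176, 5203),
                         step_sd = c(5.05, 1353, 2903),
                         turn_mu = c(0.42, -0.05, 0.03),
                         turn_kappa = c(0.07, 0.89, 1.62),
                         trans_alpha = matrix(c(0, -2.2, -2.2,
                                                -2.2, 0, -2.2,
                                                -2.2, -2.2, 0),
                                              3, 3, byrow = TRUE),
                         trans_beta = matrix(c(0, 0.41, 0,
                                               0, 0, 0,
                                               0, 1.02, 0),
                                             3, 3, byrow = TRUE),
                         colony_xy = c(0, 0)) {
  if (abs(sum(source_props) - 1) > 1e-9 || any(source_props < 0))
    stop("source_props must lie on the 3-simplex")
  if (any(step_mean <= 0) || any(step_sd <= 0))
    stop("gamma means and SDs must be > 0")
  if (any(turn_kappa < 0)) stop("kappa must be >= 0")
  structure(list(source_props = source_props, ssf_beta = ssf_beta,
                 step_mean = step_mean, step_sd = step_sd,
                 turn_mu = turn_mu, turn_kappa = turn_kappa,
                 trans_alpha = trans_alpha, trans_beta = trans_beta,
                 colony_xy = colony_xy),
            class = "truth_params")
}

#' Simulate consumer isotope samples from a known mixture
#'
#' Draws `n` consumer (delta13C, delta34S) pairs around the
#' concentration-weighted, TEF-corrected mixture mean of the sources
#' ([mixture_mean()]) with independent Gaussian noise per tracer.
#'
#' @param props 3-simplex of source proportions.
#' @param sources a [source_signature()].
#' @param tef a [tef()]; its means shift the sources into consumer space.
#' @param n number of samples (>= 1).
#' @param noise_sd per-tracer noise SD (per mil), length 2 or scalar.
#' @param seed RNG seed.
#' @return data.frame with columns `d13C`, `d34S`.
#' @export
simulate_isotopes <- function(props, sources, tef = tef_defaults(),
                              n = 4, noise_sd = c(0.5, 0.5), seed = 1L) {
  if (abs(sum(props) - 1) > 1e-9 || any(props < -1e-12))
    stop("props must lie on the 3-simplex")
  if (n < 1) stop("n must be >= 1")
  noise_sd <- rep(noise_sd, length.out = 2L)
  mu <- mixture_mean(props, sources, tef)
  set.seed(seed)
  data.frame(d13C = stats::rnorm(n, mu[1], noise_sd[1]),
             d34S = stats::rnorm(n, mu[2], noise_sd[2]))
}

# log(HRI) at a point, with missing/zero HRI imputed as the landscape
# average (log 1 = 0) so simulation never stalls off-grid.
loghri_at <- function(escape, x, y) {
  h <- as.numeric(sample_hri(escape, x, y))
  lh <- ifelse(is.finite(h) & h > 0, log(h), 0)
  lh
}

realized_transition <- function(truth, loghri) {
  eta <- truth$trans_alpha + truth$trans_beta * loghri
  diag(eta) <- 0
  p <- exp(eta - apply(eta, 1L, max))
  p / rowSums(p)
}

stationary_dist <- function(P) {
  A <- rbind(t(diag(3) - P), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_hat <- tryCatch(as.numeric(stats::lm.fit(A, b)$coefficients),
                     error = function(e) rep(1 / 3, 3))
  if (any(!is.finite(pi_hat)) || any(pi_hat < -1e-8)) pi_hat <- rep(1 / 3, 3)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}

# one state-machine step: sample state, length, turn; redirect heading
# toward `home` when `force_home` (length still state-distributed).
sim_step <- function(truth, state_prev, heading, x, y, escape,
                     force_home = FALSE, home = c(0, 0),
                     home_travel = FALSE) {
  lh <- loghri_at(escape, x, y)
  P <- realized_transition(truth, lh)
  state <- sample.int(3L, 1L, prob = P[state_prev, ])
  len_state <- if (force_home && home_travel)
    which.max(truth$step_mean) else state
  len <- stats::rgamma(1, shape = (truth$step_mean[len_state] /
                                     truth$step_sd[len_state])^2,
                       scale = truth$step_sd[len_state]^2 /
                         truth$step_mean[len_state])
  if (force_home) {
    # homeward drift with angular noise (an exact homeward heading would
    # put a point mass at turn = 0, which no continuous turn model has)
    new_heading <- wrap_angle(atan2(home[2] - y, home[1] - x) +
                                rvonmises(1, 0, 4))
    if (home_travel)
      len <- min(len, sqrt((home[1] - x)^2 + (home[2] - y)^2))
  } else {
    new_heading <- wrap_angle(heading +
                                rvonmises(1, truth$turn_mu[state],
                                          truth$turn_kappa[state]))
  }
  list(state = state, len = len, heading = new_heading, loghri = lh,
       x = x + len * cos(new_heading), y = y + len * sin(new_heading))
}

#' Simulate step series from the covariate-dependent HMM
#'
#' Free-ranging tracks (no colony anchoring): states evolve by the
#' multinomial-logit transition matrix evaluated at log(HRI) of the
#' current location, step lengths are gamma and turns von Mises per
#' state. A soft homing rule steers headings back toward the arena
#' center when a track drifts beyond `max_range`, keeping tracks on the
#' mapped landscape. The true state sequence is returned for decoding
#' accuracy checks.
#'
#' @param escape an [compute_hri()] result covering the arena.
#' @param truth a [truth_params()].
#' @param n_tracks,steps_per_track series dimensions.
#' @param max_range soft arena radius (m); default 40% of the shorter
#'   extent.
#' @param seed RNG seed.
#' @return data.frame: `track`, `step`, `x1,y1,x2,y2`, `sl`, `turn`
#'   (`NA` on each track's first step), `loghri` (at step start),
#'   `state` (true state, 1 = shortest-step state).
#' @export
simulate_hmm_steps <- function(escape, truth, n_tracks = 30,
                               steps_per_track = 200, max_range = NULL,
                               seed = 1L) {
  ext <- raster_extent(escape$hri)
  cx <- mean(ext[c("xmin", "xmax")]); cy <- mean(ext[c("ymin", "ymax")])
  if (is.null(max_range))
    max_range <- 0.4 * min(diff(ext[c("xmin", "xmax")]),
                           diff(ext[c("ymin", "ymax")]))
  set.seed(seed)
  out <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    x <- stats::runif(1, cx - max_range / 2, cx + max_range / 2)
    y <- stats::runif(1, cy - max_range / 2, cy + max_range / 2)
    heading <- stats::runif(1, -pi, pi)
    lh0 <- loghri_at(escape, x, y)
    state <- sample.int(3L, 1L,
                        prob = stationary_dist(realized_transition(truth,
                                                                   lh0)))
    rec <- matrix(NA_real_, steps_per_track, 9L)
    prev_heading <- heading
    for (t in seq_len(steps_per_track)) {
      far <- sqrt((x - cx)^2 + (y - cy)^2) > max_range
      st <- sim_step(truth, state, prev_heading, x, y, escape,
                     force_home = far, home = c(cx, cy))
      turn <- if (t == 1L) NA_real_ else
        wrap_angle(st$heading - prev_heading)
      rec[t, ] <- c(t, x, y, st$x, st$y, st$len, turn, st$loghri, st$state)
      x <- st$x; y <- st$y
      prev_heading <- st$heading
      state <- st$state
    }
    out[[tr]] <- data.frame(track = tr, step = rec[, 1], x1 = rec[, 2],
                            y1 = rec[, 3], x2 = rec[, 4], y2 = rec[, 5],
                            sl = rec[, 6], turn = rec[, 7],
                            loghri = rec[, 8], state = as.integer(rec[, 9]))
  }
  do.call(rbind, out)
}

#' Simulate observed steps under the step-selection model
#'
#' Independent strata for selection-coefficient recovery: start points
#' and previous headings are uniform over the arena interior, and each
#' observed step is drawn exactly from the density proportional to
#' `kernel(step) * exp(beta * log(HRI at endpoint))` by rejection
#' sampling (the bound uses the landscape-wide maximum of
#' `beta * log(HRI)`). Endpoints off the mapped landscape are treated as
#' unavailable.
#'
#' @param escape an [compute_hri()] result.
#' @param kernel list with `shape`, `scale` (gamma, m) and `mu`,
#'   `kappa` (von Mises).
#' @param beta selection coefficient on log(HRI); 0 gives the null.
#' @param n number of strata.
#' @param margin fraction of the extent kept clear of the boundary for
#'   start points.
#' @param seed RNG seed.
#' @return step data.frame compatible with [make_controls()] (`stratum`,
#'   `x1,y1,x2,y2`, `sl`, `turn`, `heading`, `bird_id`).
#' @export
simulate_ssf_steps <- function(escape, kernel, beta = 1, n = 1000,
                               margin = 0.25, seed = 1L) {
  ext <- raster_extent(escape$hri)
  v <- escape$hri$values
  lhv <- log(v[is.finite(v) & v > 0])
  if (!length(lhv)) stop("escape has no positive HRI cells")
  bound <- max(beta * lhv)
  set.seed(seed)
  dx <- ext["xmax"] - ext["xmin"]; dy <- ext["ymax"] - ext["ymin"]
  x1 <- stats::runif(n, ext["xmin"] + margin * dx,
                     ext["xmax"] - margin * dx)
  y1 <- stats::runif(n, ext["ymin"] + margin * dy,
                     ext["ymax"] - margin * dy)
  h_prev <- stats::runif(n, -pi, pi)
  sl <- turn <- x2 <- y2 <- rep(NA_real_, n)
  filled <- logical(n)
  while (any(!filled)) {
    idx <- which(!filled)
    m <- length(idx)
    len <- stats::rgamma(m, shape = kernel$shape, scale = kernel$scale)
    tr <- rvonmises(m, kernel$mu, kernel$kappa)
    hd <- h_prev[idx] + tr
    ex <- x1[idx] + len * cos(hd)
    ey <- y1[idx] + len * sin(hd)
    h <- as.numeric(sample_hri(escape, ex, ey))
    lh <- ifelse(is.finite(h) & h > 0, log(h), NA_real_)
    acc <- !is.na(lh) & stats::runif(m) < exp(beta * lh - bound)
    w <- idx[acc]
    sl[w] <- len[acc]
    turn[w] <- wrap_angle(tr[acc])
    x2[w] <- ex[acc]
    y2[w] <- ey[acc]
    filled[w] <- TRUE
  }
  data.frame(stratum = seq_len(n), bird_id = "sim",
             x1 = x1, y1 = y1, x2 = x2, y2 = y2, sl = sl, turn = turn,
             heading = wrap_angle(h_prev + turn))
}

#' Simulate colony-anchored GPS trajectories
#'
#' Birds start each day at the colony, move under the covariate-dependent
#' HMM of [simulate_hmm_steps()], and are steered home near day end (a
#' forced return, so same-day complete trips exist for segmentation).
#' Fixes are emitted every `dt` seconds inside a fixed daylight window.
#'
#' @param escape an [compute_hri()] result; colony must lie inside it.
#' @param truth a [truth_params()].
#' @param n_birds,n_days trajectory dimensions.
#' @param dt fix interval (s); default 900 (15 min).
#' @param day_steps fixes per daylight window; default 48 (12 h).
#' @param start_date first day (Date or string).
#' @param seed RNG seed.
#' @return data.frame: `bird_id`, `timestamp` (POSIXct UTC), `x`, `y`,
#'   with true states per fix in attribute `states`.
#' @export
simulate_tracks <- function(escape, truth, n_birds = 5, n_days = 3,
                            dt = 900, day_steps = 48,
                            start_date = "2019-05-01", max_range = NULL,
                            seed = 1L) {
  ext <- raster_extent(escape$hri)
  if (is.null(max_range))
    max_range <- 0.35 * min(diff(ext[c("xmin", "xmax")]),
                            diff(ext[c("ymin", "ymax")]))
  col_xy <- truth$colony_xy
  if (col_xy[1] < ext["xmin"] || col_xy[1] >= ext["xmax"] ||
      col_xy[2] < ext["ymin"] || col_xy[2] >= ext["ymax"])
    stop("colony lies outside the landscape extent")
  set.seed(seed)
  t0 <- as.POSIXct(paste(as.Date(start_date), "07:00:00"), tz = "UTC")
  mean_travel <- max(truth$step_mean)
  rows <- list()
  for (b in seq_len(n_birds)) {
    for (d in seq_len(n_days)) {
      x <- col_xy[1]; y <- col_xy[2]
      heading <- stats::runif(1, -pi, pi)
      lh0 <- loghri_at(escape, x, y)
      state <- sample.int(3L, 1L,
                          prob = stationary_dist(realized_transition(truth,
                                                                     lh0)))
      day_origin <- t0 + (d - 1) * 86400
      xs <- numeric(day_steps + 1L); ys <- numeric(day_steps + 1L)
      sts <- integer(day_steps + 1L)
      xs[1] <- x; ys[1] <- y; sts[1] <- state
      for (t in seq_len(day_steps)) {
        remaining <- day_steps - t
        dist_home <- sqrt((x - col_xy[1])^2 + (y - col_xy[2])^2)
        go_home <- dist_home > 0.6 * remaining * mean_travel
        st <- sim_step(truth, state, heading, x, y, escape,
                       force_home = go_home || dist_home > max_range,
                       home = col_xy, home_travel = go_home)
        x <- st$x; y <- st$y
        heading <- st$heading
        state <- st$state
        xs[t + 1L] <- x; ys[t + 1L] <- y; sts[t + 1L] <- state
      }
      rows[[length(rows) + 1L]] <-
        data.frame(bird_id = sprintf("bird%02d", b),
                   timestamp = day_origin + dt * (0:day_steps),
                   x = xs, y = ys, state = sts)
    }
  }
  traj <- do.call(rbind, rows)
  out <- traj[, c("bird_id", "timestamp", "x", "y")]
  attr(out, "states") <- traj$state
  out
}
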