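# Synthetic experiments: biased persistent random-walk trajectories coupled to
# the simulated chemoattractant gradient, and noisy gray-level series.
#
# Mover velocities follow a first-order autoregressive ("persistent") update
#   v(t+dt) = alpha * v(t) + (1 - alpha) * (drift(t) * ghat + s * eta)
# with spherical standard-normal noise eta, so alpha in [0, 1) sets the
# direction memory and s the speed scale. The drift magnitude is
#   baseline_drift + chemotactic_coupling * |d(C/C0)/dy| * envelope(t)
# evaluated at the cell's current distance from the membrane: cells feel
# nothing until the diffusing front reaches them, and the optional exponential
# envelope phenomenologically reproduces the transient (receptor-saturation
# -like) decay of the response. Non-movers jitter around an anchor point with
# sub-diameter amplitude, emulating stage repositioning error.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of the synthetic biased persistent random walk
#'
#' Defaults describe the emulated neutrophil/IL-8 experiment: ~70 cells
#' imaged once a minute for 110 min, chemoattractant added at 30 min,
#' gradient toward negative y, a motile subpopulation that grows after
#' stimulation, basal mover speed 0.65 um/min rising to a scale that puts
#' stimulated movers in the 2-7 um/min band.
#'
#' @param n_cells Number of cells.
#' @param duration_min Experiment duration, minutes.
#' @param frame_interval_min Acquisition interval, minutes.
#' @param t_stimulus_min Chemoattractant addition time, minutes.
#' @param motile_fraction_pre,motile_fraction_post Probability a cell is a
#'   mover before / after the stimulus.
#' @param speed_scale_pre,speed_scale_post Mover speed scale s, um/min.
#' @param persistence Direction-memory coefficient alpha in [0, 1).
#' @param chemotactic_coupling Drift per unit normalized gradient,
#'   um/min per (1/mm); drift = coupling * |d(C/C0)/dy| at the cell.
#' @param baseline_drift Constant drift toward the source, um/min, active
#'   for the whole experiment (models a pre-existing bias; 0 by default).
#' @param transient_tau_min Decay time of the exponential envelope on the
#'   chemotactic coupling, minutes; `Inf` (default) disables the decay.
#' @param jitter_sd Positional jitter of non-movers, um.
#' @param redraw_at_stimulus Redraw mover status at the stimulus
#'   (Bernoulli with `motile_fraction_post`)? Default TRUE, reproducing
#'   the observed rise in motile fraction.
#' @param y_center_mm Centre of the imaging volume, mm from the membrane.
#' @param volume_um Imaging volume extents (x, y, z), um; cells start
#'   uniformly inside it.
#' @param diameter_um Cell diameter, um.
#' @param seed RNG seed; all randomness in [simulate_tracks()] flows from
#'   it.
#' @return Object of class `walk_params`.
#' @export
walk_params <- function(n_cells = 70, duration_min = 110,
                        frame_interval_min = 1, t_stimulus_min = 30,
                        motile_fraction_pre = 0.2, motile_fraction_post = 0.6,
                        speed_scale_pre = 0.65, speed_scale_post = 3,
                        persistence = 0.5, chemotactic_coupling = 20,
                        baseline_drift = 0, transient_tau_min = Inf,
                        jitter_sd = 0.3, redraw_at_stimulus = TRUE,
                        y_center_mm = 2, volume_um = c(1000, 1000, 100),
                        diameter_um = 10, seed = 1) {
  stopifnot(n_cells >= 1, duration_min > t_stimulus_min, t_stimulus_min >= 0,
            frame_interval_min > 0,
            motile_fraction_pre >= 0, motile_fraction_pre <= 1,
            motile_fraction_post >= 0, motile_fraction_post <= 1,
            speed_scale_pre >= 0, speed_scale_post >= 0,
            persistence >= 0, persistence < 1,
            chemotactic_coupling >= 0, baseline_drift >= 0,
            transient_tau_min > 0, jitter_sd >= 0,
            y_center_mm > 0, length(volume_um) == 3, all(volume_um > 0),
            diameter_um > 0)
  structure(as.list(environment()), class = "walk_params")
}

# |d(C/C0)/dy| (1/mm) at distance y_mm, t_el seconds after chemoattractant
# addition; `field` may be NULL (closed form), a concentration_field, or a
# single number (fixed gradient magnitude)
.gradient_magnitude <- function(field, diffusion, y_mm, t_el_s) {
  if (t_el_s <= 0) return(rep(0, length(y_mm)))
  y <- pmax(y_mm, 0)
  if (is.null(field)) {
    abs(gradient_profile(y, t_el_s, diffusion))
  } else if (inherits(field, "concentration_field")) {
    abs(eval_field_gradient(field, y, t_el_s))
  } else if (is.numeric(field) && length(field) == 1L) {
    rep(abs(field), length(y))
  } else stop("field must be NULL, a concentration_field, or a single number")
}

#' Simulate a synthetic tracking experiment
#'
#' Generates mover and non-mover trajectories under the biased persistent
#' random walk described in [walk_params()], coupled to a chemoattractant
#' gradient. Cells are seeded uniformly in the imaging volume centred
#' `y_center_mm` from the membrane; the gradient a mover feels is
#' evaluated at its own current distance from the membrane at each frame,
#' so the chemotactic drift switches on only once the diffusing front
#' arrives there. Fully reproducible from `params$seed`.
#'
#' @param params A [walk_params()] object.
#' @param field Gradient source: `NULL` (default) uses the closed-form
#'   semi-infinite profile with `diffusion`; a `concentration_field` from
#'   [solve_chamber_1d()] uses its stored gradient; a single number
#'   imposes that fixed gradient magnitude (1/mm) after the stimulus.
#' @param diffusion [diffusion_params()] used when `field` is `NULL`.
#' @return Object of class `synthetic_experiment`: `tracks` (a
#'   [track_set()]), `params`, and `ground_truth` (per-cell mover flags
#'   pre/post, speed scales, and the per-frame drift magnitude applied to
#'   each cell).
#' @export
simulate_tracks <- function(params, field = NULL,
                            diffusion = diffusion_params()) {
  stopifnot(inherits(params, "walk_params"))
  p <- params
  if (p$y_center_mm * 1000 - p$volume_um[2] / 2 < 0)
    stop("imaging volume extends past the membrane; increase y_center_mm")
  .with_seed(p$seed, {
    n <- p$n_cells
    dt <- p$frame_interval_min
    t_frames <- seq(0, p$duration_min, by = dt)
    K <- length(t_frames)
    ghat <- c(0, -1, 0)

    mover_pre <- stats::runif(n) < p$motile_fraction_pre
    mover_post <- if (p$redraw_at_stimulus)
      stats::runif(n) < p$motile_fraction_post else mover_pre

    pos <- cbind(
      stats::runif(n, -p$volume_um[1] / 2, p$volume_um[1] / 2),
      stats::runif(n, p$y_center_mm * 1000 - p$volume_um[2] / 2,
                   p$y_center_mm * 1000 + p$volume_um[2] / 2),
      stats::runif(n, -p$volume_um[3] / 2, p$volume_um[3] / 2))
    anchor <- pos
    # stationary AR(1) per-axis sd is s * sqrt((1-a)/(1+a))
    sd0 <- p$speed_scale_pre * sqrt((1 - p$persistence) / (1 + p$persistence))
    v <- matrix(stats::rnorm(3 * n, sd = max(sd0, 1e-12)), n, 3)
    v <- v + matrix(p$baseline_drift * ghat, n, 3, byrow = TRUE)

    X <- array(NA_real_, c(K, n, 3))
    X[1, , ] <- pos
    drift_applied <- matrix(0, K, n)
    was_post <- FALSE

    for (k in 2:K) {
      tk <- t_frames[k]
      post <- tk > p$t_stimulus_min
      s <- if (post) p$speed_scale_post else p$speed_scale_pre
      mover <- if (post) mover_post else mover_pre
      if (post && !was_post) {
        # stimulus transition: re-anchor demoted cells, re-init promoted ones
        demoted <- mover_pre & !mover_post
        promoted <- !mover_pre & mover_post
        anchor[demoted, ] <- pos[demoted, ]
        sd1 <- p$speed_scale_post *
          sqrt((1 - p$persistence) / (1 + p$persistence))
        v[promoted, ] <- matrix(stats::rnorm(3 * sum(promoted),
                                             sd = max(sd1, 1e-12)),
                                sum(promoted), 3)
        was_post <- TRUE
      }
      y_mm <- pos[, 2] / 1000
      g <- if (post)
        .gradient_magnitude(field, diffusion, y_mm,
                            (tk - p$t_stimulus_min) * 60) else rep(0, n)
      env <- if (post && is.finite(p$transient_tau_min))
        exp(-(tk - p$t_stimulus_min) / p$transient_tau_min) else 1
      drift <- p$baseline_drift + p$chemotactic_coupling * g * env
      drift_applied[k, ] <- drift * mover

      eta <- matrix(stats::rnorm(3 * n), n, 3)
      v <- p$persistence * v +
        (1 - p$persistence) * (outer(drift, ghat) + s * eta)
      pos[mover, ] <- pos[mover, ] + v[mover, , drop = FALSE] * dt
      jit <- matrix(stats::rnorm(3 * n, sd = p$jitter_sd), n, 3)
      pos[!mover, ] <- anchor[!mover, , drop = FALSE] +
        jit[!mover, , drop = FALSE]
      X[k, , ] <- pos
    }

    tr <- data.frame(
      cell_id = rep(sprintf("cell%03d", seq_len(n)), each = K),
      t_min = rep(t_frames, n),
      x_um = as.vector(X[, , 1]), y_um = as.vector(X[, , 2]),
      z_um = as.vector(X[, , 3]),
      diameter_um = p$diameter_um)
    tracks <- track_set(tr, t_stimulus = p$t_stimulus_min,
                        gradient_dir = ghat, frame_interval = dt)
    structure(list(
      tracks = tracks, params = p,
      ground_truth = list(
        cell_id = sprintf("cell%03d", seq_len(n)),
        mover_pre = mover_pre, mover_post = mover_post,
        speed_scale_pre = p$speed_scale_pre,
        speed_scale_post = p$speed_scale_post,
        drift_um_min = drift_applied, t_frames = t_frames)),
      class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic experiment: %d cells, %g min, stimulus at %g min (seed %d)\n",
    x$params$n_cells, x$params$duration_min, x$params$t_stimulus_min,
    x$params$seed))
  invisible(x)
}

#' Simulate noisy gray-level time series
#'
#' Converts a simulated concentration field to epifluorescence mean gray
#' levels at fixed distances from the membrane via a calibration line and
#' additive Gaussian detector noise:
#' gray(y, t) = slope * C0 * C_norm(y, t) + intercept + N(0, noise_sd).
#'
#' @param curve A [fit_calibration()] curve (or compatible list with
#'   `slope` and `intercept`).
#' @param field A `concentration_field`.
#' @param positions_mm Measurement distances from the membrane, mm;
#'   default 2-5 mm at 1 mm spacing, the imaged range.
#' @param noise_sd Gray-level noise SD (>= 0).
#' @param C0 Reservoir concentration in calibration units; defaults to
#'   the field's `params$C0`.
#' @param t_s Sampling times, s; defaults to the field's stored times.
#' @param seed RNG seed.
#' @return Data frame with `y_mm`, `t_s`, `gray_level`, `c_norm_true`.
#' @export
simulate_gray_series <- function(curve, field, positions_mm = c(2, 3, 4, 5),
                                 noise_sd = 1, C0 = field$params$C0,
                                 t_s = field$t_s, seed = 1) {
  stopifnot(inherits(field, "concentration_field"), noise_sd >= 0)
  if (any(positions_mm < min(field$y_mm)) || any(positions_mm > max(field$y_mm)))
    stop("positions_mm outside the field's spatial range")
  grid <- expand.grid(y_mm = positions_mm, t_s = t_s)
  cn <- eval_field(field, grid$y_mm, grid$t_s)
  .with_seed(seed, {
    gray <- curve$slope * C0 * cn + curve$intercept +
      stats::rnorm(nrow(grid), sd = noise_sd)
    data.frame(y_mm = grid$y_mm, t_s = grid$t_s, gray_level = gray,
               c_norm_true = cn)
  })
}

#' Convert a gray-level series to normalized-concentration observations
#'
#' Inverts the calibration and normalizes by `C0`, producing the
#' observation table [fit_diffusion_coefficient()] expects.
#'
#' @param series Output of [simulate_gray_series()] (or measured data
#'   with `y_mm`, `t_s`, `gray_level`).
#' @param curve The calibration curve.
#' @param C0 Reservoir concentration in calibration units.
#' @return Data frame with `y_mm`, `t_s`, `c_norm`.
#' @export
gray_series_to_observations <- function(series, curve, C0) {
  conc <- suppressWarnings(gray_to_concentration(curve, series$gray_level))
  data.frame(y_mm = series$y_mm, t_s = series$t_s,
             c_norm = as.numeric(conc) / C0)
}

#' Packaged fixture experiments
#'
#' Deterministic synthetic experiments qualitatively matching the assay's
#' observed population behaviours. `"donorA-like"`: low basal motility,
#' basal chemotactic index near 0, sustained directed response after the
#' stimulus. `"donorB-like"`: higher basal motility with a pre-existing
#' directional bias (index near 0.25, reproduced by an explicit baseline
#' drift — a modelling choice, not a mechanism claim) and a transient
#' response that decays back toward baseline. `"isotropic"`: no stimulus
#' response at all (control).
#'
#' @param profile `"donorA-like"`, `"donorB-like"` or `"isotropic"`.
#' @param seed RNG seed.
#' @return A `synthetic_experiment` (see [simulate_tracks()]).
#' @export
make_fixture_experiment <- function(profile = c("donorA-like", "donorB-like",
                                                "isotropic"), seed = 1) {
  profile <- match.arg(profile)
  p <- switch(profile,
    "donorA-like" = walk_params(
      motile_fraction_pre = 0.15, motile_fraction_post = 0.6,
      speed_scale_pre = 0.65, speed_scale_post = 3,
      chemotactic_coupling = 20, transient_tau_min = Inf, seed = seed),
    "donorB-like" = walk_params(
      motile_fraction_pre = 0.4, motile_fraction_post = 0.7,
      speed_scale_pre = 1.7, speed_scale_post = 3.5,
      chemotactic_coupling = 600, baseline_drift = 0.5,
      transient_tau_min = 12, seed = seed),
    "isotropic" = walk_params(
      motile_fraction_pre = 0.3, motile_fraction_post = 0.3,
      speed_scale_pre = 1.5, speed_scale_post = 1.5,
      chemotactic_coupling = 0, redraw_at_stimulus = FALSE, seed = seed))
  simulate_tracks(p)
}
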