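# Cell-trajectory motility statistics.
#
# Trajectories live in a long data frame (one row per cell per frame) inside a
# `track_set` that also carries the experiment metadata: stimulus time,
# gradient direction and nominal frame interval. Times are minutes, positions
# micrometres. Time bins are half-open [start, end); the cumulative
# chemotactic index and window displacements use closed intervals so that a
# bin's right edge sample closes the preceding displacement.

#' Construct a track set
#'
#' @param tracks Data frame with columns `cell_id`, `t_min`, `x_um`,
#'   `y_um`, and optionally `z_um` (default 0) and `diameter_um`
#'   (default `default_diameter`). One row per cell per frame; time must
#'   be strictly increasing within each cell.
#' @param t_stimulus Stimulus (chemoattractant addition) time, minutes.
#'   Default 30: the chemoattractant is added 30 min into acquisition so
#'   each cell serves as its own unstimulated control.
#' @param gradient_dir Length-3 vector pointing toward the chemoattractant
#'   source; normalized internally. Default (0, -1, 0): the membrane is at
#'   the negative-y side of the imaging frame.
#' @param frame_interval Nominal acquisition interval, minutes (default 1).
#' @param default_diameter Diameter assigned to cells lacking one, um
#'   (default 10, a typical neutrophil).
#' @return Object of class `track_set`.
#' @export
track_set <- function(tracks, t_stimulus = 30, gradient_dir = c(0, -1, 0),
                      frame_interval = 1, default_diameter = 10) {
  tr <- as.data.frame(tracks)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("tracks is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"z_um" %in% names(tr)) tr$z_um <- rep(0, nrow(tr))
  if (!"diameter_um" %in% names(tr))
    tr$diameter_um <- rep(default_diameter, nrow(tr))
  tr$diameter_um[is.na(tr$diameter_um)] <- default_diameter
  if (any(tr$diameter_um <= 0)) stop("diameter_um must be positive")
  stopifnot(length(gradient_dir) == 3, t_stimulus >= 0, frame_interval > 0)
  nrm <- sqrt(sum(gradient_dir^2))
  if (nrm == 0) stop("gradient_dir must be a nonzero vector")
  # validate in the order the rows arrived: a decreasing timestamp is a
  # data defect, not something to be silently repaired by sorting
  if (nrow(tr)) {
    for (cid in unique(tr$cell_id)) {
      tt <- tr$t_min[tr$cell_id == cid]
      if (anyDuplicated(tt))
        stop(sprintf("duplicate (cell_id, t) pair for cell '%s'", cid))
      if (is.unsorted(tt, strictly = TRUE))
        stop(sprintf("time is not strictly increasing for cell '%s'", cid))
    }
  }
  tr <- tr[order(tr$cell_id, tr$t_min), , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(tracks = tr, t_stimulus = t_stimulus,
                 gradient_dir = gradient_dir / nrm,
                 frame_interval = frame_interval),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(unique(x$tracks$cell_id))
  cat(sprintf(
    "Track set: %d cells, %d samples, t in [%g, %g] min, stimulus at %g min\n",
    n, nrow(x$tracks),
    if (nrow(x$tracks)) min(x$tracks$t_min) else NA,
    if (nrow(x$tracks)) max(x$tracks$t_min) else NA, x$t_stimulus))
  invisible(x)
}

.proj_cols <- function(projection) {
  switch(projection, xy = c("x_um", "y_um"), xyz = c("x_um", "y_um", "z_um"),
         stop("projection must be 'xy' or 'xyz'"))
}

.traj_window <- function(traj, t_from, t_to)
  traj[traj$t_min >= t_from & traj$t_min <= t_to, , drop = FALSE]

#' Curvilinear length of a trajectory
#'
#' Sum of successive inter-sample Euclidean distances inside the closed
#' time window `[t_from, t_to]`. At the acquisition resolution this is the
#' measured path length; it always bounds the straight-line displacement
#' from above, and coarser sampling can only shorten it.
#'
#' @param traj Data frame for a single cell (`t_min`, `x_um`, `y_um`,
#'   `z_um`).
#' @param t_from,t_to Window bounds, minutes (defaults: whole trajectory).
#' @param projection `"xy"` (default: z is coarsely sampled in this assay)
#'   or `"xyz"`.
#' @return Length in um. Windows holding fewer than 2 samples return 0
#'   with attribute `too_few_samples = TRUE`.
#' @export
curvilinear_length <- function(traj, t_from = -Inf, t_to = Inf,
                               projection = c("xy", "xyz")) {
  projection <- match.arg(projection)
  w <- .traj_window(as.data.frame(traj), t_from, t_to)
  if (nrow(w) < 2) {
    out <- 0
    attr(out, "too_few_samples") <- TRUE
    return(out)
  }
  cols <- .proj_cols(projection)
  d2 <- 0
  for (cl in cols) d2 <- d2 + diff(w[[cl]])^2
  sum(sqrt(d2))
}

#' Chemotactic index of one cell
#'
#' Ratio of the net displacement component along the gradient direction to
#' the curvilinear length of the trajectory over the window: +1 for a
#' straight path toward the source, -1 straight away, ~0 for random
#' motion. The curvilinear length doubles as the cell's weight in the
#' population average.
#'
#' @inheritParams curvilinear_length
#' @param gradient_dir Unit vector toward the chemoattractant source.
#' @return List with `index` (in [-1, 1], NA when the path length is 0)
#'   and `weight` (the curvilinear length; 0 excludes the cell).
#' @export
chemotactic_index_cell <- function(traj, gradient_dir = c(0, -1, 0),
                                   t_from = -Inf, t_to = Inf,
                                   projection = c("xy", "xyz")) {
  projection <- match.arg(projection)
  gradient_dir <- gradient_dir / sqrt(sum(gradient_dir^2))
  w <- .traj_window(as.data.frame(traj), t_from, t_to)
  L <- curvilinear_length(w, projection = projection)
  if (L == 0) return(list(index = NA_real_, weight = 0))
  cols <- .proj_cols(projection)
  g <- gradient_dir[match(cols, c("x_um", "y_um", "z_um"))]
  net <- vapply(cols, function(cl) w[[cl]][nrow(w)] - w[[cl]][1], numeric(1))
  list(index = sum(net * g) / L, weight = as.numeric(L))
}

#' Cumulative population chemotactic index
#'
#' Length-weighted mean of per-cell chemotactic indices computed from
#' `t_origin` (the start of the experiment by default) up to `t_eval`:
#' I(t) = sum_i I_i L_i / sum_i L_i over cells with positive path length.
#' Weighting by curvilinear length lets actively moving cells dominate,
#' so a largely stationary subpopulation does not dilute the index.
#'
#' @param tracks A [track_set()].
#' @param t_eval Evaluation time, minutes.
#' @param t_origin Start of the accumulation window (default 0).
#' @param projection `"xy"` or `"xyz"`.
#' @return The population index (NA with a warning when every cell is
#'   stationary), with attributes `n_cells` (contributing cells) and
#'   `total_length`.
#' @export
chemotactic_index_population <- function(tracks, t_eval, t_origin = 0,
                                         projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"), t_eval > t_origin)
  projection <- match.arg(projection)
  per <- lapply(split(tracks$tracks, tracks$tracks$cell_id),
                chemotactic_index_cell, gradient_dir = tracks$gradient_dir,
                t_from = t_origin, t_to = t_eval, projection = projection)
  wts <- vapply(per, `[[`, numeric(1), "weight")
  idx <- vapply(per, `[[`, numeric(1), "index")
  keep <- wts > 0
  if (!any(keep)) {
    warning("all cells stationary in the window; chemotactic index undefined")
    out <- NA_real_
  } else {
    out <- sum(idx[keep] * wts[keep]) / sum(wts[keep])
  }
  attr(out, "n_cells") <- sum(keep)
  attr(out, "total_length") <- sum(wts)
  out
}

#' Cumulative chemotactic index time series
#'
#' [chemotactic_index_population()] evaluated at regular steps (5 min by
#' default, the assay's reporting resolution).
#'
#' @inheritParams chemotactic_index_population
#' @param step Evaluation step, minutes.
#' @return Data frame with `t_min`, `ci`, `n_cells`.
#' @export
chemotactic_index_series <- function(tracks, step = 5, t_origin = 0,
                                     projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"))
  projection <- match.arg(projection)
  t_max <- max(tracks$tracks$t_min)
  t_eval <- seq(t_origin + step, t_max, by = step)
  res <- lapply(t_eval, function(tt)
    suppressWarnings(
      chemotactic_index_population(tracks, tt, t_origin, projection)))
  data.frame(t_min = t_eval,
             ci = vapply(res, as.numeric, numeric(1)),
             n_cells = vapply(res, attr, numeric(1), "n_cells"))
}

#' Motile cell fraction per time window
#'
#' A cell counts as motile in a window when its net displacement over the
#' window strictly exceeds its own diameter — a threshold that screens out
#' apparent movement from stage-repositioning error and other small
#' perturbations. Windows tile the experiment from t = 0 (default width
#' 10 min); the displacement is taken between the first and last sample
#' inside the closed window.
#'
#' @param tracks A [track_set()].
#' @param window Window width, minutes.
#' @param projection `"xy"` or `"xyz"`.
#' @return Data frame with `window_start`, `fraction`, `n_motile`,
#'   `n_cells` (cells with >= 2 samples in the window).
#' @export
motile_fraction <- function(tracks, window = 10, projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"), window > 0)
  projection <- match.arg(projection)
  cols <- .proj_cols(projection)
  t_max <- max(tracks$tracks$t_min)
  starts <- seq(0, t_max - window, by = window)
  cells <- split(tracks$tracks, tracks$tracks$cell_id)
  out <- lapply(starts, function(w0) {
    res <- vapply(cells, function(tr) {
      ww <- .traj_window(tr, w0, w0 + window)
      if (nrow(ww) < 2) return(NA)
      disp <- sqrt(sum(vapply(cols, function(cl)
        (ww[[cl]][nrow(ww)] - ww[[cl]][1])^2, numeric(1))))
      disp > ww$diameter_um[1]
    }, logical(1))
    n <- sum(!is.na(res))
    data.frame(window_start = w0,
               fraction = if (n) mean(res, na.rm = TRUE) else NA_real_,
               n_motile = sum(res, na.rm = TRUE), n_cells = n)
  })
  do.call(rbind, out)
}

#' Per-frame cell velocities
#'
#' Backward-difference velocity at each frame: v(t_k) =
#' (pos(t_k) - pos(t_{k-1})) / (t_k - t_{k-1}). The first frame of each
#' cell carries no velocity. Gaps longer than twice the nominal frame
#' interval are averaged over (the velocity spans the actual elapsed
#' time) and flagged in `long_gap`.
#'
#' @param tracks A [track_set()].
#' @param projection `"xy"` or `"xyz"` — controls the modulus only; the
#'   components are always reported.
#' @return Data frame with `cell_id`, `t_min`, `v_x`, `v_y`, `v_z`,
#'   `v_mod` (um/min), `long_gap`.
#' @export
cell_velocities <- function(tracks, projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"))
  projection <- match.arg(projection)
  cells <- split(tracks$tracks, tracks$tracks$cell_id)
  out <- lapply(cells, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    dt <- diff(tr$t_min)
    vx <- diff(tr$x_um) / dt
    vy <- diff(tr$y_um) / dt
    vz <- diff(tr$z_um) / dt
    vmod <- if (projection == "xy") sqrt(vx^2 + vy^2) else
      sqrt(vx^2 + vy^2 + vz^2)
    data.frame(cell_id = tr$cell_id[-1], t_min = tr$t_min[-1],
               v_x = vx, v_y = vy, v_z = vz, v_mod = vmod,
               long_gap = dt > 2 * tracks$frame_interval)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time-binned population velocity statistics
#'
#' Per-frame velocities pooled over cells and averaged in half-open time
#' bins (default 5 min). The modulus is computed per frame and then
#' averaged — not the norm of the mean velocity — so it measures speed,
#' while the signed component means capture directional drift.
#'
#' @param tracks A [track_set()].
#' @param bin Bin width, minutes.
#' @param projection `"xy"` or `"xyz"`.
#' @return Data frame with `bin_start`, `v_x`, `v_y`, `v_mod`, `n_frames`,
#'   `n_cells`.
#' @export
velocity_series <- function(tracks, bin = 5, projection = c("xy", "xyz")) {
  stopifnot(bin > 0)
  projection <- match.arg(projection)
  v <- cell_velocities(tracks, projection)
  if (is.null(v) || !nrow(v)) return(data.frame(
    bin_start = numeric(0), v_x = numeric(0), v_y = numeric(0),
    v_mod = numeric(0), n_frames = integer(0), n_cells = integer(0)))
  b <- floor(v$t_min / bin) * bin
  agg <- function(x) tapply(x, b, mean)
  starts <- sort(unique(b))
  data.frame(bin_start = starts,
             v_x = as.numeric(agg(v$v_x)[as.character(starts)]),
             v_y = as.numeric(agg(v$v_y)[as.character(starts)]),
             v_mod = as.numeric(agg(v$v_mod)[as.character(starts)]),
             n_frames = as.integer(table(b)[as.character(starts)]),
             n_cells = as.integer(tapply(v$cell_id, b, function(z)
               length(unique(z)))[as.character(starts)]))
}

#' Per-cell mean speed before and after the stimulus
#'
#' Average velocity modulus of each cell over the pre-stimulus period
#' (velocities up to and including `t_stimulus`) and the post-stimulus
#' period. Cells tracked in only one period are reported for that period
#' only (NA elsewhere).
#'
#' @param tracks A [track_set()].
#' @param projection `"xy"` or `"xyz"`.
#' @return Data frame with `cell_id`, `pre`, `post` (um/min), plus an
#'   attribute `summary` holding population mean and SD per period.
#' @export
per_cell_mean_speed <- function(tracks, projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"))
  projection <- match.arg(projection)
  v <- cell_velocities(tracks, projection)
  ts <- tracks$t_stimulus
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  cells <- unique(tracks$tracks$cell_id)
  pre <- vapply(cells, function(cid)
    mean_or_na(v$v_mod[v$cell_id == cid & v$t_min <= ts]), numeric(1))
  post <- vapply(cells, function(cid)
    mean_or_na(v$v_mod[v$cell_id == cid & v$t_min > ts]), numeric(1))
  out <- data.frame(cell_id = cells, pre = pre, post = post)
  attr(out, "summary") <- data.frame(
    period = c("pre", "post"),
    mean = c(mean(pre, na.rm = TRUE), mean(post, na.rm = TRUE)),
    sd = c(stats::sd(pre[!is.na(pre)]), stats::sd(post[!is.na(post)])),
    n = c(sum(!is.na(pre)), sum(!is.na(post))))
  out
}

#' Speed histogram counts
#'
#' Histogram of per-cell mean speeds in fixed-width bins from 0
#' (default 1 um/min), as used to summarize the pre/post speed shift.
#'
#' @param speeds Numeric vector (NAs dropped).
#' @param binwidth Bin width, um/min.
#' @return Data frame with `bin_start`, `count`, `proportion`.
#' @export
speed_histogram <- function(speeds, binwidth = 1) {
  s <- speeds[!is.na(speeds)]
  b <- floor(s / binwidth) * binwidth
  starts <- seq(0, max(b, 0), by = binwidth)
  cnt <- as.integer(table(factor(b, levels = starts)))
  data.frame(bin_start = starts, count = cnt,
             proportion = if (length(s)) cnt / length(s) else cnt)
}

# one-sample two-sided test helper; degenerate (zero-variance) samples are
# decided by comparing the mean with mu directly
.reject_zero_mean <- function(x, mu, alpha) {
  if (length(x) < 2) return(NA)
  if (stats::sd(x) < 1e-12) return(abs(mean(x) - mu) > 1e-12)
  stats::t.test(x, mu = mu)$p.value < alpha
}

#' Fraction of cells with a biased velocity distribution
#'
#' For each time bin (default 5 min) and each cell with enough velocity
#' samples, a two-sided one-sample t-test is run: the x and y components
#' against a zero mean (the null of unbiased motion), and the velocity
#' modulus against the bin's population-mean modulus. The modulus has a
#' positive mean under any null, so its test is a delta-from-baseline
#' interpretation — it flags cells whose speed departs from the
#' population's current typical speed — and should be read as such.
#' Rejections are tallied per cell at level `alpha` with no
#' multiple-testing correction, matching the per-cell tally convention.
#'
#' @param tracks A [track_set()].
#' @param bin Bin width, minutes.
#' @param alpha Significance level (default 0.05).
#' @param min_samples Minimum velocity samples per cell per bin (default
#'   3); cells under the minimum are skipped for that bin.
#' @param projection `"xy"` or `"xyz"`.
#' @return Data frame with `bin_start`, `metric` (`"v_x"`, `"v_y"`,
#'   `"v_mod"`), `pct_biased` (percentage of tested cells rejecting),
#'   `n_cells`.
#' @export
biased_fraction_ttest <- function(tracks, bin = 5, alpha = 0.05,
                                  min_samples = 3,
                                  projection = c("xy", "xyz")) {
  stopifnot(inherits(tracks, "track_set"), bin > 0, alpha > 0, alpha < 1)
  projection <- match.arg(projection)
  v <- cell_velocities(tracks, projection)
  v$bin_start <- floor(v$t_min / bin) * bin
  out <- list()
  for (b0 in sort(unique(v$bin_start))) {
    vb <- v[v$bin_start == b0, ]
    mu_mod <- mean(vb$v_mod)
    for (metric in c("v_x", "v_y", "v_mod")) {
      mu <- if (metric == "v_mod") mu_mod else 0
      rej <- vapply(split(vb[[metric]], vb$cell_id), function(x) {
        if (length(x) < min_samples) return(NA)
        .reject_zero_mean(x, mu, alpha)
      }, logical(1))
      n <- sum(!is.na(rej))
      out[[length(out) + 1L]] <- data.frame(
        bin_start = b0, metric = metric,
        pct_biased = if (n) 100 * mean(rej, na.rm = TRUE) else NA_real_,
        n_cells = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tidy motility report
#'
#' All headline motility statistics of a track set in one long data
#' frame: 10-min motile fractions, 5-min velocity component/modulus
#' means, the cumulative chemotactic index series, and the per-bin
#' biased-cell percentages. One row per (bin, metric).
#'
#' @param tracks A [track_set()].
#' @param bin Velocity/index bin width, minutes.
#' @param motile_window Motile-fraction window width, minutes.
#' @param alpha Significance level for the bias test.
#' @param projection `"xy"` or `"xyz"`.
#' @return Data frame with `bin_start`, `metric`, `value`, `n`.
#' @export
motility_report <- function(tracks, bin = 5, motile_window = 10,
                            alpha = 0.05, projection = c("xy", "xyz")) {
  projection <- match.arg(projection)
  mf <- motile_fraction(tracks, motile_window, projection)
  vs <- velocity_series(tracks, bin, projection)
  ci <- chemotactic_index_series(tracks, step = bin, projection = projection)
  bf <- biased_fraction_ttest(tracks, bin, alpha, projection = projection)
  rows <- list(
    data.frame(bin_start = mf$window_start, metric = "motile_fraction",
               value = mf$fraction, n = mf$n_cells),
    data.frame(bin_start = rep(vs$bin_start, 3),
               metric = rep(c("v_x", "v_y", "v_mod"), each = nrow(vs)),
               value = c(vs$v_x, vs$v_y, vs$v_mod),
               n = rep(vs$n_cells, 3)),
    data.frame(bin_start = ci$t_min, metric = "chemotactic_index",
               value = ci$ci, n = ci$n_cells),
    data.frame(bin_start = bf$bin_start,
               metric = paste0("biased_pct_", sub("^v_", "", bf$metric)),
               value = bf$pct_biased, n = bf$n_cells))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
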