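# Chemoattractant transport in the gradient chamber.
#
# Unit conventions (used everywhere in the package): lengths in mm, time in
# seconds, diffusion coefficients quoted in cm^2/s as is customary for small
# solutes, converted once here. Concentrations are carried normalized (C/C0).

# 1 cm^2 = 100 mm^2
.D_mm2 <- function(D_cm2_s) D_cm2_s * 100

# complementary error function via the normal CDF identity
# erfc(x) = 2 * P(Z > x * sqrt(2))
.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Diffusion parameters
#'
#' Bundle the diffusion coefficient of the chemoattractant (or its
#' fluorescent tracer surrogate) and the initial reservoir concentration.
#' All concentration fields produced by the package are normalized to
#' `C0`, so `C0` only matters when converting to gray levels or absolute
#' concentration units.
#'
#' @param D_cm2_s Diffusion coefficient in cm^2/s. The default 2e-6 cm^2/s
#'   is typical of a ~10 kDa tracer (FITC-dextran, comparable in size to
#'   IL-8) in a dilute collagen gel.
#' @param C0 Initial reservoir concentration, in whatever unit the
#'   calibration uses (e.g. uM); must be positive.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D_cm2_s = 2e-6, C0 = 1) {
  stopifnot(is.numeric(D_cm2_s), length(D_cm2_s) == 1L, is.finite(D_cm2_s),
            D_cm2_s > 0, is.numeric(C0), length(C0) == 1L, C0 > 0)
  structure(list(D_cm2_s = D_cm2_s, C0 = C0), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Diffusion parameters: D =", format(x$D_cm2_s), "cm^2/s, C0 =",
      format(x$C0), "\n")
  invisible(x)
}

#' One-dimensional chamber geometry
#'
#' The chamber axis is split into three sections: the chemoattractant
#' reservoir, the porous membrane and the cell-seeded gel compartment.
#' Positions are measured from the membrane-gel interface (y = 0),
#' increasing into the gel; the reservoir occupies negative y.
#'
#' @param L_reservoir_mm Reservoir length along the diffusion axis (mm).
#'   The default 20 mm makes the reservoir much longer than the gel so the
#'   interface concentration stays near C0/2 over a 2 h experiment.
#' @param L_membrane_mm Membrane thickness (mm); 0.15 mm is typical of a
#'   0.22 um-pore mixed-cellulose membrane.
#' @param L_gel_mm Gel compartment length (mm); the assay chamber is 5 mm.
#' @param D_factor_membrane Dimensionless multiplier on D inside the
#'   membrane, in (0, 1]. 1 means the membrane does not hinder diffusion
#'   (pores far larger than the tracer).
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(L_reservoir_mm = 20, L_membrane_mm = 0.15,
                             L_gel_mm = 5, D_factor_membrane = 1) {
  stopifnot(L_reservoir_mm > 0, L_membrane_mm > 0, L_gel_mm > 0,
            D_factor_membrane > 0, D_factor_membrane <= 1)
  structure(list(L_reservoir_mm = L_reservoir_mm,
                 L_membrane_mm = L_membrane_mm,
                 L_gel_mm = L_gel_mm,
                 D_factor_membrane = D_factor_membrane),
            class = "chamber_geometry")
}

#' Semi-infinite-slab concentration profile
#'
#' Closed-form solution of Fick's second law in the gel, treating the gel
#' as a semi-infinite medium with the membrane held at half the reservoir
#' concentration: C(y, t)/C0 = (1/2) erfc( y / (2 sqrt(D t)) ). The
#' boundary value C0/2 arises because the membrane sits between a
#' reservoir at C0 and an initially empty half-space of equal diffusivity.
#'
#' @param y_mm Distance from the membrane into the gel (mm), >= 0. Vectorized.
#' @param t_s Time since chemoattractant addition (s), >= 0. Vectorized
#'   (recycled against `y_mm`).
#' @param params A [diffusion_params()] object.
#' @return Normalized concentration C/C0 in [0, 0.5]. At `t_s = 0` the
#'   profile is 0 for `y_mm > 0` and 0.5 at `y_mm = 0` (right limit in t,
#'   matching the imposed boundary value).
#' @seealso [gradient_profile()] for the spatial derivative,
#'   [solve_chamber_1d()] for the finite-chamber numerical solution.
#' @export
closed_form_profile <- function(y_mm, t_s, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(y_mm < 0)) stop("y_mm must be >= 0 (distance into the gel)")
  if (any(t_s < 0)) stop("t_s must be >= 0")
  n <- max(length(y_mm), length(t_s))
  y <- rep_len(y_mm, n); t <- rep_len(t_s, n)
  D <- .D_mm2(params$D_cm2_s)
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- 0.5 * .erfc(y[pos] / (2 * sqrt(D * t[pos])))
  out[!pos] <- ifelse(y[!pos] == 0, 0.5, 0)
  out
}

#' Spatial gradient of the semi-infinite-slab profile
#'
#' Analytic derivative of [closed_form_profile()] with respect to y:
#' d(C/C0)/dy = -exp(-y^2 / (4 D t)) / (2 sqrt(pi D t)), in 1/mm. Always
#' non-positive (concentration decreases away from the membrane); its
#' magnitude is what drives the chemotactic coupling in the synthetic
#' random-walk generator.
#'
#' @inheritParams closed_form_profile
#' @return d(C/C0)/dy in 1/mm (<= 0); 0 at `t_s = 0`.
#' @export
gradient_profile <- function(y_mm, t_s, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(y_mm < 0)) stop("y_mm must be >= 0")
  if (any(t_s < 0)) stop("t_s must be >= 0")
  n <- max(length(y_mm), length(t_s))
  y <- rep_len(y_mm, n); t <- rep_len(t_s, n)
  D <- .D_mm2(params$D_cm2_s)
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- -exp(-y[pos]^2 / (4 * D * t[pos])) / (2 * sqrt(pi * D * t[pos]))
  out
}

#' Finite-difference solve of the three-section chamber
#'
#' Solves Fick's second law on the full chamber axis (reservoir, membrane,
#' gel) with no-flux boundaries at both outer walls and a piecewise
#' diffusivity (`D * D_factor_membrane` inside the membrane). The spatial
#' operator is written in conservative flux form with harmonic-mean face
#' diffusivities, so discrete total mass is conserved to machine precision
#' at every step; time stepping is Crank-Nicolson by default
#' (unconditionally stable), with an explicit scheme available when its
#' CFL condition holds.
#'
#' The default initial condition places the reservoir concentration C0 in
#' both the reservoir and the membrane pore volume
#' (`membrane_initial = "reservoir"`): the membrane floods during the
#' ~1 min injection of chemoattractant, and this choice reproduces the
#' observed behaviour that the membrane-gel interface sits at C0/2
#' essentially from the start. `membrane_initial = "empty"` starts the
#' membrane at zero instead, for sensitivity analysis.
#'
#' @param geom A [chamber_geometry()] object.
#' @param params A [diffusion_params()] object.
#' @param t_end_s Final time (s); default 7200 (the 2 h assay window).
#' @param dt_s Time step (s); must divide into the save interval.
#' @param dy_mm Spatial step (mm).
#' @param t_save_s Times at which to store the profile; default every
#'   60 s from 0 to `t_end_s`. Rounded to multiples of `dt_s`.
#' @param scheme `"crank-nicolson"` (default) or `"explicit"`. The
#'   explicit scheme refuses to run (with the offending numbers) when
#'   `dt > dy^2 / (2 max D)`.
#' @param membrane_initial `"reservoir"` (membrane starts at C0, default)
#'   or `"empty"` (membrane starts at 0).
#' @return An object of class `concentration_field`: list with `y_mm`
#'   (node positions, membrane-gel interface at 0), `t_s` (saved times),
#'   `C_norm` (matrix, nodes x times), `mass` (discrete total mass per
#'   saved time, units of C0 mm), plus the geometry and parameters used.
#' @export
solve_chamber_1d <- function(geom = chamber_geometry(),
                             params = diffusion_params(),
                             t_end_s = 7200, dt_s = 10, dy_mm = 0.05,
                             t_save_s = NULL,
                             scheme = c("crank-nicolson", "explicit"),
                             membrane_initial = c("reservoir", "empty")) {
  stopifnot(inherits(geom, "chamber_geometry"),
            inherits(params, "diffusion_params"))
  scheme <- match.arg(scheme)
  membrane_initial <- match.arg(membrane_initial)
  if (dt_s <= 0 || dy_mm <= 0 || t_end_s <= 0)
    stop("t_end_s, dt_s and dy_mm must all be positive")

  y0 <- -(geom$L_reservoir_mm + geom$L_membrane_mm)
  # snap the step so the grid covers the full axis exactly
  n <- max(round((geom$L_gel_mm - y0) / dy_mm), 3) + 1
  y <- seq(y0, geom$L_gel_mm, length.out = n)
  dy_mm <- y[2] - y[1]
  D <- .D_mm2(params$D_cm2_s)
  Dn <- rep(D, n)
  in_membrane <- y >= -geom$L_membrane_mm & y <= 0
  Dn[in_membrane] <- D * geom$D_factor_membrane

  if (scheme == "explicit") {
    dt_max <- dy_mm^2 / (2 * max(Dn))
    if (dt_s > dt_max)
      stop(sprintf(
        "explicit scheme unstable: dt_s = %g s exceeds the CFL limit %g s for dy_mm = %g; reduce dt_s or use scheme = 'crank-nicolson'",
        dt_s, dt_max, dy_mm))
  }

  # face diffusivities (harmonic mean), zero flux through the outer walls
  Dface <- 2 * Dn[-n] * Dn[-1] / (Dn[-n] + Dn[-1])  # n-1 interior faces
  # conservative Laplacian L: dC_i/dt = (Dw (C_{i-1}-C_i) + De (C_{i+1}-C_i))/dy^2
  De <- c(Dface, 0) / dy_mm^2   # east face of node i
  Dw <- c(0, Dface) / dy_mm^2   # west face of node i
  Lmat <- matrix(0, n, n)
  diag(Lmat) <- -(De + Dw)
  Lmat[cbind(1:(n - 1), 2:n)] <- De[-n]
  Lmat[cbind(2:n, 1:(n - 1))] <- Dw[-1]

  # initial condition (C/C0): reservoir (and by default the membrane) at 1.
  # Each node takes the filled fraction of its control volume so the jump
  # sits exactly at the section boundary whatever the grid alignment.
  cut <- if (membrane_initial == "reservoir") 0 else -geom$L_membrane_mm
  C <- pmin(pmax((cut - (y - dy_mm / 2)) / dy_mm, 0), 1)

  n_steps <- ceiling(t_end_s / dt_s)
  if (is.null(t_save_s)) t_save_s <- seq(0, t_end_s, by = 60)
  save_steps <- unique(pmin(pmax(round(t_save_s / dt_s), 0), n_steps))
  t_saved <- save_steps * dt_s
  Cmat <- matrix(NA_real_, n, length(save_steps))
  mass <- numeric(length(save_steps))

  if (scheme == "crank-nicolson") {
    A <- diag(n) - (dt_s / 2) * Lmat
    B <- diag(n) + (dt_s / 2) * Lmat
    P <- solve(A, B)  # constant coefficients: factor once
  } else {
    P <- diag(n) + dt_s * Lmat
  }

  k_save <- match(0L, save_steps)
  if (!is.na(k_save)) { Cmat[, k_save] <- C; mass[k_save] <- sum(C) * dy_mm }
  for (step in seq_len(n_steps)) {
    C <- as.numeric(P %*% C)
    k_save <- match(step, save_steps)
    if (!is.na(k_save)) { Cmat[, k_save] <- C; mass[k_save] <- sum(C) * dy_mm }
  }

  structure(list(y_mm = y, t_s = t_saved, C_norm = Cmat, mass = mass,
                 geometry = geom, params = params, dy_mm = dy_mm,
                 dt_s = dt_s, scheme = scheme,
                 membrane_initial = membrane_initial),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "Concentration field: %d nodes (y in [%g, %g] mm), %d times (t in [%g, %g] s)\n",
    length(x$y_mm), min(x$y_mm), max(x$y_mm),
    length(x$t_s), min(x$t_s), max(x$t_s)))
  invisible(x)
}

# locate interpolation weights of v in sorted grid g (clamped)
.interp_ix <- function(v, g) {
  i <- findInterval(v, g, all.inside = TRUE)
  w <- (v - g[i]) / (g[i + 1] - g[i])
  list(i = i, w = pmin(pmax(w, 0), 1))
}

#' Evaluate a concentration field at arbitrary points
#'
#' Bilinear interpolation of a [solve_chamber_1d()] field in space and
#' time. Points are clamped to the stored grid.
#'
#' @param field A `concentration_field`.
#' @param y_mm,t_s Coordinates (vectorized, recycled to common length).
#'   `y_mm` is measured from the membrane-gel interface (reservoir at
#'   negative y).
#' @return Normalized concentration C/C0 at each point.
#' @export
eval_field <- function(field, y_mm, t_s) {
  stopifnot(inherits(field, "concentration_field"))
  n <- max(length(y_mm), length(t_s))
  y <- rep_len(y_mm, n); t <- rep_len(t_s, n)
  iy <- .interp_ix(y, field$y_mm)
  it <- .interp_ix(t, field$t_s)
  M <- field$C_norm
  c00 <- M[cbind(iy$i, it$i)]
  c10 <- M[cbind(iy$i + 1L, it$i)]
  c01 <- M[cbind(iy$i, it$i + 1L)]
  c11 <- M[cbind(iy$i + 1L, it$i + 1L)]
  (1 - iy$w) * ((1 - it$w) * c00 + it$w * c01) +
    iy$w * ((1 - it$w) * c10 + it$w * c11)
}

#' Spatial gradient of a stored concentration field
#'
#' Central-difference d(C/C0)/dy on the stored grid, interpolated to the
#' requested points.
#'
#' @inheritParams eval_field
#' @return d(C/C0)/dy in 1/mm.
#' @export
eval_field_gradient <- function(field, y_mm, t_s) {
  stopifnot(inherits(field, "concentration_field"))
  n <- max(length(y_mm), length(t_s))
  y <- rep_len(y_mm, n); t <- rep_len(t_s, n)
  g <- field$y_mm
  ny <- length(g)
  # central differences, one-sided at the walls
  Gy <- field$C_norm
  dC <- (Gy[c(2:ny, ny), ] - Gy[c(1, 1:(ny - 1)), ]) /
    (g[c(2:ny, ny)] - g[c(1, 1:(ny - 1))])
  iy <- .interp_ix(y, g)
  it <- .interp_ix(t, field$t_s)
  c00 <- dC[cbind(iy$i, it$i)]
  c10 <- dC[cbind(iy$i + 1L, it$i)]
  c01 <- dC[cbind(iy$i, it$i + 1L)]
  c11 <- dC[cbind(iy$i + 1L, it$i + 1L)]
  (1 - iy$w) * ((1 - it$w) * c00 + it$w * c01) +
    iy$w * ((1 - it$w) * c10 + it$w * c11)
}

#' Estimate the diffusion coefficient from concentration observations
#'
#' Least-squares fit of D to observed normalized concentrations at known
#' (distance, time) points, using either the semi-infinite closed form or
#' the finite-chamber numerical solution as the forward model. The
#' objective sum((C_obs - C_model(y, t; D))^2) is minimized over log10(D)
#' on a bounded interval by golden-section search ([stats::optimize()]),
#' which is deterministic for fixed inputs; the log scale conditions the
#' single-parameter problem.
#'
#' @param observations Data frame with columns `y_mm`, `t_s`, `c_norm`
#'   (at least 3 rows spanning at least 2 distinct times).
#' @param model `"closed_form"` (default) or `"numeric"` (full chamber
#'   solve per candidate D; slower).
#' @param geom Chamber geometry for `model = "numeric"`.
#' @param D_range_cm2_s Search interval for D (cm^2/s).
#' @param dy_mm,dt_s Discretization used by the numeric forward model.
#' @return Object of class `diffusion_fit`: `D_cm2_s` (the estimate),
#'   `sse`, `rmse`, `model`, `n_obs`.
#' @export
fit_diffusion_coefficient <- function(observations,
                                      model = c("closed_form", "numeric"),
                                      geom = chamber_geometry(),
                                      D_range_cm2_s = c(1e-8, 1e-4),
                                      dy_mm = 0.1, dt_s = 30) {
  model <- match.arg(model)
  obs <- as.data.frame(observations)
  need <- c("y_mm", "t_s", "c_norm")
  if (!all(need %in% names(obs)))
    stop("observations must have columns y_mm, t_s, c_norm")
  obs <- obs[stats::complete.cases(obs[need]), need]
  if (nrow(obs) < 3) stop("ill-posed fit: need at least 3 observations")
  if (length(unique(obs$t_s[obs$t_s > 0])) < 2)
    stop("ill-posed fit: observations must span at least 2 distinct positive times")
  if (all(abs(obs$c_norm) < .Machine$double.eps))
    stop("ill-posed fit: all observed concentrations are zero")

  predict_c <- if (model == "closed_form") {
    function(D) closed_form_profile(obs$y_mm, obs$t_s, diffusion_params(D))
  } else {
    t_end <- max(obs$t_s)
    function(D) {
      fld <- solve_chamber_1d(geom, diffusion_params(D), t_end_s = t_end,
                              dt_s = dt_s, dy_mm = dy_mm,
                              t_save_s = seq(0, t_end, by = dt_s))
      eval_field(fld, obs$y_mm, obs$t_s)
    }
  }
  objective <- function(log10D) sum((obs$c_norm - predict_c(10^log10D))^2)
  opt <- stats::optimize(objective, interval = log10(D_range_cm2_s),
                         tol = 1e-5)
  structure(list(D_cm2_s = 10^opt$minimum, sse = opt$objective,
                 rmse = sqrt(opt$objective / nrow(obs)),
                 model = model, n_obs = nrow(obs)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit (%s model): D = %.3g cm^2/s, RMSE = %.3g (n = %d)\n",
              x$model, x$D_cm2_s, x$rmse, x$n_obs))
  invisible(x)
}

#' Fluorescence calibration
#'
#' Ordinary least-squares line relating image mean gray level to tracer
#' concentration. Within its working range the epifluorescence mean gray
#' level is linear in FITC-dextran concentration, so a two-parameter line
#' suffices.
#'
#' @param points Data frame with columns `concentration` and `gray_level`;
#'   at least 2 distinct concentrations.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `valid_range` (range of concentrations fitted).
#' @export
fit_calibration <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("concentration", "gray_level") %in% names(pts)))
    stop("points must have columns concentration, gray_level")
  if (length(unique(pts$concentration)) < 2)
    stop("calibration requires at least 2 distinct concentrations")
  fit <- stats::lm(gray_level ~ concentration, data = pts)
  co <- stats::coef(fit)
  sst <- sum((pts$gray_level - mean(pts$gray_level))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  if (co[["concentration"]] <= 0)
    warning("calibration slope is not positive; check the input points")
  structure(list(slope = unname(co[["concentration"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = r2,
                 valid_range = range(pts$concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: gray = %.4g * concentration + %.4g (r^2 = %.4f, range [%g, %g])\n",
    x$slope, x$intercept, x$r_squared, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Convert mean gray levels back to concentration. Values outside the
#' calibration's fitted concentration range are returned (not rejected)
#' but flagged: the result carries a logical attribute `extrapolated`
#' and a warning is issued.
#'
#' @param curve A [fit_calibration()] object.
#' @param gray_level Numeric vector of gray levels.
#' @return Concentrations, with attribute `extrapolated`.
#' @export
gray_to_concentration <- function(curve, gray_level) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (gray_level - curve$intercept) / curve$slope
  extra <- conc < curve$valid_range[1] | conc > curve$valid_range[2]
  if (any(extra))
    warning(sprintf("%d of %d values fall outside the calibration range [%g, %g]",
                    sum(extra), length(conc),
                    curve$valid_range[1], curve$valid_range[2]))
  attr(conc, "extrapolated") <- extra
  conc
}
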