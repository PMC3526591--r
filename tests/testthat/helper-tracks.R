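# trajectory builders used across the motility tests

# single-cell trajectory from a matrix/list of positions, one sample per minute
traj_from_points <- function(xy, z = 0, cell_id = "c1", diameter = 10) {
  xy <- as.matrix(xy)
  data.frame(cell_id = cell_id, t_min = seq_len(nrow(xy)) - 1,
             x_um = xy[, 1], y_um = xy[, 2],
             z_um = rep_len(z, nrow(xy)), diameter_um = diameter)
}

# straight-line walker: constant step (um/min) along `dir` for `n` minutes
straight_traj <- function(dir, speed = 2, n = 20, cell_id = "c1",
                          origin = c(0, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  t <- 0:n
  data.frame(cell_id = cell_id, t_min = t,
             x_um = origin[1] + speed * t * dir[1],
             y_um = origin[2] + speed * t * dir[2],
             z_um = origin[3] + speed * t * dir[3],
             diameter_um = 10)
}

tracks_of <- function(..., t_stimulus = 30) {
  track_set(do.call(rbind, list(...)), t_stimulus = t_stimulus)
}
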