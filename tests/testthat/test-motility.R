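# Trajectory statistics: path lengths, chemotactic index, motile fraction,
# velocities, speed distributions and the bias t-test.

test_that("curvilinear length sums inter-sample distances", {
  tr <- traj_from_points(rbind(c(0, 0), c(0, -3), c(4, -6)))
  expect_equal(as.numeric(curvilinear_length(tr)), 8)  # 3 + (3-4-5 triangle)
  still <- traj_from_points(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(as.numeric(curvilinear_length(still)), 0)
  one <- traj_from_points(rbind(c(0, 0)))
  out <- curvilinear_length(one)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "too_few_samples"))
})

test_that("curvilinear length bounds displacement and shrinks under subsampling", {
  set.seed(3)
  for (i in 1:20) {
    xy <- apply(matrix(rnorm(2 * 30), ncol = 2), 2, cumsum)
    tr <- traj_from_points(xy)
    L <- as.numeric(curvilinear_length(tr))
    disp <- sqrt(sum((xy[30, ] - xy[1, ])^2))
    expect_gte(L, disp - 1e-12)
    sub <- tr[seq(1, 30, by = 2), ]
    expect_lte(as.numeric(curvilinear_length(sub)), L + 1e-12)
  }
})

test_that("per-cell chemotactic index hits its defining cases", {
  g <- c(0, -1, 0)
  expect_equal(chemotactic_index_cell(straight_traj(c(0, -1, 0)), g)$index, 1)
  expect_equal(chemotactic_index_cell(straight_traj(c(0, 1, 0)), g)$index, -1)
  worked <- traj_from_points(rbind(c(0, 0), c(0, -3), c(4, -6)))
  res <- chemotactic_index_cell(worked, g)
  expect_equal(res$index, 0.75)   # net along gradient 6, path length 8
  expect_equal(res$weight, 8)
  still <- traj_from_points(rbind(c(0, 0), c(0, 0)))
  res0 <- chemotactic_index_cell(still, g)
  expect_true(is.na(res0$index))
  expect_equal(res0$weight, 0)
})

test_that("population index is the length-weighted mean over moving cells", {
  # cell a: straight toward source, L = 10; cell b: out-and-back, I = 0, L = 30
  a <- straight_traj(c(0, -1, 0), speed = 1, n = 10, cell_id = "a")
  b <- traj_from_points(cbind(seq(0, 15, by = 1), 0), cell_id = "b")
  b <- rbind(b, within(b[nrow(b) - (1:15), ], t_min <- 16:30))
  ts <- tracks_of(a, b)
  I <- chemotactic_index_population(ts, t_eval = 30)
  expect_equal(as.numeric(I), 0.25)  # (1*10 + 0*30) / 40
  expect_equal(attr(I, "n_cells"), 2)
  # identical straight paths toward the source
  ts2 <- tracks_of(straight_traj(c(0, -1, 0), cell_id = "a"),
                   straight_traj(c(0, -1, 0), cell_id = "b", origin = c(5, 5, 0)))
  expect_equal(as.numeric(chemotactic_index_population(ts2, 20)), 1)
  # all stationary: undefined with a warning
  still <- tracks_of(traj_from_points(matrix(0, 5, 2)))
  expect_warning(I3 <- chemotactic_index_population(still, 4), "stationary")
  expect_true(is.na(I3))
})

test_that("index flips sign with the gradient and respects invariances", {
  set.seed(4)
  xy <- apply(matrix(rnorm(60, sd = 2), ncol = 2), 2, cumsum)
  tr <- traj_from_points(xy, z = rnorm(30))
  up <- chemotactic_index_cell(tr, c(0, -1, 0), projection = "xyz")
  dn <- chemotactic_index_cell(tr, c(0, 1, 0), projection = "xyz")
  expect_equal(up$index, -dn$index)
  expect_true(abs(up$index) <= 1)
  # rigid translation changes nothing
  sh <- tr; sh$x_um <- sh$x_um + 100; sh$y_um <- sh$y_um - 50; sh$z_um <- sh$z_um + 7
  expect_equal(chemotactic_index_cell(sh, c(0, -1, 0), projection = "xyz"),
               chemotactic_index_cell(tr, c(0, -1, 0), projection = "xyz"))
  # rotation about the gradient (y) axis preserves I and v_y
  th <- 0.7
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$z_um
  rot$z_um <- sin(th) * tr$x_um + cos(th) * tr$z_um
  expect_equal(chemotactic_index_cell(rot, c(0, -1, 0), projection = "xyz")$index,
               up$index, tolerance = 1e-12)
  v_tr <- cell_velocities(tracks_of(tr))
  v_rot <- cell_velocities(tracks_of(rot))
  expect_equal(v_rot$v_y, v_tr$v_y, tolerance = 1e-12)
})

test_that("motile criterion is a strict displacement-exceeds-diameter test", {
  # net displacement 12 um in the first 10-min window: motile
  fast <- straight_traj(c(0, -1, 0), speed = 1.2, n = 10, cell_id = "fast")
  # exactly the diameter: NOT motile (strict inequality)
  edge <- straight_traj(c(0, -1, 0), speed = 1.0, n = 10, cell_id = "edge")
  still <- traj_from_points(matrix(0, 11, 2), cell_id = "still")
  mf <- motile_fraction(tracks_of(fast, edge, still), window = 10)
  expect_equal(mf$fraction[1], 1 / 3)
  expect_equal(mf$n_cells[1], 3)
  # a cell absent from a window is excluded from that window's denominator
  long <- straight_traj(c(0, -1, 0), speed = 1.2, n = 20, cell_id = "long")
  late <- straight_traj(c(1, 0, 0), speed = 3, n = 5, cell_id = "late")
  late$t_min <- late$t_min + 12
  mf2 <- motile_fraction(tracks_of(long, late), window = 10)
  expect_equal(mf2$n_cells, c(1, 2))
})

test_that("velocity series reports backward-difference means per bin", {
  # constant motion (0, -2, 0) um/min
  tr <- straight_traj(c(0, -1, 0), speed = 2, n = 20)
  vs <- velocity_series(tracks_of(tr), bin = 5)
  expect_equal(vs$v_y, rep(-2, nrow(vs)))
  expect_equal(vs$v_x, rep(0, nrow(vs)))
  expect_equal(vs$v_mod, rep(2, nrow(vs)))
  # modulus is the mean of per-frame moduli, not the norm of the mean
  zig <- traj_from_points(cbind(c(0, 3, 0, 3, 0, 3), 0))
  vz <- velocity_series(tracks_of(zig), bin = 5)
  expect_equal(vz$v_mod[1], 3)          # every frame moves 3 um
  expect_lt(abs(vz$v_x[1]), 1)          # while the mean velocity ~ cancels
  # long gaps are averaged over and flagged
  gap <- traj_from_points(rbind(c(0, 0), c(0, -2), c(0, -10)))
  gap$t_min <- c(0, 1, 5)
  v <- cell_velocities(tracks_of(gap))
  expect_equal(v$v_y, c(-2, -2))
  expect_equal(v$long_gap, c(FALSE, TRUE))
})

test_that("per-cell speeds split at the stimulus and feed the histogram", {
  tr <- straight_traj(c(1, 0, 0), speed = 3, n = 60, cell_id = "c")
  ts <- track_set(tr, t_stimulus = 30)
  sp <- per_cell_mean_speed(ts)
  expect_equal(sp$pre, 3)
  expect_equal(sp$post, 3)
  # mostly-slow population: histogram mass concentrates in [0, 1)
  set.seed(5)
  speeds <- c(runif(80, 0, 0.9), runif(20, 2, 7))
  h <- speed_histogram(speeds, binwidth = 1)
  expect_equal(h$proportion[h$bin_start == 0], 0.8)
  expect_equal(sum(h$count), 100)
  # a cell tracked only post-stimulus reports NA pre
  late <- straight_traj(c(1, 0, 0), speed = 2, n = 10, cell_id = "late")
  late$t_min <- late$t_min + 40
  sp2 <- per_cell_mean_speed(tracks_of(tr, late))
  expect_true(is.na(sp2$pre[sp2$cell_id == "late"]))
  expect_equal(sp2$post[sp2$cell_id == "late"], 2)
})

test_that("bias t-test flags drifting cells and stays near level under the null", {
  set.seed(6)
  n <- 150; K <- 20
  mk <- function(vx, vy) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      x <- cumsum(c(0, vx(i))); y <- cumsum(c(0, vy(i)))
      data.frame(cell_id = sprintf("c%03d", i), t_min = 0:K,
                 x_um = x, y_um = y, z_um = 0, diameter_um = 10)
    }))
  }
  # strong constant drift in v_y, tiny noise: ~100% rejection on v_y
  drift <- track_set(mk(function(i) rnorm(K, 0, 0.01),
                        function(i) -3 + rnorm(K, 0, 0.01)))
  bf <- biased_fraction_ttest(drift, bin = 5)
  bf <- bf[bf$n_cells > 0, ]
  expect_true(all(bf$pct_biased[bf$metric == "v_y"] > 95))
  # v_x stays at the nominal level
  expect_true(mean(bf$pct_biased[bf$metric == "v_x"]) < 15)
  # pure zero-mean Gaussian velocities: rejection near alpha on both components
  null <- track_set(mk(function(i) rnorm(K), function(i) rnorm(K)))
  bf0 <- biased_fraction_ttest(null, bin = 5)
  bf0 <- bf0[bf0$n_cells > 0, ]
  comp <- bf0$pct_biased[bf0$metric %in% c("v_x", "v_y")]
  expect_lt(abs(mean(comp) - 5), 4)
  # cells with too few samples are skipped, not counted
  short <- straight_traj(c(0, -1, 0), speed = 3, n = 2, cell_id = "s")
  bfs <- biased_fraction_ttest(tracks_of(short), bin = 5, min_samples = 3)
  expect_equal(bfs$n_cells, rep(0, nrow(bfs)))
})

test_that("motility report is tidy and internally consistent", {
  ex <- make_fixture_experiment("donorA-like", seed = 3)
  rep <- motility_report(ex$tracks)
  expect_named(rep, c("bin_start", "metric", "value", "n"))
  expect_setequal(unique(rep$metric),
                  c("motile_fraction", "v_x", "v_y", "v_mod",
                    "chemotactic_index", "biased_pct_x", "biased_pct_y",
                    "biased_pct_mod"))
  mf <- rep$value[rep$metric == "motile_fraction"]
  expect_true(all(mf >= 0 & mf <= 1, na.rm = TRUE))
  ci <- rep$value[rep$metric == "chemotactic_index"]
  expect_true(all(abs(ci) <= 1, na.rm = TRUE))
  # report rows agree with the direct estimators
  vs <- velocity_series(ex$tracks)
  expect_equal(rep$value[rep$metric == "v_y"], vs$v_y)
})
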