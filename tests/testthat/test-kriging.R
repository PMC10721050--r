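test_that("local plane coordinates are an exact isometry with inverse", {
  geom <- stenosed_tube()
  plane <- poi_plane(geom)
  expect_equal(as.numeric(to_local_coords(plane$origin, plane)), c(0, 0))
  expect_equal(as.numeric(to_local_coords(plane$origin + plane$e1, plane)),
               c(1, 0))
  set.seed(61)
  XY <- cbind(runif(20, -1.5, 1.5), runif(20, -1.5, 1.5))
  pts <- from_local_coords(XY, plane)
  back <- to_local_coords(pts, plane)
  expect_equal(unname(back), unname(XY), tolerance = 1e-12)
  # in-plane distances preserved
  expect_equal(as.numeric(dist(back)), as.numeric(dist(XY)),
               tolerance = 1e-12)
})

test_that("training sets average space-time duplicates", {
  plane <- poi_plane(stenosed_tube())
  obs <- data.frame(X = c(0.5, 0.5, -0.2), Y = c(0.1, 0.1, 0),
                    t_c = c(0.2, 0.2, 0.2), v_n = c(0.4, 0.6, 0.3))
  ts <- training_set(obs, plane)
  expect_equal(nrow(ts), 2)
  expect_equal(ts$v_n[1], 0.5)
  expect_equal(attr(ts, "source"), "sampling")
})

test_that("no-slip augmentation adds the boundary ring at each instant, idempotently", {
  plane <- poi_plane(stenosed_tube())
  set.seed(62)
  obs <- data.frame(X = runif(30, -1, 1), Y = runif(30, -1, 1),
                    t_c = rep((0:14) * 0.064, 2), v_n = runif(30))
  ts <- training_set(obs, plane)
  aug <- augment_no_slip(ts, n_ring = 32)
  expect_equal(nrow(aug), 30 + 15 * 32)          # 480 added zeros
  ring <- aug[aug$v_n == 0, ]
  expect_equal(unique(round(sqrt(ring$X^2 + ring$Y^2), 10)),
               round(plane$radius, 10))
  expect_true(attr(aug, "augmented"))
  # augmenting twice changes nothing (duplicates averaged away)
  expect_equal(nrow(augment_no_slip(aug, n_ring = 32)), nrow(aug))
  # explicit instants override the data times
  aug2 <- augment_no_slip(ts, n_ring = 16, instants = c(0, 0.48))
  expect_equal(nrow(aug2), 30 + 2 * 16)
  expect_error(augment_no_slip(ts, n_ring = 4), "n_ring")
})

test_that("empirical semivariogram reproduces hand-computable cases", {
  plane <- poi_plane(stenosed_tube())
  # two points with values 0 and 2: a single bin holds gamma = 2
  two <- data.frame(X = c(0, 1), Y = 0, t_c = 0, v_n = c(0, 2))
  emp <- empirical_semivariogram(two, n_bins = 1, time_scaling = 0,
                                 max_lag_frac = 1)
  expect_equal(emp$gamma, 2)
  expect_equal(emp$n_pairs, 1L)
  # constant data: gamma identically zero
  cst <- data.frame(X = runif(20), Y = runif(20), t_c = 0, v_n = 1)
  empc <- empirical_semivariogram(cst, time_scaling = 0, max_lag_frac = 1)
  expect_true(all(empc$gamma == 0))
  # pair counts total n (n - 1) / 2 when all lags are binned
  set.seed(63)
  n <- 40
  d <- data.frame(X = runif(n), Y = runif(n), t_c = 0, v_n = runif(n))
  empn <- empirical_semivariogram(d, time_scaling = 0, max_lag_frac = 1)
  expect_equal(sum(empn$n_pairs), n * (n - 1) / 2)
})

test_that("variogram fitting recovers known exponential parameters", {
  # replicated Gaussian-process realizations on fixed sites reduce the
  # sampling noise of the method-of-moments semivariogram
  set.seed(42)
  n <- 500
  pts <- data.frame(X = runif(n, 0, 50), Y = runif(n, 0, 50), t_c = 0)
  D <- as.matrix(dist(pts[, 1:2]))
  L <- chol(exp(-D / 5) + 1e-10 * diag(n))
  emps <- lapply(1:6, function(i) {
    pts$v_n <- as.numeric(t(L) %*% rnorm(n))
    empirical_semivariogram(pts, time_scaling = 0)
  })
  avg <- emps[[1]]
  avg$gamma <- rowMeans(sapply(emps, function(e) e$gamma))
  vg <- fit_variogram(avg)
  expect_lt(abs(vg$sill - 1), 0.25)
  expect_lt(abs(vg$range - 5) / 5, 0.25)
  expect_lt(vg$nugget, 0.1 * vg$sill)
  # constant data: flagged degenerate with documented defaults
  cst <- data.frame(X = runif(30), Y = runif(30), t_c = 0, v_n = 2)
  vgc <- fit_variogram(empirical_semivariogram(cst, time_scaling = 0,
                                               max_lag_frac = 1))
  expect_true(vgc$degenerate)
})

test_that("kriging is an exact interpolator with zero variance at data sites", {
  # well-separated sites: several correlation lengths of spread
  set.seed(64)
  n <- 60
  df <- data.frame(X = runif(n, 0, 60), Y = runif(n, 0, 60),
                   t_c = runif(n, 0, 60))
  df$v_n <- sin(df$X / 8) + 0.5 * cos(df$Y / 10) + 0.02 * df$t_c
  vg <- structure(list(nugget = 0, sill = 1, range = 4, time_scaling = 1,
                       degenerate = FALSE, wrss = 0),
                  class = "variogram_model")
  fit <- ukrige(v_n ~ X + Y + t_c, df, variogram = vg, time_scaling = 1)
  pr <- predict(fit, df, se.fit = TRUE)
  expect_lt(max(abs(pr$fit - df$v_n)) / max(abs(df$v_n)), 1e-8)
  expect_lt(max(pr$se.fit^2), 1e-10 * vg$sill)
})

test_that("constant observations predict that constant everywhere", {
  set.seed(65)
  df <- data.frame(X = runif(25, -1, 1), Y = runif(25, -1, 1),
                   t_c = rep(c(0, 0.5), length.out = 25), v_n = 0.37)
  vg <- structure(list(nugget = 0, sill = 0.2, range = 1, time_scaling = 1,
                       degenerate = FALSE, wrss = 0),
                  class = "variogram_model")
  fit <- ukrige(v_n ~ X + Y + t_c, df, variogram = vg, time_scaling = 1)
  q <- data.frame(X = c(0, 0.9, -2), Y = c(0, -0.9, 1), t_c = c(0, 0.2, 3))
  expect_equal(predict(fit, q), rep(0.37, 3), tolerance = 1e-9)
})

test_that("two symmetric equal observations predict their value at the midpoint", {
  df <- data.frame(X = c(-1, 1), Y = 0, t_c = 0, v_n = 0.6)
  vg <- structure(list(nugget = 0, sill = 1, range = 2, time_scaling = 0,
                       degenerate = FALSE, wrss = 0),
                  class = "variogram_model")
  fit <- ukrige(v_n ~ 1, df, variogram = vg, time_scaling = 0)
  expect_equal(predict(fit, data.frame(X = 0, Y = 0, t_c = 0)), 0.6,
               tolerance = 1e-10)
})

test_that("universal kriging agrees with an independent GP regression oracle", {
  set.seed(66)
  worst <- 0
  for (i in 1:30) {
    m <- sample(10:50, 1)
    tr <- data.frame(X = runif(m, 0, 30), Y = runif(m, 0, 30),
                     t_c = runif(m, 0, 30))
    tr$v_n <- sin(tr$X / 4) + 0.3 * cos(tr$Y / 5) + 0.1 * tr$t_c / 30
    sill <- runif(1, 0.5, 2); rng <- runif(1, 2, 8)
    vg <- structure(list(nugget = 0, sill = sill, range = rng,
                         time_scaling = 1, degenerate = FALSE, wrss = 0),
                    class = "variogram_model")
    fit <- ukrige(v_n ~ 1, tr, variogram = vg, time_scaling = 1)
    q <- data.frame(X = runif(5, 0, 30), Y = runif(5, 0, 30),
                    t_c = runif(5, 0, 30))
    a <- predict(fit, q)
    b <- gp_regress_oracle(tr, q, sill, rng)
    worst <- max(worst, max(abs(a - b)) / max(abs(b)))
  }
  expect_lt(worst, 1e-6)
})

test_that("predictions are invariant under in-plane rotation", {
  set.seed(67)
  n <- 40
  df <- data.frame(X = runif(n, -1.5, 1.5), Y = runif(n, -1.5, 1.5),
                   t_c = rep((0:4) * 0.2, 8))
  df$v_n <- 0.5 * (1 - (df$X^2 + df$Y^2) / 4) + 0.1 * sin(df$t_c)
  vg <- structure(list(nugget = 0, sill = 0.3, range = 1.5,
                       time_scaling = 2, degenerate = FALSE, wrss = 0),
                  class = "variogram_model")
  q <- data.frame(X = c(0.3, -0.7), Y = c(0.4, 0.2), t_c = 0.2)
  th <- 0.77
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(d) {
    XY <- as.matrix(d[, c("X", "Y")]) %*% Rm
    d$X <- XY[, 1]; d$Y <- XY[, 2]; d
  }
  fit <- ukrige(v_n ~ X + Y + t_c, df, variogram = vg, time_scaling = 2)
  fit_r <- ukrige(v_n ~ X + Y + t_c, rot(df), variogram = vg,
                  time_scaling = 2)
  expect_equal(predict(fit_r, rot(q)), predict(fit, q), tolerance = 1e-8)
})

test_that("kriging variance is non-negative, small at data and inflated off-data", {
  field <- study_field()
  plane <- poi_plane(field$geometry)
  set.seed(68)
  obs <- sample_poi(field, plane, sampling_plan(n_points = 20))
  train <- augment_no_slip(training_set(obs, plane))
  fit <- ukrige(data = train)
  pr <- predict(fit, obs[1:50, ], se.fit = TRUE)
  expect_true(all(pr$se.fit >= 0))
  expect_lt(max(pr$se.fit), 1e-6 * stats::sd(train$v_n))
  # a time instant with no data is still predicted, with larger uncertainty
  on_data <- predict(fit, data.frame(X = 0.3, Y = 0.2, t_c = 0.064),
                     se.fit = TRUE)
  off_data <- predict(fit, data.frame(X = 0.3, Y = 0.2, t_c = 0.032),
                      se.fit = TRUE)
  expect_gt(off_data$se.fit, on_data$se.fit)
})

test_that("dense noiseless sampling converges to the analytic profile", {
  set.seed(10)
  field <- study_field()
  plane <- poi_plane(field$geometry)
  obs <- sample_poi(field, plane,
                    sampling_plan(n_points = 40, radius_fraction = 1))
  prof <- reconstruct_profile(training_set(obs, plane), grid_n = 24,
                              variance = FALSE)
  gg <- expand.grid(X = prof$X, Y = prof$Y)
  ins <- as.vector(prof$mask)
  worst <- 0; peak <- 0; sse <- 0; m <- 0
  for (ti in seq_along(prof$instants)) {
    vt <- as.numeric(truth_vn(field, plane, gg$X[ins], gg$Y[ins],
                              prof$instants[ti]))
    vr <- as.vector(prof$mean[, , ti])[ins]
    worst <- max(worst, max(abs(vr - vt)))
    peak <- max(peak, max(vt))
    sse <- sse + sum((vr - vt)^2); m <- m + length(vt)
  }
  expect_lt(worst / peak, 0.15)          # worst node, worst instant
  expect_lt(sqrt(sse / m) / peak, 0.05)  # RMS over the space-time lattice
})

test_that("uncertainty is lower near observations than in data-free regions", {
  set.seed(69)
  field <- study_field()
  plane <- poi_plane(field$geometry)
  obs <- sample_poi(field, plane,
                    sampling_plan(n_points = 15, radius_fraction = 0.5))
  prof <- reconstruct_profile(training_set(obs, plane), grid_n = 24,
                              instants = 0.064)
  gg <- expand.grid(X = prof$X, Y = prof$Y)
  r <- sqrt(gg$X^2 + gg$Y^2)
  sd1 <- prof$sd[, , 1]
  # samples live inside 0.5 R and the no-slip ring pins the wall; the
  # annulus between them is data-free and should be the most uncertain
  near <- as.vector(sd1)[as.vector(prof$mask) & r < 0.4 * plane$radius]
  gap <- as.vector(sd1)[as.vector(prof$mask) & r > 0.55 * plane$radius &
                          r < 0.8 * plane$radius]
  wall <- as.vector(sd1)[as.vector(prof$mask) & r > 0.9 * plane$radius]
  expect_lt(stats::median(near), stats::median(gap))
  expect_lt(stats::median(wall), stats::median(gap))
})

test_that("the fitted model exposes the standard S3 surface", {
  set.seed(70)
  field <- study_field()
  plane <- poi_plane(field$geometry)
  obs <- sample_poi(field, plane, sampling_plan(n_points = 10))
  train <- augment_no_slip(training_set(obs, plane))
  fit <- ukrige(data = train)
  expect_s3_class(fit, "ukrige")
  expect_named(coef(fit), c("(Intercept)", "X", "Y", "t_c"))
  expect_length(residuals(fit), nrow(train))
  expect_equal(fitted(fit), train$v_n, tolerance = 1e-6)
  expect_output(print(fit), "universal kriging")
  expect_output(print(summary(fit)), "drift coefficients")
  sims <- simulate(fit, nsim = 3, seed = 1,
                   newdata = data.frame(X = 0, Y = 0, t_c = 0.1))
  expect_equal(dim(sims), c(1L, 3L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
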