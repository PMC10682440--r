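test_that("thin-plate features follow r^2 log r with a zero limit", {
  ctr <- rbind(c(0, 0), c(3, 4))
  expect_equal(thin_plate_rbf(c(1, 0), ctr)[1], 0)          # r = 1
  expect_equal(thin_plate_rbf(c(exp(1), 0), ctr)[1], exp(2), # r = e
               tolerance = 1e-12)
  expect_equal(thin_plate_rbf(c(3, 4), ctr)[2], 0)          # at a center
  # matrix input returns one row per state
  M <- thin_plate_rbf(rbind(c(1, 0), c(3, 4)), ctr)
  expect_equal(dim(M), c(2, 2))
})

test_that("k-means centers land inside well-separated clusters", {
  set.seed(21)
  # two blobs in extended-state space via two output levels
  mk <- function(level) {
    y <- level + rnorm(103, sd = 0.01)
    list(y = y, u = rep(0, 103), X = cbind(B = y, E = y, Ti = y, Tu = y))
  }
  ds <- structure(list(traj = list(mk(0), mk(10)), dt = 1, seed = 21,
                       n_resampled = 0L),
                  class = "koopman_training")
  ctr <- fit_centers(ds, k = 2, seed = 1)
  expect_equal(as.numeric(sort(round(ctr[, 1]))), c(0, 10))
  # k = 1 closed form: the pooled mean
  c1 <- fit_centers(ds, k = 1, seed = 1)
  Z <- rbind(bcgrmc:::extended_states(ds$traj[[1]]$y, ds$traj[[1]]$u)$Z,
             bcgrmc:::extended_states(ds$traj[[2]]$y, ds$traj[[2]]$u)$Z)
  expect_equal(unname(c1[1, ]), unname(colMeans(Z)), tolerance = 1e-12)
  expect_identical(fit_centers(ds, k = 2, seed = 7),
                   fit_centers(ds, k = 2, seed = 7))
  expect_error(fit_centers(ds, k = 10000), "distinct")
})

test_that("EDMD recovers a truly linear data-generating process exactly", {
  ds <- make_arx_training()
  tru <- arx_truth()
  km <- fit_koopman(ds, centers = NULL)
  expect_lt(max(abs(km$A_lift - tru$A)), 1e-8)
  expect_lt(max(abs(km$B_lift - tru$B)), 1e-8)
  expect_lt(km$residual, 1e-10)
  # multi-step rollout reproduces a fresh ARX trajectory
  tr <- make_arx_training(n_traj = 1, kt = 80, seed = 99)$traj[[1]]
  z0 <- c(tr$y[3], tr$y[2], tr$y[1], tr$u[2], tr$u[1])
  pr <- koopman_predict(km, z0, inputs = tr$u[3:80], steps = 78)
  expect_lt(max(abs(pr[, 4] - tr$y[3:81])), 1e-8)
})

test_that("the default lifting has dimension 15 (5 delays + 10 RBFs)", {
  km <- small_koopman()
  expect_equal(nrow(km$A_lift), 15)
  expect_equal(dim(km$A_lift), c(15, 15))
  expect_equal(dim(km$B_lift), c(15, 1))
  expect_equal(dim(km$C_lift), c(4, 15))
  expect_equal(km$n_rbf, 10)
})

test_that("adding RBF features never hurts the training residual", {
  ds <- generate_training_data(n_traj = 5, horizon = 20, seed = 31)
  plain <- fit_koopman(ds, centers = NULL)
  rich <- suppressWarnings(fit_koopman(ds, fit_centers(ds, k = 10,
                                                       seed = 32)))
  # nested least squares on the shared (delay-coordinate) target rows
  expect_lte(rich$residual_delay, plain$residual_delay + 1e-12)
})

test_that("training data generation is seeded and within dose bounds", {
  d1 <- generate_training_data(n_traj = 3, horizon = 10, seed = 41)
  d2 <- generate_training_data(n_traj = 3, horizon = 10, seed = 41)
  expect_identical(d1, d2)
  expect_length(d1$traj, 3)
  for (tr in d1$traj) {
    expect_true(all(tr$u >= 0 & tr$u <= 6.4))
    expect_equal(tr$y, unname(tr$X[, "Tu"]))
  }
})

test_that("one-step fit error does not exceed multi-step rollout error", {
  km <- small_koopman()
  set.seed(55)
  gap <- seq(0, 4000, by = 500)
  dvec <- runif(length(gap), 0, 6.4)
  sched <- impulse_schedule(gap, dvec, 0.01, 4000)
  tr <- simulate_bcg(schedule = sched, kt = 4000)
  u <- numeric(4001); u[gap + 1] <- dvec
  z0 <- c(tr$states[3, 4], tr$states[2, 4], tr$states[1, 4], u[2], u[1])
  pr <- koopman_predict(km, z0, inputs = u[4:4001], steps = 3998)
  rollout_rmse <- sqrt(mean((pr[, 4] - tr$states[3:4001, 4])^2))
  expect_gte(rollout_rmse, km$residual * 0.01)
  expect_lt(rollout_rmse, 1)  # and the surrogate still tracks the plant
})

test_that("the analytic Jacobian matches finite differences", {
  p <- bcg_params()
  xop <- c(0.3, 0.2, 0.1, 0.7)
  lin <- taylor_linearize(p, xop)
  fd <- matrix(0, 4, 4)
  h <- 1e-6
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    fd[, j] <- (ode_rhs(xop + e, p) - ode_rhs(xop - e, p)) / (2 * h)
  }
  expect_equal(unname(lin$J), unname(fd), tolerance = 1e-6)
  # structure at the origin: block-diagonal decay/growth, one coupling
  J0 <- taylor_linearize(p, c(0, 0, 0, 0))$J
  expect_equal(unname(diag(J0)), c(-1, -0.41, 0, 0.032))
  expect_equal(unname(J0["E", "Ti"]), 0.52)
  off <- J0; diag(off) <- 0; off["E", "Ti"] <- 0
  expect_true(all(off == 0))
})

test_that("a fitted surrogate survives a serialization round trip", {
  km <- small_koopman()
  f <- tempfile(fileext = ".json")
  write_koopman_model(km, f)
  km2 <- read_koopman_model(f)
  expect_equal(km2$A_lift, unname(km$A_lift))
  expect_equal(km2$centers, unname(km$centers))
  pr1 <- koopman_predict(km, c(0.8, 0.8, 0.8, 0, 0), 2, steps = 50)
  pr2 <- koopman_predict(km2, c(0.8, 0.8, 0.8, 0, 0), 2, steps = 50)
  expect_equal(pr1, pr2, tolerance = 1e-12)
})
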