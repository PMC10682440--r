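test_that("vector field matches the model equations", {
  # origin is an equilibrium
  expect_equal(unname(ode_rhs(c(0, 0, 0, 0))), rep(0, 4))
  # direct substitution of the dimensionless defaults at the study x0
  expect_equal(unname(ode_rhs(c(0.1, 0.1, 0, 0.8))),
               c(-0.1353, -0.0398, 0.0228, 0.00257472), tolerance = 1e-12)
  # with B = E = Ti = 0 the tumor decouples to pure logistic growth
  for (tu in c(0.3, 5, 50)) {
    d <- ode_rhs(c(0, 0, 0, tu))
    expect_equal(unname(d[1:3]), rep(0, 3))
    expect_equal(unname(d[4]), 0.032 * (1 - 0.011 * tu) * tu)
  }
  expect_error(ode_rhs(c(NaN, 0, 0, 0)), "finite")
  expect_error(bcg_params(mu1 = -1), "positive")
})

test_that("RK4 stepper is exact to its order on the logistic limit", {
  expect_equal(unname(rk4_step(c(0, 0, 0, 0))), rep(0, 4))
  s <- rk4_step(c(0, 0, 0, 0.8), dt = 0.01)
  expect_equal(unname(s[4]), logistic_tu(0.01, 0.8), tolerance = 1e-10)
  expect_equal(unname(s[1:3]), rep(0, 3))
  expect_error(rk4_step(c(0, 0, 0, 0.8), dt = 0), "positive")
})

test_that("observed RK4 convergence order is four on the coupled system", {
  x0 <- bcg_x0()
  final <- function(dt) {
    tr <- simulate_bcg(x0 = x0, kt = round(1 / dt), dt = dt)
    tr$states[nrow(tr$states), ]
  }
  ref <- final(1e-3)
  e1 <- max(abs(final(0.1) - ref))
  e2 <- max(abs(final(0.05) - ref))
  order <- log2(e1 / e2)
  expect_gt(order, 3.8)
  expect_lt(order, 4.2)
})

test_that("impulses act additively on the BCG channel only", {
  x <- c(0.1, 0.1, 0, 0.8)
  expect_equal(unname(apply_impulse(x, 5.46)), c(5.56, 0.1, 0, 0.8))
  expect_equal(apply_impulse(x, 0), setNames(x, c("B", "E", "Ti", "Tu")))
  expect_equal(apply_impulse(apply_impulse(x, 2), 3), apply_impulse(x, 5))
  expect_error(apply_impulse(x, -1), "nonnegative")
  # coincident instillations merge additively in the schedule
  sch <- impulse_schedule(c(100, 100), c(2, 3), kt = 1000)
  expect_equal(sch$idx, 100L)
  expect_equal(sch$dose, 5)
})

test_that("untreated simulation reproduces the logistic solution", {
  tr <- simulate_bcg(x0 = c(0, 0, 0, 0.8), kt = 10000, dt = 0.01)
  expect_equal(tr$states[, "Tu"], logistic_tu(tr$time, 0.8),
               tolerance = 1e-6)
  expect_equal(unname(tr$states[nrow(tr$states), "Tu"]), 16.2589,
               tolerance = 1e-4)
  # zero state is a fixed point
  tr0 <- simulate_bcg(x0 = rep(0, 4), kt = 500)
  expect_true(all(tr0$states == 0))
})

test_that("compiled simulator agrees with the R stepper and conserves dose", {
  sch <- impulse_schedule(c(0, 60, 130), c(1.5, 2, 0.7), dt = 0.01, kt = 200)
  tr <- simulate_bcg(schedule = sch)
  # replay in R: impulse first, then one RK4 step
  x <- bcg_x0()
  dose_at <- numeric(201); dose_at[sch$idx + 1] <- sch$dose
  for (k in 0:200) {
    x <- apply_impulse(x, dose_at[k + 1])
    expect_equal(unname(tr$states[k + 1, ]), unname(x), tolerance = 1e-12)
    x <- rk4_step(x, dt = 0.01)
  }
  # sum of instantaneous B jumps equals the administered total
  pre_B <- c(tr$x0[1], vapply(2:201, function(i)
    rk4_step(tr$states[i - 1, ], dt = 0.01)[1], 0))
  jumps <- tr$states[, "B"] - pre_B
  expect_equal(sum(jumps), sum(sch$dose), tolerance = 1e-12)
})

test_that("states stay nonnegative up to integrator rounding", {
  sch <- build_input_signal(dosing_scheme(5.46, 5, 10))
  tr <- simulate_bcg(schedule = sch)
  expect_gte(min(tr$states), -1e-9)
})

test_that("untreated tumor maximum behaves as the logistic analysis predicts", {
  expect_equal(untreated_tumor_max(x0 = c(0, 0, 0, 0.8)),
               logistic_tu(100, 0.8), tolerance = 1e-6)
  expect_equal(untreated_tumor_max(x0 = c(0.1, 0.1, 0, 0)), 0)
  expect_gt(untreated_tumor_max(params = bcg_params(r = 0.064)),
            untreated_tumor_max())
})

test_that("settling time finds the grid crossing of the threshold", {
  # synthetic exponential decay: crossing at ln(100)/0.2 = 23.026 days
  tm <- seq(0, 100, by = 0.01)
  traj <- structure(list(time = tm,
                         states = cbind(B = 0, E = 0, Ti = 0,
                                        Tu = 0.8 * exp(-0.2 * tm)),
                         dt = 0.01),
                    class = "bcg_trajectory")
  expect_equal(settling_time(traj), log(100) / 0.2, tolerance = 0.011)
  # growing tumor never crosses
  untreated <- simulate_bcg(kt = 2000)
  expect_true(is.na(settling_time(untreated)))
  # degenerate and invalid inputs
  traj$states[1, "Tu"] <- 0
  expect_error(settling_time(traj), "positive")
  expect_error(settling_time(untreated, fraction = 1.2), "between")
})
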