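# shared in-code fixtures

# ARX(3) system whose delay-embedded extended state evolves exactly
# linearly in companion form: the ground truth EDMD must recover.
arx_truth <- function() {
  a <- c(0.5, 0.2, 0.1)
  b <- c(0.3, 0.15, 0.05)
  A <- rbind(c(a[1], a[2], a[3], b[2], b[3]),
             c(1, 0, 0, 0, 0),
             c(0, 1, 0, 0, 0),
             c(0, 0, 0, 0, 0),
             c(0, 0, 0, 1, 0))
  B <- c(b[1], 0, 0, 1, 0)
  list(a = a, b = b, A = A, B = B)
}

# training set of ARX trajectories in the koopman_training layout
make_arx_training <- function(n_traj = 4, kt = 200, seed = 5) {
  set.seed(seed)
  tru <- arx_truth()
  a <- tru$a; b <- tru$b
  traj <- replicate(n_traj, {
    y <- numeric(kt + 1); u <- numeric(kt + 1)
    y[1:3] <- rnorm(3); u[1:3] <- rnorm(3)
    for (i in 3:kt) {
      u[i] <- rnorm(1)
      y[i + 1] <- a[1] * y[i] + a[2] * y[i - 1] + a[3] * y[i - 2] +
        b[1] * u[i] + b[2] * u[i - 1] + b[3] * u[i - 2]
    }
    list(y = y, u = u, X = cbind(B = y, E = y, Ti = y, Tu = y))
  }, simplify = FALSE)
  structure(list(traj = traj, dt = 1, seed = seed, n_resampled = 0L),
            class = "koopman_training")
}

# hand-made lifted "model" with chosen matrices (no RBF features)
toy_koopman_model <- function(A, B, C, dt = 1) {
  structure(list(A_lift = A, B_lift = matrix(B, ncol = 1), C_lift = C,
                 centers = matrix(0, 0, ncol(A)), n_rbf = 0L, dt = dt,
                 n_d = 1, residual = 0),
            class = "koopman_model")
}

# Ishigami function on the unit cube (a = 7, b = 0.1); analytic Sobol
# indices: S = (0.3139, 0.4424, 0), ST = (0.5576, 0.4424, 0.2437)
ishigami_unit <- function(U) {
  X <- -pi + 2 * pi * U
  sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
}
ishigami_S_exact <- c(0.3139, 0.4424, 0)
ishigami_ST_exact <- c(0.5576, 0.4424, 0.2437)

# analytic logistic tumor solution for B = E = Ti = 0
logistic_tu <- function(t, tu0, r = 0.032, beta = 0.011) {
  K <- 1 / beta
  K / (1 + (K / tu0 - 1) * exp(-r * t))
}

# small trained surrogate shared by the koopman/mpc tests (cached)
small_koopman <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_training_data(n_traj = 8, horizon = 40, seed = 11)
      ctr <- fit_centers(ds, k = 10, seed = 12)
      cache <<- fit_koopman(ds, ctr)
    }
    cache
  }
})
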