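#' Training data for the lifted linear surrogate
#'
#' Simulates `n_traj` randomized treatment courses of the nonlinear model
#' and records, per trajectory, the output sequence `y = Tu`, the full
#' state matrix and the input sequence on the integration grid.  Initial
#' states draw `B, E, Ti ~ U[0, 0.5]` and `Tu ~ U[0.1, 1]`; instillations
#' occur every `dose_gap` days with doses `~ U[0, dose_max]`, covering the
#' operating envelope of both controllers.  Trajectories that blow up are
#' dropped and resampled (count kept in `n_resampled`).
#'
#' @param params model parameters.
#' @param n_traj number of trajectories.
#' @param horizon days per trajectory.
#' @param dt grid step (days).
#' @param dose_gap days between training instillations.
#' @param dose_max upper bound of the uniform training dose.
#' @param seed RNG seed.
#' @return List of class `koopman_training` with elements `traj` (list of
#'   `list(y, X, u)`), `dt`, `seed`, `n_resampled`.
#' @export
generate_training_data <- function(params = bcg_params(), n_traj = 100,
                                   horizon = 100, dt = 0.01, dose_gap = 5,
                                   dose_max = 6.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kt <- round(horizon / dt)
  p <- as_param_vector(params)
  gap_idx <- seq(0, kt, by = round(dose_gap / dt))
  traj <- vector("list", n_traj)
  n_resampled <- 0L
  for (i in seq_len(n_traj)) {
    repeat {
      x0 <- setNames(c(runif(3, 0, 0.5), runif(1, 0.1, 1)), .STATE_NAMES)
      doses <- runif(length(gap_idx), 0, dose_max)
      X <- tryCatch(sim_path_cpp(p, x0, as.integer(gap_idx), doses, kt, dt),
                    error = function(e) NULL)
      if (!is.null(X)) break
      n_resampled <- n_resampled + 1L
    }
    u <- numeric(kt + 1)
    u[gap_idx + 1] <- doses
    colnames(X) <- .STATE_NAMES
    traj[[i]] <- list(y = X[, "Tu"], X = X, u = u)
  }
  structure(list(traj = traj, dt = dt, seed = seed,
                 n_resampled = n_resampled),
            class = "koopman_training")
}

#' Thin-plate-spline radial basis features
#'
#' `psi(r) = r^2 log(r)` with `r` the Euclidean distance of `z` to each
#' center; the removable singularity at `r = 0` is defined as 0.
#'
#' @param z numeric vector (one extended state) or matrix (rows =
#'   states).
#' @param centers matrix of RBF centers (rows = centers).
#' @return Numeric vector (or matrix, rows matching `z`) of length
#'   `nrow(centers)`.
#' @export
thin_plate_rbf <- function(z, centers) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  centers <- as.matrix(centers)
  out <- matrix(0, nrow(z), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    r2 <- rowSums(sweep(z, 2, centers[j, ])^2)
    out[, j] <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)  # r^2 log r
  }
  if (nrow(out) == 1) drop(out) else out
}

# Extended delay-embedded state Z_k = [y_k, y_{k-1}, y_{k-2}, u_{k-1}, u_{k-2}]
# for one trajectory.  y[i] and u[i] hold the output and the applied input
# at grid step k = i - 1; samples k = (n_d + 1)..(kt - 1) have a full lag
# history and a one-step-ahead target, the first n_d + 1 steps are dropped.
extended_states <- function(y, u, n_d = 1) {
  kt <- length(y) - 1
  i <- (n_d + 2):kt             # 1-based positions of y_k
  Z <- cbind(y[i], y[i - 1], y[i - 2], u[i - 1], u[i - 2])
  Z1 <- cbind(y[i + 1], y[i], y[i - 1], u[i], u[i - 1])
  list(Z = Z, Z1 = Z1, u = u[i], rows = i)
}

#' K-means centers over the pooled extended states
#'
#' @param dataset a `koopman_training` set.
#' @param k number of centers (default 10 RBFs).
#' @param seed RNG seed for the k-means initialization.
#' @param n_d delay embedding depth.
#' @return `k x 5` matrix of centers in extended-state space.
#' @export
fit_centers <- function(dataset, k = 10, seed = NULL, n_d = 1) {
  stopifnot(inherits(dataset, "koopman_training"))
  Z <- do.call(rbind, lapply(dataset$traj, function(tr)
    extended_states(tr$y, tr$u, n_d)$Z))
  if (k > nrow(unique(Z))) stop("k exceeds the number of distinct states")
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(Z, centers = k, nstart = 1, iter.max = 50)
  km$centers
}

#' Fit the lifted linear (EDMD) model
#'
#' Stacks every aligned sample `(Z_lift(k), u(k)) -> (Z_lift(k+1), X(k))`
#' from the training set, where `Z_lift = [Z; psi(Z)]` appends the
#' thin-plate RBF features to the delay-embedded state, and solves the
#' least-squares problems
#' `Z_lift(k+1) ~ A_lift Z_lift(k) + B_lift u(k)` (jointly, via the
#' pseudo-inverse of the stacked regressor, so a rank-deficient regressor
#' yields the minimum-norm solution with a warning) and
#' `X(k) ~ C_lift Z_lift(k)` (projection back to the full state).
#' The first `n_d + 1` steps of each trajectory lack full lag history and
#' are dropped.
#'
#' @param dataset a `koopman_training` set.
#' @param centers RBF centers from [fit_centers()]; a matrix with zero
#'   rows (or `NULL`) fits the delay-embedded model without RBF features.
#' @param ridge optional Tikhonov regularization added to the normal
#'   matrix (default 0 = plain pseudo-inverse).
#' @param n_d delay embedding depth (default 1, extended-state dimension
#'   `N = n_y (n_d + 2) + (n_d + 1) n_u = 5`).
#' @return Object of class `koopman_model`: `A_lift`, `B_lift`, `C_lift`,
#'   `centers`, `n_rbf`, `dt`, `n_d`, `residual` (training one-step RMS).
#' @export
fit_koopman <- function(dataset, centers = NULL, ridge = 0, n_d = 1) {
  stopifnot(inherits(dataset, "koopman_training"))
  if (is.null(centers)) centers <- matrix(0, 0, 2 + n_d + 1 + n_d)
  centers <- as.matrix(centers)
  n_rbf <- nrow(centers)
  parts <- lapply(dataset$traj, function(tr) extended_states(tr$y, tr$u, n_d))
  Z <- do.call(rbind, lapply(parts, `[[`, "Z"))
  Z1 <- do.call(rbind, lapply(parts, `[[`, "Z1"))
  U <- unlist(lapply(parts, `[[`, "u"))
  X <- do.call(rbind, lapply(seq_along(parts), function(i)
    dataset$traj[[i]]$X[parts[[i]]$rows, , drop = FALSE]))
  lift <- function(M) if (n_rbf > 0) cbind(M, thin_plate_rbf(M, centers)) else M
  ZL <- lift(Z); ZL1 <- lift(Z1)
  # least squares of target ~ regressor via pseudo-inverse of the normal
  # matrix, with column equilibration so the RBF features (which can dwarf
  # the input column by orders of magnitude) do not wreck the conditioning
  ls_pinv <- function(regressor, target, ridge) {
    sc <- sqrt(colMeans(regressor^2))
    sc[sc == 0] <- 1
    Gs <- sweep(regressor, 2, sc, `/`)
    M <- crossprod(Gs)
    if (ridge > 0) M <- M + diag(ridge, ncol(Gs))
    if (qr(M)$rank < ncol(Gs))
      warning("rank-deficient EDMD regressor; minimum-norm solution returned")
    coefs <- pracma::pinv(M) %*% crossprod(Gs, target)
    t(coefs / sc)                       # coefficient rows on original scale
  }
  G <- cbind(ZL, U)                     # samples x (nlift + 1)
  AB <- ls_pinv(G, ZL1, ridge)          # nlift x (nlift + 1)
  nl <- ncol(ZL)
  A_lift <- AB[, seq_len(nl), drop = FALSE]
  B_lift <- AB[, nl + 1, drop = FALSE]
  # state projection regresses on the lifted state alone (the zero block of
  # the stacked solution is imposed, not estimated)
  C_lift <- ls_pinv(ZL, X, ridge)
  pred <- ZL %*% t(A_lift) + U %*% t(B_lift)
  res <- sqrt(mean((pred - ZL1)^2))
  nz <- ncol(Z)   # delay-coordinate block, shared by any dictionary size
  res_delay <- sqrt(mean((pred[, seq_len(nz)] - ZL1[, seq_len(nz)])^2))
  structure(list(A_lift = A_lift, B_lift = B_lift, C_lift = C_lift,
                 centers = centers, n_rbf = n_rbf, dt = dataset$dt,
                 n_d = n_d, residual = res, residual_delay = res_delay),
            class = "koopman_model")
}

#' @export
print.koopman_model <- function(x, ...) {
  cat(sprintf("<koopman_model> lifted dim %d (%d delay coords + %d RBFs), dt = %g d\n",
              nrow(x$A_lift), nrow(x$A_lift) - x$n_rbf, x$n_rbf, x$dt))
  cat(sprintf("  training one-step residual (RMS): %.3g\n", x$residual))
  invisible(x)
}

#' Lift an extended state
#'
#' @param model a `koopman_model`.
#' @param z extended state `[y_k, y_{k-1}, y_{k-2}, u_{k-1}, u_{k-2}]`.
#' @return Lifted vector `[z; psi(z)]`.
#' @export
lift_state <- function(model, z) {
  if (model$n_rbf > 0) c(z, thin_plate_rbf(z, model$centers)) else z
}

#' Roll the lifted linear model forward
#'
#' Iterates `Z_lift(k+1) = A_lift Z_lift(k) + B_lift u(k)` from the lifted
#' `z0` (the lifting is applied once; the recursion is purely linear) and
#' projects every step through `C_lift`.
#'
#' @param model a `koopman_model`.
#' @param z0 initial extended state (unlifted, length 5 with defaults).
#' @param inputs input sequence `u(0..steps-1)`; recycled scalars allowed.
#' @param steps number of steps.
#' @return `(steps + 1) x 4` matrix of projected state estimates
#'   (row 1 = projection of the initial lifted state).
#' @export
koopman_predict <- function(model, z0, inputs = 0, steps) {
  zl <- lift_state(model, z0)
  u <- rep_len(inputs, max(steps, 1))
  out <- matrix(0, steps + 1, nrow(model$C_lift))
  out[1, ] <- drop(model$C_lift %*% zl)
  if (steps > 0) for (k in seq_len(steps)) {
    zl <- drop(model$A_lift %*% zl) + drop(model$B_lift) * u[k]
    out[k + 1, ] <- drop(model$C_lift %*% zl)
  }
  colnames(out) <- if (nrow(model$C_lift) == 4) .STATE_NAMES else NULL
  out
}

#' Jacobian linearization of the nonlinear model
#'
#' Analytic Jacobian of the vector field at an operating point, plus the
#' affine offset, giving the local model
#' `x_dot = J (x - x_op) + f(x_op)`.  Used as the truncated-Taylor
#' comparison baseline for the lifted surrogate.
#'
#' @param params model parameters.
#' @param operating_point state at which to linearize.
#' @return List with `J` (4 x 4), `f0` (vector field value), `x_op`.
#' @export
taylor_linearize <- function(params = bcg_params(),
                             operating_point = bcg_x0()) {
  p <- as_param_vector(params)
  x <- check_state(operating_point)
  B <- x[1]; E <- x[2]; Ti <- x[3]; Tu <- x[4]
  J <- matrix(0, 4, 4, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  J[1, 1] <- -p["mu1"] - p["p1"] * E - p["p2"] * Tu
  J[1, 2] <- -p["p1"] * B
  J[1, 4] <- -p["p2"] * B
  J[2, 1] <- p["p4"] * E
  J[2, 2] <- -p["mu2"] + p["p4"] * B - p["p5"] * Ti
  J[2, 3] <- p["alpha"] - p["p5"] * E
  J[3, 1] <- p["p2"] * Tu
  J[3, 2] <- -p["p3"] * Ti
  J[3, 3] <- -p["p3"] * E
  J[3, 4] <- p["p2"] * B
  J[4, 1] <- -p["p2"] * Tu
  J[4, 4] <- -p["p2"] * B + p["r"] - 2 * p["r"] * p["beta"] * Tu
  list(J = J, f0 = ode_rhs(x, params), x_op = x)
}

#' Simulate the Taylor-linearized model with impulsive inputs
#'
#' RK4 on the affine system from [taylor_linearize()] with the same step
#' and impulse convention as the nonlinear simulator, for a like-for-like
#' comparison of surrogate quality.
#'
#' @param lin output of [taylor_linearize()].
#' @param x0 initial state.
#' @param schedule an [impulse_schedule()].
#' @return `(kt + 1) x 4` state matrix.
#' @export
taylor_predict <- function(lin, x0 = bcg_x0(), schedule) {
  stopifnot(inherits(schedule, "impulse_schedule"))
  kt <- schedule$kt; dt <- schedule$dt
  f <- function(x) drop(lin$J %*% (x - lin$x_op)) + lin$f0
  X <- matrix(0, kt + 1, 4, dimnames = list(NULL, .STATE_NAMES))
  x <- check_state(x0)
  j <- 1
  idx <- schedule$idx; dose <- schedule$dose
  for (k in 0:kt) {
    while (j <= length(idx) && idx[j] == k) { x[1] <- x[1] + dose[j]; j <- j + 1 }
    X[k + 1, ] <- x
    if (k < kt) {
      k1 <- f(x); k2 <- f(x + dt / 2 * k1)
      k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  X
}

#' Serialize / load a fitted Koopman model
#'
#' Plain-JSON round trip of the matrices, centers and layout metadata.
#'
#' @param model a `koopman_model`.
#' @param path file path.
#' @export
write_koopman_model <- function(model, path) {
  stopifnot(inherits(model, "koopman_model"))
  obj <- list(A_lift = model$A_lift, B_lift = model$B_lift,
              C_lift = model$C_lift, centers = model$centers,
              n_rbf = model$n_rbf, dt = model$dt, n_d = model$n_d,
              residual = model$residual)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_koopman_model
#' @export
read_koopman_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(A_lift = as.matrix(obj$A_lift),
                 B_lift = matrix(obj$B_lift, ncol = 1),
                 C_lift = as.matrix(obj$C_lift),
                 centers = if (obj$n_rbf > 0) as.matrix(obj$centers)
                           else matrix(0, 0, obj$n_d * 2 + 3),
                 n_rbf = obj$n_rbf, dt = obj$dt, n_d = obj$n_d,
                 residual = obj$residual),
            class = "koopman_model")
}
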