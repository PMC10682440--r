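#' Receding-horizon controller configuration
#'
#' Defaults mirror the comparison-controller study conditions: 5-day
#' prediction horizon, one free move per solve (control horizon of a
#' single treatment instant), instillations allowed every 5 days, state
#' weight `Q = diag(0, 0, 0, 1000)` (tumor channel only), input weight
#' `R = 0.1`, dose box `[0, 6.4]` (the controller may skip a treatment;
#' the clinical per-treatment lower bound 2.2 is available by setting
#' `u_min`), and an exponentially decaying tumor reference
#' `y_r(t) = Tu(0) exp(-decay t)`.
#'
#' @param Hp prediction horizon in days.
#' @param Hu number of free moves per solve (>= 1).
#' @param control_interval days between allowed instillations.
#' @param Q 4x4 state-error weight (positive semidefinite).
#' @param R scalar input weight.
#' @param u_min,u_max per-treatment dose limits.
#' @param ref_decay decay rate (1/day) of the tumor reference.
#' @return List of class `mpc_config`.
#' @export
mpc_config <- function(Hp = 5, Hu = 1, control_interval = 5,
                       Q = diag(c(0, 0, 0, 1000)), R = 0.1,
                       u_min = 0, u_max = 6.4, ref_decay = 1) {
  stopifnot(Hp > 0, Hu >= 1, control_interval > 0, u_min <= u_max,
            is.matrix(Q), nrow(Q) == 4, ncol(Q) == 4, R >= 0)
  if (Hu > ceiling(Hp / control_interval))
    stop("Hu exceeds the number of control instants inside Hp")
  structure(list(Hp = Hp, Hu = as.integer(Hu),
                 control_interval = control_interval, Q = Q, R = R,
                 u_min = u_min, u_max = u_max, ref_decay = ref_decay),
            class = "mpc_config")
}

#' Solve the discrete-time algebraic Riccati equation
#'
#' Finds the stabilizing solution of
#' `P = A' P A - (A' P B)(B' P B + R)^-1 (B' P A) + Q` by the
#' structure-preserving doubling algorithm, with a plain fixed-point
#' Riccati iteration as fallback.  The returned `P` is symmetrized; the
#' residual Frobenius norm must fall below `tol` or an error is raised
#' (with the achieved residual, so a near-miss is diagnosable).
#'
#' @param A,B system matrices (`n x n`, `n x m`).
#' @param Qc,Rc state and input weights (`Qc` PSD `n x n`, `Rc` PD
#'   `m x m`).
#' @param tol residual tolerance.
#' @param max_iter doubling iterations.
#' @return The solution matrix `P`.
#' @export
#' @examples
#' solve_dare(matrix(0.5), matrix(1), matrix(1), matrix(1)) # 1.13278...
solve_dare <- function(A, B, Qc, Rc, tol = 1e-9, max_iter = 200) {
  A <- as.matrix(A); B <- as.matrix(B)
  Qc <- as.matrix(Qc); Rc <- as.matrix(Rc)
  n <- nrow(A)
  dare_residual <- function(P) {
    S <- t(A) %*% P %*% B
    P_next <- t(A) %*% P %*% A -
      S %*% solve(t(B) %*% P %*% B + Rc, t(S)) + Qc
    norm(P_next - P, "F")
  }
  # structure-preserving doubling: Ak+1 = Ak (I + Gk Hk)^-1 Ak, etc.
  Ak <- A; Gk <- B %*% solve(Rc, t(B)); Hk <- Qc
  P <- NULL
  for (it in seq_len(max_iter)) {
    W <- diag(n) + Gk %*% Hk
    Winv <- tryCatch(solve(W), error = function(e) NULL)
    if (is.null(Winv)) break
    A1 <- Ak %*% Winv %*% Ak
    G1 <- Gk + Ak %*% Winv %*% Gk %*% t(Ak)
    H1 <- Hk + t(Ak) %*% Hk %*% Winv %*% Ak
    if (norm(H1 - Hk, "F") <= tol * max(1, norm(H1, "F"))) {
      P <- (H1 + t(H1)) / 2
      break
    }
    Ak <- A1; Gk <- G1; Hk <- H1
  }
  if (is.null(P)) P <- (Hk + t(Hk)) / 2
  if (dare_residual(P) > tol * max(1, norm(P, "F"))) {
    # fallback: fixed-point Riccati iteration from Qc
    P2 <- Qc
    for (it in seq_len(20000)) {
      S <- t(A) %*% P2 %*% B
      Pn <- t(A) %*% P2 %*% A -
        S %*% solve(t(B) %*% P2 %*% B + Rc, t(S)) + Qc
      Pn <- (Pn + t(Pn)) / 2
      if (norm(Pn - P2, "F") <= tol * max(1, norm(Pn, "F"))) { P2 <- Pn; break }
      P2 <- Pn
    }
    if (dare_residual(P2) < dare_residual(P)) P <- P2
    res <- dare_residual(P)
    if (res > tol * max(1, norm(P, "F")))
      stop(sprintf("DARE iteration did not converge (residual %.3g)", res))
  }
  P
}

#' Prediction matrices of the lifted model over the horizon
#'
#' Builds the stacked free response `W = [A; A^2; ...; A^S]` and forced
#' response `G` on the integration grid over `Hp` days (`S = Hp / dt`
#' steps).  The columns of `G` correspond to the control instants inside
#' the horizon (every `control_interval` days); impulsive dosing means a
#' move enters through `B` at its instant only, so
#' `G[i, j] = A^(i - 1 - k_j) B` for steps `i` past move step `k_j`, and
#' columns beyond the control horizon `Hu` are zeroed (those moves are
#' fixed at zero, the between-dose input).
#'
#' @param model a `koopman_model`.
#' @param Hp horizon (days).
#' @param Hu free moves.
#' @param control_interval days between moves.
#' @return List with `W` (`S*n x n`), `G` (`S*n x n_moves`), `steps`,
#'   `move_steps` (0-based), `n` (lifted dimension).
#' @export
build_prediction <- function(model, Hp = 5, Hu = 1, control_interval = 5) {
  A <- model$A_lift; B <- model$B_lift
  n <- nrow(A)
  S <- round(Hp / model$dt)
  if (S < 1) stop("horizon shorter than one integration step")
  move_steps <- seq(0, S - 1, by = round(control_interval / model$dt))
  if (length(move_steps) < 1) stop("horizon shorter than one control interval")
  W <- matrix(0, S * n, n)
  G <- matrix(0, S * n, length(move_steps))
  Apow <- diag(n)
  # cache A^i B for i = 0..S-1 (one matrix-vector product per step)
  AiB <- matrix(0, n, S)
  AiB[, 1] <- B
  if (S >= 2) for (i in 2:S) AiB[, i] <- A %*% AiB[, i - 1]
  for (i in seq_len(S)) {
    Apow <- A %*% Apow
    W[((i - 1) * n + 1):(i * n), ] <- Apow
    for (j in seq_along(move_steps)) {
      if (j > Hu) next  # beyond the control horizon: move pinned at zero
      lag <- (i - 1) - move_steps[j]
      if (lag >= 0)
        G[((i - 1) * n + 1):(i * n), j] <- AiB[, lag + 1]
    }
  }
  list(W = W, G = G, steps = S, move_steps = move_steps, n = n)
}

#' Assemble the dense QP of one receding-horizon solve
#'
#' Condenses the horizon cost
#' `sum_i ||C z(k+i) - x_r(k+i)||_Q^2 + sum_j R u_j^2 + ||z(k+S)||_P^2`
#' onto the move vector: `H = G' Qbar G + Rbar`, linear term
#' `f = G' Qbar (W z0 - Xr)`, with `Qbar` the block-diagonal stage
#' weights `C' Q C` (terminal block replaced by the DARE weight `P` in
#' lifted coordinates) and box constraints on each move encoded as
#' `A_cs u <= b_cs`.
#'
#' @param model a `koopman_model`.
#' @param pred prediction matrices from [build_prediction()].
#' @param config an [mpc_config()].
#' @param z0 current lifted state.
#' @param x_ref `steps x 4` reference matrix (or vector recycled across
#'   the horizon).
#' @param P_term terminal weight in lifted coordinates (`NULL` for the
#'   stage weight only).
#' @return List of class `qp_problem`: `H`, `f`, `A_cs`, `b_cs`,
#'   `n_moves`.
#' @export
build_qp <- function(model, pred, config, z0, x_ref, P_term = NULL) {
  Cc <- model$C_lift
  Qz <- t(Cc) %*% config$Q %*% Cc
  n <- pred$n; S <- pred$steps; nm <- ncol(pred$G)
  if (is.null(dim(x_ref))) x_ref <- matrix(x_ref, S, 4, byrow = TRUE)
  H <- matrix(0, nm, nm)
  f <- numeric(nm)
  free <- drop(pred$W %*% z0)           # stacked free response
  for (i in seq_len(S)) {
    ri <- ((i - 1) * n + 1):(i * n)
    Qi <- if (i == S && !is.null(P_term)) Qz + P_term else Qz
    Gi <- pred$G[ri, , drop = FALSE]
    # stage error in lifted coordinates: C z - x_r
    zi <- free[ri]
    err_lin <- t(Cc) %*% config$Q %*% (Cc %*% zi - x_ref[i, ])
    if (i == S && !is.null(P_term)) err_lin <- err_lin + P_term %*% zi
    H <- H + t(Gi) %*% Qi %*% Gi
    f <- f + drop(t(Gi) %*% err_lin)
  }
  H <- H + diag(config$R, nm)
  H <- (H + t(H)) / 2
  structure(list(H = H, f = f,
                 A_cs = rbind(diag(nm), -diag(nm)),
                 b_cs = c(rep(config$u_max, nm), rep(-config$u_min, nm)),
                 n_moves = nm),
            class = "qp_problem")
}

#' Solve a small dense convex QP
#'
#' Minimizes `1/2 u' H u + f' u` subject to `A_cs u <= b_cs` via the
#' active-set solver in \pkg{pracma}, and verifies the KKT conditions
#' (stationarity against the active constraints, primal feasibility) to
#' `kkt_tol` before returning.
#'
#' @param qp a `qp_problem` (or any list with `H`, `f`, `A_cs`, `b_cs`).
#' @param kkt_tol acceptance tolerance on the KKT residual.
#' @return List with `u` (solution) and `kkt_residual`.
#' @export
solve_qp <- function(qp, kkt_tol = 1e-6) {
  n <- length(qp$f)
  sol <- tryCatch(
    pracma::quadprog(qp$H, qp$f, A = qp$A_cs, b = qp$b_cs),
    error = function(e) stop("QP solve failed: ", conditionMessage(e)))
  u <- sol$xmin
  viol <- max(0, max(qp$A_cs %*% u - qp$b_cs))
  if (viol > kkt_tol) stop(sprintf("QP infeasible at tolerance (%.3g)", viol))
  # stationarity: grad + A' lambda = 0 with lambda >= 0 on active set
  g <- drop(qp$H %*% u + qp$f)
  act <- which(qp$A_cs %*% u > qp$b_cs - 1e-8)
  if (length(act) == 0) {
    kkt <- max(abs(g))
  } else {
    Aact <- qp$A_cs[act, , drop = FALSE]
    lam <- tryCatch(qr.solve(t(Aact), -g), error = function(e) NULL)
    kkt <- if (is.null(lam)) max(abs(g)) else
      max(max(abs(t(Aact) %*% lam + g)), max(0, -min(lam)))
  }
  scale <- max(1, max(abs(qp$f)))
  if (kkt / scale > kkt_tol)
    warning(sprintf("KKT residual %.3g above tolerance", kkt))
  list(u = u, kkt_residual = kkt)
}

#' Closed-loop receding-horizon dosing on the nonlinear plant
#'
#' Every `control_interval` days: form the delay-embedded tumor history
#' from the measured trajectory, lift it, build and solve the horizon QP,
#' apply the first move as an impulsive instillation to the nonlinear
#' model, and advance to the next control instant.  The reference decays
#' exponentially from the measured initial tumor load.  The terminal
#' weight is the DARE solution on the lifted pair `(A_lift, B_lift)` with
#' stage weight `C' Q C`; if that Riccati solve fails the stage weight
#' itself is used, with a warning.
#'
#' @param params nonlinear plant parameters.
#' @param x0 initial state.
#' @param model fitted `koopman_model` (surrogate used by the
#'   controller).
#' @param config an [mpc_config()].
#' @param horizon closed-loop duration in days.
#' @return List of class `mpc_run`: `trajectory` (a `bcg_trajectory`),
#'   `doses` (data frame time/dose), `config`.
#' @export
run_receding_horizon <- function(params = bcg_params(), x0 = bcg_x0(),
                                 model, config = mpc_config(),
                                 horizon = 100) {
  stopifnot(inherits(model, "koopman_model"))
  dt <- model$dt
  kt <- round(horizon / dt)
  ci_steps <- round(config$control_interval / dt)
  pred <- build_prediction(model, config$Hp, config$Hu,
                           config$control_interval)
  Qz <- t(model$C_lift) %*% config$Q %*% model$C_lift
  P_term <- tryCatch(
    solve_dare(model$A_lift, model$B_lift, Qz, matrix(config$R)),
    error = function(e) {
      warning("terminal DARE failed (", conditionMessage(e),
              "); using stage weight")
      Qz
    })
  p <- as_param_vector(params)
  x <- check_state(x0)
  tu0 <- x[4]
  states <- matrix(0, kt + 1, 4, dimnames = list(NULL, .STATE_NAMES))
  u_grid <- numeric(kt + 1)
  y_hist <- rep(x[4], 3)   # y_k, y_{k-1}, y_{k-2}; flat pre-history
  u_hist <- c(0, 0)        # u_{k-1}, u_{k-2}
  move_times <- seq(0, kt - 1, by = ci_steps)
  doses <- numeric(length(move_times))
  k <- 0
  for (mi in seq_along(move_times)) {
    km <- move_times[mi]
    z <- c(y_hist[1], y_hist[2], y_hist[3], u_hist[1], u_hist[2])
    zl <- lift_state(model, z)
    tref <- (km + seq_len(pred$steps)) * dt
    x_ref <- cbind(0, 0, 0, tu0 * exp(-config$ref_decay * tref))
    qp <- build_qp(model, pred, config, zl, x_ref, P_term)
    u_star <- solve_qp(qp)$u[1]
    u_star <- min(max(u_star, config$u_min), config$u_max)
    doses[mi] <- u_star
    # apply the move and advance the nonlinear plant to the next instant
    seg_end <- min(km + ci_steps, kt)
    seg <- sim_path_cpp(p, x, c(0L), u_star, seg_end - km, dt)
    states[km + 1, ] <- seg[1, ]   # post-impulse state at the move instant
    states[(km + 2):(seg_end + 1), ] <- seg[-1, , drop = FALSE]
    u_grid[km + 1] <- u_star
    x <- seg[nrow(seg), ]
    # refresh the delay history at the new control instant
    tu_col <- c(states[seq_len(seg_end + 1), 4])
    y_hist <- tu_col[seg_end + 1 - 0:2]
    u_hist <- c(u_grid[seg_end], u_grid[seg_end - 1])
    k <- seg_end
  }
  if (k < kt) {
    seg <- sim_path_cpp(p, x, integer(0), numeric(0), kt - k, dt)
    states[(k + 1):(kt + 1), ] <- seg
  }
  sched <- impulse_schedule(move_times[doses > 0], doses[doses > 0],
                            dt = dt, kt = kt)
  traj <- structure(list(time = seq(0, kt) * dt, states = states,
                         schedule = sched, params = p, x0 = check_state(x0),
                         dt = dt),
                    class = "bcg_trajectory")
  structure(list(trajectory = traj,
                 doses = data.frame(time = move_times * dt, dose = doses),
                 config = config),
            class = "mpc_run")
}

#' @export
print.mpc_run <- function(x, ...) {
  st <- settling_time(x$trajectory)
  cat(sprintf("<mpc_run> %d control instants, total dose %.2f\n",
              nrow(x$doses), sum(x$doses$dose)))
  cat(sprintf("  settling time (1%% of Tu(0)): %s days\n",
              if (is.na(st)) "not reached" else sprintf("%.2f", st)))
  invisible(x)
}
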