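#' @useDynLib bcgrmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames rnorm runif sd var kmeans quantile
#' @importFrom utils read.delim write.table modifyList
NULL

.PARAM_NAMES <- c("mu1", "mu2", "p1", "p2", "p3", "p4", "p5",
                  "alpha", "beta", "r")
.STATE_NAMES <- c("B", "E", "Ti", "Tu")

#' Dimensionless rate constants of the BCG treatment model
#'
#' Constructs the ten-parameter set of the four-state bladder-cancer
#' immunotherapy model: BCG decay (`mu1`), effector-cell decay (`mu2`), BCG
#' kill by antigen-presenting cells (`p1`), tumor-cell infection by BCG
#' (`p2`), infected-cell destruction by effectors (`p3`), immune activation
#' (`p4`), effector deactivation (`p5`), infected-tumor stimulation of the
#' immune response (`alpha`), inverse tumor carrying capacity (`beta`) and
#' tumor growth rate (`r`).  Defaults are the dimensionless working values;
#' states are scaled in units of 1e6 cells (1e6 c.f.u for BCG) and time in
#' days.
#'
#' @param mu1,mu2,p1,p2,p3,p4,p5,alpha,beta,r strictly positive rates.
#' @return A named numeric vector of class `bcg_params`.
#' @export
#' @examples
#' bcg_params()
#' bcg_params(r = 0.064) # faster-growing tumor
bcg_params <- function(mu1 = 1, mu2 = 0.41, p1 = 1.25, p2 = 0.285,
                       p3 = 1.1, p4 = 0.12, p5 = 0.003, alpha = 0.52,
                       beta = 0.011, r = 0.032) {
  p <- c(mu1 = mu1, mu2 = mu2, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
         p5 = p5, alpha = alpha, beta = beta, r = r)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all model parameters must be finite and strictly positive")
  structure(p, class = "bcg_params")
}

#' Default initial state: early-stage disease, naive immune system
#'
#' `[B, E, Ti, Tu] = [0.1, 0.1, 0, 0.8]` in units of 1e6 cells/c.f.u.
#' @return Named numeric vector of length 4.
#' @export
bcg_x0 <- function() {
  setNames(c(0.1, 0.1, 0, 0.8), .STATE_NAMES)
}

as_param_vector <- function(params) {
  if (inherits(params, "bcg_params")) return(unclass(params))
  p <- unlist(params)[.PARAM_NAMES]
  if (any(is.na(p))) stop("params must provide all of: ",
                          paste(.PARAM_NAMES, collapse = ", "))
  p
}

check_state <- function(state) {
  state <- unlist(state, use.names = FALSE)
  if (length(state) != 4 || !all(is.finite(state)))
    stop("state must be 4 finite numbers [B, E, Ti, Tu]")
  state
}

#' Right-hand side of the tumor-immune ODE
#'
#' Time derivative of `[B, E, Ti, Tu]`:
#' \deqn{\dot B = -\mu_1 B - p_1 E B - p_2 B T_u}
#' \deqn{\dot E = -\mu_2 E + \alpha T_i + p_4 E B - p_5 E T_i}
#' \deqn{\dot T_i = -p_3 E T_i + p_2 B T_u}
#' \deqn{\dot T_u = -p_2 B T_u + r (1 - \beta T_u) T_u}
#'
#' @param state numeric length-4 state `[B, E, Ti, Tu]`.
#' @param params a [bcg_params()] object.
#' @return Named numeric length-4 derivative.
#' @export
ode_rhs <- function(state, params = bcg_params()) {
  x <- check_state(state)
  p <- as_param_vector(params)
  B <- x[1]; E <- x[2]; Ti <- x[3]; Tu <- x[4]
  setNames(c(
    -p["mu1"] * B - p["p1"] * E * B - p["p2"] * B * Tu,
    -p["mu2"] * E + p["alpha"] * Ti + p["p4"] * E * B - p["p5"] * E * Ti,
    -p["p3"] * E * Ti + p["p2"] * B * Tu,
    -p["p2"] * B * Tu + p["r"] * (1 - p["beta"] * Tu) * Tu
  ), .STATE_NAMES)
}

#' One classical fourth-order Runge-Kutta step
#'
#' @inheritParams ode_rhs
#' @param dt step size in days (> 0).
#' @return State after one step of size `dt`.
#' @export
rk4_step <- function(state, params = bcg_params(), dt = 0.01) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number")
  x <- check_state(state)
  k1 <- ode_rhs(x, params)
  k2 <- ode_rhs(x + dt / 2 * k1, params)
  k3 <- ode_rhs(x + dt / 2 * k2, params)
  k4 <- ode_rhs(x + dt * k3, params)
  setNames(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), .STATE_NAMES)
}

#' Instantaneous BCG instillation
#'
#' Impulsive input acts on the BCG channel only: `B <- B + dose`, the other
#' three states are untouched.
#'
#' @inheritParams ode_rhs
#' @param dose nonnegative dose in 1e6 c.f.u.
#' @export
apply_impulse <- function(state, dose) {
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose < 0)
    stop("dose must be a single nonnegative number")
  x <- check_state(state)
  setNames(x + c(dose, 0, 0, 0), .STATE_NAMES)
}

#' Impulse schedule on the simulation grid
#'
#' @param idx integer grid indices (0-based, `k = 0` is `t = 0`), strictly
#'   increasing after merging of duplicates.
#' @param dose doses (1e6 c.f.u), recycled to `length(idx)`.
#' @param dt grid step in days.
#' @param kt final grid index (horizon = `kt * dt` days).
#' @return An object of class `impulse_schedule`.
#' @export
impulse_schedule <- function(idx = integer(0), dose = numeric(0),
                             dt = 0.01, kt = round(100 / dt)) {
  idx <- as.integer(idx)
  dose <- rep_len(as.numeric(dose), length(idx))
  if (any(dose < 0)) stop("doses must be nonnegative")
  if (any(idx < 0) || any(idx > kt)) stop("impulse indices must lie in [0, kt]")
  o <- order(idx)
  idx <- idx[o]; dose <- dose[o]
  if (anyDuplicated(idx)) { # coincident instillations add up
    dose <- as.numeric(tapply(dose, idx, sum))
    idx <- sort(unique(idx))
  }
  structure(list(idx = idx, dose = dose, dt = dt, kt = as.integer(kt)),
            class = "impulse_schedule")
}

#' Simulate the impulsive treatment system
#'
#' Integrates the four-state model with RK4 on a fixed grid of step `dt`.
#' At each impulse index the dose is added to `B` first, then the step is
#' integrated; the stored row is the post-impulse state (so the first dose,
#' at `k = 0`, is already visible in row 0).
#'
#' @param params a [bcg_params()] set.
#' @param x0 nonnegative initial state `[B, E, Ti, Tu]`.
#' @param schedule an [impulse_schedule()]; the default is no treatment.
#' @param kt,dt horizon index and grid step; taken from `schedule` when one
#'   is supplied.
#' @return A `bcg_trajectory`: list with `time` (days), `states`
#'   ((kt+1) x 4 matrix), `schedule`, `params`, `x0`, `dt`.
#' @export
#' @examples
#' tr <- simulate_bcg(schedule = impulse_schedule(c(0, 500), c(5.46, 5.46)))
#' tail(tr$states)
simulate_bcg <- function(params = bcg_params(), x0 = bcg_x0(),
                         schedule = NULL, kt = NULL, dt = 0.01) {
  if (is.null(schedule)) {
    if (is.null(kt)) kt <- round(100 / dt)
    schedule <- impulse_schedule(dt = dt, kt = kt)
  }
  stopifnot(inherits(schedule, "impulse_schedule"))
  dt <- schedule$dt
  kt <- if (is.null(kt)) schedule$kt else as.integer(kt)
  x0 <- check_state(x0)
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  states <- sim_path_cpp(as_param_vector(params), x0,
                         schedule$idx, schedule$dose, kt, dt)
  colnames(states) <- .STATE_NAMES
  structure(list(time = seq(0, kt) * dt, states = states,
                 schedule = schedule, params = as_param_vector(params),
                 x0 = x0, dt = dt),
            class = "bcg_trajectory")
}

#' @export
print.bcg_trajectory <- function(x, ...) {
  cat(sprintf("<bcg_trajectory> %d steps, dt = %g d, horizon = %g d\n",
              length(x$time) - 1, x$dt, max(x$time)))
  cat(sprintf("  impulses: %d (total dose %.3g)\n",
              length(x$schedule$idx), sum(x$schedule$dose)))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final state: B=%.4g E=%.4g Ti=%.4g Tu=%.4g\n",
              fin[1], fin[2], fin[3], fin[4]))
  invisible(x)
}

#' Maximal untreated tumor burden over the horizon
#'
#' Simulates the model with zero input and returns the maximum of `Tu` over
#' the grid.  Used as the normalization constant of the regimen cost: both
#' stage and terminal tumor terms are expressed relative to what the tumor
#' would have reached with no BCG at all.
#'
#' @inheritParams simulate_bcg
#' @return Scalar maximum of untreated `Tu`.
#' @export
untreated_tumor_max <- function(params = bcg_params(), x0 = bcg_x0(),
                                kt = 10000, dt = 0.01) {
  x0 <- check_state(x0)
  m <- sim_metrics_cpp(as_param_vector(params), x0, integer(0), numeric(0),
                       as.integer(kt), dt, 0.01)
  m[3]
}

#' Settling time of the tumor population
#'
#' First grid time at which `Tu(t)` drops below `fraction` of its initial
#' value `Tu(0)`.  Reported on the grid (no interpolation), so the value is
#' quantized to one `dt`.
#'
#' @param traj a `bcg_trajectory`.
#' @param fraction threshold fraction in (0, 1); default 1 percent.
#' @return Time in days, or `NA` if the threshold is never crossed.
#' @export
settling_time <- function(traj, fraction = 0.01) {
  stopifnot(inherits(traj, "bcg_trajectory"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  tu <- traj$states[, "Tu"]
  if (tu[1] <= 0) stop("Tu(0) must be positive for a settling threshold")
  hit <- which(tu < fraction * tu[1])
  if (length(hit) == 0) return(NA_real_)
  traj$time[hit[1]]
}

#' Write / read a trajectory as delimited text
#'
#' Tab-separated table with columns `time_days, B, E, Ti, Tu, dose_applied`;
#' round-trips exactly on the decimal representation written.
#'
#' @param traj a `bcg_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns a data frame.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bcg_trajectory"))
  dose <- numeric(length(traj$time))
  dose[traj$schedule$idx + 1] <- traj$schedule$dose
  df <- data.frame(time_days = traj$time, traj$states,
                   dose_applied = dose, check.names = FALSE)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Read / write the model configuration (parameters + initial state)
#'
#' YAML file with the Table-style parameter names (`mu1` ... `r`) and `x0`.
#'
#' @param path file path.
#' @param params,x0 values to write.
#' @return `read_model_config` returns `list(params, x0)`.
#' @export
write_model_config <- function(path, params = bcg_params(), x0 = bcg_x0()) {
  yaml::write_yaml(list(params = as.list(as_param_vector(params)),
                        x0 = as.list(check_state(x0))), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(params = do.call(bcg_params, cfg$params),
       x0 = setNames(unlist(cfg$x0), .STATE_NAMES))
}
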