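#' A (dose, gap, count) dosing scheme
#'
#' The regimen search space is reparameterized to three numbers: the single
#' instillation dose `d` (1e6 c.f.u), the gap `g` between consecutive
#' instillations (days) and the number of treatments `N`.  `N` is carried as
#' a real number during optimization (its integrality is enforced softly by
#' the cost); the executed impulse count is `round(N)`.
#'
#' @param d dose per treatment, `>= 0`.
#' @param g gap between treatments in days, `> 0`.
#' @param N number of treatments, `>= 1` (may be fractional during search).
#' @return Object of class `dosing_scheme`.
#' @export
dosing_scheme <- function(d, g, N) {
  if (!is.finite(d) || d < 0) stop("d must be a nonnegative number")
  if (!is.finite(g) || g <= 0) stop("g must be a positive number")
  if (!is.finite(N) || N < 1) stop("N must be >= 1")
  structure(list(d = unname(d), g = unname(g), N = unname(N)),
            class = "dosing_scheme")
}

#' @export
print.dosing_scheme <- function(x, ...) {
  cat(sprintf("<dosing_scheme> d = %.4g (1e6 c.f.u), g = %.4g d, N = %.4g\n",
              x$d, x$g, x$N))
  invisible(x)
}

#' Search bounds for the regimen variables
#'
#' Two presets: `"default"` follows clinical practice (single-dose limits
#' 2.2-6.4, weekly-like gaps 5-10 days, 3-10 treatments); `"expanded"`
#' relaxes all three ranges (d in [0, 50], g in [1, 20], N in [1, 20]) to
#' probe whether the constrained optimum is merely local.
#'
#' @param preset `"default"` or `"expanded"`, or pass `lower`/`upper`
#'   directly for custom bounds.
#' @param lower,upper numeric vectors (same length) of per-variable bounds.
#' @return List with `lower` and `upper` named vectors.
#' @export
search_bounds <- function(preset = c("default", "expanded"),
                          lower = NULL, upper = NULL) {
  if (is.null(lower)) {
    preset <- match.arg(preset)
    if (preset == "default") {
      lower <- c(d = 2.2, g = 5, N = 3); upper <- c(d = 6.4, g = 10, N = 10)
    } else {
      lower <- c(d = 0, g = 1, N = 1); upper <- c(d = 50, g = 20, N = 20)
    }
  }
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("bounds must satisfy lower < upper componentwise")
  list(lower = lower, upper = upper)
}

#' Weights of the multiobjective regimen cost
#'
#' @param w1 weight of the cumulative (stage) tumor burden.
#' @param lam weight of the cumulative dose `d * N`; larger values trade
#'   tumor clearance for fewer vaccines.
#' @param wN penalty weight on the integer-relaxation residual
#'   `|N - round(N)|`.
#' @param wt terminal penalty weight on the normalized `Tu` at the horizon
#'   (soft version of the tumor-free endpoint constraint).
#' @param tu_norm normalization constant: maximal untreated `Tu` over the
#'   horizon.  Computed from `(params, x0)` by [evaluate_cost()] when `NULL`;
#'   precompute it once when evaluating many schemes.
#' @return List of class `cost_weights`.
#' @export
cost_weights <- function(w1 = 200, lam = 1, wN = 1e4, wt = 1e5,
                         tu_norm = NULL) {
  w <- list(w1 = w1, lam = lam, wN = wN, wt = wt, tu_norm = tu_norm)
  if (any(unlist(w[1:4]) < 0)) stop("weights must be nonnegative")
  if (!is.null(tu_norm) && tu_norm <= 0) stop("tu_norm must be positive")
  structure(w, class = "cost_weights")
}

#' Impulsive input induced by a dosing scheme
#'
#' Places `round(N)` impulses of magnitude `d` at grid indices
#' `round(n * g / dt)`, `n = 0, ..., round(N) - 1` (first dose at `t = 0`).
#' Impulses that would fall beyond the horizon are dropped with a warning.
#'
#' @param scheme a [dosing_scheme()].
#' @param dt grid step (days).
#' @param kt final grid index.
#' @return An [impulse_schedule()].
#' @export
build_input_signal <- function(scheme, dt = 0.01, kt = round(100 / dt)) {
  stopifnot(inherits(scheme, "dosing_scheme"))
  if (scheme$g / dt < 1)
    stop("gap g is below the grid resolution dt")
  n_exec <- round(scheme$N)
  if (n_exec < 1) stop("round(N) must be at least 1")
  idx <- round((0:(n_exec - 1)) * scheme$g / dt)
  if (any(idx > kt)) {
    warning(sprintf("%d impulse(s) beyond the %g-day horizon dropped",
                    sum(idx > kt), kt * dt))
    idx <- idx[idx <= kt]
  }
  impulse_schedule(idx, scheme$d, dt = dt, kt = kt)
}

#' Multiobjective cost of a dosing scheme
#'
#' Simulates the treated system and returns
#' \deqn{w_1 \sum_{k=0}^{k_t} \frac{T_u(k)}{T_{norm}} \Delta t
#'   + \lambda d N + w_N |N - round(N)|
#'   + w_t \frac{T_u(k_t)}{T_{norm}}}
#' where `T_norm` is the maximal untreated tumor burden
#' ([untreated_tumor_max()]).  The dose and integer-penalty terms use the
#' raw (possibly fractional) `N`; the executed impulse count is `round(N)`.
#'
#' @inheritParams build_input_signal
#' @param params,x0 model parameters and initial state.
#' @param weights a [cost_weights()]; `tu_norm` is filled in from
#'   `(params, x0)` when missing.
#' @return Scalar cost with attribute `"breakdown"` (stage, dose,
#'   integer_penalty, terminal components).
#' @export
#' @examples
#' w <- cost_weights(tu_norm = untreated_tumor_max())
#' evaluate_cost(dosing_scheme(5.46, 5, 10), weights = w)
evaluate_cost <- function(scheme, params = bcg_params(), x0 = bcg_x0(),
                          weights = cost_weights(), dt = 0.01,
                          kt = round(100 / dt)) {
  stopifnot(inherits(scheme, "dosing_scheme"))
  tu_norm <- weights$tu_norm
  if (is.null(tu_norm))
    tu_norm <- untreated_tumor_max(params, x0, kt = kt, dt = dt)
  sched <- build_input_signal(scheme, dt = dt, kt = kt)
  m <- sim_metrics_cpp(as_param_vector(params), check_state(x0),
                       sched$idx, sched$dose, as.integer(kt), dt, 0.01)
  stage <- weights$w1 * m[1] / tu_norm
  dosec <- weights$lam * scheme$d * scheme$N
  intp <- weights$wN * abs(scheme$N - round(scheme$N))
  term <- weights$wt * m[2] / tu_norm
  structure(stage + dosec + intp + term,
            breakdown = c(stage = stage, dose = dosec,
                          integer_penalty = intp, terminal = term))
}

#' Cumulative administered dose of a scheme
#'
#' @param scheme a [dosing_scheme()].
#' @return `d * N` (raw, possibly fractional `N`), in 1e6 c.f.u.
#' @export
cumulative_dose <- function(scheme) {
  stopifnot(inherits(scheme, "dosing_scheme"))
  scheme$d * scheme$N
}

#' Regimen cost as a plain objective function of `c(d, g, N)`
#'
#' Convenience closure used by the metaheuristic optimizers; `tu_norm` is
#' computed once up front.
#'
#' @inheritParams evaluate_cost
#' @return `function(x)` mapping a numeric `c(d, g, N)` to the scalar cost.
#' @export
regimen_objective <- function(params = bcg_params(), x0 = bcg_x0(),
                              weights = cost_weights(), dt = 0.01,
                              kt = round(100 / dt)) {
  if (is.null(weights$tu_norm))
    weights$tu_norm <- untreated_tumor_max(params, x0, kt = kt, dt = dt)
  force(params); force(x0); force(dt); force(kt)
  # candidate schemes routinely spill impulses past the horizon during an
  # expanded-bounds search; the per-call warning would fire thousands of
  # times, so it is muted inside the closure
  function(x) {
    suppressWarnings(
      as.numeric(evaluate_cost(dosing_scheme(x[1], x[2], x[3]),
                               params, x0, weights, dt = dt, kt = kt)))
  }
}
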