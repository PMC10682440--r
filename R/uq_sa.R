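#' Monte-Carlo uncertainty specification
#'
#' Two perturbation modes emulate patient variability: `"parameters"` draws
#' each rate from `Normal(mu_i, (0.1 mu_i)^2)` (negative draws resampled so
#' rates stay positive); `"initial_conditions"` draws each state component
#' from `Uniform[X(0)/1.1, X(0)/0.9]`, the band implied by roughly 90
#' percent accurate imaging of the measured state.
#'
#' @param mode `"parameters"` or `"initial_conditions"`.
#' @param n_runs Monte-Carlo sample size (>= 2).
#' @param rel_sd relative sd of the parameter perturbation.
#' @param fraction settling threshold as a fraction of each run's own
#'   initial `Tu`.
#' @param conf_level confidence level of the pointwise trajectory band.
#' @param seed RNG seed.
#' @return List of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(mode = c("parameters", "initial_conditions"),
                             n_runs = 200, rel_sd = 0.1, fraction = 0.01,
                             conf_level = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (n_runs < 2) stop("n_runs must be at least 2")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  structure(list(mode = mode, n_runs = as.integer(n_runs), rel_sd = rel_sd,
                 fraction = fraction, conf_level = conf_level, seed = seed),
            class = "uncertainty_spec")
}

# Normal draws with resampling at zero: rates must stay positive
rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Monte-Carlo uncertainty analysis of a fixed dosing schedule
#'
#' Simulates `n_runs` perturbed systems under the same open-loop impulse
#' schedule and summarizes the settling time (first time `Tu` drops below
#' `fraction` of its own initial value).  Mean and sd are taken over runs
#' that settle; non-settling runs are counted separately, and when more
#' than half of the runs fail to settle the result carries `flagged =
#' TRUE`.  A pointwise `Tu(t)` band is also returned (see
#' [summarize_band()]).
#'
#' @param dose_input an [impulse_schedule()] (e.g. from
#'   [build_input_signal()]).
#' @param spec an [uncertainty_spec()].
#' @param params,x0 nominal parameters and measured initial state.
#' @param band_stride store every `band_stride`-th grid point of the Tu
#'   curves for the band (keeps memory modest).
#' @return List of class `uncertainty_result` with `settling`, `mean`,
#'   `sd`, `n_settled`, `n_unsettled`, `flagged`, `band`.
#' @export
run_uncertainty <- function(dose_input, spec = uncertainty_spec(),
                            params = bcg_params(), x0 = bcg_x0(),
                            band_stride = 10) {
  stopifnot(inherits(dose_input, "impulse_schedule"),
            inherits(spec, "uncertainty_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_runs
  p0 <- as_param_vector(params)
  x00 <- check_state(x0)
  if (spec$mode == "parameters") {
    pars <- vapply(p0, function(m) rnorm_pos(n, m, spec$rel_sd * m),
                   numeric(n))
    x0s <- matrix(x00, n, 4, byrow = TRUE)
  } else {
    pars <- matrix(p0, n, 10, byrow = TRUE)
    x0s <- vapply(x00, function(v) runif(n, v / 1.1, v / 0.9), numeric(n))
  }
  kt <- dose_input$kt; dt <- dose_input$dt
  settling <- settle_batch_cpp(pars, x0s, dose_input$idx, dose_input$dose,
                               kt, dt, spec$fraction)
  curves <- tu_curves_cpp(pars, x0s, dose_input$idx, dose_input$dose,
                          kt, dt, as.integer(band_stride))
  band <- summarize_band(curves, time = seq(0, kt, by = band_stride) * dt,
                         conf_level = spec$conf_level)
  settled <- settling[!is.na(settling)]
  n_un <- sum(is.na(settling))
  structure(list(settling = settling,
                 mean = if (length(settled)) mean(settled) else NA_real_,
                 sd = if (length(settled) > 1) sd(settled) else NA_real_,
                 n_settled = length(settled), n_unsettled = n_un,
                 flagged = n_un > n / 2, band = band, spec = spec),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> %s mode, %d runs (%d unsettled%s)\n",
              x$spec$mode, x$spec$n_runs, x$n_unsettled,
              if (x$flagged) ", FLAGGED" else ""))
  cat(sprintf("  settling time: mean %.2f d, sd %.3f d\n", x$mean, x$sd))
  invisible(x)
}

#' Pointwise mean and confidence band of a bundle of Tu curves
#'
#' @param curves matrix with one column per run, rows on a common time
#'   grid.
#' @param time optional time vector (grid row labels).
#' @param conf_level band coverage; the band is `mean +/- z * sd` with the
#'   two-sided normal quantile `z` (1.96 at 95 percent).
#' @return Data frame with `time`, `mean`, `lower`, `upper`.
#' @export
summarize_band <- function(curves, time = NULL, conf_level = 0.95) {
  curves <- as.matrix(curves)
  if (ncol(curves) < 2) stop("need at least 2 runs on a common grid")
  z <- qnorm(1 - (1 - conf_level) / 2)
  m <- rowMeans(curves)
  s <- apply(curves, 1, sd)
  data.frame(time = if (is.null(time)) seq_len(nrow(curves)) - 1 else time,
             mean = m, lower = m - z * s, upper = m + z * s)
}

#' @importFrom stats qnorm
NULL

#' Sobol sensitivity specification
#'
#' Eleven factors: the ten model rates plus one scale factor applied to
#' the whole initial state (the measured state is perturbed as a unit).
#' Each factor ranges uniformly over `[0.8, 1.2]` times nominal.
#'
#' @param n base sample size of the Saltelli design; the total number of
#'   model runs is `n * (k + 2)` with `k = 11` factors.
#' @param range_lo,range_hi multiplicative factor range around nominal.
#' @param fraction settling threshold fraction.
#' @param horizon_impute settling time assigned to non-settling samples
#'   (keeps the estimator's sample design balanced); defaults to the
#'   100-day horizon.
#' @param n_boot bootstrap replicates for the index confidence intervals
#'   (0 disables).
#' @param seed RNG seed.
#' @export
sobol_spec <- function(n = 1000, range_lo = 0.8, range_hi = 1.2,
                       fraction = 0.01, horizon_impute = 100,
                       n_boot = 100, seed = NULL) {
  if (n < 10) stop("base sample size too small for the Sobol estimators")
  stopifnot(range_lo < range_hi)
  structure(list(n = as.integer(n), range_lo = range_lo,
                 range_hi = range_hi, fraction = fraction,
                 horizon_impute = horizon_impute,
                 n_boot = as.integer(n_boot), seed = seed),
            class = "sobol_spec")
}

#' Saltelli A/B/AB sample design on the unit hypercube
#'
#' Two independent `n x k` uniform matrices `A` and `B`, plus the `k`
#' radial matrices `AB_i` (columns of `A` with column `i` replaced from
#' `B`).
#'
#' @param n base sample size.
#' @param k number of factors.
#' @return List with `A`, `B` and `AB` (list of k matrices).
#' @export
saltelli_design <- function(n, k) {
  A <- matrix(runif(n * k), n, k)
  B <- matrix(runif(n * k), n, k)
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  list(A = A, B = B, AB = AB)
}

#' Variance-based (Sobol) indices of a black-box function
#'
#' Runs the function over a Saltelli A/B/AB design and returns first-order
#' indices (Saltelli 2010 estimator `mean(f_B (f_ABi - f_A)) / V`) and
#' total-order indices (Jansen estimator `mean((f_A - f_ABi)^2) / (2 V)`).
#'
#' @param fn vectorized function: takes an `n x k` matrix of unit-cube
#'   rows, returns `n` outputs.
#' @param k number of factors.
#' @param n base sample size.
#' @param seed RNG seed.
#' @param n_boot bootstrap replicates for 95 percent CIs (0 = none).
#' @param factor_names optional names for the factors.
#' @return Object of class `sensitivity_result`: data frame `indices` with
#'   `S` (first order), `ST` (total order) and optional CI columns, plus
#'   sampling metadata.
#' @export
#' @examples
#' ishigami <- function(U) {
#'   X <- -pi + 2 * pi * U
#'   sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
#' }
#' sobol_indices(ishigami, k = 3, n = 512, seed = 1)
sobol_indices <- function(fn, k, n = 1000, seed = NULL, n_boot = 0,
                          factor_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  des <- saltelli_design(n, k)
  fA <- fn(des$A); fB <- fn(des$B)
  if (length(fA) != n || length(fB) != n)
    stop("fn must return one output per design row")
  fAB <- vapply(des$AB, fn, numeric(n))
  est <- function(idx) {
    # center and scale the outputs first (as the reference implementation
    # of these estimators does); the indices are invariant under affine
    # transforms of the output but the first-order estimator's variance
    # is drastically smaller on centered values
    mu <- mean(c(fA[idx], fB[idx]))
    sg <- sd(c(fA[idx], fB[idx]))
    if (sg == 0) return(cbind(S = rep(0, k), ST = rep(0, k)))
    a <- (fA[idx] - mu) / sg
    b <- (fB[idx] - mu) / sg
    V <- var(c(a, b))
    S <- vapply(seq_len(k), function(i) {
      ab <- (fAB[idx, i] - mu) / sg
      mean(b * (ab - a)) / V
    }, 0)
    ST <- vapply(seq_len(k), function(i) {
      ab <- (fAB[idx, i] - mu) / sg
      mean((a - ab)^2) / (2 * V)
    }, 0)
    cbind(S, ST)
  }
  full <- est(seq_len(n))
  out <- data.frame(factor = factor_names %||% paste0("x", seq_len(k)),
                    S = full[, 1], ST = full[, 2])
  if (n_boot > 0) {
    boots <- array(dim = c(k, 2, n_boot))
    for (b in seq_len(n_boot))
      boots[, , b] <- est(sample.int(n, n, replace = TRUE))
    out$S_lo <- apply(boots[, 1, , drop = FALSE], 1, quantile, 0.025)
    out$S_hi <- apply(boots[, 1, , drop = FALSE], 1, quantile, 0.975)
    out$ST_lo <- apply(boots[, 2, , drop = FALSE], 1, quantile, 0.025)
    out$ST_hi <- apply(boots[, 2, , drop = FALSE], 1, quantile, 0.975)
  }
  structure(list(indices = out, n = n, k = k, seed = seed,
                 n_runs = n * (k + 2)),
            class = "sensitivity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d factors, n = %d (%d model runs)\n",
              x$k, x$n, x$n_runs))
  print(x$indices, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Sobol sensitivity of the settling time under a fixed dosing schedule
#'
#' Variance decomposition of the treated system's settling time with
#' respect to the ten model rates and one initial-state scale factor, each
#' uniform over 0.8-1.2 times nominal.  Samples whose tumor never settles
#' within the horizon are imputed at `horizon_impute` days (count
#' reported as `n_imputed`).
#'
#' @inheritParams run_uncertainty
#' @param spec a [sobol_spec()].
#' @return A `sensitivity_result` with factors
#'   `mu1 ... r, x0_scale` and an `n_imputed` element.
#' @export
run_sobol <- function(dose_input, spec = sobol_spec(),
                      params = bcg_params(), x0 = bcg_x0()) {
  stopifnot(inherits(dose_input, "impulse_schedule"),
            inherits(spec, "sobol_spec"))
  p0 <- as_param_vector(params)
  x00 <- check_state(x0)
  kt <- dose_input$kt; dt <- dose_input$dt
  n_imputed <- 0L
  fn <- function(U) {
    fac <- spec$range_lo + (spec$range_hi - spec$range_lo) * U
    pars <- sweep(fac[, 1:10, drop = FALSE], 2, p0, `*`)
    x0s <- outer(fac[, 11], x00)
    st <- settle_batch_cpp(pars, x0s, dose_input$idx, dose_input$dose,
                           kt, dt, spec$fraction)
    miss <- is.na(st)
    n_imputed <<- n_imputed + sum(miss)
    st[miss] <- spec$horizon_impute
    st
  }
  res <- sobol_indices(fn, k = 11, n = spec$n, seed = spec$seed,
                       n_boot = spec$n_boot,
                       factor_names = c(names(p0), "x0_scale"))
  res$n_imputed <- n_imputed
  res
}
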