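#' Optimizer configurations
#'
#' Settings for the three metaheuristic minimizers.  Defaults follow the
#' regimen-search study conditions: PSO with inertia and both acceleration
#' weights at 0.5 and a swarm of 100 particles; simulated annealing with
#' unit initial temperature and geometric cooling ratio 0.95; ant colony
#' optimization on a layered discretization with pheromone/heuristic
#' exponents 1, evaporation 0.1 and 50 ants.  All three default to a budget
#' of 200 iterations.
#'
#' @param w inertia weight in `[0, 1]`.
#' @param c1,c2 cognitive (own-best) and social (swarm-best) weights.
#' @param swarm_size number of particles.
#' @param max_iters iteration budget.
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @return A config list.
#' @name optimizer_configs
NULL

#' @rdname optimizer_configs
#' @export
pso_config <- function(w = 0.5, c1 = 0.5, c2 = 0.5, swarm_size = 100,
                       max_iters = 200, seed = NULL) {
  stopifnot(w >= 0, w <= 1, c1 >= 0, c2 >= 0, swarm_size >= 1)
  list(w = w, c1 = c1, c2 = c2, swarm_size = as.integer(swarm_size),
       max_iters = as.integer(max_iters), seed = seed)
}

#' @rdname optimizer_configs
#' @param T0 initial temperature.
#' @param Cr geometric cooling ratio in (0, 1): `T <- T * Cr` per
#'   temperature level.
#' @param proposal_scale Gaussian proposal sd as a fraction of each
#'   variable's range.
#' @param chain_length Metropolis proposals per temperature level (the
#'   homogeneous-chain epoch of classical annealing; a single proposal per
#'   level quenches long before the chain can cross the integer-penalty
#'   barriers of the regimen cost).
#' @export
sa_config <- function(T0 = 1, Cr = 0.95, proposal_scale = 0.1,
                      chain_length = 30, max_iters = 200, seed = NULL) {
  stopifnot(T0 > 0, Cr > 0, Cr < 1, proposal_scale > 0, chain_length >= 1)
  list(T0 = T0, Cr = Cr, proposal_scale = proposal_scale,
       chain_length = as.integer(chain_length),
       max_iters = as.integer(max_iters), seed = seed)
}

#' @rdname optimizer_configs
#' @param levels list of numeric vectors, one per variable: the discrete
#'   values ("layer") an ant can pick for that variable.
#' @param heuristics optional list matching `levels`: the attractiveness
#'   eta of each level (all-ones when `NULL`).
#' @param exponent_alpha,exponent_beta pheromone and heuristic exponents
#'   (named after the classic ant-system notation; unrelated to the model
#'   rates `alpha`/`beta`).
#' @param evaporation pheromone evaporation rate in (0, 1).
#' @param Q_dep deposit constant: an ant with cost `L` deposits `Q_dep / L`.
#' @param n_ants ants per iteration.
#' @export
aco_config <- function(levels, heuristics = NULL, exponent_alpha = 1,
                       exponent_beta = 1, evaporation = 0.1, Q_dep = 1,
                       n_ants = 50, max_iters = 200, seed = NULL) {
  stopifnot(is.list(levels), length(levels) >= 1,
            all(vapply(levels, length, 1L) >= 1),
            evaporation > 0, evaporation < 1,
            exponent_alpha >= 0, exponent_beta >= 0, n_ants >= 1)
  if (is.null(heuristics)) heuristics <- lapply(levels, function(v) rep(1, length(v)))
  stopifnot(length(heuristics) == length(levels))
  list(levels = levels, heuristics = heuristics,
       exponent_alpha = exponent_alpha, exponent_beta = exponent_beta,
       evaporation = evaporation, Q_dep = Q_dep,
       n_ants = as.integer(n_ants), max_iters = as.integer(max_iters),
       seed = seed)
}

#' Default ant-colony discretization of the regimen box
#'
#' Dose in steps of 0.1 (43 levels over the clinical box), gap and
#' treatment count on integer grids — so `N` is integral by construction
#' for ACO.  The companion heuristic set encodes the prior "prefer large
#' gaps, low doses and few treatments": eta = g for the gap layer, 1/d and
#' 1/N for the dose and count layers.
#'
#' @param bounds a [search_bounds()] (3 variables: d, g, N).
#' @return `regimen_aco_levels`: list of level vectors;
#'   `regimen_aco_heuristics`: matching list of eta vectors.
#' @export
regimen_aco_levels <- function(bounds = search_bounds("default")) {
  list(d = seq(bounds$lower[1], bounds$upper[1], by = 0.1),
       g = seq(ceiling(bounds$lower[2]), floor(bounds$upper[2]), by = 1),
       N = seq(ceiling(bounds$lower[3]), floor(bounds$upper[3]), by = 1))
}

#' @rdname regimen_aco_levels
#' @param levels output of `regimen_aco_levels()`.
#' @export
regimen_aco_heuristics <- function(levels) {
  list(d = 1 / pmax(levels$d, 1e-6), g = levels$g,
       N = 1 / pmax(levels$N, 1e-6))
}

new_optimizer_result <- function(method, best, best_cost, history, n_evals,
                                 seed) {
  structure(list(method = method, best = best, best_cost = best_cost,
                 history = history, n_evals = n_evals, seed = seed),
            class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result:%s> best cost %.4f at (%s) after %d evals\n",
              x$method, x$best_cost,
              paste(signif(x$best, 5), collapse = ", "), x$n_evals))
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Particle swarm minimization over a box
#'
#' Standard global-best PSO.  Per particle and dimension, the velocity
#' update is `V <- w V + c1 r1 (pbest - P) + c2 r2 (gbest - P)` with
#' `r1, r2 ~ U[0,1]` drawn independently per particle, dimension and
#' iteration; positions are updated as `P <- P + V` and clamped to the
#' bounds (velocities are left unchanged).  Velocities start at zero; one
#' particle starts at `init_point`, the rest uniform in the box.
#'
#' @param objective function mapping a numeric vector to a finite scalar.
#' @param bounds a [search_bounds()]-style list with `lower` and `upper`.
#' @param cfg a [pso_config()].
#' @param init_point optional start point for the first particle.
#' @return An `optimizer_result` (best point, best cost, per-iteration
#'   global-best history, evaluation count).
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' b <- search_bounds(lower = rep(-5, 3), upper = rep(5, 3))
#' pso_minimize(sphere, b, pso_config(swarm_size = 20, max_iters = 50, seed = 1))
pso_minimize <- function(objective, bounds, cfg = pso_config(),
                         init_point = NULL) {
  if (cfg$swarm_size < 1) stop("swarm must contain at least one particle")
  if (cfg$max_iters < 0) stop("max_iters must be nonnegative")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- unname(bounds$lower); hi <- unname(bounds$upper)
  nd <- length(lo); np <- cfg$swarm_size
  P <- matrix(runif(np * nd, rep(lo, each = np), rep(hi, each = np)), np, nd)
  if (!is.null(init_point)) P[1, ] <- clamp(init_point, lo, hi)
  V <- matrix(0, np, nd)
  cost <- apply(P, 1, objective)
  if (!all(is.finite(cost))) stop("objective must be finite on the bounds")
  n_evals <- np
  pbest <- P; pcost <- cost
  gi <- which.min(pcost); gbest <- pbest[gi, ]; gcost <- pcost[gi]
  history <- numeric(cfg$max_iters + 1); history[1] <- gcost
  if (cfg$max_iters > 0) for (it in seq_len(cfg$max_iters)) {
    r1 <- matrix(runif(np * nd), np, nd)
    r2 <- matrix(runif(np * nd), np, nd)
    V <- cfg$w * V + cfg$c1 * r1 * (pbest - P) +
      cfg$c2 * r2 * (rep(gbest, each = np) - P)
    P <- clamp(P + V, rep(lo, each = np), rep(hi, each = np))
    cost <- apply(P, 1, objective)
    n_evals <- n_evals + np
    imp <- cost < pcost
    pbest[imp, ] <- P[imp, ]; pcost[imp] <- cost[imp]
    gi <- which.min(pcost)
    if (pcost[gi] < gcost) { gbest <- pbest[gi, ]; gcost <- pcost[gi] }
    history[it + 1] <- gcost
  }
  new_optimizer_result("pso", setNames(gbest, names(bounds$lower)), gcost,
                       history, n_evals, cfg$seed)
}

#' Metropolis acceptance probability of simulated annealing
#'
#' Certain acceptance for improving moves, `exp(-dc / Temp)` otherwise.
#'
#' @param dc cost difference (new minus old).
#' @param Temp current temperature (> 0).
#' @export
sa_acceptance <- function(dc, Temp) ifelse(dc < 0, 1, exp(-dc / Temp))

#' Simulated-annealing minimization over a box
#'
#' Classical annealing with a homogeneous Metropolis chain per temperature
#' level: each of the `chain_length` proposals perturbs every dimension by
#' `N(0, (proposal_scale * range)^2)` jointly and is clamped to the bounds,
#' then accepted with probability [sa_acceptance()].  After each chain the
#' temperature cools geometrically (`T <- T * Cr`).  Clamping (rather than
#' reflection) gives the bound values themselves positive probability
#' mass, which is what lets the chain settle on exact-integer treatment
#' counts at the box corners.  The best point ever visited is returned.
#'
#' @inheritParams pso_minimize
#' @param cfg an [sa_config()].
#' @export
sa_minimize <- function(objective, bounds, cfg = sa_config(),
                        init_point = NULL) {
  if (cfg$max_iters < 0) stop("max_iters must be nonnegative")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- unname(bounds$lower); hi <- unname(bounds$upper)
  nd <- length(lo)
  scale <- cfg$proposal_scale * (hi - lo)
  x <- if (is.null(init_point)) runif(nd, lo, hi) else clamp(init_point, lo, hi)
  fx <- objective(x)
  if (!is.finite(fx)) stop("objective must be finite on the bounds")
  n_evals <- 1L
  best <- x; fbest <- fx
  Temp <- cfg$T0
  history <- numeric(cfg$max_iters + 1); history[1] <- fbest
  if (cfg$max_iters > 0) for (it in seq_len(cfg$max_iters)) {
    for (m in seq_len(cfg$chain_length)) {
      prop <- clamp(x + rnorm(nd, 0, scale), lo, hi)
      fp <- objective(prop)
      n_evals <- n_evals + 1L
      if (runif(1) < sa_acceptance(fp - fx, Temp)) { x <- prop; fx <- fp }
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    Temp <- Temp * cfg$Cr
    history[it + 1] <- fbest
  }
  new_optimizer_result("sa", setNames(best, names(bounds$lower)), fbest,
                       history, n_evals, cfg$seed)
}

# per-layer selection probabilities: pheromone^alpha * eta^beta, normalized
aco_layer_probs <- function(pher, eta, ea, eb) {
  wgt <- pher^ea * eta^eb
  s <- sum(wgt)
  if (!is.finite(s) || s <= 0)
    stop("degenerate pheromone/heuristic layer (all-zero selection weights)")
  wgt / s
}

#' Ant-colony minimization on a layered discretization
#'
#' Each variable is discretized to a layer of levels; an ant builds a
#' candidate by drawing one level per layer with probability proportional
#' to `pheromone^alpha * eta^beta` within the layer.  After each cohort of
#' ants, pheromone evaporates (`rho <- (1 - eps) rho`) and every ant
#' deposits `Q_dep / L` on the levels it used, where `L` is its cost.
#' Costs must be positive for the deposit rule to make sense.
#'
#' @inheritParams pso_minimize
#' @param cfg an [aco_config()] (carries the layers and heuristics).
#' @param init_point optional point; it is snapped to the nearest levels
#'   and evaluated as the incumbent before the first cohort.
#' @export
aco_minimize <- function(objective, bounds, cfg, init_point = NULL) {
  if (cfg$max_iters < 0) stop("max_iters must be nonnegative")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  levels <- cfg$levels
  nd <- length(levels)
  pher <- lapply(levels, function(v) rep(1, length(v)))
  best <- NULL; fbest <- Inf; n_evals <- 0L
  if (!is.null(init_point)) {
    snapped <- vapply(seq_len(nd), function(j)
      levels[[j]][which.min(abs(levels[[j]] - init_point[j]))], 0)
    fbest <- objective(snapped); best <- snapped; n_evals <- 1L
  }
  history <- numeric(cfg$max_iters + 1); history[1] <- fbest
  if (cfg$max_iters > 0) for (it in seq_len(cfg$max_iters)) {
    picks <- matrix(0L, cfg$n_ants, nd)
    xs <- matrix(0, cfg$n_ants, nd)
    for (j in seq_len(nd)) {
      pr <- aco_layer_probs(pher[[j]], cfg$heuristics[[j]],
                            cfg$exponent_alpha, cfg$exponent_beta)
      picks[, j] <- sample.int(length(levels[[j]]), cfg$n_ants,
                               replace = TRUE, prob = pr)
      xs[, j] <- levels[[j]][picks[, j]]
    }
    cost <- apply(xs, 1, objective)
    n_evals <- n_evals + cfg$n_ants
    if (any(cost <= 0)) stop("ACO deposit rule requires positive costs")
    k <- which.min(cost)
    if (cost[k] < fbest) { fbest <- cost[k]; best <- xs[k, ] }
    for (j in seq_len(nd)) {
      dep <- vapply(seq_along(levels[[j]]), function(l)
        sum(cfg$Q_dep / cost[picks[, j] == l]), 0)
      pher[[j]] <- (1 - cfg$evaporation) * pher[[j]] + dep
    }
    history[it + 1] <- fbest
  }
  new_optimizer_result("aco", setNames(best, names(bounds$lower)), fbest,
                       history, n_evals, cfg$seed)
}

#' Search the dosing-regimen box with a chosen metaheuristic
#'
#' Convenience wrapper assembling the study conditions: the regimen
#' objective ([regimen_objective()]), the common start point
#' `(d, g, N) = (2.2, 10, 3)` (lowest dose, largest gap, fewest
#' treatments), and per-method defaults.  ACO uses the
#' [regimen_aco_levels()] discretization with its 1/d, g, 1/N heuristics.
#'
#' @param method `"pso"`, `"sa"` or `"aco"`.
#' @param bounds_preset `"default"` or `"expanded"` (see [search_bounds()]).
#' @param seed RNG seed for the run.
#' @param cfg optional config overriding the per-method default.
#' @param params,x0,weights,dt,kt forwarded to [regimen_objective()].
#' @return An `optimizer_result`; `$best` is `c(d, g, N)`.
#' @export
optimize_regimen <- function(method = c("pso", "sa", "aco"),
                             bounds_preset = "default", seed = NULL,
                             cfg = NULL, params = bcg_params(),
                             x0 = bcg_x0(), weights = cost_weights(),
                             dt = 0.01, kt = round(100 / dt)) {
  method <- match.arg(method)
  bounds <- search_bounds(bounds_preset)
  obj <- regimen_objective(params, x0, weights, dt = dt, kt = kt)
  init <- c(2.2, 10, 3)
  if (method == "pso") {
    if (is.null(cfg)) cfg <- pso_config(seed = seed)
    else if (!is.null(seed)) cfg$seed <- seed
    pso_minimize(obj, bounds, cfg, init_point = init)
  } else if (method == "sa") {
    if (is.null(cfg)) cfg <- sa_config(seed = seed)
    else if (!is.null(seed)) cfg$seed <- seed
    sa_minimize(obj, bounds, cfg, init_point = init)
  } else {
    if (is.null(cfg)) {
      lv <- regimen_aco_levels(bounds)
      cfg <- aco_config(lv, regimen_aco_heuristics(lv), seed = seed)
    } else if (!is.null(seed)) cfg$seed <- seed
    aco_minimize(obj, bounds, cfg, init_point = init)
  }
}
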