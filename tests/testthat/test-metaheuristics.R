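sphere <- function(x) sum(x^2)
box3 <- search_bounds(lower = c(-5, -5, -5), upper = c(5, 5, 5))

test_that("PSO drives the sphere function to its global minimum", {
  res <- pso_minimize(sphere, box3, pso_config(max_iters = 200, seed = 1))
  expect_lt(res$best_cost, 1e-4)
  expect_equal(res$n_evals, 100 * 201)
})

test_that("PSO respects its budget, bounds and monotone incumbent", {
  pts <- list()
  rec <- function(x) { pts[[length(pts) + 1]] <<- x; sphere(x) }
  res <- pso_minimize(rec, box3, pso_config(swarm_size = 15, max_iters = 20,
                                            seed = 2),
                      init_point = c(4, 4, 4))
  P <- do.call(rbind, pts)
  expect_true(all(P >= -5 & P <= 5))
  expect_true(all(diff(res$history) <= 0))
  # zero iterations: the evaluated initial swarm is returned
  res0 <- pso_minimize(sphere, box3, pso_config(swarm_size = 5, max_iters = 0,
                                                seed = 3),
                       init_point = c(0, 0, 0))
  expect_equal(res0$best_cost, 0)
  expect_equal(unname(res0$best), c(0, 0, 0))
  expect_error(pso_config(swarm_size = 0))
  bad_cfg <- pso_config(swarm_size = 5)
  bad_cfg$swarm_size <- 0L
  expect_error(pso_minimize(sphere, box3, bad_cfg), "particle")
})

test_that("annealing acceptance follows the Metropolis rule", {
  expect_equal(sa_acceptance(-1, 0.5), 1)
  expect_equal(sa_acceptance(0.5, 1), exp(-0.5))
  # frozen chain: uphill moves are essentially never accepted
  expect_lt(sa_acceptance(0.1, 0.1 / 20), 1e-6)
})

test_that("SA converges on a smooth bowl and stays in bounds", {
  pts <- list()
  rec <- function(x) { pts[[length(pts) + 1]] <<- x; sphere(x) }
  res <- sa_minimize(rec, box3,
                     sa_config(chain_length = 10, max_iters = 150, seed = 4),
                     init_point = c(4.5, -4.5, 4.5))
  P <- do.call(rbind, pts)
  expect_true(all(P >= -5 & P <= 5))
  expect_lt(res$best_cost, 0.1)
  expect_true(all(diff(res$history) <= 0))
})

test_that("ant colony selection probabilities are a proper distribution", {
  pr <- bcgrmc:::aco_layer_probs(c(1, 2, 3), c(0.5, 1, 2), 1, 1)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # uniform pheromone with the heuristic exponent off: uniform choice
  pr0 <- bcgrmc:::aco_layer_probs(rep(1, 4), c(9, 1, 5, 2), 1, 0)
  expect_equal(pr0, rep(0.25, 4))
  expect_error(bcgrmc:::aco_layer_probs(c(0, 0), c(1, 1), 1, 1),
               "degenerate")
})

test_that("ACO finds the optimum of a separable discrete objective", {
  lv <- list(seq(0, 5, by = 0.5), 1:6)
  cfg <- aco_config(lv, n_ants = 20, max_iters = 60, seed = 5)
  obj <- function(x) 1 + (x[1] - 2)^2 + (x[2] - 3)^2
  res <- aco_minimize(obj, search_bounds(lower = c(0, 1), upper = c(5, 6)),
                      cfg)
  expect_equal(unname(res$best), c(2, 3))
  expect_true(all(diff(res$history) <= 0))
})

test_that("all three optimizers are deterministic under a fixed seed", {
  a1 <- pso_minimize(sphere, box3, pso_config(swarm_size = 10,
                                              max_iters = 10, seed = 9))
  a2 <- pso_minimize(sphere, box3, pso_config(swarm_size = 10,
                                              max_iters = 10, seed = 9))
  expect_identical(a1, a2)
  b1 <- sa_minimize(sphere, box3, sa_config(max_iters = 20, seed = 9))
  b2 <- sa_minimize(sphere, box3, sa_config(max_iters = 20, seed = 9))
  expect_identical(b1, b2)
  lv <- list(0:3, 0:3, 0:3)
  pos_sphere <- function(x) 1 + sphere(x)  # ACO deposits need positive costs
  c1 <- aco_minimize(pos_sphere, box3,
                     aco_config(lv, n_ants = 8, max_iters = 10, seed = 9))
  c2 <- aco_minimize(pos_sphere, box3,
                     aco_config(lv, n_ants = 8, max_iters = 10, seed = 9))
  expect_identical(c1, c2)
})

test_that("the regimen ACO grid discretizes the clinical box as designed", {
  lv <- regimen_aco_levels()
  expect_length(lv$d, 43)
  expect_equal(lv$g, 5:10)
  expect_equal(lv$N, 3:10)
  h <- regimen_aco_heuristics(lv)
  expect_equal(h$g, lv$g)             # prefer long gaps a priori
  expect_equal(h$d, 1 / lv$d)         # prefer low doses
  expect_equal(h$N, 1 / lv$N)         # prefer few treatments
})
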