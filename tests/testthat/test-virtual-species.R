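test_that("Gaussian suitability matches its closed form", {
  # two flat layers so the study-area variance is controlled via the grid
  set.seed(10)
  m1 <- matrix(rnorm(100), 10, 10)
  m2 <- matrix(rnorm(100), 10, 10)
  env <- make_stack(list(m1, m2))
  X <- env$values[env$mask, ]
  mu <- X[17, ]
  narrow <- niche_spec("n", mu, 0.2, env)
  wide <- niche_spec("w", mu, 0.6, env)
  s_n <- gaussian_suitability(narrow, env)
  s_w <- gaussian_suitability(wide, env)
  # exact 1 at the centroid cell
  expect_equal(s_n$values[17], 1)
  expect_equal(s_w$values[17], 1)
  # one variable deviating by 1 study-area SD
  sd1 <- sd(X[, 1])
  x <- mu; x[1] <- x[1] + sd1
  q_manual <- function(f) exp(-0.5 * sd1^2 / (f * sd1^2))
  s_at <- function(niche, x)
    exp(-sum((x - niche$centroid)^2 / (2 * niche$variances)))
  expect_equal(s_at(narrow, x), exp(-2.5), tolerance = 1e-12)
  expect_equal(s_at(wide, x), exp(-1 / 1.2), tolerance = 1e-12)
  expect_equal(q_manual(0.2), exp(-2.5))
  # monotonicity in tolerance at every cell
  expect_true(all(s_w$values[s_w$mask] >= s_n$values[s_n$mask]))
})

test_that("niche specification validates tolerance and dimension", {
  env <- small_env()
  expect_error(niche_spec("a", rep(0, 4), 0, env), "tolerance_fraction")
  expect_error(niche_spec("a", rep(0, 3), 0.2, env), "length")
  n <- niche_spec("a", rep(0, 4), 0.2, env)
  expect_identical(n$tolerance_class, "narrow")
  expect_identical(niche_spec("b", rep(0, 4), 0.6, env)$tolerance_class,
                   "wide")
  expect_true(all(n$variances > 0))
})

test_that("centroid choice is spread, deterministic, and validated", {
  env <- small_env()
  cen <- choose_centroids(env, 5, seed = 3)
  expect_identical(nrow(cen), 5L)
  M <- as.matrix(cen[, env$names])
  # pairwise distinct in environmental space
  expect_gt(min(dist(scale(M))), 0)
  expect_identical(choose_centroids(env, 5, seed = 3), cen)

  # k = 1 returns the cell closest to the grand mean (direct oracle)
  one <- choose_centroids(env, 1, seed = 3)
  X <- env$values[env$mask, ]
  Z <- scale(X)
  d2 <- rowSums(sweep(Z, 2, colMeans(Z))^2)
  cells <- which(as.vector(env$mask))
  expect_identical(one$cell, cells[which.min(d2)])

  # identical environment everywhere cannot support k > 1
  flat <- make_stack(list(matrix(1, 6, 6) + 0, matrix(2, 6, 6) + 0))
  expect_error(choose_centroids(flat, 3, seed = 1), "distinct")
})

test_that("seed cell selection honours maxima and breaks ties uniformly", {
  m <- matrix(0.2, 5, 5); m[3, 4] <- 0.9
  expect_identical(select_seed_cell(make_layer(m)), 3L + 3L * 5L)

  # plateau of 4 maxima: roughly uniform over repeated draws
  m2 <- matrix(0.1, 5, 5)
  plateau <- c(1L, 7L, 13L, 25L)
  m2[plateau] <- 0.8
  set.seed(42)
  draws <- replicate(8000, select_seed_cell(make_layer(m2)))
  counts <- table(factor(draws, levels = plateau))
  chi <- sum((counts - 2000)^2 / 2000)
  expect_lt(chi, qchisq(0.999, df = 3))

  # all-zero suitability still yields a cell
  expect_true(select_seed_cell(make_layer(matrix(0, 3, 3))) %in% 1:9)
})

test_that("clamp semantics: isolated optimum stays a one-cell range", {
  m <- matrix(0.05, 9, 9); m[5, 5] <- 1
  occ <- simulate_range(make_layer(m), automaton_params(rng_seed = 1,
                                                        n_iterations = 50))
  expect_identical(which(occ$occupied), 5L + 4L * 9L)
})

test_that("uniformly perfect habitat spreads deterministically and never dies", {
  m <- matrix(1, 11, 11)
  sizes <- integer(4)
  for (it in 1:4) {
    occ <- simulate_range(make_layer(m),
                          automaton_params(rng_seed = 3, n_iterations = it))
    sizes[it] <- sum(occ$occupied)
    # containment: within Chebyshev distance max_jump * t of the seed
    seed_rc <- c(((occ$seed_cell - 1) %% 11) + 1,
                 ((occ$seed_cell - 1) %/% 11) + 1)
    rc <- which(occ$occupied, arr.ind = TRUE)
    cheb <- pmax(abs(rc[, 1] - seed_rc[1]), abs(rc[, 2] - seed_rc[2]))
    expect_lte(max(cheb), 5 * it)
  }
  expect_true(all(diff(sizes) >= 0))   # no extinction above the high clamp
  occ_end <- simulate_range(make_layer(m),
                            automaton_params(rng_seed = 3,
                                             n_iterations = 30))
  expect_identical(sum(occ_end$occupied), 121L)
})

test_that("one-step colonization probability matches the dispersal geometry", {
  # suitability s in the stochastic band: a specific ring cell at distance d
  # is colonized per iteration with prob 1 - (1 - s/(8d*max_jump))^attempts
  s <- 0.5
  nr <- 13L
  occupied0 <- matrix(FALSE, nr, nr); occupied0[7, 7] <- TRUE
  p_eff <- rep(s, nr * nr)
  mask <- matrix(TRUE, nr, nr)
  params <- automaton_params(rng_seed = 1)
  rings <- lapply(1:5, virtualsdm:::ring_offsets)
  target_d1 <- 6L + 6L * nr   # (6,7): distance 1
  target_d3 <- 4L + 6L * nr   # (4,7): distance 3
  set.seed(81)
  n_rep <- 20000
  hits <- matrix(FALSE, n_rep, 2)
  for (i in seq_len(n_rep)) {
    st <- virtualsdm:::colonize_step(occupied0, p_eff, mask, params, rings)
    hits[i, ] <- st$occupied[c(target_d1, target_d3)]
  }
  p_expected <- function(d) 1 - (1 - s / (8 * d * 5))^3
  for (j in 1:2) {
    d <- c(1, 3)[j]
    p_hat <- mean(hits[, j])
    se <- sqrt(p_expected(d) * (1 - p_expected(d)) / n_rep)
    expect_lt(abs(p_hat - p_expected(d)), 4 * se)
  }
})

test_that("occupancy implies viable suitability and seed reachability", {
  env <- default_env(50, 50, seed = 11, n_regions = 15)
  cen <- choose_centroids(env, 2, seed = 5)
  niche <- niche_spec("sp", as.numeric(unlist(cen[1, env$names])), 0.6, env)
  suit <- gaussian_suitability(niche, env)
  occ <- simulate_range(suit, automaton_params(rng_seed = 2))
  expect_gt(sum(occ$occupied), 0)
  s <- as.vector(suit$values)
  occ_cells <- which(occ$occupied)
  # invariant: occupied => suitability >= low clamp
  expect_true(all(s[occ_cells] >= 0.1))
  expect_true(all(occ$mask[occ_cells]))

  # BFS oracle: all occupied cells reachable from the seed through viable
  # masked cells by Chebyshev steps <= max_jump
  nr <- 50L
  viable <- occ$mask & matrix(s >= 0.1, nr, nr)
  seen <- matrix(FALSE, nr, nr)
  seen[occ$seed_cell] <- TRUE
  queue <- occ$seed_cell
  while (length(queue)) {
    cell <- queue[1]; queue <- queue[-1]
    r <- ((cell - 1) %% nr) + 1; c <- ((cell - 1) %/% nr) + 1
    rr <- max(1, r - 5):min(nr, r + 5)
    cc <- max(1, c - 5):min(nr, c + 5)
    for (ci in cc) for (ri in rr) {
      k <- ri + (ci - 1) * nr
      if (viable[k] && !seen[k]) { seen[k] <- TRUE; queue <- c(queue, k) }
    }
  }
  expect_true(all(seen[occ_cells]))
})

test_that("range simulation is a pure function of inputs and seed", {
  env <- small_env()
  niche <- niche_spec("sp", as.numeric(env$values[200, ]), 0.6, env)
  suit <- gaussian_suitability(niche, env)
  o1 <- simulate_range(suit, automaton_params(rng_seed = 9), "sp")
  o2 <- simulate_range(suit, automaton_params(rng_seed = 9), "sp")
  expect_identical(o1$occupied, o2$occupied)
  o3 <- simulate_range(suit, automaton_params(rng_seed = 10), "sp")
  expect_false(identical(o1$occupied, o3$occupied))
})

test_that("expected range size is non-decreasing in tolerance", {
  env <- default_env(40, 40, seed = 21, n_regions = 10)
  cen <- choose_centroids(env, 1, seed = 2)
  mu <- as.numeric(unlist(cen[1, env$names]))
  suit_n <- gaussian_suitability(niche_spec("n", mu, 0.2, env), env)
  suit_w <- gaussian_suitability(niche_spec("w", mu, 0.6, env), env)
  diffs <- vapply(1:20, function(r) {
    pn <- automaton_params(rng_seed = r, n_iterations = 40)
    sum(simulate_range(suit_w, pn)$occupied) -
      sum(simulate_range(suit_n, pn)$occupied)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("prevalence is the occupied fraction of the mask", {
  mask <- matrix(TRUE, 10, 10)
  occ <- matrix(FALSE, 10, 10); occ[1:5] <- TRUE
  expect_equal(prevalence(make_occupancy(occ, mask)), 0.05)
  expect_equal(prevalence(make_occupancy(matrix(FALSE, 10, 10), mask)), 0)
  expect_equal(prevalence(make_occupancy(matrix(TRUE, 10, 10), mask)), 1)
})

test_that("automaton parameter validation", {
  expect_error(automaton_params(low_clamp = 0.9, high_clamp = 0.1), "clamp")
  expect_error(automaton_params(max_jump = 0), "max_jump")
  expect_error(automaton_params(attempts_per_cell = 0), "attempts")
})
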