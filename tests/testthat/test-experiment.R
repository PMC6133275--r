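# A tiny but complete experiment used by several blocks (built once).
smoke_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- default_env(80, 80, seed = 11, n_regions = 25)
      cfg <- experiment_config(env = env, n_centroids = 2,
                               tolerance_fractions = 0.6,
                               predictor_sets = "RAW", algorithms = "ES",
                               n_occurrences = 20, n_replicates = 2,
                               n_background = 500, master_seed = 11)
      cache <<- run_experiment(cfg, quiet = TRUE)
    }
    cache
  }
})

# balanced synthetic evaluation table with controllable effects
synthetic_eval_table <- function(n_species = 10, algorithms = 4,
                                 predictor_sets = c("RAW", "PCA4", "PCA6"),
                                 replicates = 5, seed = 1,
                                 tss_fun = NULL) {
  set.seed(seed)
  algs <- paste0("A", seq_len(algorithms))
  species <- sprintf("sp%02d", seq_len(n_species))
  prev <- setNames(runif(n_species, 0.01, 0.2), species)
  tolc <- setNames(rep(c("narrow", "wide"), length.out = n_species), species)
  d <- expand.grid(species_id = species, predictor_set = predictor_sets,
                   algorithm = algs, replicate = seq_len(replicates),
                   stringsAsFactors = FALSE)
  d <- tibble::as_tibble(d)
  d$tolerance_class <- tolc[d$species_id]
  d$prevalence <- prev[d$species_id]
  d$threshold_rule <- "balance"
  if (is.null(tss_fun)) tss_fun <- function(d) 0.5 + rnorm(nrow(d), 0, 0.05)
  d$TSS <- tss_fun(d)
  d$OP <- pmin(pmax(0.3 + rnorm(nrow(d), 0, 0.05), 0), 1)
  d$UP <- pmin(pmax(0.2 + rnorm(nrow(d), 0, 0.05), 0), 1)
  d$real_range <- round(13500 * d$prevalence)
  d$predicted_range <- round(d$real_range * 1.1 + rnorm(nrow(d), 0, 20))
  class(d) <- c("vs_eval_table", class(d))
  d
}

test_that("a smoke-scale experiment yields the full factorial row count", {
  tbl <- smoke_table()
  # 2 species x 1 predictor set x 1 algorithm x 2 replicates x 2 rules
  expect_identical(nrow(tbl), 8L)
  expect_identical(sort(unique(tbl$threshold_rule)), c("balance", "lpt"))
  expect_identical(length(manifest(tbl)$exclusions), 0L)
  expect_true(all(tbl$TSS >= -1 & tbl$TSS <= 1))
  # prevalence constant within species
  per_sp <- tapply(tbl$prevalence, tbl$species_id,
                   function(x) length(unique(x)))
  expect_true(all(per_sp == 1))
  expect_true(all(tbl$real_range > 0))
})

test_that("the experiment is a pure function of configuration and seed", {
  strip <- function(x) { attr(x, "manifest") <- NULL; as.data.frame(x) }
  env <- default_env(80, 80, seed = 11, n_regions = 25)
  cfg <- experiment_config(env = env, n_centroids = 2,
                           tolerance_fractions = 0.6,
                           predictor_sets = "RAW", algorithms = "ES",
                           n_occurrences = 20, n_replicates = 2,
                           n_background = 500, master_seed = 11)
  again <- run_experiment(cfg, quiet = TRUE)
  expect_equal(strip(smoke_table()), strip(again))
})

test_that("ANCOVA has the design degrees of freedom of the full factorial", {
  # the full-scale study design: 30 species x 3 predictor sets x
  # 5 algorithms x 10 replicates = 4500 rows; 30 model df + the intercept
  # leave 4469 error df
  d <- synthetic_eval_table(n_species = 30, algorithms = 5, replicates = 10)
  expect_identical(nrow(d), 4500L)
  a <- ancova(d, "TSS")
  td <- tidy(a)
  expect_identical(td$df[td$term == "Prevalence"], 1L)
  expect_identical(td$df[td$term == "ENV"], 2L)
  expect_identical(td$df[td$term == "ALG"], 4L)
  expect_identical(td$df[td$term == "TOL"], 1L)
  expect_identical(td$df[td$term == "ENV:ALG"], 8L)
  expect_identical(td$df[td$term == "ENV:TOL"], 2L)
  expect_identical(td$df[td$term == "ALG:TOL"], 4L)
  expect_identical(td$df[td$term == "ENV:ALG:TOL"], 8L)
  expect_identical(td$df[td$term == "Error"], 4469L)
})

test_that("ANCOVA attributes variance where it was generated", {
  # response equal to the covariate: prevalence soaks up ~all variance
  d <- synthetic_eval_table(n_species = 12, algorithms = 3, replicates = 4,
                            tss_fun = function(d)
                              d$prevalence + rnorm(nrow(d), 0, 1e-4))
  a <- ancova(d, "TSS")
  expect_gt(a$prevalence_eta2, 0.999)
  td <- tidy(a)
  expect_lt(max(td$statistic[td$term %in%
                             c("ENV", "ALG", "TOL")], na.rm = TRUE), 5)

  # a large algorithm effect with no predictor-set effect
  d2 <- synthetic_eval_table(
    n_species = 12, algorithms = 3, replicates = 4, seed = 2,
    tss_fun = function(d) 0.5 + 0.3 * (d$algorithm == "A1") +
      rnorm(nrow(d), 0, 0.05))
  a2 <- ancova(d2, "TSS")
  td2 <- tidy(a2)
  f_alg <- td2$statistic[td2$term == "ALG"]
  f_env <- td2$statistic[td2$term == "ENV"]
  expect_gt(f_alg, 100)
  expect_lt(f_env, 10)
})

test_that("ANCOVA F values match a hand-computed balanced ANOVA", {
  # 2 x 2 x 2 balanced design: textbook sums of squares computed directly.
  # The prevalence covariate is pure noise, so with N = 480 it absorbs an
  # O(1/N) share of the variance; comparisons use a 2% relative tolerance.
  set.seed(3)
  lev <- c("L1", "L2")
  r <- 60
  d <- expand.grid(species_id = sprintf("s%d", 1:4),
                   predictor_set = lev, algorithm = lev,
                   replicate = seq_len(r), stringsAsFactors = FALSE)
  d <- tibble::as_tibble(d)
  d$tolerance_class <- ifelse(d$species_id %in% c("s1", "s2"),
                              "narrow", "wide")
  d$prevalence <- runif(nrow(d), 0.05, 0.15)
  d$threshold_rule <- "balance"
  d$TSS <- 0.5 + 0.2 * (d$predictor_set == "L1") +
    0.1 * (d$algorithm == "L1") + rnorm(nrow(d), 0, 0.08)
  d$OP <- d$UP <- 0.1
  d$real_range <- 100L; d$predicted_range <- 110L
  class(d) <- c("vs_eval_table", class(d))

  a <- ancova(d, "TSS", ss_type = 2)
  td <- tidy(a)

  # textbook oracle (balanced, so Type I/II/III coincide for the factors)
  y <- d$TSS
  f1 <- factor(d$predictor_set); f2 <- factor(d$algorithm)
  f3 <- factor(d$tolerance_class)
  N <- length(y)
  ss <- function(f) sum(tapply(y, f, function(v) length(v) * mean(v)^2)) -
    N * mean(y)^2
  ss_a <- ss(f1); ss_b <- ss(f2)
  ss_ab <- ss(interaction(f1, f2)) - ss_a - ss_b
  fit_full <- lm(y ~ f1 * f2 * f3)
  ms_err <- sum(resid(fit_full)^2) / fit_full$df.residual
  rel <- function(x, y) abs(x / y - 1)
  expect_lt(rel(td$sumsq[td$term == "ENV"], ss_a), 0.02)
  expect_lt(rel(td$sumsq[td$term == "ALG"], ss_b), 0.02)
  expect_lt(abs(td$sumsq[td$term == "ENV:ALG"] - ss_ab), 0.05 * ms_err)
  expect_lt(rel(td$statistic[td$term == "ENV"], (ss_a / 1) / ms_err), 0.02)
  expect_lt(rel(td$statistic[td$term == "ALG"], (ss_b / 1) / ms_err), 0.02)
})

test_that("ANCOVA rejects tables with empty design cells", {
  d <- synthetic_eval_table(n_species = 6, algorithms = 2, replicates = 3)
  d <- d[!(d$algorithm == "A1" & d$predictor_set == "RAW"), ]
  expect_error(ancova(d, "TSS"), "empty design cell")
})

test_that("TSS stability summarises replicate variance correctly", {
  d <- synthetic_eval_table(n_species = 4, algorithms = 2, replicates = 2,
                            tss_fun = function(d)
                              ifelse(d$replicate == 1, 0.5, 0.7))
  st <- tss_stability(d)
  expect_equal(st$mean_variance, rep(0.02, nrow(st)), tolerance = 1e-12)

  # identical TSS across replicates: zero variance, zero-width interval
  d0 <- synthetic_eval_table(n_species = 4, algorithms = 2, replicates = 3,
                             tss_fun = function(d) 0.6)
  st0 <- tss_stability(d0)
  expect_equal(st0$mean_variance, rep(0, nrow(st0)))
  expect_equal(st0$ci_upper - st0$ci_lower, rep(0, nrow(st0)))

  # heteroscedastic noise: doubling the sd quadruples the mean variance
  d2 <- synthetic_eval_table(
    n_species = 60, algorithms = 2, predictor_sets = "RAW",
    replicates = 10, seed = 4,
    tss_fun = function(d) 0.5 + rnorm(nrow(d), 0,
                                      ifelse(d$algorithm == "A1",
                                             0.10, 0.05)))
  st2 <- tss_stability(d2)
  ratio <- st2$mean_variance[st2$algorithm == "A1"] /
    st2$mean_variance[st2$algorithm == "A2"]
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.6)

  dsingle <- synthetic_eval_table(n_species = 2, replicates = 1)
  expect_error(tss_stability(dsingle), "2 replicates")
})

test_that("range-size regression recovers exact and noisy relations", {
  d <- synthetic_eval_table(n_species = 10, algorithms = 2, replicates = 3)
  d$predicted_range <- d$real_range
  rr <- suppressWarnings(range_size_regression(d))
  expect_equal(rr$intercept, rep(0, nrow(rr)), tolerance = 1e-8)
  expect_equal(rr$slope, rep(1, nrow(rr)), tolerance = 1e-10)
  expect_equal(rr$r_squared, rep(1, nrow(rr)), tolerance = 1e-10)

  d$predicted_range <- 2 * d$real_range + 100
  rr2 <- suppressWarnings(range_size_regression(d))
  expect_equal(rr2$intercept, rep(100, nrow(rr2)), tolerance = 1e-8)
  expect_equal(rr2$slope, rep(2, nrow(rr2)), tolerance = 1e-10)

  # parameter recovery within 2 SE under known noise
  set.seed(5)
  d$predicted_range <- 150 + 1.3 * d$real_range + rnorm(nrow(d), 0, 50)
  rr3 <- range_size_regression(d)
  g <- d[d$algorithm == "A1" & d$predictor_set == "RAW", ]
  f <- lm(predicted_range ~ real_range, data = g)
  se <- coef(summary(f))[, "Std. Error"]
  row <- rr3[rr3$algorithm == "A1" & rr3$predictor_set == "RAW", ]
  expect_lt(abs(row$slope - 1.3), 2 * se[2])
  expect_lt(abs(row$intercept - 150), 2 * se[1])

  # degenerate group is skipped with a reason
  d$real_range <- 100L
  rr4 <- range_size_regression(d)
  expect_identical(nrow(rr4), 0L)
  expect_gt(length(attr(rr4, "skipped")), 0L)
})

test_that("species residual summaries expose injected idiosyncrasy", {
  d <- synthetic_eval_table(
    n_species = 10, algorithms = 3, replicates = 6, seed = 6,
    tss_fun = function(d) 0.6 - 0.2 * (d$species_id == "sp03") +
      rnorm(nrow(d), 0, 0.03))
  a <- ancova(d, "TSS")
  # OLS residuals sum to zero
  expect_lt(abs(mean(resid(a$fit))), 1e-10)
  sr <- species_residual_summary(a)
  m3 <- mean(sr$mean_residual[sr$species_id == "sp03"])
  m_others <- mean(sr$mean_residual[sr$species_id != "sp03"])
  # the -0.2 shift is mean-centred over 10 species and partly absorbed by
  # the prevalence covariate, so ~ -0.18 is the ceiling
  expect_lt(m3, -0.10)
  expect_lt(abs(m_others), 0.05)
  expect_lt(m3 - m_others, -0.10)

  # permuting species labels destroys the between-species structure
  d_perm <- d
  set.seed(7)
  d_perm$species_id <- sample(d_perm$species_id)
  a_perm <- ancova(d_perm, "TSS")
  sr_perm <- species_residual_summary(a_perm)
  v_orig <- var(tapply(sr$mean_residual, sr$species_id, mean))
  v_perm <- var(tapply(sr_perm$mean_residual, sr_perm$species_id, mean))
  expect_lt(v_perm, v_orig / 2)
})

test_that("result types provide tidy, glance and autoplot surfaces", {
  d <- synthetic_eval_table(n_species = 6, algorithms = 2, replicates = 3)
  a <- ancova(d, "TSS")
  expect_s3_class(tidy(a), "tbl_df")
  g <- glance(a)
  expect_identical(g$response, "TSS")
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(autoplot(tss_stability(d)), "ggplot")
  expect_s3_class(autoplot(range_size_regression(d)), "ggplot")
  expect_s3_class(autoplot(species_residual_summary(a)), "ggplot")
  p <- fit_pca(small_env())
  expect_s3_class(autoplot(p), "ggplot")
})

test_that("sample-referenced thresholds and per-fit background are wired through", {
  env <- default_env(80, 80, seed = 11, n_regions = 25)
  base <- list(env = env, n_centroids = 2, tolerance_fractions = 0.6,
               predictor_sets = "RAW", algorithms = "ES",
               n_occurrences = 20, n_replicates = 2, n_background = 500,
               master_seed = 11)
  cfg_s <- do.call(experiment_config, c(base, threshold_ref = "sample"))
  tbl_s <- run_experiment(cfg_s, quiet = TRUE)
  expect_identical(nrow(tbl_s), 8L)
  # the sample-referenced threshold generally differs from the
  # truth-referenced one
  bal_truth <- smoke_table()$threshold[smoke_table()$threshold_rule ==
                                         "balance"]
  bal_sample <- tbl_s$threshold[tbl_s$threshold_rule == "balance"]
  expect_false(identical(bal_truth, bal_sample))

  cfg_b <- do.call(experiment_config, c(base, bg_per_fit = TRUE))
  tbl_b <- run_experiment(cfg_b, quiet = TRUE)
  expect_identical(nrow(tbl_b), 8L)
})
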