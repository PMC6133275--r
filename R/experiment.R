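# Orchestration of the factorial collinearity experiment:
# environment -> PCA -> virtual species truths -> occurrence/background
# samples -> model fits on each predictor set -> thresholded evaluation.

#' Configuration of the factorial experiment
#'
#' Defaults reproduce the standard design at desk scale: a 150 x 150
#' synthetic bioclim-like stack (19 layers, blob mask at 60% fill), 15 niche
#' centroids crossed with narrow (0.2) and wide (0.6) tolerance fractions
#' (30 species), predictor sets RAW plus the Kaiser-selected and
#' 95%-cumulative PCA score sets, all four algorithms, 10 replicates of 50
#' occurrence points, 10000 background cells, and both threshold rules.
#'
#' @param env A [vs_stack()] to use as the environment, or `NULL` to
#'   generate the default synthetic stack from the master seed.
#' @param n_centroids Number of niche centroids (default 15).
#' @param tolerance_fractions Tolerance fractions (default `c(0.2, 0.6)`).
#' @param predictor_sets Subset of `c("RAW", "PCA4", "PCA6")`. `"PCA4"` is
#'   the Kaiser-Guttman axis count, `"PCA6"` the 95%-cumulative count (the
#'   labels carry the canonical counts; the actual k comes from
#'   [select_axes()] on the fitted PCA).
#' @param algorithms Subset of `c("ES", "MAHAL", "LQ_BG", "KERNEL_BG")`.
#' @param n_occurrences Occurrence points per replicate (default 50).
#' @param n_replicates Occurrence replicates per species (default 10).
#' @param n_background Background cells (default 10000).
#' @param automaton An [automaton_params()] template (its `rng_seed` is
#'   overridden per species from the master seed).
#' @param threshold_rules Subset of `c("balance", "lpt")`.
#' @param threshold_ref Reference for the balance threshold: `"truth"`
#'   (default; ROC against the known occupancy, the virtual-species
#'   setting) or `"sample"` (training presences vs background, the
#'   practitioner's workflow).
#' @param bg_per_fit Redraw the background sample for every
#'   species x replicate instead of sharing one draw across the whole
#'   experiment (default `FALSE`).
#' @param nrows,ncols,spatial_range Synthetic environment shape (ignored
#'   when `env` is supplied).
#' @param master_seed Integer master seed; every stochastic stage draws from
#'   a named substream derived from it.
#' @return An object of class `vs_experiment_config`.
#' @export
experiment_config <- function(env = NULL,
                              n_centroids = 15L,
                              tolerance_fractions = c(0.2, 0.6),
                              predictor_sets = c("RAW", "PCA4", "PCA6"),
                              algorithms = ALGORITHMS,
                              n_occurrences = 50L,
                              n_replicates = 10L,
                              n_background = 10000L,
                              automaton = automaton_params(),
                              threshold_rules = c("balance", "lpt"),
                              threshold_ref = c("truth", "sample"),
                              bg_per_fit = FALSE,
                              nrows = 150L, ncols = 150L,
                              spatial_range = 10,
                              master_seed = 1L) {
  predictor_sets <- match.arg(predictor_sets, several.ok = TRUE)
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  threshold_rules <- match.arg(threshold_rules, c("balance", "lpt"),
                               several.ok = TRUE)
  threshold_ref <- match.arg(threshold_ref)
  stopifnot(n_centroids >= 1L, n_occurrences >= 1L, n_replicates >= 1L,
            all(tolerance_fractions > 0), all(tolerance_fractions <= 1))
  structure(
    list(env = env, n_centroids = as.integer(n_centroids),
         tolerance_fractions = tolerance_fractions,
         predictor_sets = predictor_sets, algorithms = algorithms,
         n_occurrences = as.integer(n_occurrences),
         n_replicates = as.integer(n_replicates),
         n_background = as.integer(n_background),
         automaton = automaton, threshold_rules = threshold_rules,
         threshold_ref = threshold_ref, bg_per_fit = isTRUE(bg_per_fit),
         nrows = as.integer(nrows), ncols = as.integer(ncols),
         spatial_range = spatial_range,
         master_seed = as.integer(master_seed)),
    class = "vs_experiment_config"
  )
}

#' Run the factorial collinearity experiment
#'
#' Executes the full pipeline and returns one evaluation row per
#' species x predictor set x algorithm x replicate x threshold rule. The
#' whole run is a pure function of the configuration and master seed.
#' Species whose simulated range holds fewer cells than `n_occurrences` are
#' excluded with a logged reason (never silently dropped); the exclusions,
#' seeds and axis counts are recorded in the `manifest` attribute.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress stage progress messages.
#' @return A tibble of class `vs_eval_table` with columns `species_id`,
#'   `centroid_id`, `tolerance_class`, `tolerance_fraction`, `prevalence`,
#'   `predictor_set`, `algorithm`, `replicate`, `threshold_rule`,
#'   `threshold`, `sensitivity`, `specificity`, `TSS`, `OP`, `UP`,
#'   `real_range`, `predicted_range`; attribute `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "vs_experiment_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$master_seed

  # --- environment ---------------------------------------------------------
  say("[env] building environment")
  env <- config$env
  if (is.null(env)) {
    env <- default_env(config$nrows, config$ncols,
                       seed = substream_seed(seed, "env"),
                       spatial_range = config$spatial_range)
  }

  # --- PCA and predictor sets ---------------------------------------------
  pca <- fit_pca(env)
  k_kaiser <- select_axes(pca, "kaiser")
  k_cum95 <- select_axes(pca, "cumulative95")
  stacks <- list(RAW = env)
  if ("PCA4" %in% config$predictor_sets) {
    if (k_kaiser < 1L) stop("Kaiser criterion selected 0 axes", call. = FALSE)
    stacks$PCA4 <- project_scores(pca, env, k_kaiser)
  }
  if ("PCA6" %in% config$predictor_sets)
    stacks$PCA6 <- project_scores(pca, env, k_cum95)
  stacks <- stacks[config$predictor_sets]
  say("[pca] kaiser -> %d axes, cumulative95 -> %d axes", k_kaiser, k_cum95)

  # --- virtual species -----------------------------------------------------
  say("[species] choosing %d centroids", config$n_centroids)
  centroids <- choose_centroids(env, config$n_centroids,
                                seed = substream_seed(seed, "centroids"))
  layer_cols <- env$names
  tol <- sort(config$tolerance_fractions)
  species <- list()
  exclusions <- list()
  for (i in seq_len(config$n_centroids)) {
    for (f in tol) {
      cls <- if (length(tol) == 2L) c("narrow", "wide")[match(f, tol)]
             else NULL
      sp_id <- sprintf("sp%02d_f%02.0f", i, 100 * f)
      niche <- niche_spec(sp_id,
                          as.numeric(unlist(centroids[i, layer_cols])),
                          f, env, tolerance_class = cls)
      suit <- gaussian_suitability(niche, env)
      occ <- simulate_range(
        suit,
        params = automaton_params(
          low_clamp = config$automaton$low_clamp,
          high_clamp = config$automaton$high_clamp,
          attempts_per_cell = config$automaton$attempts_per_cell,
          max_jump = config$automaton$max_jump,
          n_iterations = config$automaton$n_iterations,
          stop_window = config$automaton$stop_window,
          stop_tol = config$automaton$stop_tol,
          rng_seed = substream_seed(seed, "range", sp_id),
          extinction_spares_new = config$automaton$extinction_spares_new),
        species_id = sp_id)
      n_occ <- sum(occ$occupied)
      if (n_occ < config$n_occurrences) {
        exclusions[[sp_id]] <- sprintf(
          "species %s excluded: %d occupied cells < %d required",
          sp_id, n_occ, config$n_occurrences)
        say("[species] %s", exclusions[[sp_id]])
        next
      }
      species[[sp_id]] <- list(id = sp_id, centroid_id = i, niche = niche,
                               occ = occ, prevalence = prevalence(occ))
    }
  }
  say("[species] %d species simulated, %d excluded",
      length(species), length(exclusions))
  if (length(species) == 0L)
    stop("no species had enough occupied cells to sample", call. = FALSE)

  # --- background (shared across species and algorithms by default) -------
  draw_bg <- function(...) {
    bg <- sample_background(env, m = config$n_background,
                            seed = substream_seed(seed, "bg", ...))
    list(cells = bg$cell,
         env = lapply(stacks, function(s) env_at(s, bg$cell)))
  }
  bg_shared <- if (config$bg_per_fit) NULL else draw_bg()

  # --- fits and evaluation -------------------------------------------------
  needs_bg <- c("LQ_BG", "KERNEL_BG")
  rows <- list()
  for (sp in species) {
    occs <- sample_occurrences(sp$occ, n = config$n_occurrences,
                               replicates = config$n_replicates,
                               seed = substream_seed(seed, "occ", sp$id))
    for (r in seq_len(config$n_replicates)) {
      cells_r <- occs$cell[occs$replicate == r]
      bg <- if (config$bg_per_fit) draw_bg(sp$id, r) else bg_shared
      for (ps in names(stacks)) {
        stk <- stacks[[ps]]
        pres_env <- env_at(stk, cells_r)
        for (alg in config$algorithms) {
          res <- tryCatch({
            model <- fit_sdm(pres_env, algorithm = alg,
                             background_env = if (alg %in% needs_bg)
                               bg$env[[ps]] else NULL,
                             predictor_set = ps)
            surf <- predict_surface(model, stk)
            out <- list()
            if ("balance" %in% config$threshold_rules) {
              tb <- if (config$threshold_ref == "truth")
                balance_threshold(surf, sp$occ)
              else balance_threshold_sample(surf, cells_r, bg$cells)
              out$balance <- binary_metrics(confusion(surf, tb, sp$occ),
                                            rule = "balance", threshold = tb)
            }
            if ("lpt" %in% config$threshold_rules) {
              tl <- lpt_threshold(surf, cells_r)
              out$lpt <- binary_metrics(confusion(surf, tl, sp$occ),
                                        rule = "lpt", threshold = tl)
            }
            dplyr::bind_rows(out)
          }, error = function(e) {
            stop(sprintf("experiment cell (%s, %s, %s, rep %d) failed: %s",
                         sp$id, ps, alg, r, conditionMessage(e)),
                 call. = FALSE)
          })
          res <- tibble::add_column(
            res,
            species_id = sp$id, centroid_id = sp$centroid_id,
            tolerance_class = sp$niche$tolerance_class,
            tolerance_fraction = sp$niche$tolerance_fraction,
            predictor_set = ps, algorithm = alg, replicate = r,
            .before = 1L)
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
    say("[fit] %s done (%d rows so far)", sp$id,
        sum(vapply(rows, nrow, integer(1))))
  }
  tbl <- dplyr::bind_rows(rows)
  tbl <- tbl[, c("species_id", "centroid_id", "tolerance_class",
                 "tolerance_fraction", "prevalence", "predictor_set",
                 "algorithm", "replicate", "threshold_rule", "threshold",
                 "sensitivity", "specificity", "TSS", "OP", "UP",
                 "real_range", "predicted_range")]
  manifest <- list(
    master_seed = seed,
    n_species = length(species),
    exclusions = unname(unlist(exclusions)),
    k_kaiser = k_kaiser, k_cumulative95 = k_cum95,
    predictor_sets = config$predictor_sets,
    algorithms = config$algorithms,
    n_occurrences = config$n_occurrences,
    n_replicates = config$n_replicates,
    n_background = config$n_background,
    grid = c(nrows = env$grid$nrows, ncols = env$grid$ncols,
             masked = sum(env$mask)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  attr(tbl, "manifest") <- manifest
  class(tbl) <- c("vs_eval_table", class(tbl))
  say("[done] %d evaluation rows in %.1f s", nrow(tbl), manifest$elapsed_s)
  tbl
}

#' Manifest of an experiment run
#'
#' @param table A [run_experiment()] result.
#' @return The manifest list (seeds, axis counts, exclusions, timings).
#' @export
manifest <- function(table) attr(table, "manifest")
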