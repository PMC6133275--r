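# Virtual species: Gaussian niches in raw environmental space, suitability
# projection, and the stochastic colonization-extinction cellular automaton
# that turns a suitability surface into a "true" occupied range.

#' Choose niche centroids spread over environmental space
#'
#' Clusters the masked cells' (standardised) environmental vectors into `k`
#' groups with k-means and returns, for each group, the cell whose
#' environmental vector is closest to the group centre. This is a stratified
#' stand-in for hand-picking centroids representative of distinct regional
#' environments. Deterministic for a given seed; clusters are ordered by
#' their score on the first principal axis so the labelling is stable.
#'
#' @param stack The raw-layer [vs_stack()].
#' @param k Number of centroids.
#' @param seed Integer seed.
#' @return A tibble with `centroid_id`, `cell`, `row`, `col` and one column
#'   per layer holding the centroid's raw environmental values.
#' @export
choose_centroids <- function(stack, k, seed = 1L) {
  stopifnot(inherits(stack, "vs_stack"))
  X <- masked_values(stack)
  cells <- which(as.vector(stack$mask))
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  Z <- scale(X)
  n_distinct <- nrow(unique(Z))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct environmental vectors (",
         n_distinct, ")", call. = FALSE)
  km <- with_substream(seed, "choose_centroids", expr =
    kmeans(Z, centers = k, nstart = 5L, iter.max = 100L))
  # representative cell = nearest cell to each cluster centre
  rep_cell <- integer(k)
  for (g in seq_len(k)) {
    d2 <- colSums((t(Z) - km$centers[g, ])^2)
    rep_cell[[g]] <- which.min(d2)
  }
  # stable ordering: by projection of the centre on the leading eigenvector
  pc1 <- eigen(cor(X), symmetric = TRUE)$vectors[, 1L]
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  ord <- order(km$centers %*% pc1, decreasing = TRUE)
  rep_cell <- rep_cell[ord]
  out <- cell_rowcol(stack$grid, cells[rep_cell])
  out <- tibble::add_column(out, centroid_id = seq_len(k), .before = 1L)
  dplyr::bind_cols(out, tibble::as_tibble(X[rep_cell, , drop = FALSE]))
}

#' Define a virtual species' Gaussian niche
#'
#' The niche is a multivariate Gaussian in raw environmental space with
#' diagonal covariance: the variance on each layer is `tolerance_fraction`
#' times that layer's variance over the study area, so tolerance is expressed
#' relative to the available environmental variation (0.2 for narrow-,
#' 0.6 for wide-tolerance species in the standard design).
#'
#' @param species_id Identifier string.
#' @param centroid Numeric vector of optimal raw environmental values
#'   (length V, named or in layer order).
#' @param tolerance_fraction Fraction f in (0, 1] of the study-area variance.
#' @param stack The raw-layer [vs_stack()] defining the study area.
#' @param tolerance_class `"narrow"`/`"wide"` label; by default derived from
#'   f (narrow if f <= 0.4).
#' @return An object of class `vs_niche`.
#' @export
niche_spec <- function(species_id, centroid, tolerance_fraction, stack,
                       tolerance_class = NULL) {
  stopifnot(inherits(stack, "vs_stack"))
  if (tolerance_fraction <= 0 || tolerance_fraction > 1)
    stop("`tolerance_fraction` must be in (0, 1]", call. = FALSE)
  X <- masked_values(stack)
  if (length(centroid) != ncol(X))
    stop("`centroid` length ", length(centroid), " != ", ncol(X), " layers",
         call. = FALSE)
  variances <- tolerance_fraction * apply(X, 2L, var)
  if (any(variances <= 0))
    stop("zero study-area variance for layer(s): ",
         paste(colnames(X)[variances <= 0], collapse = ", "), call. = FALSE)
  if (is.null(tolerance_class))
    tolerance_class <- if (tolerance_fraction <= 0.4) "narrow" else "wide"
  structure(
    list(species_id = species_id,
         centroid = setNames(as.numeric(centroid), colnames(X)),
         tolerance_fraction = tolerance_fraction,
         variances = variances,
         tolerance_class = tolerance_class,
         layer_names = colnames(X)),
    class = "vs_niche"
  )
}

#' @export
print.vs_niche <- function(x, ...) {
  cat(sprintf("<vs_niche> %s: %d-dim Gaussian, tolerance %.2g (%s)\n",
              x$species_id, length(x$centroid), x$tolerance_fraction,
              x$tolerance_class))
  invisible(x)
}

#' Gaussian suitability surface of a niche
#'
#' S(x) = exp(-1/2 * sum_k (x_k - mu_k)^2 / sigma^2_k). The surface equals 1
#' exactly at the centroid (no normalising constant), so the species is
#' certain to persist in its optimal environment.
#'
#' @param niche A [niche_spec()].
#' @param stack The raw-layer stack the niche was defined on.
#' @return A [vs_layer()] with values in (0, 1].
#' @export
gaussian_suitability <- function(niche, stack) {
  stopifnot(inherits(niche, "vs_niche"), inherits(stack, "vs_stack"))
  if (n_layers(stack) != length(niche$centroid))
    stop("stack has ", n_layers(stack), " layers but the niche is defined on ",
         length(niche$centroid), call. = FALSE)
  D <- sweep(stack$values, 2L, niche$centroid)
  q <- as.vector((D^2) %*% (1 / (2 * niche$variances)))
  s <- exp(-q)
  vs_layer(stack$grid,
           matrix(s, stack$grid$nrows, stack$grid$ncols),
           stack$mask)
}

#' Automaton parameters
#'
#' Defaults follow the standard design: occupancy in cells with suitability
#' < 0.1 is impossible and > 0.9 is permanent (clamps that stabilise very
#' poor and very good habitat); three dispersal attempts per occupied cell
#' per iteration; jump distance uniform on 1..5 cells, so propagules can
#' cross unsuitable barriers up to 4 cells wide; 100 iterations.
#'
#' @param low_clamp,high_clamp Suitability clamps in `[0, 1]`,
#'   `low_clamp < high_clamp`.
#' @param attempts_per_cell Dispersal attempts per occupied cell per
#'   iteration.
#' @param max_jump Maximum Chebyshev jump distance.
#' @param n_iterations Number of automaton iterations.
#' @param stop_window,stop_tol Optional plateau stopping: stop early when the
#'   relative range-size change stays below `stop_tol` for `stop_window`
#'   consecutive iterations.
#' @param rng_seed Integer seed for the realisation.
#' @param extinction_spares_new If `TRUE`, cells colonised in the current
#'   iteration are exempt from that iteration's extinction test (alternative
#'   reading of the rescue-effect rule; default `FALSE`).
#' @return An object of class `vs_automaton_params`.
#' @export
automaton_params <- function(low_clamp = 0.1, high_clamp = 0.9,
                             attempts_per_cell = 3L, max_jump = 5L,
                             n_iterations = 100L,
                             stop_window = NULL, stop_tol = NULL,
                             rng_seed = 1L,
                             extinction_spares_new = FALSE) {
  if (!(low_clamp >= 0 && low_clamp < high_clamp && high_clamp <= 1))
    stop("need 0 <= low_clamp < high_clamp <= 1", call. = FALSE)
  if (max_jump < 1L) stop("`max_jump` must be >= 1", call. = FALSE)
  if (attempts_per_cell < 1L)
    stop("`attempts_per_cell` must be >= 1", call. = FALSE)
  structure(
    list(low_clamp = low_clamp, high_clamp = high_clamp,
         attempts_per_cell = as.integer(attempts_per_cell),
         max_jump = as.integer(max_jump),
         n_iterations = as.integer(n_iterations),
         stop_window = stop_window, stop_tol = stop_tol,
         rng_seed = as.integer(rng_seed),
         extinction_spares_new = isTRUE(extinction_spares_new)),
    class = "vs_automaton_params"
  )
}

# effective per-cell probability: clamp tails to 0/1
effective_prob <- function(s, params) {
  p <- s
  p[s < params$low_clamp] <- 0
  p[s > params$high_clamp] <- 1
  p
}

# offsets of the Chebyshev ring at exact distance d (8d cells)
ring_offsets <- function(d) {
  top    <- cbind(-d, (-d):d)
  bottom <- cbind(d, (-d):d)
  left   <- cbind((-d + 1):(d - 1), -d)
  right  <- cbind((-d + 1):(d - 1), d)
  m <- rbind(top, bottom, left, right)
  colnames(m) <- c("dr", "dc")
  m
}

#' Select the automaton seed cell
#'
#' Returns a masked cell attaining the maximum suitability; ties are broken
#' uniformly at random from the current RNG stream.
#'
#' @param suitability A [vs_layer()].
#' @return Linear cell index.
#' @export
select_seed_cell <- function(suitability) {
  stopifnot(inherits(suitability, "vs_layer"))
  idx <- which(as.vector(suitability$mask))
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  v <- as.vector(suitability$values)[idx]
  best <- idx[v >= max(v)]
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

# one colonization sweep; returns the updated occupancy and the set of
# newly colonised cells (used by the spare-new extinction variant)
colonize_step <- function(occupied, p_eff, mask, params, rings) {
  nr <- nrow(occupied); nc <- ncol(occupied)
  src <- which(occupied)
  if (length(src) == 0L) return(list(occupied = occupied, new = integer(0)))
  n_att <- length(src) * params$attempts_per_cell
  src <- rep(src, each = params$attempts_per_cell)
  d <- sample.int(params$max_jump, n_att, replace = TRUE)
  pos <- floor(runif(n_att) * (8 * d)) + 1L
  dr <- integer(n_att); dc <- integer(n_att)
  for (dd in unique(d)) {
    sel <- d == dd
    off <- rings[[dd]]
    dr[sel] <- off[pos[sel], 1L]
    dc[sel] <- off[pos[sel], 2L]
  }
  r0 <- ((src - 1L) %% nr) + 1L
  c0 <- ((src - 1L) %/% nr) + 1L
  rt <- r0 + dr; ct <- c0 + dc
  ok <- rt >= 1L & rt <= nr & ct >= 1L & ct <= nc
  tgt <- rt[ok] + (ct[ok] - 1L) * nr
  ok2 <- mask[tgt] & !occupied[tgt]
  tgt <- tgt[ok2]
  if (length(tgt) > 0L) {
    hit <- runif(length(tgt)) < p_eff[tgt]
    new <- unique(tgt[hit])
    occupied[new] <- TRUE
  } else new <- integer(0)
  list(occupied = occupied, new = new)
}

extinction_step <- function(occupied, p_eff, spare = integer(0)) {
  cur <- which(occupied)
  if (length(spare) > 0L) cur <- setdiff(cur, spare)
  if (length(cur) == 0L) return(occupied)
  die <- runif(length(cur)) >= p_eff[cur]
  occupied[cur[die]] <- FALSE
  occupied
}

#' Simulate a species' true range with the colonization-extinction automaton
#'
#' Starting from a single seed cell of maximal suitability, each iteration
#' (1) lets every occupied cell make `attempts_per_cell` dispersal attempts -
#' a jump distance d uniform on 1..`max_jump`, a target uniform on the
#' Chebyshev ring at exactly distance d, colonisation of an unoccupied,
#' masked target succeeding with its clamped suitability - and then
#' (2) subjects every occupied cell (including this iteration's colonists,
#' unless `extinction_spares_new`) to extinction with probability one minus
#' its clamped suitability. Colonisation before extinction permits rescue
#' effects. The realisation is a pure function of (suitability, params).
#'
#' @param suitability A [vs_layer()] with values in `[0, 1]`.
#' @param params An [automaton_params()].
#' @param species_id Identifier carried on the result.
#' @return An object of class `vs_occupancy`: fields `grid`, `mask`,
#'   `occupied` (logical matrix), `species_id`, `seed_cell`,
#'   `realization_seed`, `n_iterations_run`, `warning` (`TRUE` when no cell,
#'   even the seed, could persist).
#' @export
simulate_range <- function(suitability, params = automaton_params(),
                           species_id = "species") {
  stopifnot(inherits(suitability, "vs_layer"),
            inherits(params, "vs_automaton_params"))
  s <- as.vector(suitability$values)
  if (any(s[as.vector(suitability$mask)] < -1e-12 |
          s[as.vector(suitability$mask)] > 1 + 1e-12))
    stop("suitability must lie in [0, 1]", call. = FALSE)
  mask <- suitability$mask
  nr <- nrow(mask); nc <- ncol(mask)
  p_eff <- effective_prob(s, params)
  p_eff[!as.vector(mask)] <- 0
  rings <- lapply(seq_len(params$max_jump), ring_offsets)
  with_substream(params$rng_seed, "automaton", species_id, expr = {
    seed_cell <- select_seed_cell(suitability)
    occupied <- matrix(FALSE, nr, nc)
    occupied[seed_cell] <- TRUE
    degenerate <- max(p_eff) == 0
    sizes <- integer(0)
    iters_run <- 0L
    for (it in seq_len(params$n_iterations)) {
      st <- colonize_step(occupied, p_eff, mask, params, rings)
      occupied <- extinction_step(
        st$occupied, p_eff,
        spare = if (params$extinction_spares_new) st$new else integer(0))
      iters_run <- it
      n_occ <- sum(occupied)
      sizes <- c(sizes, n_occ)
      if (n_occ == 0L) break
      if (!is.null(params$stop_window) && !is.null(params$stop_tol) &&
          length(sizes) > params$stop_window) {
        recent <- sizes[(length(sizes) - params$stop_window):length(sizes)]
        if (all(abs(diff(recent)) / pmax(recent[-1L], 1L) < params$stop_tol))
          break
      }
    }
    structure(
      list(grid = suitability$grid, mask = mask, occupied = occupied,
           species_id = species_id, seed_cell = seed_cell,
           realization_seed = params$rng_seed,
           n_iterations_run = iters_run,
           warning = degenerate),
      class = "vs_occupancy"
    )
  })
}

#' @export
print.vs_occupancy <- function(x, ...) {
  cat(sprintf(
    "<vs_occupancy> %s: %d of %d masked cells occupied (prevalence %.3f)\n",
    x$species_id, sum(x$occupied), sum(x$mask), prevalence(x)))
  invisible(x)
}

#' Prevalence of an occupancy map
#'
#' Ratio of occupied cells to masked (study-area) cells.
#'
#' @param occ A [simulate_range()] result.
#' @return Number in `[0, 1]`.
#' @export
prevalence <- function(occ) {
  stopifnot(inherits(occ, "vs_occupancy"))
  sum(occ$occupied) / sum(occ$mask)
}
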