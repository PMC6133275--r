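# Occurrence and background sampling. Samples are of cells (one record per
# cell, without replacement); environmental values are extracted afterwards
# with env_at() against whichever predictor stack is being modelled, so the
# predictor-set treatment never resamples cells.

#' Sample occurrence records from a true occupancy map
#'
#' Draws `replicates` independent samples of `n` cells uniformly without
#' replacement among the occupied cells. Each replicate uses its own RNG
#' substream derived from `seed` and the species id, so samples are
#' reproducible and mutually independent.
#'
#' @param occ A [simulate_range()] result.
#' @param n Cells per replicate (default 50).
#' @param replicates Number of replicates (default 10).
#' @param seed Integer master seed.
#' @param policy `"strict"` errors when fewer than `n` cells are occupied;
#'   `"all"` falls back to every occupied cell with a warning.
#' @return A tibble with `species_id`, `replicate`, `cell`, `row`, `col`.
#' @export
sample_occurrences <- function(occ, n = 50L, replicates = 10L, seed = 1L,
                               policy = c("strict", "all")) {
  stopifnot(inherits(occ, "vs_occupancy"))
  policy <- match.arg(policy)
  pool <- which(occ$occupied)
  n_occ <- length(pool)
  if (n_occ < n) {
    if (policy == "strict")
      stop("species '", occ$species_id, "' has only ", n_occ,
           " occupied cells; cannot draw ", n, call. = FALSE)
    warning("species '", occ$species_id, "': sampling all ", n_occ,
            " occupied cells (< ", n, ")", call. = FALSE)
  }
  take <- min(n, n_occ)
  out <- lapply(seq_len(replicates), function(r) {
    cells <- with_substream(seed, "occurrences", occ$species_id, r, expr =
      pool[sample.int(n_occ, take)])
    tibble::add_column(cell_rowcol(occ$grid, cells),
                       species_id = occ$species_id, replicate = r,
                       .before = 1L)
  })
  dplyr::bind_rows(out)
}

#' Sample background cells from the study extent
#'
#' Uniform sample without replacement over the masked cells; if `m` exceeds
#' the number of masked cells, every masked cell is returned once.
#'
#' @param x A [vs_stack()] or [vs_occupancy()] supplying grid and mask.
#' @param m Number of background cells (default 10000).
#' @param seed Integer seed.
#' @return A tibble with `cell`, `row`, `col` (rows in random order).
#' @export
sample_background <- function(x, m = 10000L, seed = 1L) {
  mask <- x$mask
  grid <- x$grid
  pool <- which(as.vector(mask))
  if (length(pool) == 0L) stop("mask has no cells", call. = FALSE)
  if (m <= 0L) return(cell_rowcol(grid, integer(0)))
  cells <- with_substream(seed, "background", expr = {
    if (length(pool) <= m) pool[sample.int(length(pool))]
    else pool[sample.int(length(pool), m)]
  })
  cell_rowcol(grid, cells)
}
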