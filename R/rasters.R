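# Grid data model, ESRI ASCII I/O and the synthetic environment generator.
#
# All spatial objects use 0-free, matrix-native indexing: cell (row, col) with
# row 1 at the TOP of the grid, matching the storage order of ESRI ASCII
# files. Cells are also addressed by their column-major linear index into the
# nrows x ncols value matrix; no geographic coordinates are used internally.

#' Define a raster grid
#'
#' A `vs_grid` records the shape and georeference header of a raster:
#' number of rows/columns, lower-left corner, cell size and the nodata
#' sentinel. Row 1 is the top row, as stored in ESRI ASCII files.
#'
#' @param nrows,ncols Positive integers.
#' @param xll,yll Coordinates of the lower-left *corner*.
#' @param cellsize Positive cell edge length.
#' @param nodata Sentinel value written for masked-out cells.
#' @return An object of class `vs_grid`.
#' @export
#' @examples
#' vs_grid(10, 20)
vs_grid <- function(nrows, ncols, xll = 0, yll = 0, cellsize = 1,
                    nodata = -9999) {
  nrows <- as.integer(nrows)
  ncols <- as.integer(ncols)
  if (length(nrows) != 1L || is.na(nrows) || nrows < 1L)
    stop("`nrows` must be a positive integer", call. = FALSE)
  if (length(ncols) != 1L || is.na(ncols) || ncols < 1L)
    stop("`ncols` must be a positive integer", call. = FALSE)
  if (!is.numeric(cellsize) || cellsize <= 0)
    stop("`cellsize` must be > 0", call. = FALSE)
  structure(
    list(nrows = nrows, ncols = ncols, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata),
    class = "vs_grid"
  )
}

#' @export
print.vs_grid <- function(x, ...) {
  cat(sprintf("<vs_grid> %d x %d cells, cellsize %g, xll %g, yll %g\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  invisible(x)
}

n_cells <- function(grid) grid$nrows * grid$ncols

same_grid <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cellsize, b$cellsize))
}

#' Construct a single raster layer
#'
#' @param grid A [vs_grid()].
#' @param values Numeric `nrows x ncols` matrix; entries outside the mask are
#'   set to `NA`.
#' @param mask Logical matrix of the same shape (`TRUE` = valid/land). By
#'   default, cells with non-`NA` values.
#' @return An object of class `vs_layer` with fields `grid`, `values`, `mask`.
#' @export
vs_layer <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "vs_grid"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nrows, grid$ncols)))
    stop("`values` must be a ", grid$nrows, " x ", grid$ncols, " matrix",
         call. = FALSE)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !all(dim(mask) == dim(values)))
    stop("`mask` must be a logical matrix matching `values`", call. = FALSE)
  values[!mask] <- NA_real_
  if (anyNA(values[mask]))
    stop("`values` must be defined (non-NA) on every masked-true cell",
         call. = FALSE)
  structure(list(grid = grid, values = values, mask = mask),
            class = "vs_layer")
}

#' @export
print.vs_layer <- function(x, ...) {
  cat(sprintf("<vs_layer> %d x %d, %d masked cells, range [%g, %g]\n",
              x$grid$nrows, x$grid$ncols, sum(x$mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Bundle aligned layers into a raster stack
#'
#' All layers must share the grid and the mask. Values are stored as an
#' `(nrows*ncols) x V` matrix in column-major cell order, which is the working
#' format for PCA, niche definition and model fitting.
#'
#' @param layers List of [vs_layer()] objects.
#' @param names Unique layer names (default `"b1"..."bV"`).
#' @return An object of class `vs_stack` with fields `grid`, `mask`, `values`
#'   (cells x layers matrix, `NA` off-mask), `names`.
#' @export
vs_stack <- function(layers, names = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  lapply(layers, function(l) stopifnot(inherits(l, "vs_layer")))
  grid <- layers[[1L]]$grid
  mask <- layers[[1L]]$mask
  for (l in layers[-1L]) {
    if (!same_grid(grid, l$grid)) stop("layers do not share a grid", call. = FALSE)
    if (!identical(mask, l$mask)) stop("layers do not share a mask", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("b", seq_along(layers))
  if (anyDuplicated(names)) stop("layer names must be unique", call. = FALSE)
  if (length(names) != length(layers))
    stop("`names` length must match `layers`", call. = FALSE)
  values <- vapply(layers, function(l) as.vector(l$values),
                   numeric(n_cells(grid)))
  colnames(values) <- names
  structure(list(grid = grid, mask = mask, values = values, names = names),
            class = "vs_stack")
}

#' @export
print.vs_stack <- function(x, ...) {
  cat(sprintf("<vs_stack> %d layers (%s%s) on %d x %d grid, %d masked cells\n",
              length(x$names), paste(head(x$names, 4), collapse = ", "),
              if (length(x$names) > 4) ", ..." else "",
              x$grid$nrows, x$grid$ncols, sum(x$mask)))
  invisible(x)
}

#' Number of layers in a stack
#' @param stack A [vs_stack()].
#' @export
n_layers <- function(stack) length(stack$names)

#' Extract one layer of a stack
#' @param stack A [vs_stack()].
#' @param which Layer name or index.
#' @return A [vs_layer()].
#' @export
stack_layer <- function(stack, which) {
  if (is.character(which)) which <- match(which, stack$names)
  vs_layer(stack$grid,
           matrix(stack$values[, which], stack$grid$nrows, stack$grid$ncols),
           stack$mask)
}

#' Environmental values at a set of cells
#'
#' Looks up the environmental vector of each cell (column-major linear index)
#' in a stack. The same cell indices can be extracted against the raw stack or
#' any PCA-score stack on the same grid, so a predictor-set treatment never
#' resamples cells.
#'
#' @param stack A [vs_stack()].
#' @param cells Integer vector of linear cell indices (must be masked-true).
#' @return Numeric `length(cells) x V` matrix with layer names as columns.
#' @export
env_at <- function(stack, cells) {
  cells <- as.integer(cells)
  if (any(cells < 1L | cells > n_cells(stack$grid)))
    stop("cell index out of range", call. = FALSE)
  if (!all(stack$mask[cells]))
    stop("some cells are outside the mask", call. = FALSE)
  m <- stack$values[cells, , drop = FALSE]
  colnames(m) <- stack$names
  m
}

masked_values <- function(stack) {
  m <- stack$values[as.vector(stack$mask), , drop = FALSE]
  colnames(m) <- stack$names
  m
}

cell_rowcol <- function(grid, cells) {
  cells <- as.integer(cells)
  tibble::tibble(cell = cells,
                 row = ((cells - 1L) %% grid$nrows) + 1L,
                 col = ((cells - 1L) %/% grid$nrows) + 1L)
}

#' @export
as.data.frame.vs_stack <- function(x, ...) {
  cells <- which(as.vector(x$mask))
  rc <- cell_rowcol(x$grid, cells)
  cbind(as.data.frame(rc), as.data.frame(x$values[cells, , drop = FALSE]))
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O

#' Read an ESRI ASCII grid
#'
#' Accepts both the `xllcorner`/`yllcorner` and the `xllcenter`/`yllcenter`
#' header dialects; center coordinates are converted to the corner convention
#' (`corner = center - cellsize/2`). Cells equal to `NODATA_value` become
#' masked-false.
#'
#' @param path Path to a `.asc` file.
#' @return A [vs_layer()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[[i]])) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    hdr[[tolower(parts[[1L]])]] <- as.numeric(parts[[2L]])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  for (k in need) {
    if (is.null(hdr[[k]]))
      stop("malformed ESRI ASCII header: missing key '", k, "'", call. = FALSE)
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else stop("malformed ESRI ASCII header: missing key 'xllcorner'",
                   call. = FALSE)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else stop("malformed ESRI ASCII header: missing key 'yllcorner'",
                   call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  rows <- lines[i:length(lines)]
  if (length(rows) != nr)
    stop("expected ", nr, " data rows, found ", length(rows), call. = FALSE)
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    v <- as.numeric(strsplit(trimws(rows[[r]]), "\\s+")[[1L]])
    if (length(v) != nc)
      stop("row ", r, " has ", length(v), " values, expected ", nc,
           call. = FALSE)
    vals[r, ] <- v
  }
  mask <- vals != nodata
  vals[!mask] <- NA_real_
  grid <- vs_grid(nr, nc, xll = xll, yll = yll, cellsize = hdr$cellsize,
                  nodata = nodata)
  vs_layer(grid, vals, mask)
}

#' Write an ESRI ASCII grid
#'
#' Always writes the `xllcorner` dialect with fixed-decimal formatting, so
#' output is deterministic. Masked-out cells are written as the grid's nodata
#' sentinel.
#'
#' @param layer A [vs_layer()].
#' @param path Output path.
#' @param digits Number of decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, digits = 6) {
  stopifnot(inherits(layer, "vs_layer"))
  g <- layer$grid
  v <- layer$values
  if (any(round(v[layer$mask], digits) == g$nodata))
    stop("nodata sentinel ", g$nodata,
         " collides with a real cell value; choose another sentinel",
         call. = FALSE)
  hdr <- c(
    sprintf("ncols %d", g$ncols),
    sprintf("nrows %d", g$nrows),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  v[!layer$mask] <- g$nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.*f", digits, r),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write every layer of a stack as ESRI ASCII files
#'
#' @param stack A [vs_stack()].
#' @param dir Output directory (created if absent); one `<name>.asc` per layer.
#' @param digits Decimal places, see [write_ascii_grid()].
#' @return Vector of file paths, invisibly.
#' @export
write_stack <- function(stack, dir, digits = 6) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(stack$names, ".asc"))
  for (j in seq_along(stack$names))
    write_ascii_grid(stack_layer(stack, j), paths[[j]], digits = digits)
  invisible(paths)
}

#' Read a directory of ESRI ASCII layers into a stack
#'
#' @param paths Character vector of `.asc` paths, in layer order.
#' @param names Layer names (default: file names without extension).
#' @return A [vs_stack()].
#' @export
read_stack <- function(paths, names = NULL) {
  layers <- lapply(paths, read_ascii_grid)
  if (is.null(names))
    names <- sub("\\.asc$", "", basename(paths), ignore.case = TRUE)
  vs_stack(layers, names = names)
}

# ---------------------------------------------------------------------------
# Deterministic RNG substreams
#
# Every stochastic component draws from its own named substream derived from
# a master seed, so e.g. adding a species does not perturb the draws of the
# others. The label hash is a 31-bit multiplicative fold.

substream_seed <- function(master, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, ...))
  expr
}

# ---------------------------------------------------------------------------
# Masks

#' Grow an irregular connected "continent" mask
#'
#' Grows a single 8-connected blob from the grid centre by repeatedly
#' annexing a uniformly chosen frontier cell, until `fill_fraction` of the
#' grid is covered. The result is connected by construction and deterministic
#' for a given seed.
#'
#' @param grid A [vs_grid()].
#' @param seed Integer seed.
#' @param fill_fraction Target fraction of cells in the mask, in (0, 1].
#' @return Logical `nrows x ncols` matrix.
#' @export
blob_mask <- function(grid, seed, fill_fraction = 0.6) {
  stopifnot(inherits(grid, "vs_grid"))
  if (!is.numeric(fill_fraction) || fill_fraction <= 0 || fill_fraction > 1)
    stop("`fill_fraction` must be in (0, 1]", call. = FALSE)
  nr <- grid$nrows; nc <- grid$ncols
  target <- max(1L, round(fill_fraction * nr * nc))
  if (target == nr * nc) return(matrix(TRUE, nr, nc))
  with_substream(seed, "blob_mask", expr = {
    mask <- matrix(FALSE, nr, nc)
    queued <- matrix(FALSE, nr, nc)
    start <- ((nc %/% 2L) * nr) + (nr %/% 2L) + 1L
    frontier <- integer(0)
    push <- function(cells) {
      cells <- cells[!queued[cells] & !mask[cells]]
      queued[cells] <<- TRUE
      frontier <<- c(frontier, cells)
    }
    neighbours <- function(cell) {
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr[ok] + (cc[ok] - 1L) * nr
    }
    mask[start] <- TRUE
    push(neighbours(start))
    size <- 1L
    while (size < target && length(frontier) > 0L) {
      i <- sample.int(length(frontier), 1L)
      cell <- frontier[[i]]
      frontier <- frontier[-i]
      if (mask[cell]) next
      mask[cell] <- TRUE
      size <- size + 1L
      push(neighbours(cell))
    }
    mask
  })
}

# ---------------------------------------------------------------------------
# Synthetic collinear environment

#' Specification of a synthetic environmental stack
#'
#' @param n_layers Number of layers V.
#' @param grid A [vs_grid()].
#' @param target_corr Symmetric positive-semidefinite V x V matrix with unit
#'   diagonal: the cross-layer Pearson correlation the generator must induce.
#' @param spatial_range Autocorrelation length in cells (Gaussian smoothing
#'   scale); must be below `min(nrows, ncols)`.
#' @param mask_style `"rectangle"` (all cells) or `"blob"` (irregular
#'   connected mask via [blob_mask()]).
#' @param fill_fraction Blob mask fill fraction (ignored for rectangle).
#' @param n_regions Number of contiguous climatic regions ("biomes"): the
#'   mask is partitioned into Voronoi regions and every field is shrunk
#'   towards its region mean, producing the large plateaus of near-identical
#'   environment that continental climate data exhibit. `0` disables the
#'   plateau structure (pure smooth gradients).
#' @param region_jitter Residual within-region variation retained when
#'   `n_regions > 0` (fraction of the field's local deviation; default
#'   0.12).
#' @param seed Integer seed; the stack is a pure function of (spec, seed).
#' @return An object of class `vs_env_spec`.
#' @export
env_gen_spec <- function(n_layers, grid, target_corr,
                         spatial_range = 10,
                         mask_style = c("blob", "rectangle"),
                         fill_fraction = 0.6,
                         n_regions = 0L,
                         region_jitter = 0.12,
                         seed = 1L) {
  mask_style <- match.arg(mask_style)
  stopifnot(inherits(grid, "vs_grid"))
  target_corr <- as.matrix(target_corr)
  if (nrow(target_corr) != n_layers || ncol(target_corr) != n_layers)
    stop("`target_corr` must be ", n_layers, " x ", n_layers, call. = FALSE)
  if (max(abs(target_corr - t(target_corr))) > 1e-10)
    stop("`target_corr` must be symmetric (tolerance 1e-10)", call. = FALSE)
  if (max(abs(diag(target_corr) - 1)) > 1e-10)
    stop("`target_corr` must have unit diagonal", call. = FALSE)
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("`target_corr` is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  if (spatial_range <= 0 || spatial_range >= min(grid$nrows, grid$ncols))
    stop("`spatial_range` must be in (0, min(nrows, ncols))", call. = FALSE)
  if (n_regions < 0L || region_jitter < 0 || region_jitter > 1)
    stop("`n_regions` must be >= 0 and `region_jitter` in [0, 1]",
         call. = FALSE)
  structure(
    list(n_layers = as.integer(n_layers), grid = grid,
         target_corr = target_corr, spatial_range = spatial_range,
         mask_style = mask_style, fill_fraction = fill_fraction,
         n_regions = as.integer(n_regions), region_jitter = region_jitter,
         seed = as.integer(seed)),
    class = "vs_env_spec"
  )
}

#' Bioclim-like target correlation matrix (19 layers)
#'
#' A fixed 19 x 19 correlation matrix emulating the collinearity structure of
#' a continental bioclim stack: two large, very tight variable blocks
#' (temperature-like and precipitation-like), two small looser blocks, modest
#' between-block correlation, and two layers sign-flipped against their block
#' (as temperature seasonality and annual range load negatively in real
#' bioclim data). Its correlation-matrix PCA spectrum begins
#' 10.50, 3.93, 1.54, 1.19, 0.70, 0.35, ... so exactly four eigenvalues exceed
#' 1 (Kaiser-Guttman selects 4 axes), the 95%-cumulative criterion selects 6,
#' and PC1 carries ~55% of total variance.
#'
#' @return A 19 x 19 correlation matrix.
#' @export
#' @examples
#' eigen(worldclim_like_corr(), only.values = TRUE)$values[1:6]
worldclim_like_corr <- function() {
  sizes <- c(8L, 7L, 2L, 2L)
  r_within <- c(0.94, 0.94, 0.65, 0.30)
  between <- matrix(0, 4, 4)
  between[1, 2] <- between[2, 1] <- 0.42
  between[1, 3] <- between[3, 1] <- 0.20
  between[2, 3] <- between[3, 2] <- 0.20
  between[1, 4] <- between[4, 1] <- 0.15
  between[2, 4] <- between[4, 2] <- 0.15
  between[3, 4] <- between[4, 3] <- 0.10
  block <- rep(seq_along(sizes), sizes)
  V <- sum(sizes)
  C <- matrix(0, V, V)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    C[i, j] <- if (i == j) 1
      else if (block[i] == block[j]) r_within[block[i]]
      else between[block[i], block[j]]
  }
  # sign-flip two layers of the first block (spectrum-invariant)
  s <- rep(1, V); s[c(4L, 7L)] <- -1
  C <- diag(s) %*% C %*% diag(s)
  dimnames(C) <- list(paste0("b", 1:V), paste0("b", 1:V))
  C
}

# separable Gaussian blur: K_row %*% Z %*% K_col, rows normalised
smoothing_kernel <- function(n, range) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-0.5 * (d / range)^2)
  K / rowSums(K)
}

#' Generate a synthetic, spatially autocorrelated, collinear stack
#'
#' Simulates `n_layers` independent Gaussian white-noise fields, smooths each
#' with a separable Gaussian kernel of scale `spatial_range`, optionally
#' imprints a shared system of climatic plateaus (see below), then whitens
#' the fields over the masked cells (exact empirical decorrelation) and mixes
#' them by the symmetric square root of `target_corr`. Because the fields are
#' whitened before mixing, the empirical cross-layer Pearson correlation over
#' masked cells equals `target_corr` exactly, and every layer has mean 0 and
#' (sample) standard deviation 1 over the mask.
#'
#' With `n_regions > 0` the mask is partitioned into contiguous Voronoi
#' regions around randomly placed nuclei and each smoothed field is shrunk
#' towards its region mean, keeping only a fraction `region_jitter` of the
#' within-region deviation. The partition is shared by all layers, so the
#' plateaus survive the whitening/mixing step: large blocks of cells are
#' nearly identical across every layer, which is how biomes behave in real
#' continental climate data and is what makes narrow Gaussian niches occupy
#' non-trivial areas.
#'
#' @param spec An [env_gen_spec()].
#' @param names Layer names (default `"b1"..."bV"`, or the dimnames of
#'   `target_corr`).
#' @return A [vs_stack()].
#' @export
generate_synthetic_env <- function(spec, names = NULL) {
  stopifnot(inherits(spec, "vs_env_spec"))
  g <- spec$grid
  V <- spec$n_layers
  mask <- switch(spec$mask_style,
                 rectangle = matrix(TRUE, g$nrows, g$ncols),
                 blob = blob_mask(g, spec$seed, spec$fill_fraction))
  n_masked <- sum(mask)
  if (n_masked <= V)
    stop("mask has fewer cells (", n_masked, ") than layers (", V, ")",
         call. = FALSE)
  idx <- which(as.vector(mask))
  fields <- with_substream(spec$seed, "env_fields", expr = {
    Kr <- smoothing_kernel(g$nrows, spec$spatial_range)
    Kc <- smoothing_kernel(g$ncols, spec$spatial_range)
    f <- vapply(seq_len(V), function(j) {
      z <- matrix(rnorm(g$nrows * g$ncols), g$nrows, g$ncols)
      as.vector(Kr %*% z %*% t(Kc))
    }, numeric(g$nrows * g$ncols))
    if (spec$n_regions > 0L) {
      nuclei <- sample(idx, min(spec$n_regions, n_masked))
      rc <- cbind(((idx - 1L) %% g$nrows) + 1L, ((idx - 1L) %/% g$nrows) + 1L)
      nrc <- cbind(((nuclei - 1L) %% g$nrows) + 1L,
                   ((nuclei - 1L) %/% g$nrows) + 1L)
      d2 <- outer(rc[, 1L], nrc[, 1L], "-")^2 +
            outer(rc[, 2L], nrc[, 2L], "-")^2
      region <- max.col(-d2, ties.method = "first")
      for (j in seq_len(V)) {
        s <- f[idx, j]
        rmean <- stats::ave(s, region)
        f[idx, j] <- rmean + spec$region_jitter * (s - rmean)
      }
    }
    f
  })
  Fm <- fields[idx, , drop = FALSE]
  Fm <- sweep(Fm, 2L, colMeans(Fm))
  R <- chol(cov(Fm))
  W <- t(backsolve(R, t(Fm), transpose = TRUE))   # whitened: cov(W) = I
  es <- eigen(spec$target_corr, symmetric = TRUE)
  Csqrt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), V) %*% t(es$vectors)
  X <- W %*% Csqrt
  if (is.null(names)) {
    names <- colnames(spec$target_corr)
    if (is.null(names)) names <- paste0("b", seq_len(V))
  }
  values <- matrix(NA_real_, g$nrows * g$ncols, V,
                   dimnames = list(NULL, names))
  values[idx, ] <- X
  structure(list(grid = g, mask = mask, values = values, names = names),
            class = "vs_stack")
}

#' Default synthetic environment used by the factorial experiment
#'
#' Convenience wrapper: a 150 x 150 grid with a connected blob mask covering
#' 60% of the cells, 19 layers with the [worldclim_like_corr()] collinearity
#' structure, an autocorrelation range of 10 cells and 60 climatic plateau
#' regions (within-region jitter 0.12).
#'
#' @param nrows,ncols Grid dimensions.
#' @param seed Integer seed.
#' @param spatial_range Autocorrelation length in cells.
#' @param n_regions,region_jitter Climatic plateau structure, see
#'   [env_gen_spec()].
#' @return A [vs_stack()].
#' @export
default_env <- function(nrows = 150, ncols = 150, seed = 1L,
                        spatial_range = 10, n_regions = 60L,
                        region_jitter = 0.12) {
  spec <- env_gen_spec(19L, vs_grid(nrows, ncols),
                       worldclim_like_corr(),
                       spatial_range = spatial_range,
                       mask_style = "blob", fill_fraction = 0.6,
                       n_regions = n_regions, region_jitter = region_jitter,
                       seed = seed)
  generate_synthetic_env(spec)
}
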