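# Correlation-matrix PCA of an environmental stack, axis selection and score
# projection. The PCA always operates on the raw stack the virtual species
# are defined on; the retained score layers then form an alternative,
# collinearity-free predictor set for model fitting.

#' Principal component analysis of a raster stack (correlation matrix)
#'
#' Eigendecomposition of the Pearson correlation matrix of the layers over
#' the masked cells. Standardisation uses sample statistics (divisor n - 1).
#' Eigenvector signs are fixed so that each axis' largest-magnitude loading
#' is positive, making score rasters reproducible across linear-algebra
#' backends.
#'
#' @param stack A [vs_stack()] with at least two layers.
#' @return An object of class `vs_pca` with fields `means`, `sds`,
#'   `eigenvalues`, `eigenvectors` (V x V loadings), `proportion`,
#'   `cumulative` and `layer_names`.
#' @export
fit_pca <- function(stack) {
  stopifnot(inherits(stack, "vs_stack"))
  X <- masked_values(stack)
  V <- ncol(X)
  if (V < 2L) stop("PCA needs at least 2 layers", call. = FALSE)
  if (nrow(X) < V)
    stop("fewer masked cells (", nrow(X), ") than layers (", V, ")",
         call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("constant layer(s) over the mask: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  C <- cor(X)
  es <- eigen(C, symmetric = TRUE)
  vec <- es$vectors
  for (k in seq_len(V)) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  lam <- pmax(es$values, 0)
  structure(
    list(means = colMeans(X), sds = sds,
         eigenvalues = lam,
         eigenvectors = vec,
         proportion = lam / sum(lam),
         cumulative = cumsum(lam) / sum(lam),
         layer_names = colnames(X),
         n_cells = nrow(X)),
    class = "vs_pca"
  )
}

#' @export
print.vs_pca <- function(x, ...) {
  cat(sprintf("<vs_pca> %d layers over %d cells\n", length(x$eigenvalues),
              x$n_cells))
  cat("  eigenvalues:", paste(sprintf("%.3f", head(x$eigenvalues, 6)),
                              collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' @describeIn fit_pca Eigenvalue table (axis, eigenvalue, proportion,
#'   cumulative proportion), one row per axis.
#' @param x A `vs_pca` object.
#' @param ... Unused.
#' @method tidy vs_pca
#' @export
tidy.vs_pca <- function(x, ...) {
  tibble::tibble(
    axis = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion = 100 * x$proportion,
    cumulative = 100 * x$cumulative
  )
}

#' @describeIn fit_pca One-row summary with the axis counts chosen by each
#'   selection criterion.
#' @method glance vs_pca
#' @export
glance.vs_pca <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$eigenvalues),
    n_cells = x$n_cells,
    k_kaiser = select_axes(x, "kaiser"),
    k_cumulative95 = select_axes(x, "cumulative95"),
    pc1_proportion = 100 * x$proportion[[1L]]
  )
}

#' Number of PCA axes to retain
#'
#' Two conservative, widely used criteria: `"kaiser"` counts eigenvalues
#' (latent roots) strictly greater than one; `"cumulative95"` returns the
#' smallest k whose cumulative proportion of variance reaches 95%.
#'
#' @param model A [fit_pca()] result.
#' @param criterion `"kaiser"` or `"cumulative95"`.
#' @return Integer axis count (Kaiser may return 0 for degenerate input).
#' @export
select_axes <- function(model, criterion = c("kaiser", "cumulative95")) {
  stopifnot(inherits(model, "vs_pca"))
  criterion <- match.arg(criterion)
  switch(criterion,
         kaiser = sum(model$eigenvalues > 1),
         cumulative95 = which(model$cumulative >= 0.95 - 1e-12)[[1L]])
}

#' Project PCA scores back onto the grid
#'
#' Standardises each cell's environmental vector with the fitted means/sds
#' and multiplies by the first `k` eigenvectors, producing score layers
#' `PC1..PCk` with the original mask preserved.
#'
#' @param model A [fit_pca()] result.
#' @param stack The stack to project (layer names must match the fit).
#' @param k Number of axes, `1 <= k <= V`.
#' @return A [vs_stack()] of `k` score layers.
#' @export
project_scores <- function(model, stack, k) {
  stopifnot(inherits(model, "vs_pca"), inherits(stack, "vs_stack"))
  V <- length(model$layer_names)
  if (k < 1L || k > V) stop("`k` must be in 1..", V, call. = FALSE)
  if (!identical(stack$names, model$layer_names))
    stop("stack layer names/order do not match the fitted PCA (",
         paste(head(stack$names, 3), collapse = ","), "... vs ",
         paste(head(model$layer_names, 3), collapse = ","), "...)",
         call. = FALSE)
  Z <- sweep(sweep(stack$values, 2L, model$means), 2L, model$sds, "/")
  S <- Z %*% model$eigenvectors[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(k))
  structure(list(grid = stack$grid, mask = stack$mask, values = S,
                 names = colnames(S)),
            class = "vs_stack")
}
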