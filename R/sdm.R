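# SDM algorithms behind one fit/predict contract.
#
# Two true presence-only methods are implemented from scratch: the Envelope
# Score (a quantitative Bioclim: fraction of variables inside the rectilinear
# training envelope) and the Mahalanobis distance to the training centroid
# (with a pseudo-inverse fallback for rank-deficient covariance, the key
# degeneracy under collinearity). Two presence-background learners represent
# the complex algorithm class: a regularized linear+quadratic binomial
# learner (LQ_BG) and a radial-kernel classifier (KERNEL_BG). They are
# honestly-named stand-ins for the Maxent-class and SVM-class algorithms
# used in large SDM comparisons - not reimplementations of those programs.

ALGORITHMS <- c("ES", "MAHAL", "LQ_BG", "KERNEL_BG")

new_sdm <- function(algorithm_id, model, predictor_set = "RAW", meta = list()) {
  structure(list(algorithm_id = algorithm_id, model = model,
                 predictor_set_id = predictor_set, meta = meta),
            class = c(paste0("vs_sdm_", tolower(algorithm_id)), "vs_sdm"))
}

#' @export
print.vs_sdm <- function(x, ...) {
  cat(sprintf("<vs_sdm> %s on %s (n_presence = %s, n_background = %s)\n",
              x$algorithm_id, x$predictor_set_id,
              x$meta$n_presence %||% "?", x$meta$n_background %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_env_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

# ---------------------------------------------------------------------------
# Envelope Score

#' Fit a rectilinear environmental envelope
#'
#' Stores the per-variable min/max over the training presences.
#'
#' @param presence_env Numeric matrix of presence environmental values
#'   (n x V), at least one row.
#' @return An object of class `vs_envelope` (fields `min`, `max`).
#' @export
fit_envelope <- function(presence_env) {
  presence_env <- as_env_matrix(presence_env)
  if (nrow(presence_env) < 1L) stop("no presence rows", call. = FALSE)
  structure(list(min = apply(presence_env, 2L, min),
                 max = apply(presence_env, 2L, max)),
            class = "vs_envelope")
}

#' Envelope Score prediction
#'
#' Score = fraction of variables falling inside the training envelope
#' (values in 0, 1/V, ..., 1).
#'
#' @param model A [fit_envelope()] result.
#' @param x Environmental vector or n x V matrix.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
predict_envelope <- function(model, x) {
  x <- as_env_matrix(x)
  if (ncol(x) != length(model$min))
    stop("dimension mismatch: ", ncol(x), " vs ", length(model$min),
         call. = FALSE)
  inside <- sweep(x, 2L, model$min, ">=") & sweep(x, 2L, model$max, "<=")
  rowMeans(inside)
}

# ---------------------------------------------------------------------------
# Mahalanobis distance

#' Fit a Mahalanobis-distance model
#'
#' Stores the presence mean vector and sample covariance. When the
#' covariance is numerically singular (reciprocal condition number below
#' `tol`, e.g. with duplicated or perfectly collinear variables, or fewer
#' presences than variables), the Moore-Penrose pseudo-inverse is used and
#' recorded in `inverse_kind`.
#'
#' @param presence_env Numeric matrix (>= 2 rows).
#' @param tol Reciprocal-condition-number threshold for the pseudo-inverse
#'   fallback (default 1e-10).
#' @return An object of class `vs_mahalanobis` (fields `mean`, `cov`,
#'   `inv`, `inverse_kind`).
#' @export
fit_mahalanobis <- function(presence_env, tol = 1e-10) {
  X <- as_env_matrix(presence_env)
  if (nrow(X) < 2L) stop("need >= 2 presence rows", call. = FALSE)
  m <- colMeans(X)
  S <- cov(X)
  rc <- tryCatch(rcond(S), error = function(e) 0)
  if (is.na(rc) || rc < tol) {
    inv <- MASS::ginv(S)
    kind <- "pseudo"
  } else {
    inv <- solve(S)
    kind <- "standard"
  }
  structure(list(mean = m, cov = S, inv = inv, inverse_kind = kind),
            class = "vs_mahalanobis")
}

#' Mahalanobis suitability prediction
#'
#' Computes the squared Mahalanobis distance d2 to the training mean using
#' the recorded (pseudo-)inverse and maps it to a suitability score
#' `1/(1 + sqrt(d2))`. All downstream use is threshold-based, so any strictly
#' decreasing transform of the distance gives identical binary maps; this
#' one is fixed for reproducibility.
#'
#' @param model A [fit_mahalanobis()] result.
#' @param x Environmental vector or matrix.
#' @return Suitability in `(0, 1]`.
#' @export
predict_mahalanobis <- function(model, x) {
  x <- as_env_matrix(x)
  if (ncol(x) != length(model$mean))
    stop("dimension mismatch: ", ncol(x), " vs ", length(model$mean),
         call. = FALSE)
  D <- sweep(x, 2L, model$mean)
  d2 <- rowSums((D %*% model$inv) * D)
  if (any(d2 < -1e-8, na.rm = TRUE))
    stop("negative squared distance beyond numerical tolerance", call. = FALSE)
  d2 <- pmax(d2, 0)
  1 / (1 + sqrt(d2))
}

# ---------------------------------------------------------------------------
# LQ background learner (Maxent-class stand-in)

#' Fit the regularized linear+quadratic background learner
#'
#' A discriminative presence-vs-background fit: ridge-penalized binomial
#' likelihood on features \{x_v, x_v^2\} (plus optional hinge features), all
#' standardized by background statistics. This is the package's stand-in for
#' the Maxent-class of algorithms restricted to linear+quadratic features.
#'
#' @param presence_env Presence matrix (>= 5 rows).
#' @param background_env Background matrix (>= 50 rows).
#' @param regularization Ridge penalty lambda (default 0.01).
#' @param n_hinge Number of hinge knots per variable at background quantiles
#'   (default 0 = off).
#' @param predictor_set Label carried on the fitted object.
#' @return A `vs_sdm` object (`algorithm_id = "LQ_BG"`).
#' @export
fit_lq_background <- function(presence_env, background_env,
                              regularization = 0.01, n_hinge = 0L,
                              predictor_set = "RAW") {
  P <- as_env_matrix(presence_env)
  B <- as_env_matrix(background_env)
  if (nrow(P) < 5L) stop("need >= 5 presences", call. = FALSE)
  if (nrow(B) < 50L) stop("need >= 50 background rows", call. = FALSE)
  if (ncol(P) != ncol(B)) stop("presence/background dimension mismatch",
                               call. = FALSE)
  knots <- NULL
  if (n_hinge > 0L) {
    qs <- seq_len(n_hinge) / (n_hinge + 1)
    knots <- apply(B, 2L, quantile, probs = qs, names = FALSE)
    knots <- matrix(knots, nrow = n_hinge)
  }
  raw_features <- function(X) {
    out <- cbind(X, X^2)
    colnames(out) <- c(paste0("l_", seq_len(ncol(X))),
                       paste0("q_", seq_len(ncol(X))))
    if (!is.null(knots)) {
      h <- do.call(cbind, lapply(seq_len(ncol(X)), function(j) {
        hj <- vapply(seq_len(nrow(knots)),
                     function(i) pmax(X[, j] - knots[i, j], 0),
                     numeric(nrow(X)))
        colnames(hj) <- paste0("h_", j, "_", seq_len(nrow(knots)))
        hj
      }))
      out <- cbind(out, h)
    }
    out
  }
  Fb <- raw_features(B)
  ctr <- colMeans(Fb)
  scl <- apply(Fb, 2L, sd)
  keep <- scl > 0
  if (!all(keep))
    warning("dropping zero-background-variance feature(s): ",
            paste(colnames(Fb)[!keep], collapse = ", "), call. = FALSE)
  if (sum(keep) < 1L) stop("no informative features", call. = FALSE)
  featurize <- function(X) {
    Fx <- raw_features(X)[, keep, drop = FALSE]
    sweep(sweep(Fx, 2L, ctr[keep]), 2L, scl[keep], "/")
  }
  Xtr <- rbind(featurize(P), featurize(B))
  y <- c(rep(1L, nrow(P)), rep(0L, nrow(B)))
  # fit along a decreasing path ending at the target penalty; warm starts
  # keep the coordinate-descent solver stable at small lambda
  fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                        lambda = regularization * c(1000, 100, 10, 1),
                        standardize = FALSE)
  new_sdm("LQ_BG",
          list(fit = fit, featurize = featurize, lambda = regularization),
          predictor_set,
          meta = list(n_presence = nrow(P), n_background = nrow(B),
                      n_features = sum(keep), n_hinge = n_hinge))
}

# ---------------------------------------------------------------------------
# Radial-kernel background classifier (SVM-class stand-in)

#' Fit the radial-kernel background classifier
#'
#' A C-classification support vector machine with a radial basis kernel
#' (via kernlab), presence vs background, with class weights inversely
#' proportional to class sizes. The continuous decision value (oriented so
#' larger = more presence-like) is the suitability score; [predict_surface()]
#' rescales it to `[0, 1]` by min-max over the prediction extent. To keep the
#' quadratic-programming fit tractable the background is subsampled to
#' `max_background` rows (the incoming background sample is already in
#' random order, so the head of it is itself a uniform subsample).
#'
#' @param presence_env Presence matrix (>= 5 rows).
#' @param background_env Background matrix (>= 50 rows).
#' @param C Soft-margin cost (default 1).
#' @param sigma Radial kernel inverse width; default `1/V`.
#' @param max_background Background rows used in the fit (default 1000).
#' @param predictor_set Label carried on the fitted object.
#' @return A `vs_sdm` object (`algorithm_id = "KERNEL_BG"`).
#' @export
fit_kernel_background <- function(presence_env, background_env, C = 1,
                                  sigma = NULL, max_background = 1000L,
                                  predictor_set = "RAW") {
  P <- as_env_matrix(presence_env)
  B <- as_env_matrix(background_env)
  if (nrow(P) < 5L) stop("need >= 5 presences", call. = FALSE)
  if (nrow(B) < 50L) stop("need >= 50 background rows", call. = FALSE)
  if (ncol(P) != ncol(B)) stop("presence/background dimension mismatch",
                               call. = FALSE)
  if (nrow(B) > max_background) B <- B[seq_len(max_background), , drop = FALSE]
  if (is.null(sigma)) sigma <- 1 / ncol(P)
  X <- rbind(P, B)
  y <- factor(c(rep("pres", nrow(P)), rep("bg", nrow(B))),
              levels = c("pres", "bg"))
  w <- c(pres = nrow(B) / nrow(P), bg = 1)
  fit <- kernlab::ksvm(X, y, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = sigma), C = C,
                       class.weights = w, scaled = TRUE)
  # orient the decision value: larger = more presence-like
  dec <- kernlab::predict(fit, X, type = "decision")[, 1L]
  flip <- mean(dec[y == "pres"]) < mean(dec[y == "bg"])
  new_sdm("KERNEL_BG", list(fit = fit, flip = flip, sigma = sigma, C = C),
          predictor_set,
          meta = list(n_presence = nrow(P), n_background = nrow(B)))
}

# ---------------------------------------------------------------------------
# Common interface

#' Fit an SDM by algorithm id
#'
#' Dispatches to the four algorithm implementations behind one contract:
#' `"ES"` (Envelope Score) and `"MAHAL"` (Mahalanobis distance) are
#' presence-only; `"LQ_BG"` and `"KERNEL_BG"` additionally require
#' background data.
#'
#' @param presence_env Presence environmental matrix.
#' @param algorithm One of `"ES"`, `"MAHAL"`, `"LQ_BG"`, `"KERNEL_BG"`.
#' @param background_env Background matrix (required for the `_BG`
#'   algorithms).
#' @param predictor_set Label (e.g. `"RAW"`, `"PCA4"`, `"PCA6"`).
#' @param ... Passed to the specific fitter.
#' @return A `vs_sdm` object.
#' @export
fit_sdm <- function(presence_env, algorithm = ALGORITHMS,
                    background_env = NULL, predictor_set = "RAW", ...) {
  algorithm <- match.arg(algorithm)
  P <- as_env_matrix(presence_env)
  if (algorithm %in% c("LQ_BG", "KERNEL_BG") && is.null(background_env))
    stop(algorithm, " requires background data", call. = FALSE)
  switch(algorithm,
    ES = new_sdm("ES", fit_envelope(P), predictor_set,
                 meta = list(n_presence = nrow(P))),
    MAHAL = new_sdm("MAHAL", fit_mahalanobis(P, ...), predictor_set,
                    meta = list(n_presence = nrow(P))),
    LQ_BG = fit_lq_background(P, background_env,
                              predictor_set = predictor_set, ...),
    KERNEL_BG = fit_kernel_background(P, background_env,
                                      predictor_set = predictor_set, ...)
  )
}

#' Predict suitability scores for environmental data
#'
#' @param object A `vs_sdm` object.
#' @param newdata Environmental matrix (n x V).
#' @param ... Unused.
#' @return Numeric scores; `[0, 1]` for ES, MAHAL and LQ_BG, raw oriented
#'   decision values for KERNEL_BG (rescaled per-surface by
#'   [predict_surface()]).
#' @export
predict.vs_sdm <- function(object, newdata, ...) {
  X <- as_env_matrix(newdata)
  switch(object$algorithm_id,
    ES = predict_envelope(object$model, X),
    MAHAL = predict_mahalanobis(object$model, X),
    LQ_BG = as.vector(predict(object$model$fit, object$model$featurize(X),
                              s = object$model$lambda, type = "response")),
    KERNEL_BG = {
      dec <- kernlab::predict(object$model$fit, X, type = "decision")[, 1L]
      if (object$model$flip) -dec else dec
    },
    stop("unknown algorithm ", object$algorithm_id, call. = FALSE)
  )
}

#' Predict a suitability surface over a stack
#'
#' Evaluates the fitted model on every masked cell; masked-out cells stay
#' nodata. For the kernel classifier the oriented decision values are
#' min-max rescaled to `[0, 1]` over the prediction extent.
#'
#' @param model A `vs_sdm` object.
#' @param stack A [vs_stack()] whose layers match the model's predictor set.
#' @return A [vs_layer()] of suitability scores.
#' @export
predict_surface <- function(model, stack) {
  stopifnot(inherits(model, "vs_sdm"), inherits(stack, "vs_stack"))
  idx <- which(as.vector(stack$mask))
  sc <- predict(model, stack$values[idx, , drop = FALSE])
  if (model$algorithm_id == "KERNEL_BG") {
    rng <- range(sc)
    sc <- if (rng[2] > rng[1]) (sc - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, length(sc))
  }
  v <- rep(NA_real_, n_cells(stack$grid))
  v[idx] <- sc
  vs_layer(stack$grid, matrix(v, stack$grid$nrows, stack$grid$ncols),
           stack$mask)
}
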