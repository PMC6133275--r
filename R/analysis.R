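# Statistical analyses of the factorial evaluation table: the three-factor
# ANCOVA with prevalence as covariate, the TSS-variance stability summary,
# the predicted-vs-real range-size regressions, and per-species residual
# ("idiosyncrasy") summaries.

eval_table_factors <- function(table, rule) {
  d <- dplyr::filter(table, .data$threshold_rule == rule)
  if (nrow(d) == 0L)
    stop("no rows for threshold rule '", rule, "'", call. = FALSE)
  d$ENV <- factor(d$predictor_set)
  d$ALG <- factor(d$algorithm)
  d$TOL <- factor(d$tolerance_class)
  d
}

#' Three-factor ANCOVA with prevalence covariate
#'
#' Fits `response ~ prevalence + ENV * ALG * TOL` (predictor set, algorithm,
#' tolerance class; all factors sum-to-zero coded) on one threshold rule of
#' the evaluation table and summarises it with Type-II sums of squares,
#' which are robust to the mild imbalance left by excluded design cells.
#' Rows with a missing response (metrics whose denominator vanished) are
#' dropped with their count recorded.
#'
#' @param table A [run_experiment()] result.
#' @param response `"TSS"`, `"OP"` or `"UP"`.
#' @param rule Threshold rule to analyse (default `"balance"`).
#' @param ss_type Sum-of-squares type, `2` (default), `1` or `3`.
#' @return An object of class `vs_ancova`: the term table (`tidy()`), the
#'   underlying `lm` fit (`$fit`), the analysed data (`$data`), and the
#'   partial eta-squared of prevalence (`glance()`).
#' @export
ancova <- function(table, response = c("TSS", "OP", "UP"),
                   rule = "balance", ss_type = 2) {
  response <- match.arg(response)
  d <- eval_table_factors(table, rule)
  for (f in c("ENV", "ALG", "TOL")) {
    if (nlevels(d[[f]]) < 2L && f != "TOL")
      stop("factor ", f, " has a single level", call. = FALSE)
  }
  cells <- with(d, table(ENV, ALG, TOL))
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(apply(empty, 1L, function(i)
           paste(dimnames(cells)[[1]][i[1]], dimnames(cells)[[2]][i[2]],
                 dimnames(cells)[[3]][i[3]], sep = ":")), collapse = "; "),
         call. = FALSE)
  }
  d$.y <- d[[response]]
  n_missing <- sum(!complete.cases(d[, c(".y", "prevalence")]))
  d <- d[complete.cases(d[, c(".y", "prevalence")]), ]
  has_tol <- nlevels(droplevels(d$TOL)) > 1L
  form <- if (has_tol) .y ~ prevalence + ENV * ALG * TOL
          else .y ~ prevalence + ENV * ALG
  contr <- list(ENV = contr.sum, ALG = contr.sum)
  if (has_tol) contr$TOL <- contr.sum
  fit <- lm(form, data = d, contrasts = contr)
  an <- switch(as.character(ss_type),
               "1" = {
                 a <- stats::anova(fit)
                 data.frame(term = rownames(a), df = a$Df,
                            sumsq = a$`Sum Sq`, F = a$`F value`,
                            p = a$`Pr(>F)`)
               },
               "2" = ,
               "3" = {
                 a <- car::Anova(fit, type = as.numeric(ss_type))
                 data.frame(term = rownames(a), df = a$Df,
                            sumsq = a$`Sum Sq`, F = a$`F value`,
                            p = a$`Pr(>F)`)
               },
               stop("unsupported ss_type ", ss_type, call. = FALSE))
  resid_row <- an$term %in% c("Residuals", "Residual")
  ss_err <- an$sumsq[resid_row]
  ss_prev <- an$sumsq[an$term == "prevalence"]
  terms_tbl <- tibble::tibble(
    term = sub("^prevalence$", "Prevalence", an$term),
    df = as.integer(round(an$df)), sumsq = an$sumsq,
    statistic = an$F, p.value = an$p)
  terms_tbl$term[resid_row] <- "Error"
  structure(
    list(response = response, rule = rule, ss_type = ss_type,
         terms = terms_tbl, fit = fit, data = d,
         n_missing = n_missing,
         prevalence_eta2 = as.numeric(ss_prev / (ss_prev + ss_err))),
    class = "vs_ancova"
  )
}

#' @export
print.vs_ancova <- function(x, ...) {
  cat(sprintf("<vs_ancova> %s (%s threshold), type-%s SS\n",
              x$response, x$rule, x$ss_type))
  print(as.data.frame(x$terms), digits = 3)
  cat(sprintf("prevalence partial eta^2 = %.3f; %d rows with missing response dropped\n",
              x$prevalence_eta2, x$n_missing))
  invisible(x)
}

#' @describeIn ancova Term table: term, df, sum of squares, F, p.
#' @param x A `vs_ancova` object.
#' @param ... Unused.
#' @method tidy vs_ancova
#' @export
tidy.vs_ancova <- function(x, ...) x$terms

#' @describeIn ancova One-row model summary (n, error df, R-squared,
#'   prevalence partial eta-squared).
#' @method glance vs_ancova
#' @export
glance.vs_ancova <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    rule = x$rule,
    n = nrow(x$data),
    error_df = x$terms$df[x$terms$term == "Error"],
    r.squared = summary(x$fit)$r.squared,
    prevalence_eta2 = x$prevalence_eta2,
    n_missing = x$n_missing
  )
}

#' Model stability: variance of TSS across occurrence replicates
#'
#' For every species x algorithm x predictor set, the sample variance of TSS
#' across the occurrence replicates measures how strongly the fitted model
#' depends on which points were sampled. These variances are then averaged
#' over species within each algorithm x predictor set, with a t-based 95%
#' confidence interval across species.
#'
#' @param table A [run_experiment()] result.
#' @param rule Threshold rule (default `"balance"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `vs_stability`: `algorithm`, `predictor_set`,
#'   `mean_variance`, `ci_lower`, `ci_upper`, `n_species`; the per-species
#'   variances are in the `per_species` attribute.
#' @export
tss_stability <- function(table, rule = "balance", conf_level = 0.95) {
  d <- eval_table_factors(table, rule)
  reps <- dplyr::summarise(
    dplyr::group_by(d, .data$species_id, .data$algorithm,
                    .data$predictor_set),
    n_rep = dplyr::n(), .groups = "drop")
  if (any(reps$n_rep < 2L))
    stop("tss_stability needs >= 2 replicates per species x algorithm x predictor set",
         call. = FALSE)
  per_species <- dplyr::summarise(
    dplyr::group_by(d, .data$species_id, .data$tolerance_class,
                    .data$algorithm, .data$predictor_set),
    tss_variance = var(.data$TSS), .groups = "drop")
  alpha <- 1 - conf_level
  out <- dplyr::summarise(
    dplyr::group_by(per_species, .data$algorithm, .data$predictor_set),
    mean_variance = mean(.data$tss_variance),
    se = sd(.data$tss_variance) / sqrt(dplyr::n()),
    n_species = dplyr::n(),
    .groups = "drop")
  tcrit <- ifelse(out$n_species > 1, qt(1 - alpha / 2, out$n_species - 1), 0)
  out$ci_lower <- out$mean_variance - tcrit * out$se
  out$ci_upper <- out$mean_variance + tcrit * out$se
  out$se <- NULL
  attr(out, "per_species") <- per_species
  class(out) <- c("vs_stability", class(out))
  out
}

#' Predicted-vs-real range size regression
#'
#' For each algorithm x predictor set x threshold rule, an ordinary
#' least-squares regression of predicted range size (cells above threshold)
#' on true range size, pooled over species and replicates. High R-squared
#' with intercept near 0 and slope near 1 marks a model usable for absolute
#' range-size estimation; high R-squared alone still supports relative
#' comparisons.
#'
#' @param table A [run_experiment()] result.
#' @param min_distinct Minimum number of distinct true range sizes a group
#'   needs to be fitted (default 3); degenerate groups are skipped with a
#'   reason in the `skipped` attribute.
#' @return A tibble of class `vs_range_fit`: `algorithm`, `predictor_set`,
#'   `threshold_rule`, `intercept`, `slope`, `r_squared`, `n`; the pooled
#'   data are carried in the `data` attribute for plotting.
#' @export
range_size_regression <- function(table, min_distinct = 3L) {
  groups <- dplyr::group_split(
    dplyr::group_by(table, .data$algorithm, .data$predictor_set,
                    .data$threshold_rule))
  skipped <- character(0)
  rows <- lapply(groups, function(g) {
    lab <- sprintf("%s/%s/%s", g$algorithm[[1L]], g$predictor_set[[1L]],
                   g$threshold_rule[[1L]])
    g <- g[complete.cases(g[, c("real_range", "predicted_range")]), ]
    if (length(unique(g$real_range)) < min_distinct) {
      skipped <<- c(skipped, sprintf(
        "%s: only %d distinct real range sizes", lab,
        length(unique(g$real_range))))
      return(NULL)
    }
    f <- lm(predicted_range ~ real_range, data = g)
    tibble::tibble(
      algorithm = g$algorithm[[1L]], predictor_set = g$predictor_set[[1L]],
      threshold_rule = g$threshold_rule[[1L]],
      intercept = coef(f)[[1L]], slope = coef(f)[[2L]],
      r_squared = summary(f)$r.squared, n = nrow(g))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "data") <- table[, c("algorithm", "predictor_set",
                                 "threshold_rule", "species_id",
                                 "replicate", "real_range",
                                 "predicted_range")]
  class(out) <- c("vs_range_fit", class(out))
  out
}

#' Per-species residual summary of an ANCOVA ("idiosyncrasy")
#'
#' Groups the ANCOVA residuals by species x algorithm and reports their mean
#' with a t-based confidence interval: species whose intervals sit away from
#' zero are systematically easier or harder to model than the factorial
#' structure predicts.
#'
#' @param fit A [ancova()] result.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `vs_residuals`: `species_id`,
#'   `tolerance_class`, `algorithm`, `mean_residual`, `ci_lower`,
#'   `ci_upper`, `n`.
#' @export
species_residual_summary <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "vs_ancova"))
  d <- fit$data
  d$.resid <- resid(fit$fit)
  alpha <- 1 - conf_level
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$species_id, .data$tolerance_class,
                    .data$algorithm),
    mean_residual = mean(.data$.resid),
    se = sd(.data$.resid) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  tcrit <- ifelse(out$n > 1, qt(1 - alpha / 2, out$n - 1), 0)
  out$ci_lower <- out$mean_residual - tcrit * out$se
  out$ci_upper <- out$mean_residual + tcrit * out$se
  out$se <- NULL
  class(out) <- c("vs_residuals", class(out))
  out
}
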