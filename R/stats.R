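#' Two-factor ANOVA on experiment summaries
#'
#' Fits `response ~ A * B` by least squares and tests both main effects
#' and the interaction.  Type II sums of squares are used, which handle
#' the unbalanced culture counts of a typical recruitment design (e.g.
#' 10/10/5/5) and reduce to the classical decomposition when the design
#' is balanced.  Normality of the residuals is screened with a
#' Shapiro-Wilk test and reported as a diagnostic only.
#'
#' @param data A data frame (e.g. an [summarize_experiment_set()]
#'   table).
#' @param response,factor_a,factor_b Column names (strings).
#' @return An object of class `spike_anova`; use [tidy()] for the
#'   per-effect F table and [glance()] for fit-level diagnostics.
#' @examples
#' d <- expand.grid(g = c("wt", "ko"), w = c("basal", "fourap"),
#'                  rep = 1:2)
#' d$y <- c(1, 5, 3, 7, 2, 6, 4, 8)
#' tidy(two_way_anova(d, "y", "g", "w"))
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  data <- as.data.frame(data)
  for (v in c(response, factor_a, factor_b)) {
    if (!v %in% names(data)) abort(sprintf("column '%s' not found.", v))
  }
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  if (nlevels(data[[factor_a]]) < 2 || nlevels(data[[factor_b]]) < 2) {
    abort("each factor needs at least 2 levels.")
  }
  cells <- table(data[[factor_a]], data[[factor_b]])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s x %s.",
                  rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  fml <- stats::reformulate(sprintf("%s * %s", factor_a, factor_b),
                            response = response)
  fit <- lm(fml, data = data)
  if (sd(data[[response]]) == 0) {
    # all responses identical: every effect is exactly null
    effects <- tibble(
      effect = c(factor_a, factor_b, "interaction"),
      sum_sq = 0, df = NA_integer_, df_resid = NA_integer_,
      statistic = 0, p.value = 1
    )
    return(structure(
      list(effects = effects, fit = fit, data = data, response = response,
           factor_a = factor_a, factor_b = factor_b, ms_resid = 0,
           df_resid = stats::df.residual(fit), shapiro_p = NA_real_),
      class = "spike_anova"
    ))
  }
  av <- car::Anova(fit, type = 2)
  resid_row <- nrow(av)
  df_resid <- av$Df[resid_row]
  ms_resid <- av$`Sum Sq`[resid_row] / df_resid
  effects <- tibble(
    effect = c(factor_a, factor_b, "interaction"),
    sum_sq = av$`Sum Sq`[1:3],
    df = as.integer(av$Df[1:3]),
    df_resid = as.integer(df_resid),
    statistic = av$`F value`[1:3],
    p.value = av$`Pr(>F)`[1:3]
  )
  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  structure(
    list(effects = effects, fit = fit, data = data,
         response = response, factor_a = factor_a, factor_b = factor_b,
         ms_resid = ms_resid, df_resid = df_resid, shapiro_p = shapiro_p),
    class = "spike_anova"
  )
}

#' @export
print.spike_anova <- function(x, ...) {
  cat(sprintf("<spike_anova> %s ~ %s * %s (Type II)\n",
              x$response, x$factor_a, x$factor_b))
  print(x$effects)
  invisible(x)
}

#' @rdname two_way_anova
#' @param x A `spike_anova` object.
#' @param ... Unused.
#' @export
tidy.spike_anova <- function(x, ...) x$effects

#' @rdname two_way_anova
#' @export
glance.spike_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$df_resid,
    shapiro_p = x$shapiro_p,
    nobs = nrow(x$data)
  )
}

#' Bonferroni post hoc comparisons after a two-factor ANOVA
#'
#' Pairwise two-sample t statistics between design cells using the
#' pooled ANOVA error term (residual mean square and residual degrees
#' of freedom); raw p values are multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param anova A [two_way_anova()] result.
#' @param comparisons List of length-2 character vectors naming cells
#'   as `"levelA:levelB"`; default all pairwise cell comparisons.
#' @return A tibble `cell_1, cell_2, estimate, statistic, df, p.value,
#'   adj.p.value`.
#' @export
bonferroni_posthoc <- function(anova, comparisons = NULL) {
  stopifnot(inherits(anova, "spike_anova"))
  d <- anova$data
  cell <- interaction(d[[anova$factor_a]], d[[anova$factor_b]], sep = ":")
  means <- tapply(d[[anova$response]], cell, mean)
  ns <- tapply(d[[anova$response]], cell, length)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(means), 2, simplify = FALSE)
  }
  unknown <- setdiff(unlist(comparisons), names(means))
  if (length(unknown) > 0) {
    abort(sprintf("unknown cell(s): %s", paste(unknown, collapse = ", ")))
  }
  m <- length(comparisons)
  purrr::map_dfr(comparisons, function(cmp) {
    est <- means[[cmp[1]]] - means[[cmp[2]]]
    se <- sqrt(anova$ms_resid * (1 / ns[[cmp[1]]] + 1 / ns[[cmp[2]]]))
    tt <- est / se
    p <- 2 * pt(-abs(tt), anova$df_resid)
    tibble(cell_1 = cmp[1], cell_2 = cmp[2], estimate = est,
           statistic = tt, df = anova$df_resid, p.value = p,
           adj.p.value = pmin(1, m * p))
  })
}

#' Percentage from event counts
#'
#' @param events,total Nonnegative counts, `events <= total`,
#'   `total > 0`.
#' @param digits Decimal places to round the percentage to (default 1,
#'   the convention for printed incidence percentages).
#' @return `100 * events / total`, rounded.
#' @examples
#' proportion_from_counts(8, 18)  # 44.4
#' @export
proportion_from_counts <- function(events, total, digits = 1) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(events < 0 | events > total)) {
    abort("`events` must lie in [0, total].")
  }
  round(100 * events / total, digits)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' \eqn{\sum (O - E)^2 / E} with 1 degree of freedom, with optional
#' Yates continuity correction — the incidence comparison used for
#' seizure-occurrence counts.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return A tibble `statistic, df, p.value, yates`.
#' @examples
#' pearson_chi2_2x2(matrix(c(8, 8, 10, 13), 2))
#' @export
pearson_chi2_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort("`counts` must be 2x2.")
  if (any(counts < 0) || sum(counts) == 0) abort("invalid counts.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("degenerate table: a zero marginal leaves expected counts 0.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = yates))
  tibble(statistic = unname(ct$statistic), df = 1L,
         p.value = ct$p.value, yates = yates)
}
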