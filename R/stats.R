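## Three-group comparisons with Bonferroni-corrected pairwise contrasts, and
## the regression-coefficient correlation screen.

#' Compare a metric across the three cohort groups
#'
#' Measurements are replicated in both eyes of each patient. The default
#' `clustering = "patient_mean"` collapses fellow eyes to the patient mean
#' and runs a one-way ANOVA with patients as units (conservative, correct
#' type-I error under within-patient correlation); `"naive"` uses eyes as
#' units. Pairwise group contrasts are pooled-variance two-sample t-tests
#' with Bonferroni adjustment (raw p times the number of pairs, capped at 1).
#'
#' @param data Data.frame with columns `patient_id`, `eye_id`, `group` and
#'   the metric named by `value`.
#' @param value Name of the metric column (default `"value"`).
#' @param clustering `"patient_mean"` (default) or `"naive"`.
#' @return Object of class `group_comparison`: `metric`, `groups` (per-group
#'   n/mean/sd), `omnibus_p`, `pairwise` (pair, p_raw, p_adj), `clustering`.
#' @export
compare_groups <- function(data, value = "value",
                           clustering = c("patient_mean", "naive")) {
  clustering <- match.arg(clustering)
  rq_assert(all(c("patient_id", "group", value) %in% names(data)),
            sprintf("need columns patient_id, group, %s", value))
  d <- data.frame(patient_id = data$patient_id,
                  group = as.character(data$group), y = data[[value]])
  d <- d[is.finite(d$y), ]
  if (clustering == "patient_mean") {
    d <- stats::aggregate(y ~ patient_id + group, data = d, FUN = mean)
  }
  groups <- sort(unique(d$group))
  rq_assert(length(groups) >= 2, "need at least 2 groups")
  ns <- table(d$group)
  if (any(ns < 2))
    rq_stop(sprintf("group '%s' has < 2 units", names(ns)[ns < 2][1]),
            "rq_degenerate_error")
  d$group <- factor(d$group, levels = groups)
  fit <- stats::aov(y ~ group, data = d)
  omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    p <- tryCatch(
      stats::t.test(d$y[d$group == pr[1]], d$y[d$group == pr[2]],
                    var.equal = TRUE)$p.value,
      error = function(e) NA_real_)  # degenerate (constant) data
    data.frame(pair = paste(pr[2], "vs", pr[1]), p_raw = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE)
  }))
  gs <- do.call(rbind, lapply(groups, function(g) {
    v <- d$y[d$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  structure(list(metric = value, groups = gs, omnibus_p = omnibus_p,
                 pairwise = pw, clustering = clustering),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s units): omnibus p = %.4g\n",
              x$metric, x$clustering, x$omnibus_p))
  print(x$groups, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Regression-coefficient correlation screen
#'
#' Ordinary least-squares regression of `y` on `x`; the slope's Student-t
#' statistic (n - 2 degrees of freedom) tests whether the two metrics
#' co-vary.
#'
#' @param x,y Paired numeric vectors, n >= 3 after dropping non-finite pairs.
#' @param x_name,y_name Labels carried into the result.
#' @return Object of class `correlation_result`: `slope`, `t`, `p`, `n`.
#' @export
correlate <- function(x, y, x_name = deparse(substitute(x)),
                      y_name = deparse(substitute(y))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  rq_assert(length(x) >= 3, "need at least 3 paired finite values")
  if (stats::var(x) == 0)
    rq_stop("zero variance in x: regression undefined", "rq_degenerate_error")
  n <- length(x)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(list(x = x_name, y = y_name, slope = sm["x", "Estimate"],
                 t = sm["x", "t value"], p = sm["x", "Pr(>|t|)"], n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: slope %.4g, t = %.3f, p = %.4g (n = %d)\n",
              x$y, x$x, x$slope, x$t, x$p, x$n))
  invisible(x)
}
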