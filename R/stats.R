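#' Group summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), n, plus median and
#' range -- the descriptive form in which every measured parameter is
#' reported per group.
#'
#' @param values Numeric vector of at least 2 values.
#' @param label Group label (e.g. `"CD"`, `"CTR"`).
#' @param parameter Name of the measured parameter.
#' @return An object of class `group_summary`.
#' @examples
#' summarize(c(1, 2, 3), label = "CTR", parameter = "area")
#' @export
summarize <- function(values, label = "", parameter = "") {
  if (length(values) < 2L)
    stop("parameter error: at least 2 values are required")
  if (anyNA(values)) stop("values must not contain NA")
  structure(list(parameter = parameter, label = label,
                 n = length(values), mean = mean(values),
                 sd = stats::sd(values), median = stats::median(values),
                 min = min(values), max = max(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s %s: %.4g +/- %.4g (n = %d), median %.4g, range %.4g-%.4g\n",
              x$parameter, x$label, x$mean, x$sd, x$n, x$median,
              x$min, x$max))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: between/within mean-square F with
#' (k - 1, N - k) degrees of freedom and a p-value from the F distribution
#' (via [stats::oneway.test()] with equal variances). For two groups, F
#' equals the square of the pooled-variance t statistic. Significance is
#' called at p < 0.05.
#'
#' @param groups List of at least two numeric vectors, each with at least
#'   two values.
#' @param parameter Optional parameter name carried into the result.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `comparison_result` with `F`, `df1`, `df2`,
#'   `p` and `significant`. When every value in every group is identical
#'   the comparison is defined as F = 0, p = 1.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
anova_oneway <- function(groups, parameter = "", alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("parameter error: at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("parameter error: every group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  N <- length(values)
  if (all(values == values[1L])) {
    f <- 0; p <- 1
  } else {
    g <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))
    within_var <- vapply(groups, stats::var, numeric(1))
    if (all(within_var == 0)) {
      # distinct group means with zero within-group variance
      f <- Inf; p <- 0
    } else {
      ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
      f <- unname(ow$statistic)
      p <- unname(ow$p.value)
    }
  }
  structure(list(parameter = parameter, F = f, df1 = k - 1L, df2 = N - k,
                 p = p, significant = p < alpha, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$parameter, x$df1, x$df2, x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Rejection-rate simulation for a two-group comparison
#'
#' Repeatedly draws two groups from truncated normal laws (via
#' [sample_group_measurements()]), compares them with [anova_oneway()],
#' and reports the fraction of replicates rejecting at `alpha` and the
#' median p-value. Used to check which printed group parameters yield the
#' reported significance bounds.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group distribution parameters (sds > 0).
#' @param n Per-group sample size (>= 2).
#' @param reps Number of replicates (>= 100).
#' @param alpha Significance level.
#' @param lower_bound,upper_bound Truncation bounds shared by both groups.
#' @param seed Integer seed for reproducibility.
#' @return A list with `rejection_rate`, `median_p`, `reps`.
#' @examples
#' power_simulation(0.20, 0.06, 0.60, 0.11, n = 12, reps = 200,
#'                  lower_bound = 0, upper_bound = 1, seed = 1)
#' @export
power_simulation <- function(mean_a, sd_a, mean_b, sd_b, n, reps = 1000L,
                             alpha = 0.05, lower_bound = -Inf,
                             upper_bound = Inf, seed = NULL) {
  if (sd_a <= 0 || sd_b <= 0) stop("parameter error: sds must be positive")
  if (n < 2) stop("parameter error: n must be >= 2")
  if (reps < 100) stop("parameter error: reps must be >= 100")
  with_seed(seed, {
    p <- vapply(seq_len(reps), function(r) {
      a <- sample_group_measurements(mean_a, sd_a, n, lower_bound,
                                     upper_bound)
      b <- sample_group_measurements(mean_b, sd_b, n, lower_bound,
                                     upper_bound)
      anova_oneway(list(a, b), alpha = alpha)$p
    }, numeric(1))
    list(rejection_rate = mean(p < alpha), median_p = stats::median(p),
         reps = reps)
  })
}

#' Normalize medium transglutaminase activity to cell number
#'
#' Blank-corrected optical density at 450 nm scaled per 10^4 cells, the
#' form in which enzyme activity in the culture medium is compared between
#' groups.
#'
#' @param od_450 Measured optical density.
#' @param blank_od Blank optical density (default 0).
#' @param cell_count Number of cells in the well (> 0).
#' @param per_cells Reporting denominator (default 1e4 cells).
#' @return Normalized activity (OD per `per_cells` cells). An OD below the
#'   blank is clamped to zero with a warning.
#' @examples
#' tg_normalize(0.4, 0, 20000)
#' @export
tg_normalize <- function(od_450, blank_od = 0, cell_count, per_cells = 1e4) {
  if (any(cell_count <= 0))
    stop("parameter error: cell_count must be positive")
  if (any(blank_od < 0)) stop("parameter error: blank_od must be >= 0")
  net <- od_450 - blank_od
  if (any(net < 0)) {
    warning("optical density below blank; clamped to 0")
    net[net < 0] <- 0
  }
  net / cell_count * per_cells
}

#' Fold change between two group means
#'
#' @param a,b [summarize()] results or plain numeric means; `b` is the
#'   reference (denominator).
#' @return `mean(a) / mean(b)`.
#' @examples
#' fold_change(0.4, 0.2)
#' @export
fold_change <- function(a, b) {
  ma <- if (inherits(a, "group_summary")) a$mean else a
  mb <- if (inherits(b, "group_summary")) b$mean else b
  if (!is.finite(mb) || mb <= 0)
    stop("parameter error: reference mean must be positive")
  ma / mb
}
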