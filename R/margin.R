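# Fixed-margin (95-95) non-inferiority margin construction. Historical
# placebo-controlled trials of the active control are pooled with a
# random-effects meta-analysis; the CI bound of the pooled control-vs-placebo
# difference closest to zero effect gives a conservative estimate of the
# control's effect, and the margin preserves a stated fraction f of it.
#
# Geometry (lower-is-better endpoints, effects negative):
#   A  placebo mean
#   B  = A + conservative bound of pooled (control - placebo) difference
#   C  active-control mean
#   D  = B - f*(B - C); margin = D - C = (1 - f)*(B - C)

#' Read historical study summaries from CSV
#'
#' Expects columns `study_id`, `effect` (mean difference, active control
#' minus placebo, negative = improvement for lower-is-better endpoints) and
#' `se` (its standard error).
#'
#' @param path CSV file path.
#' @return A data frame of study summaries.
#' @export
read_studies <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "effect", "se")
  if (!all(need %in% names(d))) {
    stop("studies CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(d$effect)) || any(!is.finite(d$se)) || any(d$se <= 0)) {
    stop("effects must be finite and standard errors strictly positive")
  }
  d
}

#' Random-effects (DerSimonian-Laird) pooling of study effects
#'
#' Pools per-study effect estimates with the DerSimonian-Laird moment
#' estimator of the between-study variance tau^2 and a normal-approximation
#' confidence interval on the pooled mean.
#'
#' @param studies data frame with columns `effect` and `se` (and optionally
#'   `study_id`), as from [read_studies()].
#' @param level two-sided confidence level for the pooled CI (default 0.95).
#' @return A `pooled_effect`: list with `estimate`, `se`, `tau2`, `ci_lower`,
#'   `ci_upper`, `k`, `level`, and `single_study` (TRUE when k = 1, where
#'   tau^2 is fixed at 0).
#' @examples
#' pool_random_effects(data.frame(effect = c(-1, -2, -3), se = 0.3))
#' @export
pool_random_effects <- function(studies, level = 0.95) {
  if (!nrow(studies)) stop("need at least one study")
  single <- nrow(studies) == 1L
  if (single) warning("single study: between-study variance fixed at 0")
  fit <- metafor::rma(yi = studies$effect, sei = studies$se,
                      method = "DL", test = "z", level = 100 * level)
  structure(list(estimate = as.numeric(fit$beta), se = fit$se,
                 tau2 = fit$tau2, ci_lower = fit$ci.lb, ci_upper = fit$ci.ub,
                 k = fit$k, level = level, single_study = single),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Random-effects pooled difference over %d studies\n", x$k))
  cat(sprintf("  estimate %.4f (SE %.4f), tau^2 = %.4f\n", x$estimate, x$se, x$tau2))
  cat(sprintf("  %.0f%% CI: %.4f to %.4f\n", 100 * x$level, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Fixed-margin non-inferiority margin preserving a fraction of effect
#'
#' From the pooled control-vs-placebo difference, takes the CI bound closest
#' to zero effect (the conservative estimate of the control's effect), places
#' it at `B = placebo_mean + bound`, and selects the margin point
#' `D = B - f*(B - C)` where `C = control_mean` and `f` is the fraction of
#' the (conservatively estimated) control effect to preserve. The margin is
#' `D - C = (1 - f)*(B - C)`: the allowed excess of test drug over control,
#' positive when lower values are better.
#'
#' @param pooled a `pooled_effect` for (active control - placebo).
#' @param placebo_mean,control_mean historical means (points A and C).
#' @param preserved_fraction f in \[0, 1\]; f = 1 gives margin 0 (pure
#'   superiority), f = 0 allows the whole conservatively-estimated effect.
#' @param lower_is_better TRUE when negative change means improvement (the
#'   pooled difference must then have its upper CI bound below 0).
#' @return A `margin_spec`: list with `A`, `B`, `C`, `D`, `f`, `margin`.
#' @export
compute_margin <- function(pooled, placebo_mean, control_mean,
                           preserved_fraction = 0.5, lower_is_better = TRUE) {
  f <- preserved_fraction
  stopifnot(f >= 0, f <= 1)
  bound <- if (lower_is_better) pooled$ci_upper else pooled$ci_lower
  if ((lower_is_better && bound >= 0) || (!lower_is_better && bound <= 0)) {
    stop("conservative CI bound does not show the control effective; ",
         "no non-inferiority margin can be justified")
  }
  A <- placebo_mean
  B <- A + bound
  C <- control_mean
  D <- B - f * (B - C)
  structure(list(A = A, B = B, C = C, D = D, f = f, margin = D - C,
                 lower_is_better = lower_is_better),
            class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  cat("Fixed-margin non-inferiority margin\n")
  cat(sprintf("  A (placebo mean)        %.4f\n", x$A))
  cat(sprintf("  B (conservative effect) %.4f\n", x$B))
  cat(sprintf("  C (control mean)        %.4f\n", x$C))
  cat(sprintf("  D (margin point)        %.4f  [f = %.2f preserved]\n", x$D, x$f))
  cat(sprintf("  margin (D - C)          %.4f\n", x$margin))
  invisible(x)
}

#' One-sided non-inferiority p-value
#'
#' Tests H0: (test - control) >= margin against the alternative that the
#' test drug is within the margin, using a normal approximation:
#' `p = pnorm((diff_estimate - margin) / diff_se)`. `p < level/2` exactly
#' when the upper `1 - level` two-sided CI limit of the difference lies
#' below the margin.
#'
#' @param diff_estimate estimated mean difference (test minus control).
#' @param diff_se its standard error (> 0).
#' @param margin non-inferiority margin (0 gives a superiority test).
#' @return p-value in \[0, 1\].
#' @export
ni_pvalue <- function(diff_estimate, diff_se, margin) {
  stopifnot(diff_se > 0)
  stats::pnorm((diff_estimate - margin) / diff_se)
}
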