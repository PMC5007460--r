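# Column sets of the model variants. The base determinant set holds the 19
# abiotic/biotic/anthropogenic covariates; the year term is always appended.
base_determinants <- c("T", "P", "TC", "PC", "pH", "N", "L", "THET", "TO_T",
                       "TO_W", "DC", "NC", "HP", "dHA", "LG", "C_W", "C_N",
                       "road_prox", "HPD")
extra_determinants <- c("TBUF", "SILVP", "DISTURB", "EXOT")

variant_spec <- function(variant, late_from) {
  switch(variant,
    PLS0 = list(cols = base_determinants, late = FALSE, disturbed = NA),
    PLS1 = list(cols = base_determinants, late = TRUE, disturbed = NA),
    PLS2 = list(cols = c(base_determinants, extra_determinants),
                late = TRUE, disturbed = NA),
    PLS3 = list(cols = base_determinants, late = TRUE, disturbed = TRUE),
    PLS4 = list(cols = base_determinants, late = TRUE, disturbed = FALSE),
    stop("unknown variant: ", variant)
  )
}

# Disturbance flag: presence of any of the silvicultural-practice,
# disturbance or exotic-tree indicators (either case convention).
disturbed_flag <- function(data) {
  flags <- intersect(c("SILVP", "DISTURB", "EXOT", "silvp", "disturb", "exot"),
                     names(data))
  if (!length(flags)) stop("no disturbance flag columns present")
  rowSums(as.matrix(data[flags])) > 0
}

#' Subset a survey table for a model variant
#'
#' Applies the variant's survey filter: the later-period restriction for
#' PLS1-PLS4 and the disturbed/undisturbed split for PLS3/PLS4 (disturbance =
#' presence of any of the silvicultural, disturbance or exotic flags).
#'
#' @param data survey table.
#' @param variant one of `"PLS0"`..`"PLS4"`.
#' @param late_from first year of the later period (default 1993).
#' @return The filtered data.frame.
#' @export
variant_surveys <- function(data, variant = "PLS0", late_from = 1993) {
  vs <- variant_spec(variant, late_from)
  keep <- rep(TRUE, nrow(data))
  if (vs$late) keep <- keep & data$year >= late_from
  if (!is.na(vs$disturbed)) keep <- keep & (disturbed_flag(data) == vs$disturbed)
  data[keep, , drop = FALSE]
}

#' Bootstrapped, spatially thinned, weighted PLS of the climatic debt
#'
#' The package's inference engine. For each of `n_draws` subsample draws it
#' (1) spatially thins the surveys to a minimum pairwise distance, (2) weights
#' observations by the inverse of their year's survey count, (3) centres and
#' reduces response and covariates under those weights, (4) extracts the full
#' set of weighted PLS components, (5) retains the components passing a
#' Bonferroni-corrected t-test of their slope on the response, and
#' (6) records the back-transformed standardized coefficients, the
#' R-squared and the per-variable variance shares. Draw summaries are means,
#' percentile 95 percent confidence intervals, and the bootstrap sign test.
#'
#' Model variants: `PLS0` fits the 19 standard determinants plus the year
#' term on all surveys; `PLS1` the same on the later period (from
#' `late_from`); `PLS2` adds the canopy-buffering and disturbance covariates;
#' `PLS3`/`PLS4` fit the standard set on the disturbed/undisturbed subsets.
#'
#' @param data per-survey table with columns `dT`, `x`, `y`, `year` and the
#'   variant's covariates.
#' @param variant `"PLS0"` (default) .. `"PLS4"`.
#' @param n_draws subsample draws (default 5000; tests and examples use
#'   fewer).
#' @param min_dist thinning distance, metres (default 10 km).
#' @param max_components components to extract; default the number of
#'   predictor columns including the year term.
#' @param alpha_components familywise level of the component t-tests before
#'   the Bonferroni division (default 0.05).
#' @param alpha_sign level of the coefficient sign test (default 0.01).
#' @param error_sd optional named vector of measurement-error standard
#'   deviations; when given, each draw perturbs the named covariate columns
#'   with centred Gaussian noise before standardization (the response is
#'   never perturbed), propagating measurement error into the coefficient
#'   distribution.
#' @param late_from first year of the later period used by PLS1-PLS4.
#' @param seed integer master seed; per-draw seeds are derived from it.
#' @return An object of class `debt_pls` with `print`, `summary`, `coef`,
#'   `confint` and `plot` methods. Per-draw records are kept in `$draws`.
#' @export
debt_pls <- function(data, variant = "PLS0", n_draws = 5000,
                     min_dist = 10000, max_components = NULL,
                     alpha_components = 0.05, alpha_sign = 0.01,
                     error_sd = NULL, late_from = 1993, seed = 1L) {
  vs <- variant_spec(variant, late_from)
  data <- variant_surveys(data, variant, late_from)
  missing_cols <- setdiff(c("dT", "x", "y", "year", vs$cols), names(data))
  if (length(missing_cols))
    stop("variant ", variant, " needs missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(error_sd)) {
    if (any(error_sd < 0)) stop("negative measurement-error sd")
    bad <- setdiff(names(error_sd), vs$cols)
    if (length(bad)) stop("error_sd names not in the variant: ",
                          paste(bad, collapse = ", "))
  }

  Xall <- as.matrix(data[vs$cols])
  yrs <- data$year
  p <- length(vs$cols) + 1L  # + year term
  if (is.null(max_components)) max_components <- p
  max_components <- min(max_components, p)

  set.seed(derive_seed(seed, "draws"))
  draw_seeds <- sample.int(2147483646L, n_draws)

  coefs <- matrix(NA_real_, n_draws, p,
                  dimnames = list(NULL, c(vs$cols, "year")))
  shares <- matrix(NA_real_, n_draws, p,
                   dimnames = list(NULL, c(vs$cols, "year")))
  r2 <- rep(NA_real_, n_draws)
  n_retained <- rep(NA_integer_, n_draws)
  n_obs <- integer(n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(draw_seeds[d])
    idx <- spatial_thinning(data$x, data$y, min_dist)
    n_obs[d] <- length(idx)
    if (length(idx) < p + 5) next  # too few thinned surveys for this draw
    w <- observation_weights(yrs[idx])
    Xd <- cbind(Xall[idx, , drop = FALSE], year = yrs[idx])
    if (!is.null(error_sd))
      for (v in names(error_sd)) if (error_sd[[v]] > 0)
        Xd[, v] <- Xd[, v] + stats::rnorm(length(idx), 0, error_sd[[v]])
    Xs <- tryCatch(weighted_standardize(Xd, w), error = function(e) NULL)
    if (is.null(Xs)) next  # constant column in this subsample
    wy <- w / sum(w)
    yv <- data$dT[idx]
    ys <- (yv - sum(wy * yv)) / sqrt(sum(wy * (yv - sum(wy * yv))^2))
    fit <- fit_weighted_pls(Xs, ys, w, max_components)
    sel <- select_components(fit, alpha_components)
    if (!length(sel$retained)) next  # recorded as a failed draw
    cr <- pls_coefficients(fit, sel$retained)
    coefs[d, ] <- cr$coefficients[colnames(coefs)]
    shares[d, ] <- variance_partition(fit, sel$retained)[colnames(shares)]
    r2[d] <- cr$r2
    n_retained[d] <- length(sel$retained)
  }

  ok <- !is.na(r2)
  if (!any(ok)) stop("every draw failed component selection")
  summ <- data.frame(
    variable = colnames(coefs),
    mean = colMeans(coefs[ok, , drop = FALSE]),
    ci_lo = apply(coefs[ok, , drop = FALSE], 2, stats::quantile, 0.025),
    ci_hi = apply(coefs[ok, , drop = FALSE], 2, stats::quantile, 0.975),
    share = colMeans(shares[ok, , drop = FALSE]),
    row.names = NULL
  )
  if (sum(ok) >= 100) {
    sig <- coefficient_significance(coefs[ok, , drop = FALSE], alpha_sign)
    summ$frac_positive <- attr(sig, "frac_positive")
    summ$significance <- as.character(sig)
  } else {
    # too few draws for the sign test: report fractions, no calls
    summ$frac_positive <- colMeans(coefs[ok, , drop = FALSE] > 0)
    summ$significance <- "ns"
  }

  structure(
    list(variant = variant, summary = summ,
         r2_mean = mean(r2[ok]),
         r2_ci = stats::quantile(r2[ok], c(0.025, 0.975)),
         n_draws = n_draws, n_failed = sum(!ok),
         n_obs_mean = mean(n_obs[ok]),
         n_retained_mean = mean(n_retained[ok]),
         draws = list(coefficients = coefs, shares = shares, r2 = r2,
                      n_retained = n_retained, n_obs = n_obs),
         alpha_sign = alpha_sign, alpha_components = alpha_components,
         min_dist = min_dist, error_sd = error_sd, seed = seed),
    class = "debt_pls")
}

#' Measurement-error propagation for the debt PLS
#'
#' Re-runs [debt_pls()] with per-draw Gaussian perturbation of the covariates
#' at their stated measurement-error standard deviations, to check that the
#' estimated effects are robust to the uncertainty of the underlying
#' variables.
#'
#' @param data,variant,n_draws,seed,... as in [debt_pls()].
#' @param error_sd named non-negative vector of per-variable error sd
#'   (omitted variables are unperturbed).
#' @return A `debt_pls` object fitted under measurement error.
#' @export
error_propagation <- function(data, error_sd, variant = "PLS0",
                              n_draws = 5000, seed = 1L, ...) {
  debt_pls(data, variant = variant, n_draws = n_draws, error_sd = error_sd,
           seed = seed, ...)
}

#' @export
print.debt_pls <- function(x, ...) {
  cat(sprintf("Climatic-debt PLS (%s): %d draws (%d failed), mean n = %.0f, mean components = %.1f\n",
              x$variant, x$n_draws, x$n_failed, x$n_obs_mean,
              x$n_retained_mean))
  cat(sprintf("  R2 = %.3f [%.3f, %.3f]\n", x$r2_mean,
              x$r2_ci[1], x$r2_ci[2]))
  sig <- x$summary[x$summary$significance != "ns", ]
  if (nrow(sig)) {
    cat("  significant effects (99% sign rule):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-10s %+0.3f [%+0.3f, %+0.3f] (%s)\n",
                  sig$variable[i], sig$mean[i], sig$ci_lo[i], sig$ci_hi[i],
                  sig$significance[i]))
  } else cat("  no significant effects\n")
  invisible(x)
}

#' @export
summary.debt_pls <- function(object, ...) {
  out <- object$summary
  attr(out, "r2_mean") <- object$r2_mean
  attr(out, "variant") <- object$variant
  out
}

#' @export
coef.debt_pls <- function(object, ...)
  stats::setNames(object$summary$mean, object$summary$variable)

#' @export
confint.debt_pls <- function(object, parm, level = 0.95, ...) {
  ok <- !is.na(object$draws$r2)
  a <- (1 - level) / 2
  cf <- object$draws$coefficients[ok, , drop = FALSE]
  if (!missing(parm)) cf <- cf[, parm, drop = FALSE]
  t(apply(cf, 2, stats::quantile, c(a, 1 - a)))
}

#' Coefficient plot for a debt PLS fit
#'
#' Dot-and-whisker display of the mean standardized coefficients with their
#' percentile confidence intervals, significant effects filled.
#'
#' @param x a `debt_pls` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.debt_pls <- function(x, ...) {
  s <- x$summary[order(x$summary$mean), ]
  n <- nrow(s)
  graphics::plot(s$mean, seq_len(n), xlim = range(c(s$ci_lo, s$ci_hi, 0)),
                 yaxt = "n", xlab = "standardized coefficient", ylab = "",
                 pch = ifelse(s$significance == "ns", 1, 19),
                 main = sprintf("%s: mean and CI95 over %d draws",
                                x$variant, x$n_draws - x$n_failed), ...)
  graphics::segments(s$ci_lo, seq_len(n), s$ci_hi, seq_len(n))
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = seq_len(n), labels = s$variable, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
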