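#' Binned occupancy distribution of a climate variable
#'
#' Relative-frequency histogram of the climate values at a species' occupied
#' localities, on fixed-width bins. Distributions meant to be compared must
#' share bin edges; use `edges` (or build them once with [niche_bin_edges()]).
#'
#' @param values numeric climate values (one per occurrence).
#' @param edges bin edges; when `NULL`, fixed-width bins of `binwidth`
#'   spanning the data are used.
#' @param binwidth bin width used when `edges` is NULL (0.5 suits degrees C;
#'   use 50 for precipitation in mm).
#' @return An object of class `occupancy_distribution`: `freq` (sums to 1),
#'   `edges`, `n`.
#' @export
occupancy_distribution <- function(values, edges = NULL, binwidth = 0.5) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty occurrence set")
  if (is.null(edges)) edges <- niche_bin_edges(values, binwidth)
  tol <- 1e-9 * max(1, abs(edges[length(edges)]))
  if (min(values) < edges[1] - tol || max(values) > edges[length(edges)] + tol)
    stop("values fall outside the bin edges")
  cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                               all.inside = TRUE),
                  nbins = length(edges) - 1L)
  structure(list(freq = cnt / sum(cnt), edges = edges, n = length(values)),
            class = "occupancy_distribution")
}

#' @rdname occupancy_distribution
#' @param ... numeric vectors whose pooled range the edges must span.
#' @export
niche_bin_edges <- function(..., binwidth = 0.5) {
  r <- range(unlist(list(...)), finite = TRUE)
  lo <- floor(r[1] / binwidth) * binwidth
  nb <- max(1L, ceiling((r[2] - lo) / binwidth - 1e-9))
  lo + binwidth * (0:nb)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |p_b - q_b|` over shared bins; 0 = disjoint niches,
#' 1 = identical.
#'
#' @param p,q [occupancy_distribution]s on identical bin edges.
#' @return Overlap in [0, 1].
#' @export
schoener_d <- function(p, q) {
  stopifnot(inherits(p, "occupancy_distribution"),
            inherits(q, "occupancy_distribution"))
  if (length(p$edges) != length(q$edges) ||
      any(abs(p$edges - q$edges) > 1e-9))
    stop("mismatched bin edges")
  1 - 0.5 * sum(abs(p$freq - q$freq))
}

#' Climatic tolerance range
#'
#' Breadth of the realized climate niche: the range (max minus min) of the
#' baseline-period climate values at the species' occupied localities. Used
#' for the thermal (`TO_T`, degrees C) and water (`TO_W`, mm) stress-tolerance
#' covariates.
#'
#' @param values climate values at occurrences.
#' @return `max(values) - min(values)`.
#' @export
climatic_tolerance <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty occurrence set")
  max(values) - min(values)
}

# Histogram-matched subsampling: draw without replacement from `candidates`
# so the drawn sample reproduces, bin by bin, the target distribution at the
# target's sample size. Bins short of candidates contribute what they have;
# the shortfall is reported.
matched_sample <- function(candidates, target, edges) {
  want <- round(target$freq * target$n)
  bin <- findInterval(candidates, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- numeric(0); short <- 0L
  for (b in which(want > 0)) {
    avail <- candidates[bin == b]
    k <- min(want[b], length(avail))
    short <- short + (want[b] - k)
    if (k > 0) out <- c(out, avail[sample.int(length(avail), k)])
  }
  list(values = out, shortfall = short, wanted = sum(want))
}

conservatism_result <- function(d_ref, d_obs, n_replicates) {
  d_obs <- min(d_obs, d_ref)  # sampling noise cannot beat the reference
  structure(list(d_ref = d_ref, d_obs = d_obs,
                 index = max(0, min(1, d_obs / d_ref)),
                 n_replicates = n_replicates),
            class = "conservatism_result")
}

#' @export
print.conservatism_result <- function(x, ...) {
  cat(sprintf("conservatism: D_ref = %.3f, D_obs = %.3f, index = %.3f (%d replicates)\n",
              x$d_ref, x$d_obs, x$index, x$n_replicates))
  invisible(x)
}

#' Distribution conservatism over time (DC)
#'
#' How much a species kept its former spatial distribution despite climate
#' change (1 = full persistence in place, via tolerance, adaptation,
#' acclimation or plasticity). Steps: the past niche `N_0` is the baseline
#' climate at baseline localities; the expected niche `N_exp` is the
#' study-period climate at those *same* localities (distribution assumed
#' unchanged); `D_ref = D(N_0, N_exp)`. The observed niche `N_obs` is a
#' histogram-matched subsample of the study-period climate at study-period
#' localities, matched to `N_exp` so both periods are compared with similar
#' accuracy; `D_obs = D(N_0, N_obs)` is averaged over replicates and
#' `DC = D_obs / D_ref`, bounded by 1.
#'
#' @param baseline_clim baseline-period climate at baseline localities (N_0).
#' @param baseline_now study-period climate at the same baseline localities
#'   (N_exp).
#' @param study_clim study-period climate at study-period localities (the
#'   sampling pool for N_obs).
#' @param binwidth histogram bin width (0.5 degrees C default).
#' @param n_replicates matched-sampling replicates (default 100).
#' @return A `conservatism_result` (`index` is DC_sp).
#' @export
distribution_conservatism <- function(baseline_clim, baseline_now, study_clim,
                                      binwidth = 0.5, n_replicates = 100) {
  edges <- niche_bin_edges(baseline_clim, baseline_now, study_clim,
                           binwidth = binwidth)
  n0 <- occupancy_distribution(baseline_clim, edges)
  nexp <- occupancy_distribution(baseline_now, edges)
  if (length(study_clim) < nexp$n)
    stop("fewer study-period occurrences than the matching size")
  d_ref <- schoener_d(n0, nexp)
  if (d_ref <= 0) stop("D_ref = 0: reference niches do not overlap")
  d_obs <- mean(vapply(seq_len(n_replicates), function(r) {
    ms <- matched_sample(study_clim, nexp, edges)
    if (!length(ms$values)) return(0)
    schoener_d(n0, occupancy_distribution(ms$values, edges))
  }, 0))
  conservatism_result(d_ref, d_obs, n_replicates)
}

#' Thermal niche conservatism over time (NC)
#'
#' How closely a species' occupied climate tracks its former niche
#' (1 = perfect climate-niche tracking via migration). The past niche `N_0`
#' is as in [distribution_conservatism()]. The expected niche `N_exp`
#' reconstructs `N_0` from the study period: a histogram-matched subsample of
#' study-period climate over *background* surveys, irrespective of the
#' species' presence; `D_ref = D(N_0, N_exp)` (averaged over replicates).
#' The observed niche `N_obs` is a matched subsample of the study-period
#' climate at the species' study localities, matched to `N_0`;
#' `D_obs = D(N_0, N_obs)` and `NC = D_obs / D_ref`, bounded by 1.
#'
#' @param baseline_clim baseline climate at baseline localities (N_0).
#' @param study_clim study-period climate at the species' study localities.
#' @param background_clim study-period climate at background surveys.
#' @param binwidth,n_replicates as in [distribution_conservatism()].
#' @return A `conservatism_result` (`index` is NC_sp), or an error when the
#'   background cannot reconstruct `N_0` (uncovered bins).
#' @export
niche_conservatism <- function(baseline_clim, study_clim, background_clim,
                               binwidth = 0.5, n_replicates = 100) {
  edges <- niche_bin_edges(baseline_clim, study_clim, background_clim,
                           binwidth = binwidth)
  n0 <- occupancy_distribution(baseline_clim, edges)
  bbin <- findInterval(background_clim, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  uncovered <- which(round(n0$freq * n0$n) > 0 & !seq_along(n0$freq) %in% bbin)
  if (length(uncovered))
    stop("background does not cover ", length(uncovered),
         " bin(s) of the past niche: index undefined")
  reps <- vapply(seq_len(n_replicates), function(r) {
    ref <- matched_sample(background_clim, n0, edges)
    obs <- matched_sample(study_clim, n0, edges)
    c(ref = if (length(ref$values))
        schoener_d(n0, occupancy_distribution(ref$values, edges)) else 0,
      obs = if (length(obs$values))
        schoener_d(n0, occupancy_distribution(obs$values, edges)) else 0)
  }, c(ref = 0, obs = 0))
  d_ref <- mean(reps["ref", ])
  if (d_ref <= 0) stop("D_ref = 0: background reconstruction failed")
  conservatism_result(d_ref, mean(reps["obs", ]), n_replicates)
}

#' Community mean of a species attribute
#'
#' Unweighted arithmetic mean of a species-level value over the species
#' co-occurring in one survey (the data are presence/absence, so no abundance
#' weighting applies). Species without a value are dropped and counted.
#'
#' @param values named numeric vector of per-species values.
#' @param species character vector of the survey's species.
#' @return The mean, with attribute `n_missing`.
#' @export
community_mean <- function(values, species) {
  v <- values[species]
  ok <- !is.na(v)
  if (!any(ok)) stop("no species with a defined value")
  structure(mean(v[ok]), n_missing = sum(!ok))
}
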