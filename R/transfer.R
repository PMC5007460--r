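#' Build a presence/absence community matrix
#'
#' @param occupancy either a named list of species-id vectors (one per survey)
#'   or a character vector of semicolon-joined species ids.
#' @param species optional character vector fixing the column set and order;
#'   defaults to the union of observed species, sorted.
#' @return Binary integer matrix, surveys in rows, species in columns.
#' @export
build_community_matrix <- function(occupancy, species = NULL) {
  if (is.character(occupancy)) occupancy <- strsplit(occupancy, ";", fixed = TRUE)
  if (is.null(species)) species <- sort(unique(unlist(occupancy)))
  m <- matrix(0L, length(occupancy), length(species),
              dimnames = list(names(occupancy), species))
  for (i in seq_along(occupancy)) {
    j <- match(occupancy[[i]], species)
    m[i, j[!is.na(j)]] <- 1L
  }
  m
}

#' Iterative calibration filter
#'
#' Repeatedly removes surveys with fewer than `min_richness` co-occurring
#' species and species with fewer than `min_occurrences` occurrences until
#' both thresholds hold, the standard cleaning step before fitting a
#' transfer function to floristic data.
#'
#' @param comm binary community matrix (surveys x species).
#' @param response optional response vector aligned with rows; filtered along.
#' @param min_richness minimum species per survey (default 5).
#' @param min_occurrences minimum occurrences per species (default 5).
#' @return A list: `comm` (filtered matrix), `response` (filtered vector or
#'   NULL), `removed_surveys`, `removed_species` (counts).
#' @export
filter_calibration <- function(comm, response = NULL, min_richness = 5,
                               min_occurrences = 5) {
  comm <- as.matrix(comm)
  if (!is.null(response) && length(response) != nrow(comm))
    stop("response length must match rows of comm")
  keep_r <- rep(TRUE, nrow(comm)); keep_c <- rep(TRUE, ncol(comm))
  repeat {
    rs <- rowSums(comm[, keep_c, drop = FALSE])
    cs <- colSums(comm[keep_r, , drop = FALSE])
    drop_r <- keep_r & rs < min_richness
    drop_c <- keep_c & cs < min_occurrences
    if (!any(drop_r) && !any(drop_c)) break
    keep_r[drop_r] <- FALSE
    keep_c[drop_c] <- FALSE
    if (!any(keep_r) || !any(keep_c))
      stop("community matrix empty after filtering")
  }
  list(comm = comm[keep_r, keep_c, drop = FALSE],
       response = if (!is.null(response)) response[keep_r],
       removed_surveys = sum(!keep_r), removed_species = sum(!keep_c))
}

#' Weighted-averaging partial least squares
#'
#' Fits the WA-PLS stage of the transfer function. Component 1 is classical
#' weighted averaging: species optima are occurrence-weighted means of the
#' response, site scores are presence-weighted means of the optima, and the
#' deshrinking step regresses the observed response on the scores by ordinary
#' least squares. Each further component repeats the optimum/score cycle on
#' the residuals of the previous fit, with site scores orthogonalised (under
#' site-total weights) against the earlier components before the deshrinking
#' regression is refitted on all scores.
#'
#' @param comm binary community matrix, already filtered (no empty species).
#' @param x response vector (e.g. annual mean temperature, degrees C).
#' @param n_components number of components to extract.
#' @return An object of class `wapls`: species score matrix `u`
#'   (species x components), orthogonalisation and deshrinking coefficients,
#'   per-component fitted values (`fitted_by_comp`), and RMSD per component
#'   count.
#' @export
fit_wapls <- function(comm, x, n_components = 3) {
  comm <- as.matrix(comm)
  storage.mode(comm) <- "double"
  n <- nrow(comm); m <- ncol(comm)
  stopifnot(length(x) == n, n_components >= 1)
  if (stats::sd(x) == 0) stop("constant response vector")
  cs <- colSums(comm)
  if (any(cs == 0)) stop("species with zero total occurrence present")
  rs <- rowSums(comm)
  if (any(rs == 0)) stop("surveys with no species present")
  H <- n_components
  u <- matrix(NA_real_, m, H, dimnames = list(colnames(comm), NULL))
  scores <- matrix(NA_real_, n, H)
  orth <- vector("list", H)      # per component: centring + projection coefs
  deshrink <- vector("list", H)  # per component count: lm coefficients
  fitted_by_comp <- matrix(NA_real_, n, H)
  wr <- rs / sum(rs)

  resid <- x
  for (h in seq_len(H)) {
    u[, h] <- drop(crossprod(comm, resid)) / cs
    s_raw <- drop(comm %*% u[, h]) / rs
    ctr <- sum(wr * s_raw)
    s <- s_raw - ctr
    proj <- numeric(0)
    if (h > 1) {
      proj <- vapply(seq_len(h - 1), function(g)
        sum(wr * s * scores[, g]) / sum(wr * scores[, g]^2), 0)
      s <- s - drop(scores[, seq_len(h - 1), drop = FALSE] %*% proj)
    }
    if (sum(wr * s^2) < 1e-14)
      stop("degenerate component ", h, ": scores collapse to zero")
    scores[, h] <- s
    orth[[h]] <- list(center = ctr, proj = proj)
    fit <- stats::lm.fit(cbind(1, scores[, seq_len(h), drop = FALSE]), x)
    deshrink[[h]] <- fit$coefficients
    fitted_by_comp[, h] <- fit$fitted.values
    resid <- x - fitted_by_comp[, h]
  }

  rmsd <- sqrt(colMeans((x - fitted_by_comp)^2))
  structure(
    list(u = u, orth = orth, deshrink = deshrink, scores = scores,
         fitted_by_comp = fitted_by_comp, rmsd = rmsd, x = x,
         species = colnames(comm), n_components = H),
    class = "wapls")
}

#' @export
print.wapls <- function(x, ...) {
  cat(sprintf("WA-PLS transfer stage: %d species, %d component(s)\n",
              length(x$species), x$n_components))
  cat("training RMSD by components:",
      paste(sprintf("%.3f", x$rmsd), collapse = ", "), "\n")
  invisible(x)
}

# Site scores for new presence data over the model's species set.
wapls_scores <- function(object, comm) {
  comm <- as.matrix(comm)
  storage.mode(comm) <- "double"
  rs <- rowSums(comm)
  if (any(rs == 0)) stop("no shared species for ", sum(rs == 0), " survey(s)")
  H <- object$n_components
  scores <- matrix(NA_real_, nrow(comm), H)
  for (h in seq_len(H)) {
    s <- drop(comm %*% object$u[, h]) / rs - object$orth[[h]]$center
    if (h > 1)
      s <- s - drop(scores[, seq_len(h - 1), drop = FALSE] %*%
                      object$orth[[h]]$proj)
    scores[, h] <- s
  }
  scores
}

#' Predict from a WA-PLS stage
#'
#' @param object a `wapls` fit.
#' @param comm binary matrix whose columns are the model's species.
#' @param n_components components to use (default all fitted).
#' @param ... unused.
#' @return Numeric vector of deshrunken predictions.
#' @export
predict.wapls <- function(object, comm, n_components = object$n_components,
                          ...) {
  stopifnot(n_components >= 1, n_components <= object$n_components)
  sc <- wapls_scores(object, comm)[, seq_len(n_components), drop = FALSE]
  drop(cbind(1, sc) %*% object$deshrink[[n_components]])
}

#' Random-forest residual stage
#'
#' Trains a random-forest regression on the presence/absence columns with the
#' WA-PLS calibration residuals as target; the hybrid transfer function
#' predicts as WA-PLS + forest.
#'
#' @param wapls_stage a fitted [fit_wapls()] object.
#' @param comm the calibration community matrix (same rows as the fit).
#' @param x the calibration response.
#' @param n_components WA-PLS components used for the residuals.
#' @param num_trees number of trees (default 500).
#' @param seed integer seed for the forest.
#' @return A `ranger` model (or NULL when residuals are numerically zero,
#'   in which case the hybrid equals the WA-PLS stage).
#' @export
fit_residual_learner <- function(wapls_stage, comm, x,
                                 n_components = wapls_stage$n_components,
                                 num_trees = 500, seed = 1L) {
  resid <- x - wapls_stage$fitted_by_comp[, n_components]
  if (all(abs(resid) < 1e-12)) return(NULL)
  df <- as.data.frame(comm)
  names(df) <- paste0("f", seq_len(ncol(df)))  # ranger-safe feature names
  ranger::ranger(x = df, y = resid, num.trees = num_trees, seed = seed,
                 respect.unordered.factors = "order")
}

#' Fit a bioindication transfer function
#'
#' The package's calibration front end: filters the community matrix, fits the
#' weighted-averaging PLS stage, selects the number of components by 10-fold
#' cross-validated RMSD (unless given), and trains the random-forest residual
#' stage. The same machinery calibrates any bioindicated variable —
#' temperature, soil pH, or inverse C:N ratio.
#'
#' @param comm binary community matrix (surveys x species), or anything
#'   [build_community_matrix()] accepts.
#' @param response response values aligned with the surveys.
#' @param n_components integer, or `"cv"` (default) for cross-validated
#'   selection among `1:max_components`.
#' @param max_components upper bound for selection.
#' @param min_richness,min_occurrences calibration filter thresholds.
#' @param learner logical, train the random-forest residual stage.
#' @param num_trees forest size.
#' @param cv_folds folds for component selection.
#' @param seed integer seed (forest and fold assignment).
#' @return An object of class `transfer_function` with `print`, `predict`,
#'   `fitted` and `residuals` methods.
#' @export
transfer_function <- function(comm, response, n_components = "cv",
                              max_components = 5, min_richness = 5,
                              min_occurrences = 5, learner = TRUE,
                              num_trees = 500, cv_folds = 10, seed = 1L) {
  if (!is.matrix(comm)) comm <- build_community_matrix(comm)
  flt <- filter_calibration(comm, response, min_richness, min_occurrences)
  comm <- flt$comm; response <- flt$response
  if (nrow(comm) < 10) stop("too few calibration surveys after filtering")
  max_components <- min(max_components, ncol(comm) - 1L, nrow(comm) - 2L)

  cv_rmsd <- NULL
  if (identical(n_components, "cv")) {
    set.seed(derive_seed(seed, "cvfolds"))
    fold <- sample(rep_len(seq_len(cv_folds), nrow(comm)))
    se <- matrix(0, cv_folds, max_components)
    cnt <- integer(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      # refilter the training part: held-out rows may orphan rare species
      sub <- filter_calibration(comm[tr, , drop = FALSE], response[tr],
                                min_richness = 1, min_occurrences = 1)
      wt <- fit_wapls(sub$comm, sub$response, max_components)
      te <- comm[!tr, colnames(sub$comm), drop = FALSE]
      ok <- rowSums(te) > 0
      cnt[f] <- sum(ok)
      for (h in seq_len(max_components)) {
        p <- predict(wt, te[ok, , drop = FALSE], n_components = h)
        se[f, h] <- sum((p - response[!tr][ok])^2)
      }
    }
    cv_rmsd <- sqrt(colSums(se) / sum(cnt))
    n_components <- which.min(cv_rmsd)
  }

  wstage <- fit_wapls(comm, response, n_components)
  forest <- if (learner)
    fit_residual_learner(wstage, comm, response, n_components,
                         num_trees = num_trees,
                         seed = derive_seed(seed, "forest")) else NULL
  fitted <- wstage$fitted_by_comp[, n_components]
  if (!is.null(forest)) {
    df <- as.data.frame(comm); names(df) <- paste0("f", seq_len(ncol(df)))
    fitted <- fitted + stats::predict(forest, data = df)$predictions
  }
  structure(
    list(wapls = wstage, forest = forest, species = colnames(comm),
         comm = comm,
         n_components = n_components, cv_rmsd = cv_rmsd,
         fitted = fitted, observed = response,
         rmsd = sqrt(mean((fitted - response)^2)),
         r2 = stats::cor(fitted, response)^2,
         removed_surveys = flt$removed_surveys,
         removed_species = flt$removed_species,
         num_trees = num_trees, seed = seed),
    class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat("Bioindication transfer function (WA-PLS + random-forest residuals)\n")
  cat(sprintf("  calibration: %d surveys, %d species (filter removed %d / %d)\n",
              length(x$observed), length(x$species),
              x$removed_surveys, x$removed_species))
  cat(sprintf("  components retained: %d%s\n", x$n_components,
              if (!is.null(x$cv_rmsd)) " (10-fold CV)" else ""))
  cat(sprintf("  residual forest: %s\n",
              if (is.null(x$forest)) "none" else
                sprintf("%d trees", x$num_trees)))
  cat(sprintf("  calibration R2 = %.3f, RMSD = %.3f\n", x$r2, x$rmsd))
  invisible(x)
}

#' @export
fitted.transfer_function <- function(object, ...) object$fitted

#' @export
residuals.transfer_function <- function(object, ...)
  object$observed - object$fitted

#' Predict the bioindicated variable for new surveys
#'
#' Species unknown to the calibration are dropped and counted; a survey
#' sharing no species with the model is an error.
#'
#' @param object a [transfer_function()] fit.
#' @param newdata new surveys: a binary matrix, a named list of species
#'   vectors, or a character vector of semicolon-joined ids.
#' @param ... unused.
#' @return Numeric vector of predictions with attributes `n_unknown`
#'   (unknown-species count per survey) and `n_used`.
#' @export
predict.transfer_function <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    known <- intersect(colnames(newdata), object$species)
    n_tot <- rowSums(newdata)
    m <- matrix(0L, nrow(newdata), length(object$species),
                dimnames = list(rownames(newdata), object$species))
    m[, known] <- newdata[, known, drop = FALSE]
  } else {
    if (is.character(newdata)) newdata <- strsplit(newdata, ";", fixed = TRUE)
    n_tot <- lengths(newdata)
    m <- build_community_matrix(newdata, species = object$species)
  }
  n_used <- rowSums(m)
  if (any(n_used == 0))
    stop(sum(n_used == 0), " survey(s) share no species with the model")
  pred <- predict(object$wapls, m, n_components = object$n_components)
  if (!is.null(object$forest)) {
    df <- as.data.frame(m); names(df) <- paste0("f", seq_len(ncol(df)))
    pred <- pred + stats::predict(object$forest, data = df)$predictions
  }
  attr(pred, "n_unknown") <- as.integer(n_tot - n_used)
  attr(pred, "n_used") <- as.integer(n_used)
  pred
}

#' Validate a transfer function on a holdout set
#'
#' @param object a [transfer_function()] fit.
#' @param comm holdout community data (any form [predict.transfer_function()]
#'   accepts), disjoint from the calibration set.
#' @param response observed holdout values.
#' @return A list: `r2` (squared Pearson correlation of predictions and
#'   observations), `rmsd`, `n`.
#' @export
validate_transfer <- function(object, comm, response) {
  if (length(response) < 2) stop("holdout smaller than 2")
  p <- predict(object, comm)
  list(r2 = stats::cor(p, response)^2,
       rmsd = sqrt(mean((p - response)^2)),
       n = length(response))
}

#' Climatic debt
#'
#' The debt is the gap between the climatically observed temperature and the
#' temperature bioindicated from the plant assemblage:
#' `dT = CrT - FrT`. Positive values mean community reshuffling lags behind
#' warming.
#'
#' @param crt climatically reconstructed temperature(s), degrees C.
#' @param frt floristically reconstructed temperature(s), degrees C.
#' @return `crt - frt`, vectorised.
#' @export
compute_debt <- function(crt, frt) {
  if (!all(is.finite(crt)) || !all(is.finite(frt)))
    stop("non-finite temperature input")
  unname(crt - frt)
}
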