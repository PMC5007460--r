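# End-to-end orchestration of the synthetic debt study: simulate ->
# bioindicate -> determinants -> fit -> diagnose, with a run manifest.

# Community means of a per-species vector over the occupancy lists;
# NA when no listed species carries a value.
community_means <- function(values, occupancy) {
  vapply(occupancy, function(sp) {
    v <- values[sp]; v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
}

# Per-survey averages of per-(species, survey) habitat metrics. `per_species`
# is called once per species with the indices of the surveys holding it and
# must return a numeric vector of that length (NAs allowed).
accumulate_by_survey <- function(occupancy, species, per_species) {
  n <- length(occupancy)
  sums <- numeric(n); cnts <- numeric(n)
  for (s in species) {
    idx <- which(vapply(occupancy, function(sp) s %in% sp, TRUE))
    if (!length(idx)) next
    vals <- per_species(s, idx)
    ok <- !is.na(vals)
    sums[idx[ok]] <- sums[idx[ok]] + vals[ok]
    cnts[idx[ok]] <- cnts[idx[ok]] + 1
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

#' Compute the determinant covariates for the study-period surveys
#'
#' Builds the 19-variable design table of the debt-determinants regression
#' from a synthetic study: baseline climate (T, P) and its change (TC, PC),
#' bioindicated soil pH and inverse C:N (pH, N), community light (L),
#' within-cell temperature heterogeneity (THET), community tolerance ranges
#' (TO_T, TO_W), distribution and niche conservatism (DC, NC), past-habitat
#' proximity and aggregation change (HP, dHA), community longevity (LG),
#' water and nutrient competition (C_W, C_N), road proximity and human
#' population (road_prox, HPD).
#'
#' @param study a [simulate_debt_study()] result.
#' @param nc_replicates matched-sampling replicates for DC/NC (default 20
#'   here; the species-level functions default to 100).
#' @param min_occ minimum per-period occurrences for a species to get DC/NC.
#' @param num_trees forest size of the soil bioindication models.
#' @param seed integer seed.
#' @return data.frame, one row per study-period survey, with the covariates
#'   plus `id`, `x`, `y`, `year`.
#' @export
compute_determinants <- function(study, nc_replicates = 20, min_occ = 8,
                                 num_trees = 200, seed = 1L) {
  land <- study$landscape; pool <- study$pool; cfg <- study$config
  surv <- study$communities$surveys
  occ_all <- study$communities$occupancy
  is_base <- surv$period == "baseline"
  bs <- surv[is_base, ]; ss <- surv[!is_base, ]
  occ_b <- occ_all[is_base]; occ_s <- occ_all[!is_base]
  tgrid <- land$temperature; pgrid <- land$precipitation
  by <- cfg$baseline_years; sy <- cfg$study_years
  cs <- cfg$cell_size

  out <- data.frame(id = ss$id, x = ss$x, y = ss$y, year = ss$year)

  # --- climate context ------------------------------------------------------
  out$T <- extract_baseline(tgrid, ss$x, ss$y, by)
  out$P <- extract_baseline(pgrid, ss$x, ss$y, by)
  out$TC <- extract_change(tgrid, ss$x, ss$y, ss$year, by)
  out$PC <- extract_change(pgrid, ss$x, ss$y, ss$year, by)

  # fine-scale heterogeneity: 4x upsampled baseline field with local noise
  set.seed(derive_seed(seed, "finegrid"))
  fine_mat <- land$base_t[rep(seq_len(nrow(land$base_t)), each = 4),
                          rep(seq_len(ncol(land$base_t)), each = 4)]
  fine_mat <- fine_mat + matrix(stats::rnorm(length(fine_mat), 0, 0.15),
                                nrow(fine_mat))
  fine <- climate_grid(fine_mat, by[1], cell_size = cs / 4)
  out$THET <- temperature_heterogeneity(fine, ss$x, ss$y, coarse_cell = cs)

  # --- bioindicated soil conditions ----------------------------------------
  bmat <- build_community_matrix(occ_b)
  bcell <- cell_index(tgrid, bs$x, bs$y)
  ph_b <- land$soil_ph[bcell]
  n_b <- 1 / land$soil_cn[bcell]
  tf_ph <- transfer_function(bmat, ph_b, num_trees = num_trees,
                             seed = derive_seed(seed, "ph"))
  tf_n <- transfer_function(bmat, n_b, num_trees = num_trees,
                            seed = derive_seed(seed, "cn"))
  out$pH <- as.numeric(predict(tf_ph, ss$species))
  out$N <- as.numeric(predict(tf_n, ss$species))

  # --- community means of species traits -----------------------------------
  lvals <- stats::setNames(as.numeric(pool$L), pool$species)
  lgvals <- stats::setNames(pool$longevity, pool$species)
  out$L <- community_means(lvals, occ_s)
  out$LG <- community_means(lgvals, occ_s)

  # --- tolerance ranges -----------------------------------------------------
  t_base_surv <- extract_baseline(tgrid, bs$x, bs$y, by)
  p_base_surv <- extract_baseline(pgrid, bs$x, bs$y, by)
  occ_of <- function(occ) {
    m <- build_community_matrix(occ, species = pool$species)
    lapply(stats::setNames(seq_len(ncol(m)), colnames(m)),
           function(j) which(m[, j] > 0))
  }
  idx_b <- occ_of(occ_b); idx_s <- occ_of(occ_s)
  to_t <- vapply(pool$species, function(s)
    if (length(idx_b[[s]])) climatic_tolerance(t_base_surv[idx_b[[s]]])
    else NA_real_, 0)
  to_w <- vapply(pool$species, function(s)
    if (length(idx_b[[s]])) climatic_tolerance(p_base_surv[idx_b[[s]]])
    else NA_real_, 0)
  out$TO_T <- community_means(to_t, occ_s)
  out$TO_W <- community_means(to_w, occ_s)

  # --- conservatism indices -------------------------------------------------
  set.seed(derive_seed(seed, "conservatism"))
  t_now_at_base <- extract_baseline(tgrid, bs$x, bs$y, sy)
  t_now_at_study <- extract_baseline(tgrid, ss$x, ss$y, sy)
  dc <- nc <- stats::setNames(rep(NA_real_, nrow(pool)), pool$species)
  for (s in pool$species) {
    ib <- idx_b[[s]]; is <- idx_s[[s]]
    if (length(ib) < min_occ || length(is) < min_occ) next
    dc[s] <- tryCatch(
      distribution_conservatism(t_base_surv[ib], t_now_at_base[ib],
                                t_now_at_study[is],
                                n_replicates = nc_replicates)$index,
      error = function(e) NA_real_)
    nc[s] <- tryCatch(
      niche_conservatism(t_base_surv[ib], t_now_at_study[is],
                         t_now_at_study,
                         n_replicates = nc_replicates)$index,
      error = function(e) NA_real_)
  }
  out$DC <- community_means(dc, occ_s)
  out$NC <- community_means(nc, occ_s)

  # --- habitat proximity and aggregation change ----------------------------
  past_mean <- grid_mean(tgrid, by)
  cur_mean <- grid_mean(tgrid, sy)
  sp_used <- pool$species[!is.na(to_t)]
  habs <- lapply(stats::setNames(sp_used, sp_used), function(s) {
    lim <- range(t_base_surv[idx_b[[s]]])
    list(past = potential_habitat(lim, past_mean, land$forest_mask),
         current = potential_habitat(lim, cur_mean, land$forest_mask))
  })
  out$HP <- accumulate_by_survey(occ_s, sp_used, function(s, idx) {
    if (!any(habs[[s]]$past)) return(rep(NA_real_, length(idx)))
    habitat_proximity(ss$x[idx], ss$y[idx], habs[[s]]$past, cs)
  })
  dha_cache <- new.env(parent = emptyenv())
  out$dHA <- accumulate_by_survey(occ_s, sp_used, function(s, idx) {
    cells <- cell_index(tgrid, ss$x[idx], ss$y[idx])
    key <- paste(s, cells[, 1], cells[, 2])
    vapply(seq_along(idx), function(i) {
      if (!is.null(dha_cache[[key[i]]])) return(dha_cache[[key[i]]])
      val <- tryCatch({
        pa <- clip_radius(habs[[s]]$past, ss$x[idx[i]], ss$y[idx[i]],
                          cell_size = cs)
        cu <- clip_radius(habs[[s]]$current, ss$x[idx[i]], ss$y[idx[i]],
                          cell_size = cs)
        habitat_aggregation_change(pa, cu)
      }, error = function(e) NA_real_)
      dha_cache[[key[i]]] <- val
      val
    }, 0)
  })

  # --- competition ----------------------------------------------------------
  p_study <- extract_baseline(pgrid, ss$x, ss$y, sy)
  cn_study <- land$soil_cn[cell_index(tgrid, ss$x, ss$y)]
  sp_comp <- pool$species[vapply(pool$species,
                                 function(s) length(idx_s[[s]]) >= 2, TRUE)]
  edges_w <- niche_bin_edges(p_study, binwidth = 50)
  edges_n <- niche_bin_edges(cn_study, binwidth = 0.5)
  dist_w <- lapply(stats::setNames(sp_comp, sp_comp), function(s)
    occupancy_distribution(p_study[idx_s[[s]]], edges_w))
  dist_n <- lapply(stats::setNames(sp_comp, sp_comp), function(s)
    occupancy_distribution(cn_study[idx_s[[s]]], edges_n))
  diff_w <- pairwise_differentiation(dist_w)
  diff_n <- pairwise_differentiation(dist_n)
  comp_of <- function(mat) vapply(occ_s, function(sp)
    tryCatch(community_competition(sp, mat), error = function(e) NA_real_), 0)
  out$C_W <- comp_of(diff_w)
  out$C_N <- comp_of(diff_n)

  # --- human pressure -------------------------------------------------------
  out$road_prox <- distance_to_network(ss$x, ss$y, land$roads)
  out$HPD <- population_within_radius(land$population, ss$x, ss$y,
                                      cell_size = cs)

  out$SILVP <- ss$silvp; out$DISTURB <- ss$disturb; out$EXOT <- ss$exot
  out
}

#' Run the full synthetic climatic-debt pipeline
#'
#' Sequences the whole analysis on generated data: simulate the study,
#' calibrate the temperature transfer function on baseline surveys, predict
#' FrT and compute the debt `dT = CrT - FrT` for study surveys, build the
#' determinant covariates, fit the requested bootstrap PLS variants, and run
#' the spatial correlograms on the debt and on the first variant's residuals.
#'
#' @param config a [sim_config].
#' @param variants character vector of model variants to fit.
#' @param n_draws bootstrap draws per variant.
#' @param min_dist thinning distance (metres).
#' @param nc_replicates matched-sampling replicates for the conservatism
#'   indices.
#' @param out_dir optional output directory; when given, per-stage tables and
#'   a digest manifest are written there.
#' @param seed integer master seed (defaults to the config's).
#' @return An object of class `debt_pipeline`: `study`, `transfer`, `debt`
#'   (per-survey CrT/FrT/dT merged with the true planted debt), `predictors`,
#'   `fits` (per variant), `correlograms`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), variants = "PLS0",
                         n_draws = 200, min_dist = 10000,
                         nc_replicates = 20, out_dir = NULL,
                         seed = config$seed) {
  t0 <- proc.time()[3]
  timing <- numeric(0)
  tick <- function(stage) {
    dt <- proc.time()[3] - t0
    timing[stage] <<- round(dt - sum(timing), 2)
  }

  study <- simulate_debt_study(config)
  tick("simulate")

  surv <- study$communities$surveys
  is_base <- surv$period == "baseline"
  if (sum(is_base) < 50 || sum(!is_base) < 50)
    stop("too few surveys per period for the pipeline")
  crt_cal <- grid_extract(study$landscape$temperature,
                          surv$x[is_base], surv$y[is_base],
                          surv$year[is_base])
  tf <- transfer_function(surv$species[is_base], crt_cal,
                          seed = derive_seed(seed, "transfer"))
  frt <- predict(tf, surv$species[!is_base])
  crt <- grid_extract(study$landscape$temperature,
                      surv$x[!is_base], surv$y[!is_base], surv$year[!is_base])
  debt <- data.frame(id = surv$id[!is_base], CrT = crt,
                     FrT = as.numeric(frt),
                     dT = compute_debt(crt, as.numeric(frt)),
                     n_unknown = attr(frt, "n_unknown"))
  debt <- merge(debt, study$communities$true_state, by = "id", sort = FALSE)
  tick("bioindicate")

  preds <- compute_determinants(study, nc_replicates = nc_replicates,
                                seed = derive_seed(seed, "determinants"))
  preds <- merge(debt[c("id", "dT")], preds, by = "id", sort = FALSE)
  complete <- stats::complete.cases(preds)
  n_dropped <- sum(!complete)
  preds <- preds[complete, ]
  tick("determinants")

  fits <- lapply(stats::setNames(variants, variants), function(v)
    debt_pls(preds, variant = v, n_draws = n_draws, min_dist = min_dist,
             seed = derive_seed(seed, paste0("fit", v))))
  tick("fit")

  # residuals under the first variant's mean coefficients, on the global
  # standardized scale, for the spatial diagnostic
  f1 <- fits[[1]]
  vars <- f1$summary$variable
  Xs <- scale(as.matrix(preds[vars]))
  ys <- as.numeric(scale(preds$dT))
  resid <- ys - drop(Xs %*% f1$summary$mean)
  cg_debt <- correlogram(preds$dT, preds$x, preds$y,
                         seed = derive_seed(seed, "cg1"))
  cg_resid <- correlogram(resid, preds$x, preds$y,
                          seed = derive_seed(seed, "cg2"))
  tick("diagnose")

  out <- structure(
    list(study = study, transfer = tf, debt = debt, predictors = preds,
         n_dropped = n_dropped, fits = fits,
         correlograms = list(debt = cg_debt, residuals = cg_resid),
         timing = timing, config = config, seed = seed, manifest = NULL),
    class = "debt_pipeline")
  if (!is.null(out_dir)) out$manifest <- write_pipeline(out, out_dir)
  out
}

#' @export
print.debt_pipeline <- function(x, ...) {
  cat("Climatic-debt pipeline run\n")
  cat(sprintf("  surveys: %d baseline / %d study (%d dropped incomplete)\n",
              sum(x$study$communities$surveys$period == "baseline"),
              nrow(x$debt), x$n_dropped))
  cat(sprintf("  mean dT = %.3f (true planted debt %.3f)\n",
              mean(x$debt$dT), mean(x$debt$true_debt)))
  for (v in names(x$fits))
    cat(sprintf("  %s: R2 = %.3f, %d significant effect(s)\n", v,
                x$fits[[v]]$r2_mean,
                sum(x$fits[[v]]$summary$significance != "ns")))
  cat("  stage seconds:",
      paste(names(x$timing), unlist(x$timing), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# Write the pipeline tables and a digest manifest; returns the manifest.
write_pipeline <- function(pipe, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(debt = file.path(out_dir, "debt.csv"),
             predictors = file.path(out_dir, "predictors.csv"),
             correlogram_debt = file.path(out_dir, "correlogram_debt.csv"),
             correlogram_resid = file.path(out_dir, "correlogram_residuals.csv"))
  utils::write.csv(pipe$debt, paths["debt"], row.names = FALSE)
  utils::write.csv(pipe$predictors, paths["predictors"], row.names = FALSE)
  utils::write.csv(pipe$correlograms$debt, paths["correlogram_debt"],
                   row.names = FALSE)
  utils::write.csv(pipe$correlograms$residuals, paths["correlogram_resid"],
                   row.names = FALSE)
  for (v in names(pipe$fits)) {
    p <- file.path(out_dir, sprintf("summary_%s.csv", v))
    utils::write.csv(pipe$fits[[v]]$summary, p, row.names = FALSE)
    paths[paste0("summary_", v)] <- p
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("climdebt")),
    seed = pipe$seed,
    timing_seconds = as.list(pipe$timing),
    n_surveys = nrow(pipe$debt),
    files = lapply(stats::setNames(as.character(paths), names(paths)),
                   function(p) list(path = p,
                                    md5 = unname(tools::md5sum(p)),
                                    bytes = file.size(p)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}

#' Read and validate a species-level benchmark table
#'
#' Schema of the published per-species table: columns `species`, `n`, `L`,
#' `TO_T`, `TO_W`, `LG`, `NC`, `DC`, with `NC` and `DC` in [0, 1]. Errors
#' name the first violated column.
#'
#' @param path CSV file.
#' @return The validated data.frame with attribute `n_species`.
#' @export
load_supplementary_species <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("species", "n", "L", "TO_T", "TO_W", "LG", "NC", "DC"))
    if (!col %in% names(df)) stop("missing column: ", col)
  for (col in c("NC", "DC")) {
    v <- df[[col]][!is.na(df[[col]])]
    if (any(v < 0 | v > 1)) stop("column out of [0, 1]: ", col)
  }
  attr(df, "n_species") <- nrow(df)
  df
}

#' Read and validate a per-survey debt benchmark table
#'
#' Schema of the published per-survey table: columns `x`, `y`, `year`, `dT`,
#' with finite `dT`. Reports the mean and standard deviation of the debt.
#'
#' @param path CSV file.
#' @return The validated data.frame with attributes `n_surveys`, `mean_dT`,
#'   `sd_dT`.
#' @export
load_supplementary_debt <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("x", "y", "year", "dT"))
    if (!col %in% names(df)) stop("missing column: ", col)
  if (!all(is.finite(df$dT))) stop("non-finite values in column: dT")
  attr(df, "n_surveys") <- nrow(df)
  attr(df, "mean_dT") <- mean(df$dT)
  attr(df, "sd_dT") <- stats::sd(df$dT)
  df
}
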