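#' Configuration for the synthetic debt study
#'
#' Bundles every knob of the synthetic-data generator: landscape geometry,
#' climate fields and warming, the species pool, survey placement and the
#' community response lag that plants a known climatic debt.
#'
#' The generator emulates the structure of a national forest-understory
#' resurvey effort: a baseline period in climatic equilibrium, a warmed study
#' period, a pool of a few hundred herbaceous species with unimodal
#' temperature and precipitation niches, and clustered survey locations with
#' uneven yearly counts.
#'
#' @param grid_nx,grid_ny cell counts of the landscape grid (each >= 2).
#' @param cell_size cell edge, metres.
#' @param n_species species-pool size (default 760).
#' @param baseline_years,study_years integer year vectors of the two periods.
#' @param n_surveys_per_year named integer vector of survey counts, one entry
#'   per year of both periods. Defaults to even baseline counts and a
#'   geometrically increasing study-period series, so per-year weights differ.
#' @param warming_total total deterministic warming (degrees C) reached by the
#'   linear trend at the last study year; 0 gives a no-warming control.
#' @param warming_spatial_sd relative spatial modulation of warming (sd of the
#'   multiplicative field; 0 = spatially uniform warming).
#' @param lag_lambda community response lag: either a scalar in [0, 1] or a
#'   function of the survey's baseline temperature returning values in [0, 1].
#'   The planted debt is `lag_lambda * warming realized at the survey's cell
#'   and year`.
#' @param temp_range range of baseline annual mean temperature across the
#'   landscape gradient (degrees C).
#' @param precip_range range of baseline annual precipitation (mm).
#' @param noise_sd_t,noise_sd_p sd of the iid year-to-year cell noise for
#'   temperature (degrees C) and precipitation (mm).
#' @param niche_breadth_mean,niche_breadth_sd mean and sd of species thermal
#'   niche breadth (degrees C, truncated at `0.3`).
#' @param precip_breadth_mean,precip_breadth_sd as above for the precipitation
#'   niche (mm).
#' @param forced_opt_t optional numeric vector of length `n_species` fixing the
#'   thermal optima (bypasses the random draw).
#' @param forest_cover fraction of cells that are forest.
#' @param forest_frag spatial frequency of the forest pattern; larger values
#'   fragment the mask more.
#' @param n_parents number of cluster parents of the Poisson-cluster survey
#'   placement.
#' @param cluster_sd sd (metres) of survey scatter around its parent.
#' @param min_richness minimum species per survey; assemblages below it are
#'   re-drawn (mirrors the calibration filter).
#' @param max_attempts re-draw attempts before failing a survey location.
#' @param disturbance_prev length-3 numeric, prevalence of the silvicultural
#'   practice, disturbance and exotic-tree flags.
#' @param seed integer master seed; all stages derive their streams from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_nx = 40, grid_ny = 40, cell_size = 1000,
                       n_species = 760,
                       baseline_years = 1965:1986, study_years = 1987:2008,
                       n_surveys_per_year = NULL,
                       warming_total = 1.07, warming_spatial_sd = 0.15,
                       lag_lambda = 0.5,
                       temp_range = c(6, 14), precip_range = c(600, 1400),
                       noise_sd_t = 0.2, noise_sd_p = 30,
                       niche_breadth_mean = 2.2, niche_breadth_sd = 0.6,
                       precip_breadth_mean = 250, precip_breadth_sd = 70,
                       forced_opt_t = NULL,
                       forest_cover = 0.7, forest_frag = 1.5,
                       n_parents = 25, cluster_sd = 3000,
                       min_richness = 5, max_attempts = 50,
                       disturbance_prev = c(silvp = 0.25, disturb = 0.15,
                                            exot = 0.05),
                       seed = 1L) {
  if (grid_nx < 2 || grid_ny < 2) stop("grid dimensions must be >= 2")
  if (warming_total < 0) stop("warming_total must be >= 0")
  if (n_species < 2) stop("n_species must be >= 2")
  if (niche_breadth_mean <= 0) stop("niche breadth must be positive")
  if (is.numeric(lag_lambda)) {
    if (any(lag_lambda < 0 | lag_lambda > 1))
      stop("lag_lambda must lie in [0, 1]")
  } else if (!is.function(lag_lambda)) {
    stop("lag_lambda must be a scalar or a function of baseline temperature")
  }
  all_years <- c(baseline_years, study_years)
  if (is.null(n_surveys_per_year)) {
    nb <- rep(25L, length(baseline_years))
    # geometric increase across the study period: deliberately uneven
    ns <- pmax(5L, round(18 * 1.07^seq_along(study_years)))
    n_surveys_per_year <- stats::setNames(c(nb, ns), all_years)
  }
  if (is.null(names(n_surveys_per_year)) ||
      !all(as.character(all_years) %in% names(n_surveys_per_year)))
    stop("n_surveys_per_year must be named by year and cover both periods")
  structure(
    list(grid_nx = grid_nx, grid_ny = grid_ny, cell_size = cell_size,
         n_species = n_species, baseline_years = baseline_years,
         study_years = study_years, n_surveys_per_year = n_surveys_per_year,
         warming_total = warming_total, warming_spatial_sd = warming_spatial_sd,
         lag_lambda = lag_lambda, temp_range = temp_range,
         precip_range = precip_range, noise_sd_t = noise_sd_t,
         noise_sd_p = noise_sd_p, niche_breadth_mean = niche_breadth_mean,
         niche_breadth_sd = niche_breadth_sd,
         precip_breadth_mean = precip_breadth_mean,
         precip_breadth_sd = precip_breadth_sd, forced_opt_t = forced_opt_t,
         forest_cover = forest_cover, forest_frag = forest_frag,
         n_parents = n_parents, cluster_sd = cluster_sd,
         min_richness = min_richness, max_attempts = max_attempts,
         disturbance_prev = disturbance_prev, seed = as.integer(seed)),
    class = "sim_config")
}

# Smooth random field on the unit square evaluated at points (x01, y01):
# a low-order random cosine series, standardized to mean 0 / sd 1 over a
# reference lattice so amplitudes are comparable across draws.
smooth_field <- function(x01, y01, n_waves = 6, freq_scale = 1) {
  fx <- stats::runif(n_waves, 0.5, 2.5) * freq_scale
  fy <- stats::runif(n_waves, 0.5, 2.5) * freq_scale
  ph <- stats::runif(n_waves, 0, 2 * pi)
  am <- stats::rnorm(n_waves)
  f <- function(u, v) {
    out <- 0
    for (k in seq_len(n_waves))
      out <- out + am[k] * cos(2 * pi * (fx[k] * u + fy[k] * v) + ph[k])
    out
  }
  ref <- f(rep(seq(0, 1, length.out = 25), 25),
           rep(seq(0, 1, length.out = 25), each = 25))
  vals <- f(x01, y01)
  (vals - mean(ref)) / stats::sd(ref)
}

#' Generate the synthetic landscape
#'
#' Builds yearly temperature and precipitation grids for both periods and a
#' binary forest mask. Baseline layers are a smooth spatial field (a dominant
#' south-north gradient plus random smooth structure) with iid yearly noise;
#' study-period layers add a deterministic linear warming trend that reaches
#' `warming_total` at the last study year, optionally modulated by a smooth
#' spatial field.
#'
#' @param config a [sim_config].
#' @return A list of class `sim_landscape` with elements `temperature` and
#'   `precipitation` ([climate_grid]s covering both periods), `forest_mask`
#'   (logical matrix), `base_t`, `base_p` (deterministic baseline fields),
#'   `warm_field` (per-cell multiplicative warming modulation) and
#'   `warming_at(year)`-style helper data. Deterministic warming at cell
#'   (r, c) and study year y is
#'   `warming_total * rank(y) / n_study * warm_field[r, c]`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  nx <- config$grid_nx; ny <- config$grid_ny
  rows <- rep(seq_len(ny), times = nx); cols <- rep(seq_len(nx), each = ny)
  u <- (cols - 0.5) / nx; v <- (rows - 0.5) / ny

  tr <- config$temp_range; pr <- config$precip_range
  # dominant gradient (70% of the range) + smooth residual structure
  g_t <- (1 - v) * 0.7 + 0.15 + 0.12 * smooth_field(u, v)
  base_t <- matrix(tr[1] + g_t * diff(tr), ny, nx)
  g_p <- v * 0.6 + 0.2 + 0.12 * smooth_field(u, v)
  base_p <- matrix(pr[1] + g_p * diff(pr), ny, nx)

  wf <- matrix(1 + config$warming_spatial_sd * smooth_field(u, v), ny, nx)
  wf <- pmax(wf, 0)

  yrs <- c(config$baseline_years, config$study_years)
  n_study <- length(config$study_years)
  tv <- array(NA_real_, c(ny, nx, length(yrs)))
  pv <- array(NA_real_, c(ny, nx, length(yrs)))
  for (j in seq_along(yrs)) {
    ramp <- if (yrs[j] %in% config$study_years)
      config$warming_total * match(yrs[j], config$study_years) / n_study else 0
    tv[, , j] <- base_t + ramp * wf +
      matrix(stats::rnorm(ny * nx, 0, config$noise_sd_t), ny, nx)
    pv[, , j] <- base_p +
      matrix(stats::rnorm(ny * nx, 0, config$noise_sd_p), ny, nx)
  }

  forest_score <- matrix(smooth_field(u, v, n_waves = 8,
                                      freq_scale = config$forest_frag), ny, nx)
  forest <- forest_score <= stats::quantile(forest_score, config$forest_cover)

  # static ancillary layers: soil gradients, a road network, population
  soil_ph <- matrix(6 + 1.2 * smooth_field(u, v), ny, nx)
  soil_cn <- matrix(pmax(8, 18 + 4 * smooth_field(u, v)), ny, nx)
  ext_x <- nx * config$cell_size; ext_y <- ny * config$cell_size
  roads <- lapply(seq_len(6), function(i) {
    if (i %% 2 == 0)
      cbind(c(0, ext_x), stats::runif(2, 0, ext_y))
    else
      cbind(stats::runif(2, 0, ext_x), c(0, ext_y))
  })
  population <- matrix(exp(3 + 1.5 * smooth_field(u, v, freq_scale = 2)),
                       ny, nx)

  structure(
    list(temperature = climate_grid(tv, yrs, config$cell_size),
         precipitation = climate_grid(pv, yrs, config$cell_size,
                                      varname = "precipitation"),
         forest_mask = forest, base_t = base_t, base_p = base_p,
         warm_field = wf, soil_ph = soil_ph, soil_cn = soil_cn,
         roads = roads, population = population, config = config),
    class = "sim_landscape")
}

# Deterministic realized warming at given cells (matrix index) and years.
realized_warming <- function(landscape, rows, cols, years) {
  cfg <- landscape$config
  n_study <- length(cfg$study_years)
  ramp <- ifelse(years %in% cfg$study_years,
                 cfg$warming_total * match(years, cfg$study_years) / n_study, 0)
  ramp * landscape$warm_field[cbind(rows, cols)]
}

#' Generate the synthetic species pool
#'
#' Draws a pool of species with Gaussian (unimodal) niches on the temperature
#' precipitation and soil-pH gradients plus life-history traits: thermal
#' optima uniform across the landscape's baseline temperature range, niche
#' breadths normal (truncated at 0.3 degrees C / 30 mm / 0.4 pH units),
#' longevity log-normal (median 20 y), Ellenberg light values integer 1-9,
#' and a per-species maximum occupancy probability uniform on [0.1, 0.5].
#'
#' @param config a [sim_config].
#' @return A data.frame of class `species_pool` with one row per species:
#'   `species`, `opt_t`, `br_t`, `opt_p`, `br_p`, `opt_ph`, `br_ph`,
#'   `p_max`, `longevity`, `L`.
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$niche_breadth_mean <= 0 || config$precip_breadth_mean <= 0)
    stop("degenerate niche breadth")
  set.seed(derive_seed(config$seed, "pool"))
  n <- config$n_species
  tr <- config$temp_range; pr <- config$precip_range
  opt_t <- if (!is.null(config$forced_opt_t)) {
    if (length(config$forced_opt_t) != n)
      stop("forced_opt_t must have length n_species")
    config$forced_opt_t
  } else stats::runif(n, tr[1], tr[2])
  pool <- data.frame(
    species = sprintf("sp%04d", seq_len(n)),
    opt_t = opt_t,
    br_t = pmax(0.3, stats::rnorm(n, config$niche_breadth_mean,
                                  config$niche_breadth_sd)),
    opt_p = stats::runif(n, pr[1], pr[2]),
    br_p = pmax(30, stats::rnorm(n, config$precip_breadth_mean,
                                 config$precip_breadth_sd)),
    opt_ph = stats::runif(n, 4.5, 7.5),
    br_ph = pmax(0.4, stats::rnorm(n, 1.2, 0.3)),
    p_max = stats::runif(n, 0.1, 0.5),
    longevity = stats::rlnorm(n, log(20), 0.6),
    L = pmin(9L, pmax(1L, round(stats::rnorm(n, 6, 1.6))))
  )
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Assemble synthetic plant communities with a planted climatic debt
#'
#' Places surveys by a Poisson-cluster process, then samples species occupancy
#' from Gaussian niche suitability evaluated at the *effective* temperature
#' `T_eff = T_baseline + (1 - lambda) * dT(cell, year)`, where `dT` is the
#' deterministic realized warming. A community that has only tracked a
#' fraction `1 - lambda` of the warming carries a true climatic debt of
#' `lambda * dT`, which is recorded per survey in the returned `true_state`.
#'
#' Assemblages with fewer than `min_richness` species are re-drawn (new
#' occupancy, then new location) up to `max_attempts` times, mirroring the
#' calibration filter applied to real floristic data.
#'
#' @param landscape a `sim_landscape` from [generate_landscape()].
#' @param pool a `species_pool` from [generate_species_pool()].
#' @param config the same [sim_config] used to build both.
#' @return A list of class `sim_communities`: `surveys` (data.frame: `id`,
#'   `x`, `y`, `year`, `period`, `richness`, `species` semicolon-joined,
#'   `silvp`, `disturb`, `exot`), `occupancy` (named list of species-id
#'   vectors), and `true_state` (data.frame: `id`, `lag_lambda`, `delta_t`,
#'   `true_debt` with `true_debt = lag_lambda * delta_t` exactly).
#' @export
assemble_communities <- function(landscape, pool, config) {
  stopifnot(inherits(landscape, "sim_landscape"),
            inherits(pool, "species_pool"))
  set.seed(derive_seed(config$seed, "communities"))
  nx <- config$grid_nx; ny <- config$grid_ny; cs <- config$cell_size
  ext_x <- nx * cs; ext_y <- ny * cs

  parents <- cbind(stats::runif(config$n_parents, 0, ext_x),
                   stats::runif(config$n_parents, 0, ext_y))
  draw_location <- function() {
    repeat {
      p <- parents[sample.int(config$n_parents, 1L), ]
      x <- p[1] + stats::rnorm(1, 0, config$cluster_sd)
      y <- p[2] + stats::rnorm(1, 0, config$cluster_sd)
      if (x > 0 && x < ext_x && y > 0 && y < ext_y) return(c(x, y))
    }
  }

  years <- c(config$baseline_years, config$study_years)
  counts <- config$n_surveys_per_year[as.character(years)]
  total <- sum(counts)
  ids <- sprintf("su%05d", seq_len(total))
  out_year <- rep(years, counts)

  lam_fun <- if (is.function(config$lag_lambda)) config$lag_lambda
             else function(tb) rep_len(config$lag_lambda, length(tb))

  xs <- ys <- lam <- dts <- tb <- numeric(total)
  occ <- vector("list", total)
  for (i in seq_len(total)) {
    ok <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      loc <- draw_location()
      col <- floor(loc[1] / cs) + 1L; row <- floor(loc[2] / cs) + 1L
      t_base <- landscape$base_t[row, col]
      p_base <- landscape$base_p[row, col]
      dt <- realized_warming(landscape, row, col, out_year[i])
      l <- lam_fun(t_base)
      if (l < 0 || l > 1) stop("lag_lambda evaluated outside [0, 1]")
      t_eff <- t_base + (1 - l) * dt
      ph_loc <- landscape$soil_ph[row, col]
      suit <- pool$p_max *
        exp(-0.5 * ((t_eff - pool$opt_t) / pool$br_t)^2
            - 0.5 * ((p_base - pool$opt_p) / pool$br_p)^2
            - 0.5 * ((ph_loc - pool$opt_ph) / pool$br_ph)^2)
      pres <- stats::runif(nrow(pool)) < suit
      if (sum(pres) >= config$min_richness) {
        xs[i] <- loc[1]; ys[i] <- loc[2]; lam[i] <- l; dts[i] <- dt
        tb[i] <- t_base
        occ[[i]] <- pool$species[pres]
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("empty community after ", config$max_attempts,
                  " resampling attempts (survey ", ids[i], ")")
  }
  names(occ) <- ids

  prev <- config$disturbance_prev
  surveys <- data.frame(
    id = ids, x = xs, y = ys, year = out_year,
    period = ifelse(out_year %in% config$baseline_years, "baseline", "study"),
    richness = lengths(occ),
    species = vapply(occ, paste, "", collapse = ";"),
    silvp = as.integer(stats::runif(total) < prev[["silvp"]]),
    disturb = as.integer(stats::runif(total) < prev[["disturb"]]),
    exot = as.integer(stats::runif(total) < prev[["exot"]])
  )
  true_state <- data.frame(id = ids, baseline_t = tb, lag_lambda = lam,
                           delta_t = dts, true_debt = lam * dts)
  structure(list(surveys = surveys, occupancy = occ, true_state = true_state),
            class = "sim_communities")
}

#' Run the full synthetic debt study
#'
#' Convenience wrapper: landscape, species pool and communities from one
#' configuration.
#'
#' @param config a [sim_config].
#' @return A list with `landscape`, `pool`, `communities` and the `config`.
#' @export
simulate_debt_study <- function(config = sim_config()) {
  landscape <- generate_landscape(config)
  pool <- generate_species_pool(config)
  communities <- assemble_communities(landscape, pool, config)
  list(landscape = landscape, pool = pool, communities = communities,
       config = config)
}

#' Simulate a predictor table with planted covariate effects
#'
#' Generates a per-survey table shaped like the debt-determinants design
#' matrix (response `dT`, the 19 standard covariates, the year term, optional
#' disturbance extras, clustered coordinates, uneven yearly counts) in which
#' the response is a linear combination of the covariates with *known*
#' standardized coefficients plus Gaussian noise.
#'
#' Covariates are drawn from a Gaussian one-factor model whose common factor
#' is a smooth spatial field, so they are both mutually and spatially
#' correlated, and the noise variance is set to `1 - b' S b` (with `S` the
#' covariance of the generated covariates), giving the response unit variance:
#' planted effects are therefore directly on the standardized scale that the
#' regression estimates.
#'
#' @param n number of surveys.
#' @param effects named numeric vector of planted standardized effects;
#'   unnamed covariates get 0. Defaults plant `T = +0.4`, `TO_T = +0.3`,
#'   `NC = -0.25` and leave `road_prox` (and the rest) at zero.
#' @param years study years over which surveys are spread with geometrically
#'   increasing counts.
#' @param factor_loading loading of the shared spatial factor (controls
#'   covariate correlation, about `factor_loading^2` pairwise).
#' @param extras add the `TBUF`/`SILVP`/`DISTURB`/`EXOT` columns used by the
#'   extended model variant.
#' @param extent square landscape edge (metres) for survey placement.
#' @param n_parents,cluster_sd Poisson-cluster placement parameters.
#' @param seed integer seed.
#' @return A data.frame with attributes `effects` (the full planted vector)
#'   and `noise_sd`.
#' @export
simulate_predictor_table <- function(n = 3000,
                                     effects = c(T = 0.4, TO_T = 0.3,
                                                 NC = -0.25, road_prox = 0),
                                     years = 1987:2008,
                                     factor_loading = 0.45,
                                     extras = FALSE,
                                     extent = 3e5, n_parents = 60,
                                     cluster_sd = 8000, seed = 1L) {
  set.seed(derive_seed(seed, "predictors"))
  vars <- c("T", "P", "TC", "PC", "pH", "N", "L", "THET", "TO_T", "TO_W",
            "DC", "NC", "HP", "dHA", "LG", "C_W", "C_N", "road_prox", "HPD")
  if (extras) vars <- c(vars, "TBUF", "SILVP", "DISTURB", "EXOT")
  beta <- stats::setNames(numeric(length(vars) + 1L), c(vars, "year"))
  unknown <- setdiff(names(effects), names(beta))
  if (length(unknown)) stop("unknown covariate(s) in effects: ",
                            paste(unknown, collapse = ", "))
  beta[names(effects)] <- effects

  parents <- cbind(stats::runif(n_parents, 0, extent),
                   stats::runif(n_parents, 0, extent))
  pid <- sample.int(n_parents, n, replace = TRUE)
  x <- pmin(pmax(parents[pid, 1] + stats::rnorm(n, 0, cluster_sd), 0), extent)
  y <- pmin(pmax(parents[pid, 2] + stats::rnorm(n, 0, cluster_sd), 0), extent)

  cnt <- pmax(1L, round(n * 1.08^seq_along(years) /
                          sum(1.08^seq_along(years))))
  year <- rep(years, times = cnt)
  if (length(year) < n)
    year <- c(year, rep(years[length(years)], n - length(year)))
  year <- year[seq_len(n)]

  # shared spatial factor induces covariate and spatial correlation
  fac <- smooth_field(x / extent, y / extent, n_waves = 8, freq_scale = 2)
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  lam <- factor_loading
  for (j in seq_along(vars)) {
    sgn <- if (j %% 2 == 0) -1 else 1
    X[, j] <- sgn * lam * fac + sqrt(1 - lam^2) * stats::rnorm(n)
  }
  if (extras) for (v in c("SILVP", "DISTURB", "EXOT"))
    X[, v] <- as.numeric(X[, v] > stats::quantile(X[, v], 0.75))

  yr_std <- (year - mean(year)) / stats::sd(year)
  Z <- cbind(scale(X), year = yr_std)
  sig2 <- 1 - drop(t(beta) %*% stats::cov(Z) %*% beta)
  if (sig2 <= 0.05)
    stop("planted effects leave too little residual variance")
  dT <- drop(Z %*% beta) + stats::rnorm(n, 0, sqrt(sig2))

  out <- data.frame(id = sprintf("su%05d", seq_len(n)), x = x, y = y,
                    year = year, dT = dT)
  out <- cbind(out, as.data.frame(X))
  attr(out, "effects") <- beta
  attr(out, "noise_sd") <- sqrt(sig2)
  out
}

#' Write a synthetic study to disk
#'
#' Surveys and true state as CSV, climate grids as plain-text grid CSV, the
#' configuration as YAML.
#'
#' @param study result of [simulate_debt_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    surveys = file.path(dir, "surveys.csv"),
    true_state = file.path(dir, "true_state.csv"),
    temperature = file.path(dir, "temperature.csv"),
    precipitation = file.path(dir, "precipitation.csv"),
    config = file.path(dir, "config.yaml")
  )
  utils::write.csv(study$communities$surveys, paths["surveys"],
                   row.names = FALSE)
  utils::write.csv(study$communities$true_state, paths["true_state"],
                   row.names = FALSE)
  write_grid_csv(study$landscape$temperature, paths["temperature"])
  write_grid_csv(study$landscape$precipitation, paths["precipitation"])
  cfg <- study$config
  cfg$lag_lambda <- if (is.function(cfg$lag_lambda)) "function" else
    cfg$lag_lambda
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
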