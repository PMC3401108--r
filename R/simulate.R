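#' Configuration for the synthetic NDVI generator
#'
#' Bundles and validates the parameters of [simulateNdvi()]. The generator
#' emulates a bi-monthly satellite NDVI record: a raised-cosine seasonal cycle
#' whose amplitude varies from year to year, white observation noise, and
#' injected artefacts (transient spikes, runs of negative values, winter
#' negatives at snow-covered sites) whose positions are recorded in a
#' ground-truth ledger.
#'
#' @param n_years number of years of record.
#' @param periods_per_year observations per year (default 24, bi-monthly).
#' @param baseline mean NDVI level, in \[-1, 1\].
#' @param seasonal_amplitude peak-to-baseline seasonal swing (NDVI units).
#' @param peak_period period index at which the seasonal cycle peaks.
#' @param interannual_sd SD of white observation noise (NDVI units).
#' @param year_amplitude_sd SD of the per-year multiplicative amplitude
#'   factor; tunes inter-annual variability (constancy) semi-independently of
#'   the seasonal contrast (contingency).
#' @param spike_rate probability that any single observation is replaced by a
#'   transient spike.
#' @param negative_run_rate probability that a pixel receives one injected run
#'   of >= 3 negative values.
#' @param winter_negative_rate probability that a winter observation of a
#'   northern pixel is made negative (snow signal).
#' @param winter_window period indices counted as winter.
#' @return object of class `"ndvi_gen_config"`.
#' @export
ndviGenConfig <- function(n_years = 27, periods_per_year = 24,
                          baseline = 0.35, seasonal_amplitude = 0.3,
                          peak_period = 13, interannual_sd = 0.02,
                          year_amplitude_sd = 0.15,
                          spike_rate = 0, negative_run_rate = 0,
                          winter_negative_rate = 0,
                          winter_window = c(21:24, 1:9)) {
  if (n_years < 1 || periods_per_year < 2)
    stop("need n_years >= 1 and periods_per_year >= 2")
  if (interannual_sd < 0 || year_amplitude_sd < 0)
    stop("noise SDs must be non-negative")
  if (spike_rate < 0 || spike_rate > 1 || negative_run_rate < 0 ||
      negative_run_rate > 1)
    stop("rates must be probabilities in [0, 1]")
  if (abs(baseline) + seasonal_amplitude > 1 + 1e-12)
    warning("baseline +/- amplitude exceeds [-1, 1]; values will be clipped")
  structure(list(n_years = as.integer(n_years),
                 periods_per_year = as.integer(periods_per_year),
                 baseline = baseline, seasonal_amplitude = seasonal_amplitude,
                 peak_period = peak_period, interannual_sd = interannual_sd,
                 year_amplitude_sd = year_amplitude_sd,
                 spike_rate = spike_rate,
                 negative_run_rate = negative_run_rate,
                 winter_negative_rate = winter_negative_rate,
                 winter_window = as.integer(winter_window)),
            class = "ndvi_gen_config")
}

#' Simulate NDVI pixel series with a ground-truth anomaly ledger
#'
#' Generates `n_pixels` pixel series for one location under a raised-cosine
#' seasonal model: for year y and period p,
#' `ndvi = baseline + A_y * amplitude * (1 + cos(2*pi*(p - peak)/t)) / 2 - amplitude/2 + noise`,
#' where `A_y` is a per-year lognormal amplitude factor. Artefacts are then
#' injected and every injection is recorded, so that downstream screening can
#' be scored against truth. Values are clipped to \[-1, 1\].
#'
#' Spikes are injected only at interior positions with two clean neighbours on
#' each side (the isolated, rapid-return anomaly the screening rules target)
#' and displace the value by 0.4 NDVI units away from its current level.
#'
#' @param config an [ndviGenConfig()].
#' @param n_pixels number of pixels.
#' @param location_id location identifier stamped on the output.
#' @param northern logical: inject negative winter values (snow) at
#'   `winter_negative_rate`.
#' @param seed integer seed; the generator is a pure function of
#'   (config, n_pixels, seed).
#' @return list with `data` (long data.frame location_id, pixel_id, year,
#'   period, ndvi), `clean` (same frame before artefact injection) and
#'   `ledger` (data.frame pixel_id, index, year, period, kind).
#' @export
simulateNdvi <- function(config = ndviGenConfig(), n_pixels = 4,
                         location_id = "loc1", northern = FALSE, seed = 1) {
  stopifnot(inherits(config, "ndvi_gen_config"))
  if (n_pixels < 1) stop("n_pixels must be positive")
  set.seed(seed)
  t <- config$periods_per_year; ny <- config$n_years
  T_ <- t * ny
  period <- rep(seq_len(t), times = ny)
  year <- rep(seq_len(ny), each = t)
  season_shape <- (1 + cos(2 * pi * (period - config$peak_period) / t)) / 2
  rows <- list(); ledger <- list(); clean_rows <- list()
  for (px in seq_len(n_pixels)) {
    pid <- sprintf("%s_px%02d", location_id, px)
    A <- exp(stats::rnorm(ny, 0, config$year_amplitude_sd))
    amp_y <- config$seasonal_amplitude * A[year]
    v <- config$baseline + amp_y * (season_shape - 0.5) +
      stats::rnorm(T_, 0, config$interannual_sd)
    v <- pmin(1, pmax(-1, v))
    clean_rows[[px]] <- v
    # winter negatives (snow): genuine signal at northern sites
    if (northern && config$winter_negative_rate > 0) {
      wmask <- period %in% config$winter_window
      hit <- which(wmask & stats::runif(T_) < config$winter_negative_rate)
      if (length(hit)) {
        v[hit] <- -stats::runif(length(hit), 0.01, 0.1)
        ledger[[length(ledger) + 1L]] <- data.frame(
          pixel_id = pid, index = hit, year = year[hit], period = period[hit],
          kind = "winter_negative", stringsAsFactors = FALSE)
      }
    }
    # one injected negative run per selected pixel
    if (stats::runif(1) < config$negative_run_rate) {
      len <- sample(3:4, 1)
      start <- sample.int(T_ - len + 1L, 1)
      idx <- start:(start + len - 1L)
      v[idx] <- -stats::runif(len, 0.05, 0.2)
      ledger[[length(ledger) + 1L]] <- data.frame(
        pixel_id = pid, index = idx, year = year[idx], period = period[idx],
        kind = "negative_run", stringsAsFactors = FALSE)
    }
    # isolated spikes with clean flanks (no two injections within 2 steps)
    if (config$spike_rate > 0 && T_ >= 5L) {
      cand <- which(stats::runif(T_) < config$spike_rate)
      cand <- cand[cand >= 3L & cand <= T_ - 2L]
      keep <- integer(0)
      for (i in cand)
        if (!length(keep) || i - keep[length(keep)] > 2L)
          keep <- c(keep, i)
      if (length(keep)) {
        dirn <- ifelse(v[keep] > 0, -1, 1)  # push toward the unused range
        v[keep] <- pmin(1, pmax(-1, v[keep] + dirn * 0.4))
        ledger[[length(ledger) + 1L]] <- data.frame(
          pixel_id = pid, index = keep, year = year[keep],
          period = period[keep], kind = "spike", stringsAsFactors = FALSE)
      }
    }
    rows[[px]] <- data.frame(location_id = location_id, pixel_id = pid,
                             year = year, period = period, ndvi = v,
                             stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows); rownames(data) <- NULL
  clean <- data
  clean$ndvi <- unlist(clean_rows)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(pixel_id = character(0), index = integer(0),
               year = integer(0), period = integer(0), kind = character(0))
  rownames(ledger) <- NULL
  list(data = data, clean = clean, ledger = ledger)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate per unit time.
#' @param seed integer seed.
#' @return an ultrametric rooted binary `phylo` object.
#' @export
simulateYuleTree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) stop("n_species must be at least 2")
  set.seed(seed)
  ape::rphylo(n_species, birth = birth_rate, death = 0)
}

#' Configuration for the trait simulator
#'
#' @param beta generating coefficients (intercept, contingency, constancy,
#'   contingency x constancy) on the log-days scale.
#' @param lambda_true phylogenetic signal of the residuals, in \[0, 1\].
#' @param sigma_resid residual SD (log-days) at the tips.
#' @param contingency_range,constancy_range uniform sampling ranges for the
#'   two environmental covariates.
#' @return object of class `"trait_gen_config"`.
#' @export
traitGenConfig <- function(beta = c(9.33, -11.53, -6.18, 7.67),
                           lambda_true = 0.3, sigma_resid = 0.8,
                           contingency_range = c(0, 0.5),
                           constancy_range = c(0, 1)) {
  if (lambda_true < 0 || lambda_true > 1)
    stop("lambda_true must lie in [0, 1]")
  if (sigma_resid <= 0) stop("sigma_resid must be positive")
  if (length(beta) != 4) stop("beta must have 4 elements")
  structure(list(beta = beta, lambda_true = lambda_true,
                 sigma_resid = sigma_resid,
                 contingency_range = contingency_range,
                 constancy_range = constancy_range),
            class = "trait_gen_config")
}

#' Simulate population traits on a phylogeny
#'
#' Draws contingency and constancy uniformly on their configured ranges and
#' generates log birth-season length from the interaction model
#' `log(BSL) = b0 + b1*contingency + b2*constancy + b3*contingency*constancy + e`
#' with `e ~ MVN(0, sigma^2 * V(lambda))`, where V comes from the (typically
#' population-grafted) tree and the lambda transform multiplies its
#' off-diagonal entries. By default V is rescaled to unit height so
#' `sigma_resid` is the tip-level residual SD. Auxiliary life-history
#' covariates (diet, calf behaviour, gregariousness, coordinates) are drawn
#' independently so the full candidate model set can be exercised.
#'
#' @param tree a `phylo` whose tips are the populations.
#' @param config a [traitGenConfig()].
#' @param seed integer seed.
#' @param scale_height rescale V to unit height before applying
#'   `sigma_resid` (default TRUE).
#' @param covariates optional data.frame with columns `population_id`,
#'   `contingency`, `constancy`: use these measured environmental covariates
#'   instead of drawing them uniformly (one row per tip).
#' @return data.frame with one row per tip: population_id, species_id,
#'   contingency, constancy, log_bsl, birth_season_length, latitude,
#'   longitude, diet, calf_behaviour, gregariousness.
#' @export
simulateTraits <- function(tree, config = traitGenConfig(), seed = 1,
                           scale_height = TRUE, covariates = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "trait_gen_config"))
  set.seed(seed)
  n <- length(tree$tip.label)
  V <- phyloCovariance(tree)
  if (scale_height) V <- V / max(diag(V))
  Vl <- lambdaTransform(V, config$lambda_true)
  if (is.null(covariates)) {
    contingency <- stats::runif(n, config$contingency_range[1],
                                config$contingency_range[2])
    constancy <- stats::runif(n, config$constancy_range[1],
                              config$constancy_range[2])
  } else {
    stopifnot(all(c("population_id", "contingency", "constancy") %in%
                  names(covariates)))
    idx <- match(tree$tip.label, covariates$population_id)
    if (anyNA(idx)) stop("covariates missing for some tips")
    contingency <- covariates$contingency[idx]
    constancy <- covariates$constancy[idx]
  }
  X <- cbind(1, contingency, constancy, contingency * constancy)
  mu <- drop(X %*% config$beta)
  L <- t(chol(Vl))
  eps <- config$sigma_resid * drop(L %*% stats::rnorm(n))
  log_bsl <- mu + eps
  species <- sub("_pop[0-9]+$", "", tree$tip.label)
  data.frame(
    population_id = tree$tip.label,
    species_id = species,
    contingency = contingency, constancy = constancy,
    log_bsl = log_bsl,
    birth_season_length = pmin(365, pmax(1, exp(log_bsl))),
    latitude = stats::runif(n, -70, 70),
    longitude = stats::runif(n, -180, 180),
    diet = sample(c("grazer", "mixed", "browser"), n, replace = TRUE),
    calf_behaviour = sample(c("hider", "follower"), n, replace = TRUE),
    gregariousness = sample(1:5, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Write simulated inputs to disk
#'
#' Convenience writer used by the pipeline: long NDVI CSV, Newick tree, trait
#' CSV and anomaly-ledger CSV.
#'
#' @param ndvi,tree,traits,ledger objects as produced by the simulators.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeBundle <- function(ndvi, tree, traits, ledger = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ndvi = file.path(dir, "ndvi.csv"),
             tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.csv"),
             ledger = file.path(dir, "ledger.csv"))
  utils::write.csv(ndvi, paths["ndvi"], row.names = FALSE)
  ape::write.tree(tree, paths["tree"])
  utils::write.csv(traits, paths["traits"], row.names = FALSE)
  if (!is.null(ledger)) utils::write.csv(ledger, paths["ledger"],
                                         row.names = FALSE)
  invisible(paths)
}
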