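#' Replace winter negatives with zero
#'
#' At high-latitude sites, snow cover makes negative NDVI in winter an
#' expected signal rather than an anomaly; such values are set to exactly 0
#' before any other screening so they are not mistaken for sensor artefacts.
#'
#' @param values numeric NDVI vector, ordered in time.
#' @param period integer vector, same length: within-year period index of each
#'   observation.
#' @param winter_window integer vector of period indices counted as winter.
#'   Must span at most half the year (the Nov-May ceiling).
#' @param periods_per_year within-year sampling frequency (used to enforce the
#'   six-month ceiling).
#' @return numeric vector with negative values in the window replaced by 0.
#' @export
zeroWinterNegatives <- function(values, period, winter_window,
                                periods_per_year = 24) {
  if (length(values) != length(period))
    stop("'values' and 'period' must have equal length")
  if (length(winter_window) > periods_per_year / 2)
    stop("winter window spans more than 6 months (",
         length(winter_window), " of ", periods_per_year, " periods)")
  hit <- period %in% winter_window & values < 0
  values[hit] <- 0
  values
}

#' Flag pixels with runs of consecutive negative values
#'
#' A pixel whose series contains three or more consecutive strictly negative
#' NDVI values is considered unreliable (open water, persistent snow or
#' sensor failure) and is dropped from the analysis.
#'
#' @param values numeric NDVI vector, ordered in time.
#' @param min_run run length triggering removal (default 3).
#' @return logical: `TRUE` if the pixel should be removed.
#' @examples
#' flagNegativeRuns(c(0.2, -0.1, -0.1, -0.1, 0.3))  # TRUE
#' flagNegativeRuns(c(0.2, -0.1, -0.1, 0.3))        # FALSE
#' @export
flagNegativeRuns <- function(values, min_run = 3) {
  if (length(values) == 0L) stop("empty series")
  r <- rle(values < 0)
  any(r$values & r$lengths >= min_run)
}

#' Correct transient spikes in an NDVI series
#'
#' Identifies rapid changes of more than `threshold` NDVI units followed by a
#' rapid return to the original level -- the signature of cloud, snow or
#' atmospheric contamination in a single composite -- and replaces them by
#' interpolation from the flanking values. A single-step anomaly at position t
#' (|v_t - v_(t-1)| > threshold with |v_(t+1) - v_(t-1)| <= threshold) is
#' replaced by the mean of its neighbours. Two consecutive anomalous values
#' (both departing from the flanks, with a return at t+2) are each replaced by
#' a weighted average of the flanking values v_(t-1) and v_(t+2) with weights
#' 2/3-1/3 and 1/3-2/3, i.e. linear interpolation across the gap. The pass is
#' applied once, left to right.
#'
#' @param values numeric NDVI vector, ordered in time.
#' @param threshold jump size defining a rapid change (NDVI units).
#' @return list with `values` (corrected vector) and `corrected` (integer
#'   indices that were altered).
#' @examples
#' correctSpikes(c(0.5, 0.8, 0.5))$values        # 0.5 0.5 0.5
#' correctSpikes(c(0.3, 0.9, 0.9, 0.3))$values   # 0.3 0.3 0.3 0.3
#' @export
correctSpikes <- function(values, threshold = 0.25) {
  n <- length(values)
  if (n < 3L) {
    warning("series shorter than 3: spike correction skipped")
    return(list(values = values, corrected = integer(0)))
  }
  v <- values
  corrected <- integer(0)
  t <- 2L
  while (t <= n - 1L) {
    jump <- abs(v[t] - v[t - 1L]) > threshold
    if (jump && abs(v[t + 1L] - v[t - 1L]) <= threshold) {
      # isolated spike: rapid return within one step
      v[t] <- (v[t - 1L] + v[t + 1L]) / 2
      corrected <- c(corrected, t)
      t <- t + 2L
    } else if (jump && t + 2L <= n &&
               abs(v[t + 1L] - v[t + 2L]) > threshold &&
               abs(v[t + 2L] - v[t - 1L]) <= threshold) {
      # paired anomaly: both points off the flanks, return at t+2
      a <- v[t - 1L]; b <- v[t + 2L]
      v[t]      <- (2 * a + b) / 3
      v[t + 1L] <- (a + 2 * b) / 3
      corrected <- c(corrected, t, t + 1L)
      t <- t + 3L
    } else {
      t <- t + 1L
    }
  }
  list(values = v, corrected = corrected)
}

#' Aggregate pixel series to a location series
#'
#' Averages NDVI over the retained pixels of a location at each (year, period)
#' time step. A location keeping fewer than `min_fraction` of its pixels is
#' excluded (a fraction of exactly `min_fraction` is kept: the rule removes
#' locations with *less than* 50\% of pixels remaining).
#'
#' @param px data.frame with columns `pixel_id`, `year`, `period`, `ndvi` for
#'   one location, already screened.
#' @param removed character vector of removed pixel ids.
#' @param min_fraction minimum retained-pixel fraction (default 0.5).
#' @return list with `retained` (logical), `n_pixels_retained`,
#'   `n_pixels_initial`, and `series` (data.frame year, period, ndvi; `NULL`
#'   when excluded).
#' @export
aggregateLocation <- function(px, removed = character(0), min_fraction = 0.5) {
  ids <- unique(px$pixel_id)
  if (length(ids) == 0L) stop("no pixels supplied")
  keep_ids <- setdiff(ids, removed)
  frac <- length(keep_ids) / length(ids)
  if (frac < min_fraction || length(keep_ids) == 0L) {
    return(list(retained = FALSE, n_pixels_retained = length(keep_ids),
                n_pixels_initial = length(ids), series = NULL))
  }
  d <- px[px$pixel_id %in% keep_ids, , drop = FALSE]
  agg <- stats::aggregate(ndvi ~ year + period, data = d, FUN = mean)
  agg <- agg[order(agg$year, agg$period), , drop = FALSE]
  rownames(agg) <- NULL
  list(retained = TRUE, n_pixels_retained = length(keep_ids),
       n_pixels_initial = length(ids), series = agg)
}

#' Smooth and aggregate an NDVI pixel table
#'
#' Runs the full pixel-screening pipeline on a long-format NDVI table and
#' aggregates to location level. Order of operations, applied per pixel:
#' winter zeroing (northern locations only), negative-run removal, spike
#' correction, then pixel-to-location averaging with the 50\% retention rule.
#'
#' @param ndvi data.frame with columns `location_id`, `pixel_id`, `year`,
#'   `period`, `ndvi`, ordered or orderable by (year, period). Pixels may
#'   arrive pre-flagged as water via an optional logical column `water`.
#' @param northern character vector of location_ids where winter negatives
#'   are genuine (snow) and are zeroed rather than treated as anomalies.
#' @param winter_window integer periods counted as winter (default: periods
#'   21-24 and 1-9 of a 24-period year, i.e. Nov-May).
#' @param threshold spike threshold in NDVI units.
#' @param min_fraction minimum fraction of pixels a location must retain.
#' @param periods_per_year within-year sampling frequency.
#' @return list with `series` (long data.frame location_id, year, period,
#'   ndvi over retained locations), `qc` (per-location report: pixel counts,
#'   spike corrections, retention flag), and `pixel_qc` (per-pixel removal
#'   flags and reasons).
#' @export
smoothNdvi <- function(ndvi, northern = character(0),
                       winter_window = c(21:24, 1:9),
                       threshold = 0.25, min_fraction = 0.5,
                       periods_per_year = 24) {
  need <- c("location_id", "pixel_id", "year", "period", "ndvi")
  if (!all(need %in% names(ndvi)))
    stop("'ndvi' must have columns ", paste(need, collapse = ", "))
  has_water <- "water" %in% names(ndvi)
  ser_list <- list(); qc_list <- list(); pqc_list <- list()
  for (loc in unique(ndvi$location_id)) {
    d <- ndvi[ndvi$location_id == loc, , drop = FALSE]
    d <- d[order(d$pixel_id, d$year, d$period), , drop = FALSE]
    removed <- character(0); reasons <- character(0)
    n_spikes <- 0L
    out_px <- list()
    for (pid in unique(d$pixel_id)) {
      p <- d[d$pixel_id == pid, , drop = FALSE]
      if (has_water && any(p$water)) {
        removed <- c(removed, pid); reasons <- c(reasons, "water")
        next
      }
      v <- p$ndvi
      if (loc %in% northern)
        v <- zeroWinterNegatives(v, p$period, winter_window, periods_per_year)
      if (flagNegativeRuns(v)) {
        removed <- c(removed, pid); reasons <- c(reasons, "negative_run")
        next
      }
      cs <- correctSpikes(v, threshold = threshold)
      n_spikes <- n_spikes + length(cs$corrected)
      p$ndvi <- cs$values
      out_px[[pid]] <- p
    }
    keep_df <- if (length(out_px)) do.call(rbind, out_px) else d[0, , drop = FALSE]
    # removed pixels re-appended (uncorrected) so the retention fraction sees
    # the full pixel count; they are excluded from the average by 'removed'
    full_df <- rbind(keep_df[, need], d[d$pixel_id %in% removed, need])
    agg <- aggregateLocation(full_df, removed = removed,
                             min_fraction = min_fraction)
    qc_list[[loc]] <- data.frame(
      location_id = loc,
      n_pixels_initial = agg$n_pixels_initial,
      n_pixels_retained = agg$n_pixels_retained,
      n_spike_corrections = n_spikes,
      retained = agg$retained,
      stringsAsFactors = FALSE)
    if (length(removed))
      pqc_list[[loc]] <- data.frame(location_id = loc, pixel_id = removed,
                                    removal_reason = reasons,
                                    stringsAsFactors = FALSE)
    if (agg$retained) {
      s <- agg$series
      s$location_id <- loc
      ser_list[[loc]] <- s[, c("location_id", "year", "period", "ndvi")]
    }
  }
  series <- if (length(ser_list)) do.call(rbind, ser_list) else
    data.frame(location_id = character(0), year = integer(0),
               period = integer(0), ndvi = numeric(0))
  rownames(series) <- NULL
  qc <- do.call(rbind, qc_list); rownames(qc) <- NULL
  pixel_qc <- if (length(pqc_list)) do.call(rbind, pqc_list) else
    data.frame(location_id = character(0), pixel_id = character(0),
               removal_reason = character(0))
  rownames(pixel_qc) <- NULL
  list(series = series, qc = qc, pixel_qc = pixel_qc)
}
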