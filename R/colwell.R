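#' Discretize an environmental series into states
#'
#' Assigns each observation of a continuous seasonal variable (typically NDVI,
#' bounded in \[-1, 1\]) to one of `n_states` ordered categories, the first
#' step of Colwell's predictability analysis.
#'
#' Three binning schemes are offered. `equal_width_global` divides the fixed
#' NDVI range \[-1, 1\] into equal-width bins; `equal_width_local` divides
#' \[min(x), max(x)\]; `quantile` uses empirical quantiles so states are
#' (approximately) equally occupied. Values falling exactly on an interior bin
#' boundary are assigned to the lower bin; the series maximum joins the top
#' bin.
#'
#' @param x numeric vector of observations.
#' @param n_states integer >= 2, number of states.
#' @param scheme binning scheme, one of `"equal_width_local"`,
#'   `"equal_width_global"`, `"quantile"`.
#' @return integer vector of states in `1:n_states`.
#' @examples
#' discretizeSeries(c(0, 0.5, 1), n_states = 2)
#' @export
discretizeSeries <- function(x, n_states = 8,
                             scheme = c("equal_width_local",
                                        "equal_width_global",
                                        "quantile")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(x) || length(x) == 0L)
    stop("'x' must be a non-empty numeric vector")
  if (anyNA(x)) stop("'x' contains missing values")
  if (n_states < 2) stop("'n_states' must be at least 2")
  edges <- switch(scheme,
    equal_width_global = seq(-1, 1, length.out = n_states + 1L),
    equal_width_local  = seq(min(x), max(x), length.out = n_states + 1L),
    quantile = {
      q <- stats::quantile(x, probs = seq(0, 1, length.out = n_states + 1L),
                           names = FALSE, type = 7)
      if (anyDuplicated(q))
        stop("quantile binning failed: series is constant or nearly so; ",
             "use an equal_width scheme")
      q
    })
  if (edges[1L] == edges[n_states + 1L]) {
    # constant series: every observation occupies a single state
    return(rep.int(1L, length(x)))
  }
  # (e_{j-1}, e_j] intervals: boundary values fall in the lower bin;
  # the minimum (findInterval -> 0) is clamped into state 1
  st <- findInterval(x, edges, left.open = TRUE, all.inside = FALSE)
  st[st < 1L] <- 1L
  st[st > n_states] <- n_states
  as.integer(st)
}

#' Build the state-by-season frequency matrix
#'
#' Cross-tabulates discretized states against time-of-year category, pooling
#' all years, to give the s x t count matrix underlying Colwell's entropies.
#'
#' @param states integer vector of state labels (any coding; levels are taken
#'   from the data unless `n_states` is given).
#' @param period integer vector, same length, the within-year time category of
#'   each observation (1..`periods_per_year`).
#' @param periods_per_year number of time-of-year categories t.
#' @param n_states optional fixed number of state rows s; defaults to the
#'   number of distinct observed states.
#' @return an object of class `"colwell_matrix"`: an s x t integer matrix with
#'   attributes `Z` (grand total), `s`, and `t`.
#' @examples
#' st <- rep(rep(1:2, each = 6), times = 3)   # 3 years, 12 periods
#' per <- rep(1:12, times = 3)
#' frequencyMatrix(st, per, periods_per_year = 12)
#' @export
frequencyMatrix <- function(states, period, periods_per_year,
                            n_states = NULL) {
  if (length(states) != length(period))
    stop("'states' and 'period' must have equal length")
  keep <- !(is.na(states) | is.na(period))
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("frequencyMatrix: skipped ", n_skipped,
            " observations with missing state or period")
  states <- states[keep]; period <- period[keep]
  if (length(states) == 0L) stop("no complete observations")
  if (any(period < 1L | period > periods_per_year))
    stop("'period' values must lie in 1..periods_per_year")
  lev <- sort(unique(states))
  if (!is.null(n_states)) {
    if (any(states < 1L | states > n_states))
      stop("'states' outside 1..n_states")
    lev <- seq_len(n_states)
  }
  N <- table(factor(states, levels = lev),
             factor(period, levels = seq_len(periods_per_year)))
  N <- unclass(matrix(as.integer(N), nrow = length(lev),
                      dimnames = list(state = lev,
                                      period = seq_len(periods_per_year))))
  structure(N, Z = sum(N), s = nrow(N), t = ncol(N),
            class = c("colwell_matrix", "matrix"))
}

# Shannon entropy of a count vector, 0 log 0 = 0 convention
.entropy <- function(counts, Z, base) {
  p <- counts[counts > 0] / Z
  -sum(p * log(p, base = base))
}

#' Colwell's predictability, constancy and contingency
#'
#' Computes Colwell's (1974) information-theoretic partition of environmental
#' predictability from a state-by-season frequency matrix. With column totals
#' \eqn{X_j}, row totals \eqn{Y_i} and grand total Z, the entropies are
#' \eqn{H(X) = -\sum_j (X_j/Z) \log(X_j/Z)},
#' \eqn{H(Y) = -\sum_i (Y_i/Z) \log(Y_i/Z)} and
#' \eqn{H(XY) = -\sum_{ij} (N_{ij}/Z) \log(N_{ij}/Z)}
#' (with the convention \eqn{0 \log 0 = 0}), and
#' \deqn{C = 1 - H(Y)/\log s, \quad M = (H(X) + H(Y) - H(XY))/\log s, \quad
#'       P = 1 - (H(XY) - H(X))/\log s.}
#' Constancy C measures how invariant the state is overall (high C = low
#' inter-annual and seasonal variability); contingency M measures how strongly
#' the state depends on time of year (the strength of seasonality);
#' predictability P = C + M. All three lie in \[0, 1\] and are invariant to
#' the logarithm base because of the \eqn{\log s} normalization.
#'
#' @param N a `"colwell_matrix"` from [frequencyMatrix()], or any non-negative
#'   count matrix (states in rows, time-of-year categories in columns).
#' @param base base of the logarithm (default natural log; the results do not
#'   depend on it).
#' @return an object of class `"colwell"`: a list with elements `C`, `M`, `P`,
#'   `H_X`, `H_Y`, `H_XY`, `s`, `t`, `Z`.
#' @references Colwell, R. K. (1974) Predictability, constancy, and
#'   contingency of periodic phenomena. Ecology 55, 1148-1153.
#' @examples
#' st <- rep(rep(1:2, each = 6), times = 3); per <- rep(1:12, times = 3)
#' colwellMetrics(frequencyMatrix(st, per, 12))
#' @export
colwellMetrics <- function(N, base = exp(1)) {
  N <- as.matrix(N)
  if (any(N < 0)) stop("counts must be non-negative")
  Z <- sum(N)
  if (Z <= 0) stop("frequency matrix has zero total")
  s <- nrow(N)
  if (s < 2) stop("at least 2 states required (constancy undefined for s = 1)")
  X <- colSums(N)  # per time-of-year totals
  Y <- rowSums(N)  # per state totals
  H_X  <- .entropy(X, Z, base)
  H_Y  <- .entropy(Y, Z, base)
  H_XY <- .entropy(N, Z, base)
  logs <- log(s, base = base)
  C <- 1 - H_Y / logs
  M <- (H_X + H_Y - H_XY) / logs
  P <- 1 - (H_XY - H_X) / logs
  structure(list(C = C, M = M, P = P,
                 H_X = H_X, H_Y = H_Y, H_XY = H_XY,
                 s = s, t = ncol(N), Z = Z),
            class = "colwell")
}

#' @export
print.colwell <- function(x, digits = 4, ...) {
  cat("Colwell predictability decomposition\n")
  cat(sprintf("  states s = %d, time categories t = %d, Z = %d observations\n",
              x$s, x$t, as.integer(x$Z)))
  cat(sprintf("  constancy   C = %.*f\n", digits, x$C))
  cat(sprintf("  contingency M = %.*f\n", digits, x$M))
  cat(sprintf("  predictability P = C + M = %.*f\n", digits, x$P))
  invisible(x)
}

#' Per-location Colwell metrics from a smoothed NDVI table
#'
#' Convenience wrapper: discretizes each retained location's series and
#' returns one row of C/M/P per location.
#'
#' @param loc a location-series data frame with columns `location_id`, `year`,
#'   `period`, `ndvi` (e.g. the `series` element returned by [smoothNdvi()]).
#' @param periods_per_year within-year sampling frequency.
#' @param n_states,scheme passed to [discretizeSeries()].
#' @return data.frame with columns location_id, constancy, contingency,
#'   predictability, s, t, Z.
#' @export
locationPredictability <- function(loc, periods_per_year = 24, n_states = 8,
                                   scheme = "equal_width_local") {
  stopifnot(all(c("location_id", "year", "period", "ndvi") %in% names(loc)))
  out <- lapply(split(loc, loc$location_id), function(d) {
    st <- discretizeSeries(d$ndvi, n_states = n_states, scheme = scheme)
    cm <- colwellMetrics(frequencyMatrix(st, d$period, periods_per_year,
                                         n_states = n_states))
    data.frame(location_id = d$location_id[1L],
               constancy = cm$C, contingency = cm$M, predictability = cm$P,
               s = cm$s, t = cm$t, Z = cm$Z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
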