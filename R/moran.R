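#' Spatial weights from geographic coordinates
#'
#' Builds an n x n spatial weight matrix from great-circle (haversine)
#' distances. The k-nearest-neighbour scheme links each point to its k
#' closest neighbours, symmetrizes by the max rule (a link in either
#' direction counts), and row-standardizes by default. The inverse-distance
#' scheme uses 1/d weights; coincident points are separated by a small
#' epsilon offset with a message.
#'
#' @param coords data.frame or matrix with columns `longitude` and `latitude`
#'   in decimal degrees.
#' @param scheme `"knn"` or `"inverse_distance"`.
#' @param k number of neighbours for knn.
#' @param row_standardize divide each nonzero row by its sum.
#' @return list of class `"spatial_weights"`: `W` (matrix), `scheme`, `k`,
#'   `row_standardized`.
#' @export
buildWeights <- function(coords, scheme = c("knn", "inverse_distance"),
                         k = 4, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.data.frame(coords)
  stopifnot(all(c("longitude", "latitude") %in% names(coords)))
  n <- nrow(coords)
  xy <- cbind(coords$longitude, coords$latitude)
  D <- geosphere::distm(xy, fun = geosphere::distHaversine)
  if (scheme == "knn") {
    if (n < k + 1) stop("knn needs at least k + 1 points")
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(k)]
      nb <- seq_len(n)[-i][nb]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))   # symmetrize: neighbour in either direction
  } else {
    if (any(D[upper.tri(D)] == 0)) {
      message("coincident coordinates: adding epsilon offset to distances")
      D[D == 0] <- min(D[D > 0]) * 1e-6
    }
    W <- 1 / D
    diag(W) <- 0
  }
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(list(W = W, scheme = scheme, k = if (scheme == "knn") k else NA,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I with the standard-deviate test
#'
#' Computes Moran's I global spatial autocorrelation statistic
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ab} W_{ab} z_a z_b}{\sum_a z_a^2}}
#' (z = centred values) with its expectation \eqn{E[I] = -1/(n-1)} and the
#' variance under the normality assumption, giving the standard deviate
#' \eqn{z = (I - E[I])/\sqrt{var(I)}} and a two-sided normal p-value. A
#' permutation test is available as a cross-check.
#'
#' @param values numeric vector (n >= 4), e.g. log birth-season length or
#'   model residuals.
#' @param W a `"spatial_weights"` object or a bare weight matrix with zero
#'   diagonal.
#' @param permutations if > 0, also compute a two-sided permutation p-value
#'   from this many random relabellings.
#' @return list of class `"moran"`: `I`, `expected_I`, `variance_I`, `z`,
#'   `p`, and `p_perm` when requested.
#' @export
moransI <- function(values, W, permutations = 0) {
  if (inherits(W, "spatial_weights")) W <- W$W
  W <- as.matrix(W)
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  if (nrow(W) != n || ncol(W) != n) stop("W dimension mismatch")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  zv <- values - mean(values)
  denom <- sum(zv^2)
  if (denom == 0) stop("zero variance in values")
  S0 <- sum(W)
  if (S0 <= 0) stop("total weight is zero")
  obs_I <- function(z) (n / S0) * sum(W * tcrossprod(z)) / sum(z^2)
  I <- obs_I(zv)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(varI)
  p <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  out <- list(I = I, expected_I = EI, variance_I = varI, z = zstat, p = p)
  if (permutations > 0) {
    perm <- replicate(permutations, obs_I(sample(zv)))
    out$p_perm <- (1 + sum(abs(perm - EI) >= abs(I - EI))) /
      (permutations + 1)
  }
  class(out) <- "moran"
  out
}

#' @export
print.moran <- function(x, digits = 4, ...) {
  cat(sprintf("Moran's I = %.*f (expected %.*f, sd %.*f)\n",
              digits, x$I, digits, x$expected_I, digits,
              sqrt(x$variance_I)))
  cat(sprintf("  standard deviate z = %.*f, two-sided p = %.3g\n",
              digits, x$z, x$p))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.3g\n", x$p_perm))
  invisible(x)
}
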