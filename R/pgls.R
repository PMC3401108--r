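#' Candidate model formulas for birth-season length
#'
#' The default candidate set regressing log birth-season length on
#' environmental predictability (contingency = seasonality, constancy =
#' inter-annual stability), latitude and life-history covariates, including
#' the interaction models. `*` expands to both main effects plus their
#' product.
#'
#' @return character vector of 23 model formulas (right-hand sides).
#' @export
candidateModels <- function() {
  c("contingency * constancy",
    "contingency * constancy + gregariousness",
    "contingency + constancy",
    "contingency * constancy + calf_behaviour",
    "contingency + constancy + gregariousness",
    "contingency + constancy + latitude",
    "contingency * constancy + diet",
    "contingency + constancy + calf_behaviour",
    "contingency + constancy + diet",
    "latitude + contingency",
    "latitude + contingency + calf_behaviour",
    "latitude + contingency + diet",
    "latitude + contingency + gregariousness",
    "latitude + contingency * diet",
    "latitude",
    "contingency",
    "latitude + constancy",
    "latitude + diet",
    "latitude + constancy + diet",
    "latitude + constancy * diet",
    "constancy",
    "calf_behaviour",
    "diet")
}

#' Build a design matrix from a trait table
#'
#' Treatment (reference-level) coding with fixed, documented reference
#' levels: diet reference = browser, calf behaviour reference = follower.
#' Gregariousness enters as a numeric covariate, latitude as absolute
#' latitude (distance from the equator). Interaction columns are elementwise
#' products of the main-effect columns; the intercept column comes first.
#'
#' @param data trait data.frame (columns among contingency, constancy,
#'   latitude, diet, calf_behaviour, gregariousness).
#' @param formula_rhs right-hand side of the model formula as a string, e.g.
#'   `"contingency * constancy"`.
#' @return numeric design matrix with labelled columns.
#' @export
designMatrix <- function(data, formula_rhs) {
  d <- data
  if ("latitude" %in% names(d)) d$latitude <- abs(d$latitude)
  if ("diet" %in% names(d)) {
    bad <- setdiff(unique(d$diet), c("browser", "grazer", "mixed"))
    if (length(bad)) stop("unknown diet level(s): ", paste(bad, collapse = ", "))
    d$diet <- factor(d$diet, levels = c("browser", "grazer", "mixed"))
  }
  if ("calf_behaviour" %in% names(d)) {
    bad <- setdiff(unique(d$calf_behaviour), c("follower", "hider"))
    if (length(bad))
      stop("unknown calf_behaviour level(s): ", paste(bad, collapse = ", "))
    d$calf_behaviour <- factor(d$calf_behaviour,
                               levels = c("follower", "hider"))
  }
  if ("gregariousness" %in% names(d))
    d$gregariousness <- as.numeric(d$gregariousness)
  f <- stats::as.formula(paste("~", formula_rhs))
  used <- all.vars(f)
  miss <- used[!used %in% names(d)]
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(d[used])) stop("missing values in model columns")
  stats::model.matrix(f, data = d)
}

# GLS core for a fixed covariance structure V (ML):
# beta = (X'V^-1 X)^-1 X'V^-1 y via Cholesky whitening; sigma2_ML = RSS_w/n.
.glsCore <- function(X, y, V) {
  n <- length(y); p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite"))
  Xw <- forwardsolve(t(R), X)
  yw <- forwardsolve(t(R), y)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < p)
    stop("singular design: collinear columns ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  beta <- solve(qrX, crossprod(Xw, yw))
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  ll <- if (sigma2_ml > 0)
    -0.5 * (n * log(2 * pi * sigma2_ml) + n + logdetV) else Inf
  list(beta = drop(beta), rss = rss, sigma2 = sigma2_ml, logLik = ll,
       XtX_inv = solve(qrX, diag(p)), resid_w = drop(rw),
       fitted_w = drop(Xw %*% beta), yw = yw, logdetV = logdetV)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Fits the linear model `y = X b + e`, `e ~ MVN(0, sigma2 * V(lambda))`,
#' where `V(lambda)` is the lambda transform of a phylogenetic covariance
#' matrix. For fixed lambda the GLS estimates are analytic; lambda is
#' estimated by maximizing the profile log-likelihood on \[0, 1\]
#' (`lambda = "ML"`), or can be fixed. Standard errors use the
#' `sigma2` estimate with the `n - p` denominator; t statistics are compared
#' to a Student t with `n - p` degrees of freedom. AICc counts the
#' regression coefficients, sigma2 and (when estimated) lambda.
#'
#' @param formula_rhs model right-hand side (string), see [designMatrix()].
#' @param data trait data.frame; the response column is `response` (default
#'   `"log_bsl"`).
#' @param V phylogenetic covariance matrix with dimnames matching
#'   `data[[id_col]]`, or a `phylo` tree.
#' @param response name of the response column.
#' @param id_col column holding tip identifiers (default `"population_id"`).
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param method `"ML"` (default) or `"REML"` for the variance/likelihood.
#' @param tol optimizer tolerance for lambda.
#' @return object of class `"pgls"`; see [summary.pgls()]. Key elements:
#'   `coefficients` (data.frame estimate/SE/t/P), `lambda`, `sigma2`,
#'   `logLik`, `k`, `AIC`, `AICc`, `adj_r_squared`.
#' @export
pglsFit <- function(formula_rhs, data, V, response = "log_bsl",
                    id_col = "population_id", lambda = "ML",
                    method = c("ML", "REML"), tol = 1e-8) {
  method <- match.arg(method)
  if (inherits(V, "phylo")) V <- phyloCovariance(V)
  if (!response %in% names(data)) stop("response column '", response,
                                       "' not found")
  if (!is.null(dimnames(V)) && id_col %in% names(data)) {
    ids <- as.character(data[[id_col]])
    if (!setequal(ids, rownames(V)))
      stop("tip labels of V do not match data[['", id_col, "']]")
    V <- V[ids, ids]
  } else if (nrow(V) != nrow(data)) {
    stop("dimension of V does not match the data")
  }
  X <- designMatrix(data, formula_rhs)
  y <- as.numeric(data[[response]])
  n <- length(y); p <- ncol(X)
  est_lambda <- identical(lambda, "ML")
  profile <- function(l) .glsCore(X, y, lambdaTransform(V, l))$logLik
  if (est_lambda) {
    opt <- stats::optimize(profile, c(0, 1), maximum = TRUE, tol = tol)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, profile(0), profile(1))
    lambda_hat <- cand[which.max(ll)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"ML\" or a number in [0, 1]")
    lambda_hat <- lambda
  }
  core <- .glsCore(X, y, lambdaTransform(V, lambda_hat))
  k <- p + 1 + as.integer(est_lambda)     # beta, sigma2 (+ lambda)
  if (n <= k + 1) stop("too few observations for AICc (n <= k + 1)")
  sigma2_inf <- core$rss / (n - p)        # denominator for inference
  se <- sqrt(sigma2_inf * diag(core$XtX_inv))
  tval <- core$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  logLik <- core$logLik
  sigma2 <- core$sigma2
  if (method == "REML") {
    Vl <- lambdaTransform(V, lambda_hat)
    R <- chol(Vl); Xw <- forwardsolve(t(R), X)
    sigma2 <- core$rss / (n - p)
    logLik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
                      core$logdetV + determinant(crossprod(Xw))$modulus[1])
  }
  AIC <- 2 * k - 2 * logLik
  AICc <- AIC + 2 * k * (k + 1) / (n - k - 1)
  r2 <- stats::cor(core$yw, core$fitted_w)^2
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  out <- list(
    formula_rhs = formula_rhs,
    coefficients = data.frame(term = colnames(X), estimate = core$beta,
                              se = se, t = tval, p = pval,
                              row.names = NULL, stringsAsFactors = FALSE),
    lambda = lambda_hat, lambda_estimated = est_lambda,
    sigma2 = sigma2, logLik = logLik, k = k, n = n, p = p,
    AIC = AIC, AICc = AICc,
    r_squared = r2, adj_r_squared = adj_r2,
    method = method,
    residuals_w = core$resid_w, fitted_w = core$fitted_w,
    X = X, y = y, V = V)
  class(out) <- "pgls"
  out
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("PGLS fit: log response ~", x$formula_rhs, "\n")
  cat(sprintf("  n = %d, lambda = %.*f%s, sigma2 = %.*f (%s)\n",
              x$n, digits, x$lambda,
              if (x$lambda_estimated) " (ML)" else " (fixed)",
              digits, x$sigma2, x$method))
  cat(sprintf("  logLik = %.*f, k = %d, AICc = %.*f, adj R2 = %.*f\n",
              digits, x$logLik, x$k, digits, x$AICc, digits,
              x$adj_r_squared))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  print(object)
  co <- object$coefficients
  co$p <- format.pval(co$p, digits = 3)
  print(co, digits = 4)
  invisible(object)
}

#' Residuals of a PGLS fit on the original (unwhitened) scale
#' @param object a `pgls` fit.
#' @param ... unused.
#' @export
residuals.pgls <- function(object, ...) {
  drop(object$y - object$X %*% object$coefficients$estimate)
}

#' Compare candidate PGLS models by AICc
#'
#' Fits each candidate formula (by default re-estimating lambda per model)
#' and ranks them by small-sample-corrected AIC.
#'
#' @param data trait data.frame.
#' @param V phylogenetic covariance matrix or `phylo`.
#' @param formulas character vector of model right-hand sides.
#' @param ... passed to [pglsFit()].
#' @return data.frame (model, lambda, logLik, k, AICc, dAICc) sorted by
#'   AICc; inestimable models are dropped with a message.
#' @export
modelComparison <- function(data, V, formulas = candidateModels(), ...) {
  rows <- list()
  for (f in formulas) {
    fit <- tryCatch(pglsFit(f, data, V, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      message("skipping model '", f, "': ", conditionMessage(fit))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(model = f, lambda = fit$lambda,
                            logLik = fit$logLik, k = fit$k, AICc = fit$AICc,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no estimable models")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  tab
}

#' Simple regression and correlation helpers
#'
#' `simpleRegression` fits `y ~ x` by ordinary least squares and reports the
#' slope with its SE, t, two-sided P and the R-squared; `pearsonCor` reports
#' Pearson's r with its t test. Both wrap the base fitting routines.
#'
#' @param x,y numeric vectors.
#' @return `simpleRegression`: list (slope, se, t, p, r_squared, intercept);
#'   `pearsonCor`: list (r, t, p, r_squared).
#' @export
simpleRegression <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  list(slope = co["x", "Estimate"], se = co["x", "Std. Error"],
       t = co["x", "t value"], p = co["x", "Pr(>|t|)"],
       r_squared = summary(fit)$r.squared,
       intercept = co["(Intercept)", "Estimate"])
}

#' @rdname simpleRegression
#' @export
pearsonCor <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = ct$p.value, r_squared = unname(ct$estimate)^2)
}

#' Prediction surface over the environmental covariates
#'
#' Evaluates a fitted interaction model on a regular grid of contingency and
#' constancy values (defaults matching the observed covariate ranges:
#' contingency 0-0.5, constancy 0-1), holding any other covariates at their
#' sample means / reference levels.
#'
#' @param fit a `pgls` fit of a model containing contingency and constancy.
#' @param contingency,constancy grid vectors.
#' @return data.frame (contingency, constancy, predicted_log_bsl).
#' @export
predictionSurface <- function(fit,
                              contingency = seq(0, 0.5, length.out = 26),
                              constancy = seq(0, 1, length.out = 26)) {
  stopifnot(inherits(fit, "pgls"))
  grid <- expand.grid(contingency = contingency, constancy = constancy)
  co <- fit$coefficients
  pred <- rep(0, nrow(grid))
  for (i in seq_len(nrow(co))) {
    term <- co$term[i]; b <- co$estimate[i]
    val <- switch(term,
      "(Intercept)" = 1,
      "contingency" = grid$contingency,
      "constancy" = grid$constancy,
      "contingency:constancy" = grid$contingency * grid$constancy,
      {
        # other covariates held at their sample mean column value
        mean(fit$X[, term])
      })
    pred <- pred + b * val
  }
  grid$predicted_log_bsl <- pred
  grid
}
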