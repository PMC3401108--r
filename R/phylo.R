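#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that enforce
#' the package's contract: branch lengths present, tip labels unique.
#'
#' @param text a Newick string, or `file` a path.
#' @param file optional path to read from instead of `text`.
#' @return `readNewick`: a `phylo`; `writeNewick`: a Newick string.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else
    ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

# escape a tip label for use in a regular expression
.rxEscape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Graft populations onto a species tree
#'
#' Replaces each species tip that hosts two or more study populations by a
#' polytomy of population tips attached with near-zero branch lengths
#' (within-species phylogenetic distance is taken to be approximately zero).
#' Species with a single population keep the topology and are simply
#' relabelled. A strictly zero epsilon would make the phylogenetic covariance
#' matrix singular, so requests for `epsilon = 0` are replaced by
#' `1e-6 * tree height` with a warning; that is also the default.
#'
#' @param tree species-level `phylo`.
#' @param mapping data.frame with columns `population_id` and `species_id`.
#' @param epsilon branch length for the population tips (time units).
#' @return a `phylo` whose tips are the populations.
#' @export
graftPopulations <- function(tree, mapping, epsilon = NULL) {
  stopifnot(inherits(tree, "phylo"),
            all(c("population_id", "species_id") %in% names(mapping)))
  if (anyDuplicated(mapping$population_id))
    stop("duplicate population_id in mapping")
  height <- max(ape::node.depth.edgelength(tree))
  if (is.null(epsilon)) epsilon <- 1e-6 * height
  if (epsilon <= 0) {
    warning("epsilon must be positive; using 1e-6 * tree height")
    epsilon <- 1e-6 * height
  }
  missing_sp <- setdiff(unique(mapping$species_id), tree$tip.label)
  if (length(missing_sp))
    stop("species not found in tree: ", paste(missing_sp, collapse = ", "))
  txt <- ape::write.tree(tree)
  for (sp in unique(mapping$species_id)) {
    pops <- mapping$population_id[mapping$species_id == sp]
    pat <- paste0("([(,])", .rxEscape(sp), ":")
    if (length(pops) == 1L) {
      repl <- paste0("\\1", pops, ":")
    } else {
      poly <- paste0(pops, ":", format(epsilon, scientific = FALSE,
                                       digits = 15),
                     collapse = ",")
      repl <- paste0("\\1(", poly, "):")
    }
    new_txt <- sub(pat, repl, txt)
    if (identical(new_txt, txt))
      stop("failed to graft species tip: ", sp)
    txt <- new_txt
  }
  out <- ape::read.tree(text = txt)
  extra <- setdiff(out$tip.label, mapping$population_id)
  if (length(extra))
    out <- ape::drop.tip(out, extra)
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of two tips equals the shared path
#' length from the root to their most recent common ancestor; the diagonal
#' holds root-to-tip distances.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return n x n matrix with tip labels as dimnames.
#' @export
phyloCovariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the full Brownian structure, `lambda = 0`
#' a star phylogeny (independent tips).
#'
#' @param V phylogenetic covariance matrix.
#' @param lambda signal strength in \[0, 1\].
#' @return transformed matrix.
#' @export
lambdaTransform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}

# ML profile of (z0, sigma2) for fixed covariance structure V:
# z0 = (1'V^-1 1)^-1 1'V^-1 y,  sigma2 = r'V^-1 r / n,
# logLik = -(n/2)(log 2*pi*sigma2 + 1) - (1/2) log|V|
# computed via Cholesky, no explicit inverse.
.profileLogLik <- function(y, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite; ",
         "try a larger grafting epsilon"))
  one <- rep(1, n)
  w_y <- backsolve(R, forwardsolve(t(R), y))
  w_1 <- backsolve(R, forwardsolve(t(R), one))
  z0 <- sum(w_y) / sum(w_1)
  r <- y - z0
  w_r <- backsolve(R, forwardsolve(t(R), r))
  sigma2 <- sum(r * w_r) / n
  logdetV <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n + logdetV)
  list(z0 = z0, sigma2 = sigma2, logLik = ll)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits one of three single-trait evolutionary models on a phylogeny by
#' maximizing the multivariate-normal likelihood with mean `z0 * 1` and
#' covariance `sigma2 * V(model)`:
#' \describe{
#'   \item{BM}{Brownian motion, V from the tree (k = 2 parameters).}
#'   \item{white}{no phylogenetic structure, V = I (k = 2).}
#'   \item{lambda}{Pagel's lambda transform of the Brownian V, lambda
#'     estimated on \[0, 1\] by bounded optimization over the analytic
#'     profile of (z0, sigma2) (k = 3).}
#' }
#'
#' @param tree rooted `phylo` whose tips carry the trait.
#' @param trait named numeric vector (names = tip labels) or unnamed vector
#'   in tip order.
#' @param model `"BM"`, `"white"` or `"lambda"`.
#' @param tol optimizer tolerance for lambda.
#' @return object of class `"evo_fit"`: list with `model`, `z0`, `sigma2`,
#'   `lambda` (lambda model only), `logLik`, `k`, `AIC`.
#' @export
fitEvoModel <- function(tree, trait, model = c("lambda", "BM", "white"),
                        tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3) stop("need at least 3 tips")
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label))
      stop("trait names do not match tip labels")
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n) {
    stop("trait length does not match tip count")
  }
  y <- as.numeric(trait)
  V <- phyloCovariance(tree)
  fit <- switch(model,
    BM = c(.profileLogLik(y, V), lambda = NA_real_, k = 2),
    white = c(.profileLogLik(y, diag(n)), lambda = NA_real_, k = 2),
    lambda = {
      obj <- function(l) .profileLogLik(y, lambdaTransform(V, l))$logLik
      opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                             tol = tol)
      # guard against boundary optima missed by golden-section search
      cand <- c(opt$maximum, 0, 1)
      ll <- c(opt$objective, obj(0), obj(1))
      lhat <- cand[which.max(ll)]
      c(.profileLogLik(y, lambdaTransform(V, lhat)), lambda = lhat, k = 3)
    })
  out <- list(model = model, z0 = fit$z0, sigma2 = fit$sigma2,
              lambda = fit$lambda, logLik = fit$logLik, k = fit$k,
              AIC = 2 * fit$k - 2 * fit$logLik, n = n)
  class(out) <- "evo_fit"
  out
}

#' @export
print.evo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Evolutionary model fit (%s), n = %d tips\n", x$model, x$n))
  cat(sprintf("  z0 = %.*f, sigma2 = %.*f", digits, x$z0, digits, x$sigma2))
  if (!is.na(x$lambda)) cat(sprintf(", lambda = %.*f", digits, x$lambda))
  cat(sprintf("\n  logLik = %.*f, k = %d, AIC = %.*f\n",
              digits, x$logLik, x$k, digits, x$AIC))
  invisible(x)
}

#' Compare trait-evolution models by AIC
#'
#' @param tree,trait as in [fitEvoModel()].
#' @param models character vector of models to compare.
#' @return data.frame (model, logLik, k, AIC, dAIC) sorted by AIC.
#' @export
compareEvoModels <- function(tree, trait,
                             models = c("lambda", "BM", "white")) {
  fits <- lapply(models, function(m) fitEvoModel(tree, trait, model = m))
  tab <- data.frame(model = models,
                    logLik = vapply(fits, `[[`, 0, "logLik"),
                    k = vapply(fits, `[[`, 0, "k"),
                    lambda = vapply(fits, `[[`, 0, "lambda"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  rownames(tab) <- NULL
  tab
}
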