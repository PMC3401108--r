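test_that("Newick round trip preserves topology and branch lengths", {
  tr <- readNewick("(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2L)
  big <- simulateYuleTree(64, seed = 13)
  rt <- readNewick(writeNewick(big))
  expect_equal(ape::cophenetic.phylo(rt)[big$tip.label, big$tip.label],
               ape::cophenetic.phylo(big), tolerance = 1e-10)
  expect_error(readNewick("(A:1,A:1);"), "duplicate tip labels: A")
  expect_error(readNewick("((A:1,B:2);"), "parse|Newick|failed")
})

test_that("population grafting builds near-zero polytomies", {
  tr <- simulateYuleTree(4, seed = 2)
  mp <- data.frame(
    population_id = c("t1_a", "t1_b", "t1_c", "t2_a", "t3_a", "t4_a"),
    species_id = c("t1", "t1", "t1", "t2", "t3", "t4"))
  g <- graftPopulations(tr, mp)
  expect_setequal(g$tip.label, mp$population_id)
  V <- phyloCovariance(g)
  h <- max(ape::node.depth.edgelength(tr))
  # populations of one species share the full species-tip covariance
  Vsp <- phyloCovariance(tr)
  expect_equal(V["t1_a", "t1_b"], Vsp["t1", "t1"], tolerance = 1e-9)
  expect_equal(V["t1_a", "t2_a"], Vsp["t1", "t2"], tolerance = 1e-9)
  # epsilon default keeps V positive definite
  expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)
  # single-population species: same topology, new labels
  mp1 <- data.frame(population_id = paste0(tr$tip.label, "_x"),
                    species_id = tr$tip.label)
  g1 <- graftPopulations(tr, mp1)
  expect_equal(g1$Nnode, tr$Nnode)
  expect_equal(sort(g1$edge.length), sort(tr$edge.length))
  # zero epsilon is replaced with a warning
  expect_warning(g0 <- graftPopulations(tr, mp, epsilon = 0), "positive")
  expect_gt(min(eigen(phyloCovariance(g0), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(graftPopulations(tr, data.frame(population_id = "p",
                                               species_id = "nope")),
               "nope")
})

test_that("phylogenetic covariance encodes shared path lengths", {
  # star covariance: all tips attach at the root (zero shared history)
  star <- readNewick("((A:2,B:2):0,C:2);")
  expect_equal(unname(phyloCovariance(star)), 2 * diag(3))
  expect_error(phyloCovariance(ape::unroot(ape::rtree(5))), "rooted")
  tr <- readNewick("((A:1,B:1):1,C:2);")
  V <- phyloCovariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)
  # PSD across random trees
  set.seed(3)
  for (i in 1:100) {
    rt <- ape::rtree(sample(4:20, 1))
    ev <- eigen(phyloCovariance(rt), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("lambda transform scales only the off-diagonal", {
  V <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(lambdaTransform(V, 1), V)
  expect_equal(lambdaTransform(V, 0), diag(c(2, 2)))
  half <- lambdaTransform(V, 0.5)
  expect_equal(half[1, 2], 0.5)
  expect_equal(diag(half), c(2, 2))
  expect_error(lambdaTransform(V, 1.2), "lambda")
})

test_that("evolutionary-model likelihoods match the brute-force oracle", {
  set.seed(5)
  for (n in c(4, 7, 10)) {
    tr <- simulateYuleTree(n, seed = n)
    y <- setNames(rnorm(n, 3, 1), tr$tip.label)
    V <- phyloCovariance(tr)
    bm <- fitEvoModel(tr, y, "BM")
    expect_equal(bm$logLik,
                 mvn_loglik(y, rep(bm$z0, n), bm$sigma2 * V),
                 tolerance = 1e-8)
    wh <- fitEvoModel(tr, y, "white")
    expect_equal(wh$logLik,
                 mvn_loglik(y, rep(wh$z0, n), wh$sigma2 * diag(n)),
                 tolerance = 1e-8)
    lm_ <- fitEvoModel(tr, y, "lambda")
    expect_equal(lm_$logLik,
                 mvn_loglik(y, rep(lm_$z0, n),
                            lm_$sigma2 * lambdaTransform(V, lm_$lambda)),
                 tolerance = 1e-8)
    # nesting: the lambda profile at 1 equals the BM likelihood, and at 0 on
    # a unit-height ultrametric tree equals white noise
    expect_gte(lm_$logLik, bm$logLik - 1e-8)
  }
  tr <- simulateYuleTree(12, seed = 1)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  y <- setNames(rnorm(12), tr$tip.label)
  V <- phyloCovariance(tr)
  prof1 <- phenosync:::.profileLogLik(y, lambdaTransform(V, 1))
  prof0 <- phenosync:::.profileLogLik(y, lambdaTransform(V, 0))
  expect_equal(prof1$logLik, fitEvoModel(tr, y, "BM")$logLik,
               tolerance = 1e-10)
  expect_equal(prof0$logLik, fitEvoModel(tr, y, "white")$logLik,
               tolerance = 1e-10)
})

test_that("AIC bookkeeping and model comparison are consistent", {
  tr <- simulateYuleTree(16, seed = 6)
  set.seed(6)
  y <- setNames(rnorm(16), tr$tip.label)
  tab <- compareEvoModels(tr, y)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_equal(tab$dAIC[1], 0)
  expect_true(!is.unsorted(tab$AIC))
  fit <- fitEvoModel(tr, y, "lambda")
  expect_equal(fit$k, 3)
  expect_error(fitEvoModel(tr, y[-1], "BM"), "match tip labels|length")
})

test_that("ML lambda is recovered from simulated data (quick check)", {
  err <- sapply(c(0, 1), function(l_true) {
    est <- sapply(1:25, function(r) {
      tr <- simulateYuleTree(64, seed = 500 * l_true + r)
      V <- lambdaTransform(phyloCovariance(tr), l_true)
      set.seed(900 + r)
      y <- setNames(drop(t(chol(V)) %*% rnorm(64)), tr$tip.label)
      fitEvoModel(tr, y, "lambda")$lambda
    })
    mean(abs(est - l_true))
  })
  expect_lt(err[1], 0.15)
  expect_lt(err[2], 0.15)
})
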