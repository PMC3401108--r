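test_that("design matrix uses documented treatment coding", {
  d <- data.frame(contingency = c(0.1, 0.2, 0.3),
                  constancy = c(0.5, 0.6, 0.7),
                  latitude = c(-10, 20, 30),
                  diet = c("browser", "grazer", "mixed"),
                  calf_behaviour = c("follower", "hider", "hider"),
                  gregariousness = c(1, 3, 5))
  X <- designMatrix(d, "contingency * constancy + diet + calf_behaviour +
                         gregariousness + latitude")
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_equal(unname(X[, "contingency:constancy"]),
               d$contingency * d$constancy)
  # 3 diet levels -> 2 indicators, browser as reference
  expect_equal(unname(X[, "dietgrazer"]), c(0, 1, 0))
  expect_equal(unname(X[, "dietmixed"]), c(0, 0, 1))
  expect_equal(unname(X[, "calf_behaviourhider"]), c(0, 1, 1))
  # latitude enters as absolute distance from the equator
  expect_equal(unname(X[, "latitude"]), c(10, 20, 30))
  expect_equal(ncol(designMatrix(d, "1")), 1L)
  d$diet[1] <- "frugivore"
  expect_error(designMatrix(d, "diet"), "frugivore")
})

test_that("PGLS with identity covariance reproduces OLS exactly", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    d <- data.frame(population_id = paste0("p", 1:n),
                    contingency = runif(n, 0, 0.5),
                    constancy = runif(n),
                    log_bsl = rnorm(n, 4, 1))
    V <- diag(n); dimnames(V) <- list(d$population_id, d$population_id)
    fit <- pglsFit("contingency * constancy", d, V, lambda = 1)
    ols <- summary(lm(log_bsl ~ contingency * constancy, data = d))
    expect_equal(fit$coefficients$estimate,
                 unname(ols$coefficients[, "Estimate"]), tolerance = 1e-8)
    expect_equal(fit$coefficients$se,
                 unname(ols$coefficients[, "Std. Error"]), tolerance = 1e-8)
    expect_equal(fit$coefficients$t,
                 unname(ols$coefficients[, "t value"]), tolerance = 1e-8)
    expect_equal(fit$coefficients$p,
                 unname(ols$coefficients[, "Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("PGLS profile likelihood matches the direct MVN oracle", {
  set.seed(11)
  gr <- make_grafted(5, 2, seed = 11)       # 10 tips
  V <- phyloCovariance(gr$grafted)
  d <- data.frame(population_id = gr$grafted$tip.label,
                  contingency = runif(10, 0, 0.5), constancy = runif(10),
                  log_bsl = rnorm(10, 4, 1))
  for (lam in c(0, 0.37, 1)) {
    fit <- pglsFit("contingency + constancy", d, V, lambda = lam)
    X <- designMatrix(d, "contingency + constancy")
    mu <- drop(X %*% fit$coefficients$estimate)
    Vl <- lambdaTransform(V[d$population_id, d$population_id], lam)
    expect_equal(fit$logLik, mvn_loglik(d$log_bsl, mu, fit$sigma2 * Vl),
                 tolerance = 1e-8)
  }
})

test_that("noiseless data is fit exactly and ML lambda maximizes profile", {
  gr <- make_grafted(20, 2, seed = 12)
  V <- phyloCovariance(gr$grafted)
  n <- 40
  set.seed(12)
  d <- data.frame(population_id = gr$grafted$tip.label,
                  contingency = runif(n, 0, 0.5), constancy = runif(n))
  b <- c(9, -11, -6, 7)
  X <- designMatrix(d, "contingency * constancy")
  d$log_bsl <- drop(X %*% b) + 0.5 * rnorm(n)
  fit <- pglsFit("contingency * constancy", d, V)
  # ML lambda beats a grid of fixed-lambda fits
  grid_ll <- sapply(seq(0, 1, by = 0.1), function(l)
    pglsFit("contingency * constancy", d, V, lambda = l)$logLik)
  expect_gte(fit$logLik, max(grid_ll) - 1e-6)
  # exact-fit degenerate case
  d2 <- d; d2$log_bsl <- drop(X %*% b)
  fit2 <- pglsFit("contingency * constancy", d2, V, lambda = 0.5)
  expect_equal(fit2$coefficients$estimate, b, tolerance = 1e-6)
  expect_lt(fit2$sigma2, 1e-12)
})

test_that("AICc corrects AIC by the small-sample term", {
  gr <- make_grafted(25, 2, seed = 14)
  V <- phyloCovariance(gr$grafted)
  set.seed(14)
  d <- data.frame(population_id = gr$grafted$tip.label,
                  contingency = runif(50, 0, 0.5), constancy = runif(50),
                  log_bsl = rnorm(50, 4))
  fit <- pglsFit("contingency + constancy", d, V)
  expect_equal(fit$AICc - fit$AIC,
               2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1))
  expect_equal(fit$k, fit$p + 2)
  fixed <- pglsFit("contingency + constancy", d, V, lambda = 0.5)
  expect_equal(fixed$k, fixed$p + 1)   # lambda not counted when fixed
})

test_that("model comparison ranks deterministically and drops bad specs", {
  gr <- make_grafted(20, 2, seed = 15)
  V <- phyloCovariance(gr$grafted)
  tt <- simulateTraits(gr$grafted, traitGenConfig(), seed = 15)
  tab <- modelComparison(tt, V, formulas = c("contingency", "contingency",
                                             "constancy"))
  expect_equal(tab$AICc[tab$model == "contingency"][1],
               tab$AICc[tab$model == "contingency"][2])
  expect_true(!is.unsorted(tab$AICc))
  expect_equal(tab$dAICc[1], 0)
  # inestimable model is skipped with a message, not an error
  tt$dup <- tt$contingency
  expect_message(tab2 <- modelComparison(tt, V,
                                         formulas = c("contingency + dup",
                                                      "contingency")),
                 "skipping")
  expect_equal(tab2$model, "contingency")
})

test_that("the generating interaction model wins AICc on its own data", {
  gr <- make_grafted(35, 2, seed = 16)
  V <- phyloCovariance(gr$grafted)
  wins <- 0L
  formulas <- c("contingency * constancy", "contingency + constancy",
                "contingency", "constancy", "latitude",
                "contingency * constancy + gregariousness")
  for (r in 1:20) {
    tt <- simulateTraits(gr$grafted, traitGenConfig(), seed = 300 + r)
    tab <- modelComparison(tt, V, formulas = formulas)
    wins <- wins + (tab$model[1] == "contingency * constancy")
  }
  expect_gt(wins, 10)
})

test_that("simple regression and Pearson helpers give textbook answers", {
  x <- 1:10
  # lm warns about the perfect fit; the exact slope/R2 are what we check
  sr <- suppressWarnings(simpleRegression(x, 2 * x))
  expect_equal(sr$slope, 2)
  expect_equal(sr$r_squared, 1)
  expect_equal(pearsonCor(x, x)$r, 1)
  expect_error(simpleRegression(rep(1, 5), rnorm(5)), "zero variance")
  # slope CI behaves under the null: within 3 SE of 0 in >= 99% of draws
  set.seed(17)
  inside <- replicate(400, {
    sr <- simpleRegression(rnorm(30), rnorm(30))
    abs(sr$slope) < 3 * sr$se
  })
  expect_gte(mean(inside), 0.99)
})

test_that("prediction surface reproduces the fitted interaction plane", {
  gr <- make_grafted(20, 2, seed = 18)
  V <- phyloCovariance(gr$grafted)
  tt <- simulateTraits(gr$grafted, traitGenConfig(), seed = 18)
  fit <- pglsFit("contingency * constancy", tt, V)
  surf <- predictionSurface(fit, contingency = c(0, 0.5),
                            constancy = c(0, 1))
  b <- fit$coefficients$estimate
  manual <- b[1] + b[2] * surf$contingency + b[3] * surf$constancy +
    b[4] * surf$contingency * surf$constancy
  expect_equal(surf$predicted_log_bsl, manual, tolerance = 1e-12)
})
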