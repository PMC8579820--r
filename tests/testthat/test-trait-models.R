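test_that("gaussian log-likelihood kernel matches closed forms and dense algebra", {
  expect_equal(mvnorm_loglik(0, 0, matrix(1)), -0.5 * log(2 * pi))
  expect_equal(mvnorm_loglik(c(3, 3), 3, diag(2)), -log(2 * pi))
  set.seed(42)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    V <- crossprod(A) + diag(4)
    x <- rnorm(4); mu <- rnorm(1)
    expect_equal(mvnorm_loglik(x, mu, V), dense_mvn_loglik(x, mu, V),
                 tolerance = 1e-10)
  }
  expect_error(mvnorm_loglik(c(1, 2), 0, matrix(c(1, 1, 1, 1), 2)),
               "singular")
})

test_that("BM on a symmetric cherry recovers the closed-form GLS estimates", {
  # 2 tips at distance t from the root: z0 = (a+b)/2, ML sigma2 = (a-b)^2/(4t)
  for (t in c(0.5, 1, 3)) {
    tr <- cherry_tree(t)
    a <- 2.7; b <- -1.1
    # closed form derived by hand from the GLS expressions (n divisor)
    f <- fit_trait_model(tr, c(A = a, B = b), "BM")
    expect_equal(unname(f$params["z0"]), (a + b) / 2, tolerance = 1e-10)
    expect_equal(unname(f$params["sigma2"]), (a - b)^2 / (4 * t),
                 tolerance = 1e-10)
    expect_equal(f$AIC, 2 * f$k - 2 * f$lnL)
  }
})

test_that("lambda model collapses to BM at lambda 1 and WN at lambda 0", {
  fx <- argylia_fx()
  C <- vcv_matrix(fx$tree)
  tm <- fx$traits
  for (v in setdiff(names(tm), "species")) {
    x <- setNames(tm[[v]], tm$species)
    bm <- fit_trait_model(fx$tree, x, "BM")
    wn <- fit_trait_model(fx$tree, x, "WN")
    g1 <- nicherange:::gls_profile(nicherange:::align_traits(fx$tree, x),
                                   nicherange:::lambda_covariance(C, 1))
    g0 <- nicherange:::gls_profile(nicherange:::align_traits(fx$tree, x),
                                   nicherange:::lambda_covariance(C, 0))
    expect_equal(g1$lnL, bm$lnL, tolerance = 1e-8)
    expect_equal(g0$lnL, wn$lnL, tolerance = 1e-8)
  }
})

test_that("model fits report correct parameter counts and a true maximum", {
  fx <- argylia_fx()
  x <- setNames(fx$traits$AP, fx$traits$species)
  ks <- c(BM = 2L, OU = 3L, WN = 2L, LAMBDA = 3L)
  for (kind in names(ks)) {
    f <- fit_trait_model(fx$tree, x, kind)
    expect_identical(f$k, ks[[kind]])
    expect_equal(f$AIC, 2 * f$k - 2 * f$lnL)
    s2 <- if ("sigma2" %in% names(f$params)) f$params["sigma2"]
          else f$params["sigma2_wn"]
    expect_gt(unname(s2), 0)
  }
  # OU and LAMBDA contain BM in (or at the edge of) their parameter space
  bm <- fit_trait_model(fx$tree, x, "BM")
  expect_gte(fit_trait_model(fx$tree, x, "OU")$lnL, bm$lnL - 1e-6)
  expect_gte(fit_trait_model(fx$tree, x, "LAMBDA")$lnL, bm$lnL - 1e-6)
})

test_that("lambda signal test agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  fx <- argylia_fx()
  for (v in c("MAT", "AP", "TS", "PS")) {
    x <- setNames(fx$traits[[v]], fx$traits$species)
    ours <- lambda_signal_test(fx$tree, x)
    ref <- phytools::phylosig(fx$tree$phy, x, method = "lambda", test = TRUE)
    expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
    expect_equal(ours$lnL_lambda, ref$logL, tolerance = 1e-4)
    expect_gte(ours$lnL_lambda, ref$logL - 1e-4)  # ours is a true maximum
    expect_equal(ours$p, ref$P, tolerance = 1e-3)
    expect_gte(ours$lnL_lambda, ours$lnL_zero)  # boundary included in search
    expect_true(ours$p >= 0 && ours$p <= 1)
  }
})

test_that("lambda estimation separates phylogenetic signal from noise", {
  tr <- balanced_tree(64)
  lam_bm <- lam_perm <- numeric(200)
  set.seed(99)
  for (i in 1:200) {
    x <- simulate_traits(tr, "BM", c(sigma2 = 1, z0 = 0))
    lam_bm[i] <- lambda_signal_test(tr, x)$lambda
    xp <- setNames(sample(x), names(x))
    lam_perm[i] <- lambda_signal_test(tr, xp)$lambda
  }
  expect_gt(median(lam_bm), 0.9)
  expect_gte(mean(lam_perm < 0.2), 0.9)
})

test_that("akaike weights reproduce printed pairwise comparisons", {
  w <- aic_weights(c(A = 44.64, B = 50.81))
  expect_equal(w$weight, c(0.956, 0.044), tolerance = 5e-3)
  w2 <- aic_weights(c(altJ = 47.45, null = 43.1))
  expect_equal(w2$weight, c(0.102, 0.898), tolerance = 5e-3)
  w3 <- aic_weights(c(10, 10, 10))
  expect_equal(w3$weight, rep(1 / 3, 3))
  expect_equal(sum(w3$weight), 1, tolerance = 1e-9)
  # invariant to adding a constant
  w4 <- aic_weights(c(A = 144.64, B = 150.81))
  expect_equal(w4$weight, w$weight, tolerance = 1e-12)
  expect_error(aic_weights(c(1, NA)), "non-finite")
  expect_error(aic_weights(c(1)), "at least 2")
})

test_that("degenerate traits are rejected where the model is undefined", {
  fx <- argylia_fx()
  const <- setNames(rep(5, 13), fx$traits$species)
  expect_error(fit_trait_model(fx$tree, const, "WN"), "zero variance")
  expect_error(fit_trait_model(fx$tree, const, "LAMBDA"), "zero variance")
  bad <- setNames(rnorm(5), letters[1:5])
  expect_error(fit_trait_model(fx$tree, bad, "BM"), "mismatch")
})
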