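test_that("two-SD standardization gives mean 0 and sd 0.5", {
  expect_equal(standardize_2sd(c(1, 2, 3)), c(-0.5, 0, 0.5))
  expect_error(standardize_2sd(rep(4, 5), "flat"), "flat.*zero variance")
  set.seed(3)
  for (i in 1:10) {
    z <- standardize_2sd(rnorm(sample(5:50, 1), sd = runif(1, 0.1, 10)))
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 0.5, tolerance = 1e-12)
  }
})

test_that("OLS reproduces the hand-solved normal equations", {
  f <- fit_ols(c(0, 1, 2, 4), cbind(x = c(0, 1, 2, 3)))
  expect_equal(unname(f$coefficients["x"]), 1.3, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["(Intercept)"]), -0.2, tolerance = 1e-12)
  expect_equal(f$rss, 0.3, tolerance = 1e-12)
  expect_equal(f$r2_mult, 1 - 0.3 / 8.75, tolerance = 1e-12)
  expect_equal(f$log_likelihood,
               -(4 / 2) * (log(2 * pi * 0.3 / 4) + 1), tolerance = 1e-12)
  expect_equal(f$k, 3)
  expect_true(is.na(f$aicc))  # n - k - 1 = 0: criterion undefined here

  perfect <- suppressWarnings(fit_ols(1:5, cbind(x = 1:5)))
  expect_equal(perfect$r2_mult, 1, tolerance = 1e-12)
  expect_equal(unname(perfect$coefficients["x"]), 1, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to the design; r2_adj <= r2_mult", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- 1 + 0.5 * X[, "a"] + rnorm(n)
    f <- fit_ols(y, X)
    res <- stats::residuals(f$lm)
    expect_equal(sum(res), 0, tolerance = 1e-9)
    expect_equal(unname(colSums(res * X)), c(0, 0), tolerance = 1e-8)
    expect_lte(f$r2_adj, f$r2_mult)
    expect_gte(f$r2_mult, 0)
    expect_lte(f$r2_mult, 1)
  }
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), X), "collinear.*b")
})

test_that("under the null, p-values are approximately uniform", {
  set.seed(99)
  p <- replicate(400, {
    n <- 30
    fit_ols(rnorm(n), cbind(x = rnorm(n)))$p_values["x"]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.08)
})

test_that("AICc matches the hand formula and guards its domain", {
  expect_equal(aicc(-5, n = 24, k = 3), 16 + 1.2, tolerance = 1e-12)
  expect_error(aicc(-5, n = 4, k = 3), "n - k - 1")
  # converges to plain AIC for large n
  expect_lt(abs(aicc(-5, n = 10000, k = 3) - 16), 0.01)
})

test_that("Akaike weights use the logistic form and sum to 1", {
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  set.seed(2)
  w2 <- akaike_weights(cumsum(runif(7)))
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_true(all(w2 >= 0))
})

test_that("all-subsets selection agrees with a brute-force oracle", {
  set.seed(123)
  n <- 24
  X <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
  y <- 2 + 0.8 * X[, "A"] + rnorm(n, sd = 0.5)
  sel <- all_subsets_selection(y, X)
  oracle <- brute_force_selection(y, X)
  expect_equal(nrow(sel$table), 16)
  expect_equal(sel$table$model, oracle$model)
  expect_equal(sel$table$aicc, oracle$aicc, tolerance = 1e-10)
  expect_equal(sel$table$delta, oracle$delta, tolerance = 1e-10)
  expect_equal(sel$table$weight, oracle$weight, tolerance = 1e-10)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_match(sel$table$model[1], "A")
  expect_equal(sel$table$delta[1], 0)
})

test_that("a single-predictor pool enumerates two candidates", {
  set.seed(5)
  y <- rnorm(10)
  sel <- all_subsets_selection(y, cbind(A = rnorm(10)))
  expect_equal(nrow(sel$table), 2)
  expect_setequal(sel$table$model, c("(intercept only)", "A"))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
})

test_that("the combinatorial guard rejects oversized pools unless raised", {
  X <- matrix(rnorm(40 * 13), 40, dimnames = list(NULL, paste0("v", 1:13)))
  expect_error(all_subsets_selection(rnorm(40), X), "guard")
  sel <- all_subsets_selection(rnorm(40), X[, 1:3], max_predictors = 13)
  expect_equal(nrow(sel$table), 8)
})

test_that("AICc ranking is invariant to affine rescaling of the response", {
  set.seed(8)
  n <- 20
  X <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  y <- 1 + X[, "A"] - 0.5 * X[, "C"] + rnorm(n)
  s1 <- all_subsets_selection(y, X)
  s2 <- all_subsets_selection(3.7 * y - 11, X)
  expect_equal(s1$table$model, s2$table$model)
  expect_equal(s1$table$delta, s2$table$delta, tolerance = 1e-9)
  expect_equal(s1$table$weight, s2$table$weight, tolerance = 1e-9)
})

test_that("single-predictor t equals the Pearson-correlation t", {
  set.seed(31)
  n <- 24
  x <- standardize_2sd(rnorm(n))
  y <- 0.3 * x + rnorm(n)
  f <- fit_ols(y, cbind(x = x))
  r <- cor(x, y)
  expect_equal(unname(f$t_values["x"]), r * sqrt((n - 2) / (1 - r^2)),
               tolerance = 1e-10)
})

test_that("|r| exceeds the 0.404 critical value in about 5% of null draws", {
  set.seed(77)
  n <- 24
  hits <- mean(replicate(1000, abs(cor(rnorm(n), rnorm(n))) > 0.404))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.07)
})

test_that("approach comparison picks the truthful pool and handles nesting", {
  set.seed(14)
  b <- suppressWarnings(generate(synthetic_config(seed = 14)))
  rep14 <- run_all(b)
  comp <- rep14$composition
  ft <- rep14$fai

  # response driven purely by urban: the land-cover approach must win
  resp <- data.frame(landscape_id = comp$landscape_id,
                     seeds_per_pod = 2.5 +
                       0.8 * standardize_2sd(comp$urban) + rnorm(24, 0, 0.1))
  ac <- approach_comparison(resp, ft, comp)
  cm <- ac$comparison
  r2 <- setNames(cm$r2_mult, cm$approach)
  expect_gt(r2["land_cover_fine"], r2["floral_resources"])
  expect_match(cm$model[cm$approach == "land_cover_fine"], "urban")

  # fine categories nest the coarse sum: R2 can only go up
  y <- resp$seeds_per_pod
  coarse_fit <- fit_ols(y, cbind(crop = standardize_2sd(
    comp$arable + comp$permanent_crop)))
  fine_fit <- fit_ols(y, cbind(arable = standardize_2sd(comp$arable),
                               permanent_crop = standardize_2sd(comp$permanent_crop)))
  expect_gte(fine_fit$r2_mult, coarse_fit$r2_mult - 1e-12)

  # identical pools give identical selections
  s1 <- all_subsets_selection(y, cbind(u = standardize_2sd(comp$urban)))
  s2 <- all_subsets_selection(y, cbind(u = standardize_2sd(comp$urban)))
  expect_identical(s1$table, s2$table)
})

test_that("landscape regressions report the self- and inverse-correlation limits", {
  b <- suppressWarnings(generate(synthetic_config(seed = 9)))
  rep9 <- run_all(b)
  lr <- landscape_fai_regressions(rep9$fai, rep9$composition)
  expect_true(all(c("period", "variable", "t", "r2_mult", "p") %in%
                    names(lr$regressions)))
  expect_equal(dim(lr$correlations)[1], dim(lr$correlations)[2])
  expect_equal(diag(lr$correlations), setNames(rep(1, nrow(lr$correlations)),
                                               rownames(lr$correlations)))

  # degenerate checks of the correlation machinery itself
  comp <- rep9$composition
  fai_fake <- rep9$fai[rep9$fai$period == "preceding", ]
  fai_fake$fai <- comp$arable[match(fai_fake$landscape_id, comp$landscape_id)]
  lr2 <- suppressWarnings(landscape_fai_regressions(fai_fake, comp))
  row <- lr2$regressions[lr2$regressions$variable == "arable" &
                           lr2$regressions$period == "preceding", ]
  expect_equal(row$r2_mult, 1, tolerance = 1e-9)
  expect_gt(row$t, 0)
  # perfect inverse relation: slope negative, fit still exact
  fai_fake$fai <- -fai_fake$fai
  lr3 <- suppressWarnings(landscape_fai_regressions(fai_fake, comp))
  row3 <- lr3$regressions[lr3$regressions$variable == "arable" &
                            lr3$regressions$period == "preceding", ]
  expect_equal(row3$r2_mult, 1, tolerance = 1e-9)
  expect_lt(row3$t, 0)
})
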