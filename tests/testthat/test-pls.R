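test_that("a single proportional predictor is fitted exactly with one component", {
  withr::with_seed(1, d <- tibble::tibble(x1 = rnorm(30)))
  d$y <- 2 * d$x1
  fit <- fit_pls(d, "y", "x1", ncomp = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-12)
  # standardized coefficient: b * sd(x) / sd(y) = 2 * sd/(2 sd) = 1
  expect_equal(unname(fit$beta_std), 1, tolerance = 1e-12)
})

test_that("full-component PLS equals ordinary least squares on full-rank data", {
  withr::with_seed(2, {
    x <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("x", 1:6)))
    y <- drop(x %*% c(1, -2, 0.5, 0, 3, -1)) + rnorm(60)
  })
  d <- tibble::as_tibble(as.data.frame(x))
  d$y <- y
  fit <- fit_pls(d, "y", paste0("x", 1:6), ncomp = 6)
  ols <- lm(y ~ ., data = as.data.frame(x))
  expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("jointly permuting rows leaves the coefficients unchanged", {
  withr::with_seed(3, {
    d <- tibble::tibble(a = rnorm(40), b = rnorm(40))
    d$y <- d$a - d$b + rnorm(40, 0, 0.2)
    perm <- sample.int(40)
  })
  f1 <- fit_pls(d, "y", c("a", "b"), ncomp = 2)
  f2 <- fit_pls(d[perm, ], "y", c("a", "b"), ncomp = 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("standardized coefficients are scale invariant and contributions sum to one", {
  withr::with_seed(4, {
    d <- tibble::tibble(a = rnorm(100), b = rnorm(100), cc = rnorm(100))
    d$y <- 2 * d$a + 2 * d$b + rnorm(100, 0, 0.3)
  })
  f1 <- fit_pls(d, "y", c("a", "b", "cc"), ncomp = 3)
  d2 <- d
  d2$a <- d$a * 10
  f2 <- fit_pls(d2, "y", c("a", "b", "cc"), ncomp = 3)
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)
  sc <- standardized_coefficients(f1)
  expect_equal(sum(sc$contribution), 1, tolerance = 1e-12)
  # two features with equal planted effects and equal SDs contribute ~equally
  expect_equal(sc$contribution[1], sc$contribution[2], tolerance = 0.1)
  expect_lt(sc$contribution[3], 0.1)
  # contribution weights are permutation-equivariant in feature order
  f3 <- fit_pls(d, "y", c("b", "a", "cc"), ncomp = 3)
  expect_equal(f3$contributions[["a"]], f1$contributions[["a"]], tolerance = 1e-10)
})

test_that("tidy and glance summarise a PLS fit", {
  withr::with_seed(5, d <- tibble::tibble(x = rnorm(25)))
  d$y <- 3 * d$x + rnorm(25, 0, 0.1)
  fit <- fit_pls(d, "y", "x", ncomp = 1)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std_estimate", "contribution"))
  gl <- generics::glance(fit)
  expect_named(gl, c("r.squared", "adj.r.squared", "ncomp", "nobs"))
  expect_equal(gl$nobs, 25)
  expect_error(fit_pls(dplyr::mutate(d, x = 1), "y", "x", 1), "Zero-variance")
})

test_that("cross-validated component selection returns the MSE minimizer deterministically", {
  withr::with_seed(6, {
    x <- matrix(rnorm(50 * 5), 50, 5)
    y <- 3 * x[, 2] # noise-free multiple of a single column
  })
  sel <- select_components_cv(x, y, folds = 5, seed = 9)
  expect_equal(sel$ncomp, which.min(sel$cv_mse))
  # a single latent direction already explains essentially everything
  r2_1 <- 1 - sel$cv_mse[1] / mean((y - mean(y))^2)
  expect_gt(r2_1, 0.8)
  sel2 <- select_components_cv(x, y, folds = 5, seed = 9)
  expect_identical(sel$cv_mse, sel2$cv_mse)
  expect_error(select_components_cv(x[1:3, ], y[1:3], folds = 5), "folds")
})

test_that("under a pure-noise response component selection does not pile on components", {
  withr::with_seed(7, {
    picks <- replicate(60, {
      x <- matrix(rnorm(40 * 5), 40, 5)
      y <- rnorm(40)
      select_components_cv(x, y, folds = 5, seed = sample.int(1e6, 1))$ncomp
    })
  })
  expect_lt(mean(picks == 5), 0.2) # no preference for the maximum
  expect_lte(median(picks), 2)
})

test_that("PLS agrees with an independent implementation on predictions", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(8, {
    x <- matrix(rnorm(45 * 4), 45, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- drop(x %*% c(1, 0.5, -1, 0)) + rnorm(45, 0, 0.4)
  })
  d <- tibble::as_tibble(as.data.frame(x))
  d$y <- y
  mine <- fit_pls(d, "y", paste0("x", 1:4), ncomp = 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = TRUE)
  ref_pred <- predict(ref, x)$predict[, 1, 2]
  expect_equal(unname(mine$fitted), unname(ref_pred), tolerance = 1e-6)
})

test_that("exhaustive selection recovers a planted three-feature signal and logs the search", {
  withr::with_seed(10, {
    x <- matrix(rnorm(100 * 12), 100, 12,
                dimnames = list(NULL, paste0("f", 1:12)))
    d <- tibble::as_tibble(as.data.frame(x))
    d$age <- rnorm(100, 50, 10)
    d$out <- 2 * d$f2 - 1.5 * d$f7 + d$f11 + rnorm(100, 0, 0.8)
  })
  sel <- suppressWarnings(exhaustive_feature_selection(
    d, "out", search_settings(pool = paste0("f", 1:12), max_size = 3, seed = 4)
  ))
  expect_true(all(c("f2", "f7", "f11") %in% sel$selected_parameters))
  expect_true("age" %in% sel$features)
  # the winner maximizes the metric over everything evaluated
  expect_gte(sel$r_squared + 1e-12, max(sel$search_log$metric))
  expect_true(sel$capped)
  expect_warning(
    exhaustive_feature_selection(
      d, "out", search_settings(pool = paste0("f", 1:4), max_size = 2, seed = 1)),
    "not fully exhaustive"
  )
})

test_that("a noise-free planted linear outcome is recovered perfectly", {
  withr::with_seed(11, {
    d <- tibble::tibble(p1 = rnorm(60), p2 = rnorm(60), p3 = rnorm(60))
    d$age <- rnorm(60, 50, 8)
    d$out <- d$p1 - 2 * d$p3
  })
  sel <- suppressWarnings(exhaustive_feature_selection(
    d, "out", search_settings(pool = c("p1", "p2", "p3"), max_size = 3, seed = 2)
  ))
  expect_equal(sel$r_squared, 1, tolerance = 1e-9)
  expect_equal(sel$adj_r_squared, 1, tolerance = 1e-9)
})

test_that("complete cases are scoped per candidate subset", {
  withr::with_seed(12, {
    d <- tibble::tibble(p1 = rnorm(80), p2 = rnorm(80), junk = rnorm(80))
    d$age <- rnorm(80, 50, 8)
    d$out <- 1.5 * d$p1 - d$p2 + rnorm(80, 0, 0.4)
  })
  d_miss <- d
  d_miss$junk[1:40] <- NA # structural missingness in an irrelevant parameter
  st <- search_settings(pool = c("p1", "p2", "junk"), max_size = 2, seed = 3)
  a <- suppressWarnings(exhaustive_feature_selection(d, "out", st))
  b <- suppressWarnings(exhaustive_feature_selection(d_miss, "out", st))
  expect_equal(sort(a$selected_parameters), sort(b$selected_parameters))
  expect_equal(b$n, 80) # the winning subset never touched the gappy column
  expect_error(
    exhaustive_feature_selection(d, "out",
                                 search_settings(pool = "nope", max_size = 1)),
    "not in data"
  )
})

test_that("greedy forward search matches exhaustive search on a well-separated signal", {
  withr::with_seed(13, {
    d <- tibble::tibble(a = rnorm(90), b = rnorm(90), cc = rnorm(90),
                        dd = rnorm(90))
    d$age <- rnorm(90, 50, 8)
    d$out <- 3 * d$a + 2 * d$b + rnorm(90, 0, 0.5)
  })
  ex <- suppressWarnings(exhaustive_feature_selection(
    d, "out", search_settings(pool = c("a", "b", "cc", "dd"), max_size = 2, seed = 5)))
  gr <- suppressWarnings(exhaustive_feature_selection(
    d, "out", search_settings(pool = c("a", "b", "cc", "dd"), max_size = 2,
                              seed = 5, mode = "greedy")))
  expect_setequal(ex$selected_parameters, c("a", "b"))
  expect_true(all(c("a", "b") %in% gr$selected_parameters))
})
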