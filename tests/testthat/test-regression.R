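fake_diffs <- function(n, p = 5, seed = 1, prefix = "d_f") {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n))
  names(d) <- paste0(prefix, seq_len(p))
  tibble::as_tibble(d)
}

test_that("a noiseless linear response is fit exactly", {
  d <- fake_diffs(40)
  y <- 2 + 3 * d$d_f1 - 0.5 * d$d_f4
  fit <- fit_feature_regression(d, y, order = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
})

test_that("pure-noise responses show near-zero explained variance", {
  set.seed(2)
  r2 <- replicate(150, {
    d <- fake_diffs(100, seed = sample.int(1e6, 1))
    fit_feature_regression(d, rnorm(100), order = 1)$r_squared
  })
  expect_lt(median(r2), 0.1)
})

test_that("second-order terms are needed for and recover interactions", {
  set.seed(3)
  d <- fake_diffs(54, p = 3, seed = 33)
  y <- 1.5 * d$d_f1 + 2 * d$d_f1 * d$d_f2 + rnorm(54, 0, 0.3)
  fit2 <- fit_feature_regression(d, y, order = 2)
  co <- generics::tidy(fit2)
  b1 <- co[co$term == "d_f1", ]
  bint <- co[co$term == "d_f1_x_d_f2", ]
  expect_lt(abs(b1$estimate - 1.5) / b1$std_error, 2.5)
  expect_lt(abs(bint$estimate - 2) / bint$std_error, 2.5)
  fit1 <- fit_feature_regression(d, y, order = 1)
  expect_gt(fit2$r_squared, fit1$r_squared + 0.1)
})

test_that("rank-deficient designs error unless PCA is requested", {
  d <- fake_diffs(10, p = 12, seed = 4)
  y <- rnorm(10)
  expect_error(fit_feature_regression(d, y, order = 1), "rank deficient")
  fit <- fit_feature_regression(d, y, order = 1, use_pca = TRUE,
                                pca_components = 3)
  expect_equal(fit$n_components, 3L)
  expect_true(is.finite(fit$r_squared))
})

test_that("cross-validated component selection finds planted dimensionality", {
  set.seed(5)
  n <- 80
  latent <- rnorm(n)
  d <- tibble::as_tibble(as.data.frame(
    sapply(1:6, function(j) latent * (j <= 2) + rnorm(n, 0, 0.3))))
  names(d) <- paste0("d_f", 1:6)
  y <- latent + rnorm(n, 0, 0.2)
  fit <- fit_feature_regression(d, y, order = 1, use_pca = TRUE,
                                pca_components = "cv")
  expect_true(fit$n_components %in% 1:6)
  expect_gt(fit$r_squared, 0.5)
  # the leading component already carries the planted signal
  fit1 <- fit_feature_regression(d, y, order = 1, use_pca = TRUE,
                                 pca_components = 1)
  expect_gt(fit1$r_squared, 0.5)
})

test_that("LOSO prediction is exact for noiseless responses and honest otherwise", {
  d <- fake_diffs(30, p = 3, seed = 6)
  d$subject_id <- sprintf("s%02d", seq_len(30))
  y <- 1 + 2 * d$d_f1 - d$d_f3
  out <- loso_predict(d, y, order = 1)
  expect_equal(out$r_squared, 1, tolerance = 1e-9)
  expect_equal(out$predictions$predicted, out$predictions$observed,
               tolerance = 1e-9)

  # removing an unrelated subject leaves other predictions unchanged
  d2 <- d[d$subject_id != "s01", ]
  out2 <- loso_predict(d2, y[-1], order = 1)
  keep <- out$predictions$subject_id != "s01"
  expect_equal(out$predictions$predicted[keep], out2$predictions$predicted,
               tolerance = 1e-9)
})

test_that("LOSO recovery sits inside Monte-Carlo bands of the planted SNR", {
  set.seed(7)
  n <- 54
  slope <- 0.8; noise <- 0.5
  r2s <- replicate(60, {
    x <- rnorm(n)
    d <- tibble::tibble(d_f1 = x, subject_id = sprintf("s%02d", 1:n))
    y <- slope * x + rnorm(n, 0, noise)
    loso_predict(d, y, order = 1)$r_squared
  })
  pop_r2 <- slope^2 / (slope^2 + noise^2)     # planted signal fraction
  expect_lt(abs(median(r2s) - pop_r2), 0.1)
  # out-of-sample never beats the in-sample fit systematically
  set.seed(8)
  gaps <- replicate(40, {
    x <- rnorm(30)
    d <- tibble::tibble(d_f1 = x, subject_id = sprintf("s%02d", 1:30))
    y <- 0.5 * x + rnorm(30, 0, 0.7)
    fit <- fit_feature_regression(d, y, order = 1)
    fit$r_squared - loso_predict(d, y, order = 1)$r_squared
  })
  expect_gt(mean(gaps > 0), 0.9)
})
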