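test_that("height categories are lower-closed with an unbounded top", {
  expect_equal(height_category(c(0.5, 9.999, 10, 29.9, 50, 58)),
               c(1, 1, 2, 3, 6, 6))
})

test_that("category weights give every populated category mass 1/6", {
  w <- compute_category_weights(c(5, 15, 25, 35, 45, 55))
  expect_equal(w$weight, rep(1 / 6, 6))  # one point per category
  set.seed(51)
  rh <- runif(5000, 0, 60)
  w2 <- compute_category_weights(rh)
  expect_equal(sum(w2$n_points * w2$weight), 1)
  # empty categories are excluded
  w3 <- compute_category_weights(c(2, 3, 55))
  expect_equal(w3$category, c(1, 6))
})

test_that("the stratified split uses floor rounding per category and is seeded", {
  pairs <- tibble::tibble(rh98 = c(runif(10, 0, 10), 15))
  sp <- stratified_split(pairs, frac = 0.7, seed = 4L)
  cat_train <- height_category(sp$train$rh98)
  expect_equal(sum(cat_train == 1), 7)   # floor(0.7 * 10)
  expect_equal(sum(cat_train == 2), 0)   # floor(0.7 * 1): singleton validates
  expect_equal(nrow(sp$train) + nrow(sp$valid), 11)
  expect_equal(sort(c(sp$train$rh98, sp$valid$rh98)), sort(pairs$rh98))

  sp2 <- stratified_split(pairs, frac = 0.7, seed = 4L)
  expect_identical(sp$train$rh98, sp2$train$rh98)
  expect_error(stratified_split(pairs, frac = 1.2), "frac")
})

test_that("split proportions hold within floor rounding in every category", {
  set.seed(52)
  pairs <- tibble::tibble(rh98 = runif(2000, 0, 60))
  sp <- stratified_split(pairs, frac = 0.7, seed = 9L)
  for (k in 1:6) {
    n_all <- sum(height_category(pairs$rh98) == k)
    n_train <- sum(height_category(sp$train$rh98) == k)
    expect_equal(n_train, floor(0.7 * n_all))
  }
})

test_that("noiseless square-root data recovers its generating coefficients", {
  pairs <- sqrt_law_pairs(500, a = 1.02, b = 0.33)
  models <- fit_candidates(pairs)
  expect_equal(unname(models$sqrt_linear$coef["a"]), 1.02, tolerance = 1e-7)
  expect_equal(unname(models$sqrt_linear$coef["b"]), 0.33, tolerance = 1e-7)
  expect_lt(models$sqrt_linear$metrics$rmse, 1e-6)
})

test_that("noiseless linear data favors the linear form over the sqrt form", {
  set.seed(53)
  x <- runif(400, 1, 50)
  pairs <- tibble::tibble(tdx_max = x, rh98 = 2 * x + 1)
  models <- fit_candidates(pairs)
  expect_equal(unname(models$linear$coef), c(2, 1), tolerance = 1e-8)
  expect_gt(models$sqrt_linear$metrics$rmse, models$linear$metrics$rmse)
  expect_identical(select_model(models[c("linear", "sqrt_linear")])$form,
                   "linear")
})

test_that("uniform weights reproduce the unweighted fit", {
  set.seed(54)
  x <- runif(300, 1, 50)
  pairs <- tibble::tibble(tdx_max = x, rh98 = (sqrt(x) + 0.2 + rnorm(300, 0, 0.1))^2)
  uniform <- tibble::tibble(category = 1:6, label = height_category_labels(),
                            n_points = 1L, weight = 1 / 6)
  m_w <- fit_candidates(pairs, uniform)$sqrt_linear
  m_ref <- stats::lm(sqrt(rh98) ~ sqrt(tdx_max), data = pairs)
  expect_equal(unname(m_w$coef["a"]), unname(coef(m_ref)[2]), tolerance = 1e-10)
  expect_equal(unname(m_w$coef["b"]), unname(coef(m_ref)[1]), tolerance = 1e-10)
})

test_that("too few distinct DEM values is an error", {
  expect_error(fit_candidates(tibble::tibble(tdx_max = c(5, 5), rh98 = c(4, 6))),
               "distinct")
})

test_that("model selection ranks by RMSE with MAE/bias/corr tie-breaks", {
  mk <- function(form, rmse, mae, bias = 0, corr = 0.9) {
    m <- mangroveheight:::new_calibration_model(form, c(a = 1, b = 0))
    m$metrics <- list(corr = corr, mae = mae, rmse = rmse, bias = bias, n = 10)
    m
  }
  expect_identical(select_model(list(mk("linear", 2.4, 2), mk("power", 3, 1)))$form,
                   "linear")
  expect_identical(select_model(list(mk("linear", 2.4, 1.9),
                                     mk("power", 2.4, 2.1)))$form, "linear")
  expect_identical(select_model(list(mk("linear", 2.4, 1.9, bias = 0.5),
                                     mk("power", 2.4, 1.9, bias = 0.1)))$form,
                   "power")
  expect_identical(select_model(list(mk("solo", 1, 1)))$form, "solo")
  expect_error(select_model(list()), "no models")
})

test_that("the published-form calibration evaluates as hand computation says", {
  model <- mangroveheight:::new_calibration_model("sqrt_linear",
                                                  c(a = 1.02, b = 0.33))
  dem <- tile_m(matrix(c(0, 25, NA, 4), 2, 2), vdatum = "geoid")
  out <- apply_calibration(model, dem)
  expect_equal(out$values[1, 1], 0.33^2)                 # 0.1089
  expect_equal(out$values[2, 1], (1.02 * 5 + 0.33)^2)    # 29.4849
  expect_true(is.na(out$values[1, 2]))
  expect_equal(apply_calibration(identity_model(), dem)$values, dem$values)
  neg <- tile_m(matrix(-1, 1, 1), vdatum = "geoid")
  expect_error(apply_calibration(model, neg), "negative")
})

test_that("calibration with positive slope is strictly increasing in height", {
  model <- mangroveheight:::new_calibration_model("sqrt_linear",
                                                  c(a = 1.02, b = 0.33))
  x <- seq(0, 60, by = 0.5)
  expect_true(all(diff(predict(model, x)) > 0))
})

test_that("fit metrics match their textbook formulas", {
  obs <- c(1, 2, 3, 5)
  m <- evaluate_metrics(obs, obs)
  expect_equal(unlist(m[c("rmse", "mae", "bias", "corr")]),
               c(rmse = 0, mae = 0, bias = 0, corr = 1))
  shift <- evaluate_metrics(obs + 2, obs)
  expect_equal(unlist(shift[c("bias", "mae", "rmse", "corr")]),
               c(bias = 2, mae = 2, rmse = 2, corr = 1))
  set.seed(55)
  p <- rnorm(100); o <- rnorm(100)
  m2 <- evaluate_metrics(p, o)
  expect_equal(m2$rmse, sqrt(sum((p - o)^2) / 100), tolerance = 1e-12)
  expect_equal(m2$mae, sum(abs(p - o)) / 100, tolerance = 1e-12)
  expect_equal(m2$bias, sum(p - o) / 100, tolerance = 1e-12)
  expect_equal(m2$corr,
               sum((p - mean(p)) * (o - mean(o))) /
                 sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2)),
               tolerance = 1e-12)
  expect_error(evaluate_metrics(1, 1), "at least 2")
})

test_that("models serialize to JSON and back", {
  m <- mangroveheight:::new_calibration_model("sqrt_linear",
                                              c(a = 1.02, b = 0.33))
  m$metrics <- list(corr = 0.99, mae = 1.9, rmse = 2.4, bias = 0.5, n = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path, extra = list(seed = 1))
  back <- read_model_json(path)
  expect_identical(back$form, "sqrt_linear")
  expect_equal(back$coef, m$coef)
  expect_equal(predict(back, 25), predict(m, 25))
})
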