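#' Height categories for weighting and the stratified split
#'
#' Six contiguous RH98 categories: \[0,10), \[10,20), \[20,30), \[30,40),
#' \[40,50) and >= 50 m (lower-closed, upper-open, last unbounded).
#'
#' @param rh98 numeric vector of heights (m).
#' @return integer category index 1..6.
#' @export
height_category <- function(rh98) {
  findInterval(rh98, c(0, 10, 20, 30, 40, 50), rightmost.closed = FALSE)
}

#' @rdname height_category
#' @export
height_category_labels <- function() {
  c("0-10", "10-20", "20-30", "30-40", "40-50", ">=50")
}

#' Per-category regression weights
#'
#' Weight = 1 / (number of points in the category x 6), so every populated
#' category contributes total mass 1/6 and all height categories are equally
#' weighted in the regression regardless of their (very unequal) abundance.
#' Empty categories are excluded.
#'
#' @param rh98 RH98 values (m) of the points being weighted.
#' @return tibble with `category`, `label`, `n_points`, `weight`.
#' @export
compute_category_weights <- function(rh98) {
  cat <- height_category(rh98)
  n <- tabulate(cat, nbins = 6)
  keep <- which(n > 0)
  tibble::tibble(category = keep,
                 label = height_category_labels()[keep],
                 n_points = n[keep],
                 weight = 1 / (n[keep] * 6))
}

#' Stratified 70/30 split by height category
#'
#' Within each category, `floor(frac * n)` points are drawn without
#' replacement for training; the remainder validate. Seeded, so the split is
#' reproducible.
#'
#' @param pairs tibble with an `rh98` column.
#' @param frac training fraction, in (0,1).
#' @param seed RNG seed.
#' @return list with disjoint tibbles `train` and `valid` whose union is the
#'   input.
#' @export
stratified_split <- function(pairs, frac = 0.7, seed = 1L) {
  if (!(frac > 0 && frac < 1)) stop("frac must be in (0,1)")
  set.seed(seed)
  cat <- height_category(pairs$rh98)
  train_idx <- integer(0)
  for (k in sort(unique(cat))) {
    members <- which(cat == k)
    n_train <- floor(frac * length(members))
    if (n_train > 0)
      train_idx <- c(train_idx, sample(members, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = pairs[train_idx, , drop = FALSE],
       valid = pairs[setdiff(seq_len(nrow(pairs)), train_idx), , drop = FALSE])
}

#' Fit metrics in original height units
#'
#' Pearson correlation, mean absolute error, root mean squared error and
#' bias, with bias = mean(predicted - observed).
#'
#' @param predicted,observed equal-length numeric vectors, n >= 2.
#' @return list with `corr`, `mae`, `rmse`, `bias`, `n`.
#' @export
evaluate_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  n <- length(predicted)
  if (n < 2) stop("need at least 2 paired values")
  res <- predicted - observed
  list(corr = stats::cor(predicted, observed),
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       bias = mean(res),
       n = n)
}

#' Construct a calibration model
#'
#' @param form functional form; see [predict.calibration_model()].
#' @param coef named coefficient vector (`a`, `b`, and `c` for the
#'   quadratic form).
#' @param metrics optional list of fit metrics ([evaluate_metrics()]).
#' @export
calibration_model <- function(form, coef, metrics = NULL) {
  structure(list(form = form, coef = coef, metrics = metrics),
            class = "calibration_model")
}

new_calibration_model <- calibration_model

#' Identity calibration model
#'
#' Predicts the input height unchanged; used for noiseless end-to-end
#' closure checks.
#' @export
identity_model <- function() new_calibration_model("identity", c(a = 1, b = 0))

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %s\n", x$form,
              paste(sprintf("%s=%.4f", names(x$coef), x$coef), collapse = ", ")))
  if (!is.null(x$metrics))
    cat(sprintf("  train CORR %.4f  MAE %.3f  RMSE %.3f  bias %.3f (n=%d)\n",
                x$metrics$corr, x$metrics$mae, x$metrics$rmse,
                x$metrics$bias, x$metrics$n))
  invisible(x)
}

#' Predict canopy height from DEM height
#'
#' Functional forms: `sqrt_linear` (a*sqrt(x) + b)^2 — a linear regression
#' on square-root-transformed variables, squared back; `linear` a*x + b;
#' `power` b*x^a; `quadratic` a*x^2 + b*x + c; `identity` x.
#'
#' @param object a `calibration_model`.
#' @param x DEM heights (m), nonnegative for the sqrt and power forms.
#' @param ... unused.
#' @export
predict.calibration_model <- function(object, x, ...) {
  cf <- object$coef
  switch(object$form,
    identity = x,
    linear = cf[["a"]] * x + cf[["b"]],
    sqrt_linear = (cf[["a"]] * sqrt(x) + cf[["b"]])^2,
    power = cf[["b"]] * x^cf[["a"]],
    quadratic = cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]],
    stop("unknown model form: ", object$form))
}

#' Fit the candidate calibration regressions
#'
#' Weighted least squares fits of four candidate forms of RH98 on the
#' footprint max DEM value: linear, quadratic, power (on log-log) and the
#' square-root-transformed linear regression (sqrt(RH98) = a*sqrt(DEM) + b,
#' predictions squared back). Each observation carries the weight of its
#' RH98 height category. Metrics are computed on the training data in the
#' original height units.
#'
#' @param train tibble with `rh98` and `tdx_max` columns.
#' @param weights [compute_category_weights()] table (computed on `train` if
#'   omitted).
#' @return named list of `calibration_model`s.
#' @export
fit_candidates <- function(train, weights = compute_category_weights(train$rh98)) {
  x <- train$tdx_max; y <- train$rh98
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stop("need at least 2 distinct DEM values")
  w <- weights$weight[match(height_category(y), weights$category)]
  dat <- data.frame(x = x, y = y, w = w)

  lin <- stats::lm(y ~ x, data = dat, weights = w)
  quad <- stats::lm(y ~ I(x^2) + x, data = dat, weights = w)
  sq <- stats::lm(sqrt(y) ~ sqrt(x), data = dat, weights = w)
  pos <- dat$x > 0 & dat$y > 0
  pow <- stats::lm(log(y) ~ log(x), data = dat[pos, ], weights = dat$w[pos])

  models <- list(
    linear = new_calibration_model("linear",
      c(a = unname(stats::coef(lin)[2]), b = unname(stats::coef(lin)[1]))),
    quadratic = new_calibration_model("quadratic",
      c(a = unname(stats::coef(quad)[2]), b = unname(stats::coef(quad)[3]),
        c = unname(stats::coef(quad)[1]))),
    power = new_calibration_model("power",
      c(a = unname(stats::coef(pow)[2]), b = exp(unname(stats::coef(pow)[1])))),
    sqrt_linear = new_calibration_model("sqrt_linear",
      c(a = unname(stats::coef(sq)[2]), b = unname(stats::coef(sq)[1])))
  )
  lapply(models, function(m) {
    m$metrics <- evaluate_metrics(predict(m, x), y)
    m
  })
}

#' Select the best calibration model
#'
#' Lowest RMSE; ties broken by lower MAE, then lower |bias|, then higher
#' correlation.
#'
#' @param models list of `calibration_model`s with metrics.
#' @export
select_model <- function(models) {
  if (!length(models)) stop("no models to select from")
  score <- vapply(models, function(m)
    c(m$metrics$rmse, m$metrics$mae, abs(m$metrics$bias), -m$metrics$corr),
    numeric(4))
  best <- do.call(order, as.data.frame(t(score)))[1]
  models[[best]]
}

#' Apply a calibration model to a DEM tile
#'
#' Maps every valid pixel through the model's prediction; nodata is
#' preserved. Errors on negative heights for square-root forms (such pixels
#' must be clipped out beforehand).
#'
#' @param model a `calibration_model`.
#' @param dem height [raster_tile()].
#' @return calibrated canopy-height [raster_tile()].
#' @export
apply_calibration <- function(model, dem) {
  v <- dem$values
  ok <- !is.na(v)
  if (model$form %in% c("sqrt_linear", "power") && any(v[ok] < 0))
    stop("negative heights under a square-root model; clip the DEM first")
  v[ok] <- predict(model, v[ok])
  with_values(dem, v)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path JSON path.
#' @param extra named list merged into the JSON record (seed, weight table,
#'   provenance of the run).
#' @export
write_model_json <- function(model, path, extra = list()) {
  rec <- c(list(form = model$form, coef = as.list(model$coef),
                metrics = model$metrics), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_model(rec$form, unlist(rec$coef), rec$metrics)
}
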