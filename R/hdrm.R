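#' Parametric depth-bias prediction
#'
#' The parametric stage of the hybrid depth regression model (HDRM) maps a
#' camera-measured depth `d_c` (mm) to a first-pass corrected depth
#' \deqn{d_{param} = (1+\alpha) d_c + \beta d_c^2 + \phi + \gamma g(d_c)}
#' where `g` is `sqrt(d_c)` by default (`gamma_form = "sqrt"`) or `1/d_c`
#' (`gamma_form = "recip"`). A term strictly linear in `d_c` would be
#' collinear with the `(1+alpha)` term, so the gamma term must be one of
#' these curved forms for the four coefficients to be identifiable.
#'
#' @param d_c camera depth in mm, `> 0`; vectorized.
#' @param coeffs named vector/list with `alpha`, `beta`, `phi`, `gamma`.
#' @param gamma_form `"sqrt"` or `"recip"`.
#' @return predicted depth `d_param` (mm).
#' @export
predict_parametric <- function(d_c, coeffs, gamma_form = c("sqrt", "recip")) {
  gamma_form <- match.arg(gamma_form)
  if (any(d_c <= 0)) tp_stop("d_c must be positive", "tp_domain_error")
  g <- if (gamma_form == "sqrt") sqrt(d_c) else 1 / d_c
  (1 + coeffs[["alpha"]]) * d_c + coeffs[["beta"]] * d_c^2 +
    coeffs[["phi"]] + coeffs[["gamma"]] * g
}

#' Fit the parametric depth-bias coefficients by least squares
#'
#' Linear least squares of `d_b - d_c` on the design
#' `[d_c, d_c^2, 1, g(d_c)]`, which is exactly the minimization of
#' `sum (d_b - d_param)^2` over `(alpha, beta, phi, gamma)`.
#'
#' @param d_c,d_b paired camera and reference depths (mm), `> 0`.
#' @param gamma_form see [predict_parametric()].
#' @return named numeric vector `alpha`, `beta`, `phi`, `gamma`.
#' @export
fit_parametric <- function(d_c, d_b, gamma_form = c("sqrt", "recip")) {
  gamma_form <- match.arg(gamma_form)
  if (length(d_c) != length(d_b)) tp_stop("paired samples required", "tp_format_error")
  if (length(d_c) < 4L || length(unique(d_c)) < 3L)
    tp_stop("need >= 4 samples spanning >= 3 distinct d_c values", "tp_format_error")
  if (any(d_c <= 0) || any(d_b <= 0)) tp_stop("depths must be positive", "tp_domain_error")
  g <- if (gamma_form == "sqrt") sqrt(d_c) else 1 / d_c
  X <- cbind(d = d_c, d2 = d_c^2, one = 1, g = g)
  fit <- lm.fit(X, d_b - d_c)
  if (fit$rank < 4L) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    tp_stop(sprintf("rank-deficient design; collinear terms: %s",
                    paste(dropped, collapse = ", ")), "tp_rank_error")
  }
  co <- fit$coefficients
  c(alpha = unname(co["d"]), beta = unname(co["d2"]),
    phi = unname(co["one"]), gamma = unname(co["g"]))
}

#' Residuals of the parametric stage
#'
#' `e = d_b - d_param`, the deviation left for the random-forest stage.
#'
#' @inheritParams fit_parametric
#' @param coeffs fitted parametric coefficients.
#' @return numeric vector of residuals (mm).
#' @export
hdrm_residuals <- function(d_c, d_b, coeffs, gamma_form = c("sqrt", "recip")) {
  d_b - predict_parametric(d_c, coeffs, match.arg(gamma_form))
}

#' Extended feature set for the residual regressor
#'
#' Per sample: `[d, d^2, d^3, ln(d + 1), 1/d]` (linear, quadratic, cubic,
#' logarithmic and reciprocal terms).
#'
#' @param d_c camera depths (mm), `> 0`.
#' @return n x 5 numeric matrix.
#' @export
build_features <- function(d_c) {
  if (any(d_c <= 0)) tp_stop("d_c must be positive", "tp_domain_error")
  cbind(d = d_c, d2 = d_c^2, d3 = d_c^3, log1d = log(d_c + 1), recip = 1 / d_c)
}

#' Standardize features with training-set statistics
#'
#' `X_norm = (X - mu) / sigma` column-wise. `mu`/`sigma` must come from the
#' training set only; pass them explicitly when transforming held-out data.
#'
#' @param X feature matrix.
#' @param mu,sigma per-column center and scale; estimated from `X` when
#'   omitted.
#' @return list with `X_norm`, `mu`, `sigma`.
#' @export
standardize_features <- function(X, mu = NULL, sigma = NULL) {
  if (is.null(mu)) mu <- colMeans(X)
  if (is.null(sigma)) sigma <- apply(X, 2, sd)
  if (any(sigma <= 0))
    tp_stop("degenerate training set: zero-variance feature column", "tp_degenerate_error")
  list(X_norm = sweep(sweep(X, 2, mu), 2, sigma, "/"), mu = mu, sigma = sigma)
}

#' @rdname standardize_features
#' @param X_norm standardized matrix.
#' @export
unstandardize_features <- function(X_norm, mu, sigma) {
  sweep(sweep(X_norm, 2, sigma, "*"), 2, mu, "+")
}

#' Fit the random-forest residual corrector
#'
#' An ensemble of regression trees fitted to the parametric-stage residuals
#' on standardized extended features; the prediction is the ensemble mean.
#'
#' @param X_norm standardized feature matrix.
#' @param e residual vector.
#' @param seed RNG seed (forest construction is randomized).
#' @param ntree number of trees.
#' @return a `randomForest` object.
#' @export
fit_residual_forest <- function(X_norm, e, seed = 42L, ntree = 200L) {
  if (nrow(X_norm) < 10L) tp_stop("need >= 10 samples for the forest", "tp_format_error")
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(X_norm), y = e, ntree = ntree)
}

#' @rdname fit_residual_forest
#' @param forest fitted forest.
#' @export
predict_residual <- function(forest, X_norm) {
  unname(predict(forest, as.data.frame(X_norm)))
}

#' Fit the full hybrid depth regression model
#'
#' Pipeline: least-squares parametric fit, residual computation, extended
#' feature construction, standardization (training statistics retained), and
#' random-forest residual regression.
#'
#' @inheritParams fit_parametric
#' @param seed RNG seed for the forest.
#' @param ntree forest size.
#' @return object of class `hdrm_model` holding `coeffs`, `mu`, `sigma`,
#'   `forest`, `gamma_form`.
#' @export
hdrm_fit <- function(d_c, d_b, gamma_form = c("sqrt", "recip"),
                     seed = 42L, ntree = 200L) {
  gamma_form <- match.arg(gamma_form)
  coeffs <- fit_parametric(d_c, d_b, gamma_form)
  e <- hdrm_residuals(d_c, d_b, coeffs, gamma_form)
  st <- standardize_features(build_features(d_c))
  forest <- fit_residual_forest(st$X_norm, e, seed = seed, ntree = ntree)
  structure(list(coeffs = coeffs, mu = st$mu, sigma = st$sigma,
                 forest = forest, gamma_form = gamma_form),
            class = "hdrm_model")
}

#' Correct camera depths with a fitted HDRM
#'
#' `d_final = d_param + e_hat`, the parametric prediction plus the forest's
#' residual estimate.
#'
#' @param model an `hdrm_model`.
#' @param d_c camera depths (mm), `> 0`.
#' @return corrected depths (mm).
#' @export
correct_depth <- function(model, d_c) {
  stopifnot(inherits(model, "hdrm_model"))
  d_param <- predict_parametric(d_c, model$coeffs, model$gamma_form)
  st <- standardize_features(build_features(d_c), model$mu, model$sigma)
  d_param + predict_residual(model$forest, st$X_norm)
}

#' @export
print.hdrm_model <- function(x, ...) {
  cat("Hybrid depth regression model (HDRM)\n")
  cat(sprintf("  parametric: alpha=%.4g beta=%.4g phi=%.4g gamma=%.4g (%s form)\n",
              x$coeffs["alpha"], x$coeffs["beta"], x$coeffs["phi"],
              x$coeffs["gamma"], x$gamma_form))
  cat(sprintf("  residual forest: %d trees\n", x$forest$ntree))
  invisible(x)
}

#' k-fold cross-validation of the HDRM
#'
#' Disjoint, exhaustive folds (sizes differing by at most one); per fold the
#' parametric stage and forest are refitted on the remaining folds and the
#' held-out RMSE of the raw camera depth, the parametric stage and the full
#' hybrid model are reported.
#'
#' @inheritParams hdrm_fit
#' @param k number of folds.
#' @return data.frame with columns `fold`, `n`, `rmse_raw`, `rmse_param`,
#'   `rmse_hybrid`, plus attribute `folds` (the held-out index list).
#' @export
hdrm_cross_validate <- function(d_c, d_b, k = 10L, seed = 42L,
                                gamma_form = c("sqrt", "recip"), ntree = 200L) {
  gamma_form <- match.arg(gamma_form)
  n <- length(d_c)
  if (k > n) tp_stop("k exceeds the number of samples", "tp_format_error")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  rows <- lapply(seq_len(k), function(f) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    coeffs <- fit_parametric(d_c[tr], d_b[tr], gamma_form)
    e <- hdrm_residuals(d_c[tr], d_b[tr], coeffs, gamma_form)
    st <- standardize_features(build_features(d_c[tr]))
    forest <- fit_residual_forest(st$X_norm, e, seed = seed + f, ntree = ntree)
    d_param <- predict_parametric(d_c[te], coeffs, gamma_form)
    ste <- standardize_features(build_features(d_c[te]), st$mu, st$sigma)
    d_final <- d_param + predict_residual(forest, ste$X_norm)
    data.frame(fold = f, n = length(te),
               rmse_raw = regression_metrics(d_b[te], d_c[te])$rmse,
               rmse_param = regression_metrics(d_b[te], d_param)$rmse,
               rmse_hybrid = regression_metrics(d_b[te], d_final)$rmse)
  })
  out <- do.call(rbind, rows)
  attr(out, "folds") <- split(seq_len(n), fold_id)
  out
}
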