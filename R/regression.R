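#' Regress a targeting outcome on anatomical feature differences
#'
#' Ordinary least squares of a response (typically the target mean En or
#' NERNI observed when one subject's montage is applied to another) on
#' anatomical feature differences. `order = 1` uses the linear terms;
#' `order = 2` uses, for every pair of features, the full second-order
#' quintuple (f1, f2, f1 x f2, f1^2, f2^2), i.e. the complete degree-2
#' polynomial expansion of the feature set. With `use_pca`, features are
#' z-scored and projected on principal components before the fit — the
#' standard remedy when the expanded design is collinear or wider than the
#' sample — keeping either a fixed number of components or the number
#' minimizing leave-one-out cross-validated prediction error
#' (`pca_components = "cv"`).
#'
#' @param data tibble containing the feature columns (and possibly the
#'   response and id columns).
#' @param response response values: a numeric vector or the name of a
#'   column of `data`.
#' @param features character vector of feature column names; default all
#'   numeric columns except the response and id columns.
#' @param order 1 (linear) or 2 (full second-order expansion).
#' @param use_pca logical.
#' @param pca_components integer, or `"cv"` for leave-one-out selection.
#' @return object of class `feature_regression`: list with `model` (lm),
#'   `r_squared`, `f_statistic`, `p_value` (overall F-test), `terms`,
#'   `n_components` (NA without PCA), plus the projection needed to
#'   predict new data.
#' @export
fit_feature_regression <- function(data, response, features = NULL,
                                   order = 1, use_pca = FALSE,
                                   pca_components = NULL) {
  prep <- regression_design(data, response, features, order)
  X <- prep$X; y <- prep$y
  n <- nrow(X)
  if (!use_pca) {
    if (n <= ncol(X) || qr(cbind(1, X))$rank < ncol(X) + 1)
      stop("design is rank deficient (", ncol(X), " regressors, n = ", n,
           "); consider `use_pca = TRUE`")
    d <- data.frame(.y = y, X, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = d)
    proj <- NULL
    ncomp <- NA_integer_
  } else {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Z <- scale(X, ctr, scl)
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    kmax <- sum(pc$sdev > 1e-10)
    kmax <- min(kmax, n - 2L)
    if (is.null(pca_components)) pca_components <- kmax
    if (identical(pca_components, "cv")) {
      ncomp <- select_components_loocv(pc$x[, seq_len(kmax), drop = FALSE], y)
    } else {
      ncomp <- min(as.integer(pca_components), kmax)
    }
    S <- pc$x[, seq_len(ncomp), drop = FALSE]
    d <- data.frame(.y = y, S)
    fit <- stats::lm(.y ~ ., data = d)
    proj <- list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE])
  }
  s <- summary(fit)
  fs <- s$fstatistic
  pval <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  structure(list(model = fit, r_squared = s$r.squared,
                 f_statistic = if (is.null(fs)) NA_real_ else unname(fs[1]),
                 p_value = unname(pval),
                 terms = colnames(X), order = order,
                 features = prep$features,
                 n_components = ncomp, projection = proj),
            class = "feature_regression")
}

# Build the polynomial design matrix and response vector.
regression_design <- function(data, response, features, order) {
  if (is.character(response) && length(response) == 1 &&
        response %in% names(data)) {
    y <- data[[response]]
    resp_col <- response
  } else {
    y <- as.numeric(response)
    resp_col <- NULL
  }
  if (is.null(features)) {
    drop <- c(resp_col, "subject_id", "template_id", "protocol_id",
              "nerni", "mean_en")
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], drop)
  }
  if (!length(features)) stop("no feature columns")
  X <- as.matrix(data[features])
  if (nrow(X) != length(y)) stop("response length != row count")
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2")
  if (order == 2) {
    sq <- X^2
    colnames(sq) <- paste0(features, "_sq")
    inter <- NULL
    if (length(features) >= 2) {
      pr <- utils::combn(length(features), 2)
      inter <- X[, pr[1, ], drop = FALSE] * X[, pr[2, ], drop = FALSE]
      colnames(inter) <- paste0(features[pr[1, ]], "_x_", features[pr[2, ]])
    }
    X <- cbind(X, sq, inter)
  }
  list(X = X, y = y, features = features)
}

# Leave-one-out CV over the number of leading principal-component scores,
# minimizing squared prediction error (closed-form via hat values).
select_components_loocv <- function(scores, y) {
  n <- length(y)
  kmax <- ncol(scores)
  errs <- vapply(seq_len(kmax), function(k) {
    S <- scores[, seq_len(k), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, S), y)
    h <- stats::hat(cbind(1, S), intercept = FALSE)
    mean((fit$residuals / (1 - h))^2)
  }, numeric(1))
  which.min(errs)
}

#' @export
print.feature_regression <- function(x, ...) {
  cat("<feature_regression> order ", x$order,
      if (!is.na(x$n_components)) paste0(", PCA (", x$n_components,
                                         " components)"),
      ": R^2 = ", format(x$r_squared, digits = 3),
      ", F p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.feature_regression <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' @exportS3Method generics::glance
glance.feature_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, f_statistic = x$f_statistic,
                 p_value = x$p_value,
                 n_terms = length(x$terms), n_components = x$n_components)
}

#' Predict from a feature regression
#' @param object a `feature_regression`.
#' @param newdata tibble with the original feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.feature_regression <- function(object, newdata, ...) {
  X <- regression_design(newdata, rep(0, nrow(newdata)),
                         object$features, object$order)$X
  if (!is.null(object$projection)) {
    Z <- scale(X, object$projection$center, object$projection$scale)
    S <- Z %*% object$projection$rotation
    d <- as.data.frame(S)
    names(d) <- paste0("PC", seq_len(ncol(S)))
    stats::predict(object$model, d)
  } else {
    stats::predict(object$model, as.data.frame(X))
  }
}

#' Leave-one-subject-out prediction of targeting outcomes
#'
#' For each subject, removes all of that subject's rows, fits the feature
#' regression on the remaining rows, and predicts the held-out rows from
#' anatomical features alone. The aggregate prediction R-squared is
#' `1 - SS_residual / SS_total` over held-out predictions (so it can go
#' negative when prediction is worse than the mean).
#'
#' @inheritParams fit_feature_regression
#' @param subject_col column of `data` identifying the held-out unit.
#' @return list with `predictions` (tibble: subject id, observed,
#'   predicted) and `r_squared`.
#' @export
loso_predict <- function(data, response, features = NULL, order = 1,
                         use_pca = FALSE, pca_components = NULL,
                         subject_col = "subject_id") {
  ids <- data[[subject_col]]
  if (is.null(ids)) stop("no `", subject_col, "` column")
  uids <- unique(ids)
  if (length(uids) < 3) stop("leave-one-subject-out needs >= 3 subjects")
  y <- if (is.character(response) && length(response) == 1)
    data[[response]] else as.numeric(response)
  preds <- rep(NA_real_, nrow(data))
  for (u in uids) {
    hold <- ids == u
    fit <- fit_feature_regression(data[!hold, , drop = FALSE], y[!hold],
                                  features = features, order = order,
                                  use_pca = use_pca,
                                  pca_components = pca_components)
    preds[hold] <- predict(fit, data[hold, , drop = FALSE])
  }
  r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  list(predictions = tibble::tibble(subject_id = ids, observed = y,
                                    predicted = preds),
       r_squared = r2)
}
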