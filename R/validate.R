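#' Coefficient of determination
#'
#' `1 - SSE/SST` with the reference mean computed from `y` itself; the
#' statistic used for both training and test sets.  It can be negative
#' for predictions worse than the mean, and equals 1 only for a perfect
#' fit.  (The quantity is often loosely called a squared Pearson
#' correlation; the two differ for biased predictions, and this function
#' implements the 1 - SSE/SST form.)
#'
#' @param y Observed values (length >= 2, not constant).
#' @param yhat Predicted values.
#' @return The coefficient of determination.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < 2) stop("need at least two observations", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant y: zero denominator", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' External predictivity statistic
#'
#' Like [r_squared()] on the test set, but the denominator deviates the
#' observed test values from the training-set mean, so the spread of the
#' training activities enters the assessment.  Values of 0.6 and above
#' conventionally qualify a prediction model.
#'
#' @param y_test Observed test values.
#' @param yhat_test Predicted test values.
#' @param ybar_train Mean of the training-set observations.
#' @return The external predictivity statistic.
#' @export
r2_pred <- function(y_test, yhat_test, ybar_train) {
  stopifnot(length(y_test) == length(yhat_test))
  denom <- sum((y_test - ybar_train)^2)
  if (denom == 0) stop("all test values equal the training mean",
                       call. = FALSE)
  1 - sum((y_test - yhat_test)^2) / denom
}

#' Evaluate a fitted model on a training/test subset
#'
#' Predicts pIC50 for both sets (denormalized, i.e. on the experimental
#' scale), computes the training and test coefficients of determination
#' and the external predictivity statistic, flags qualification at the
#' 0.6 threshold and reports per-molecule residuals including the two
#' largest absolute errors.
#'
#' @param model A trained `ann_model`.
#' @param pca The matching [pca_fit()] model.
#' @param train_desc,test_desc Descriptor matrices (rownames = ids).
#' @param train_y,test_y Experimental pIC50 vectors.
#' @param subset_index Optional subset label carried into the report.
#' @return A `qsar_metrics` object; see [glance.qsar_metrics()] and
#'   [tidy.qsar_metrics()].
#' @export
evaluate_model <- function(model, pca, train_desc, train_y, test_desc,
                           test_y, subset_index = NA_integer_) {
  if (anyNA(train_y) || anyNA(test_y)) {
    bad <- c(rownames(train_desc)[is.na(train_y)],
             rownames(test_desc)[is.na(test_y)])
    stop("missing experimental pIC50 for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  yhat_train <- predict_pic50(model, pca, train_desc)
  yhat_test <- predict_pic50(model, pca, test_desc)
  res <- dplyr::bind_rows(
    tibble::tibble(id = rownames(train_desc), split = "train",
                   observed = train_y, predicted = yhat_train),
    tibble::tibble(id = rownames(test_desc), split = "test",
                   observed = test_y, predicted = yhat_test)
  )
  res$residual <- res$predicted - res$observed
  r2tr <- r_squared(train_y, yhat_train)
  r2te <- r_squared(test_y, yhat_test)
  r2pr <- r2_pred(test_y, yhat_test, mean(train_y))
  worst <- res[order(-abs(res$residual)), ][1:min(2, nrow(res)), ]
  structure(
    list(subset_index = subset_index,
         r2_train = r2tr, r2_test = r2te, r2_pred = r2pr,
         overtraining_gap = r2tr - r2te,
         qualified = r2pr >= 0.6,
         residuals = res,
         top_residuals = worst),
    class = "qsar_metrics"
  )
}

#' @export
print.qsar_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<qsar_metrics%s: R2_train %.3f, R2_test %.3f, r2_pred %.3f",
           " (%squalified)>\n"),
    if (is.na(x$subset_index)) "" else paste0(" subset ", x$subset_index),
    x$r2_train, x$r2_test, x$r2_pred, if (x$qualified) "" else "not "))
  invisible(x)
}

#' One-row summary of a metrics report
#'
#' @param x A `qsar_metrics` object.
#' @param ... Unused.
#' @return Tibble: `subset`, `r2_train`, `r2_test`, `r2_pred`,
#'   `overtraining_gap`, `qualified`.
#' @export
#' @exportS3Method
glance.qsar_metrics <- function(x, ...) {
  tibble::tibble(
    subset = x$subset_index, r2_train = x$r2_train, r2_test = x$r2_test,
    r2_pred = x$r2_pred, overtraining_gap = x$overtraining_gap,
    qualified = x$qualified
  )
}

#' Per-molecule residuals of a metrics report
#'
#' @param x A `qsar_metrics` object.
#' @param ... Unused.
#' @return Tibble: `id`, `split`, `observed`, `predicted`, `residual`.
#' @export
#' @exportS3Method
tidy.qsar_metrics <- function(x, ...) x$residuals

#' Experimental-vs-calculated scatter plot of a metrics report
#'
#' @param object A `qsar_metrics` object.
#' @param ... Unused.
#' @return A ggplot object: observed vs predicted pIC50, training and
#'   test molecules distinguished, identity line for reference.
#' @export
#' @exportS3Method
autoplot.qsar_metrics <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(train = "black", test = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "experimental pIC50", y = "calculated pIC50", colour = NULL,
      title = if (is.na(object$subset_index)) "pIC50 prediction" else
        sprintf("Subset %d: R2_train %.2f, R2_test %.2f, r2_pred %.2f",
                object$subset_index, object$r2_train, object$r2_test,
                object$r2_pred))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
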