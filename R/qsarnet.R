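#' Overflow-safe logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, evaluated so that extreme arguments saturate to 0
#' or 1 without overflow.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1) (closed at the ends only by floating-point
#'   saturation).
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

#' Min-max normalization of activities to [0, 1]
#'
#' Bounds are taken from the training set only; test values may map
#' outside [0, 1] and are not clipped.  `denormalize_activity()` inverts
#' the map exactly.
#'
#' @param y Numeric pIC50 values.
#' @param bounds List with `act_min`, `act_max` (see [activity_bounds()]).
#' @return Normalized values.
#' @export
normalize_activity <- function(y, bounds) {
  (y - bounds$act_min) / (bounds$act_max - bounds$act_min)
}

#' @rdname normalize_activity
#' @export
denormalize_activity <- function(y_norm, bounds) {
  y_norm * (bounds$act_max - bounds$act_min) + bounds$act_min
}

#' @rdname normalize_activity
#' @param y_train Training-set pIC50 values.
#' @export
activity_bounds <- function(y_train) {
  act_min <- min(y_train)
  act_max <- max(y_train)
  if (act_max <= act_min) {
    stop("degenerate activity bounds: act_max must exceed act_min",
         call. = FALSE)
  }
  list(act_min = act_min, act_max = act_max)
}

# weight container; w_in is N x M, w_out length M; no bias terms
new_ann_model <- function(w_in, w_out, bounds, seed, final_F = NA_real_,
                          iterations = 0L, converged = FALSE) {
  structure(
    list(n_in = nrow(w_in), n_hidden = ncol(w_in),
         w_in = w_in, w_out = as.numeric(w_out),
         act_min = bounds$act_min, act_max = bounds$act_max,
         seed = seed, final_F = final_F, iterations = iterations,
         converged = converged),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model %dx%dx1 sigmoid net: F = %.3g after %d iteration(s)%s>\n",
    x$n_in, x$n_hidden, x$final_F, x$iterations,
    if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Forward pass of the sigmoid feed-forward network
#'
#' Hidden activations `H = sgm(I %*% w_in)` and output
#' `O = sgm(H %*% w_out)`; no bias terms anywhere, matching the two-sum
#' composition the model is defined by.
#'
#' @param model An `ann_model`.
#' @param input Length-N vector or n x N matrix of (projected, normalized
#'   or raw score) inputs.
#' @return Scalar or length-n vector of outputs in (0, 1).
#' @export
ann_forward <- function(model, input) {
  if (is.null(dim(input))) input <- matrix(input, nrow = 1)
  if (ncol(input) != model$n_in) {
    stop("input width ", ncol(input), " does not match n_in = ", model$n_in,
         call. = FALSE)
  }
  H <- sigmoid(input %*% model$w_in)
  drop(sigmoid(H %*% model$w_out))
}

#' Sum-of-squares training loss
#'
#' `F = sum((D - O)^2)` over the training molecules, with normalized
#' targets D and network outputs O.
#'
#' @param model An `ann_model`.
#' @param inputs n x N input matrix.
#' @param targets_norm Length-n normalized targets.
#' @return The scalar loss F.
#' @export
ann_loss <- function(model, inputs, targets_norm) {
  if (length(targets_norm) != nrow(inputs)) stop("shape mismatch",
                                                 call. = FALSE)
  sum((targets_norm - ann_forward(model, inputs))^2)
}

# analytic backpropagation gradients of F wrt both weight layers
ann_gradient <- function(model, inputs, targets_norm) {
  Z1 <- inputs %*% model$w_in
  H <- sigmoid(Z1)
  o <- drop(sigmoid(H %*% model$w_out))
  delta_out <- 2 * (o - targets_norm) * o * (1 - o)         # n
  g_out <- drop(crossprod(H, delta_out))                    # M
  delta_hid <- (delta_out %o% model$w_out) * H * (1 - H)    # n x M
  g_in <- crossprod(inputs, delta_hid)                      # N x M
  list(w_in = g_in, w_out = g_out,
       loss = sum((targets_norm - o)^2))
}

#' Train the N x M x 1 network by full-batch gradient descent
#'
#' Weights start uniform in \[-0.5, 0.5\] from the seed.  Each iteration
#' takes a full-batch backpropagation step on the sum-of-squares loss F
#' over normalized targets; with `adaptive = TRUE` (default) a
#' bold-driver schedule grows the step by 5% after an accepted
#' (non-increasing) step and halves it, rejecting the move and resetting
#' momentum, after an increase, so F is non-increasing over accepted
#' steps.  Training stops at `F <= tol` (default 1e-4, the convergence
#' criterion of the model) or at `max_iter`.
#'
#' @param inputs n x N matrix of projected descriptor scores.
#' @param pic50 Length-n experimental activities (unnormalized).
#' @param n_hidden Hidden-layer width M (default 35).
#' @param seed Integer seed for the weight initialization.
#' @param lr Initial learning rate (default 0.1).
#' @param momentum Momentum coefficient (default 0.9; 0 disables).
#' @param max_iter Iteration cap (default 200000).
#' @param tol Convergence criterion on F (default 1e-4).
#' @param adaptive Use the bold-driver step control (default TRUE); with
#'   FALSE the step size stays fixed at `lr`.
#' @param record_trace Keep the per-iteration F trace (default TRUE).
#' @return List with `model` (an `ann_model`) and `record` (list: `F_trace`,
#'   `converged`, `stop_reason`, `iterations`).
#' @export
ann_train <- function(inputs, pic50, n_hidden = 35, seed = 1, lr = 0.1,
                      momentum = 0.9, max_iter = 200000, tol = 1e-4,
                      adaptive = TRUE, record_trace = TRUE) {
  inputs <- as.matrix(inputs)
  n <- nrow(inputs)
  if (length(pic50) != n) stop("shape mismatch between inputs and pic50",
                               call. = FALSE)
  bounds <- activity_bounds(pic50)
  d <- normalize_activity(pic50, bounds)
  n_in <- ncol(inputs)
  with_preserved_seed({
    set.seed(as.integer(seed))
    w_in <- matrix(stats::runif(n_in * n_hidden, -0.5, 0.5), n_in, n_hidden)
    w_out <- stats::runif(n_hidden, -0.5, 0.5)
  })
  v_in <- matrix(0, n_in, n_hidden)
  v_out <- numeric(n_hidden)
  step <- lr
  g <- ann_gradient(new_ann_model(w_in, w_out, bounds, seed), inputs, d)
  f_cur <- g$loss
  trace <- if (record_trace) numeric(min(max_iter, 2^20)) else NULL
  it <- 0L
  while (f_cur > tol && it < max_iter) {
    it <- it + 1L
    v_in <- momentum * v_in - step * g$w_in
    v_out <- momentum * v_out - step * g$w_out
    w_new_in <- w_in + v_in
    w_new_out <- w_out + v_out
    g_new <- ann_gradient(new_ann_model(w_new_in, w_new_out, bounds, seed),
                          inputs, d)
    if (!is.finite(g_new$loss)) {
      stop("non-finite loss at iteration ", it, call. = FALSE)
    }
    if (!adaptive || g_new$loss <= f_cur) {
      w_in <- w_new_in; w_out <- w_new_out
      g <- g_new
      f_cur <- g_new$loss
      if (adaptive) step <- step * 1.05
    } else {
      # rejected step: halve the rate, drop momentum, keep old weights
      step <- step / 2
      v_in[] <- 0
      v_out[] <- 0
    }
    if (record_trace) {
      if (it > length(trace)) trace <- c(trace, numeric(length(trace)))
      trace[it] <- f_cur
    }
  }
  converged <- f_cur <= tol
  model <- new_ann_model(w_in, w_out, bounds, seed, final_F = f_cur,
                         iterations = it, converged = converged)
  record <- list(
    F_trace = if (record_trace) trace[seq_len(it)] else NULL,
    converged = converged,
    stop_reason = if (converged) "tolerance" else "max_iter",
    iterations = it
  )
  list(model = model, record = record)
}

#' Predict pIC50 for a descriptor vector
#'
#' Projects the ESP descriptor with the fitted PCA model, runs the
#' network forward and denormalizes with the training-set activity
#' bounds.  Because the output neuron is a sigmoid, predictions always
#' fall strictly inside the training activity range - a documented range
#' limitation of the model.
#'
#' @param model A trained `ann_model`.
#' @param pca The [pca_fit()] model fitted on the same training subset.
#' @param descriptor K-vector or m x K matrix of ESP descriptors.
#' @return Predicted pIC50 value(s).
#' @export
predict_pic50 <- function(model, pca, descriptor) {
  if (pca$n_comp != model$n_in) {
    stop("PCA n_comp (", pca$n_comp, ") does not match network input width (",
         model$n_in, ")", call. = FALSE)
  }
  scores <- pca_project(pca, descriptor)
  denormalize_activity(
    ann_forward(model, scores),
    list(act_min = model$act_min, act_max = model$act_max))
}

#' Tidy network weights
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return Tibble with columns `layer` (`"input-hidden"` /
#'   `"hidden-output"`), `from`, `to`, `weight`.
#' @export
#' @exportS3Method
tidy.ann_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      layer = "input-hidden",
      from = rep(seq_len(x$n_in), x$n_hidden),
      to = rep(seq_len(x$n_hidden), each = x$n_in),
      weight = as.vector(x$w_in)),
    tibble::tibble(
      layer = "hidden-output",
      from = seq_len(x$n_hidden), to = 1L, weight = x$w_out)
  )
}

#' One-row training summary of a fitted network
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return Tibble: `n_in`, `n_hidden`, `iterations`, `final_F`,
#'   `converged`, `act_min`, `act_max`, `seed`.
#' @export
#' @exportS3Method
glance.ann_model <- function(x, ...) {
  tibble::tibble(
    n_in = x$n_in, n_hidden = x$n_hidden, iterations = x$iterations,
    final_F = x$final_F, converged = x$converged,
    act_min = x$act_min, act_max = x$act_max, seed = x$seed
  )
}

#' Write/read a fitted network as JSON
#'
#' Plain-text serialization of the weight matrices, activity bounds and
#' training metadata; `read_ann_model()` restores a model whose
#' predictions agree to near machine precision.
#'
#' @param model An `ann_model`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored model.
#' @export
write_ann_model <- function(model, path) {
  payload <- list(
    n_in = model$n_in, n_hidden = model$n_hidden,
    w_in = model$w_in, w_out = model$w_out,
    act_min = model$act_min, act_max = model$act_max,
    seed = model$seed, final_F = model$final_F,
    iterations = model$iterations, converged = model$converged
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ann_model(matrix(p$w_in, p$n_in, p$n_hidden), p$w_out,
                list(act_min = p$act_min, act_max = p$act_max),
                seed = p$seed, final_F = p$final_F,
                iterations = as.integer(p$iterations),
                converged = isTRUE(p$converged))
}
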