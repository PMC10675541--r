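test_that("sigmoid is exact, symmetric and saturates without overflow", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(c(1e4, -1e4)), c(1, 0))
  for (x in c(1, 10, 100, 750)) {
    expect_equal(sigmoid(x) + sigmoid(-x), 1, tolerance = 1e-12)
  }
  expect_no_warning(sigmoid(c(-1e6, 1e6)))
  expect_true(all(diff(sigmoid(seq(-5, 5, by = 0.1))) > 0))
})

test_that("activity normalization is exact and invertible", {
  y <- c(3.5, 9.0, 4.2, 7.7)
  b <- activity_bounds(y)
  n <- normalize_activity(y, b)
  expect_equal(n[1:2], c(0, 1))
  set.seed(3)
  y2 <- runif(56, 2.4, 9.41)
  b2 <- activity_bounds(y2)
  expect_equal(denormalize_activity(normalize_activity(y2, b2), b2), y2,
               tolerance = 1e-12)
  # extrapolation beyond the training bounds is not clipped
  expect_gt(normalize_activity(10, b2), 1)
  expect_error(activity_bounds(rep(5, 4)), "degenerate")
})

test_that("the forward pass equals a brute-force loop over the two sums", {
  # zero weights: hidden all 0.5, output sgm(0) = 0.5... except the
  # second layer sees 0.5 * 0 = 0, so output is exactly 0.5
  zero <- espqsar:::new_ann_model(matrix(0, 5, 3), rep(0, 3),
                                  list(act_min = 0, act_max = 1), seed = 1)
  expect_equal(ann_forward(zero, rnorm(5)), 0.5)

  # N = 1, M = 1 hand case: w_in = 0 -> H = 0.5, O = sgm(0.5 w)
  for (w in c(-2, 0.3, 1.7)) {
    m11 <- espqsar:::new_ann_model(matrix(0, 1, 1), w,
                                   list(act_min = 0, act_max = 1), seed = 1)
    expect_equal(ann_forward(m11, 123), sigmoid(0.5 * w), tolerance = 1e-14)
  }

  # vectorized path vs explicit loops on random 56-wide nets
  set.seed(14)
  for (rep in 1:3) {
    m <- espqsar:::new_ann_model(
      matrix(runif(56 * 35, -0.5, 0.5), 56, 35), runif(35, -0.5, 0.5),
      list(act_min = 0, act_max = 1), seed = 1)
    x <- rnorm(56)
    H <- vapply(1:35, function(i) sigmoid(sum(m$w_in[, i] * x)), 0)
    o_loop <- sigmoid(sum(m$w_out * H))
    expect_equal(ann_forward(m, x), o_loop, tolerance = 1e-12)
  }
  expect_error(ann_forward(zero, rnorm(4)), "width")
})

test_that("the loss is the plain sum of squared residuals", {
  m <- espqsar:::new_ann_model(matrix(0, 2, 2), c(0, 0),
                               list(act_min = 0, act_max = 1), seed = 1)
  X <- matrix(rnorm(4), 2, 2)
  # outputs are all 0.5; residuals 0.1 and 0.2 -> F = 0.05
  expect_equal(ann_loss(m, X, c(0.4, 0.7)), 0.05, tolerance = 1e-12)
  expect_equal(ann_loss(m, X, c(0.5, 0.5)), 0)
  expect_equal(ann_loss(m, X[2:1, ], c(0.7, 0.4)),
               ann_loss(m, X, c(0.4, 0.7)))
  expect_error(ann_loss(m, X, c(0.4, 0.7, 0.1)), "mismatch")
})

test_that("backprop gradients match central finite differences", {
  eps <- 1e-6
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6; N <- 8; M <- 4
    X <- matrix(rnorm(n * N), n, N)
    d <- runif(n, 0.1, 0.9)
    m <- espqsar:::new_ann_model(
      matrix(runif(N * M, -0.5, 0.5), N, M), runif(M, -0.5, 0.5),
      list(act_min = 0, act_max = 1), seed = seed)
    g <- espqsar:::ann_gradient(m, X, d)
    maxrel <- 0
    for (i in 1:N) for (j in 1:M) {
      up <- m; up$w_in[i, j] <- up$w_in[i, j] + eps
      dn <- m; dn$w_in[i, j] <- dn$w_in[i, j] - eps
      fd <- (ann_loss(up, X, d) - ann_loss(dn, X, d)) / (2 * eps)
      maxrel <- max(maxrel, abs(fd - g$w_in[i, j]) / max(1e-8, abs(fd)))
    }
    for (j in 1:M) {
      up <- m; up$w_out[j] <- up$w_out[j] + eps
      dn <- m; dn$w_out[j] <- dn$w_out[j] - eps
      fd <- (ann_loss(up, X, d) - ann_loss(dn, X, d)) / (2 * eps)
      maxrel <- max(maxrel, abs(fd - g$w_out[j]) / max(1e-8, abs(fd)))
    }
    expect_lt(maxrel, 1e-6)
  }
})

test_that("training is seeded, monotone over accepted steps, and inert at lr = 0", {
  set.seed(20)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- runif(12, 3, 9)

  # lr = 0: weights never move, stop_reason max_iter
  f0 <- ann_train(X, y, n_hidden = 4, seed = 5, lr = 0, max_iter = 50)
  expect_equal(f0$record$stop_reason, "max_iter")
  ref <- ann_train(X, y, n_hidden = 4, seed = 5, lr = 0, max_iter = 0)
  expect_identical(f0$model$w_in, ref$model$w_in)

  # bitwise determinism for a fixed seed
  f1 <- ann_train(X, y, n_hidden = 4, seed = 9, max_iter = 500)
  f2 <- ann_train(X, y, n_hidden = 4, seed = 9, max_iter = 500)
  expect_identical(f1$model$w_in, f2$model$w_in)
  expect_identical(f1$record$F_trace, f2$record$F_trace)

  # accepted-step trace is non-increasing under the bold driver
  expect_true(all(diff(f1$record$F_trace) <= 1e-12))

  # final F matches the loss recomputed from the stored weights
  b <- list(act_min = f1$model$act_min, act_max = f1$model$act_max)
  expect_equal(f1$model$final_F,
               ann_loss(f1$model, X, normalize_activity(y, b)),
               tolerance = 1e-12)

  # fixed small learning rate also descends monotonically
  f3 <- ann_train(X, y, n_hidden = 4, seed = 9, lr = 1e-3, momentum = 0,
                  adaptive = FALSE, max_iter = 300)
  expect_true(all(diff(f3$record$F_trace) <= 1e-12))
})

test_that("a realizable teacher is learned to the convergence criterion", {
  # noiseless targets generated by a same-architecture teacher network
  set.seed(33)
  X <- matrix(rnorm(16 * 8), 16, 8)
  teacher <- espqsar:::new_ann_model(
    matrix(runif(8 * 4, -0.5, 0.5), 8, 4), runif(4, -0.5, 0.5),
    list(act_min = 0, act_max = 1), seed = 1)
  y <- 3 + 5 * ann_forward(teacher, X)
  fit <- ann_train(X, y, n_hidden = 4, seed = 2, max_iter = 50000)
  expect_true(fit$record$converged)
  expect_lte(fit$model$final_F, 1e-4)
  # per-molecule residuals are bounded by the loss criterion
  b <- list(act_min = fit$model$act_min, act_max = fit$model$act_max)
  pred <- denormalize_activity(ann_forward(fit$model, X), b)
  expect_lt(max(abs(pred - y)), sqrt(1e-4) * (b$act_max - b$act_min) * 1.01)
})

test_that("predictions stay in range and ignore out-of-subspace noise", {
  set.seed(40)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- runif(10, 3, 9)
  fit <- ann_train(X, y, n_hidden = 3, seed = 7, max_iter = 2000)
  p <- pca_fit(matrix(rnorm(10 * 30), 10, 30), n_comp = 4)

  # PCA width must match the network input width
  wrong <- pca_fit(matrix(rnorm(20), 4, 5), n_comp = 3)
  expect_error(predict_pic50(fit$model, wrong, rnorm(30)), "match")

  # sigmoid output keeps predictions strictly inside the training range
  pred <- predict_pic50(fit$model, p, matrix(rnorm(3 * 30), 3, 30))
  expect_true(all(pred > fit$model$act_min & pred < fit$model$act_max))

  # adding a descriptor component orthogonal to the fitted subspace
  # leaves the prediction unchanged
  x0 <- rnorm(30)
  ortho <- x0 - p$mean -
    drop(p$components %*% crossprod(p$components, x0 - p$mean))
  expect_gt(sqrt(sum(ortho^2)), 0.1)       # genuinely out of subspace
  expect_equal(predict_pic50(fit$model, p, x0 + 5 * ortho),
               predict_pic50(fit$model, p, x0), tolerance = 1e-8)

  # degenerate (constant) activities are rejected at normalization
  expect_error(ann_train(X, rep(5, 10), n_hidden = 3, seed = 1),
               "degenerate")
})

test_that("model serialization round-trips predictions exactly", {
  set.seed(44)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- runif(8, 3, 9)
  fit <- ann_train(X, y, n_hidden = 3, seed = 3, max_iter = 200)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_model(fit$model, path)
  back <- read_ann_model(path)
  expect_equal(ann_forward(back, X), ann_forward(fit$model, X),
               tolerance = 1e-12)
  expect_equal(back$act_min, fit$model$act_min)
})
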