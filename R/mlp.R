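# One-hidden-layer feed-forward regression network trained full-batch with
# Levenberg-Marquardt and validation-based early stopping.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(theta, x, n_hidden) {
  w1 <- theta[seq_len(n_hidden)]
  b1 <- theta[n_hidden + seq_len(n_hidden)]
  w2 <- theta[2 * n_hidden + seq_len(n_hidden)]
  b2 <- theta[3 * n_hidden + 1]
  h <- sigmoid(outer(x, w1) + matrix(b1, length(x), n_hidden, byrow = TRUE))
  list(yhat = drop(h %*% w2) + b2, h = h)
}

# Jacobian of predictions wrt parameters (n x (3N+1))
mlp_jacobian <- function(theta, x, n_hidden, fwd) {
  w2 <- theta[2 * n_hidden + seq_len(n_hidden)]
  hp <- fwd$h * (1 - fwd$h)                       # sigmoid'
  d_w1 <- hp * matrix(w2, nrow(hp), n_hidden, byrow = TRUE) * x
  d_b1 <- hp * matrix(w2, nrow(hp), n_hidden, byrow = TRUE)
  cbind(d_w1, d_b1, fwd$h, 1)
}

#' Fit a small feed-forward calibration network
#'
#' A two-layer (one hidden layer) feed-forward network with `hidden_units`
#' sigmoid hidden neurons and a linear output neuron, mapping standardised
#' differential pressure to standardised flow. Training is full-batch
#' Levenberg-Marquardt: a damped Gauss-Newton step is accepted when it
#' reduces the training SSE (damping divided by 10) and rejected otherwise
#' (damping multiplied by 10). The samples are randomly split 70/15/15
#' into training, validation and test sets; training stops when the
#' validation MSE has not improved for `patience` accepted steps (or at
#' `max_iter`), and the best-validation weights are returned. Everything
#' is deterministic for a given seed.
#'
#' @inheritParams fit_root
#' @param hidden_units Hidden layer width N (>= 1).
#' @param seed Integer seed for the split and the uniform(-0.5, 0.5)
#'   weight initialisation.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param patience Accepted steps without validation improvement before
#'   stopping.
#' @param lambda0 Initial damping factor.
#' @param split Train/validation/test fractions (sums to 1).
#' @return An `mlp_model` with weights, standardisation constants, split
#'   indices, the validation-MSE history and a `report` whose `rmse_gof`
#'   is measured on the held-out test split.
#' @export
fit_mlp <- function(pairs, hidden_units = 7, seed = 1L,
                    max_iter = 1000L, patience = 6L, lambda0 = 1e-3,
                    split = c(0.7, 0.15, 0.15)) {
  stopifnot(hidden_units >= 1, abs(sum(split) - 1) < 1e-8)
  xy <- as_xy(pairs)
  n <- length(xy$x)
  if (n < 10L) stop("need at least 10 samples to form train/val/test splits", call. = FALSE)
  n_hidden <- as.integer(hidden_units)

  x_center <- mean(xy$x); x_scale <- sd(xy$x)
  y_center <- mean(xy$y); y_scale <- sd(xy$y)
  if (x_scale == 0) stop("all x identical: cannot standardise", call. = FALSE)
  if (y_scale == 0) y_scale <- 1   # constant targets are representable exactly
  xs <- (xy$x - x_center) / x_scale
  ys <- (xy$y - y_center) / y_scale

  with_seed(seed, {
    perm <- sample.int(n)
    n_tr <- max(1L, floor(split[1] * n))
    n_va <- max(1L, floor(split[2] * n))
    idx_tr <- perm[seq_len(n_tr)]
    idx_va <- perm[n_tr + seq_len(n_va)]
    idx_te <- perm[(n_tr + n_va + 1L):n]
    theta <- runif(3L * n_hidden + 1L, -0.5, 0.5)

    sse <- function(th, idx) {
      r <- mlp_forward(th, xs[idx], n_hidden)$yhat - ys[idx]
      sum(r^2)
    }
    lambda <- lambda0
    best_val <- Inf
    best_theta <- theta
    val_history <- numeric(0)
    stall <- 0L
    warn_overflow <- FALSE
    train_sse <- sse(theta, idx_tr)

    for (it in seq_len(max_iter)) {
      fwd <- mlp_forward(theta, xs[idx_tr], n_hidden)
      r <- fwd$yhat - ys[idx_tr]
      J <- mlp_jacobian(theta, xs[idx_tr], n_hidden, fwd)
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      accepted <- FALSE
      while (!accepted) {
        step <- tryCatch(
          solve(JtJ + lambda * diag(ncol(J)), -g),
          error = function(e) NULL
        )
        if (!is.null(step)) {
          cand <- theta + as.numeric(step)
          cand_sse <- sse(cand, idx_tr)
          if (is.finite(cand_sse) && cand_sse < train_sse) {
            theta <- cand
            train_sse <- cand_sse
            lambda <- lambda / 10
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
      if (!accepted) {
        warn_overflow <- lambda > 1e10
        break
      }
      val_mse <- sse(theta, idx_va) / length(idx_va)
      val_history <- c(val_history, val_mse)
      if (val_mse < best_val - 1e-15) {
        best_val <- val_mse
        best_theta <- theta
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    if (warn_overflow) {
      warning("Levenberg-Marquardt damping overflowed; returning best weights so far")
    }

    theta <- best_theta
    model <- structure(
      list(hidden_units = n_hidden,
           weights = list(w1 = theta[seq_len(n_hidden)],
                          b1 = theta[n_hidden + seq_len(n_hidden)],
                          w2 = theta[2 * n_hidden + seq_len(n_hidden)],
                          b2 = theta[3 * n_hidden + 1]),
           standardize = list(x_center = x_center, x_scale = x_scale,
                              y_center = y_center, y_scale = y_scale)),
      class = c("mlp_model", "calibration_model")
    )
    test_rmse <- rmse(xy$y[idx_te] - predict(model, xy$x[idx_te]))
    model$report <- list(rmse_gof = test_rmse, n_samples = n,
                         split = list(train = idx_tr, validation = idx_va, test = idx_te),
                         val_mse_history = val_history,
                         damping_overflow = warn_overflow)
    model
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (!length(x)) return(numeric(0))
  assert_finite(x, "newdata")
  s <- object$standardize
  theta <- c(object$weights$w1, object$weights$b1, object$weights$w2, object$weights$b2)
  ys <- mlp_forward(theta, (x - s$x_center) / s$x_scale, object$hidden_units)$yhat
  ys * s$y_scale + s$y_center
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model:ANN%d> test RMSE %.4g L/s on %d samples\n",
              x$hidden_units, x$report$rmse_gof, x$report$n_samples))
  invisible(x)
}
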