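# Regression families mapping conditioned differential pressure x (Pa) to
# reference flow y (L/s): asymmetric root-basis curves and polynomials,
# fitted by linear least squares with an optional least-absolute-residual
# robust refinement.

# term order fixed as (a, b, c, d, e) <-> (x, 1, x^1/2, x^1/3, x^1/4)
ROOT_TERMS <- c("a", "b", "c", "d", "e")
ROOT_VARIANTS <- list(
  root2only = "c",
  root2 = c("a", "b", "c"),
  root3 = c("a", "b", "c", "d"),
  root4 = c("a", "b", "c", "d", "e")
)

# design matrix over u >= 0 for the active terms
root_basis <- function(u, active) {
  cols <- list(a = u, b = rep(1, length(u)), c = sqrt(u),
               d = u^(1 / 3), e = u^(1 / 4))
  do.call(cbind, cols[active])
}

# plain or iteratively-reweighted least-absolute-residual linear fit.
# LAR weights are 1/max(|r|, 1e-6); iterate to coefficient change < 1e-8
# or 50 iterations.
lls_fit <- function(X, y, robust = FALSE) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("rank-deficient basis: the x samples do not span the model terms",
         call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  if (robust) {
    for (it in seq_len(50L)) {
      r <- y - X %*% beta
      w <- 1 / pmax(abs(r), 1e-6)
      sw <- sqrt(as.numeric(w))
      beta_new <- qr.coef(qr(X * sw), y * sw)
      if (max(abs(beta_new - beta)) < 1e-8) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
  }
  as.numeric(beta)
}

fit_report <- function(model, x, y, robust) {
  res <- y - predict(model, x)
  list(rmse_gof = rmse(res), n_samples = length(y), robust = robust)
}

#' Fit an asymmetric root-basis calibration curve
#'
#' Fits `y = a*x + b + c*x^(1/2) + d*x^(1/3) + e*x^(1/4)` on samples with
#' `x > 0` and the mirrored basis in `-x` on samples with `x < 0`, as two
#' independent branches (`x = 0` joins the positive branch). The variant
#' selects the active terms: `root2only` keeps only `c` (the ideal-orifice
#' square-root form), `root2` adds the linear and constant terms, `root3`
#' adds the cube root, `root4` the fourth root. Coefficients come from
#' linear least squares; with `robust = TRUE` a least-absolute-residual
#' refinement is applied by iterative reweighting.
#'
#' @param pairs A `conditioned_pair` (or list of them, pooled), or any list
#'   with `dp` and `flow` vectors.
#' @param variant One of `"root2only"`, `"root2"`, `"root3"`, `"root4"`.
#' @param robust Apply the least-absolute-residual refinement?
#' @return A `root_model` with `pos_coeffs` and `neg_coeffs` (named a-e,
#'   inactive terms zero) and a `report` (gof RMSE over all samples,
#'   sample count).
#' @export
fit_root <- function(pairs, variant = c("root4", "root3", "root2", "root2only"),
                     robust = FALSE) {
  variant <- match.arg(variant)
  active <- ROOT_VARIANTS[[variant]]
  xy <- as_xy(pairs)
  pos <- xy$x >= 0
  n_min <- 2L * length(active)
  if (sum(pos) < n_min || sum(!pos) < n_min) {
    stop(sprintf("need at least %d samples on each sign branch for '%s'",
                 n_min, variant), call. = FALSE)
  }
  fit_branch <- function(u, y) {
    beta <- lls_fit(root_basis(u, active), y, robust)
    full <- stats::setNames(numeric(5L), ROOT_TERMS)
    full[active] <- beta
    full
  }
  model <- structure(
    list(variant = variant,
         pos_coeffs = fit_branch(xy$x[pos], xy$y[pos]),
         neg_coeffs = fit_branch(-xy$x[!pos], xy$y[!pos]),
         active_terms = active),
    class = c("root_model", "calibration_model")
  )
  model$report <- fit_report(model, xy$x, xy$y, robust)
  model
}

#' @export
predict.root_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (!length(x)) return(numeric(0))
  assert_finite(x, "newdata")
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) out[pos] <- root_basis(x[pos], ROOT_TERMS) %*% object$pos_coeffs
  if (any(!pos)) out[!pos] <- root_basis(-x[!pos], ROOT_TERMS) %*% object$neg_coeffs
  out
}

#' Fit a polynomial calibration curve
#'
#' A single polynomial `y = p1 + p2*x + ... + p(d+1)*x^d` over the full
#' signed pressure range (no branch split). The coefficient convention
#' puts the constant term first (`p1`). Fitted by the same least-squares /
#' least-absolute-residual machinery as [fit_root()]. Polynomials are not
#' constrained to be monotone; use [is_monotone()] as a diagnostic.
#'
#' @inheritParams fit_root
#' @param degree Polynomial degree, 2-5.
#' @return A `poly_model` with `coeffs` (p1..p(d+1)) and a `report`.
#' @export
fit_poly <- function(pairs, degree = 5, robust = FALSE) {
  stopifnot(degree >= 2, degree <= 5)
  xy <- as_xy(pairs)
  if (length(unique(xy$x)) < degree + 2) {
    stop(sprintf("need at least %d distinct x values for degree %d",
                 degree + 2, degree), call. = FALSE)
  }
  X <- outer(xy$x, 0:degree, `^`)
  beta <- lls_fit(X, xy$y, robust)
  model <- structure(
    list(degree = degree,
         coeffs = stats::setNames(beta, paste0("p", seq_len(degree + 1)))),
    class = c("poly_model", "calibration_model")
  )
  model$report <- fit_report(model, xy$x, xy$y, robust)
  model
}

#' @export
predict.poly_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (!length(x)) return(numeric(0))
  assert_finite(x, "newdata")
  drop(outer(x, 0:object$degree, `^`) %*% object$coeffs)
}

#' Goodness of fit as RMSE
#'
#' Root mean squared error between the reference flow and the model's
#' prediction from the differential pressure, over all supplied samples.
#' Smaller is better; on real data it does not reach zero because the
#' sample cloud is not a perfect curve.
#'
#' @param model A fitted calibration model.
#' @param pairs Samples (see [fit_root()]).
#' @return RMSE in L/s.
#' @export
gof_rmse <- function(model, pairs) {
  xy <- as_xy(pairs)
  if (!length(xy$y)) stop("no samples", call. = FALSE)
  rmse(xy$y - predict(model, xy$x))
}

#' Monotonicity diagnostic for a calibration curve
#'
#' Checks that predicted flow is non-decreasing over a pressure range on a
#' dense grid. Root models are monotone by construction for typical
#' coefficient signs; polynomial fits can lose monotonicity near the data
#' range edges.
#'
#' @param model A fitted calibration model.
#' @param range Length-2 numeric: pressure interval in Pa.
#' @param n Grid size.
#' @return Logical.
#' @export
is_monotone <- function(model, range, n = 1000L) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  grid <- seq(range[1], range[2], length.out = n)
  all(diff(predict(model, grid)) >= -1e-12)
}

#' @export
print.root_model <- function(x, ...) {
  cat(sprintf("<root_model:%s> gof RMSE %.4g L/s on %d samples\n",
              x$variant, x$report$rmse_gof, x$report$n_samples))
  cat("  pos:", paste(sprintf("%s=%.4g", names(x$pos_coeffs), x$pos_coeffs), collapse = " "), "\n")
  cat("  neg:", paste(sprintf("%s=%.4g", names(x$neg_coeffs), x$neg_coeffs), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("<poly_model:degree %d> gof RMSE %.4g L/s on %d samples\n",
              x$degree, x$report$rmse_gof, x$report$n_samples))
  cat("  ", paste(sprintf("%s=%.4g", names(x$coeffs), x$coeffs), collapse = " "), "\n")
  invisible(x)
}

#' Serialise a calibration model to JSON
#'
#' Writes the model family, structure, coefficients (or weights and
#' standardisation constants for the network) and fit metadata. Models
#' written by this function are restored by [read_model()].
#'
#' @param model A fitted calibration model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- if (inherits(model, "root_model")) {
    list(family = "root", variant = model$variant,
         pos_coeffs = as.list(model$pos_coeffs),
         neg_coeffs = as.list(model$neg_coeffs))
  } else if (inherits(model, "poly_model")) {
    list(family = "poly", degree = model$degree, coeffs = as.list(model$coeffs))
  } else if (inherits(model, "mlp_model")) {
    list(family = "mlp", hidden_units = model$hidden_units,
         w1 = model$weights$w1, b1 = model$weights$b1,
         w2 = model$weights$w2, b2 = model$weights$b2,
         x_center = model$standardize$x_center, x_scale = model$standardize$x_scale,
         y_center = model$standardize$y_center, y_scale = model$standardize$y_scale)
  } else {
    stop("unknown model class", call. = FALSE)
  }
  obj$report <- model$report[c("rmse_gof", "n_samples")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path Path to a file written by [write_model()].
#' @return The restored calibration model.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- switch(obj$family,
    root = structure(
      list(variant = obj$variant,
           pos_coeffs = stats::setNames(as.numeric(obj$pos_coeffs), ROOT_TERMS),
           neg_coeffs = stats::setNames(as.numeric(obj$neg_coeffs), ROOT_TERMS),
           active_terms = ROOT_VARIANTS[[obj$variant]]),
      class = c("root_model", "calibration_model")),
    poly = structure(
      list(degree = obj$degree,
           coeffs = stats::setNames(as.numeric(obj$coeffs),
                                    paste0("p", seq_len(obj$degree + 1)))),
      class = c("poly_model", "calibration_model")),
    mlp = structure(
      list(hidden_units = obj$hidden_units,
           weights = list(w1 = as.numeric(obj$w1), b1 = as.numeric(obj$b1),
                          w2 = as.numeric(obj$w2), b2 = as.numeric(obj$b2)),
           standardize = list(x_center = obj$x_center, x_scale = obj$x_scale,
                              y_center = obj$y_center, y_scale = obj$y_scale)),
      class = c("mlp_model", "calibration_model")),
    stop(sprintf("unknown model family '%s' in '%s'", obj$family, path), call. = FALSE)
  )
  model$report <- obj$report
  model
}
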