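# Linear latent-space class model and latent/reconstruction quality metrics.
# The class model supplies the per-grade weight vectors that traversal shifts
# along; it is fitted on standardized semantic codes.

#' Fit the linear latent class model
#'
#' Multinomial logistic regression (ridge-regularized, symmetric
#' parameterization) on standardized semantic codes. The per-dimension
#' standardizer (mean, scale) is computed from the training codes and frozen
#' in the model; all later traversal arithmetic happens in this standardized
#' space. Regularization keeps the weight vectors finite and the fit
#' row-order invariant even on linearly separable cohorts.
#'
#' @param codes numeric matrix, one row per sample (semantic codes).
#' @param grades integer/factor class labels (grades 1..4; >= 2 classes).
#' @param lambda ridge penalty (small; default 1e-3).
#' @return An object of class `latent_class_model` with elements `mu`,
#'   `sigma`, `weights` (C x d, one row per class), `bias`, `classes`,
#'   `training_accuracy`.
#' @export
fit_latent_class_model <- function(codes, grades, lambda = 1e-3) {
  codes <- as.matrix(codes)
  grades <- as.integer(as.character(factor(grades)))
  if (nrow(codes) != length(grades)) dm_abort("codes/grades length mismatch")
  classes <- sort(unique(grades))
  if (length(classes) < 2) dm_abort("need at least two classes to fit the latent class model")
  d <- ncol(codes)
  if (nrow(codes) < d / 10) {
    warn(sprintf("only %d samples for %d code dimensions; fit may be unstable",
                 nrow(codes), d))
  }
  mu <- colMeans(codes)
  sigma <- apply(codes, 2, sd)
  sigma[!is.finite(sigma) | sigma < 1e-8] <- 1
  z <- sweep(sweep(codes, 2, mu), 2, sigma, "/")
  fit <- glmnet::glmnet(z, factor(grades, levels = classes),
                        family = "multinomial", alpha = 0, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  co <- stats::coef(fit, s = lambda)
  weights <- t(vapply(co, function(m) as.numeric(m)[-1], numeric(d)))
  bias <- vapply(co, function(m) as.numeric(m)[1], numeric(1))
  rownames(weights) <- names(bias) <- as.character(classes)
  colnames(weights) <- colnames(codes) %||% paste0("z", seq_len(d))
  model <- structure(list(
    mu = mu, sigma = sigma, weights = weights, bias = bias,
    classes = classes, lambda = lambda, n = nrow(codes), fitted = TRUE
  ), class = "latent_class_model")
  acc <- mean(predict_grade_code(model, codes) == grades)
  model$training_accuracy <- acc
  inform(sprintf("latent class model: %d samples, %d dims, training accuracy %.3f",
                 nrow(codes), d, acc))
  model
}

check_fitted <- function(model) {
  if (!inherits(model, "latent_class_model") || !isTRUE(model$fitted)) {
    dm_abort("latent class model is not fitted")
  }
  invisible(model)
}

#' Standardize a semantic code with a fitted class model
#'
#' Entry j maps to `(x_j - mu_j) / sigma_j` using the standardizer frozen in
#' the model. [destandardize()] is the exact inverse.
#'
#' @param code numeric vector (length d) or matrix (n x d).
#' @param model fitted `latent_class_model`.
#' @return Standardized code, same shape.
#' @export
standardize <- function(code, model) {
  check_fitted(model)
  if (is.matrix(code)) {
    sweep(sweep(code, 2, model$mu), 2, model$sigma, "/")
  } else {
    (code - model$mu) / model$sigma
  }
}

#' @rdname standardize
#' @export
destandardize <- function(code, model) {
  check_fitted(model)
  if (is.matrix(code)) {
    sweep(sweep(code, 2, model$sigma, "*"), 2, model$mu, "+")
  } else {
    code * model$sigma + model$mu
  }
}

#' Class logits and predicted grade for semantic codes
#'
#' @param model fitted `latent_class_model`.
#' @param codes vector or matrix of raw (unstandardized) codes.
#' @return `class_logits`: n x C matrix; `predict_grade_code`: integer vector.
#' @export
class_logits <- function(model, codes) {
  check_fitted(model)
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1)
  z <- standardize(codes, model)
  sweep(z %*% t(model$weights), 2, model$bias, "+")
}

#' @rdname class_logits
#' @export
predict_grade_code <- function(model, codes) {
  lg <- class_logits(model, codes)
  model$classes[max.col(lg, ties.method = "first")]
}

#' @export
print.latent_class_model <- function(x, ...) {
  cat(sprintf("<latent_class_model  classes: %s  d=%d  accuracy=%.3f>\n",
              paste(x$classes, collapse = ","), ncol(x$weights),
              x$training_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-class weight vectors of a latent class model
#'
#' @param x fitted `latent_class_model`.
#' @param ... unused.
#' @return Tibble with columns class, term, estimate.
#' @export
tidy.latent_class_model <- function(x, ...) {
  check_fitted(x)
  tibble(
    class = rep(x$classes, each = ncol(x$weights)),
    term = rep(colnames(x$weights), length(x$classes)),
    estimate = as.numeric(t(x$weights))
  )
}

#' @rdname tidy.latent_class_model
#' @export
glance.latent_class_model <- function(x, ...) {
  tibble(n = x$n, d = ncol(x$weights), n_classes = length(x$classes),
         lambda = x$lambda, training_accuracy = x$training_accuracy)
}

#' Neighborhood quality metrics of a latent embedding
#'
#' For every sample, takes its k nearest neighbours (Euclidean, excluding
#' self, ties broken by sample index) and reports the average fraction coming
#' from the same slide and carrying the same grade, plus the held-out accuracy
#' of a linear discriminant separating low ({1,2}) from high ({3,4}) grades.
#'
#' @param codes n x d matrix of codes.
#' @param slide_ids character vector of slide identifiers.
#' @param grades integer grades 1..4.
#' @param k neighbourhood size (default 10; must satisfy k < n).
#' @param split_seed seed of the 50/50 train/test split for the LDA accuracy.
#' @return One-row tibble: same_slide_fraction, same_grade_fraction,
#'   low_vs_high_linear_accuracy, k, n.
#' @export
latent_quality_metrics <- function(codes, slide_ids, grades, k = 10,
                                   split_seed = 1) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (n < k + 1) dm_abort("need at least k + 1 samples for k-NN metrics")
  stopifnot(length(slide_ids) == n, length(grades) == n)
  dmat <- as.matrix(dist(codes))
  diag(dmat) <- Inf
  same_slide <- same_grade <- numeric(n)
  for (i in seq_len(n)) {
    nn <- order(dmat[i, ], seq_len(n))[seq_len(k)]
    same_slide[i] <- mean(slide_ids[nn] == slide_ids[i])
    same_grade[i] <- mean(grades[nn] == grades[i])
  }
  high <- factor(grades >= 3, levels = c(FALSE, TRUE))
  keep <- apply(codes, 2, sd) > 1e-10   # constant dims carry no signal
  acc <- with_seed(split_seed, {
    idx <- sample(n, floor(n / 2))
    if (length(unique(high[idx])) < 2 || !any(keep)) {
      NA_real_
    } else {
      ld <- MASS::lda(codes[idx, keep, drop = FALSE], grouping = high[idx])
      mean(predict(ld, codes[-idx, keep, drop = FALSE])$class == high[-idx])
    }
  })
  tibble(same_slide_fraction = mean(same_slide),
         same_grade_fraction = mean(same_grade),
         low_vs_high_linear_accuracy = acc,
         k = as.integer(k), n = as.integer(n))
}

# structural similarity, standard constants (K1=0.01, K2=0.03, L=1,
# Gaussian window sigma 1.5, radius 5)
ssim_channel <- function(x, y, sigma = 1.5, radius = 5) {
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- gaussian_smooth(x, sigma, radius)
  my <- gaussian_smooth(y, sigma, radius)
  sxx <- gaussian_smooth(x * x, sigma, radius) - mx^2
  syy <- gaussian_smooth(y * y, sigma, radius) - my^2
  sxy <- gaussian_smooth(x * y, sigma, radius) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Reconstruction quality metrics (MSE, PSNR, SSIM)
#'
#' Standard definitions for images in \[0, 1\]; PSNR in dB with peak 1
#' (`Inf` for identical images); SSIM with the usual Gaussian window and
#' constants, averaged over channels.
#'
#' @param original,reconstruction images of identical dimensions, in \[0,1\].
#' @return One-row tibble: mse, psnr, ssim.
#' @export
reconstruction_metrics <- function(original, reconstruction) {
  if (!identical(dim(original), dim(reconstruction))) {
    dm_abort("reconstruction_metrics: image dimensions differ")
  }
  mse <- mean((original - reconstruction)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  if (length(dim(original)) == 3) {
    ssim <- mean(vapply(seq_len(dim(original)[3]), function(ch) {
      ssim_channel(original[, , ch], reconstruction[, , ch])
    }, numeric(1)))
  } else {
    ssim <- ssim_channel(as.matrix(original), as.matrix(reconstruction))
  }
  tibble(mse = mse, psnr = psnr, ssim = ssim)
}
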