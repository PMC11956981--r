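# A deliberately small trainable backend satisfying the generative-backend
# contract on synthetic cohorts: a fixed seeded convolutional feature bank
# feeds a linear encoder to a low-dimensional code; a linear decoder maps the
# code back to a low-resolution image which is bilinearly upsampled. The two
# linear maps are trained by alternating least squares, so the reconstruction
# loss decreases monotonically by construction. Its convolutional stage
# doubles as a trained Delta-March filter via [filter_from_backend()].

toy_conv_net <- function(seed = 17) {
  w1 <- with_seed(seed, array(rnorm(3 * 3 * 3 * 8, 0, 1 / sqrt(27)),
                              dim = c(3, 3, 3, 8)))
  w2 <- with_seed(seed + 1, array(rnorm(3 * 3 * 8 * 16, 0, 1 / sqrt(72)),
                                  dim = c(3, 3, 8, 16)))
  filter_net(list(
    list(type = "conv", w = w1, b = numeric(8), activation = "relu"),
    list(type = "pool", size = 2L),
    list(type = "conv", w = w2, b = numeric(16), activation = "relu"),
    list(type = "pool", size = 2L)
  ), name = sprintf("toy-ae-conv-%d", seed))
}

downsample_image <- function(image, size) {
  out <- array(0, dim = c(size, size, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- bilinear_resize(image[, , ch], size, size)
  }
  out
}

flatten_features <- function(stack) {
  unlist(lapply(stack$channels, as.numeric), use.names = FALSE)
}

#' Train the toy autoencoder backend
#'
#' @param cohort cohort list as from [make_cohort()] (>= 200 patches
#'   recommended; fewer triggers a warning).
#' @param code_dim semantic code length (default 32).
#' @param epochs alternating-least-squares rounds (default 4).
#' @param recon_size side of the decoded low-resolution image (default 48).
#' @param lambda ridge stabilizer of both linear solves (default 1e-6,
#'   relative to feature scale).
#' @param seed seed of the convolutional bank and encoder initialization.
#' @return A `dm_backend` (kind "toy") whose `encode` takes a
#'   `labeled_patch`, `encode_stochastic` returns NULL (the decoder is
#'   deterministic and carries no stochastic state), and `decode(code)`
#'   returns a patch with image only. Extra elements: `filter_net`, `loss`
#'   (per-epoch reconstruction MSE), `patch_size`.
#' @export
train_toy_autoencoder <- function(cohort, code_dim = 32, epochs = 4,
                                  recon_size = 48, lambda = 1e-6, seed = 17) {
  patches <- cohort$patches %||% cohort
  n <- length(patches)
  if (n < 200) warn(sprintf("toy autoencoder: only %d patches (< 200 recommended)", n))
  net <- toy_conv_net(seed)
  patch_size <- nrow(patches[[1]]$image)

  phi <- t(vapply(patches, function(p) {
    flatten_features(extract_features(p$image, net))
  }, numeric(length(flatten_features(extract_features(patches[[1]]$image, net))))))
  y <- t(vapply(patches, function(p) {
    as.numeric(downsample_image(p$image, recon_size))
  }, numeric(recon_size * recon_size * 3)))
  phi_mean <- colMeans(phi); y_mean <- colMeans(y)
  phi_c <- sweep(phi, 2, phi_mean)
  y_c <- sweep(y, 2, y_mean)

  # dual-form ridge for the encoder (p >> n): A' = phi' (phi phi' + l I)^-1 Z
  gram <- phi_c %*% t(phi_c)
  ridge <- lambda * mean(diag(gram))
  a_mat <- with_seed(seed + 2,
                     matrix(rnorm(code_dim * ncol(phi), 0, 1e-3), code_dim))
  loss <- numeric(epochs)
  z <- NULL; b_mat <- NULL
  for (e in seq_len(epochs)) {
    z <- phi_c %*% t(a_mat)                               # n x code_dim
    # decoder: least squares y_c ~ z
    b_mat <- t(solve(crossprod(z) + 1e-10 * diag(code_dim), t(z) %*% y_c))
    # encoder: dual ridge towards the decoder's preimage targets
    z_target <- y_c %*% b_mat %*% solve(crossprod(b_mat) + 1e-10 * diag(code_dim))
    a_mat <- t(t(phi_c) %*% solve(gram + ridge * diag(n), z_target))
    z <- phi_c %*% t(a_mat)
    b_mat <- t(solve(crossprod(z) + 1e-10 * diag(code_dim), t(z) %*% y_c))
    recon <- z %*% t(b_mat)
    loss[e] <- mean((y_c - recon)^2)
    if (!is.finite(loss[e])) {
      dm_abort(sprintf("toy autoencoder diverged at epoch %d (loss %s)", e, loss[e]))
    }
  }
  inform(sprintf("toy autoencoder: %d patches, loss %s",
                 n, paste(signif(loss, 4), collapse = " -> ")))

  encode <- function(x) {
    img <- if (is.list(x) && !is.null(x$image)) x$image else x
    f <- flatten_features(extract_features(img, net))
    as.numeric(a_mat %*% (f - phi_mean))
  }
  decode <- function(code, state = NULL) {
    flat <- as.numeric(code %*% t(b_mat)) + y_mean
    small <- array(pmin(pmax(flat, 0), 1), dim = c(recon_size, recon_size, 3))
    img <- array(0, dim = c(patch_size, patch_size, 3))
    for (ch in 1:3) img[, , ch] <- bilinear_resize(small[, , ch], patch_size, patch_size)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, nuclei_mask = NULL, vasc_mask = NULL,
                   slide_id = NA_character_, grade_label = NA_integer_,
                   params = NULL, nucleoli_truth = NULL),
              class = "labeled_patch")
  }
  structure(list(
    kind = "toy",
    encode = encode,
    encode_stochastic = function(patch) NULL,
    decode = decode,
    code_dim = as.integer(code_dim),
    code_names = paste0("z", seq_len(code_dim)),
    filter_net = net,
    loss = loss,
    patch_size = as.integer(patch_size)
  ), class = "dm_backend")
}

#' Delta-March filter derived from a trained backend
#'
#' Returns the backend's convolutional stage as a `filter_net` (the analogue
#' of reusing the first layers of a pretrained autoencoder as the Delta-March
#' filter).
#'
#' @param backend a toy `dm_backend`.
#' @return A `filter_net`.
#' @export
filter_from_backend <- function(backend) {
  stopifnot(inherits(backend, "dm_backend"))
  backend$filter_net %||% dm_abort("backend exposes no filter network")
}
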