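# Delta-Maps: localized saliency of change between two images, computed by
# differencing intermediate feature maps of a small convolutional filter
# network, upscaling each channel to image size (bilinear, align-corners off),
# taking absolute values and averaging over channels.

#' Construct a filter network
#'
#' A filter network is an ordered list of layers, each either a convolution
#' (`type = "conv"`, weights `[kh, kw, c_in, c_out]`, bias per output channel,
#' activation "linear" or "relu") or an average pooling (`type = "pool"`,
#' integer factor). Depth is counted in layers, pooling included.
#'
#' @param layers list of layer specs.
#' @param name optional identifier recorded in manifests.
#' @return An object of class `filter_net`.
#' @export
filter_net <- function(layers, name = "custom") {
  for (ly in layers) {
    if (!ly$type %in% c("conv", "pool")) dm_abort("unknown layer type")
    if (ly$type == "conv") stopifnot(length(dim(ly$w)) == 4)
  }
  structure(list(layers = layers, name = name), class = "filter_net")
}

#' @export
print.filter_net <- function(x, ...) {
  kinds <- vapply(x$layers, function(l) {
    if (l$type == "conv") {
      d <- dim(l$w)
      sprintf("conv %dx%d %d->%d (%s)", d[1], d[2], d[3], d[4], l$activation)
    } else sprintf("pool /%d", l$size)
  }, character(1))
  cat(sprintf("<filter_net '%s': %s>\n", x$name, paste(kinds, collapse = ", ")))
  invisible(x)
}

#' Default untrained multi-scale filter bank
#'
#' A fixed two-stage convolutional filter: stage one applies per-channel
#' identity, Sobel, Laplacian and smoothing kernels to the RGB planes; stage
#' two mixes them with seeded random 3x3 kernels. Deterministic given the
#' seed; useful as a structure-sensitive Delta-March filter when no trained
#' backend is available.
#'
#' @param in_channels input channel count (3 for RGB).
#' @param mix_channels output channels of the mixing stage.
#' @param seed seed for the mixing weights.
#' @return A `filter_net` with layers conv, pool, conv, pool.
#' @export
default_filter_net <- function(in_channels = 3, mix_channels = 16, seed = 11) {
  ident <- matrix(0, 3, 3); ident[2, 2] <- 1
  sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 4
  sobel_y <- t(sobel_x)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE) / 4
  blur <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
  basis <- list(ident, sobel_x, sobel_y, lap, blur)
  c1 <- length(basis) * in_channels
  w1 <- array(0, dim = c(3, 3, in_channels, c1))
  k <- 0
  for (b in basis) for (ci in seq_len(in_channels)) {
    k <- k + 1
    w1[, , ci, k] <- b
  }
  w2 <- with_seed(seed,
    array(rnorm(3 * 3 * c1 * mix_channels, 0, 1 / sqrt(9 * c1)),
          dim = c(3, 3, c1, mix_channels)))
  filter_net(list(
    list(type = "conv", w = w1, b = numeric(c1), activation = "linear"),
    list(type = "pool", size = 2L),
    list(type = "conv", w = w2, b = numeric(mix_channels), activation = "linear"),
    list(type = "pool", size = 2L)
  ), name = sprintf("multiscale-bank-%d", seed))
}

apply_conv_layer <- function(feats, ly) {
  d <- dim(ly$w)
  if (length(feats) != d[3]) dm_abort("filter layer channel mismatch")
  out <- vector("list", d[4])
  for (co in seq_len(d[4])) {
    acc <- matrix(ly$b[co], nrow(feats[[1]]), ncol(feats[[1]]))
    for (ci in seq_len(d[3])) {
      k <- ly$w[, , ci, co]
      if (any(k != 0)) acc <- acc + conv2d_same(feats[[ci]], k)
    }
    if (identical(ly$activation, "relu")) acc <- pmax(acc, 0)
    out[[co]] <- acc
  }
  out
}

apply_pool_layer <- function(feats, size) {
  lapply(feats, function(m) {
    h <- (nrow(m) %/% size) * size; w <- (ncol(m) %/% size) * size
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    # average pool by block sums
    m2 <- matrix(colMeans(matrix(m, size)), h %/% size, w)
    t(matrix(colMeans(matrix(t(m2), size)), w %/% size, h %/% size))
  })
}

#' Extract an intermediate feature stack
#'
#' Applies the first `depth` layers of a filter network to an image.
#' Deterministic: identical inputs give bit-identical stacks.
#'
#' @param image H x W x C array (or matrix for single-channel input).
#' @param net a `filter_net`.
#' @param depth number of layers to apply (pooling layers count).
#' @return A `feature_stack`: list of channel matrices plus source size.
#' @export
extract_features <- function(image, net, depth = length(net$layers)) {
  stopifnot(inherits(net, "filter_net"))
  if (depth > length(net$layers)) {
    dm_abort(sprintf("depth %d exceeds network depth %d", depth, length(net$layers)))
  }
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  feats <- lapply(seq_len(dim(image)[3]), function(ch) image[, , ch])
  for (ly in net$layers[seq_len(depth)]) {
    feats <- if (ly$type == "conv") apply_conv_layer(feats, ly)
    else apply_pool_layer(feats, ly$size)
  }
  structure(list(channels = feats, source_h = dim(image)[1],
                 source_w = dim(image)[2]),
            class = "feature_stack")
}

#' Compute the Delta-Map of an image pair
#'
#' Pipeline order: per-channel feature subtraction, bilinear upscale of each
#' channel to the source image size, absolute value, mean over channels. The
#' result is symmetric in its arguments.
#'
#' @param image_a,image_b images of identical size.
#' @param net a `filter_net`.
#' @param depth layers to apply (default: whole net).
#' @return A `delta_map` with element `raw` (H x W, non-negative).
#' @export
compute_delta_map <- function(image_a, image_b, net, depth = length(net$layers)) {
  if (!identical(dim(image_a), dim(image_b))) {
    dm_abort("compute_delta_map: image dimensions differ")
  }
  fa <- extract_features(image_a, net, depth)
  fb <- extract_features(image_b, net, depth)
  h <- fa$source_h; w <- fa$source_w
  acc <- matrix(0, h, w)
  for (ch in seq_along(fa$channels)) {
    diff_up <- bilinear_resize(fa$channels[[ch]] - fb$channels[[ch]], h, w)
    acc <- acc + abs(diff_up)
  }
  structure(list(raw = acc / length(fa$channels), normalized = NULL,
                 binary = NULL, threshold = NULL,
                 filter = net$name, depth = depth),
            class = "delta_map")
}

#' Normalize and binarize a Delta-Map
#'
#' Default normalization is per-patch min-max scaling to \[0, 1\] (a constant
#' map normalizes to all zeros); `mode = "min"` subtracts the per-patch
#' minimum only. Binarization keeps values strictly greater than the
#' threshold.
#'
#' @param map a `delta_map`.
#' @param threshold binarization threshold (default 0.5).
#' @param mode "minmax" (default) or "min".
#' @return The `delta_map` with `normalized`, `binary`, `threshold` filled in.
#' @export
normalize_binarize <- function(map, threshold = 0.5, mode = c("minmax", "min")) {
  stopifnot(inherits(map, "delta_map"))
  mode <- match.arg(mode)
  raw <- map$raw
  lo <- min(raw); hi <- max(raw)
  norm <- if (mode == "minmax") {
    if (hi > lo) (raw - lo) / (hi - lo) else matrix(0, nrow(raw), ncol(raw))
  } else {
    raw - lo
  }
  map$normalized <- norm
  map$binary <- matrix(as.integer(norm > threshold), nrow(raw), ncol(raw))
  map$threshold <- threshold
  map$norm_mode <- mode
  map
}

#' @export
print.delta_map <- function(x, ...) {
  cat(sprintf("<delta_map %dx%d  filter=%s depth=%d  %s>\n",
              nrow(x$raw), ncol(x$raw), x$filter, x$depth,
              if (is.null(x$binary)) "raw" else
                sprintf("binarized@%.2f (%.1f%% on)", x$threshold,
                        100 * mean(x$binary))))
  invisible(x)
}

#' Plot a Delta-Map as a raster
#'
#' @param object a `delta_map`.
#' @param which "raw", "normalized" or "binary".
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.delta_map <- function(object, which = c("raw", "normalized", "binary"),
                               ...) {
  which <- match.arg(which)
  m <- object[[which]]
  if (is.null(m)) dm_abort(sprintf("delta_map has no '%s' layer; run normalize_binarize()", which))
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.numeric(m[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = which) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Delta-Map (%s, depth %d)", object$filter,
                                  object$depth))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' March over a trajectory: one Delta-Map per grade sub-transition
#'
#' Splits a trajectory into sub-transitions at the first node where the
#' predicted grade changes, and computes one Delta-Map per adjacent grade
#' pair. With `direct = TRUE` the single start-vs-end map is returned instead
#' (the large-jump comparison).
#'
#' @param trajectory a `dm_trajectory` (see [traverse_grade()]).
#' @param net a `filter_net`.
#' @param depth layers to apply.
#' @param direct if TRUE, return one start-to-end map.
#' @param threshold,mode passed to [normalize_binarize()].
#' @return A list of binarized `delta_map`s; each carries attributes
#'   `from_grade`, `to_grade`, `from_node`, `to_node`.
#' @export
march <- function(trajectory, net, depth = length(net$layers), direct = FALSE,
                  threshold = 0.5, mode = "minmax") {
  stopifnot(inherits(trajectory, "dm_trajectory"))
  nodes <- trajectory$nodes
  if (nrow(nodes) < 2) dm_abort("march: trajectory has fewer than two nodes")
  pairs <- if (direct) {
    list(c(1L, nrow(nodes)))
  } else {
    bounds <- sub_transition_boundaries(nodes$pred_grade)
    if (length(bounds) < 2) bounds <- c(1L, nrow(nodes))  # no grade change
    purrr::map(seq_len(length(bounds) - 1), ~ c(bounds[.x], bounds[.x + 1]))
  }
  purrr::map(pairs, function(pr) {
    dm <- compute_delta_map(nodes$patch[[pr[1]]]$image,
                            nodes$patch[[pr[2]]]$image, net, depth)
    dm <- normalize_binarize(dm, threshold = threshold, mode = mode)
    attr(dm, "from_node") <- pr[1]
    attr(dm, "to_node") <- pr[2]
    attr(dm, "from_grade") <- nodes$pred_grade[pr[1]]
    attr(dm, "to_grade") <- nodes$pred_grade[pr[2]]
    dm
  })
}

# boundary rule: the first node at which the predicted grade changes opens a
# new sub-transition; segments run between first nodes of consecutive
# predicted grades (a monotone 1->4 trajectory gives 1->2, 2->3, 3->4)
sub_transition_boundaries <- function(pred_grades) {
  change <- which(diff(pred_grades) != 0) + 1L
  unique(c(1L, change))
}
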