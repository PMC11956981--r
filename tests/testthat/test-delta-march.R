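test_that("feature extraction is deterministic with contracted shapes", {
  net <- default_filter_net()
  img <- array(with_seed2(1, runif(24 * 24 * 3)), dim = c(24, 24, 3))
  fa <- extract_features(img, net)
  fb <- extract_features(img, net)
  expect_identical(fa, fb)
  expect_length(fa$channels, 16)         # mixing stage channels
  expect_equal(dim(fa$channels[[1]]), c(6, 6))  # two /2 poolings
  expect_error(extract_features(img, net, depth = 9), "exceeds")
})

test_that("a zero image through a bias-free linear filter gives a zero stack", {
  net <- hand_filter(seed = 2)
  net$layers[[1]]$b <- c(0, 0)
  st <- extract_features(matrix(0, 12, 12), filter_net(list(
    list(type = "conv", w = array(1, dim = c(3, 3, 1, 2)), b = c(0, 0),
         activation = "linear"))))
  expect_true(all(vapply(st$channels, function(m) all(m == 0), logical(1))))
})

test_that("delta maps vanish for identical pairs and are symmetric", {
  net <- hand_filter()
  img <- array(with_seed2(3, runif(16 * 16 * 3)), dim = c(16, 16, 3))
  img2 <- array(with_seed2(4, runif(16 * 16 * 3)), dim = c(16, 16, 3))
  expect_true(all(compute_delta_map(img, img, net)$raw == 0))
  expect_identical(compute_delta_map(img, img2, net)$raw,
                   compute_delta_map(img2, img, net)$raw)
  expect_true(all(compute_delta_map(img, img2, net)$raw >= 0))
  expect_error(compute_delta_map(img, img2[1:8, 1:8, , drop = FALSE], net),
               "differ")
})

test_that("the pipeline matches a brute-force per-pixel recomputation", {
  net <- hand_filter(seed = 9)
  a <- array(with_seed2(11, runif(8 * 8 * 3)), dim = c(8, 8, 3))
  b <- array(with_seed2(12, runif(8 * 8 * 3)), dim = c(8, 8, 3))
  got <- compute_delta_map(a, b, net)$raw
  want <- oracle_delta_map(a, b, net)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("scaling both inputs of a linear filter scales the raw map by |c|", {
  net <- hand_filter(seed = 5)
  net$layers[[1]]$b <- c(0, 0)   # strictly linear
  a <- array(with_seed2(13, runif(12 * 12 * 3)), dim = c(12, 12, 3))
  b <- array(with_seed2(14, runif(12 * 12 * 3)), dim = c(12, 12, 3))
  base <- compute_delta_map(a, b, net)$raw
  for (c_ in c(2, -3)) {
    scaled <- compute_delta_map(c_ * a, c_ * b, net)$raw
    expect_equal(scaled, abs(c_) * base, tolerance = 1e-12)
  }
})

test_that("normalization and binarization follow the strict-threshold rule", {
  mk <- function(raw) structure(list(raw = raw, filter = "x", depth = 1),
                                class = "delta_map")
  const <- normalize_binarize(mk(matrix(3.7, 5, 5)))
  expect_true(all(const$normalized == 0))
  expect_true(all(const$binary == 0))
  cb <- matrix(c(0, 1), 4, 4)
  bin <- normalize_binarize(mk(cb))$binary
  expect_equal(bin, matrix(as.integer(cb == 1), 4, 4))
  raw <- matrix(with_seed2(6, runif(256)), 16, 16)
  nb <- normalize_binarize(mk(raw))
  # enumeration oracle: strictly above midrange after min-max scaling
  mid <- min(raw) + 0.5 * (max(raw) - min(raw))
  expect_equal(sum(nb$binary), sum(raw > mid))
  # min-only mode keeps the raw scale
  expect_equal(normalize_binarize(mk(raw), mode = "min")$normalized,
               raw - min(raw))
})

test_that("a 1->4 trajectory marches into exactly 3 sub-transition maps", {
  tr <- std_trajectory()
  expect_setequal(unique(tr$nodes$pred_grade), 1:4)
  maps <- march(tr, default_filter_net(), depth = 4)
  expect_length(maps, 3)
  expect_equal(purrr::map_int(maps, ~ attr(.x, "from_grade")), 1:3)
  expect_equal(purrr::map_int(maps, ~ attr(.x, "to_grade")), 2:4)
  direct <- march(tr, default_filter_net(), depth = 4, direct = TRUE)
  expect_length(direct, 1)
  expect_equal(attr(direct[[1]], "to_node"), nrow(tr$nodes))
})

test_that("marching a null trajectory yields all-zero maps", {
  b <- std_backend()
  m <- std_model()
  p <- scene_params(2, seed = 77)
  tr <- traverse_grade(b, b$encode(p), p$seed, m, std_predictor(),
                       target_grade = 4, step_scale = 0, max_steps = 1,
                       n_nodes = 3)
  maps <- march(tr, default_filter_net(), depth = 4)
  for (mp in maps) expect_true(all(mp$raw == 0))
  single <- tr
  single$nodes <- tr$nodes[1, ]
  expect_error(march(single, default_filter_net()), "fewer than two")
})

test_that("delta maps localize on the tissue that actually changed", {
  b <- std_backend()
  dir_radius <- c(1, 0, 0, 0, 0, 0)   # only tumor radius moves
  start <- b$encode(scene_params(1, seed = 91))
  end <- start + 3 * dir_radius * b$grade_direction[1]
  pa <- b$decode(start, 91)
  pb <- b$decode(end, 91)
  mp <- normalize_binarize(compute_delta_map(pa$image, pb$image,
                                             default_filter_net(), 4))
  merged <- merge_masks(pa$nuclei_mask, pb$nuclei_mask)
  tumor <- merged == 2
  bg <- merged == 0 & pa$vasc_mask == 0 & pb$vasc_mask == 0
  expect_gt(mean(mp$binary[tumor]), mean(mp$binary[bg]))
})
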