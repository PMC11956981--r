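manual_model <- function(mu, sigma, d = length(mu)) {
  structure(list(mu = mu, sigma = sigma,
                 weights = matrix(0, 2, d,
                                  dimnames = list(c("1", "4"), NULL)),
                 bias = c(0, 0), classes = c(1L, 4L), lambda = 0, n = 0,
                 fitted = TRUE, training_accuracy = NA_real_),
            class = "latent_class_model")
}

test_that("standardization centers, inverts, and is identity for unit scales", {
  m <- manual_model(mu = c(2, -1, 5), sigma = c(1.5, 2, 0.5))
  expect_equal(standardize(m$mu, m), c(0, 0, 0))
  x <- c(3.3, -0.7, 4.1)
  expect_lt(max(abs(destandardize(standardize(x, m), m) - x)), 1e-10)
  id <- manual_model(mu = rep(0, 3), sigma = rep(1, 3))
  expect_identical(standardize(x, id), x)
  expect_error(standardize(x, unclass(m)), "not fitted")
})

test_that("separable clouds are fitted perfectly and order-invariantly", {
  x <- rbind(matrix(rnorm(200, -3), 100, 2), matrix(rnorm(200, 3), 100, 2))
  y <- rep(c(1, 4), each = 100)
  m <- suppressMessages(fit_latent_class_model(x, y))
  expect_equal(m$training_accuracy, 1.0)
  perm <- with_seed2(5, sample(200))
  m2 <- suppressMessages(fit_latent_class_model(x[perm, ], y[perm]))
  expect_lt(max(abs(m$weights - m2$weights)), 1e-8)
  expect_error(suppressMessages(fit_latent_class_model(x, rep(1, 200))),
               "two classes")
})

test_that("the grade-4 weight vector recovers the analytic grade axis", {
  b <- std_backend()
  m <- std_model()
  axis_std <- b$grade_direction / m$sigma    # true axis in standardized space
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cosine(axis_std, m$weights["4", ]), 0.9)
  expect_gt(cosine(-axis_std, m$weights["1", ]), 0.9)
})

test_that("tidy/glance expose weights and fit summary", {
  m <- std_model()
  td <- tidy(m)
  expect_equal(nrow(td), length(m$classes) * ncol(m$weights))
  expect_named(td, c("class", "term", "estimate"))
  gl <- glance(m)
  expect_equal(gl$n_classes, 4)
  expect_gt(gl$training_accuracy, 0.6)
})

test_that("k-NN metrics are exact on constructed slide clusters", {
  set.seed(3)
  centers <- matrix(rnorm(12, sd = 50), 4, 3)
  codes <- centers[rep(1:4, each = 12), ] + matrix(rnorm(48 * 3, sd = 0.1), 48)
  slides <- rep(sprintf("S%d", 1:4), each = 12)
  grades <- rep(1:4, each = 12)
  qm <- latent_quality_metrics(codes, slides, grades, k = 10)
  expect_equal(qm$same_slide_fraction, 1.0)
  expect_equal(qm$same_grade_fraction, 1.0)
  expect_equal(qm$low_vs_high_linear_accuracy, 1.0)
  expect_error(latent_quality_metrics(codes[1:5, ], slides[1:5], grades[1:5], k = 10),
               "k \\+ 1")
})

test_that("random codes give chance-level grade neighbourhoods", {
  set.seed(7)
  n <- 2000
  codes <- matrix(rnorm(n * 8), n, 8)
  grades <- rep(1:4, length.out = n)
  qm <- latent_quality_metrics(codes, rep("S1", n), grades, k = 10)
  expect_lt(abs(qm$same_grade_fraction - 0.25), 0.03)
})

test_that("analytic codes beat a pixel-level embedding on grade neighbourhoods", {
  co <- std_cohort()
  sub <- seq(1, length(co$patches), by = 2)
  codes <- encode_cohort(std_backend(), co$patches[sub])
  pix <- t(vapply(co$patches[sub], function(p) {
    as.numeric(vapply(1:3, function(ch) bilinear_resize(p$image[, , ch], 6, 6),
                      matrix(0, 6, 6)))
  }, numeric(108)))
  g <- co$metadata$grade[sub]
  s <- co$metadata$slide_id[sub]
  q_code <- latent_quality_metrics(codes, s, g, k = 10)
  q_pix <- latent_quality_metrics(pix, s, g, k = 10)
  expect_gt(q_code$same_grade_fraction, q_pix$same_grade_fraction)
})

test_that("reconstruction metrics match closed forms and are symmetric", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  ident <- reconstruction_metrics(img, img)
  expect_equal(ident$mse, 0)
  expect_equal(ident$psnr, Inf)
  expect_equal(ident$ssim, 1)
  a <- array(0.5, dim = c(32, 32, 3))
  b <- array(0.6, dim = c(32, 32, 3))
  rm <- reconstruction_metrics(a, b)
  expect_equal(rm$mse, 0.01, tolerance = 1e-12)
  expect_equal(rm$psnr, 20, tolerance = 1e-10)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(reconstruction_metrics(img, x)[c("mse", "ssim")],
               reconstruction_metrics(x, img)[c("mse", "ssim")])
  expect_error(reconstruction_metrics(img, array(0, dim = c(16, 16, 3))),
               "dimensions")
})
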