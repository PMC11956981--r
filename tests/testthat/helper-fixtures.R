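# Shared fixtures (built lazily, cached for the whole run) and independent
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# mid-size rendered cohort shared by latent/traversal/phenotype tests
std_cohort <- function() {
  fixture("std_cohort", function() {
    suppressMessages(make_cohort(60, 1:4, 6, seed = 2))
  })
}

std_backend <- function() fixture("std_backend", function() analytic_backend())

std_model <- function() {
  fixture("std_model", function() {
    co <- std_cohort()
    suppressMessages(fit_latent_class_model(
      encode_cohort(std_backend(), co$patches), co$metadata$grade))
  })
}

std_predictor <- function() {
  fixture("std_predictor", function() morphometric_grade_predictor())
}

# one default grade 1 -> 4 trajectory
std_trajectory <- function() {
  fixture("std_trajectory", function() {
    co <- std_cohort()
    i <- which(co$metadata$grade == 1)[1]
    p <- co$patches[[i]]
    traverse_grade(std_backend(), std_backend()$encode(p$params),
                   p$params$seed, std_model(), std_predictor(),
                   target_grade = 4)
  })
}

# --- independent oracle: connected components by iterative label propagation
# (minimum-label diffusion to a fixed point; mechanism unrelated to the
# package's BFS labelling)
oracle_count_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  shift <- function(m, di, dj) {
    out <- matrix(0L, h, w)
    si <- max(1, 1 + di):min(h, h + di)
    sj <- max(1, 1 + dj):min(w, w + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    new_lab <- lab
    for (o in offs) {
      s <- shift(lab, o[1], o[2])
      upd <- mask != 0 & s > 0 & (new_lab == 0 | s < new_lab)
      new_lab[upd] <- s[upd]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  length(unique(lab[lab > 0]))
}

# --- independent oracle: Delta-Map by explicit per-pixel loops
# (naive convolution, pooling, half-pixel-centre bilinear interpolation)
oracle_delta_map <- function(img_a, img_b, net, depth = length(net$layers)) {
  naive_forward <- function(img) {
    if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
    feats <- lapply(seq_len(dim(img)[3]), function(ch) img[, , ch])
    for (ly in net$layers[seq_len(depth)]) {
      if (ly$type == "conv") {
        d <- dim(ly$w)
        h <- nrow(feats[[1]]); w <- ncol(feats[[1]])
        out <- vector("list", d[4])
        for (co in seq_len(d[4])) {
          m <- matrix(0, h, w)
          for (i in seq_len(h)) for (j in seq_len(w)) {
            acc <- ly$b[co]
            for (ci in seq_len(d[3])) for (ki in seq_len(d[1])) for (kj in seq_len(d[2])) {
              ii <- i + ki - 1 - (d[1] - 1) / 2
              jj <- j + kj - 1 - (d[2] - 1) / 2
              v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) feats[[ci]][ii, jj] else 0
              acc <- acc + v * ly$w[ki, kj, ci, co]
            }
            m[i, j] <- if (identical(ly$activation, "relu")) max(acc, 0) else acc
          }
          out[[co]] <- m
        }
        feats <- out
      } else {
        s <- ly$size
        feats <- lapply(feats, function(m) {
          h2 <- nrow(m) %/% s; w2 <- ncol(m) %/% s
          out <- matrix(0, h2, w2)
          for (i in seq_len(h2)) for (j in seq_len(w2)) {
            out[i, j] <- mean(m[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s)])
          }
          out
        })
      }
    }
    feats
  }
  naive_upscale <- function(m, h_out, w_out) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h_out, w_out)
    for (i in seq_len(h_out)) for (j in seq_len(w_out)) {
      sy <- min(max((i - 0.5) * h / h_out - 0.5, 0), h - 1)
      sx <- min(max((j - 0.5) * w / w_out - 0.5, 0), w - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * m[y0 + 1, x0 + 1] + fx * m[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * m[y1 + 1, x0 + 1] + fx * m[y1 + 1, x1 + 1])
    }
    out
  }
  fa <- naive_forward(img_a)
  fb <- naive_forward(img_b)
  h <- if (is.matrix(img_a)) nrow(img_a) else dim(img_a)[1]
  w <- if (is.matrix(img_a)) ncol(img_a) else dim(img_a)[2]
  acc <- matrix(0, h, w)
  for (ch in seq_along(fa)) {
    acc <- acc + abs(naive_upscale(fa[[ch]] - fb[[ch]], h, w))
  }
  acc / length(fa)
}

# small hand-specified 2-layer filter (conv then pool) for oracle tests
hand_filter <- function(seed = 4, cin = 3, cout = 2) {
  w <- with_seed2(seed, array(stats::rnorm(3 * 3 * cin * cout, 0, 0.5),
                              dim = c(3, 3, cin, cout)))
  filter_net(list(
    list(type = "conv", w = w, b = c(0.1, -0.2)[seq_len(cout)],
         activation = "linear"),
    list(type = "pool", size = 2L)
  ), name = "hand-2layer")
}

# local seeded evaluation without touching the session RNG
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# synthetic nucleus image built directly in stain space: flat hematoxylin
# ellipse plus optional Gaussian peaks; returns list(image, mask)
stain_nucleus_image <- function(size = 40, peaks = NULL, base_h = 0.75,
                                bg_h = 0.05, amp = 0.6, peak_sigma = 1) {
  cy <- (size + 1) / 2; cx <- (size + 1) / 2; r <- size * 0.3
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  inside <- ((yy - cy)^2 + (xx - cx)^2) <= r^2
  hmat <- matrix(bg_h, size, size)
  hmat[inside] <- base_h
  if (!is.null(peaks)) {
    for (k in seq_len(nrow(peaks))) {
      hmat <- hmat + amp * exp(-((yy - peaks[k, 1])^2 + (xx - peaks[k, 2])^2) /
                                 (2 * peak_sigma^2))
    }
  }
  hed <- array(0, dim = c(size, size, 3))
  hed[, , 1] <- hmat
  hed[, , 2] <- 0.2
  list(image = hed_to_rgb(hed), mask = matrix(as.integer(inside) * 2L, size, size))
}
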