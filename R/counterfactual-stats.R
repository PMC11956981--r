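# Statistical-power comparison of sampling strategies for grade contrasts:
# Real-Unpair (random real patches per grade), Syn-Pair (counterfactual
# endpoints from the same latent trajectory), Syn-Unpair (endpoints from
# independent trajectories), each evaluated by repeated one-sided sign tests
# on a per-patch phenotype summary, summarized as the mean log p-value.

#' One-sided paired sign test
#'
#' Ties are dropped. With m non-tied pairs and `s = #\{y_i > x_i\}`, the
#' p-value is the upper binomial tail `P(S >= s | m, 1/2)` for the
#' alternative `y > x`. All-tied input yields a missing p-value.
#'
#' @param x,y paired numeric vectors.
#' @return One-row tibble: n_pairs, n_nonties, statistic (s), p_value.
#' @export
sign_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  nt <- x != y
  m <- sum(nt)
  if (m == 0) {
    warn("sign_test: all pairs tied; p-value undefined")
    return(tibble(n_pairs = length(x), n_nonties = 0L,
                  statistic = NA_integer_, p_value = NA_real_))
  }
  s <- sum(y[nt] > x[nt])
  p <- pbinom(s - 1, m, 0.5, lower.tail = FALSE)
  tibble(n_pairs = length(x), n_nonties = as.integer(m),
         statistic = as.integer(s), p_value = p)
}

#' Per-grade phenotype features of a set of trajectories
#'
#' For each trajectory, picks the node where each grade is first predicted
#' (the sub-transition boundary rule) and records the requested phenotype
#' summary of the decoded patch at that node. Grades a trajectory never
#' reaches are absent.
#'
#' @param trajectories list of `dm_trajectory`.
#' @param feature_fun function `labeled_patch -> scalar` (default: mean tumor
#'   nuclear area).
#' @return Tibble: trajectory, grade, feature.
#' @export
trajectory_grade_features <- function(trajectories,
                                      feature_fun = mean_tumor_area) {
  purrr::imap_dfr(trajectories, function(tr, i) {
    nodes <- tr$nodes
    first <- !duplicated(nodes$pred_grade)
    tibble(
      trajectory = i,
      grade = nodes$pred_grade[first],
      feature = purrr::map_dbl(nodes$patch[first], feature_fun)
    )
  })
}

#' @rdname trajectory_grade_features
#' @param patch a `labeled_patch`.
#' @export
mean_tumor_area <- function(patch) {
  nuclear_morphometrics(patch$nuclei_mask)$summary$mean_tumor_nuclear_area
}

#' Repeated sign-test power analysis across sampling strategies
#'
#' Per repetition and grade pair (g1, g2): draws `n_per_group` feature values
#' per grade without replacement according to the strategy, forms pairs
#' (trajectory-matched for `syn_pair`; by draw index after independent
#' shuffles for the unpaired strategies), applies the one-sided sign test of
#' `grade g2 > grade g1` (or a Wilcoxon rank-sum alternative), and records
#' the p-value. Reports the mean natural-log p-value per strategy and grade
#' pair.
#'
#' @param real_features tibble with columns `grade`, `feature` (one row per
#'   real patch); required for the `real_unpair` strategy.
#' @param syn_features tibble with columns `trajectory`, `grade`, `feature`
#'   as from [trajectory_grade_features()]; required for `syn_pair` /
#'   `syn_unpair`.
#' @param grade_pairs list of 2-vectors `c(g1, g2)` with g1 < g2.
#' @param strategies subset of `c("real_unpair", "syn_pair", "syn_unpair")`.
#' @param n_per_group patches per group and rep (default 100).
#' @param n_reps repetitions (default 1000).
#' @param seed master seed; every rep draws from a derived stream.
#' @param test "sign" (default) or "wilcoxon" (unpaired Mann-Whitney,
#'   sensitivity alternative).
#' @return A `power_result`: tibble with one row per (strategy, grade pair):
#'   mean_log_p plus the rep-level p-values as a list column.
#' @export
power_analysis <- function(real_features = NULL, syn_features = NULL,
                           grade_pairs = list(c(1, 2), c(1, 4)),
                           strategies = c("real_unpair", "syn_pair", "syn_unpair"),
                           n_per_group = 100, n_reps = 1000, seed = 1,
                           test = c("sign", "wilcoxon")) {
  test <- match.arg(test)
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (n_per_group < 5) dm_abort("n_per_group must be >= 5")
  for (gp in grade_pairs) stopifnot(length(gp) == 2, gp[1] < gp[2])

  pool_real <- function(g) {
    v <- real_features$feature[real_features$grade == g]
    v[is.finite(v)]
  }
  syn_wide <- NULL
  if (!is.null(syn_features)) {
    syn_wide <- tidyr::pivot_wider(syn_features, id_cols = "trajectory",
                                   names_from = "grade", values_from = "feature",
                                   names_prefix = "g")
  }
  pool_syn <- function(g, need_pair_with = NULL) {
    col <- paste0("g", g)
    if (!col %in% names(syn_wide)) return(numeric(0))
    syn_wide[[col]]
  }

  rows <- list()
  for (strat in strategies) {
    for (gp in grade_pairs) {
      g1 <- gp[1]; g2 <- gp[2]
      pair_label <- sprintf("%d_vs_%d", g1, g2)
      if (strat == "real_unpair") {
        if (is.null(real_features)) dm_abort("real_unpair needs real_features")
        x_pool <- pool_real(g1); y_pool <- pool_real(g2)
        if (length(x_pool) < n_per_group || length(y_pool) < n_per_group) {
          dm_abort(sprintf("not enough real patches for grades %d/%d", g1, g2))
        }
        draw <- function() list(x = sample(x_pool, n_per_group),
                                y = sample(y_pool, n_per_group))
      } else {
        if (is.null(syn_wide)) dm_abort(sprintf("%s needs syn_features", strat))
        c1 <- paste0("g", g1); c2 <- paste0("g", g2)
        if (!all(c(c1, c2) %in% names(syn_wide))) {
          dm_abort(sprintf("trajectories never reach grades %d and %d", g1, g2))
        }
        complete <- syn_wide[is.finite(syn_wide[[c1]]) & is.finite(syn_wide[[c2]]), ]
        if (strat == "syn_pair") {
          if (nrow(complete) < n_per_group) {
            dm_abort(sprintf("only %d trajectories cover grades %d and %d",
                             nrow(complete), g1, g2))
          }
          draw <- function() {
            idx <- sample(nrow(complete), n_per_group)
            list(x = complete[[c1]][idx], y = complete[[c2]][idx])
          }
        } else {
          x_pool <- syn_wide[[c1]][is.finite(syn_wide[[c1]])]
          y_pool <- syn_wide[[c2]][is.finite(syn_wide[[c2]])]
          if (length(x_pool) < n_per_group || length(y_pool) < n_per_group) {
            dm_abort(sprintf("not enough trajectories for grades %d/%d", g1, g2))
          }
          draw <- function() list(x = sample(x_pool, n_per_group),
                                  y = sample(y_pool, n_per_group))
        }
      }
      pvals <- with_seed(derive_seed(seed, paste("power", strat, pair_label)), {
        vapply(seq_len(n_reps), function(r) {
          d <- draw()
          if (test == "sign") {
            sign_test(d$x, d$y)$p_value
          } else {
            stats::wilcox.test(d$y, d$x, alternative = "greater",
                               exact = FALSE)$p.value
          }
        }, numeric(1))
      })
      rows[[length(rows) + 1]] <- tibble(
        strategy = strat, grade_pair = pair_label,
        n_per_group = as.integer(n_per_group), n_reps = as.integer(n_reps),
        mean_log_p = mean(log(pvals)),
        p_values = list(pvals)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_result", class(out))
  out
}

#' Plot mean log p-values per strategy and grade pair
#'
#' @param object a `power_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grade_pair,
                                       y = .data$mean_log_p,
                                       fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "grade pair", y = "mean log(p)", fill = NULL) +
    ggplot2::theme_minimal()
}
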