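# Enrichment of binarized Delta-Maps over tissue components: merge endpoint
# masks, drop ghost nuclei, build a composite component map (3 = tumor
# nuclei, 2 = non-tumor nuclei, 1 = vasculature, 0 = other), compute
# per-component Jaccard indexes against the Delta-Map, compare with a
# random-patch baseline, and test enrichment significance.

#' Merge two label masks by per-pixel maximum
#'
#' @param mask_a,mask_b integer matrices with the same shape and label
#'   convention (applied separately to nuclei and vasculature masks).
#' @return Merged mask.
#' @export
merge_masks <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    dm_abort("merge_masks: mask shapes differ")
  }
  pmax(mask_a, mask_b)
}

#' Remove ghost nuclei from a merged nuclei mask
#'
#' A nucleus connected component of the merged mask is kept only if it
#' overlaps at least `min_overlap` nucleus pixels in *both* source masks;
#' components present in only one endpoint (generative artifacts) are erased.
#'
#' @param merged_nuclei merged nuclei mask (codes 0/1/2).
#' @param mask_a,mask_b the two source masks.
#' @param min_overlap minimum overlapping pixels required in each source
#'   (default 1).
#' @return Cleaned merged mask.
#' @export
remove_ghost_nuclei <- function(merged_nuclei, mask_a, mask_b,
                                min_overlap = 1) {
  lab <- label_components(merged_nuclei > 0, connectivity = 8)
  n <- max(lab)
  if (n == 0) return(merged_nuclei)
  out <- merged_nuclei
  for (i in seq_len(n)) {
    comp <- lab == i
    if (sum(mask_a[comp] > 0) < min_overlap ||
        sum(mask_b[comp] > 0) < min_overlap) {
      out[comp] <- 0L
    }
  }
  out
}

#' Build the composite component map
#'
#' Codes: 3 = tumor nuclei, 2 = non-tumor nuclei, 1 = vasculature, 0 = other.
#' Pixels claimed by both a nucleus and the vasculature are reassigned by a
#' fair seeded coin to vasculature or their nucleus code; everything else is
#' deterministic.
#'
#' @param nuclei_mask (merged, ghost-cleaned) nuclei mask with codes 0/1/2.
#' @param vasc_mask (merged) binary vasculature mask.
#' @param seed seed of the tie-break coin.
#' @return Integer matrix with labels in \{0, 1, 2, 3\}.
#' @export
build_composite <- function(nuclei_mask, vasc_mask, seed = 1) {
  if (!identical(dim(nuclei_mask), dim(vasc_mask))) {
    dm_abort("build_composite: mask shapes differ")
  }
  out <- matrix(0L, nrow(nuclei_mask), ncol(nuclei_mask))
  out[vasc_mask != 0] <- 1L
  out[nuclei_mask == 1L] <- 2L
  out[nuclei_mask == 2L] <- 3L
  conflict <- which(vasc_mask != 0 & nuclei_mask > 0)
  if (length(conflict)) {
    coin <- with_seed(seed, runif(length(conflict)) < 0.5)
    out[conflict[coin]] <- 1L
  }
  out
}

#' Composite map from the endpoints of a sub-transition
#'
#' Convenience wrapper: merges the endpoint nuclei and vasculature masks,
#' removes ghost nuclei, and builds the composite.
#'
#' @param patch_a,patch_b endpoint `labeled_patch`es.
#' @param seed tie-break seed.
#' @param min_overlap ghost-nucleus overlap threshold.
#' @return Composite label matrix.
#' @export
composite_from_patches <- function(patch_a, patch_b, seed = 1,
                                   min_overlap = 1) {
  nuc <- remove_ghost_nuclei(
    merge_masks(patch_a$nuclei_mask, patch_b$nuclei_mask),
    patch_a$nuclei_mask, patch_b$nuclei_mask, min_overlap)
  vas <- merge_masks(patch_a$vasc_mask, patch_b$vasc_mask)
  build_composite(nuc, vas, seed)
}

#' Jaccard index of a binary Delta-Map against each component
#'
#' For component i, `J_i = |B intersect M_i| / |B union M_i|` with `M_i` the
#' indicator of composite code i. An empty union gives a missing value.
#'
#' @param binary_delta binary matrix (the Delta-Map's `binary` layer).
#' @param composite composite label matrix (codes 0..3).
#' @return Named numeric vector `J_0` .. `J_3`.
#' @export
jaccard_components <- function(binary_delta, composite) {
  if (!identical(dim(binary_delta), dim(composite))) {
    dm_abort("jaccard_components: shapes differ")
  }
  b <- binary_delta != 0
  vapply(0:3, function(i) {
    m <- composite == i
    u <- sum(b | m)
    if (u == 0) NA_real_ else sum(b & m) / u
  }, numeric(1)) |> setNames(paste0("J_", 0:3))
}

component_names <- c("0" = "other", "1" = "vasculature",
                     "2" = "non_tumor_nuclei", "3" = "tumor_nuclei")

#' Enrichment analysis of Delta-Maps over tissue components
#'
#' For every patch, computes the Jaccard index of its binarized Delta-Map
#' against its own composite (`J_true`) and against the composite of a
#' uniformly drawn *different* patch of the same transition (`J_rand`), and
#' their ratio. Aggregates (median ratio and a one-sided paired t-test of
#' `J_true > J_rand`) per transition and component are available via
#' [enrichment_summary()].
#'
#' Zero-baseline rule: `J_rand = 0` with `J_true > 0` yields an infinite
#' ratio; infinite ratios are kept in the table and excluded from medians,
#' with a warning when they exceed 5% of rows.
#'
#' @param cohort tibble with columns `patch_id`, `transition` (label of the
#'   sub-transition grade pair), `binary` (list of binary matrices) and
#'   `composite` (list of composite matrices).
#' @param seed seed of the baseline draws.
#' @param baseline_draws number of random baselines averaged per patch
#'   (default 1, as a single draw).
#' @return An `enrichment_table`: long tibble with one row per patch x
#'   component (patch_id, transition, component, code, J_true, J_rand,
#'   ratio).
#' @export
enrichment_analysis <- function(cohort, seed = 1, baseline_draws = 1) {
  stopifnot(is.data.frame(cohort),
            all(c("patch_id", "transition", "binary", "composite")
                %in% names(cohort)))
  rows <- list()
  for (tr in unique(cohort$transition)) {
    sub <- cohort[cohort$transition == tr, ]
    n <- nrow(sub)
    draw_tbl <- with_seed(derive_seed(seed, paste0("baseline-", tr)), {
      lapply(seq_len(n), function(i) {
        if (n < 2) return(integer(0))
        pool <- setdiff(seq_len(n), i)
        sample(pool, baseline_draws, replace = baseline_draws > length(pool))
      })
    })
    for (i in seq_len(n)) {
      j_true <- jaccard_components(sub$binary[[i]], sub$composite[[i]])
      if (length(draw_tbl[[i]]) == 0) {
        j_rand <- rep(NA_real_, 4)
        warn(sprintf("transition %s has a single patch: baseline impossible", tr))
      } else {
        j_rand <- rowMeans(vapply(draw_tbl[[i]], function(j) {
          jaccard_components(sub$binary[[i]], sub$composite[[j]])
        }, numeric(4)))
      }
      rows[[length(rows) + 1]] <- tibble(
        patch_id = sub$patch_id[i],
        transition = tr,
        code = 0:3,
        component = unname(component_names[as.character(0:3)]),
        J_true = unname(j_true),
        J_rand = unname(j_rand),
        ratio = unname(ifelse(j_rand > 0, j_true / j_rand,
                              ifelse(j_true > 0, Inf, NA_real_)))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  inf_frac <- mean(is.infinite(out$ratio), na.rm = TRUE)
  if (is.finite(inf_frac) && inf_frac > 0.05) {
    warn(sprintf("%.1f%% of Jaccard ratios are infinite (zero baselines)",
                 100 * inf_frac))
  }
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Aggregate an enrichment table
#'
#' Median finite ratio and a one-sided t-test of `J_true > J_rand` per
#' (transition, component). The test is paired across patches by default.
#'
#' @param table an `enrichment_table`.
#' @param paired use a paired t-test (default TRUE).
#' @return Tibble: transition, component, n, median_ratio, p_value.
#' @export
enrichment_summary <- function(table, paired = TRUE) {
  table |>
    dplyr::group_by(.data$transition, .data$code, .data$component) |>
    dplyr::summarise(
      n = sum(!is.na(.data$ratio)),
      median_ratio = {
        r <- .data$ratio[!is.na(.data$ratio)]
        # infinite ratios (zero baselines) stay in the median unless they
        # dominate (> 5% of rows), in which case they are dropped
        if (length(r) && mean(is.infinite(r)) > 0.05) r <- r[is.finite(r)]
        median(r)
      },
      p_value = {
        ok <- is.finite(.data$J_true) & is.finite(.data$J_rand)
        x <- .data$J_true[ok]; y <- .data$J_rand[ok]
        if (length(x) < 3 || (paired && sd(x - y) == 0) ||
            (!paired && (sd(x) == 0 && sd(y) == 0))) {
          NA_real_
        } else {
          t.test(x, y, paired = paired, alternative = "greater")$p.value
        }
      },
      .groups = "drop"
    )
}

#' Plot median Jaccard ratios per transition and component
#'
#' @param object an `enrichment_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  agg <- enrichment_summary(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$component, y = .data$median_ratio,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~transition) +
    ggplot2::labs(x = NULL, y = "median Jaccard ratio (true / random)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
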