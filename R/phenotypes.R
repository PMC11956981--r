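# Grade-linked phenotypes per patch: nuclear morphometrics by cell type,
# nucleolus counts as prominent hematoxylin peaks, vasculature coverage.

#' Nuclear morphometrics from a label mask
#'
#' Connected components (8-connectivity) are computed separately for tumor
#' (code 2) and non-tumor (code 1) nuclei; a nucleus's area is its pixel
#' count. Types with no nuclei get a missing (not zero) mean.
#'
#' @param nuclei_mask matrix with codes 0 (background), 1 (non-tumor),
#'   2 (tumor).
#' @return List with `nuclei` (tibble: type, nucleus, area, cy, cx) and
#'   `summary` (one-row tibble: mean_tumor_nuclear_area,
#'   mean_other_nuclear_area, n_tumor_nuclei, n_other_nuclei).
#' @export
nuclear_morphometrics <- function(nuclei_mask) {
  stopifnot(is.matrix(nuclei_mask))
  per_type <- function(code, type_name) {
    lab <- label_components(nuclei_mask == code, connectivity = 8)
    n <- max(lab)
    if (n == 0) {
      return(tibble(type = character(), nucleus = integer(),
                    area = double(), cy = double(), cx = double()))
    }
    idx <- which(lab > 0)
    comp <- lab[idx]
    rows <- ((idx - 1) %% nrow(lab)) + 1
    cols <- ((idx - 1) %/% nrow(lab)) + 1
    tibble(
      type = type_name,
      nucleus = seq_len(n),
      area = as.double(tabulate(comp, n)),
      cy = as.double(tapply(rows, comp, mean)),
      cx = as.double(tapply(cols, comp, mean))
    )
  }
  nuclei <- dplyr::bind_rows(per_type(2L, "tumor"), per_type(1L, "other"))
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  summary <- tibble(
    mean_tumor_nuclear_area = mean_or_na(nuclei$area[nuclei$type == "tumor"]),
    mean_other_nuclear_area = mean_or_na(nuclei$area[nuclei$type == "other"]),
    n_tumor_nuclei = sum(nuclei$type == "tumor"),
    n_other_nuclei = sum(nuclei$type == "other")
  )
  list(nuclei = nuclei, summary = summary)
}

# Persistence-based peak count inside one connected component.
# Candidate peaks are strict 8-neighbour local maxima whose neighbours all lie
# inside the component (so boundary pixels never qualify); each candidate is
# counted if its topographic prominence -- peak value minus the highest saddle
# to higher terrain within the component, computed by descending union-find
# flooding -- reaches `prominence`. A flat component has no strict maxima and
# therefore zero peaks.
count_component_peaks <- function(values, comp_mask, prominence) {
  h <- nrow(values); w <- ncol(values)
  idx <- which(comp_mask)
  if (length(idx) == 0) return(0L)
  off <- c(-1, 1, -h, h, -h - 1, -h + 1, h - 1, h + 1)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  interior <- rows > 1 & rows < h & cols > 1 & cols < w
  # strict local maxima with the full 8-neighbourhood inside the component
  strict <- logical(length(idx))
  for (k in seq_along(idx)) {
    if (!interior[k]) next
    nb <- idx[k] + off
    if (all(comp_mask[nb]) && all(values[idx[k]] > values[nb])) strict[k] <- TRUE
  }
  pos <- integer(h * w); pos[idx] <- seq_along(idx)   # pixel -> local index
  ord <- order(values[idx], seq_along(idx), decreasing = c(TRUE, FALSE),
               method = "radix")
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  peak_val <- rep(NA_real_, length(idx))
  peak_strict <- logical(length(idx))
  processed <- logical(length(idx))
  n_peaks <- 0L
  vmin <- min(values[idx])
  for (k in ord) {
    p <- idx[k]
    v <- values[p]
    nb <- p + off
    pr <- rows[k]; pc <- cols[k]
    ok <- c(pr > 1, pr < h, pc > 1, pc < w,
            pr > 1 & pc > 1, pr < h & pc > 1, pr > 1 & pc < w, pr < h & pc < w)
    nb <- nb[ok]
    nb <- nb[comp_mask[nb]]
    nb_loc <- pos[nb]
    nb_loc <- nb_loc[processed[nb_loc]]
    roots <- unique(vapply(nb_loc, find, integer(1)))
    if (length(roots) == 0) {
      peak_val[k] <- v
      peak_strict[k] <- strict[k]
    } else {
      main <- roots[which.max(peak_val[roots])]
      if (length(roots) > 1) {
        for (r in roots[roots != main]) {
          # r's peak dies here: v is its saddle to higher terrain
          if (peak_strict[r] && (peak_val[r] - v) >= prominence) {
            n_peaks <- n_peaks + 1L
          }
          parent[r] <- main
        }
      }
      parent[k] <- main
    }
    processed[k] <- TRUE
  }
  # surviving roots: prominence relative to the component minimum
  roots <- unique(vapply(seq_along(idx), find, integer(1)))
  for (r in roots) {
    if (peak_strict[r] && (peak_val[r] - vmin) >= prominence) {
      n_peaks <- n_peaks + 1L
    }
  }
  n_peaks
}

#' Detect nucleoli as prominent hematoxylin peaks
#'
#' Converts the RGB image to HED stain space, takes the hematoxylin channel,
#' min-max normalizes it to \[0, 1\], smooths with a Gaussian of the given
#' sigma, and counts, per nucleus, strict 8-neighbour local maxima (strictly
#' inside the component) whose topographic prominence reaches the threshold.
#' Because a nucleus is itself a hematoxylin peak, the corrected count
#' subtracts one from every nucleus with at least one detection:
#' `corrected = max(raw - 1, 0)`. Per-type averages run over all nuclei of
#' the type, zeros included.
#'
#' @param image H x W x 3 RGB array in \[0, 1\]; grayscale input is an error.
#' @param nuclei_mask aligned mask with codes 0/1/2.
#' @param sigma Gaussian smoothing SD in pixels (default 1).
#' @param prominence peak prominence threshold on the normalized channel
#'   (default 0.08).
#' @return List with `nucleoli` (tibble: type, nucleus, raw_count,
#'   corrected_count) and `summary` (one-row tibble:
#'   nucleoli_per_tumor_nucleus, nucleoli_per_other_nucleus).
#' @export
detect_nucleoli <- function(image, nuclei_mask, sigma = 1, prominence = 0.08) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    dm_abort("detect_nucleoli: stain separation requires a 3-channel RGB image")
  }
  if (!all(dim(image)[1:2] == dim(nuclei_mask))) {
    dm_abort("detect_nucleoli: image and mask dimensions differ")
  }
  hema <- rgb_to_hed(image)[, , 1]
  lo <- min(hema); hi <- max(hema)
  hema <- if (hi > lo) (hema - lo) / (hi - lo) else hema * 0
  hema <- gaussian_smooth(hema, sigma)
  per_type <- function(code, type_name) {
    lab <- label_components(nuclei_mask == code, connectivity = 8)
    n <- max(lab)
    if (n == 0) {
      return(tibble(type = character(), nucleus = integer(),
                    raw_count = integer(), corrected_count = integer()))
    }
    raw <- vapply(seq_len(n), function(i) {
      count_component_peaks(hema, lab == i, prominence)
    }, integer(1))
    tibble(type = type_name, nucleus = seq_len(n), raw_count = raw,
           corrected_count = pmax(raw - 1L, 0L))
  }
  nucleoli <- dplyr::bind_rows(per_type(2L, "tumor"), per_type(1L, "other"))
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  summary <- tibble(
    nucleoli_per_tumor_nucleus =
      mean_or_na(nucleoli$corrected_count[nucleoli$type == "tumor"]),
    nucleoli_per_other_nucleus =
      mean_or_na(nucleoli$corrected_count[nucleoli$type == "other"])
  )
  list(nucleoli = nucleoli, summary = summary)
}

#' Percentage of patch area covered by vasculature
#'
#' @param vasc_mask binary matrix (1 = vasculature).
#' @return Percent in \[0, 100\].
#' @export
vasculature_fraction <- function(vasc_mask) {
  stopifnot(is.matrix(vasc_mask))
  100 * mean(vasc_mask != 0)
}

#' Phenotype record for one labelled patch
#'
#' @param patch a `labeled_patch`.
#' @param sigma,prominence nucleolus detector settings.
#' @param nucleoli if FALSE, skip peak detection (counts become NA) — useful
#'   when only areas are needed.
#' @return One-row tibble: patch_id, slide_id, grade, mean areas, nucleoli
#'   rates, vasc_fraction.
#' @export
phenotype_record <- function(patch, sigma = 1, prominence = 0.08,
                             nucleoli = TRUE) {
  morph <- nuclear_morphometrics(patch$nuclei_mask)$summary
  nuc <- if (nucleoli) {
    detect_nucleoli(patch$image, patch$nuclei_mask, sigma, prominence)$summary
  } else {
    tibble(nucleoli_per_tumor_nucleus = NA_real_,
           nucleoli_per_other_nucleus = NA_real_)
  }
  dplyr::bind_cols(
    tibble(patch_id = patch$patch_id %||% NA_character_,
           slide_id = patch$slide_id %||% NA_character_,
           grade = patch$grade_label %||% NA_integer_),
    morph, nuc,
    tibble(vasc_fraction = vasculature_fraction(patch$vasc_mask))
  )
}

#' Phenotype table for a list of patches
#'
#' @param patches list of `labeled_patch`.
#' @inheritParams phenotype_record
#' @return Tibble, one row per patch.
#' @export
cohort_phenotypes <- function(patches, sigma = 1, prominence = 0.08,
                              nucleoli = TRUE) {
  purrr::map_dfr(patches, phenotype_record, sigma = sigma,
                 prominence = prominence, nucleoli = nucleoli)
}

#' Morphometric grade predictor
#'
#' Returns a function mapping a decoded patch to an integer grade 1..4 by
#' combining two morphological cues: the grade implied by the mean equivalent
#' tumor nucleus radius (`sqrt(area / pi)` inverted through the tumor-radius
#' anchor map) and the grade implied by the vasculature area fraction
#' (inverted through the decreasing vasculature anchor map). The two implied
#' grades are averaged and rounded. Using more than one cue mirrors a
#' CNN grade classifier: no single feature pins the prediction, so patches
#' predicted as the same grade still vary in each individual feature.
#' Serves as the image-level grade validator of traversal halting.
#'
#' @param anchors anchor list as from [grade_anchors()].
#' @param patch_size patch side used to scale the anchors.
#' @return A function `labeled_patch -> integer grade`.
#' @export
morphometric_grade_predictor <- function(anchors = grade_anchors(),
                                         patch_size = 96) {
  a <- anchors$tumor_radius * patch_size / 96
  v <- anchors$vasc_density
  function(patch) {
    m <- nuclear_morphometrics(patch$nuclei_mask)$summary
    if (is.na(m$mean_tumor_nuclear_area)) return(NA_integer_)
    r <- sqrt(m$mean_tumor_nuclear_area / pi)
    g_r <- 1 + (r - a[1]) / (a[4] - a[1]) * 3
    vf <- mean(patch$vasc_mask != 0)
    g_v <- 1 + (vf - v[1]) / (v[4] - v[1]) * 3
    g <- (pmin(pmax(g_r, 1), 4) + pmin(pmax(g_v, 1), 4)) / 2
    as.integer(pmin(pmax(round(g), 1), 4))
  }
}
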