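# One-command end-to-end synthetic study: cohort -> backend + latent
# classifier -> grade traversals and within-grade controls -> Delta-Maps ->
# component enrichment -> phenotype tables -> power analysis. Every stage
# draws from a seed derived from the single config seed, so identical configs
# give byte-identical CSV reports.

#' Default experiment configuration
#'
#' Nested configuration of the full synthetic experiment. All method
#' constants live here: traversal step cap 4 and 20 interior nodes, Delta-Map
#' binarization threshold 0.5, nucleolus detector sigma 1 and prominence
#' 0.08, power analysis with 100 patches per group and 1000 repetitions.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param ... named overrides of top-level sections (lists are merged
#'   shallowly).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    synthetic = list(
      n_per_grade = 100, grade_levels = 1:4, n_slides = 8, patch_size = 96,
      grade_jitter_sd = 0.5, slide_sd = 0.08
    ),
    backend = "analytic",
    traversal = list(step_scale = 1, max_steps = 4, n_nodes = 20,
                     n_trajectories = 100, n_swaps = 20),
    filter = list(type = "default", seed = 11, depth = 4),
    delta = list(threshold = 0.5, norm_mode = "minmax"),
    nucleoli = list(sigma = 1, prominence = 0.08),
    enrichment = list(baseline_draws = 1, paired = TRUE),
    power = list(n_per_group = 100, n_reps = 1000,
                 grade_pairs = list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
                 strategies = c("real_unpair", "syn_pair", "syn_unpair"))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' The round trip is lossless for every field the default config contains.
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$power$grade_pairs <- lapply(cfg$power$grade_pairs, as.numeric)
  structure(cfg, class = "experiment_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    dm_abort(sprintf("experiment stage '%s' failed: %s", name,
                     conditionMessage(e)), parent = e)
  })
}

#' Run the full synthetic experiment
#'
#' Executes the whole pipeline and writes a report directory of CSV/JSON
#' artifacts plus a manifest of seeds and settings. Deterministic: two runs
#' with identical configs produce byte-identical CSVs.
#'
#' @param config an `experiment_config`.
#' @param out_dir report directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results
#'   (cohort metadata, latent metrics, enrichment table and summary,
#'   phenotype tables, power result, manifest).
#' @export
run_full_experiment <- function(config = experiment_config(), out_dir,
                                quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  seed <- config$seed
  syn <- config$synthetic

  say("stage 1/7: synthetic cohort (%d patches/grade)", syn$n_per_grade)
  cohort <- run_stage("cohort", make_cohort(
    n_per_grade = syn$n_per_grade, grade_levels = syn$grade_levels,
    n_slides = syn$n_slides, seed = derive_seed(seed, "cohort"),
    patch_size = syn$patch_size, grade_jitter_sd = syn$grade_jitter_sd,
    slide_sd = syn$slide_sd))
  readr::write_csv(cohort$metadata, file.path(out_dir, "cohort_metadata.csv"))

  say("stage 2/7: backend and latent class model")
  backend <- run_stage("backend", {
    if (!identical(config$backend, "analytic")) {
      train_toy_autoencoder(cohort, seed = derive_seed(seed, "toy-ae"))
    } else {
      analytic_backend(patch_size = syn$patch_size)
    }
  })
  codes <- encode_cohort(backend, cohort$patches)
  model <- run_stage("classifier", suppressMessages(
    fit_latent_class_model(codes, cohort$metadata$grade)))
  readr::write_csv(tidy(model), file.path(out_dir, "classifier_weights.csv"))
  latent_metrics <- run_stage("latent-metrics", latent_quality_metrics(
    codes, cohort$metadata$slide_id, cohort$metadata$grade,
    split_seed = derive_seed(seed, "lda-split")))
  readr::write_csv(latent_metrics, file.path(out_dir, "latent_metrics.csv"))

  say("stage 3/7: grade traversals and within-grade controls")
  predictor <- morphometric_grade_predictor(patch_size = syn$patch_size)
  trv <- config$traversal
  g1_idx <- which(cohort$metadata$grade == min(syn$grade_levels))
  g4_idx <- which(cohort$metadata$grade == max(syn$grade_levels))
  n_up <- min(trv$n_trajectories, length(g1_idx))
  n_down <- min(max(trv$n_trajectories %/% 4, 5), length(g4_idx))
  trajectories_up <- run_stage("traverse-up", purrr::map(g1_idx[seq_len(n_up)], function(i) {
    p <- cohort$patches[[i]]
    traverse_grade(backend, backend$encode(p$params), p$params$seed, model,
                   predictor, target_grade = 4, step_scale = trv$step_scale,
                   max_steps = trv$max_steps, n_nodes = trv$n_nodes)
  }))
  trajectories_down <- run_stage("traverse-down", purrr::map(g4_idx[seq_len(n_down)], function(i) {
    p <- cohort$patches[[i]]
    grade_down(backend, backend$encode(p$params), p$params$seed, model,
               predictor, step_scale = trv$step_scale,
               max_steps = trv$max_steps, n_nodes = trv$n_nodes)
  }))
  traj_summary <- dplyr::bind_rows(
    purrr::imap_dfr(trajectories_up, ~ dplyr::mutate(glance(.x), id = .y,
                                                     direction = "up")),
    purrr::imap_dfr(trajectories_down, ~ dplyr::mutate(glance(.x), id = .y,
                                                       direction = "down")))
  readr::write_csv(traj_summary, file.path(out_dir, "trajectory_summary.csv"))

  say("stage 4/7: Delta-March and component enrichment")
  net <- if (identical(config$filter$type, "default")) {
    default_filter_net(seed = config$filter$seed)
  } else {
    filter_from_backend(backend)
  }
  enr_rows <- run_stage("march", {
    rows <- list()
    for (ti in seq_along(trajectories_up)) {
      tr <- trajectories_up[[ti]]
      maps <- march(tr, net, depth = config$filter$depth,
                    threshold = config$delta$threshold,
                    mode = config$delta$norm_mode)
      for (mp in maps) {
        a <- tr$nodes$patch[[attr(mp, "from_node")]]
        b <- tr$nodes$patch[[attr(mp, "to_node")]]
        comp <- composite_from_patches(a, b,
          seed = derive_seed(seed, sprintf("composite-%d-%d", ti, attr(mp, "from_node"))))
        rows[[length(rows) + 1]] <- tibble(
          patch_id = sprintf("T%03d", ti),
          transition = sprintf("%d_to_%d", attr(mp, "from_grade"),
                               attr(mp, "to_grade")),
          binary = list(mp$binary), composite = list(comp))
      }
    }
    # within-grade (across-patient) negative controls
    meta <- cohort$metadata
    swap_seed <- derive_seed(seed, "swaps")
    swaps <- with_seed(swap_seed, {
      cand <- which(meta$grade == min(syn$grade_levels))
      out <- list()
      for (k in seq_len(min(trv$n_swaps, floor(length(cand) / 2)))) {
        pick <- sample(cand, 2)
        if (meta$slide_id[pick[1]] != meta$slide_id[pick[2]]) out[[length(out) + 1]] <- pick
      }
      out
    })
    for (k in seq_along(swaps)) {
      a <- cohort$patches[[swaps[[k]][1]]]
      b <- cohort$patches[[swaps[[k]][2]]]
      cf <- within_grade_swap(a, b, backend)
      mp <- normalize_binarize(
        compute_delta_map(a$image, cf$image, net, config$filter$depth),
        threshold = config$delta$threshold, mode = config$delta$norm_mode)
      comp <- composite_from_patches(a, cf,
        seed = derive_seed(seed, sprintf("composite-swap-%d", k)))
      rows[[length(rows) + 1]] <- tibble(
        patch_id = sprintf("W%03d", k),
        transition = "within_grade",
        binary = list(mp$binary), composite = list(comp))
    }
    dplyr::bind_rows(rows)
  })
  enrichment <- run_stage("enrichment", enrichment_analysis(
    enr_rows, seed = derive_seed(seed, "enrichment"),
    baseline_draws = config$enrichment$baseline_draws))
  readr::write_csv(as_tibble(enrichment), file.path(out_dir, "enrichment.csv"))
  enr_summary <- enrichment_summary(enrichment, paired = config$enrichment$paired)
  readr::write_csv(enr_summary, file.path(out_dir, "enrichment_summary.csv"))

  say("stage 5/7: phenotypes (real cohort and synthetic nodes)")
  pheno_real <- run_stage("phenotypes-real", cohort_phenotypes(
    cohort$patches, sigma = config$nucleoli$sigma,
    prominence = config$nucleoli$prominence))
  readr::write_csv(pheno_real, file.path(out_dir, "phenotypes_real.csv"))
  pheno_syn <- run_stage("phenotypes-synthetic", {
    purrr::imap_dfr(trajectories_up, function(tr, i) {
      nodes <- tr$nodes
      first <- !duplicated(nodes$pred_grade)
      purrr::map2_dfr(which(first), nodes$pred_grade[first], function(ni, g) {
        rec <- phenotype_record(nodes$patch[[ni]],
                                sigma = config$nucleoli$sigma,
                                prominence = config$nucleoli$prominence)
        dplyr::mutate(rec, patch_id = sprintf("T%03d_n%02d", i, ni), grade = g,
                      trajectory = i)
      })
    })
  })
  readr::write_csv(pheno_syn, file.path(out_dir, "phenotypes_synthetic.csv"))

  say("stage 6/7: counterfactual power analysis")
  pw <- config$power
  syn_feat <- pheno_syn |>
    dplyr::select(trajectory, grade, feature = "mean_tumor_nuclear_area")
  real_feat <- pheno_real |>
    dplyr::select(grade, feature = "mean_tumor_nuclear_area")
  power <- run_stage("power", power_analysis(
    real_features = real_feat, syn_features = syn_feat,
    grade_pairs = pw$grade_pairs, strategies = pw$strategies,
    n_per_group = min(pw$n_per_group, length(trajectories_up), syn$n_per_grade),
    n_reps = pw$n_reps, seed = derive_seed(seed, "power")))
  readr::write_csv(dplyr::select(power, -"p_values"),
                   file.path(out_dir, "power.csv"))

  say("stage 7/7: manifest")
  manifest <- list(
    package = "deltamarch",
    version = as.character(utils::packageVersion("deltamarch")),
    seed = seed,
    stage_seeds = list(
      cohort = derive_seed(seed, "cohort"),
      enrichment = derive_seed(seed, "enrichment"),
      power = derive_seed(seed, "power")
    ),
    config = unclass(config),
    n_trajectories_up = length(trajectories_up),
    n_trajectories_down = length(trajectories_down)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    cohort = cohort, backend = backend, model = model,
    latent_metrics = latent_metrics,
    trajectories_up = trajectories_up, trajectories_down = trajectories_down,
    enrichment = enrichment, enrichment_summary = enr_summary,
    phenotypes_real = pheno_real, phenotypes_synthetic = pheno_syn,
    power = power, manifest = manifest
  ))
}
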