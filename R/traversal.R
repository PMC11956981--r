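# Counterfactual trajectories: shift a standardized semantic code along a
# class weight vector in steps proportional to sqrt(d), decode with a fixed
# stochastic state after each shift, halt at the terminal grade prediction or
# a step cap, then interpolate interior nodes along the final path.

#' Traverse the latent space towards a target grade
#'
#' In standardized code space the code is repeatedly shifted by
#' `step_scale * sqrt(d)` along the unit-normalized weight vector of the
#' target class. After each shift the code is destandardized and decoded with
#' the fixed stochastic state, and the image-level grade predictor is
#' consulted; the walk halts when the prediction equals `target_grade` or
#' after `max_steps` shifts. `n_nodes` strictly interior nodes are then
#' interpolated linearly between the start and final codes, each decoded with
#' the same state, and the predicted grade of every node is recorded (nodes
#' are never discarded by this validation).
#'
#' If the start image is already predicted as `target_grade` a degenerate
#' zero-shift trajectory is returned (not an error).
#'
#' @param backend a `dm_backend` providing `decode(code, state)`.
#' @param code semantic code of the start patch (raw, unstandardized).
#' @param state stochastic state shared by every decoded node.
#' @param model fitted `latent_class_model` supplying the class axes.
#' @param grade_predictor function mapping a decoded patch to a grade label.
#' @param target_grade grade whose weight vector defines the direction.
#' @param step_scale proportionality constant of the sqrt(d) step (default 1).
#' @param max_steps shift cap (default 4).
#' @param n_nodes number of strictly interior interpolated nodes (default 20).
#' @param direction optional raw replacement direction in *standardized*
#'   space (unit-normalized internally); defaults to the target class's
#'   weight vector.
#' @return A `dm_trajectory`: list with `start_code`, `end_code`, `state`,
#'   `nodes` (tibble: node, frac, role, code list-col, patch list-col,
#'   pred_grade), `direction_class`, `n_shift_steps`, `halted_by`.
#' @export
traverse_grade <- function(backend, code, state, model, grade_predictor,
                           target_grade, step_scale = 1, max_steps = 4,
                           n_nodes = 20, direction = NULL) {
  check_fitted(model)
  stopifnot(inherits(backend, "dm_backend"), step_scale >= 0, max_steps >= 1)
  code <- as.numeric(code)
  d <- length(code)
  key <- as.character(target_grade)
  if (is.null(direction) && !key %in% rownames(model$weights)) {
    dm_abort("target grade has no weight vector in the model")
  }
  w <- direction %||% model$weights[key, ]
  nw <- sqrt(sum(w^2))
  if (nw == 0) dm_abort("direction vector has zero norm")
  unit <- w / nw
  step <- step_scale * sqrt(d)

  z0 <- standardize(code, model)
  z <- z0
  n_shift <- 0L
  halted_by <- "terminal_grade"
  start_pred <- grade_predictor(backend$decode(destandardize(z0, model), state))
  if (!identical(as.integer(start_pred), as.integer(target_grade))) {
    halted_by <- "step_cap"
    for (s in seq_len(max_steps)) {
      z <- z + step * unit
      n_shift <- s
      patch <- backend$decode(destandardize(z, model), state)
      pred <- grade_predictor(patch)
      if (identical(as.integer(pred), as.integer(target_grade))) {
        halted_by <- "terminal_grade"
        break
      }
    }
  } else {
    n_shift <- 0L
  }
  z_end <- z

  fracs <- seq(0, 1, length.out = n_nodes + 2)
  roles <- c("start", rep("interior", n_nodes), "end")
  nodes <- purrr::map(seq_along(fracs), function(i) {
    zi <- z0 + fracs[i] * (z_end - z0)
    ci <- destandardize(zi, model)
    patch <- backend$decode(ci, state)
    list(code = ci, patch = patch, pred = grade_predictor(patch))
  })
  node_tbl <- tibble(
    node = seq_along(fracs),
    frac = fracs,
    role = roles,
    code = purrr::map(nodes, "code"),
    patch = purrr::map(nodes, "patch"),
    pred_grade = purrr::map_int(nodes, ~ as.integer(.x$pred))
  )
  structure(list(
    start_code = destandardize(z0, model),
    end_code = destandardize(z_end, model),
    state = state,
    nodes = node_tbl,
    direction_class = target_grade,
    n_shift_steps = n_shift,
    halted_by = halted_by,
    step_scale = step_scale,
    model = model
  ), class = "dm_trajectory")
}

#' Traverse towards grade 1
#'
#' Same walk as [traverse_grade()] with the grade-1 weight vector as the
#' direction and grade 1 as the terminal prediction.
#'
#' @inheritParams traverse_grade
#' @param ... passed to [traverse_grade()].
#' @return A `dm_trajectory`.
#' @export
grade_down <- function(backend, code, state, model, grade_predictor, ...) {
  traverse_grade(backend, code, state, model, grade_predictor,
                 target_grade = 1, ...)
}

#' @export
print.dm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dm_trajectory -> grade %s  %d shifts (%s)  %d nodes  grades: %s>\n",
    x$direction_class, x$n_shift_steps, x$halted_by, nrow(x$nodes),
    paste(x$nodes$pred_grade, collapse = " ")))
  invisible(x)
}

#' Tidy the node table of a trajectory
#'
#' @param x a `dm_trajectory`.
#' @param ... unused.
#' @return Tibble with node index, interpolation fraction, role and predicted
#'   grade (image columns dropped).
#' @export
tidy.dm_trajectory <- function(x, ...) {
  dplyr::select(x$nodes, "node", "frac", "role", "pred_grade")
}

#' @rdname tidy.dm_trajectory
#' @export
glance.dm_trajectory <- function(x, ...) {
  tibble(direction_class = x$direction_class, n_shift_steps = x$n_shift_steps,
         halted_by = x$halted_by, n_nodes = sum(x$nodes$role == "interior"),
         start_grade = x$nodes$pred_grade[1],
         end_grade = x$nodes$pred_grade[nrow(x$nodes)])
}

#' Within-grade (across-patient) counterfactual swap
#'
#' Keeps patch A's stochastic state but replaces its semantic code with patch
#' B's, where B shares the grade label but comes from a different slide. The
#' negative control of the grade traversal: grade statistics should follow B
#' while positions follow A.
#'
#' @param patch_a,patch_b `labeled_patch`es with equal `grade_label` and
#'   different `slide_id`.
#' @param backend a `dm_backend`.
#' @return The decoded counterfactual patch.
#' @export
within_grade_swap <- function(patch_a, patch_b, backend) {
  stopifnot(inherits(backend, "dm_backend"))
  if (!identical(patch_a$grade_label, patch_b$grade_label)) {
    dm_abort("within_grade_swap: patches must share a grade label")
  }
  same_slide <- !is.na(patch_a$slide_id) && !is.na(patch_b$slide_id) &&
    identical(patch_a$slide_id, patch_b$slide_id)
  if (same_slide && !identical(patch_a, patch_b)) {
    dm_abort("within_grade_swap: patches must come from different slides")
  }
  code_b <- backend$encode(patch_b$params %||% patch_b)
  state_a <- backend$encode_stochastic(patch_a)
  backend$decode(code_b, state_a)
}
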