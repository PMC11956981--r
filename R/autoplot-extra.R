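# Plot methods for the remaining result types.

#' Plot a labelled patch
#'
#' Renders the RGB image as a raster, optionally outlining the ground-truth
#' nuclei and vasculature masks.
#'
#' @param object a `labeled_patch`.
#' @param masks overlay mask contours (default TRUE).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_patch <- function(object, masks = TRUE, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- tidyr::expand_grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(img[, , 1][cbind(df$row, df$col)],
                            img[, , 2][cbind(df$row, df$col)],
                            img[, , 3][cbind(df$row, df$col)])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (masks && !is.null(object$nuclei_mask)) {
    mk <- tidyr::expand_grid(row = seq_len(h), col = seq_len(w))
    mk$nuc <- as.integer(object$nuclei_mask[cbind(mk$row, mk$col)])
    mk$vas <- as.integer(object$vasc_mask[cbind(mk$row, mk$col)])
    gg <- gg +
      ggplot2::geom_contour(data = mk, ggplot2::aes(z = .data$nuc),
                            breaks = 0.5, colour = "blue", linewidth = 0.2) +
      ggplot2::geom_contour(data = mk, ggplot2::aes(z = .data$vas),
                            breaks = 0.5, colour = "red", linewidth = 0.2)
  }
  gg
}

#' Plot the grade progression of a trajectory
#'
#' Predicted grade of every node against its interpolation fraction along the
#' standardized latent path.
#'
#' @param object a `dm_trajectory`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dm_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac, y = .data$pred_grade)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role)) +
    ggplot2::scale_y_continuous(breaks = 1:4, limits = c(1, 4)) +
    ggplot2::labs(x = "interpolation fraction", y = "predicted grade",
                  colour = NULL,
                  title = sprintf("Trajectory toward grade %s (%d shifts, %s)",
                                  object$direction_class, object$n_shift_steps,
                                  object$halted_by)) +
    ggplot2::theme_minimal()
}
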