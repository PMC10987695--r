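#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a beta posterior density
#'
#' @param object A [beta_posterior()].
#' @param ... Additional posteriors to overlay, optionally named.
#' @return A ggplot.
#' @export
autoplot.beta_posterior <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "beta_posterior")]
  all_post <- c(list(object), extra)
  nms <- names(all_post)
  if (is.null(nms)) nms <- rep("", length(all_post))
  nms[nms == ""] <- paste0("posterior ", seq_along(all_post))[nms == ""]
  x <- seq(0.001, 0.999, length.out = 512)
  df <- purrr::map2_dfr(all_post, nms, function(p, nm) {
    tibble::tibble(accuracy = x, density = stats::dbeta(x, p$alpha, p$beta),
                   posterior = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy, .data$density,
                                   color = .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accuracy", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot the posterior trajectory of an Independent Validation run
#'
#' Shows the running MAP with a +/- 2 posterior-SD ribbon and the chance
#' level for six classes.
#'
#' @param object An `svc_iv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svc_iv <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(.data$chunk, .data$map)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$map - 2 * .data$sd),
                                      ymax = pmin(1, .data$map + 2 * .data$sd)),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed") +
    ggplot2::labs(x = "chunk", y = "posterior MAP accuracy") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation balanced accuracies
#'
#' @param object An `svc_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svc_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = "", y = .data$bac)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05, height = 0) +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed") +
    ggplot2::labs(x = object$design, y = "balanced accuracy") +
    ggplot2::theme_minimal()
}

#' Plot time-segment Shapley attributions
#'
#' @param object An `svc_shap` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svc_shap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$start_s, .data$value)) +
    ggplot2::geom_col(ggplot2::aes(width = .data$end_s - .data$start_s),
                      just = 0, fill = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "Shapley value") +
    ggplot2::theme_minimal()
}

#' Display a spectrogram or saliency map
#'
#' @param object A `spectrogram` or `svc_saliency` object.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.spectrogram <- function(object, ...) {
  d <- dim(object)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(object[, , 1][as.matrix(df)] / 255,
                            object[, , 2][as.matrix(df)] / 255,
                            object[, , 3][as.matrix(df)] / 255)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.spectrogram
#' @export
autoplot.svc_saliency <- function(object, ...) {
  m <- unclass(object)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$saliency <- m[as.matrix(df)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
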