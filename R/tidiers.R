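#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta posterior
#'
#' @param x A [beta_posterior()].
#' @param ... Unused.
#' @return One-row tibble with `alpha`, `beta`, `mean`, `map`, `sd` and the
#'   central 95% credible interval.
#' @export
tidy.beta_posterior <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, mean = beta_mean(x),
                 map = beta_map(x), sd = beta_sd(x),
                 conf.low = stats::qbeta(0.025, x$alpha, x$beta),
                 conf.high = stats::qbeta(0.975, x$alpha, x$beta))
}

#' Tidy / summarize an Independent Validation run
#'
#' `tidy()` returns the chunk-wise trace; `glance()` the one-row summary.
#'
#' @param x An `svc_iv` object.
#' @param ... Unused.
#' @export
tidy.svc_iv <- function(x, ...) x$trace

#' @rdname tidy.svc_iv
#' @export
glance.svc_iv <- function(x, ...) {
  tibble::tibble(design = x$design, n_chunks = nrow(x$trace),
                 chunk = x$chunk, n_stream = x$n_stream,
                 n_correct = sum(x$trace$n_correct),
                 alpha = x$posterior$alpha, beta = x$posterior$beta,
                 map = beta_map(x$posterior), sd = beta_sd(x$posterior),
                 final_val_accuracy = utils::tail(x$trace$val_accuracy, 1))
}

#' Tidy / summarize a cross-validation result
#'
#' `tidy()` returns per-fold balanced accuracies; `glance()` the pooled
#' summary.
#'
#' @param x An `svc_cv` object.
#' @param ... Unused.
#' @export
tidy.svc_cv <- function(x, ...) x$folds[c("fold", "bac", "accuracy")]

#' @rdname tidy.svc_cv
#' @export
glance.svc_cv <- function(x, ...) {
  pooled <- Reduce(`+`, x$folds$confusion)
  tibble::tibble(design = x$design, k = x$k,
                 mean_bac = mean(x$folds$bac), sd_bac = stats::sd(x$folds$bac),
                 mean_accuracy = mean(x$folds$accuracy),
                 pooled_bac = balanced_accuracy(pooled))
}

#' Tidy a trained model's training history
#'
#' @param x An `svc_model`.
#' @param ... Unused.
#' @export
tidy.svc_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_accuracy = numeric(), val_bac = numeric())
}

#' @rdname tidy.svc_model
#' @export
glance.svc_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(design = x$design,
                 n_parameters = sum(vapply(x$params, length, integer(1))),
                 trained = x$trained, epochs_run = nrow(h),
                 best_val_accuracy = if (nrow(h) > 0) max(h$val_accuracy) else NA_real_)
}
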