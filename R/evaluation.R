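#' Beta posterior over a classifier's accuracy
#'
#' Conjugate container for binomial accuracy estimation: a beta(alpha, beta)
#' density updated with correct/incorrect prediction counts. The flat
#' beta(1, 1) prior represents minimal prior information.
#'
#' @param alpha,beta Positive shape parameters.
#' @return A `beta_posterior` object.
#' @export
#' @examples
#' p <- beta_update(beta_posterior(1, 1), successes = 3, failures = 1)
#' beta_map(p)
beta_posterior <- function(alpha = 1, beta = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("<beta(%g, %g): MAP %.4f, mean %.4f, sd %.4f>\n",
              x$alpha, x$beta, beta_map(x), beta_mean(x), beta_sd(x)))
  invisible(x)
}

#' @rdname beta_posterior
#' @param p A `beta_posterior`.
#' @param successes,failures Non-negative prediction counts.
#' @export
beta_update <- function(p, successes, failures) {
  stopifnot(inherits(p, "beta_posterior"))
  if (successes < 0 || failures < 0) {
    stop("success/failure counts must be non-negative", call. = FALSE)
  }
  beta_posterior(p$alpha + successes, p$beta + failures)
}

#' Summaries of a beta posterior
#'
#' `beta_map()` is the posterior mode `(alpha - 1) / (alpha + beta - 2)` when
#' both parameters exceed 1; when the mode is undefined (either parameter
#' at or below 1) the posterior mean is returned instead.
#'
#' @param p A [beta_posterior()].
#' @return A scalar summary.
#' @export
beta_map <- function(p) {
  stopifnot(inherits(p, "beta_posterior"))
  if (p$alpha > 1 && p$beta > 1) {
    (p$alpha - 1) / (p$alpha + p$beta - 2)
  } else {
    beta_mean(p)
  }
}

#' @rdname beta_map
#' @export
beta_mean <- function(p) p$alpha / (p$alpha + p$beta)

#' @rdname beta_map
#' @export
beta_sd <- function(p) {
  ab <- p$alpha + p$beta
  sqrt(p$alpha * p$beta / (ab^2 * (ab + 1)))
}

#' Probability that one posterior exceeds another
#'
#' Estimates `P(X_a > X_b)` for independent beta posteriors, either by
#' seeded Monte-Carlo sampling or by deterministic numeric integration of
#' `f_a(x) F_b(x)`.
#'
#' @param a,b [beta_posterior()] objects.
#' @param draws Monte-Carlo sample size (>= 10,000).
#' @param method `"mc"` (seeded sampling) or `"quadrature"` (deterministic).
#' @param seed Seed for the Monte-Carlo path.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' prob_greater(beta_posterior(2, 1), beta_posterior(1, 2), method = "quadrature")
prob_greater <- function(a, b, draws = 10000, method = c("mc", "quadrature"),
                         seed = 1) {
  stopifnot(inherits(a, "beta_posterior"), inherits(b, "beta_posterior"))
  method <- match.arg(method)
  if (method == "quadrature") {
    val <- stats::integrate(function(x) {
      stats::dbeta(x, a$alpha, a$beta) * stats::pbeta(x, b$alpha, b$beta)
    }, 0, 1, subdivisions = 1000L, rel.tol = 1e-9, stop.on.error = FALSE)$value
    return(min(1, max(0, val)))
  }
  if (draws < 10000) stop("draws must be at least 10,000", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  mean(stats::rbeta(draws, a$alpha, a$beta) > stats::rbeta(draws, b$alpha, b$beta))
}

#' Overlap coefficient of two beta posteriors
#'
#' The shared probability mass `integral of min(f_a, f_b)` over \[0, 1\],
#' computed by adaptive quadrature (with a fine-grid Simpson fallback for
#' extremely peaked densities). 1 means identical posteriors; near 0 means
#' practically disjoint.
#'
#' @param a,b [beta_posterior()] objects.
#' @return Overlap fraction in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  stopifnot(inherits(a, "beta_posterior"), inherits(b, "beta_posterior"))
  f <- function(x) pmin(stats::dbeta(x, a$alpha, a$beta),
                        stats::dbeta(x, b$alpha, b$beta))
  val <- tryCatch(
    stats::integrate(f, 0, 1, subdivisions = 2000L, rel.tol = 1e-8,
                     stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (!is.finite(val) || val < 0 || val > 1 + 1e-6) {
    x <- seq(0, 1, length.out = 200001)
    y <- f(x)
    val <- sum((y[-length(y)] + y[-1]) / 2) * (x[2] - x[1])
  }
  min(1, max(0, val))
}

#' Balanced accuracy from a confusion table
#'
#' The mean over classes of per-class recall (diagonal over row sum). On
#' balanced data this equals plain accuracy; chance level for six classes
#' is 1/6.
#'
#' @param confusion Square count matrix, rows = truth, columns = prediction.
#' @return Balanced accuracy in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(diag(6) * 5)
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    stop("confusion table has class(es) with no true instances: ",
         paste(which(rs == 0), collapse = ", "), call. = FALSE)
  }
  mean(diag(confusion) / rs)
}

confusion_table <- function(truth, pred) {
  lv <- emotion_levels()
  table(truth = factor(as.character(truth), levels = lv),
        pred = factor(as.character(pred), levels = lv))
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into k stratified folds, trains a fresh model on each
#' training partition (with a stratified 85/15 internal validation split for
#' epoch checkpointing) and evaluates balanced accuracy on the held-out fold.
#'
#' @param dataset An `svc_dataset` from [build_dataset()].
#' @param design Classifier design.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and training.
#' @param config Optional [model_config()]; a default is derived otherwise.
#' @return An `svc_cv` object: tibble of per-fold results (`fold`, `bac`,
#'   `accuracy`, `confusion` list-column) with the pooled confusion and mean
#'   BAC retrievable via [glance()].
#' @export
run_cv <- function(dataset, design = "dnn", k = 10, seed = 1, config = NULL) {
  stopifnot(inherits(dataset, "svc_dataset"), k >= 2, dataset$n >= k)
  if (is.null(config)) config <- model_config(design = design, seed = seed)
  fold <- stratified_folds(dataset$labels, k, seed)
  if (any(table(fold) == 0)) stop("dataset too small for ", k, " folds",
                                  call. = FALSE)
  res <- lapply(seq_len(k), function(f) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    inner <- stratified_split(droplevels_safe(dataset$labels[train_idx]),
                              c(0.85, 0.15), seed + f)
    tr <- train_idx[inner[[1]]]
    va <- train_idx[inner[[2]]]
    model <- build_model(config,
                         feature_dim = if (!is.null(dataset$features))
                           ncol(dataset$features) else NULL)
    model <- train_model(model, dataset_inputs(dataset, tr), dataset$labels[tr],
                         dataset_inputs(dataset, va), dataset$labels[va])
    pred <- predict(model, dataset_inputs(dataset, test_idx))
    cm <- confusion_table(dataset$labels[test_idx], pred)
    rs <- rowSums(cm)
    recalls <- (diag(cm) / ifelse(rs > 0, rs, 1))[rs > 0]
    tibble::tibble(fold = f, bac = mean(recalls),
                   accuracy = mean(as.character(pred) ==
                                     as.character(dataset$labels[test_idx])),
                   confusion = list(cm))
  })
  structure(list(folds = dplyr::bind_rows(res), design = design, k = k,
                 seed = seed), class = "svc_cv")
}

droplevels_safe <- function(f) factor(as.character(f), levels = levels(f))

#' @export
print.svc_cv <- function(x, ...) {
  cat(sprintf("<svc_cv: %s, %d folds, mean BAC %.3f>\n", x$design, x$k,
              mean(x$folds$bac)))
  invisible(x)
}

#' Independent Validation with sequential beta updating
#'
#' The dataset is stratified into an initial training partition
#' (`init_frac`), a fixed validation partition (`val_frac`) used only to
#' monitor overfitting, and a stream holding the remainder. The model is
#' trained on the initial partition, then the stream is consumed in chunks
#' of `chunk` items (16 by default): each chunk is predicted *before* being
#' added to the training set, the correct/incorrect counts update the beta
#' posterior, and the model continues training for one epoch on the enlarged
#' set (set `full_retrain = TRUE` to retrain from scratch each chunk). Every
#' prediction is therefore out-of-sample at the time it is made.
#'
#' @param dataset An `svc_dataset`.
#' @param design Classifier design.
#' @param chunk Chunk size (default 16).
#' @param init_frac,val_frac Initial-training and validation fractions.
#' @param prior A [beta_posterior()] prior (default flat beta(1, 1)).
#' @param seed Integer seed.
#' @param config Optional [model_config()].
#' @param full_retrain Retrain from scratch after each chunk instead of
#'   continuing incrementally.
#' @param mode `"accuracy"` updates one posterior over plain correctness;
#'   `"balanced"` additionally maintains six per-class recall posteriors.
#' @return An `svc_iv` object with the chunk-wise `trace` tibble, the final
#'   `posterior`, per-class posteriors (in `"balanced"` mode), the fitted
#'   model and the stream bookkeeping.
#' @export
run_independent_validation <- function(dataset, design = "dnn", chunk = 16,
                                       init_frac = 0.10, val_frac = 0.10,
                                       prior = beta_posterior(1, 1), seed = 1,
                                       config = NULL, full_retrain = FALSE,
                                       mode = c("accuracy", "balanced")) {
  stopifnot(inherits(dataset, "svc_dataset"))
  mode <- match.arg(mode)
  if (is.null(config)) config <- model_config(design = design, seed = seed)
  split <- stratified_split(dataset$labels,
                            c(init_frac, val_frac, 1 - init_frac - val_frac),
                            seed)
  init_idx <- split[[1]]; val_idx <- split[[2]]; stream_idx <- split[[3]]
  if (length(init_idx) < 6 || length(val_idx) < 6 || length(stream_idx) < chunk) {
    stop("dataset too small for Independent Validation: need at least ",
         ceiling(chunk / (1 - init_frac - val_frac)), " items", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed + 1)
  stream_idx <- sample(stream_idx)

  model <- build_model(config,
                       feature_dim = if (!is.null(dataset$features))
                         ncol(dataset$features) else NULL)
  model <- train_model(model, dataset_inputs(dataset, init_idx),
                       dataset$labels[init_idx],
                       dataset_inputs(dataset, val_idx),
                       dataset$labels[val_idx])

  posterior <- prior
  class_post <- stats::setNames(lapply(emotion_levels(), function(.) prior),
                                emotion_levels())
  train_pool <- init_idx
  n_chunks <- ceiling(length(stream_idx) / chunk)
  trace <- vector("list", n_chunks)
  correct_flags <- logical(0)
  pred_all <- character(0)
  truth_all <- character(0)

  for (ci in seq_len(n_chunks)) {
    take <- stream_idx[((ci - 1) * chunk + 1):min(ci * chunk, length(stream_idx))]
    pred <- predict(model, dataset_inputs(dataset, take))
    truth <- dataset$labels[take]
    ok <- as.character(pred) == as.character(truth)
    posterior <- beta_update(posterior, sum(ok), sum(!ok))
    if (mode == "balanced") {
      for (cl in unique(as.character(truth))) {
        m <- as.character(truth) == cl
        class_post[[cl]] <- beta_update(class_post[[cl]], sum(ok[m]), sum(!ok[m]))
      }
    }
    correct_flags <- c(correct_flags, ok)
    pred_all <- c(pred_all, as.character(pred))
    truth_all <- c(truth_all, as.character(truth))
    train_pool <- c(train_pool, take)
    if (full_retrain) {
      model <- build_model(config,
                           feature_dim = if (!is.null(dataset$features))
                             ncol(dataset$features) else NULL)
      model <- train_model(model, dataset_inputs(dataset, train_pool),
                           dataset$labels[train_pool],
                           dataset_inputs(dataset, val_idx),
                           dataset$labels[val_idx])
    } else {
      model <- train_model(model, dataset_inputs(dataset, train_pool),
                           dataset$labels[train_pool],
                           dataset_inputs(dataset, val_idx),
                           dataset$labels[val_idx],
                           epochs = 1, reset_optimizer = FALSE)
    }
    val_acc <- utils::tail(model$history$val_accuracy, 1)
    trace[[ci]] <- tibble::tibble(
      chunk = ci, n_items = length(take), n_correct = sum(ok),
      alpha = posterior$alpha, beta = posterior$beta,
      map = beta_map(posterior), sd = beta_sd(posterior),
      val_accuracy = val_acc)
  }

  structure(list(
    trace = dplyr::bind_rows(trace), posterior = posterior,
    class_posteriors = if (mode == "balanced") class_post else NULL,
    model = model, design = design, chunk = chunk, seed = seed, mode = mode,
    n_init = length(init_idx), n_val = length(val_idx),
    n_stream = length(stream_idx),
    predictions = tibble::tibble(truth = truth_all, pred = pred_all,
                                 correct = correct_flags)),
    class = "svc_iv")
}

#' @export
print.svc_iv <- function(x, ...) {
  cat(sprintf(
    "<svc_iv: %s, %d chunks of %d (stream %d), posterior beta(%g, %g), MAP %.3f>\n",
    x$design, nrow(x$trace), x$chunk, x$n_stream,
    x$posterior$alpha, x$posterior$beta, beta_map(x$posterior)))
  invisible(x)
}

#' Posterior of a random six-class classifier
#'
#' Simulates uniform guessing over `n_items` predictions with seeded draws
#' and updates the prior with the resulting correct/incorrect counts. The
#' analytic expected success rate, `1 / n_classes`, is attached as attribute
#' `expected_rate`.
#'
#' @param n_items Number of simulated predictions (>= 1).
#' @param n_classes Number of classes (default 6).
#' @param prior A [beta_posterior()].
#' @param seed Integer seed.
#' @return A [beta_posterior()].
#' @export
random_classifier_posterior <- function(n_items, n_classes = 6,
                                        prior = beta_posterior(1, 1), seed = 1) {
  if (n_items < 1) stop("n_items must be at least 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  guesses <- sample.int(n_classes, n_items, replace = TRUE)
  truths <- sample.int(n_classes, n_items, replace = TRUE)
  correct <- sum(guesses == truths)
  out <- beta_update(prior, correct, n_items - correct)
  attr(out, "expected_rate") <- 1 / n_classes
  out
}

#' Per-emotion accuracy posteriors from human rating counts
#'
#' Converts per-emotion correct/total rating counts into beta posteriors
#' (`beta(prior_alpha + correct, prior_beta + total - correct)`), for
#' comparison with a model's per-class recall posteriors via
#' [overlap_coefficient()] and [prob_greater()]. Emotions with zero total
#' ratings are excluded with a warning.
#'
#' @param ratings Tibble/data frame with columns `emotion`, `correct`,
#'   `total`.
#' @param prior A [beta_posterior()].
#' @return A tibble with `emotion`, `alpha`, `beta` and a `posterior`
#'   list-column.
#' @export
human_posteriors <- function(ratings, prior = beta_posterior(1, 1)) {
  stopifnot(all(c("emotion", "correct", "total") %in% names(ratings)))
  if (any(ratings$correct > ratings$total)) {
    stop("correct counts exceed totals", call. = FALSE)
  }
  if (any(ratings$correct < 0 | ratings$total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  zero <- ratings$total == 0
  if (any(zero)) {
    warning("excluding emotion(s) with no ratings: ",
            paste(ratings$emotion[zero], collapse = ", "))
    ratings <- ratings[!zero, , drop = FALSE]
  }
  invisible(as_emotion(ratings$emotion))
  post <- purrr::map2(ratings$correct, ratings$total, function(c_, t_) {
    beta_update(prior, c_, t_ - c_)
  })
  tibble::tibble(emotion = ratings$emotion,
                 alpha = vapply(post, `[[`, numeric(1), "alpha"),
                 beta = vapply(post, `[[`, numeric(1), "beta"),
                 posterior = post)
}

#' Per-class recall posteriors from a confusion table
#'
#' @param confusion 6x6 count table (rows = truth).
#' @param prior A [beta_posterior()].
#' @return A tibble as in [human_posteriors()].
#' @export
recall_posteriors <- function(confusion, prior = beta_posterior(1, 1)) {
  confusion <- as.matrix(confusion)
  correct <- diag(confusion)
  total <- rowSums(confusion)
  human_posteriors(tibble::tibble(emotion = emotion_levels(),
                                  correct = as.numeric(correct),
                                  total = as.numeric(total)), prior)
}

#' Compare model and human posteriors emotion by emotion
#'
#' @param model_post,human_post Tibbles from [recall_posteriors()] /
#'   [human_posteriors()].
#' @return Tibble with per-emotion overlap coefficient and
#'   `P(model > human)`.
#' @export
compare_posteriors <- function(model_post, human_post) {
  joined <- dplyr::inner_join(model_post, human_post, by = "emotion",
                              suffix = c("_model", "_human"))
  joined$overlap <- purrr::map2_dbl(joined$posterior_model,
                                    joined$posterior_human,
                                    overlap_coefficient)
  joined$p_model_greater <- purrr::map2_dbl(joined$posterior_model,
                                            joined$posterior_human,
                                            function(a, b)
                                              prob_greater(a, b, method = "quadrature"))
  joined[c("emotion", "overlap", "p_model_greater")]
}
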