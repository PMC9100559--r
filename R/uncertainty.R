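#' Monte-Carlo-dropout prediction
#'
#' Runs `n_replicates` stochastic forward passes with dropout active. For a
#' classifier, the replicate softmax vectors are averaged; the predicted
#' class is the argmax of the mean vector (ties toward the less-threatened
#' class) and the confidence is the mean probability of that class. For a
#' regression model, each replicate's score is rounded to a class; the
#' predicted class is the modal class and the confidence the modal fraction.
#'
#' @param model A `trained_model` with `dropout_rate > 0`.
#' @param x Normalized feature matrix.
#' @param n_replicates Number of dropout replicates (default 100).
#' @param seed Integer RNG seed for the dropout masks.
#' @param species Optional character vector labelling the rows.
#' @return Data frame of class `mc_prediction`: `species` (if given),
#'   `pred_class` (0-based), `confidence`, and one `prob_<k>` column per
#'   class with the mean replicate probability.
#' @export
mc_predict <- function(model, x, n_replicates = 100, seed = 1L, species = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (model$spec$dropout_rate <= 0) {
    stop("MC dropout requires a model trained with dropout_rate > 0")
  }
  x <- as.matrix(x)
  if (ncol(x) != model$n_in) stop("feature dimension mismatch")
  set.seed(seed)
  n <- nrow(x)
  K <- model$n_classes
  L <- length(model$params)
  acc <- matrix(0, n, K)
  for (r in seq_len(n_replicates)) {
    cache <- nn_forward(model$params, x, model$spec$dropout_rate, training = TRUE)
    out <- cache$A[[L + 1]]
    if (model$spec$mode == "classifier") {
      acc <- acc + softmax(out)
    } else {
      cls <- score_to_class(out[, 1], K)
      acc[cbind(seq_len(n), cls + 1L)] <- acc[cbind(seq_len(n), cls + 1L)] + 1
    }
  }
  probs <- acc / n_replicates
  pred <- max.col(probs, ties.method = "first") - 1L
  conf <- probs[cbind(seq_len(n), pred + 1L)]
  out <- data.frame(
    pred_class = pred, confidence = conf,
    setNames(as.data.frame(probs), paste0("prob_", seq_len(K) - 1L))
  )
  if (!is.null(species)) out <- cbind(species = species, out)
  class(out) <- c("mc_prediction", class(out))
  out
}

#' MC-dropout confidences for cross-validation held-out predictions
#'
#' Applies [mc_predict()] fold by fold, each fold's model predicting its own
#' held-out instances, and pools the results. This is the calibration set for
#' [find_threshold()].
#'
#' @param cv A `cv_result` (with stored per-fold models).
#' @param x The normalized feature matrix the CV was run on.
#' @param n_replicates,seed Passed to [mc_predict()] (seed offset per fold).
#' @return Data frame: `index`, `fold`, `truth`, `pred_class`, `confidence`,
#'   `correct`.
#' @export
mc_cv_predictions <- function(cv, x, n_replicates = 100, seed = 1L) {
  x <- as.matrix(x)
  out <- vector("list", length(cv$models))
  for (f in seq_along(cv$models)) {
    idx <- which(cv$folds == f)
    mc <- mc_predict(cv$models[[f]], x[idx, , drop = FALSE],
      n_replicates = n_replicates, seed = seed + f)
    out[[f]] <- data.frame(
      index = idx, fold = f,
      truth = cv$predictions$truth[idx],
      pred_class = mc$pred_class,
      confidence = mc$confidence
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$index), ]
  res$correct <- res$pred_class == res$truth
  rownames(res) <- NULL
  res
}

#' Confidence threshold attaining a target accuracy
#'
#' Finds the smallest confidence value t* among the observed confidences such
#' that the instances with confidence >= t* are predicted with at least the
#' target accuracy; instances below t* would be left unclassified. If the
#' overall accuracy already meets the target, t* is the minimum confidence
#' and nothing is unclassified; if no candidate attains the target, the
#' result is flagged unattainable.
#'
#' @param confidence Numeric confidences of a labeled evaluation set.
#' @param correct Logical, whether each prediction is correct.
#' @param target_accuracy Desired accuracy among retained instances.
#' @return List of class `threshold_result`: `target_accuracy`, `threshold`,
#'   `retained_accuracy`, `n_retained`, `n_unclassified`,
#'   `frac_unclassified`, `attainable`.
#' @export
find_threshold <- function(confidence, correct, target_accuracy) {
  if (!length(confidence)) stop("empty evaluation set")
  stopifnot(length(confidence) == length(correct))
  candidates <- sort(unique(confidence))
  for (t in candidates) {
    keep <- confidence >= t
    acc <- mean(correct[keep])
    if (acc >= target_accuracy) {
      return(structure(
        list(
          target_accuracy = target_accuracy,
          threshold = t,
          retained_accuracy = acc,
          n_retained = sum(keep),
          n_unclassified = sum(!keep),
          frac_unclassified = mean(!keep),
          attainable = TRUE
        ),
        class = "threshold_result"
      ))
    }
  }
  structure(
    list(
      target_accuracy = target_accuracy, threshold = NA_real_,
      retained_accuracy = NA_real_, n_retained = 0L,
      n_unclassified = length(confidence), frac_unclassified = 1,
      attainable = FALSE
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$attainable) {
    cat(sprintf(
      "<threshold_result> t* = %.4f for target %.2f: retained accuracy %.3f, %d unclassified (%.1f%%)\n",
      x$threshold, x$target_accuracy, x$retained_accuracy,
      x$n_unclassified, 100 * x$frac_unclassified
    ))
  } else {
    cat(sprintf("<threshold_result> target %.2f unattainable\n", x$target_accuracy))
  }
  invisible(x)
}

#' Partition predictions by a confidence threshold
#'
#' Instances with confidence >= t* are classified (ties at the threshold are
#' retained); the rest stay unclassified. The class composition of the
#' retained set is reported so shifts induced by thresholding are visible.
#'
#' @param mc An `mc_prediction` data frame (or any data frame with
#'   `pred_class` and `confidence`).
#' @param threshold The threshold t* (from [find_threshold()]).
#' @return List: `classified`, `unclassified` (row subsets), `composition`
#'   (retained-set class proportions), `frac_retained`.
#' @export
apply_threshold <- function(mc, threshold) {
  keep <- mc$confidence >= threshold
  classified <- mc[keep, , drop = FALSE]
  comp <- if (nrow(classified)) {
    prop.table(table(factor(classified$pred_class,
      levels = sort(unique(mc$pred_class)))))
  } else {
    table(factor(integer(0)))
  }
  list(
    classified = classified,
    unclassified = mc[!keep, , drop = FALSE],
    composition = comp,
    frac_retained = mean(keep)
  )
}

#' Write a threshold result as JSON
#'
#' @param x A `threshold_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
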