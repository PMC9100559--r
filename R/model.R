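#' Encode Red List labels as integer targets
#'
#' Five-class scheme: LC < NT < VU < EN < CR mapped to 0..4 by severity.
#' Binary scheme: LC and NT map to 0 ("not threatened"), VU, EN and CR map
#' to 1 ("possibly threatened"). DD (Data Deficient) species are excluded
#' from training and listed.
#'
#' @param labels Data frame with columns `species` and `category`
#'   (values in LC, NT, VU, EN, CR, DD).
#' @param scheme `"five_class"` or `"binary"`.
#' @return List of class `encoded_labels`: `species`, `y` (integer 0-based
#'   targets), `excluded` (species left out, with their category),
#'   `n_classes`, `class_names`, `scheme`.
#' @export
encode_labels <- function(labels, scheme = c("five_class", "binary")) {
  scheme <- match.arg(scheme)
  known <- c(RL_CLASSES, "DD")
  bad <- !(labels$category %in% known)
  if (any(bad)) {
    stop("unknown Red List category for species: ",
      paste(labels$species[bad], collapse = ", "))
  }
  use <- labels$category %in% RL_CLASSES
  cat_ <- labels$category[use]
  y <- if (scheme == "five_class") {
    match(cat_, RL_CLASSES) - 1L
  } else {
    as.integer(cat_ %in% THREATENED_CLASSES)
  }
  structure(
    list(
      species = labels$species[use],
      y = y,
      excluded = labels[!use, , drop = FALSE],
      n_classes = if (scheme == "five_class") 5L else 2L,
      class_names = if (scheme == "five_class") RL_CLASSES else
        c("not_threatened", "possibly_threatened"),
      scheme = scheme
    ),
    class = "encoded_labels"
  )
}

#' Stratified cross-validation folds
#'
#' Partitions indices into `k` folds, stratified by class: within each class
#' the (shuffled) members are dealt round-robin, so per-class fold sizes
#' differ by at most one. Classes with fewer than `k` members cannot appear
#' in every fold; a warning notes them.
#'
#' @param y Integer class targets (any coding).
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @return Integer vector of fold ids in `1..k`, same length as `y`.
#' @export
make_folds <- function(y, k = 5, seed = 1L) {
  n <- length(y)
  k <- as.integer(k)
  if (n < k) stop("need at least k labeled instances")
  set.seed(seed)
  fold <- integer(n)
  small <- character(0)
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    if (length(idx) < k) small <- c(small, as.character(cls))
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx) # stagger so small classes spread over folds
  }
  if (length(small)) {
    warning("classes with fewer than k members: ",
      paste(small, collapse = ", "))
  }
  fold
}

#' Cross-validate a network
#'
#' Five-fold (by default) stratified cross-validation. In each fold the
#' remaining folds form the training set and the held-out fold doubles as
#' the early-stopping validation set (80/20 usage), whose predictions are
#' recorded as the held-out predictions of the fold.
#'
#' @param x Normalized feature matrix (rows align with `y`).
#' @param y Integer 0-based targets.
#' @param spec An [mlp_spec()].
#' @param k Number of folds.
#' @param seed Integer seed controlling fold assignment and per-fold training.
#' @param n_classes Number of classes; default `max(y) + 1`.
#' @return List of class `cv_result`: `folds`, `fold_accuracy`,
#'   `mean_accuracy` (pooled over held-out predictions), `confusion`
#'   (true classes in rows, predicted in columns), `per_class`, `predictions`
#'   (data frame `index`, `fold`, `truth`, `pred`), `models` (per-fold
#'   trained networks), `spec`.
#' @export
cross_validate <- function(x, y, spec, k = 5, seed = 1L,
                           n_classes = max(y) + 1L) {
  x <- as.matrix(x)
  folds <- make_folds(y, k, seed)
  preds <- integer(length(y))
  models <- vector("list", k)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    va <- !tr
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f # independent init/batching per fold
    model <- train_network(
      x[tr, , drop = FALSE], y[tr],
      x[va, , drop = FALSE], y[va],
      fold_spec, n_classes
    )
    models[[f]] <- model
    p <- predict_class(model, x[va, , drop = FALSE])
    preds[va] <- p
    fold_acc[f] <- mean(p == y[va])
  }
  confusion <- table(
    factor(y, levels = 0:(n_classes - 1)),
    factor(preds, levels = 0:(n_classes - 1))
  )
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "predicted")
  structure(
    list(
      folds = folds,
      fold_accuracy = fold_acc,
      mean_accuracy = sum(diag(confusion)) / sum(confusion),
      confusion = confusion,
      per_class = NULL,
      predictions = data.frame(
        index = seq_along(y), fold = folds, truth = y, pred = preds
      ),
      models = models,
      spec = spec
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean held-out accuracy %.3f\n",
    length(x$fold_accuracy), x$mean_accuracy))
  cat("  per-fold:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Per-class accuracy from a cross-validation confusion matrix
#'
#' @param cv A `cv_result` (or a plain confusion matrix with true classes in
#'   rows).
#' @return Numeric vector: diagonal over row sum per class; `NA` for classes
#'   with no true instances.
#' @export
per_class_accuracy <- function(cv) {
  m <- if (inherits(cv, "cv_result")) cv$confusion else as.matrix(cv)
  rs <- rowSums(m)
  acc <- diag(m) / rs
  acc[rs == 0] <- NA_real_
  acc
}

#' Write a cross-validation result as JSON
#'
#' @param cv A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  jsonlite::write_json(
    list(
      fold_accuracy = cv$fold_accuracy,
      mean_accuracy = cv$mean_accuracy,
      confusion = cv$confusion,
      per_class = as.numeric(per_class_accuracy(cv))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
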