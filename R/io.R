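#' Write a feature set as CSV
#'
#' One row per species: the named feature columns plus a `complete` flag;
#' dropped species appear with `complete = FALSE`, empty feature cells and
#' their drop reason.
#'
#' @param feature_set A `feature_set` from [assemble_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feature_set, path) {
  stopifnot(inherits(feature_set, "feature_set"))
  feats <- feature_set$features
  feats$complete <- TRUE
  feats$drop_reason <- ""
  if (nrow(feature_set$dropped)) {
    pad <- feats[rep(NA_integer_, nrow(feature_set$dropped)), ]
    pad$species <- feature_set$dropped$species
    pad$complete <- FALSE
    pad$drop_reason <- feature_set$dropped$reason
    feats <- rbind(feats, pad)
  }
  write.csv(feats, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature CSV written by [write_features()]
#'
#' @param path CSV path.
#' @return A `feature_set` (complete rows in `features`, the rest in
#'   `dropped`).
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  complete <- df$complete %in% c(TRUE, "TRUE")
  features <- df[complete, setdiff(names(df), c("complete", "drop_reason")),
    drop = FALSE]
  rownames(features) <- NULL
  dropped <- data.frame(
    species = df$species[!complete],
    reason = df$drop_reason[!complete],
    stringsAsFactors = FALSE
  )
  structure(list(features = features, dropped = dropped), class = "feature_set")
}

#' Save a trained network as a JSON checkpoint
#'
#' A single portable text file: the specification, class count, input width
#' and best epoch as a header, plus the full-precision weight matrices and
#' bias vectors per layer.
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  obj <- list(
    spec = unclass(model$spec),
    n_classes = model$n_classes,
    n_in = model$n_in,
    best_epoch = model$best_epoch,
    layers = lapply(model$params, function(p) {
      list(W = p$W, b = p$b, dim = dim(p$W))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained network from a JSON checkpoint
#'
#' @param path Checkpoint path written by [write_model()].
#' @return A `trained_model` (without the training history).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- obj$spec
  spec$hidden <- as.numeric(spec$hidden)
  class(spec) <- "mlp_spec"
  params <- lapply(seq_along(obj$layers$W), function(l) {
    W <- obj$layers$W[[l]]
    d <- as.integer(obj$layers$dim[[l]])
    if (!is.matrix(W)) W <- matrix(unlist(W), d[1], d[2])
    list(W = W, b = as.numeric(obj$layers$b[[l]]))
  })
  structure(
    list(
      params = params, spec = spec, n_classes = obj$n_classes,
      n_in = obj$n_in, best_epoch = obj$best_epoch,
      history = data.frame(epoch = integer(0), train_loss = numeric(0),
        val_loss = numeric(0))
    ),
    class = "trained_model"
  )
}
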