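# Build a species universe whose per-category label and prediction counts
# are exactly as given (used for merged-table arithmetic checks).
mk_universe <- function(label_counts, pred_counts, n_total) {
  n_lab <- sum(label_counts)
  n_pred <- sum(pred_counts)
  stopifnot(n_lab + n_pred <= n_total)
  species <- sprintf("sp%05d", seq_len(n_total))
  labels <- data.frame(
    species = species[seq_len(n_lab)],
    category = rep(names(label_counts), label_counts),
    stringsAsFactors = FALSE
  )
  predictions <- data.frame(
    species = species[n_lab + seq_len(n_pred)],
    category = rep(names(pred_counts), pred_counts),
    stringsAsFactors = FALSE
  )
  list(species = species, labels = labels, predictions = predictions)
}
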