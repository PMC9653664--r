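# Independent oracles, deliberately written brute-force so they share no
# code path with the package implementations they check.

# AUC by enumerating every positive-negative pair (ties count 1/2).
oracle_auc_pairwise <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Micro-averaged metrics by explicitly building each one-vs-rest table.
oracle_micro <- function(y_true, y_pred, classes = 0:2) {
  tp <- tn <- fp <- fn <- 0
  for (k in classes) {
    for (i in seq_along(y_true)) {
      t_pos <- y_true[i] == k
      p_pos <- y_pred[i] == k
      if (t_pos && p_pos) tp <- tp + 1
      if (!t_pos && !p_pos) tn <- tn + 1
      if (!t_pos && p_pos) fp <- fp + 1
      if (t_pos && !p_pos) fn <- fn + 1
    }
  }
  c(micro_accuracy = 100 * (tp + tn) / (tp + tn + fn + fp),
    micro_sensitivity = 100 * tp / (tp + fn),
    micro_specificity = 100 * tn / (tn + fp))
}

# Small-dimension network configuration used by unit tests so that a
# forward/backward pass costs milliseconds; scientific behavior (not
# capacity) is what these tests probe.
tiny_hnn_config <- function(task, ...) {
  hnn_config(task = task, embedding_dim = 8L, max_len = 60L,
             conv_filters = 6L, conv_kernel = 3L, ffnn_hidden = c(12L, 6L),
             merge_hidden = 6L, dropout = 0, epochs = 10L, batch_size = 8L,
             ...)
}

# Standardize held-out rows with training statistics from
# standardize_features().
apply_standardization <- function(tab, std) {
  for (j in seq_along(tab)) {
    tab[[j]] <- if (std$scale[j] > 0)
      (tab[[j]] - std$center[j]) / std$scale[j] else 0
  }
  tab
}
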