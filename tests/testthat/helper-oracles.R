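# independent brute-force oracles used to cross-check the implementation

# Spearman via explicit rank-then-Pearson
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# confusion counts by enumerating every unordered gene pair
classify_oracle <- function(inf_edges, gold_edges, genes) {
  tp <- fp <- tn <- fn <- 0L
  key <- function(e) unique(paste(pmin(e$regulator, e$target),
                                  pmax(e$regulator, e$target)))
  gk <- key(gold_edges)
  ik <- key(inf_edges)
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    k <- paste(min(genes[i], genes[j]), max(genes[i], genes[j]))
    in_g <- k %in% gk
    in_i <- k %in% ik
    if (in_g && in_i) tp <- tp + 1L
    else if (!in_g && in_i) fp <- fp + 1L
    else if (in_g && !in_i) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# binomial coefficients from Pascal's triangle
choose_oracle <- function(n, k) {
  if (k > n) return(0)
  row <- 1
  for (i in seq_len(n)) row <- c(1, head(row, -1) + row[-1], 1)[seq_len(i + 1)]
  row[k + 1]
}

# random-guess probability by enumerating every draw of tp+fp edges
rgp_oracle <- function(n_true, n_false, tp, fp) {
  edges <- c(rep(TRUE, n_true), rep(FALSE, n_false))
  draws <- combn(length(edges), tp + fp)
  hits <- apply(draws, 2, function(idx) sum(edges[idx]) == tp)
  mean(hits)
}

# window pruning scan, reimplemented from the stated rule
prune_oracle <- function(windows) {
  rho <- vapply(windows, `[[`, 0, "mean_abs_rho")
  ids <- vapply(windows, `[[`, 0L, "id")
  kept <- list()
  covered <- character()
  for (w in windows[order(-rho, ids)]) {
    if (!all(w$genes %in% covered)) {
      kept <- c(kept, list(w))
      covered <- union(covered, w$genes)
    }
  }
  kept
}

# tiny dataset builder
mk_ds <- function(mat, times = seq_len(ncol(mat)) - 1, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  rownames(mat) <- genes
  grn_dataset(mat, times, genes)
}

edge_key_set <- function(edges) {
  sort(paste(edges$regulator, edges$target))
}
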