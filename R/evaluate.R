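#' Classify inferred edges against a gold standard
#'
#' Both edge sets are reduced to undirected gene pairs (presence or
#' absence of an edge between two genes, ignoring direction) and every one
#' of the N(N-1)/2 pairs over the union gene universe is counted as TP,
#' FP, TN or FN.
#'
#' @param inferred a [grn_network()] or a tibble with `regulator`/`target`
#'   columns.
#' @param gold a [gold_standard()].
#' @param directed if `TRUE`, classify directed gene pairs instead (not
#'   the scoring of record; kept for completeness).
#' @return a one-row tibble of class `grn_confusion` with columns `tp`,
#'   `fp`, `tn`, `fn`, `n_genes`, `n_pairs`.
#' @export
classify_edges <- function(inferred, gold, directed = FALSE) {
  stopifnot(inherits(gold, "grn_gold"))
  inf_edges <- if (inherits(inferred, "grn_network")) inferred$edges
               else tibble::as_tibble(inferred)
  inf_genes <- if (inherits(inferred, "grn_network")) inferred$genes
               else unique(c(inf_edges$regulator, inf_edges$target))
  genes <- sort(union(gold$genes, inf_genes))
  n <- length(genes)
  if (directed) {
    univ <- expand.grid(a = genes, b = genes, stringsAsFactors = FALSE)
    univ <- univ[univ$a != univ$b, ]
    key <- function(e) paste(e$regulator, e$target)
    all_keys <- paste(univ$a, univ$b)
    gold_keys <- key(gold$edges)
    inf_keys <- key(inf_edges)
  } else {
    all_keys <- if (n >= 2) {
      p <- combn(genes, 2)
      pair_key(p[1, ], p[2, ])
    } else character()
    gold_keys <- gold$pairs
    inf_keys <- unique(pair_key(inf_edges$regulator, inf_edges$target))
  }
  in_gold <- all_keys %in% gold_keys
  in_inf <- all_keys %in% inf_keys
  tibble::new_tibble(tibble::tibble(
    tp = sum(in_gold & in_inf), fp = sum(!in_gold & in_inf),
    tn = sum(!in_gold & !in_inf), fn = sum(in_gold & !in_inf),
    n_genes = n, n_pairs = length(all_keys)
  ), class = "grn_confusion")
}

#' Sensitivity, specificity and positive predictive value
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `ppv = TP/(TP+FP)`, as percentages. A zero denominator yields `NA`
#' (undefined). Values are exact; `display` carries the conventional
#' 2-decimal rounding.
#'
#' @param counts a `grn_confusion` row from [classify_edges()], or a list
#'   with `tp`, `fp`, `tn`, `fn`.
#' @return tibble with `metric`, `value` (exact percent) and `display`.
#' @export
performance_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv"),
    value = c(ratio(tp, tp + fn), ratio(tn, tn + fp), ratio(tp, tp + fp))
  )
  out$display <- round(out$value, 2)
  out
}

# exact integer binomial coefficient: multiply/divide stepwise so every
# intermediate is an exact integer (C(n,k) * (n-k+i) is divisible by i)
exact_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(0)
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) r <- (r * (n - k + i)) / i
  if (r > 2^53) stop("binomial coefficient exceeds exact integer range")
  r
}

#' Probability of a confusion outcome under random guessing
#'
#' The hypergeometric chance of drawing exactly `tp` true and `fp` false
#' edges when `tp + fp` edges are guessed uniformly at random from a
#' universe of `true_edges + false_edges` candidates:
#' `C(true_edges, tp) * C(false_edges, fp) / C(total, tp + fp)`. Computed
#' with exact integer arithmetic. The edge universe (directed or
#' undirected) is whatever the caller's counts refer to.
#'
#' @param true_edges number of true candidate edges in the universe.
#' @param false_edges number of false candidate edges in the universe.
#' @param tp correct edges drawn.
#' @param fp wrong edges drawn.
#' @return the probability.
#' @export
random_guess_probability <- function(true_edges, false_edges, tp, fp) {
  stopifnot(true_edges >= 0, false_edges >= 0)
  if (tp < 0 || fp < 0 || tp > true_edges || fp > false_edges)
    stop("invalid counts: need 0 <= tp <= true_edges, 0 <= fp <= false_edges")
  exact_choose(true_edges, tp) * exact_choose(false_edges, fp) /
    exact_choose(true_edges + false_edges, tp + fp)
}

#' Keep the top-k edges of a ranked list
#'
#' @param ranked tibble with `regulator`, `target` and `score` columns.
#' @param k number of edges to keep; ties straddling the cutoff are broken
#'   lexicographically by (regulator, target) for determinism.
#' @return the top-k rows.
#' @export
truncate_ranked_edges <- function(ranked, k) {
  ranked <- tibble::as_tibble(ranked)
  stopifnot(all(c("regulator", "target", "score") %in% names(ranked)))
  if (k > nrow(ranked)) {
    warning("k = ", k, " exceeds the ", nrow(ranked),
            "-edge list; returning all edges")
    k <- nrow(ranked)
  }
  if (k <= 0) return(ranked[0, ])
  ord <- order(-ranked$score, ranked$regulator, ranked$target)
  ranked[ord[seq_len(k)], ]
}

#' Evaluate an inferred network against a gold standard
#'
#' Convenience wrapper producing the confusion counts, the three
#' performance metrics and the random-guess probability of the observed
#' outcome over the undirected-pair universe.
#'
#' @inheritParams classify_edges
#' @return list with `counts`, `metrics`, and `random_guess` (the
#'   hypergeometric probability of the observed TP/FP split at the same
#'   number of guessed pairs).
#' @export
evaluate_network <- function(inferred, gold) {
  counts <- classify_edges(inferred, gold)
  pg <- if (counts$tp + counts$fp > 0)
    random_guess_probability(counts$tp + counts$fn,
                             counts$fp + counts$tn,
                             counts$tp, counts$fp)
  else NA_real_
  list(counts = counts, metrics = performance_metrics(counts),
       random_guess = pg)
}
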