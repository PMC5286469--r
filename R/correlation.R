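#' Spearman correlation matrix of a dataset
#'
#' Rank correlations between gene trajectories; with multiple series the
#' values are concatenated across series per gene before ranking (ties get
#' average ranks). Constant genes have zero rank variance; their
#' correlations are set to 0 with a warning.
#'
#' @param ds a [grn_dataset()] with at least 3 time points.
#' @return a symmetric gene-by-gene correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(ds) {
  stopifnot(inherits(ds, "grn_dataset"))
  if (length(ds$times) < 3) stop("at least 3 time points are required")
  x <- do.call(cbind, ds$series)
  const <- apply(x, 1, function(v) diff(range(v)) == 0)
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (any(const))
    warning("constant gene(s), correlations set to 0: ",
            paste(ds$genes[const], collapse = ", "))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  dimnames(rho) <- list(ds$genes, ds$genes)
  rho
}

# window bookkeeping ---------------------------------------------------------

#' Construct a three-gene window
#'
#' @param genes three distinct gene names.
#' @param corr correlation matrix (for the window's mean |rho|).
#' @param id window identifier.
#' @param new_gene the gene introduced by migration (`NA` for initial
#'   windows).
#' @param parent id of the window this one migrated from.
#' @return an object of class `grn_window`.
#' @export
new_window <- function(genes, corr, id = NA_integer_, new_gene = NA_character_,
                       parent = NA_integer_) {
  genes <- as.character(genes)
  stopifnot(length(genes) == 3, !anyDuplicated(genes))
  structure(list(genes = genes, new_gene = new_gene, id = id,
                 parent = parent,
                 mean_abs_rho = mean_abs_rho(genes, corr)),
            class = "grn_window")
}

mean_abs_rho <- function(genes, corr) {
  p <- combn(genes, 2)
  mean(abs(corr[cbind(p[1, ], p[2, ])]))
}

#' Canonical key of a window's unordered gene triple
#' @param genes gene names.
#' @return sorted genes joined by "|".
#' @export
window_key <- function(genes) paste(sort(genes), collapse = "|")

#' @export
print.grn_window <- function(x, ...) {
  cat("<grn_window #", x$id, "> {", paste(x$genes, collapse = ", "), "}",
      if (!is.na(x$new_gene)) paste0(" new: ", x$new_gene),
      sprintf("  mean |rho| = %.3f", x$mean_abs_rho), "\n", sep = "")
  invisible(x)
}

#' Seed the initial three-gene window(s)
#'
#' Every gene pair whose absolute Spearman correlation is within `tie_tol`
#' of the maximum seeds one window; each pair is completed by the outside
#' gene with the largest correlation to either member. Duplicate triples
#' are merged.
#'
#' @param corr correlation matrix from [spearman_matrix()].
#' @param tie_tol tolerance on |rho| for calling two pairs tied at the
#'   maximum.
#' @return list of window objects.
#' @export
select_initial_windows <- function(corr, tie_tol = 0.005) {
  genes <- rownames(corr)
  n <- length(genes)
  if (n < 3) stop("at least 3 genes required")
  a <- abs(corr)
  diag(a) <- -Inf
  top <- max(a)
  seeds <- which(a >= top - tie_tol & upper.tri(a), arr.ind = TRUE)
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  triples <- list()
  for (r in seq_len(nrow(seeds))) {
    i <- seeds[r, 1]; j <- seeds[r, 2]
    outside <- setdiff(seq_len(n), c(i, j))
    score <- pmax(a[outside, i], a[outside, j])
    third <- outside[which.max(score)]  # first index wins exact ties
    key <- window_key(genes[c(i, j, third)])
    if (!key %in% names(triples))
      triples[[key]] <- genes[c(i, j, third)]
  }
  purrr::imap(unname(triples), function(g, k)
    new_window(g, corr, id = k))
}

#' Migrate a window by the one-gene-in one-gene-out rule
#'
#' The outside gene with the highest |rho| to any window gene comes in and
#' the window gene least correlated with it leaves. If the resulting triple
#' was already visited, the next-ranked outside gene is tried, walking down
#' the correlation ranking. Returns `NULL` when every candidate migration
#' would revisit an old window (exhaustion).
#'
#' @param w a window object.
#' @param corr correlation matrix.
#' @param visited character vector of visited window keys (sorted triples
#'   joined by "|").
#' @param id id to assign to the migrated window.
#' @return a new window, or `NULL` on exhaustion.
#' @export
migrate_window <- function(w, corr, visited, id = NA_integer_) {
  genes <- rownames(corr)
  a <- abs(corr)
  outside <- setdiff(genes, w$genes)
  if (!length(outside)) return(NULL)
  best_in <- apply(a[outside, w$genes, drop = FALSE], 1, max)
  ranking <- outside[order(-best_in, outside)]
  for (g in ranking) {
    inside_rho <- a[w$genes, g]
    out_gene <- w$genes[order(inside_rho, w$genes)][1]
    triple <- c(setdiff(w$genes, out_gene), g)
    if (!window_key(triple) %in% visited)
      return(new_window(triple, corr, id = id, new_gene = g, parent = w$id))
  }
  NULL
}

#' Enumerate the full migration sequence and prune it
#'
#' Runs the initial-window seeding and the full one-in one-out migration
#' until exhaustion (lineages advance round-robin), then sorts all windows
#' by mean within-window |rho| (descending) and keeps a window iff it
#' contains at least one gene not present in any window kept so far. Used
#' for larger networks where the raw migration sequence is long.
#'
#' @inheritParams select_initial_windows
#' @param max_windows hard cap on generated windows.
#' @return the kept windows (in scan order), with the full generated
#'   sequence in attribute `"all_windows"`.
#' @export
enumerate_and_prune_windows <- function(corr, tie_tol = 0.005,
                                        max_windows = 5 * nrow(corr)) {
  seq_windows <- generate_window_sequence(corr, tie_tol, max_windows)
  rho <- vapply(seq_windows, `[[`, 0, "mean_abs_rho")
  ids <- vapply(seq_windows, `[[`, 0L, "id")
  ord <- order(-rho, ids)
  kept <- list()
  covered <- character()
  for (w in seq_windows[ord]) {
    if (!all(w$genes %in% covered)) {
      kept <- c(kept, list(w))
      covered <- union(covered, w$genes)
    }
  }
  attr(kept, "all_windows") <- seq_windows
  kept
}

# initial windows plus round-robin migration of every lineage to exhaustion
generate_window_sequence <- function(corr, tie_tol = 0.005,
                                     max_windows = 5 * nrow(corr)) {
  lineages <- select_initial_windows(corr, tie_tol)
  seq_windows <- lineages
  visited <- vapply(lineages, function(w) window_key(w$genes), "")
  active <- rep(TRUE, length(lineages))
  next_id <- length(lineages) + 1L
  while (any(active) && length(seq_windows) < max_windows) {
    for (l in which(active)) {
      if (length(seq_windows) >= max_windows) break
      nw <- migrate_window(lineages[[l]], corr, visited, id = next_id)
      if (is.null(nw)) {
        active[l] <- FALSE
      } else {
        next_id <- next_id + 1L
        visited <- c(visited, window_key(nw$genes))
        seq_windows <- c(seq_windows, list(nw))
        lineages[[l]] <- nw
      }
    }
  }
  seq_windows
}
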