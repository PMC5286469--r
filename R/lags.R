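#' Estimate a gene's activation lag
#'
#' The lag is the earliest time point after which expression increases (or
#' decreases) for at least two consecutive time steps, each step changing
#' by more than `delta` times the trajectory's range. A trajectory that
#' satisfies the condition at the first time point has lag 0; one that
#' never satisfies it has no activation (`NA`).
#'
#' @param values expression trajectory (unit-max scale recommended).
#' @param times time points in hours; at least 3.
#' @param delta relative change threshold, as a fraction of the
#'   trajectory's range.
#' @return the lag in hours, or `NA_real_` for no activation. The direction
#'   of the first sustained change ("up"/"down") is attached as attribute
#'   `"direction"`.
#' @export
estimate_lag <- function(values, times, delta = 0.05) {
  if (length(values) < 3) stop("at least 3 time points are required")
  stopifnot(length(values) == length(times))
  rng <- diff(range(values))
  if (rng == 0) return(structure(NA_real_, direction = NA_character_))
  thr <- delta * rng
  d <- diff(values)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] > thr && d[i + 1] > thr)
      return(structure(times[i], direction = "up"))
    if (d[i] < -thr && d[i + 1] < -thr)
      return(structure(times[i], direction = "down"))
  }
  structure(NA_real_, direction = NA_character_)
}

#' Per-gene lag profile of a dataset
#'
#' With multiple perturbation series, a gene's lag is the earliest lag over
#' the series in which it activates (a perturbation may reach some genes
#' only).
#'
#' @param ds a [grn_dataset()].
#' @inheritParams estimate_lag
#' @return tibble with columns `gene`, `lag` (hours, `NA` = no activation)
#'   and `direction`.
#' @export
lag_profile <- function(ds, delta = 0.05) {
  stopifnot(inherits(ds, "grn_dataset"))
  rows <- lapply(ds$genes, function(g) {
    per_series <- lapply(ds$series, function(m)
      estimate_lag(m[g, ], ds$times, delta))
    lags <- vapply(per_series, as.numeric, 0)
    if (all(is.na(lags)))
      return(tibble::tibble(gene = g, lag = NA_real_,
                            direction = NA_character_))
    i <- which.min(lags)
    tibble::tibble(gene = g, lag = lags[i],
                   direction = attr(per_series[[i]], "direction"))
  })
  dplyr::bind_rows(rows)
}

#' Lag-based hierarchy constraints for a window
#'
#' A regulator must activate no later than its target: the ordered pair
#' (g_i -> g_j) is allowed iff `lag(g_i) + min_gap <= lag(g_j)` (strict
#' inequality when `min_gap = 0`). Genes with no activation can only be
#' targets. When no pair is allowed, the window has no usable lag
#' differences and the full unconstrained order is returned with
#' `no_lag_difference = TRUE`, so the top gene is chosen by fit quality
#' instead.
#'
#' @param lags a [lag_profile()] tibble or a named numeric vector of lags.
#' @param genes the window's gene triple (any length >= 2 accepted).
#' @param min_gap minimum lag difference in hours; 0 means lags must simply
#'   differ.
#' @return list with `allowed` (tibble of `regulator`, `target`),
#'   `no_lag_difference` flag and the window `lags` used.
#' @export
hierarchy_constraints <- function(lags, genes, min_gap = 0) {
  lv <- lag_lookup(lags, genes)
  ord <- lv
  ord[is.na(ord)] <- Inf
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  ok <- if (min_gap > 0) {
    ord[pairs$regulator] + min_gap <= ord[pairs$target]
  } else {
    ord[pairs$regulator] < ord[pairs$target]
  }
  ok <- ok & is.finite(ord[pairs$regulator])
  allowed <- tibble::as_tibble(pairs[ok, ])
  if (!nrow(allowed)) {
    list(allowed = tibble::as_tibble(pairs), no_lag_difference = TRUE,
         lags = lv)
  } else {
    list(allowed = allowed, no_lag_difference = FALSE, lags = lv)
  }
}

lag_lookup <- function(lags, genes) {
  if (is.data.frame(lags)) {
    lv <- setNames(lags$lag, lags$gene)[genes]
  } else {
    lv <- lags[genes]
  }
  if (anyNA(names(lv)) || length(lv) != length(genes))
    stop("lags missing for some window genes")
  setNames(as.numeric(lv), genes)
}
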