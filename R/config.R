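#' Run configuration
#'
#' Collects every tunable threshold of the inference pipeline with its
#' default. The resolved configuration is echoed into all outputs so runs
#' are reproducible.
#'
#' @param tie_tol tolerance on |rho| for tied maximum-correlation pairs
#'   when seeding initial windows.
#' @param lag_delta relative change threshold for lag calling, as a
#'   fraction of each trajectory's range.
#' @param min_gap minimum lag difference (hours) for a regulator-target
#'   ordering; 0 means lags must simply differ.
#' @param delta_bic_min BIC margin by which the winning structure must
#'   undercut the null model before its new edges are accepted. The
#'   default 2 is the usual "positive evidence" BIC threshold: a
#'   regulator-target edge spends one parameter fewer than the null's
#'   free-input description of the target, so accepting on any strict
#'   improvement would admit every wrong edge whose misfit stays under one
#'   parameter's worth of BIC.
#' @param min_rate accepted new edges with a fitted |rate| below this
#'   (hr^-1) are dropped as kinetically negligible (multi-edge structures
#'   otherwise carry along zero-rate edges).
#' @param tau_min floor on the pooled residual standard deviation used in
#'   the BIC (unit-max scale).
#' @param n_starts number of multi-start initializations per model fit:
#'   one data-driven start plus `n_starts - 1` seeded jitters.
#' @param maxiter,ftol,ptol Levenberg-Marquardt controls.
#' @param sse_early_stop stop multi-starting once a fit reaches this
#'   aggregate SSE (an essentially perfect fit).
#' @param prune_threshold gene count at or above which the window sequence
#'   is enumerated and pruned up front.
#' @param max_windows_factor hard cap on windows = factor * gene count.
#' @param joint_series fit multiple perturbation series jointly with shared
#'   parameters (`TRUE`, default) or with per-series parameter sets.
#' @param structures candidate structure families to test.
#' @param refit_inherited refit rates of inherited edges in later windows
#'   (`TRUE`, default) or freeze them at their previous estimates.
#' @param h0,h_growth,h_max integrator step controls (initial step, growth
#'   per step, maximum step in hours).
#' @param nonneg clamp simulated expression at zero (expression is
#'   nonnegative; removal constants otherwise drag unexpressed genes below
#'   zero before their regulator rises).
#' @param seed integer seed for all stochastic steps (multi-start jitter).
#' @return an object of class `grn_config` (a named list).
#' @export
grn_config <- function(tie_tol = 0.005, lag_delta = 0.05, min_gap = 0,
                       delta_bic_min = 2, min_rate = 0.005,
                       tau_min = 1e-3, n_starts = 5,
                       maxiter = 25, ftol = 1e-8, ptol = 1e-8,
                       sse_early_stop = 1e-10, prune_threshold = 10,
                       max_windows_factor = 5, joint_series = TRUE,
                       structures = c("single", "parallel", "serial", "convergent"),
                       refit_inherited = TRUE,
                       h0 = 0.05, h_growth = 1.05, h_max = 6,
                       nonneg = TRUE, seed = 1L) {
  stopifnot(tie_tol >= 0, lag_delta >= 0, min_gap >= 0, tau_min > 0,
            n_starts >= 1, maxiter >= 1, prune_threshold >= 3,
            max_windows_factor >= 1, h0 > 0, h_growth >= 1, h_max > 0)
  structure(list(
    tie_tol = tie_tol, lag_delta = lag_delta, min_gap = min_gap,
    delta_bic_min = delta_bic_min, min_rate = min_rate,
    tau_min = tau_min, n_starts = n_starts,
    maxiter = maxiter, ftol = ftol, ptol = ptol,
    sse_early_stop = sse_early_stop, prune_threshold = prune_threshold,
    max_windows_factor = max_windows_factor, joint_series = joint_series,
    structures = structures, refit_inherited = refit_inherited,
    h0 = h0, h_growth = h_growth, h_max = h_max, nonneg = nonneg,
    seed = as.integer(seed)
  ), class = "grn_config")
}

#' @export
print.grn_config <- function(x, ...) {
  cat("<grn_config>\n")
  for (nm in names(x))
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# evaluate expr with a private RNG stream, leaving the caller's RNG alone
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# small deterministic seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) %% 104729) %% 2147483629
  as.integer(s) + 1L
}
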