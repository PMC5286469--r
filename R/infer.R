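#' Infer a gene regulatory network from time-series expression data
#'
#' Runs the full sliding-window pipeline: seed initial window(s) from the
#' top Spearman-correlated gene pair(s), infer the best regulatory
#' structure within each window by SSE fitting and BIC selection (with lag
#' analysis ordering regulators before targets), then migrate windows by
#' the one-gene-in one-gene-out rule, carrying previously inferred edges,
#' until every gene has been covered by a window. For `prune_threshold` or
#' more genes the full migration sequence is enumerated and pruned up
#' front and windows are processed in decreasing mean within-window |rho|.
#' The result is a sparse directed network annotated with kinetic rates,
#' external inputs, and activation-time zones.
#'
#' @param ds a [grn_dataset()] with at least 3 genes; normalized to unit
#'   max internally (idempotent).
#' @param config a [grn_config()].
#' @return a [grn_network()]; `$trace` holds the per-window inference
#'   trace (candidate BIC tables and decisions) and `$config` echoes the
#'   resolved configuration.
#' @export
infer_network <- function(ds, config = grn_config()) {
  stopifnot(inherits(ds, "grn_dataset"))
  if (length(ds$genes) < 3) stop("at least 3 genes required")
  ds <- suppressWarnings(normalize_unit_max(ds))
  corr <- spearman_matrix(ds)
  lags <- lag_profile(ds, config$lag_delta)

  a <- abs(corr); diag(a) <- 0
  unreachable <- rownames(corr)[apply(a, 1, max) == 0]
  keep <- setdiff(ds$genes, unreachable)
  if (length(unreachable))
    warning("gene(s) with no correlation to any other gene excluded: ",
            paste(unreachable, collapse = ", "))
  if (length(keep) < 3) stop("fewer than 3 connectable genes")
  corr_k <- corr[keep, keep]

  state <- new.env(parent = emptyenv())
  state$edges <- empty_edges()
  state$inputs <- list()
  state$trace <- list()

  max_windows <- config$max_windows_factor * length(keep)
  if (length(keep) >= config$prune_threshold) {
    kept <- enumerate_and_prune_windows(corr_k, config$tie_tol, max_windows)
    for (w in kept)
      process_window(w, ds, lags, config, state)
    termination <- "pruned window list processed"
  } else {
    lineages <- select_initial_windows(corr_k, config$tie_tol)
    visited <- vapply(lineages, function(w) window_key(w$genes), "")
    for (w in lineages) process_window(w, ds, lags, config, state)
    covered <- unique(unlist(lapply(lineages, `[[`, "genes")))
    active <- rep(TRUE, length(lineages))
    next_id <- length(lineages) + 1L
    n_windows <- length(lineages)
    # lineages advance round-robin until no lineage can reach an unvisited
    # triple (exhaustion); coverage is tracked for the trace
    termination <- "migration exhausted"
    while (any(active)) {
      if (n_windows >= max_windows) {
        termination <- "window cap reached"; break
      }
      for (l in which(active)) {
        nw <- migrate_window(lineages[[l]], corr_k, visited, id = next_id)
        if (is.null(nw)) { active[l] <- FALSE; next }
        next_id <- next_id + 1L
        n_windows <- n_windows + 1L
        visited <- c(visited, window_key(nw$genes))
        lineages[[l]] <- nw
        process_window(nw, ds, lags, config, state)
        covered <- union(covered, nw$genes)
        if (n_windows >= max_windows) break
      }
    }
    if (!all(keep %in% covered))
      warning("migration exhausted before covering: ",
              paste(setdiff(keep, covered), collapse = ", "))
  }

  edges <- state$edges
  regulated <- unique(edges$target)
  root_genes <- setdiff(keep, regulated)
  inputs <- dplyr::bind_rows(lapply(root_genes, function(g) {
    rec <- state$inputs[[g]]
    if (is.null(rec))
      rec <- tibble::tibble(gene = g, type = "constant", level = NA_real_,
                            u_max = NA_real_, t_half = NA_real_,
                            theta = NA_real_)
    rec
  }))
  trace <- dplyr::bind_rows(state$trace)
  attr(trace, "termination") <- termination
  attr(trace, "unreachable") <- unreachable
  net <- grn_network(keep, edges, inputs, activation = NULL,
                     config = config, trace = trace)
  assign_activation_zones(net, lags)
}

# fit and select the regulatory relationship for one window, updating the
# accumulated network state
process_window <- function(w, ds, lags, config, state) {
  genes <- w$genes
  seed_w <- derive_seed(config$seed, w$id, sum(utf8ToInt(window_key(genes))))
  constraints <- hierarchy_constraints(lags, genes, config$min_gap)

  acc <- state$edges
  inherited <- acc[acc$regulator %in% genes & acc$target %in% genes,
                   c("regulator", "target", "rate")]
  exo <- acc[!acc$regulator %in% genes & acc$target %in% genes,
             c("regulator", "target")]

  top <- NULL
  top_sse <- NULL
  if (is.na(w$new_gene)) {
    lv <- constraints$lags
    if (constraints$no_lag_difference) {
      sel_top <- select_top_gene(genes, ds, config, seed_w)
      top <- sel_top$gene; top_sse <- sel_top$sse
    } else {
      ordv <- ifelse(is.na(lv), Inf, lv)
      tied <- genes[ordv == min(ordv)]
      if (length(tied) > 1) {
        sel_top <- select_top_gene(sort(tied), ds, config, seed_w)
        top <- sel_top$gene; top_sse <- sel_top$sse
      } else top <- tied
    }
  }

  models <- build_candidate_models(w, constraints, top_gene = top,
                                   inherited = inherited, exo = exo,
                                   config = config)
  # drop candidates whose new edges would close a cycle in the accumulated
  # network
  models <- Filter(function(m) {
    ne <- m$edges[m$edges$new, , drop = FALSE]
    if (!nrow(ne)) return(TRUE)
    all_edges <- rbind(acc[, c("regulator", "target")],
                       ne[, c("regulator", "target")])
    !has_cycle(all_edges, unique(c(all_edges$regulator, all_edges$target)))
  }, models)

  fits <- lapply(models, fit_model, ds = ds, config = config, tau = NULL,
                 seed = seed_w)
  tau <- estimate_tau(fits, config)
  fits <- lapply(fits, set_fit_tau, tau = tau)
  sel <- select_relationship(fits, config$delta_bic_min)

  kept_edges <- sel$new_edges[abs(sel$new_edges$rate) >= config$min_rate, ]
  if (sel$accepted && nrow(kept_edges)) {
    state$edges <- dplyr::bind_rows(
      state$edges,
      tibble::tibble(regulator = kept_edges$regulator,
                     target = kept_edges$target,
                     sign = kept_edges$sign,
                     rate = kept_edges$rate,
                     window = as.integer(w$id),
                     delta_bic = sel$delta_bic))
  }
  record_inputs(sel$fit, state)

  state$trace <- c(state$trace, list(tibble::tibble(
    window = as.integer(w$id),
    genes = paste(genes, collapse = ","),
    new_gene = w$new_gene,
    mean_abs_rho = w$mean_abs_rho,
    top_gene = if (is.null(top)) NA_character_ else top,
    no_lag_difference = constraints$no_lag_difference,
    tau = as.numeric(tau),
    chosen = sel$fit$model$name,
    accepted = sel$accepted,
    n_new_edges = nrow(kept_edges) * sel$accepted,
    candidates = list(sel$table),
    new_edges = list(sel$new_edges),
    top_gene_sse = list(top_sse)
  )))
  invisible(sel)
}

# remember the fitted external input of every root gene the first time it
# is seen, for the final network document
record_inputs <- function(fit, state) {
  m <- fit$model
  for (g in m$roots) {
    if (!is.null(state$inputs[[g]])) next
    get_p <- function(nm) {
      v <- fit$params$estimate[match(sprintf("%s[%s]", nm, g),
                                     fit$params$name)]
      if (length(v)) v[1] else NA_real_
    }
    state$inputs[[g]] <- if (m$input_types[[g]] == "constant") {
      tibble::tibble(gene = g, type = "constant", level = get_p("U"),
                     u_max = NA_real_, t_half = NA_real_, theta = NA_real_)
    } else {
      tibble::tibble(gene = g, type = "sigmoid", level = NA_real_,
                     u_max = get_p("umax"), t_half = get_p("thalf"),
                     theta = get_p("theta"))
    }
  }
}

#' Group genes into activation-time zones
#'
#' A gene's activation time is its lag; genes are grouped into zones by
#' the distinct lag values in ascending order, and genes that never
#' activate go in a final zone of their own. Zone indices are
#' nondecreasing with activation time.
#'
#' @param net a [grn_network()].
#' @param lags a [lag_profile()] tibble or named lag vector for the same
#'   dataset.
#' @return the network with its `activation` tibble (`gene`,
#'   `activation_time`, `zone`) filled in.
#' @export
assign_activation_zones <- function(net, lags) {
  stopifnot(inherits(net, "grn_network"))
  lv <- lag_lookup(lags, net$genes)
  finite_vals <- sort(unique(lv[is.finite(lv)]))
  zone <- integer(length(lv))
  for (i in seq_along(lv)) {
    zone[i] <- if (is.finite(lv[i])) match(lv[i], finite_vals)
               else length(finite_vals) + 1L
  }
  if (!length(finite_vals)) zone[] <- 1L
  net$activation <- tibble::tibble(gene = net$genes,
                                   activation_time = unname(lv),
                                   zone = zone)
  net
}
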