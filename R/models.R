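#' @section Model form:
#' Every candidate structure is a linear ODE cascade. A root gene A driven
#' by an external input follows `dA/dt = U(t) - k_self * A`; a regulated
#' gene follows `d(target)/dt = sum_regulators k_reg * regulator
#' - k_self * target - removal`, with a constant removal term. Inputs are
#' either time-invariant constants or sigmoids
#' `U(t) = u_max / (1 + exp(-(t - t_half) / theta))` that delay onset.
#' @name ode-model-form
#' @keywords internal
NULL

new_grn_model <- function(name, structure, genes, edges = NULL, exo = NULL,
                          input_types = NULL, fixed_edges = NULL,
                          lags = NULL) {
  if (is.null(edges))
    edges <- tibble::tibble(regulator = character(), target = character(),
                            new = logical())
  edges <- tibble::as_tibble(edges)
  if (!"regulator" %in% names(edges))
    edges <- tibble::tibble(regulator = character(), target = character(),
                            new = logical())
  if (!"new" %in% names(edges)) edges$new <- TRUE
  if (is.null(exo))
    exo <- tibble::tibble(regulator = character(), target = character())
  if (is.null(fixed_edges))
    fixed_edges <- tibble::tibble(regulator = character(),
                                  target = character(), rate = numeric())
  regulated <- unique(c(edges$target, exo$target, fixed_edges$target))
  roots <- setdiff(genes, regulated)
  if (is.null(input_types)) input_types <- setNames(
    rep("constant", length(roots)), roots)
  structure(list(name = name, structure = structure, genes = genes,
                 edges = edges, exo = tibble::as_tibble(exo),
                 fixed_edges = tibble::as_tibble(fixed_edges),
                 roots = roots, input_types = input_types, lags = lags),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model> ", x$name, " on {", paste(x$genes, collapse = ", "),
      "}\n", sep = "")
  if (nrow(x$edges))
    cat("  edges: ", paste0(x$edges$regulator, "->", x$edges$target,
                            ifelse(x$edges$new, "*", ""), collapse = ", "),
        "  (* = new)\n", sep = "")
  if (nrow(x$exo))
    cat("  exogenous regulators: ",
        paste0(x$exo$regulator, "->", x$exo$target, collapse = ", "), "\n",
        sep = "")
  cat("  inputs: ", if (length(x$roots))
    paste0(x$roots, " (", x$input_types[x$roots], ")", collapse = ", ")
    else "none", "\n", sep = "")
  invisible(x)
}

# parameter template: one row per free parameter, in a fixed order
model_params <- function(model, t_max) {
  rows <- list()
  add <- function(name, lower, upper, start)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, lower = lower, upper = upper, start = start)
  e <- model$edges
  if (nrow(e)) for (i in seq_len(nrow(e)))
    add(sprintf("k[%s->%s]", e$regulator[i], e$target[i]), -10, 10, 0.1)
  x <- model$exo
  if (nrow(x)) for (i in seq_len(nrow(x)))
    add(sprintf("k[%s->%s]", x$regulator[i], x$target[i]), -10, 10, 0.1)
  for (g in model$genes)
    add(sprintf("kself[%s]", g), 0, 10, 0.1)
  regulated <- setdiff(model$genes, model$roots)
  for (g in regulated)
    add(sprintf("rem[%s]", g), 0, 10, 0.01)
  for (g in model$roots) {
    if (model$input_types[[g]] == "constant") {
      add(sprintf("U[%s]", g), 0, 10, 0.05)
    } else {
      lag <- if (!is.null(model$lags)) model$lags[[g]] else NA_real_
      add(sprintf("umax[%s]", g), 0, 10, 0.1)
      add(sprintf("thalf[%s]", g), 0, t_max,
          if (is.finite(lag) && lag > 0) lag else t_max / 6)
      add(sprintf("theta[%s]", g), 0.5, t_max / 4, 3)
    }
  }
  dplyr::bind_rows(rows)
}

p_total <- function(model, t_max = 672) nrow(model_params(model, t_max))

#' Simulate a candidate regulatory model
#'
#' Integrates the window's linear ODE cascade at the given parameter values
#' and returns expression at the requested times. Regulators outside the
#' window enter as fixed forcing trajectories interpolated from observed
#' data.
#'
#' @param model a model produced by [build_candidate_models()].
#' @param params named numeric vector matching the model's parameter
#'   template (see the `name` column of its fit's `tidy()` output).
#' @param x0 initial expression of the window genes (observed t = 0
#'   values).
#' @param times time points (hours) to report.
#' @param exo_data matrix of observed trajectories for exogenous
#'   regulators (rows named by gene), columns matching `exo_times`.
#' @param exo_times time points of `exo_data` columns.
#' @param control integrator controls (list with `h0`, `h_growth`,
#'   `h_max`).
#' @return matrix (genes x times) of simulated expression; rows carry
#'   `NA` if the integration diverged.
#' @export
simulate_model <- function(model, params, x0, times, exo_data = NULL,
                           exo_times = times, control = list()) {
  ctl <- utils::modifyList(list(h0 = 0.05, h_growth = 1.05, h_max = 6,
                                nonneg = TRUE), control)
  n <- length(model$genes)
  gidx <- setNames(seq_len(n), model$genes)
  K <- matrix(0, n, n)
  for (i in seq_len(nrow(model$edges)))
    K[gidx[[model$edges$regulator[i]]], gidx[[model$edges$target[i]]]] <-
      params[[sprintf("k[%s->%s]", model$edges$regulator[i],
                      model$edges$target[i])]]
  for (i in seq_len(nrow(model$fixed_edges)))
    K[gidx[[model$fixed_edges$regulator[i]]],
      gidx[[model$fixed_edges$target[i]]]] <- model$fixed_edges$rate[i]
  kself <- vapply(model$genes, function(g)
    params[[sprintf("kself[%s]", g)]], 0)
  removal <- vapply(model$genes, function(g) {
    nm <- sprintf("rem[%s]", g)
    if (nm %in% names(params)) params[[nm]] else 0
  }, 0)
  input_type <- integer(n)
  input_par <- matrix(0, n, 3)
  for (g in model$roots) {
    i <- gidx[[g]]
    if (model$input_types[[g]] == "constant") {
      input_type[i] <- 1L
      input_par[i, 1] <- params[[sprintf("U[%s]", g)]]
    } else {
      input_type[i] <- 2L
      input_par[i, ] <- c(params[[sprintf("umax[%s]", g)]],
                          params[[sprintf("thalf[%s]", g)]],
                          params[[sprintf("theta[%s]", g)]])
    }
  }
  exo_genes <- unique(model$exo$regulator)
  ne <- length(exo_genes)
  KE <- matrix(0, max(ne, 0), n)
  if (ne) {
    stopifnot(!is.null(exo_data), all(exo_genes %in% rownames(exo_data)))
    for (i in seq_len(nrow(model$exo)))
      KE[match(model$exo$regulator[i], exo_genes),
         gidx[[model$exo$target[i]]]] <-
        params[[sprintf("k[%s->%s]", model$exo$regulator[i],
                        model$exo$target[i])]]
    exo_m <- exo_data[exo_genes, , drop = FALSE]
  } else {
    exo_m <- matrix(0, 0, 0)
    exo_times <- numeric()
  }
  out <- ode_cascade_cpp(K, kself, removal, input_type, input_par,
                         KE, exo_m, exo_times, as.numeric(x0),
                         as.numeric(times), ctl$h0, ctl$h_growth,
                         ctl$h_max, ctl$nonneg)
  dimnames(out) <- list(model$genes, times)
  out
}

#' List the candidate structure library
#'
#' @return tibble naming each structure family, the new edges it
#'   introduces in a window with top gene A and remaining genes B, C, and
#'   its free-parameter count for a standard initial window with a
#'   constant input and 8 time points.
#' @export
list_structures <- function() {
  tibble::tibble(
    structure = c("parallel", "serial", "serial", "convergent", "null"),
    variant = c("A->B, A->C", "A->B->C", "A->C->B",
                "A->C<-B (two inputs)", "no new edges"),
    p_total = c(8L, 8L, 8L, 9L, 6L),
    note = c("fan-out from the top gene",
             "cascade through B", "cascade through C",
             "fan-in on the longest-lag gene",
             "guards against overfitting")
  )
}

#' Build the admissible candidate models for a window
#'
#' For an initial window the structure menu is the two single-edge
#' relationships, parallel fan-out, the two serial orders and convergent
#' fan-in, all rooted at the top gene and filtered by the lag hierarchy
#' constraints. For a migrated window, candidates are all acyclic
#' combinations of new edges incident to the incoming gene. Inherited
#' edges ride along in every candidate (rates refit by default), and the
#' null model (no new edges) is always appended. Roots whose lag is
#' positive additionally get a sigmoid-input variant of each candidate.
#'
#' @param window a window object (from [select_initial_windows()] or
#'   [migrate_window()]).
#' @param constraints output of [hierarchy_constraints()] for the window.
#' @param top_gene the top-of-hierarchy gene (initial windows only;
#'   ignored for migrated windows).
#' @param inherited tibble (`regulator`, `target`, optional `rate`) of
#'   previously inferred edges among window genes.
#' @param exo tibble of previously inferred regulators of window genes
#'   that lie outside the window.
#' @param config a [grn_config()].
#' @return named list of candidate models; the null model is always last.
#' @export
build_candidate_models <- function(window, constraints, top_gene = NULL,
                                   inherited = NULL, exo = NULL,
                                   config = grn_config()) {
  genes <- window$genes
  lags <- constraints$lags
  if (is.null(inherited))
    inherited <- tibble::tibble(regulator = character(),
                                target = character(), rate = numeric())
  inherited <- tibble::as_tibble(inherited)
  if (!"rate" %in% names(inherited)) inherited$rate <- NA_real_
  if (is.null(exo))
    exo <- tibble::tibble(regulator = character(), target = character())

  allowed_key <- paste(constraints$allowed$regulator,
                       constraints$allowed$target)
  inh_key <- paste(inherited$regulator, inherited$target)

  edge_sets <- list()
  if (is.na(window$new_gene)) {
    if (is.null(top_gene)) stop("top_gene required for an initial window")
    others <- sort(setdiff(genes, top_gene))
    x <- others[1]; y <- others[2]
    menu <- list()
    if ("single" %in% config$structures) {
      menu[[sprintf("single(%s>%s)", top_gene, x)]] <-
        rbind(c(top_gene, x))
      menu[[sprintf("single(%s>%s)", top_gene, y)]] <-
        rbind(c(top_gene, y))
    }
    if ("parallel" %in% config$structures)
      menu[["parallel"]] <- rbind(c(top_gene, x), c(top_gene, y))
    if ("serial" %in% config$structures) {
      menu[[sprintf("serial(%s>%s>%s)", top_gene, x, y)]] <-
        rbind(c(top_gene, x), c(x, y))
      menu[[sprintf("serial(%s>%s>%s)", top_gene, y, x)]] <-
        rbind(c(top_gene, y), c(y, x))
    }
    if ("convergent" %in% config$structures) {
      menu[[sprintf("convergent(sink=%s)", y)]] <-
        rbind(c(top_gene, y), c(x, y))
      menu[[sprintf("convergent(sink=%s)", x)]] <-
        rbind(c(top_gene, x), c(y, x))
    }
    for (nm in names(menu)) {
      m <- menu[[nm]]
      keys <- paste(m[, 1], m[, 2])
      if (!constraints$no_lag_difference &&
          !all(keys %in% c(allowed_key, inh_key))) next
      if (all(keys %in% inh_key)) next  # nothing new: same as null
      edge_sets[[nm]] <- tibble::tibble(regulator = m[, 1], target = m[, 2])
    }
  } else {
    ng <- window$new_gene
    retained <- setdiff(genes, ng)
    cand <- tibble::tibble(
      regulator = c(retained, rep(ng, length(retained))),
      target = c(rep(ng, length(retained)), retained))
    keys <- paste(cand$regulator, cand$target)
    keep <- !keys %in% inh_key &
      !rev_keys_in(cand, inh_key) &
      (constraints$no_lag_difference | keys %in% allowed_key)
    cand <- cand[keep, ]
    singles <- seq_len(nrow(cand))
    combos <- if (nrow(cand) >= 2) combn(singles, 2, simplify = FALSE)
              else list()
    sets <- c(as.list(singles), combos)
    for (idx in sets) {
      sub <- cand[idx, ]
      if (anyDuplicated(pair_key(sub$regulator, sub$target))) next
      all_e <- rbind(sub,
                     inherited[, c("regulator", "target")])
      if (has_cycle(all_e, genes)) next
      nm <- sprintf("edges(%s)", paste0(sub$regulator, "->", sub$target,
                                        collapse = ","))
      edge_sets[[nm]] <- sub
    }
  }

  exo_by_target <- exo[exo$target %in% genes, , drop = FALSE]
  mk <- function(nm, new_edges, input_types) {
    edges <- dplyr::bind_rows(
      if (!is.null(new_edges) && nrow(new_edges))
        tibble::tibble(regulator = new_edges$regulator,
                       target = new_edges$target, new = TRUE),
      if (nrow(inherited) && config$refit_inherited)
        tibble::tibble(regulator = inherited$regulator,
                       target = inherited$target, new = FALSE))
    fixed <- if (nrow(inherited) && !config$refit_inherited &&
                 all(is.finite(inherited$rate)))
      inherited[, c("regulator", "target", "rate")] else NULL
    new_grn_model(nm, structure_of(nm), genes, edges, exo_by_target,
                  input_types = input_types, fixed_edges = fixed,
                  lags = lags)
  }

  # input variants: all-constant, all-sigmoid, and (when they differ) the
  # mixed form with sigmoids on the lagged roots only; BIC arbitrates the
  # extra sigmoid parameters
  variants <- function(nm, new_edges) {
    probe <- mk(nm, new_edges, NULL)
    roots <- probe$roots
    lagged <- roots[vapply(roots, function(g)
      is.finite(lags[[g]]) && lags[[g]] > 0, TRUE)]
    out <- list()
    out[[nm]] <- mk(nm, new_edges,
                    setNames(rep("constant", length(roots)), roots))
    if (length(roots)) {
      out[[paste0(nm, "+sigmoidU")]] <- mk(
        paste0(nm, "+sigmoidU"), new_edges,
        setNames(rep("sigmoid", length(roots)), roots))
      if (length(lagged) && length(lagged) < length(roots)) {
        ty <- setNames(ifelse(roots %in% lagged, "sigmoid", "constant"),
                       roots)
        out[[paste0(nm, "+sigmoidUlag")]] <- mk(
          paste0(nm, "+sigmoidUlag"), new_edges, ty)
      }
    }
    out
  }

  models <- list()
  for (nm in names(edge_sets))
    models <- c(models, variants(nm, edge_sets[[nm]]))
  models <- c(models, variants("null", NULL))
  models
}

structure_of <- function(nm) {
  base <- sub("\\+sigmoidU(lag)?$", "", nm)
  if (base == "null") "null"
  else if (grepl("^parallel", base)) "parallel"
  else if (grepl("^serial", base)) "serial"
  else if (grepl("^convergent", base)) "convergent"
  else if (grepl("^single", base)) "single"
  else "custom"
}

rev_keys_in <- function(cand, keys) {
  paste(cand$target, cand$regulator) %in% keys
}

# cycle check on a small directed edge table restricted to `genes`
has_cycle <- function(edges, genes) {
  if (!nrow(edges)) return(FALSE)
  adj <- lapply(setNames(genes, genes), function(g)
    edges$target[edges$regulator == g])
  state <- setNames(rep(0L, length(genes)), genes)  # 0 new, 1 open, 2 done
  visit <- function(g) {
    if (state[[g]] == 1L) return(TRUE)
    if (state[[g]] == 2L) return(FALSE)
    state[[g]] <<- 1L
    for (h in adj[[g]]) if (h %in% genes && visit(h)) return(TRUE)
    state[[g]] <<- 2L
    FALSE
  }
  any(vapply(genes, visit, TRUE))
}
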