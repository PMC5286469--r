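ds_restrict <- function(ds, genes) {
  stopifnot(all(genes %in% ds$genes))
  list(obs = lapply(ds$series, function(m) m[genes, , drop = FALSE]),
       x0 = lapply(ds$series, function(m) m[genes, 1]),
       times = ds$times)
}

# multi-start initial values; start 1 is the template, the rest are seeded
# log-uniform jitters (every 3rd start flips regulation-rate signs so
# inhibitory optima are reachable)
make_starts <- function(par_tbl, n_starts, seed, t_max) {
  base <- setNames(par_tbl$start, par_tbl$name)
  if (n_starts == 1) return(list(base))
  with_local_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1) return(base)
      v <- base
      for (i in seq_along(v)) {
        nm <- par_tbl$name[i]
        if (grepl("^k\\[", nm)) {
          sgn <- if (s %% 3 == 0) -1 else 1
          v[i] <- sgn * 10^runif(1, -2, 0)
        } else if (grepl("^kself|^U\\[|^umax", nm)) {
          v[i] <- 10^runif(1, -2, 0)
        } else if (grepl("^rem", nm)) {
          v[i] <- runif(1, 0, 0.1)
        } else if (grepl("^thalf", nm)) {
          v[i] <- runif(1, 0, t_max / 2)
        } else if (grepl("^theta", nm)) {
          v[i] <- runif(1, 0.5, 10)
        }
      }
      pmin(pmax(v, par_tbl$lower), par_tbl$upper)
    })
  })
}

# seed sigmoid-input starts from the target's own trajectory: half-time at
# the observed onset, steepness from the onset sharpness (generic starts
# routinely miss sharp onsets, handicapping models that deserve to fit)
data_driven_starts <- function(model, par_tbl, dat) {
  sig_roots <- model$roots[model$input_types[model$roots] == "sigmoid"]
  for (g in sig_roots) {
    v <- do.call(pmax, lapply(dat$obs, function(m) m[g, ]))
    mx <- max(v)
    if (mx <= 0) next
    i_on <- which(v > 0.05 * mx)[1]
    if (is.na(i_on)) next
    t_pre <- if (i_on == 1) 0 else dat$times[i_on - 1]
    t_on <- max(dat$times[i_on], dat$times[2] / 2)
    par_tbl$start[par_tbl$name == sprintf("thalf[%s]", g)] <-
      (t_pre + t_on) / 2
    par_tbl$start[par_tbl$name == sprintf("theta[%s]", g)] <-
      max(0.5, (t_on - t_pre) / 4)
    par_tbl$start[par_tbl$name == sprintf("umax[%s]", g)] <- 0.1 * mx
  }
  par_tbl
}

# precompute integer index maps from the parameter vector into the
# integrator's argument matrices, so residual evaluations avoid name lookup
model_packer <- function(model, par_names) {
  n <- length(model$genes)
  gidx <- setNames(seq_len(n), model$genes)
  pidx <- function(nm) match(nm, par_names)
  e <- model$edges
  K_pos <- K_par <- integer(0)
  if (nrow(e)) {
    K_pos <- gidx[e$regulator] + (gidx[e$target] - 1L) * n
    K_par <- pidx(sprintf("k[%s->%s]", e$regulator, e$target))
  }
  f <- model$fixed_edges
  Kf_pos <- if (nrow(f)) gidx[f$regulator] + (gidx[f$target] - 1L) * n
            else integer(0)
  exo_genes <- unique(model$exo$regulator)
  ne <- length(exo_genes)
  KE_pos <- KE_par <- integer(0)
  if (ne) {
    KE_pos <- match(model$exo$regulator, exo_genes) +
      (gidx[model$exo$target] - 1L) * ne
    KE_par <- pidx(sprintf("k[%s->%s]", model$exo$regulator,
                           model$exo$target))
  }
  kself_par <- pidx(sprintf("kself[%s]", model$genes))
  regulated <- setdiff(model$genes, model$roots)
  rem_pos <- unname(gidx[regulated])
  rem_par <- pidx(sprintf("rem[%s]", regulated))
  input_type <- integer(n)
  ip_pos <- ip_par <- integer(0)
  for (g in model$roots) {
    i <- gidx[[g]]
    if (model$input_types[[g]] == "constant") {
      input_type[i] <- 1L
      ip_pos <- c(ip_pos, i)
      ip_par <- c(ip_par, pidx(sprintf("U[%s]", g)))
    } else {
      input_type[i] <- 2L
      ip_pos <- c(ip_pos, i, i + n, i + 2L * n)
      ip_par <- c(ip_par, pidx(sprintf("umax[%s]", g)),
                  pidx(sprintf("thalf[%s]", g)),
                  pidx(sprintf("theta[%s]", g)))
    }
  }
  list(n = n, K_pos = K_pos, K_par = K_par,
       Kf_pos = Kf_pos, Kf_val = f$rate,
       KE_pos = KE_pos, KE_par = KE_par, ne = ne, exo_genes = exo_genes,
       kself_par = kself_par, rem_pos = rem_pos, rem_par = rem_par,
       input_type = input_type, ip_pos = ip_pos, ip_par = ip_par)
}

pack_and_sim <- function(pk, par, x0, times, exo_m, exo_times, ctl,
                         input_type = pk$input_type) {
  n <- pk$n
  K <- matrix(0, n, n)
  K[pk$K_pos] <- par[pk$K_par]
  K[pk$Kf_pos] <- pk$Kf_val
  kself <- par[pk$kself_par]
  removal <- numeric(n)
  removal[pk$rem_pos] <- par[pk$rem_par]
  ip <- matrix(0, n, 3)
  ip[pk$ip_pos] <- par[pk$ip_par]
  KE <- matrix(0, pk$ne, n)
  KE[pk$KE_pos] <- par[pk$KE_par]
  ode_cascade_cpp(K, kself, removal, input_type, ip, KE,
                  exo_m, exo_times, x0, times,
                  ctl$h0, ctl$h_growth, ctl$h_max,
                  if (is.null(ctl$nonneg)) TRUE else ctl$nonneg)
}

#' Fit a candidate model to window data
#'
#' Bounded Levenberg-Marquardt least squares on the aggregate SSE of
#' simulated versus observed trajectories for all window genes, from a
#' seeded set of multi-start initializations (stopping early once an
#' essentially perfect fit is found). Multiple perturbation series are
#' fitted jointly with shared parameters by default; initial conditions are
#' the observed t = 0 values. Standard errors come from the
#' Jacobian-based covariance at the optimum.
#'
#' @param model a candidate model from [build_candidate_models()].
#' @param ds a [grn_dataset()] (the model's window genes must be present;
#'   exogenous regulators are taken from it as fixed forcing).
#' @param config a [grn_config()].
#' @param tau pooled residual SD used for the BIC (from
#'   [estimate_tau()]); if `NULL` the BIC is left `NA`.
#' @param seed seed for the multi-start jitter (defaults to the config
#'   seed).
#' @return an object of class `grn_fit`: parameter estimates with standard
#'   errors, per-gene and aggregate SSE, `p_total`, `n` and BIC. If no
#'   start converges the SSE and BIC are infinite.
#' @export
fit_model <- function(model, ds, config = grn_config(), tau = NULL,
                      seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!config$joint_series && length(ds$series) > 1)
    return(fit_per_series(model, ds, config, tau, seed))
  dat <- ds_restrict(ds, model$genes)
  t_max <- max(ds$times)
  ctl <- list(h0 = config$h0, h_growth = config$h_growth,
              h_max = config$h_max, nonneg = config$nonneg)
  par_tbl <- model_params(model, t_max)
  p <- nrow(par_tbl)
  n_obs <- n_obs_per_gene(ds)
  pk <- model_packer(model, par_tbl$name)
  # exogenous regulators force the window ODEs through a monotone spline of
  # their observed trajectories, evaluated on a fine grid (linear
  # interpolation of the sparse samples is too coarse next to an
  # integrated state)
  exo_times <- if (pk$ne) seq(dat$times[1], t_max, length.out = 337)
               else numeric()
  exo_list <- lapply(ds$series, function(m) {
    if (!pk$ne) return(matrix(0, 0, 0))
    t(vapply(pk$exo_genes, function(g)
      stats::splinefun(dat$times, m[g, ], method = "monoH.FC")(exo_times),
      numeric(length(exo_times))))
  })
  par_tbl <- data_driven_starts(model, par_tbl, dat)
  # perturbation series switch inputs on and off: a root gene that is
  # identically zero in a series has its external input inactive there
  type_by_series <- lapply(dat$obs, function(m) {
    ty <- pk$input_type
    for (g in model$roots) {
      i <- match(g, model$genes)
      if (all(m[g, ] <= 0)) ty[i] <- 0L
    }
    ty
  })

  sim_all <- function(par) {
    lapply(seq_along(dat$obs), function(s)
      pack_and_sim(pk, par, dat$x0[[s]], dat$times, exo_list[[s]],
                   exo_times, ctl, type_by_series[[s]]))
  }
  resid_fun <- function(par) {
    sims <- sim_all(par)
    r <- unlist(Map(function(sim, obs) as.vector(sim - obs),
                    sims, dat$obs), use.names = FALSE)
    r[!is.finite(r)] <- 1e6
    r
  }

  starts <- make_starts(par_tbl, config$n_starts,
                        derive_seed(seed, sum(utf8ToInt(model$name))), t_max)
  best <- NULL
  best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = par_tbl$lower, upper = par_tbl$upper,
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = config$maxiter, ftol = config$ftol,
          ptol = config$ptol))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
    if (best_sse < config$sse_early_stop) break
  }

  if (is.null(best)) {
    return(new_grn_fit(model, par_tbl, estimates = NULL, se = NULL,
                       sse_by_gene = setNames(rep(Inf, length(model$genes)),
                                              model$genes),
                       sse = Inf, tau = tau, n = n_obs, p = p,
                       bic = Inf, converged = FALSE, fitted = NULL))
  }
  est <- setNames(best$par, par_tbl$name)
  sims <- sim_all(est)
  sse_by_gene <- Reduce(`+`, Map(function(sim, obs)
    rowSums((sim - obs)^2), sims, dat$obs))
  sse <- sum(sse_by_gene)
  se <- tryCatch({
    n_res <- length(best$fvec)
    sigma2 <- if (n_res > p) sse / (n_res - p) else NA_real_
    sqrt(diag(sigma2 * solve(best$hessian)))
  }, error = function(e) rep(NA_real_, p))
  bic <- if (!is.null(tau) && is.finite(sse))
    bic_score(sse, tau, p, n_obs) else NA_real_
  new_grn_fit(model, par_tbl, estimates = est, se = se,
              sse_by_gene = sse_by_gene, sse = sse, tau = tau,
              n = n_obs, p = p, bic = bic,
              converged = best$info %in% 1:4, fitted = sims)
}

# independent parameter sets per series; SSEs summed, parameters counted
# per series
fit_per_series <- function(model, ds, config, tau, seed) {
  fits <- lapply(seq_along(ds$series), function(s) {
    ds1 <- grn_dataset(ds$series[[s]], ds$times, ds$genes,
                       ds$series_labels[s])
    fit_model(model, ds1, config, tau = NULL, seed = derive_seed(seed, s))
  })
  par_tbl <- dplyr::bind_rows(lapply(seq_along(fits), function(s) {
    tb <- fits[[s]]$params
    tb$name <- paste0(tb$name, "@", ds$series_labels[s])
    tb
  }))
  sse_by_gene <- Reduce(`+`, lapply(fits, `[[`, "sse_by_gene"))
  sse <- sum(sse_by_gene)
  p <- sum(vapply(fits, `[[`, 0L, "p_total"))
  n_obs <- n_obs_per_gene(ds)
  bic <- if (!is.null(tau) && is.finite(sse))
    bic_score(sse, tau, p, n_obs) else NA_real_
  new_grn_fit(model, NULL, estimates = setNames(par_tbl$estimate,
                                                par_tbl$name),
              se = par_tbl$se, sse_by_gene = sse_by_gene, sse = sse,
              tau = tau, n = n_obs, p = p, bic = bic,
              converged = all(vapply(fits, `[[`, TRUE, "converged")),
              fitted = lapply(fits, function(f) f$fitted[[1]]),
              params_tbl = par_tbl)
}

new_grn_fit <- function(model, par_tbl, estimates, se, sse_by_gene, sse,
                        tau, n, p, bic, converged, fitted,
                        params_tbl = NULL) {
  params <- if (!is.null(params_tbl)) params_tbl
  else if (is.null(estimates)) {
    tibble::tibble(name = par_tbl$name, estimate = NA_real_,
                   se = NA_real_, lower = par_tbl$lower,
                   upper = par_tbl$upper)
  } else {
    tibble::tibble(name = par_tbl$name, estimate = unname(estimates),
                   se = unname(se), lower = par_tbl$lower,
                   upper = par_tbl$upper)
  }
  structure(list(model = model, params = params,
                 sse_by_gene = sse_by_gene, sse = sse,
                 tau = if (is.null(tau)) NA_real_ else tau,
                 n = n, p_total = p, bic = bic, converged = converged,
                 fitted = fitted),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("<grn_fit> ", x$model$name, ": SSE = ", signif(x$sse, 4),
      ", p = ", x$p_total, ", BIC = ", signif(x$bic, 6), "\n", sep = "")
  invisible(x)
}

#' @method tidy grn_fit
#' @export
tidy.grn_fit <- function(x, ...) x$params

#' @method glance grn_fit
#' @export
glance.grn_fit <- function(x, ...) {
  tibble::tibble(name = x$model$name, structure = x$model$structure,
                 sse = x$sse, p_total = x$p_total, n = x$n,
                 tau = x$tau, bic = x$bic, converged = x$converged)
}

#' @method autoplot grn_fit
#' @export
autoplot.grn_fit <- function(object, ds, ...) {
  stopifnot(!is.null(object$fitted))
  genes <- object$model$genes
  times <- ds$times
  obs <- purrr::map2_dfr(ds$series, ds$series_labels, function(m, lab)
    tibble::tibble(series = lab, gene = rep(genes, length(times)),
                   time = rep(times, each = length(genes)),
                   value = as.vector(m[genes, , drop = FALSE]),
                   kind = "observed"))
  fit <- purrr::map2_dfr(object$fitted, ds$series_labels, function(m, lab)
    tibble::tibble(series = lab, gene = rep(genes, length(times)),
                   time = rep(times, each = length(genes)),
                   value = as.vector(m), kind = "fitted"))
  ggplot2::ggplot(dplyr::bind_rows(obs, fit),
                  ggplot2::aes(.data$time, .data$value,
                               colour = .data$gene,
                               linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series) +
    ggplot2::labs(x = "time (h)", y = "expression",
                  title = object$model$name)
}

#' SSE-based Bayesian information criterion
#'
#' `BIC = aggregate SSE / tau + p_total * ln(n)`, the selection score used
#' to compare candidate structures within a window. All candidates in a
#' window share the same `tau` so their scores are on one scale.
#'
#' @param sse aggregate sum of squared errors over the window genes.
#' @param tau pooled residual standard deviation (> 0).
#' @param p_total total number of free parameters in the model.
#' @param n number of time points per gene (pooled over series).
#' @return the BIC value.
#' @export
bic_score <- function(sse, tau, p_total, n) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  stopifnot(n >= 2, p_total >= 0, sse >= 0)
  sse / tau + p_total * log(n)
}

single_gene_model <- function(gene, input_type = "constant", lag = NA_real_) {
  new_grn_model(sprintf("single(%s,%s)", gene, input_type), "single",
                genes = gene,
                input_types = setNames(input_type, gene),
                lags = setNames(lag, gene))
}

#' Pooled residual SD for a window
#'
#' The error scale used in the window's BIC: the residual standard
#' deviation pooled across the window genes, taken from the best-fitting
#' candidate (the candidate that tracks the data most closely gives the
#' least upward-biased estimate of the measurement error), and floored at
#' `config$tau_min` so noiseless data cannot collapse the scale to zero.
#' The same tau is shared by every candidate in the window so BIC
#' comparisons are on one scale, and it is invariant to gene ordering.
#'
#' @param fits list of `grn_fit` candidates for one window.
#' @param config a [grn_config()].
#' @return tau (scalar).
#' @export
estimate_tau <- function(fits, config = grn_config()) {
  sses <- vapply(fits, `[[`, 0, "sse")
  ok <- is.finite(sses)
  if (!any(ok)) return(config$tau_min)
  i <- which(ok)[which.min(sses[ok])]
  n_res <- fits[[i]]$n * length(fits[[i]]$model$genes)
  max(sqrt(sses[i] / n_res), config$tau_min)
}

# recompute the BIC of a fit under a window-level tau
set_fit_tau <- function(fit, tau) {
  fit$tau <- as.numeric(tau)
  fit$bic <- if (is.finite(fit$sse))
    bic_score(fit$sse, fit$tau, fit$p_total, fit$n) else Inf
  fit
}

#' Choose the top-of-hierarchy gene by fit quality
#'
#' Used when lag analysis finds no usable lag differences in a window:
#' each gene is fitted with the single-gene model driven by a
#' time-invariant input, and the gene with the smallest SSE takes the top
#' position. Exact ties are broken lexicographically with a warning.
#'
#' @param genes the window's gene triple.
#' @param ds a [grn_dataset()].
#' @param config a [grn_config()].
#' @param seed multi-start seed.
#' @return list with `gene` (the winner) and `sse` (named per-gene SSEs).
#' @export
select_top_gene <- function(genes, ds, config = grn_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  sses <- vapply(genes, function(g) {
    fit <- fit_model(single_gene_model(g, "constant"), ds, config,
                     seed = derive_seed(seed, sum(utf8ToInt(g))))
    fit$sse
  }, 0)
  best <- min(sses)
  tied <- sort(genes[sses <= best + 1e-12])
  if (length(tied) > 1)
    warning("top-gene tie between ", paste(tied, collapse = ", "),
            "; choosing ", tied[1], " lexicographically")
  list(gene = tied[1], sse = sses)
}

#' Select the optimal regulatory relationship in a window
#'
#' Chooses the minimal-BIC candidate. New edges are accepted only if the
#' winner undercuts the best null-model BIC by more than `delta_bic_min`;
#' otherwise the null outcome (no new edges) is returned. Exact ties are
#' broken by fewer parameters, then by structure name, so selection is
#' invariant to candidate ordering.
#'
#' @param fits named list of `grn_fit` objects including at least one null
#'   model.
#' @param delta_bic_min required BIC improvement over null (default 0:
#'   strict improvement suffices).
#' @return list with `fit` (the chosen fit), `accepted` (were new edges
#'   accepted), `new_edges` (tibble `regulator`, `target`, `rate`, `sign`)
#'   and `table` (per-candidate comparison mirroring the window's BIC
#'   table).
#' @export
select_relationship <- function(fits, delta_bic_min = 0) {
  stopifnot(length(fits) >= 1)
  tab <- dplyr::bind_rows(lapply(fits, glance))
  nulls <- tab$structure == "null"
  if (!any(nulls)) stop("candidate list must include the null model")
  ord <- order(tab$bic, tab$p_total, tab$name)
  if (all(!is.finite(tab$bic))) {
    warning("no candidate produced a finite BIC; returning null outcome")
    winner_i <- which(nulls)[1]
  } else {
    winner_i <- ord[1]
  }
  null_bic <- min(tab$bic[nulls])
  accepted <- !tab$structure[winner_i] == "null" &&
    is.finite(tab$bic[winner_i]) &&
    (null_bic - tab$bic[winner_i]) > delta_bic_min
  if (!accepted) {
    null_ord <- which(nulls)[order(tab$bic[nulls], tab$p_total[nulls],
                                   tab$name[nulls])]
    winner_i <- null_ord[1]
  }
  fit <- fits[[winner_i]]
  tab$chosen <- seq_len(nrow(tab)) == winner_i
  new_edges <- extract_new_edges(fit)
  list(fit = fit, accepted = accepted && nrow(new_edges) > 0,
       new_edges = new_edges, table = tab,
       delta_bic = null_bic - tab$bic[winner_i])
}

extract_new_edges <- function(fit) {
  e <- fit$model$edges
  e <- e[e$new, , drop = FALSE]
  if (!nrow(e))
    return(tibble::tibble(regulator = character(), target = character(),
                          rate = numeric(), sign = character()))
  rates <- vapply(seq_len(nrow(e)), function(i) {
    nm <- sprintf("k[%s->%s]", e$regulator[i], e$target[i])
    idx <- which(fit$params$name == nm)
    if (!length(idx))  # per-series fits carry an @series suffix
      idx <- which(startsWith(fit$params$name, paste0(nm, "@")))
    if (length(idx)) mean(fit$params$estimate[idx]) else NA_real_
  }, 0)
  tibble::tibble(regulator = e$regulator, target = e$target,
                 rate = rates, sign = ifelse(rates < 0, "-", "+"))
}
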