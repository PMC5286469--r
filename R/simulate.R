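#' Simulation scenario for a ground-truth cascade network
#'
#' Bundles everything needed to generate a benchmark dataset: an acyclic
#' signed rate matrix, self-degradation and removal constants, external
#' inputs on root genes, the sampling grid, the noise level and which
#' inputs are active in each perturbation series.
#'
#' @param name scenario label.
#' @param genes gene identifiers.
#' @param edges tibble `regulator`, `target`, `rate` (hr^-1; negative =
#'   inhibitory).
#' @param kself named self-degradation rates (hr^-1), one per gene.
#' @param removal named constant removal terms for regulated genes
#'   (defaults to 0).
#' @param inputs tibble `gene`, `type` ("constant"/"sigmoid"), `level`,
#'   `u_max`, `t_half`, `theta`; one row per root gene.
#' @param times sampling grid in hours.
#' @param noise_sd additive Gaussian noise SD on the unit-max scale.
#' @param series_inputs list of character vectors: the input genes active
#'   in each perturbation series.
#' @param resolution measurement resolution on the unit-max scale: sampled
#'   values are rounded to this grid (sub-resolution expression reads as
#'   zero, as on a real array).
#' @param seed default RNG seed for [generate_time_series()].
#' @return an object of class `grn_scenario`.
#' @export
grn_scenario <- function(name, genes, edges, kself, removal = NULL,
                         inputs, times = c(0, 6, 12, 24, 48, 72, 96, 672),
                         noise_sd = 0, series_inputs = NULL,
                         resolution = 1e-6, seed = 1L) {
  genes <- as.character(genes)
  edges <- tibble::as_tibble(edges)
  if (has_cycle(edges, genes)) stop("scenario network must be acyclic")
  stopifnot(all(c(edges$regulator, edges$target) %in% genes),
            noise_sd >= 0, all(diff(times) > 0))
  if (is.null(removal)) removal <- setNames(rep(0, length(genes)), genes)
  if (is.null(series_inputs)) series_inputs <- list(inputs$gene)
  stopifnot(resolution > 0)
  structure(list(name = name, genes = genes, edges = edges,
                 kself = kself, removal = removal,
                 inputs = tibble::as_tibble(inputs), times = times,
                 noise_sd = noise_sd, series_inputs = series_inputs,
                 resolution = resolution, seed = as.integer(seed)),
            class = "grn_scenario")
}

#' @export
print.grn_scenario <- function(x, ...) {
  cat("<grn_scenario> '", x$name, "': ", length(x$genes), " genes, ",
      nrow(x$edges), " edges, ", length(x$series_inputs), " series, ",
      "noise SD ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Sample a random acyclic ground-truth network
#'
#' Draws a DAG with the requested edge count over a uniformly random
#' topological order. Rates are sampled from the range spanned by typical
#' fitted kinetic estimates on unit-max data (0.02-0.30 hr^-1), removal
#' constants as a fraction of each target's steady-state drive (so every
#' cascade gene activates, with a staggered delay), and every root gene
#' receives an external input (alternating constant and sigmoid, with
#' staggered onset times so activation zones are nontrivial).
#'
#' @param n_genes number of genes.
#' @param n_edges number of edges; at most `n_genes * (n_genes - 1) / 2`.
#' @param seed RNG seed (scenario is reproducible from it).
#' @param times sampling grid in hours.
#' @param noise_sd additive noise SD.
#' @param n_series number of perturbation series; root inputs are dealt
#'   round-robin across series.
#' @return a [grn_scenario()].
#' @export
sample_random_dag <- function(n_genes, n_edges, seed = 1L,
                              times = c(0, 6, 12, 24, 48, 72, 96, 672),
                              noise_sd = 0, n_series = 1L) {
  if (n_edges > n_genes * (n_genes - 1) / 2)
    stop("too many edges for an acyclic network of ", n_genes, " genes")
  if (n_genes < 2) stop("need at least 2 genes")
  genes <- sprintf("G%d", seq_len(n_genes))
  with_local_seed(derive_seed(seed, n_genes, n_edges), {
    topo <- sample(genes)
    pairs <- t(combn(seq_len(n_genes), 2))  # i < j in topo order
    pick <- sample(nrow(pairs), n_edges)
    edges <- tibble::tibble(
      regulator = topo[pairs[pick, 1]],
      target = topo[pairs[pick, 2]],
      rate = runif(n_edges, 0.02, 0.30))
    kself <- setNames(runif(n_genes, 0.02, 0.30), genes)
    roots <- setdiff(genes, edges$target)
    onset <- c(12, 24, 48)
    inputs <- dplyr::bind_rows(lapply(seq_along(roots), function(i) {
      if (i %% 2 == 1) {
        tibble::tibble(gene = roots[i], type = "constant",
                       level = runif(1, 0.04, 0.10), u_max = NA_real_,
                       t_half = NA_real_, theta = NA_real_)
      } else {
        tibble::tibble(gene = roots[i], type = "sigmoid", level = NA_real_,
                       u_max = runif(1, 0.04, 0.12),
                       t_half = onset[(i / 2 - 1) %% 3 + 1],
                       theta = runif(1, 2, 6))
      }
    }))
    # removal constants are a fraction of each target's steady-state drive
    # (walked in topological order), so every cascade gene activates, with
    # a delay set by the fraction
    steady <- setNames(numeric(n_genes), genes)
    removal <- setNames(numeric(n_genes), genes)
    for (g in topo) {
      inp <- 0
      i <- match(g, inputs$gene)
      if (!is.na(i)) inp <- if (inputs$type[i] == "constant")
        inputs$level[i] else inputs$u_max[i]
      drive <- sum(edges$rate[edges$target == g] *
                     steady[edges$regulator[edges$target == g]])
      if (!g %in% roots) removal[g] <- runif(1, 0.35, 0.8) * drive
      steady[g] <- max(0, (inp + drive - removal[g]) / kself[g])
    }
    series_inputs <- if (n_series <= 1) list(roots) else
      lapply(seq_len(n_series), function(s) {
        act <- roots[seq_along(roots) %% n_series == (s %% n_series)]
        if (!length(act)) roots else act
      })
    grn_scenario(sprintf("random%d-%d", n_genes, n_edges), genes, edges,
                 kself, removal, inputs, times, noise_sd,
                 series_inputs = series_inputs, seed = seed)
  })
}

#' Generate a noisy time-series dataset from a scenario
#'
#' Integrates the scenario's cascade ODEs (states clamped at zero:
#' expression is nonnegative) from a zero initial state for each
#' perturbation series (a series switches on a subset of the root inputs),
#' samples the time grid, adds iid Gaussian noise, clips at 0, normalizes
#' each gene to unit max and rounds to the measurement resolution. The
#' matching gold standard is returned alongside.
#'
#' @param scn a [grn_scenario()].
#' @param seed RNG seed for the noise; defaults to the scenario's seed.
#' @return list with `dataset` (a [grn_dataset()]), `gold` (a
#'   [gold_standard()]), `scenario`, and `scale` (the per-gene maxima
#'   divided out by normalization, needed to put fitted rates back on the
#'   generating scale).
#' @export
generate_time_series <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "grn_scenario"))
  if (is.null(seed)) seed <- scn$seed
  n <- length(scn$genes)
  gidx <- setNames(seq_len(n), scn$genes)
  K <- matrix(0, n, n)
  for (i in seq_len(nrow(scn$edges)))
    K[gidx[[scn$edges$regulator[i]]], gidx[[scn$edges$target[i]]]] <-
      scn$edges$rate[i]
  kself <- as.numeric(scn$kself[scn$genes])
  removal <- as.numeric(scn$removal[scn$genes])

  series <- lapply(scn$series_inputs, function(active) {
    input_type <- integer(n)
    input_par <- matrix(0, n, 3)
    for (i in seq_len(nrow(scn$inputs))) {
      g <- scn$inputs$gene[i]
      if (!g %in% active) next
      if (scn$inputs$type[i] == "constant") {
        input_type[gidx[[g]]] <- 1L
        input_par[gidx[[g]], 1] <- scn$inputs$level[i]
      } else {
        input_type[gidx[[g]]] <- 2L
        input_par[gidx[[g]], ] <- c(scn$inputs$u_max[i],
                                    scn$inputs$t_half[i],
                                    scn$inputs$theta[i])
      }
    }
    out <- ode_cascade_cpp(K, kself, removal, input_type, input_par,
                           matrix(0, 0, 0), matrix(0, 0, 0), numeric(),
                           rep(0, n), scn$times, 0.05, 1.05, 6)
    rownames(out) <- scn$genes
    out
  })
  # noise_sd is on the unit-max scale: scale the additive noise by each
  # gene's signal amplitude (a gene that stays silent reads as zero)
  sig_max <- apply(do.call(cbind, series), 1, max)
  noisy <- with_local_seed(derive_seed(seed, 977), {
    lapply(series, function(m) {
      if (scn$noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, scn$noise_sd), nrow(m)) *
          sig_max
      pmax(m, 0)
    })
  })
  maxima <- apply(do.call(cbind, noisy), 1, max)
  ds <- suppressWarnings(normalize_unit_max(
    grn_dataset(noisy, scn$times, scn$genes,
                paste0("S", seq_along(noisy)))))
  ds$series <- lapply(ds$series, function(m)
    round(m / scn$resolution) * scn$resolution)
  gold <- gold_standard(scn$edges[, c("regulator", "target")],
                        genes = scn$genes)
  list(dataset = ds, gold = gold, scenario = scn,
       scale = setNames(maxima, scn$genes))
}

#' Three-gene benchmark scenario for one library structure
#'
#' Draws a randomized 3-gene scenario whose generating topology is one of
#' the candidate structure families, with rates in the range of typical
#' fitted kinetic estimates and removal constants placed so activation
#' lags stagger down the hierarchy (the regime the window method assumes).
#' Used to measure how often structure selection recovers the generating
#' relationship.
#'
#' @param structure one of `"parallel"`, `"serial"`, `"convergent"`,
#'   `"null"`.
#' @param seed RNG seed; the scenario is reproducible from it.
#' @param noise_sd additive noise SD.
#' @return a [grn_scenario()] over genes A, B, C. For `"serial"` the
#'   cascade is A -> B -> C; for `"convergent"`, A -> C <- B with inputs
#'   on A (constant) and B (delayed sigmoid); `"null"` has independent
#'   genes only.
#' @export
scenario_structure <- function(structure = c("parallel", "serial",
                                             "convergent", "null"),
                               seed = 1L, noise_sd = 0) {
  structure <- match.arg(structure)
  genes <- c("A", "B", "C")
  times <- c(0, 6, 12, 24, 48, 72, 96, 672)
  with_local_seed(derive_seed(seed, sum(utf8ToInt(structure))), {
    r1 <- runif(1, 0.10, 0.28)
    r2 <- runif(1, 0.10, 0.28)
    kself <- c(A = 0.05, B = runif(1, 0.04, 0.10), C = runif(1, 0.04, 0.10))
    u_level <- 0.06
    # unnormalized trajectory of the constant-input root
    root_traj <- function(t) u_level / 0.05 * (1 - exp(-0.05 * t))
    sig <- list(u_max = 0.08, t_half = runif(1, 16, 24), theta = 1.0,
                kself = 0.12)
    # onsets sit in distinct lag classes of the sampling grid (regulator
    # strictly earlier than target), with room against the 5% call
    # threshold on either side
    onset_b <- runif(1, 9, 14)
    onset_c <- runif(1, 25, 33)
    inp_const <- function(g) tibble::tibble(
      gene = g, type = "constant", level = u_level, u_max = NA_real_,
      t_half = NA_real_, theta = NA_real_)
    inp_sig <- function(g, t_half) tibble::tibble(
      gene = g, type = "sigmoid", level = NA_real_, u_max = sig$u_max,
      t_half = t_half, theta = sig$theta)
    series_inputs <- NULL
    if (structure == "parallel") {
      edges <- tibble::tibble(regulator = c("A", "A"),
                              target = c("B", "C"), rate = c(r1, r2))
      removal <- c(A = 0, B = r1 * root_traj(onset_b),
                   C = r2 * root_traj(onset_c))
      inputs <- inp_const("A")
    } else if (structure == "serial") {
      edges <- tibble::tibble(regulator = c("A", "B"),
                              target = c("B", "C"), rate = c(r1, r2))
      rem_b <- r1 * root_traj(onset_b)
      # B's own trajectory (clamped linear ODE), for placing C's onset
      b_traj <- ode_cascade_cpp(
        matrix(c(0, 0, r1, 0), 2, 2), c(0.05, kself[["B"]]), c(0, rem_b),
        c(1L, 0L), matrix(c(u_level, 0, 0, 0, 0, 0), 2, 3),
        matrix(0, 0, 0), matrix(0, 0, 0), numeric(), c(0, 0),
        seq(0, 96, by = 2), 0.05, 1.05, 6)
      bfun <- stats::approxfun(seq(0, 96, by = 2), b_traj[2, ])
      edges$rate <- c(r1, r2)
      removal <- c(A = 0, B = rem_b,
                   C = r2 * max(bfun(onset_c + 10), 0.02))
      inputs <- inp_const("A")
    } else if (structure == "convergent") {
      # both parents must still be varying while C rises (a saturated
      # regulator degenerates into a constant and the fan-in becomes
      # unidentifiable), and the sink needs its onset inside the densely
      # sampled region so the two-phase shape is visible: A ramps slowly
      # across the whole window, B switches on sharply at ~15-20 h, C
      # follows at ~20 h
      edges <- tibble::tibble(regulator = c("A", "B"),
                              target = c("C", "C"), rate = c(r1, r2))
      kself[["A"]] <- 0.02
      kself[["B"]] <- sig$kself
      t_half_b <- runif(1, 14, 17)
      onset_cc <- runif(1, 24, 28)
      # keep A's share small enough that B's drive alone still clears C's
      # removal threshold, so C responds in the B-only series
      r1 <- runif(1, 0.04, 0.06)
      r2 <- runif(1, 0.18, 0.28)
      edges$rate <- c(r1, r2)
      a_level <- function(t) u_level / 0.02 * (1 - exp(-0.02 * t))
      b_traj <- ode_cascade_cpp(
        matrix(0, 1, 1), sig$kself, 0, 2L,
        matrix(c(sig$u_max, t_half_b, sig$theta), 1, 3),
        matrix(0, 0, 0), matrix(0, 0, 0), numeric(), 0,
        seq(0, 96, by = 2), 0.05, 1.05, 6)
      bfun <- stats::approxfun(seq(0, 96, by = 2), b_traj[1, ])
      # cap the removal below B's solo drive so C still responds in the
      # B-only perturbation series
      removal <- c(A = 0, B = 0,
                   C = min(r1 * a_level(onset_cc) + r2 * bfun(onset_cc),
                           0.78 * r2 * bfun(92)))
      inputs <- dplyr::bind_rows(inp_const("A"), inp_sig("B", t_half_b))
      # a second perturbation series with only input B switched on is what
      # makes the fan-in identifiable: a single-regulator explanation of C
      # contradicts one of the two series
      series_inputs <- list(c("A", "B"), "B")
    } else {
      edges <- tibble::tibble(regulator = character(), target = character(),
                              rate = numeric())
      removal <- c(A = 0, B = 0, C = 0)
      kself[["A"]] <- 0.05
      inputs <- dplyr::bind_rows(inp_const("A"), inp_sig("B", sig$t_half),
                                 inp_sig("C", runif(1, 42, 50)))
      # a series with only A's input on exposes any spurious A -> B or
      # A -> C edge: the claimed targets stay silent in it
      series_inputs <- list(c("A", "B", "C"), "A")
    }
    grn_scenario(paste0("structure-", structure), genes, edges, kself,
                 removal, inputs, times, noise_sd,
                 series_inputs = series_inputs, seed = seed)
  })
}

#' Seven-gene serial-parallel cascade fixture
#'
#' A hand-built benchmark emulating a small differentiation cascade: two
#' sub-cascades driven by a time-invariant input (immediate onset) and a
#' sigmoid input (delayed onset), sampled on the uneven 0-672 h grid.
#' Self-degradation rates differ along the cascade so sibling genes are
#' distinguishable, and onsets stagger so activation zones are
#' nontrivial. Noiseless by default: the round-trip benchmark for the
#' whole inference pipeline.
#'
#' @param noise_sd additive noise SD (default 0).
#' @return a [grn_scenario()] named "adipo7".
#' @export
scenario_adipo7 <- function(noise_sd = 0) {
  genes <- sprintf("G%d", 1:7)
  edges <- tibble::tribble(
    ~regulator, ~target, ~rate,
    "G1", "G2", 0.25,
    "G2", "G3", 0.24,
    "G2", "G4", 0.20,
    "G5", "G6", 0.25,
    "G5", "G7", 0.24
  )
  # Removal constants set the onset of each target (the target stays at
  # zero until rate * regulator exceeds its removal), staggering lags zone
  # by zone: G1 at 0 h, G2 at ~7 h, G3/G4 at ~21-23 h, G5 at ~44 h
  # (delayed input), G6/G7 at ~56-60 h. G1 decays slowly so it is still
  # rising across the sampled window (a regulator that saturates early is
  # kinetically indistinguishable from a step input), and G5's rise is
  # anchored by the 48 h sample.
  kself <- setNames(c(0.05, 0.06, 0.10, 0.05, 0.12, 0.08, 0.05), genes)
  removal <- setNames(c(0, 0.089, 0.150, 0.153, 0, 0.114, 0.129), genes)
  inputs <- tibble::tribble(
    ~gene, ~type, ~level, ~u_max, ~t_half, ~theta,
    "G1", "constant", 0.06, NA_real_, NA_real_, NA_real_,
    "G5", "sigmoid", NA_real_, 0.08, 46, 1.5
  )
  grn_scenario("adipo7", genes, edges, kself, removal, inputs = inputs,
               noise_sd = noise_sd, seed = 7L)
}

#' Ten-gene DREAM-style fixture
#'
#' A reproducible 10-gene, 11-edge random cascade with two perturbation
#' series (mirroring challenge-style data shapes) and mild additive
#' noise.
#'
#' @param noise_sd additive noise SD (default 0.02).
#' @return a [grn_scenario()] named "dream10".
#' @export
scenario_dream10 <- function(noise_sd = 0.02) {
  scn <- sample_random_dag(10, 11, seed = 10L, noise_sd = noise_sd,
                           n_series = 2L)
  scn$name <- "dream10"
  scn
}
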