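paper_grid <- c(0, 6, 12, 24, 48, 72, 96, 672)

mk_parallel_model <- function() {
  wingrn:::new_grn_model(
    "parallel", "parallel", c("A", "B", "C"),
    edges = tibble::tibble(regulator = c("A", "A"), target = c("B", "C"),
                           new = TRUE),
    input_types = c(A = "constant"))
}

mk_serial_model <- function() {
  wingrn:::new_grn_model(
    "serial", "serial", c("A", "B", "C"),
    edges = tibble::tibble(regulator = c("A", "B"), target = c("B", "C"),
                           new = TRUE),
    input_types = c(A = "constant"))
}

sim_ds <- function(model, par) {
  m <- simulate_model(model, par, x0 = c(0, 0, 0), times = paper_grid)
  grn_dataset(m, paper_grid, c("A", "B", "C"))
}

true_par <- c(`k[A->B]` = 0.28, `k[A->C]` = 0.24, `kself[A]` = 0.13,
              `kself[B]` = 0.03, `kself[C]` = 0.02, `rem[B]` = 0.012,
              `rem[C]` = 0.01, `U[A]` = 0.06)

test_that("simulate-then-fit recovers parallel-model rates within 1%", {
  ds <- sim_ds(mk_parallel_model(), true_par)
  fit <- fit_model(mk_parallel_model(), ds, grn_config(seed = 2))
  expect_lt(fit$sse, 1e-8)
  est <- setNames(fit$params$estimate, fit$params$name)
  for (nm in c("k[A->B]", "k[A->C]", "kself[A]", "U[A]"))
    expect_lt(abs(est[[nm]] - true_par[[nm]]) / true_par[[nm]], 0.01)
})

test_that("refitting a model to its own output is self-consistent", {
  ds <- sim_ds(mk_parallel_model(), true_par)
  fit <- fit_model(mk_parallel_model(), ds, grn_config(seed = 5))
  est <- setNames(fit$params$estimate, fit$params$name)
  ds2 <- sim_ds(mk_parallel_model(), est)
  fit2 <- fit_model(mk_parallel_model(), ds2, grn_config(seed = 5))
  expect_lt(fit2$sse, 1e-8)
})

test_that("a misspecified structure fits strictly worse than the truth", {
  serial_par <- c(`k[A->B]` = 0.28, `k[B->C]` = 0.2, `kself[A]` = 0.13,
                  `kself[B]` = 0.03, `kself[C]` = 0.05, `rem[B]` = 0.05,
                  `rem[C]` = 0.03, `U[A]` = 0.06)
  ds <- sim_ds(mk_serial_model(), serial_par)
  fit_true <- fit_model(mk_serial_model(), ds, grn_config(seed = 3))
  fit_wrong <- fit_model(mk_parallel_model(), ds, grn_config(seed = 3))
  expect_lt(fit_true$sse, 1e-8)
  expect_gt(fit_wrong$sse, fit_true$sse)
})

test_that("fitted standard errors are finite for identifiable parameters", {
  ds <- sim_ds(mk_parallel_model(), true_par)
  fit <- fit_model(mk_parallel_model(), ds, grn_config(seed = 2))
  expect_true(all(is.finite(fit$params$se) | is.na(fit$params$se)))
  expect_equal(fit$p_total, 8)
  expect_equal(fit$n, 8)
})

mk_fit_stub <- function(name, structure, sse_by_gene, p, n = 8,
                        genes = c("A", "B", "C")) {
  model <- wingrn:::new_grn_model(name, structure, genes,
                                  input_types = setNames(
                                    rep("constant", length(genes)), genes))
  structure(list(model = model,
                 params = tibble::tibble(name = character(),
                                         estimate = numeric(),
                                         se = numeric()),
                 sse_by_gene = sse_by_gene, sse = sum(sse_by_gene),
                 tau = NA_real_, n = n, p_total = p, bic = NA_real_,
                 converged = TRUE, fitted = NULL),
            class = "grn_fit")
}

test_that("tau pools the best candidate's residual SD and floors it", {
  cfg <- grn_config(tau_min = 1e-3)
  # noiseless: essentially zero residuals hit the floor
  f0 <- mk_fit_stub("perfect", "parallel", c(A = 0, B = 0, C = 0), 8)
  f1 <- mk_fit_stub("bad", "serial", c(A = 1, B = 1, C = 1), 8)
  expect_equal(as.numeric(estimate_tau(list(f1, f0), cfg)), 1e-3)

  # residuals all equal to r: tau = |r| (24 residuals of 0.05 each)
  r <- 0.05
  fr <- mk_fit_stub("uniform", "parallel",
                    c(A = 8 * r^2, B = 8 * r^2, C = 8 * r^2), 8)
  expect_equal(as.numeric(estimate_tau(list(fr), cfg)), r)

  # invariant to candidate/gene ordering
  expect_equal(estimate_tau(list(f0, f1), cfg), estimate_tau(list(f1, f0), cfg))
})

test_that("bic_score evaluates SSE/tau + p ln n exactly", {
  expect_equal(bic_score(0, 1, 0, 8), 0)
  expect_equal(bic_score(2, 1, 8, 8), 2 + 8 * log(8))
  expect_error(bic_score(1, 0, 2, 8), "tau")
  # monotone in p at fixed SSE and tau
  expect_gt(bic_score(1, 0.1, 9, 8), bic_score(1, 0.1, 8, 8))
  # random literal re-evaluations
  set.seed(9)
  for (i in 1:20) {
    sse <- runif(1, 0, 5); tau <- runif(1, 1e-3, 1)
    p <- sample(1:12, 1); n <- sample(3:20, 1)
    expect_identical(bic_score(sse, tau, p, n), sse / tau + p * log(n))
  }
})

test_that("select_top_gene picks the input-driven gene, ties break by name", {
  # A is driven by the input; B and C are downstream with delays
  ds <- sim_ds(mk_parallel_model(),
               c(`k[A->B]` = 0.28, `k[A->C]` = 0.24, `kself[A]` = 0.13,
                 `kself[B]` = 0.03, `kself[C]` = 0.02, `rem[B]` = 0.1,
                 `rem[C]` = 0.09, `U[A]` = 0.06))
  sel <- select_top_gene(c("A", "B", "C"), ds, grn_config(seed = 4))
  expect_equal(sel$gene, "A")
  expect_equal(sel$sse[["A"]], min(sel$sse))

  dup <- grn_dataset(rbind(a = c(0, 0.5, 0.8, 1), b = c(0, 0.5, 0.8, 1)),
                     c(0, 6, 12, 24), c("a", "b"))
  expect_warning(sel2 <- select_top_gene(c("a", "b"), dup,
                                         grn_config(seed = 4)),
                 "tie")
  expect_equal(sel2$gene, "a")
})

test_that("select_relationship keeps the minimal-BIC structure over null", {
  cfg_tau <- 0.01
  f_par <- wingrn:::set_fit_tau(
    mk_fit_stub("parallel", "parallel", c(A = 0, B = 0, C = 0), 8), cfg_tau)
  f_ser <- wingrn:::set_fit_tau(
    mk_fit_stub("serial", "serial", c(A = 0, B = 0.3, C = 0), 8), cfg_tau)
  f_null <- wingrn:::set_fit_tau(
    mk_fit_stub("null", "null", c(A = 0.2, B = 0.3, C = 0.2), 6), cfg_tau)
  sel <- select_relationship(list(f_ser, f_par, f_null), delta_bic_min = 2)
  expect_equal(sel$fit$model$name, "parallel")
  expect_true(sel$table$chosen[sel$table$name == "parallel"])

  # null strictly smallest: zero new edges
  f_null2 <- wingrn:::set_fit_tau(
    mk_fit_stub("null", "null", c(A = 0, B = 0, C = 0), 6), cfg_tau)
  sel2 <- select_relationship(list(f_par, f_null2), delta_bic_min = 2)
  expect_false(sel2$accepted)
  expect_equal(nrow(sel2$new_edges), 0)
})

test_that("exact BIC ties break by parameter count then structure name", {
  stub <- function(name, p, bic) {
    f <- mk_fit_stub(name, if (name == "null") "null" else "custom",
                     c(A = 0.1, B = 0, C = 0), p)
    f$bic <- bic
    f
  }
  a <- stub("zebra", 7, 42)
  b <- stub("apple", 7, 42)
  lean <- stub("lean", 6, 42)
  nul <- stub("null", 6, 99)
  sel <- select_relationship(list(a, b, lean, nul), delta_bic_min = 0)
  expect_equal(sel$fit$model$name, "lean")  # fewest parameters wins
  sel2 <- select_relationship(list(a, b, nul), delta_bic_min = 0)
  expect_equal(sel2$fit$model$name, "apple")  # then name order
  # invariance to candidate ordering
  sel3 <- select_relationship(list(nul, b, a), delta_bic_min = 0)
  expect_equal(sel3$fit$model$name, "apple")
})

test_that("all-infinite candidates fall back to the null outcome", {
  bad <- mk_fit_stub("parallel", "parallel", c(A = Inf, B = Inf, C = Inf), 8)
  bad$bic <- Inf
  nul <- mk_fit_stub("null", "null", c(A = Inf, B = Inf, C = Inf), 6)
  nul$bic <- Inf
  expect_warning(sel <- select_relationship(list(bad, nul)), "finite")
  expect_false(sel$accepted)
})

test_that("per-series fitting uses independent parameter sets", {
  scn <- scenario_structure("convergent", seed = 5)
  g <- generate_time_series(scn)
  model <- wingrn:::new_grn_model(
    "single-edge", "custom", c("A", "B", "C"),
    edges = tibble::tibble(regulator = "B", target = "C", new = TRUE),
    input_types = c(A = "constant", B = "sigmoid"))
  joint <- fit_model(model, g$dataset, grn_config(seed = 5, n_starts = 2))
  per <- fit_model(model, g$dataset,
                   grn_config(seed = 5, n_starts = 2, joint_series = FALSE))
  expect_equal(per$p_total, 2 * joint$p_total)
  expect_true(all(grepl("@S[12]$", per$params$name)))
  expect_equal(per$n, joint$n)
})
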