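single_model <- function(gene = "A", type = "constant") {
  wingrn:::single_gene_model(gene, type)
}

paper_grid <- c(0, 6, 12, 24, 48, 72, 96, 672)

test_that("integrator matches closed forms of the linear system", {
  m <- single_model()
  # pure exponential decay
  sim <- simulate_model(m, c(`kself[A]` = 0.1, `U[A]` = 0), x0 = 1,
                        times = paper_grid)
  expect_equal(unname(sim["A", ]), exp(-0.1 * paper_grid), tolerance = 1e-6)
  expect_equal(unname(sim["A", "672"]), exp(-67.2), tolerance = 1e-6)

  # constant input: A(t) = U/k + (A0 - U/k) exp(-k t)
  for (k in c(0.02, 0.3, 2, 10)) {
    sim2 <- simulate_model(m, c(`kself[A]` = k, `U[A]` = 0.06), x0 = 0,
                           times = paper_grid)
    cf <- 0.06 / k * (1 - exp(-k * paper_grid))
    expect_lt(max(abs(sim2["A", ] - cf)), 1e-6)
  }
})

test_that("parallel-structure equilibrium matches B* = (k2 A* - D)/k4", {
  m <- wingrn:::new_grn_model(
    "parallel", "parallel", c("A", "B", "C"),
    edges = tibble::tibble(regulator = c("A", "A"), target = c("B", "C"),
                           new = TRUE),
    input_types = c(A = "constant"))
  par <- c(`k[A->B]` = 0.28, `k[A->C]` = 0.24, `kself[A]` = 0.13,
           `kself[B]` = 0.03, `kself[C]` = 0.02, `rem[B]` = 0.012,
           `rem[C]` = 0.01, `U[A]` = 0.06)
  sim <- simulate_model(m, par, x0 = c(0, 0, 0), times = c(0, 2000, 4000))
  a_star <- 0.06 / 0.13
  expect_equal(unname(sim["B", 3]), (0.28 * a_star - 0.012) / 0.03,
               tolerance = 1e-4)
  expect_equal(unname(sim["C", 3]), (0.24 * a_star - 0.01) / 0.02,
               tolerance = 1e-4)
})

test_that("integrator agrees with deSolve on random linear cascades", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  for (rep in 1:4) {
    n <- 3
    K <- matrix(0, n, n)
    K[1, 2] <- runif(1, 0.05, 0.3)
    K[2, 3] <- runif(1, 0.05, 0.3)
    kself <- runif(n, 0.02, 0.3)
    u <- runif(1, 0.02, 0.1)
    rhs <- function(t, y, p) {
      list(c(u, 0, 0) + as.vector(t(K) %*% y) - kself * y)
    }
    ref <- deSolve::ode(rep(0, n), paper_grid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    got <- wingrn:::ode_cascade_cpp(
      K, kself, rep(0, n), c(1L, 0L, 0L),
      matrix(c(u, 0, 0, rep(0, 6)), n, 3),
      matrix(0, 0, 0), matrix(0, 0, 0), numeric(),
      rep(0, n), paper_grid, 0.05, 1.05, 6, FALSE)
    expect_lt(max(abs(got - t(ref[, -1]))), 1e-6)
  }
})

test_that("sigmoid input halves at t_half and respects steepness", {
  m <- single_model(type = "sigmoid")
  par <- c(`kself[A]` = 0, `umax[A]` = 1, `thalf[A]` = 24, `theta[A]` = 2)
  # with no decay, dA/dt = U(t); slope at t_half is umax/2
  sim <- simulate_model(m, par, x0 = 0, times = c(0, 23.9, 24.1, 60))
  slope <- (sim["A", 3] - sim["A", 2]) / 0.2
  expect_equal(unname(slope), 0.5, tolerance = 1e-3)
})

test_that("initial-window candidate menus respect lag constraints", {
  corr <- diag(3); rownames(corr) <- colnames(corr) <- c("A", "B", "C")
  w <- new_window(c("A", "B", "C"), corr, id = 1L)
  cfg <- grn_config()

  # no lag differences: singles, parallel, both serials (+ variants), null
  cons <- hierarchy_constraints(c(A = 0, B = 0, C = 0), c("A", "B", "C"))
  ms <- build_candidate_models(w, cons, top_gene = "A", config = cfg)
  st <- vapply(ms, `[[`, "", "structure")
  expect_setequal(unique(st),
                  c("single", "parallel", "serial", "convergent", "null"))
  # two serial orders, each with constant- and sigmoid-input variants
  expect_equal(sum(st == "serial"), 4)
  expect_equal(unname(st[length(ms)]), "null")  # null always appended last

  # strict lag ordering A < B < C kills the serial through C
  cons2 <- hierarchy_constraints(c(A = 0, B = 6, C = 12), c("A", "B", "C"))
  ms2 <- build_candidate_models(w, cons2, top_gene = "A", config = cfg)
  expect_false(any(grepl("serial\\(A>C>B\\)", names(ms2))))
  expect_true(any(grepl("serial\\(A>B>C\\)", names(ms2))))
  # convergent admissible only with sink C
  expect_true(any(grepl("convergent\\(sink=C\\)", names(ms2))))
  expect_false(any(grepl("convergent\\(sink=B\\)", names(ms2))))
})

test_that("migrated windows only test edges incident to the new gene", {
  corr <- diag(3); rownames(corr) <- colnames(corr) <- c("A", "B", "C")
  w <- new_window(c("A", "B", "C"), corr, id = 2L, new_gene = "C")
  cons <- hierarchy_constraints(c(A = 0, B = 6, C = 12), c("A", "B", "C"))
  ms <- build_candidate_models(w, cons, config = grn_config())
  for (m in ms) {
    ne <- m$edges[m$edges$new, ]
    if (nrow(ne))
      expect_true(all(ne$regulator == "C" | ne$target == "C"))
  }
  # C has the longest lag, so it can only be a target
  all_new <- dplyr::bind_rows(lapply(ms, function(m) m$edges[m$edges$new, ]))
  expect_true(all(all_new$target == "C"))
})

test_that("inherited edges ride along and duplicates collapse into null", {
  corr <- diag(3); rownames(corr) <- colnames(corr) <- c("A", "B", "C")
  w <- new_window(c("A", "B", "C"), corr, id = 3L, new_gene = "C")
  cons <- hierarchy_constraints(c(A = 0, B = 6, C = 12), c("A", "B", "C"))
  inh <- tibble::tibble(regulator = c("A", "B"), target = c("C", "C"),
                        rate = c(0.1, 0.2))
  ms <- build_candidate_models(w, cons, inherited = inh,
                               config = grn_config())
  # every incident pair is already inherited: only null remains
  expect_true(all(vapply(ms, function(m) m$structure == "null", TRUE)))
  expect_true(all(vapply(ms, function(m)
    nrow(m$edges[m$edges$new, ]) == 0, TRUE)))
})

test_that("no candidate structure contains a cycle", {
  corr <- diag(3); rownames(corr) <- colnames(corr) <- c("A", "B", "C")
  cfg <- grn_config()
  for (top in c("A", "B", "C")) {
    w <- new_window(c("A", "B", "C"), corr, id = 1L)
    cons <- hierarchy_constraints(setNames(c(0, 0, 0), c("A", "B", "C")),
                                  c("A", "B", "C"))
    for (m in build_candidate_models(w, cons, top_gene = top, config = cfg))
      expect_false(wingrn:::has_cycle(m$edges, m$genes))
  }
})

test_that("the structure library lists its parameter census", {
  tab <- list_structures()
  expect_true(all(c("parallel", "serial", "convergent", "null") %in%
                    tab$structure))
  expect_true(all(tab$p_total > 0))
})
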