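test_that("spearman_matrix reproduces hand-computed rank correlations", {
  ds <- mk_ds(rbind(1:4, 4:1, c(1, 3, 2, 4)), times = c(0, 1, 2, 3))
  rho <- spearman_matrix(ds)
  expect_equal(unname(rho["g1", "g2"]), -1)
  expect_equal(unname(rho["g1", "g1"]), 1)
  # d^2 = (0,1,1,0): 1 - 6*2/(4*15) = 0.8
  expect_equal(unname(rho["g1", "g3"]), 0.8)
  expect_true(isSymmetric(rho))
})

test_that("constant genes get zero correlation with a warning", {
  ds <- mk_ds(rbind(1:4, c(2, 2, 2, 2)), times = 0:3)
  expect_warning(rho <- spearman_matrix(ds), "g2")
  expect_equal(unname(rho["g1", "g2"]), 0)
  expect_equal(unname(rho["g2", "g2"]), 1)
})

test_that("spearman_matrix agrees with a rank-then-Pearson oracle", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(5 * 8), 5)
    m[2, 3] <- m[2, 4]  # inject a tie
    ds <- mk_ds(m, times = 0:7)
    rho <- spearman_matrix(ds)
    for (a in 1:4) for (b in (a + 1):5)
      expect_equal(unname(rho[a, b]), spearman_oracle(m[a, ], m[b, ]),
                   tolerance = 1e-12)
  }
})

test_that("initial windows seed from tied top pairs, completed by best third", {
  corr <- diag(4)
  rownames(corr) <- colnames(corr) <- paste0("g", 1:4)
  corr["g1", "g2"] <- corr["g2", "g1"] <- 0.9
  corr["g3", "g4"] <- corr["g4", "g3"] <- 0.899  # within tie_tol of max
  corr["g1", "g3"] <- corr["g3", "g1"] <- 0.5
  corr["g2", "g4"] <- corr["g4", "g2"] <- 0.1
  ws <- select_initial_windows(corr, tie_tol = 0.005)
  expect_length(ws, 2)
  expect_setequal(ws[[1]]$genes, c("g1", "g2", "g3"))
  expect_setequal(ws[[2]]$genes, c("g3", "g4", "g1"))
})

test_that("3-gene input yields exactly one window; <3 genes error", {
  corr <- diag(3) * 0.5 + 0.5
  rownames(corr) <- colnames(corr) <- c("a", "b", "c")
  ws <- select_initial_windows(corr)
  expect_length(ws, 1)
  expect_setequal(ws[[1]]$genes, c("a", "b", "c"))
  expect_error(select_initial_windows(corr[1:2, 1:2]), "3 genes")
})

test_that("unique maximum pair plus argmax third gene", {
  corr <- diag(4)
  rownames(corr) <- colnames(corr) <- paste0("g", 1:4)
  corr["g1", "g2"] <- corr["g2", "g1"] <- 0.9
  corr["g3", "g1"] <- corr["g1", "g3"] <- 0.5
  corr["g4", "g1"] <- corr["g1", "g4"] <- 0.3
  corr["g4", "g2"] <- corr["g2", "g4"] <- 0.2
  ws <- select_initial_windows(corr)
  expect_length(ws, 1)
  expect_setequal(ws[[1]]$genes, c("g1", "g2", "g3"))
})

mk_corr <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  rownames(m) <- colnames(m) <- paste0("g", seq_len(n))
  m
}

test_that("migration follows one-in one-out and avoids visited triples", {
  corr <- diag(5)
  rownames(corr) <- colnames(corr) <- paste0("g", 1:5)
  set_r <- function(a, b, v) corr[a, b] <<- corr[b, a] <<- v
  set_r("g1", "g2", 0.9); set_r("g1", "g3", 0.8)
  set_r("g4", "g2", 0.7)  # g4 is the top incoming gene
  set_r("g4", "g1", 0.05); set_r("g4", "g3", 0.3)
  set_r("g5", "g1", 0.4); set_r("g5", "g2", 0.1); set_r("g5", "g3", 0.1)
  w <- new_window(c("g1", "g2", "g3"), corr, id = 1L)
  nw <- migrate_window(w, corr, visited = window_key(w$genes), id = 2L)
  expect_equal(nw$new_gene, "g4")
  # g1 is least correlated with g4, so it leaves
  expect_setequal(nw$genes, c("g2", "g3", "g4"))

  # if that triple is already visited, the next-ranked candidate (g5) is used
  nw2 <- migrate_window(w, corr,
                        visited = c(window_key(w$genes),
                                    window_key(c("g2", "g3", "g4"))),
                        id = 2L)
  expect_equal(nw2$new_gene, "g5")

  # no outside genes left: exhaustion
  expect_null(migrate_window(w, corr[1:3, 1:3], visited = character()))
})

test_that("migrated windows always share genes with their parent", {
  for (seed in 1:4) {
    corr <- mk_corr(7, seed)
    ws <- select_initial_windows(corr)
    w <- ws[[1]]
    visited <- window_key(w$genes)
    for (i in 1:6) {
      nw <- migrate_window(w, corr, visited, id = i + 1L)
      if (is.null(nw)) break
      expect_gte(length(intersect(nw$genes, w$genes)), 2)
      expect_false(window_key(nw$genes) %in% visited)
      visited <- c(visited, window_key(nw$genes))
      w <- nw
    }
  }
})

test_that("window pruning matches the brute-force scan oracle and covers all genes", {
  for (seed in 1:3) {
    corr <- mk_corr(10, seed)
    kept <- enumerate_and_prune_windows(corr)
    all_w <- attr(kept, "all_windows")
    oracle <- prune_oracle(all_w)
    expect_equal(lapply(kept, `[[`, "genes"), lapply(oracle, `[[`, "genes"))
    expect_setequal(unique(unlist(lapply(kept, `[[`, "genes"))),
                    rownames(corr))
    # once all genes are covered, later windows add nothing
    covered <- character()
    for (w in kept) {
      expect_false(all(w$genes %in% covered))
      covered <- union(covered, w$genes)
    }
  }
})
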