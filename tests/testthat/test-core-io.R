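test_that("expression tables parse in both orientations to the same dataset", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\t0\t6\t12\t24",
               "g1\t0\t0.5\t0.8\t1",
               "g2\t0\t0.2\t0.6\t0.9",
               "g3\t0.1\t0.1\t0.4\t0.7"), f1)
  ds <- read_expression_table(f1, "genes_in_rows")
  expect_s3_class(ds, "grn_dataset")
  expect_equal(ds$genes, c("g1", "g2", "g3"))
  expect_equal(ds$times, c(0, 6, 12, 24))
  expect_equal(unname(ds$series[[1]]["g2", 3]), 0.6)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tg1\tg2\tg3",
               "0\t0\t0\t0.1",
               "6\t0.5\t0.2\t0.1",
               "12\t0.8\t0.6\t0.4",
               "24\t1\t0.9\t0.7"), f2)
  ds2 <- read_expression_table(f2, "times_in_rows")
  expect_equal(ds2$series, ds$series)
  expect_equal(ds2$times, ds$times)
})

test_that("a restarting time header becomes separate series; ragged blocks fail", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\t0\t6\t12\t0\t6\t12",
               "g1\t0\t1\t2\t0\t2\t4",
               "g2\t1\t1\t1\t2\t2\t2"), f)
  ds <- read_expression_table(f)
  expect_length(ds$series, 2)
  expect_equal(ds$times, c(0, 6, 12))
  expect_equal(unname(ds$series[[2]]["g1", ]), c(0, 2, 4))

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\t0\t6\t6\t12", "g1\t0\t1\t2\t3"), fbad)
  expect_error(read_expression_table(fbad), "non-increasing times")
})

test_that("malformed tables are rejected with located errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\t0\t6", "g1\t0.1\toops", "g2\t0\t1"), f)
  expect_error(read_expression_table(f), "row 2.*column 3")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\t0\t6", "g1\t0\t1", "g1\t0\t2"), f2)
  expect_error(read_expression_table(f2), "duplicate gene")
})

test_that("unit-max normalization divides by the max, flags flat genes, idempotent", {
  ds <- mk_ds(rbind(c(2, 4, 8), c(0, 0, 0)), times = c(0, 6, 12))
  expect_warning(nrm <- normalize_unit_max(ds), "g2")
  expect_equal(unname(nrm$series[[1]]["g1", ]), c(0.25, 0.5, 1))
  expect_equal(unname(nrm$series[[1]]["g2", ]), c(0, 0, 0))
  nrm2 <- suppressWarnings(normalize_unit_max(nrm))
  expect_identical(nrm$series, nrm2$series)
})

test_that("normalization preserves within-gene rank order and zero crossings", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(runif(12, 0, 5), 3)
    m[1, 2] <- 0
    ds <- mk_ds(m, times = c(0, 1, 2, 3))
    nrm <- normalize_unit_max(ds)
    for (g in ds$genes) {
      expect_equal(order(nrm$series[[1]][g, ]), order(m[match(g, ds$genes), ]))
      expect_equal(nrm$series[[1]][g, ] == 0, m[match(g, ds$genes), ] == 0,
                   ignore_attr = TRUE)
    }
    expect_true(all(apply(nrm$series[[1]], 1, max) == 1))
  }
})

test_that("gold standards keep flag-1 edges and reject bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2\t1", "G2\tG3\t0"), f)
  gold <- read_gold_standard(f)
  expect_equal(nrow(gold$edges), 1)
  expect_equal(gold$genes, c("G1", "G2", "G3"))

  fself <- withr::local_tempfile(fileext = ".tsv")
  writeLines("G1\tG1\t1", fself)
  expect_error(read_gold_standard(fself), "self-edge")
  fflag <- withr::local_tempfile(fileext = ".tsv")
  writeLines("G1\tG2\t2", fflag)
  expect_error(read_gold_standard(fflag), "unknown flag")
})

test_that("an 11-edge gold standard over 10 genes has at most 45 pairs", {
  g <- sample_random_dag(10, 11, seed = 3)
  gold <- gold_standard(g$edges[, c("regulator", "target")], genes = g$genes)
  expect_equal(nrow(gold$edges), 11)
  expect_lte(length(gold$pairs), 45)
})

test_that("network writing is bit-stable and round-trips", {
  net <- grn_network(
    c("A", "B", "C"),
    tibble::tibble(regulator = c("B", "A"), target = c("C", "B"),
                   sign = c("-", "+"), rate = c(-0.21, 1 / 3),
                   window = c(2L, 1L)),
    inputs = tibble::tibble(gene = "A", type = "constant", level = 0.06,
                            u_max = NA_real_, t_half = NA_real_,
                            theta = NA_real_))
  net <- assign_activation_zones(net, c(A = 0, B = 6, C = 12))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, "edge_list")
  lines <- readLines(f)
  expect_equal(lines[1], "regulator\ttarget\tsign\trate\twindow")
  expect_equal(length(lines), 3)
  expect_match(lines[2], "^A\tB")  # lexicographic order
  back <- read_network(f, "edge_list")
  expect_equal(back$edges$rate, sort(net$edges$rate, decreasing = TRUE),
               tolerance = 1e-15)

  fj <- withr::local_tempfile(fileext = ".json")
  write_network(net, fj, "json")
  back2 <- read_network(fj, "json")
  expect_equal(back2$genes, net$genes)
  expect_equal(back2$edges, net$edges)
  expect_equal(back2$inputs, net$inputs)
  expect_equal(back2$activation, net$activation)

  fempty <- withr::local_tempfile(fileext = ".tsv")
  write_network(grn_network(c("A", "B")), fempty, "edge_list")
  expect_equal(length(readLines(fempty)), 1)
})
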