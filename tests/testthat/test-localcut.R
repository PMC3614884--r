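# Graph construction, the imbalance/cut-objective identities, and the
# seeded local max-cut search against exhaustive oracles.

test_that("build_graph yields a symmetric weight map over the table's genes", {
  tab <- tbl_from_lines(c("A\tB\t-2"))
  g <- build_graph(tab)
  expect_equal(g$genes, c("A", "B"))
  expect_equal(g$w["A", "B"], -2)
  expect_equal(g$w["B", "A"], -2)

  tab2 <- tbl_from_lines(c("A\tB\t1", "B\tC\t-1"))
  g2 <- build_graph(tab2)
  expect_equal(g2$w["A", "C"], 0)   # absent edge

  # record order is irrelevant
  g3 <- build_graph(tbl_from_lines(c("B\tC\t-1", "A\tB\t1")))
  expect_equal(as.matrix(g3$w), as.matrix(g2$w))
})

test_that("imbalance matches the same-side-minus-other-side definition", {
  g <- triangle_graph()
  part <- make_part(c(0, 0, 1), c("a", "b", "c"))
  expect_equal(imbalance(g, part, "a"), 3)   # 1 - (-2)
  expect_equal(imbalance(g, part, "c"), 4)   # 0 - (-2 - 2)
  expect_error(imbalance(g, part, "zz"), "unknown gene")
  # a vertex whose neighbors are all opposite with negative weights has h > 0
  gneg <- build_graph(tbl_from_lines(c("a\tb\t-1", "a\tc\t-3")))
  p <- make_part(c(0, 1, 1), c("a", "b", "c"))
  expect_gt(imbalance(gneg, p, "a"), 0)
})

test_that("cut objective is cross-minus-within and flips by 2h per move", {
  g <- triangle_graph()
  expect_equal(cut_objective(g, make_part(c(0, 0, 1), c("a", "b", "c"))), -5)
  # all genes on one side: no cross edges
  expect_equal(cut_objective(g, make_part(c(0, 0, 0), c("a", "b", "c"))),
               -(1 - 2 - 2))

  # brute force over every bipartition and vertex of a random 6-gene graph:
  # flipping v changes Phi by exactly 2 * imbalance(v) computed pre-move
  g6 <- build_graph(rand_table(6, density = 0.7, seed = 3))
  for (code in 0:63) {
    side <- as.integer(intToBits(code)[1:6])
    part <- make_part(side, g6$genes)
    phi <- cut_objective(g6, part)
    for (v in seq_len(6)) {
      flipped <- side
      flipped[v] <- 1L - flipped[v]
      part2 <- make_part(flipped, g6$genes)
      expect_equal(cut_objective(g6, part2) - phi,
                   2 * imbalance(g6, part, g6$genes[v]),
                   tolerance = 1e-12)
    }
  }
})

test_that("random bipartitions are seeded, balanced, and leave the RNG alone", {
  tab <- rand_table(30, seed = 5)
  g <- build_graph(tab)
  expect_identical(random_bipartition(g, 11), random_bipartition(g, 11))
  expect_false(identical(random_bipartition(g, 11),
                         random_bipartition(g, 12)))

  big <- build_graph(rand_table(1000, density = 0.002, seed = 6))
  frac <- mean(random_bipartition(big, 1) == 0L)
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)

  set.seed(99)
  before <- .Random.seed
  invisible(random_bipartition(g, 123))
  expect_identical(.Random.seed, before)
})

test_that("local_maxcut reaches the unique stable cut of the triangle", {
  g <- triangle_graph()
  stable <- brute_stable(g)
  expect_equal(nrow(stable), 1L)                 # {a,b} | {c} only
  expect_equal(stable[1, ], c(0L, 0L, 1L))
  for (s in 1:4) {
    res <- local_maxcut(g, random_bipartition(g, s), rng_seed = s)
    expect_equal(canon_sides(res[g$genes]), c(0L, 0L, 1L))
  }
  # an already-stable start is a fixed point with zero moves
  start <- make_part(c(0, 0, 1), c("a", "b", "c"))
  res <- local_maxcut(g, start)
  expect_identical(as.integer(res), as.integer(start))
  expect_equal(attr(res, "moves"), 0)
})

test_that("a noiseless planted 3+3 pair is recovered from any start", {
  gen <- generate_planted_table(
    plant_spec(pathway_pairs = list(c(3L, 3L)), background_genes = 0L,
               noise_sd = 0, seed = 1))
  g <- build_graph(gen$table)
  planted <- canon_sides(as.integer(grepl("B", g$genes)))
  # exhaustive check: the planted split is the one and only stable cut
  stable <- brute_stable(g)
  expect_equal(nrow(stable), 1L)
  expect_equal(canon_sides(stable[1, ]), planted)
  for (s in 1:10) {
    res <- local_maxcut(g, random_bipartition(g, s), rng_seed = s + 100)
    expect_equal(canon_sides(unname(res[g$genes])), planted)
  }
})

test_that("accepted moves descend the objective by exactly 2h", {
  for (s in 1:5) {
    g <- build_graph(rand_table(12, density = 0.5, seed = s))
    start <- random_bipartition(g, s)
    res <- local_maxcut(g, start, rng_seed = s, trace = TRUE)
    side <- as.integer(start[g$genes])
    phi <- cut_objective(g, start)
    for (v in attr(res, "trace")) {
      part <- make_part(side, g$genes)
      h <- imbalance(g, part, v)
      expect_lt(h, 0)                     # only losing vertices move
      i <- match(v, g$genes)
      side[i] <- 1L - side[i]
      phi2 <- cut_objective(g, make_part(side, g$genes))
      expect_equal(phi2 - phi, 2 * h, tolerance = 1e-9)
      expect_lt(phi2, phi)                # strict monotone descent
      phi <- phi2
    }
    expect_identical(side, unname(as.integer(res[g$genes])))
  }
})

test_that("the sweep safety valve raises an error carrying partial state", {
  g <- triangle_graph()
  start <- make_part(c(0, 1, 0), c("a", "b", "c"))
  err <- tryCatch(local_maxcut(g, start, max_sweeps = 0),
                  condition = function(e) e)
  expect_s3_class(err, "bpmcut_sweep_limit")
  expect_s3_class(err$partial, "bipartition")
})

test_that("ensembles are stable, seeded, and invariant to worker count", {
  expect_equal(eval(formals(generate_ensemble)$M), 250L)  # default restarts
  g <- build_graph(rand_table(25, density = 0.3, seed = 8))
  e1 <- generate_ensemble(g, M = 10, base_seed = 7, workers = 1)
  e4 <- generate_ensemble(g, M = 10, base_seed = 7, workers = 4)
  expect_identical(e1$sides, e4$sides)
  expect_identical(e1$seeds, 7L + 0:9)
  for (i in seq_len(e1$M)) {
    part <- make_part(e1$sides[i, ], g$genes)
    expect_true(is_stable(g, part))
  }
  expect_error(generate_ensemble(g, M = 10,
                                 base_seed = .Machine$integer.max - 2L),
               "integer range")
})
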