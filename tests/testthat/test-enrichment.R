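# Hypergeometric enrichment, the simulation-count rule, and the min-p
# resampling correction.

test_that("association files parse in TSV and GAF form", {
  space <- c("A", "B", "C")
  tsv <- c("A\tGO:1\tfirst", "B\tGO:1\tfirst", "C\tGO:2\tsecond")
  am <- parse_associations(textConnection(tsv), space)
  expect_length(am$term_genes, 2L)
  expect_setequal(am$term_genes[["GO:1"]], c("A", "B"))
  expect_equal(unname(am$term_names["GO:2"]), "second")

  # restricting the genespace drops terms with no surviving genes
  am2 <- parse_associations(textConnection(tsv), c("A", "B"))
  expect_length(am2$term_genes, 1L)

  # GAF: ! comments skipped, gene from column 3, term from column 5
  gaf_row <- function(sym, go) {
    paste(c("DB", "ID0", sym, "", go, "REF", "IEA", "", "P", "", "",
            "gene", "taxon:559292", "20240101", "SGD"), collapse = "\t")
  }
  gaf <- c("!gaf-version: 2.2", gaf_row("A", "GO:9"), gaf_row("B", "GO:9"))
  am3 <- parse_associations(textConnection(gaf), space)
  expect_setequal(am3$term_genes[["GO:9"]], c("A", "B"))

  expect_error(parse_associations(textConnection("lonefield"), space),
               "line 1")
  expect_error(parse_associations(textConnection(tsv), character()),
               "genespace")
})

test_that("raw hypergeometric tails match the combinatorial oracle", {
  # worked case: genespace 20, term of 5, module of 5 with k = 4
  space <- sprintf("g%02d", 1:20)
  rows <- sprintf("%s\tGO:X\tx", space[1:5])
  am <- parse_associations(textConnection(rows), space)
  res <- module_enrichment(c(space[1:4], space[20]), am)
  expect_equal(res$k, 4L)
  expect_equal(res$p_raw, 76 / 15504, tolerance = 1e-12)

  # independent oracle: explicit tail sum of point masses
  tail_sum <- function(k, K, N, n) {
    sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1)))
  }
  expect_equal(res$p_raw, tail_sum(4, 5, 20, 5), tolerance = 1e-12)

  # k = 0 terms are not reported; a term covering the genespace has p = 1
  rows2 <- c(rows, sprintf("%s\tGO:ALL\tall", space))
  am2 <- parse_associations(textConnection(rows2), space)
  res2 <- module_enrichment(space[6:10], am2)
  expect_false("GO:X" %in% res2$term)
  expect_equal(res2$p_raw[res2$term == "GO:ALL"], 1.0)

  expect_error(module_enrichment(c("nope"), am), "outside the genespace")
})

test_that("the simulation-count rule is max(1000, n) capped at 10000", {
  expect_equal(choose_simulations(44), 1000L)
  expect_equal(choose_simulations(2500), 2500L)
  expect_equal(choose_simulations(20000), 10000L)
  expect_equal(choose_simulations(0), 1000L)
  expect_equal(choose_simulations(1000), 1000L)
  expect_equal(choose_simulations(10000), 10000L)
})

test_that("resampling correction behaves as an add-one min-p rank", {
  space <- sprintf("g%02d", 1:30)
  am <- rand_assoc(space, n_terms = 8, seed = 2)
  # a module made of one term's genes: tiny raw p, minimal corrected p
  strong <- am$term_genes[[which.max(lengths(am$term_genes))]]
  res <- resampling_correction(list(strong), am, n_simulations = 200,
                               rng_seed = 5)
  top <- res[which.min(res$p_raw), ]
  if (top$p_raw < 1e-6) {
    expect_equal(top$p_corrected, 1 / 201)
  }
  # corrected p is non-decreasing in raw p within a module
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_corrected[ord]) >= 0))
  # raw p of 1 corrects to exactly 1 (every draw's min-p is <= 1)
  expect_true(all(res$p_corrected[res$p_raw == 1] == 1))
  # deterministic per seed
  res2 <- resampling_correction(list(strong), am, 200, rng_seed = 5)
  expect_identical(res, res2)
})

test_that("enrich_bpms flags dual and single enrichment correctly", {
  space <- c(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5),
             sprintf("n%02d", 1:20))
  rows <- c(sprintf("a%02d\tGO:A\tpathway A", 1:5),
            sprintf("b%02d\tGO:B\tpathway B", 1:5))
  am <- parse_associations(textConnection(rows), space)
  dual <- bpm(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5))
  single <- bpm(sprintf("a%02d", 1:5), sprintf("n%02d", 1:5))
  none <- bpm(sprintf("n%02d", 6:10), sprintf("n%02d", 11:15))
  rep <- enrich_bpms(list(dual, single, none), am,
                     enrichment_params(n_simulations = 300), rng_seed = 7)
  expect_equal(rep$flags$dually_enriched, c(TRUE, FALSE, FALSE))
  expect_equal(rep$flags$singly_enriched, c(FALSE, TRUE, FALSE))
  # dual and single are mutually exclusive by construction
  expect_false(any(rep$flags$dually_enriched & rep$flags$singly_enriched))
  # every reported entry satisfies the cutoff, with k/n ratio strings
  expect_true(all(rep$table$p_corrected <= rep$p_cutoff))
  expect_match(rep$table$ratio, "^[0-9]+/[0-9]+$")
  expect_true(all(rep$table$k <= rep$table$n))
  expect_equal(rep$table$ratio[1], sprintf("%d/%d", rep$table$k[1],
                                           rep$table$n[1]))
  # report writes as TSV
  f <- withr::local_tempfile()
  write_enrichment(rep, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(rep$table))

  # no annotations anywhere: empty report, no flags raised
  am0 <- parse_associations(textConnection("z\tGO:Z\tz"), c("z", space))
  rep0 <- enrich_bpms(list(none), am0,
                      enrichment_params(n_simulations = 50), rng_seed = 1)
  expect_equal(nrow(rep0$table), 0L)
  expect_false(any(rep0$flags$dually_enriched | rep0$flags$singly_enriched))
})
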