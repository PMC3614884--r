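# Fixtures are built in code: small hand-checkable graphs, random
# interaction tables, and an exhaustive stable-cut enumerator that serves
# as the independent oracle for the local search.

tbl_from_lines <- function(lines) {
  parse_interactions(textConnection(paste(lines, collapse = "\n")))
}

# triangle with w(a,b)=1, w(a,c)=-2, w(b,c)=-2; its unique nontrivial
# stable cut is {a,b} | {c}
triangle_graph <- function() {
  build_graph(tbl_from_lines(c("a\tb\t1", "a\tc\t-2", "b\tc\t-2")))
}

make_part <- function(side, genes) {
  structure(stats::setNames(as.integer(side), genes), class = "bipartition")
}

# random connected signed table: a chain guarantees every gene an edge,
# extra pairs appear with the given density
rand_table <- function(n, density = 0.4, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  chain <- cbind(genes[-n], genes[-1])
  extra <- t(combn(genes, 2))
  extra <- extra[stats::runif(nrow(extra)) < density, , drop = FALSE]
  pairs <- unique(rbind(chain, extra))
  lines <- sprintf("%s\t%s\t%.6f", pairs[, 1], pairs[, 2],
                   stats::rnorm(nrow(pairs)))
  suppressWarnings(tbl_from_lines(lines))
}

canon_sides <- function(side) {
  side <- as.integer(side)
  if (side[[1L]] == 1L) 1L - side else side
}

# exhaustive enumeration of all stable bipartitions (side of gene 1
# fixed to 0); rows are 0/1 assignments over graph$genes
brute_stable <- function(graph, eps = 1e-9) {
  n <- length(graph$genes)
  stopifnot(n <= 16)
  out <- list()
  for (code in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code)[seq_len(n - 1)]))
    part <- make_part(side, graph$genes)
    if (all(imbalance_all(graph, part) >= -eps)) {
      out[[length(out) + 1L]] <- side
    }
  }
  do.call(rbind, out)
}

# build an ensemble object by hand from a 0/1 side matrix
manual_ensemble <- function(sides) {
  structure(list(sides = sides, seeds = seq_len(nrow(sides)),
                 M = nrow(sides), genes = colnames(sides)),
            class = "bipartition_ensemble")
}

# random association map over a genespace, for enrichment tests
rand_assoc <- function(genespace, n_terms, size_range = c(3L, 12L),
                       seed = 1) {
  set.seed(seed)
  rows <- unlist(lapply(seq_len(n_terms), function(t) {
    k <- sample(size_range[1]:size_range[2], 1)
    sprintf("%s\tT%03d\tterm %d", sample(genespace, k), t, t)
  }))
  parse_associations(textConnection(rows), genespace)
}
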