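# Signed weighted gene graph and the randomized local max-cut search.
#
# A bipartition (side 0 / side 1 per gene) is scored by the cut objective
#   Phi = sum_{cross pairs} w - sum_{within pairs} w,
# which the search drives as negative as possible: compensatory structure
# has negative epistasis across the two sides and positive within them.
# A partition is a LocalMaxCut when no single gene's imbalance
#   h(v) = sum_{u same side} w(u,v) - sum_{u other side} w(u,v)
# is materially negative; flipping v changes Phi by exactly 2 h(v).

#' Build a gene graph from an interaction table
#'
#' Vertices are exactly the table's genes; edge weights are the epistasis
#' scores, symmetric, and 0 for non-interacting pairs.
#'
#' @param table An `interaction_table`.
#' @return A `gene_graph`: list with `genes` (canonical order) and `w`
#'   (symmetric sparse weight matrix).
#' @export
build_graph <- function(table) {
  stopifnot(inherits(table, "interaction_table"), nrow(table) > 0L)
  genes <- attr(table, "genes")
  ia <- match(table$gene_a, genes)
  ib <- match(table$gene_b, genes)
  w <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(table$weight, 2L),
                            dims = c(length(genes), length(genes)),
                            dimnames = list(genes, genes))
  structure(list(genes = genes, w = w), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene graph: %d genes, %d weighted edges\n",
              length(x$genes), length(x$w@x) / 2L))
  invisible(x)
}

new_bipartition <- function(side, genes) {
  side <- as.integer(side)
  names(side) <- genes
  structure(side, class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("bipartition: %d | %d genes\n", sum(x == 0L), sum(x == 1L)))
  invisible(x)
}

# +1 for side 0, -1 for side 1, aligned to graph$genes
sigma_of <- function(graph, part) {
  if (is.null(names(part)) || !all(graph$genes %in% names(part))) {
    stop("bipartition does not cover every graph gene")
  }
  1 - 2 * as.integer(part[graph$genes])
}

#' Per-gene imbalance of a bipartition
#'
#' `imbalance()` returns h(v), the same-side weight sum minus the
#' other-side weight sum of gene `v`; `imbalance_all()` returns the
#' vector over all genes. A partition is stable (a LocalMaxCut) when
#' every h(v) >= -eps.
#'
#' @param graph A `gene_graph`.
#' @param part A `bipartition` covering the graph's genes.
#' @param v A gene identifier.
#' @return `imbalance()`: a number; `imbalance_all()`: named numeric
#'   vector over `graph$genes`.
#' @export
imbalance <- function(graph, part, v) {
  if (!v %in% graph$genes) stop("unknown gene: ", v)
  imbalance_all(graph, part)[[v]]
}

#' @rdname imbalance
#' @export
imbalance_all <- function(graph, part) {
  s <- sigma_of(graph, part)
  h <- as.vector(graph$w %*% s) * s
  names(h) <- graph$genes
  h
}

#' Cut objective of a bipartition
#'
#' Phi = (sum of weights across the cut) - (sum of weights within the
#' sides); equivalently -sigma' W sigma / 2 with sigma = +/-1 side labels.
#' The local search minimizes Phi.
#'
#' @inheritParams imbalance
#' @return A number.
#' @export
cut_objective <- function(graph, part) {
  s <- sigma_of(graph, part)
  -0.5 * sum(s * as.vector(graph$w %*% s))
}

#' Check LocalMaxCut stability
#'
#' @inheritParams imbalance
#' @param eps Stability tolerance.
#' @return TRUE iff every gene's imbalance is >= -eps.
#' @export
is_stable <- function(graph, part, eps = 1e-9) {
  all(imbalance_all(graph, part) >= -eps)
}

#' Seeded uniform random bipartition
#'
#' Each gene lands on side 0 or 1 independently with probability 1/2;
#' deterministic for a fixed seed, and the caller's RNG state is left
#' untouched.
#'
#' @param graph A `gene_graph`.
#' @param rng_seed Integer seed.
#' @return A `bipartition`.
#' @export
random_bipartition <- function(graph, rng_seed) {
  side <- with_seed(rng_seed,
                    sample(c(0L, 1L), length(graph$genes), replace = TRUE))
  new_bipartition(side, graph$genes)
}

#' Drive a bipartition to a LocalMaxCut
#'
#' Repeated full sweeps over the genes in a seeded random order (a fresh
#' permutation per sweep), flipping any gene whose imbalance is below
#' `-eps`; flips are applied immediately. Each flip lowers the cut
#' objective by at least `2*eps`, so the search terminates; a sweep with
#' no flips ends it.
#'
#' @param graph A `gene_graph`.
#' @param start Starting `bipartition`.
#' @param eps Stability tolerance (> 0); a gene moves only when its
#'   imbalance is < -eps.
#' @param max_sweeps Safety valve; default `10 * n` sweeps. Exceeding it
#'   raises an error (class `bpmcut_sweep_limit`) carrying the partial
#'   partition in its `partial` field.
#' @param rng_seed Seed for the sweep orders.
#' @param trace If TRUE, attach the sequence of accepted moves (gene
#'   names, in order) as attribute `"trace"`.
#' @return A stable `bipartition`, with attributes `sweeps` and `moves`.
#' @export
local_maxcut <- function(graph, start, eps = 1e-9, max_sweeps = NULL,
                         rng_seed = 0L, trace = FALSE) {
  stopifnot(eps > 0)
  n <- length(graph$genes)
  if (is.null(max_sweeps)) max_sweeps <- 10L * n
  w <- methods::as(graph$w, "CsparseMatrix")
  res <- local_maxcut_core(w@p, w@i, w@x, as.integer(start[graph$genes]),
                           eps, as.integer(max_sweeps),
                           as.double(rng_seed), trace)
  if (!res$converged) {
    stop(errorCondition(
      sprintf("local max-cut did not stabilize within %d sweeps",
              max_sweeps),
      class = "bpmcut_sweep_limit",
      partial = new_bipartition(res$side, graph$genes)))
  }
  out <- new_bipartition(res$side, graph$genes)
  attr(out, "sweeps") <- res$sweeps
  attr(out, "moves") <- res$moves
  if (trace) attr(out, "trace") <- graph$genes[res$trace]
  out
}

#' Generate an ensemble of M LocalMaxCut bipartitions
#'
#' Partition i (0-based) is produced from seed `base_seed + i`: a seeded
#' uniform random start driven to stability by [local_maxcut()]. All
#' randomness is derived per partition, so the result is identical for
#' any `workers` count.
#'
#' @param graph A `gene_graph`.
#' @param M Number of independent restarts (default 250).
#' @param base_seed Integer; `base_seed + M - 1` must stay below
#'   `.Machine$integer.max`.
#' @param workers Number of parallel worker processes (forked).
#' @param eps,max_sweeps Passed to [local_maxcut()].
#' @return A `bipartition_ensemble`: list with `sides` (M x n 0/1 matrix,
#'   columns named by gene), `seeds`, `M`, `genes`.
#' @export
generate_ensemble <- function(graph, M = 250L, base_seed = 1L,
                              workers = 1L, eps = 1e-9, max_sweeps = NULL) {
  stopifnot(M >= 1L, workers >= 1L)
  seeds <- as.numeric(base_seed) + seq_len(M) - 1
  if (max(seeds) > .Machine$integer.max) {
    stop("base_seed + M - 1 exceeds the 32-bit integer range")
  }
  run_one <- function(i) {
    start <- random_bipartition(graph, seeds[i])
    tryCatch(
      local_maxcut(graph, start, eps = eps, max_sweeps = max_sweeps,
                   rng_seed = seeds[i]),
      error = function(e) {
        stop("partition ", i, ": ", conditionMessage(e), call. = FALSE)
      })
  }
  parts <- if (workers > 1L) {
    parallel::mclapply(seq_len(M), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(M), run_one)
  }
  errs <- vapply(parts, inherits, logical(1), "try-error")
  if (any(errs)) stop(attr(parts[[which(errs)[1L]]], "condition"))
  sides <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
  colnames(sides) <- graph$genes
  structure(list(sides = sides, seeds = as.integer(seeds), M = M,
                 genes = graph$genes),
            class = "bipartition_ensemble")
}

#' @export
print.bipartition_ensemble <- function(x, ...) {
  cat(sprintf("bipartition ensemble: M = %d partitions over %d genes\n",
              x$M, length(x$genes)))
  invisible(x)
}
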