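# BPM extraction from the bipartition ensemble, and pruning by module
# size and pairwise Jaccard overlap.

#' Construct a BPM (between-pathway module pair)
#'
#' An ordered pair of disjoint, non-empty gene sets; `module1` contains
#' the generating gene when one is known.
#'
#' @param module1,module2 Character vectors of gene identifiers.
#' @param generator The gene whose co-occurrence profile generated this
#'   BPM, or `NA` when unknown (e.g. after [read_bpms()]).
#' @return A `bpm` object.
#' @export
bpm <- function(module1, module2, generator = NA_character_) {
  module1 <- as.character(module1)
  module2 <- as.character(module2)
  if (!length(module1) || !length(module2)) {
    stop("both BPM modules must be non-empty")
  }
  if (anyDuplicated(module1) || anyDuplicated(module2)) {
    stop("BPM modules must not contain duplicate genes")
  }
  if (length(intersect(module1, module2))) {
    stop("BPM modules must be disjoint")
  }
  if (!is.na(generator) && !generator %in% module1) {
    stop("the generating gene must lie in module1")
  }
  structure(list(generator = generator, module1 = module1,
                 module2 = module2), class = "bpm")
}

#' @export
print.bpm <- function(x, ...) {
  cat(sprintf("BPM (generator %s)\n  module1: %s\n  module2: %s\n",
              x$generator, paste(x$module1, collapse = " "),
              paste(x$module2, collapse = " ")))
  invisible(x)
}

#' Pruning parameters
#'
#' @param C Co-occurrence threshold: minimum fraction of the ensemble in
#'   which a gene must sit with (or against) the generating gene to join
#'   its BPM. Default 0.9.
#' @param J Jaccard threshold: every pair of output BPMs has flattened
#'   Jaccard index < `J`. Default 0.66.
#' @param min_size,max_size Inclusive bounds on each module's gene count.
#'   Defaults 3 and 25.
#' @return A `prune_params` list.
#' @export
prune_params <- function(C = 0.9, J = 0.66, min_size = 3L, max_size = 25L) {
  stopifnot(C > 0, C <= 1, J > 0, J <= 1,
            min_size >= 1L, min_size <= max_size)
  structure(list(C = C, J = J, min_size = as.integer(min_size),
                 max_size = as.integer(max_size)),
            class = "prune_params")
}

#' Same-side co-occurrence fractions for a gene
#'
#' For each gene u, the fraction of the ensemble's M partitions in which
#' u is on the same side as `g` (so `fraction(g)` is always 1).
#'
#' @param ensemble A `bipartition_ensemble`.
#' @param g Gene identifier present in the ensemble.
#' @return Named numeric vector over all genes.
#' @export
cooccurrence_fractions <- function(ensemble, g) {
  if (!g %in% ensemble$genes) stop("unknown gene: ", g)
  colMeans(ensemble$sides == ensemble$sides[, g])
}

#' Extract the candidate BPM generated by one gene
#'
#' module1 holds `g` and every gene on `g`'s side in at least a fraction
#' `C` of the partitions; module2 holds every gene on the opposite side
#' at least a fraction `C` of the time. Returns `NULL` when module2 is
#' empty (the gene then contributes no candidate). For `C > 0.5` the two
#' modules are disjoint by construction; smaller `C` is rejected.
#'
#' @inheritParams cooccurrence_fractions
#' @param C Co-occurrence threshold in (0.5, 1].
#' @return A `bpm` or `NULL`.
#' @export
extract_bpm <- function(ensemble, g, C = 0.9) {
  stopifnot(C > 0.5, C <= 1)
  f <- cooccurrence_fractions(ensemble, g)
  module1 <- ensemble$genes[f >= C]
  module2 <- ensemble$genes[(1 - f) >= C]
  if (!length(module2)) return(NULL)
  bpm(module1, module2, generator = g)
}

set_jaccard <- function(x, y) {
  length(intersect(x, y)) / length(union(x, y))
}

#' Jaccard index between two BPMs
#'
#' Computed on the flattened gene sets (module1 U module2 of each BPM):
#' |intersection| / |union|. Symmetric, in [0, 1].
#'
#' @param x,y `bpm` objects.
#' @return A number in [0, 1].
#' @export
jaccard <- function(x, y) {
  gx <- union(x$module1, x$module2)
  gy <- union(y$module1, y$module2)
  if (!length(gx) && !length(gy)) stop("both BPMs are empty")
  set_jaccard(gx, gy)
}

#' Filter BPMs by module size
#'
#' Keeps exactly the BPMs whose two modules both have between `min_size`
#' and `max_size` genes (inclusive); input order preserved.
#'
#' @param bpms List of `bpm` objects.
#' @param min_size,max_size Inclusive bounds.
#' @return Filtered list.
#' @export
prune_size <- function(bpms, min_size = 3L, max_size = 25L) {
  stopifnot(min_size >= 1L, min_size <= max_size)
  ok <- vapply(bpms, function(b) {
    n1 <- length(b$module1)
    n2 <- length(b$module2)
    n1 >= min_size && n1 <= max_size && n2 >= min_size && n2 <= max_size
  }, logical(1))
  bpms[ok]
}

#' Remove redundant (overlapping) BPMs
#'
#' Greedy selection over a canonical ordering — descending flattened gene
#' count, ties broken by the byte-wise smallest generating gene (first
#' module1 gene when the generator is unknown): a BPM is kept iff its
#' Jaccard index with every already-kept BPM is < `J`. The largest
#' representative of an overlapping family therefore survives, and the
#' result is deterministic. Every pair in the output has Jaccard < `J`.
#'
#' @param bpms List of `bpm` objects.
#' @param J Jaccard threshold in (0, 1].
#' @return Filtered list in canonical order.
#' @export
prune_overlap <- function(bpms, J = 0.66) {
  stopifnot(J > 0, J <= 1)
  if (length(bpms) <= 1L) return(bpms)
  sizes <- vapply(bpms, function(b) {
    length(union(b$module1, b$module2))
  }, integer(1))
  tie <- vapply(bpms, function(b) {
    if (is.na(b$generator)) b$module1[[1L]] else b$generator
  }, character(1))
  ord <- order(-sizes, tie, method = "radix")
  kept <- list()
  for (k in ord) {
    cand <- bpms[[k]]
    clear <- all(vapply(kept, function(b) jaccard(cand, b) < J,
                        logical(1)))
    if (clear) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Run the full BPM discovery pipeline
#'
#' build graph -> M seeded LocalMaxCut restarts -> one candidate BPM per
#' gene from co-occurrence fractions -> size pruning -> overlap pruning.
#' Deterministic in (`base_seed`, `M`) for any `workers` count.
#'
#' @param table An `interaction_table` (apply [transform_weights()]
#'   first if desired).
#' @param M Number of restarts (default 250).
#' @param params A [prune_params()] object.
#' @param base_seed Integer seed.
#' @param workers Parallel workers for the restarts.
#' @param verbose Log stage-by-stage counts to stderr.
#' @return Ordered list of `bpm` objects.
#' @export
run_pipeline <- function(table, M = 250L, params = prune_params(),
                         base_seed = 1L, workers = 1L, verbose = FALSE) {
  stopifnot(inherits(params, "prune_params"))
  say <- if (verbose) message else function(...) invisible()
  graph <- build_graph(table)
  say(length(graph$genes), " genes, ", nrow(table), " interactions")
  ens <- generate_ensemble(graph, M = M, base_seed = base_seed,
                           workers = workers)
  say("generated ", M, " stable bipartitions")
  cand <- lapply(graph$genes, extract_bpm, ensemble = ens, C = params$C)
  cand <- cand[!vapply(cand, is.null, logical(1))]
  say(length(cand), " candidate BPMs (C = ", params$C, ")")
  sized <- prune_size(cand, params$min_size, params$max_size)
  say(length(sized), " after size pruning [", params$min_size, ", ",
      params$max_size, "]")
  final <- prune_overlap(sized, params$J)
  say(length(final), " after overlap pruning (J = ", params$J, ")")
  final
}
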