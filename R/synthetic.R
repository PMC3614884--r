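# Synthetic interaction tables with planted between-pathway structure,
# and a side-aware recovery score. This is the package's test bed: the
# planted signal (positive within each pathway set, negative between the
# paired sets) is the only systematic structure; everything else is
# zero-mean noise.

#' Specification of a planted-BPM interaction table
#'
#' @param pathway_pairs List of 2-vectors `c(a, b)`: sizes of the two
#'   gene sets of each planted compensatory pair. Default one 5+5 pair.
#' @param within_weight Positive epistasis weight on within-set edges
#'   (default +1).
#' @param between_weight Negative weight on between-set edges
#'   (default -1).
#' @param background_genes Number of unstructured background genes
#'   (default 40).
#' @param noise_sd Gaussian noise sd added to every edge weight, and the
#'   sd of pure-background edge weights (default 0.1).
#' @param edge_density Probability that a pair of background genes
#'   carries a (noise) edge at all (default 0.25, the sparsity of a
#'   thresholded screen).
#' @param seed Integer seed; the table is a pure function of these
#'   parameters.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(pathway_pairs = list(c(5L, 5L)), within_weight = 1,
                       between_weight = -1, background_genes = 40L,
                       noise_sd = 0.1, edge_density = 0.25, seed = 1L) {
  stopifnot(length(pathway_pairs) >= 1L,
            all(vapply(pathway_pairs, length, integer(1)) == 2L),
            all(unlist(pathway_pairs) >= 1L),
            within_weight > 0, between_weight < 0, noise_sd >= 0,
            background_genes >= 0L,
            edge_density >= 0, edge_density <= 1)
  structure(list(pathway_pairs = lapply(pathway_pairs, as.integer),
                 within_weight = within_weight,
                 between_weight = between_weight,
                 background_genes = as.integer(background_genes),
                 noise_sd = noise_sd, edge_density = edge_density,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate an interaction table with planted BPMs
#'
#' For every planted pathway pair, all within-set pairs get weight
#' `within_weight + N(0, noise_sd^2)` and all between-set pairs
#' `between_weight + N(0, noise_sd^2)`. Pairs of background genes are
#' present with probability `edge_density`, with pure-noise weight
#' `N(0, noise_sd^2)`; background genes carry no measured pair with any
#' planted gene, so the planted signal is the only systematic structure
#' in the table (the vignette discusses what this isolation does and
#' does not show about real screens). Background genes that draw no edge
#' simply do not appear in the table.
#'
#' @param spec A [plant_spec()].
#' @return List with `table` (an `interaction_table`) and `truth` (list
#'   of the planted [bpm()] pairs).
#' @export
generate_planted_table <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  np <- length(spec$pathway_pairs)
  set_a <- vector("list", np)
  set_b <- vector("list", np)
  for (p in seq_len(np)) {
    sz <- spec$pathway_pairs[[p]]
    set_a[[p]] <- sprintf("P%02dA%02d", p, seq_len(sz[1L]))
    set_b[[p]] <- sprintf("P%02dB%02d", p, seq_len(sz[2L]))
  }
  planted <- c(unlist(set_a), unlist(set_b))
  if (anyDuplicated(planted)) stop("planted gene sets overlap")
  bg <- if (spec$background_genes > 0L) {
    sprintf("BG%03d", seq_len(spec$background_genes))
  } else {
    character()
  }
  edges <- with_seed(spec$seed, {
    acc <- vector("list", np + 1L)
    for (p in seq_len(np)) {
      a <- set_a[[p]]
      b <- set_b[[p]]
      wpairs <- rbind(if (length(a) > 1L) t(combn(a, 2L)),
                      if (length(b) > 1L) t(combn(b, 2L)))
      bpairs <- as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
      nw <- if (is.null(wpairs)) 0L else nrow(wpairs)
      w <- c(rep(spec$within_weight, nw),
             rep(spec$between_weight, nrow(bpairs)))
      ga <- c(if (nw) wpairs[, 1L], bpairs[, 1L])
      gb <- c(if (nw) wpairs[, 2L], bpairs[, 2L])
      acc[[p]] <- data.frame(gene_a = ga, gene_b = gb,
                             weight = w + rnorm(length(w), 0, spec$noise_sd),
                             stringsAsFactors = FALSE)
    }
    # noise edges among the background genes only
    if (length(bg) > 1L) {
      cand <- t(combn(bg, 2L))
      present <- runif(nrow(cand)) < spec$edge_density
      cand <- cand[present, , drop = FALSE]
      if (nrow(cand)) {
        acc[[np + 1L]] <- data.frame(
          gene_a = cand[, 1L], gene_b = cand[, 2L],
          weight = rnorm(nrow(cand), 0, spec$noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  })
  if (is.null(edges) || !nrow(edges)) {
    stop("planted specification produced no edges")
  }
  table <- new_interaction_table(
    canonicalize_pairs(edges$gene_a, edges$gene_b, edges$weight))
  truth <- lapply(seq_len(np), function(p) {
    bpm(set_a[[p]], set_b[[p]], generator = set_a[[p]][1L])
  })
  list(table = table, truth = truth)
}

#' Side-aware recovery score of predicted BPMs against planted truth
#'
#' For each true BPM, the maximum over predicted BPMs of the mean
#' per-module Jaccard index, taking the better of the two module
#' alignments (side labels are arbitrary). 1.0 means exact recovery;
#' an empty prediction scores 0 everywhere.
#'
#' @param predicted,truth Lists of [bpm()] objects; `truth` non-empty.
#' @return Numeric vector, one score per true BPM.
#' @export
recovery_score <- function(predicted, truth) {
  stopifnot(length(truth) >= 1L)
  pair_score <- function(p, t) {
    max((set_jaccard(p$module1, t$module1) +
           set_jaccard(p$module2, t$module2)) / 2,
        (set_jaccard(p$module1, t$module2) +
           set_jaccard(p$module2, t$module1)) / 2)
  }
  vapply(truth, function(t) {
    if (!length(predicted)) return(0)
    max(vapply(predicted, pair_score, numeric(1), t = t))
  }, numeric(1))
}
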