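# Offline GO enrichment of BPM modules: one-sided hypergeometric
# over-representation tests against a genespace background, corrected for
# multiple testing by a min-p resampling null (random genespace subsets
# of the same module size). Mirrors the semantics of simulation-corrected
# enrichment services while staying fully offline and seeded.

#' Parse a gene -> GO-term association file
#'
#' Accepts either 2-3 column TSV rows (gene, term accession, optional
#' term name) or GAF 2.x rows (gene symbol from column 3, term accession
#' from column 5; GAF carries no term name, so the accession is used).
#' Lines starting with `!` or `#` and blank lines are skipped. The map is
#' restricted to `genespace`; terms annotating no genespace gene are
#' dropped.
#'
#' @param source Path or connection.
#' @param genespace Non-empty character vector: the background gene
#'   universe for enrichment tests.
#' @return An `association_map`: list with `term_genes` (named list),
#'   `term_names` (named character), `genespace`.
#' @export
parse_associations <- function(source, genespace) {
  genespace <- unique(as.character(genespace))
  if (!length(genespace)) stop("genespace must be non-empty")
  lines <- readLines(source, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^[[:space:]]*([!#]|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("line ", lineno[which(nf < 2L)[1L]],
         ": expected gene and term columns")
  }
  gaf <- nf >= 15L
  gene <- ifelse(gaf, vapply(fields, `[[`, character(1), 3L),
                 vapply(fields, `[[`, character(1), 1L))
  term <- ifelse(gaf, vapply(fields, `[[`, character(1), 5L),
                 vapply(fields, `[[`, character(1), 2L))
  name <- vapply(seq_along(fields), function(i) {
    if (!gaf[i] && nf[i] >= 3L && nzchar(fields[[i]][[3L]])) {
      fields[[i]][[3L]]
    } else {
      term[i]
    }
  }, character(1))
  if (any(gene == "" | term == "")) {
    i <- which(gene == "" | term == "")[1L]
    stop("line ", lineno[i], ": empty gene or term field")
  }
  in_space <- gene %in% genespace
  gene <- gene[in_space]
  term <- term[in_space]
  name <- name[in_space]
  term_genes <- lapply(split(gene, term), unique)
  term_names <- vapply(split(name, term), `[[`, character(1), 1L)
  structure(list(term_genes = term_genes,
                 term_names = term_names[names(term_genes)],
                 genespace = genespace),
            class = "association_map")
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf("association map: %d terms over a genespace of %d genes\n",
              length(x$term_genes), length(x$genespace)))
  invisible(x)
}

#' Raw hypergeometric enrichment of one module
#'
#' For each term with at least one annotated gene in the module, the
#' one-sided over-representation tail P(X >= k) of the hypergeometric
#' distribution with population `|genespace|`, `K` annotated genes, and
#' `|module|` draws.
#'
#' @param module Character vector of genes, a subset of the genespace.
#' @param assoc An `association_map`.
#' @return Data frame (term, name, k, n, p_raw), ordered by `p_raw`.
#' @export
module_enrichment <- function(module, assoc) {
  stopifnot(inherits(assoc, "association_map"))
  module <- unique(as.character(module))
  out_of_space <- setdiff(module, assoc$genespace)
  if (length(out_of_space)) {
    stop("module genes outside the genespace: ",
         paste(out_of_space, collapse = ", "))
  }
  N <- length(assoc$genespace)
  n <- length(module)
  k <- vapply(assoc$term_genes, function(g) length(intersect(g, module)),
              integer(1))
  K <- lengths(assoc$term_genes)
  hit <- k >= 1L
  p <- phyper(k[hit] - 1L, K[hit], N - K[hit], n, lower.tail = FALSE)
  res <- data.frame(term = names(assoc$term_genes)[hit],
                    name = unname(assoc$term_names[hit]),
                    k = unname(k[hit]), n = rep.int(n, sum(hit)),
                    p_raw = unname(p), stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$term, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulation count rule for the resampling correction
#'
#' The greater of 1000 and the number of modules tested, capped at 10000.
#'
#' @param n_modules Non-negative integer.
#' @return Integer in [1000, 10000].
#' @export
choose_simulations <- function(n_modules) {
  stopifnot(n_modules >= 0)
  min(10000L, max(1000L, as.integer(n_modules)))
}

# Null distribution of the per-draw minimum raw p over all terms, for
# random genespace subsets of size s. Shared by every module of size s.
null_min_p <- function(s, assoc, n_simulations) {
  N <- length(assoc$genespace)
  terms <- assoc$term_genes
  Tn <- length(terms)
  if (Tn == 0L) return(rep(1, n_simulations))
  tm <- matrix(0, nrow = Tn, ncol = N)
  for (t in seq_len(Tn)) {
    tm[t, match(terms[[t]], assoc$genespace)] <- 1
  }
  idx <- vapply(seq_len(n_simulations), function(i) sample.int(N, s),
                integer(s))
  dm <- matrix(0, nrow = N, ncol = n_simulations)
  dm[cbind(as.vector(idx), rep(seq_len(n_simulations), each = s))] <- 1
  counts <- tm %*% dm                       # Tn x n_simulations
  K <- lengths(terms)
  pm <- matrix(phyper(counts - 1, K, N - K, s, lower.tail = FALSE),
               nrow = Tn)
  do.call(pmin, lapply(seq_len(Tn), function(r) pm[r, ]))
}

#' Resampling-based multiple-testing correction
#'
#' For each module size s present, draws `n_simulations` random genespace
#' subsets of size s and records each draw's minimum raw p over all
#' terms. The corrected p of an observed (module, term) pair is
#' `(1 + #draws with min-p <= p_raw) / (1 + n_simulations)` — the
#' (add-one) rank of the observed p in the null of best-anywhere p
#' values, so it accounts for testing every term at once. Deterministic
#' per seed.
#'
#' @param modules List of gene sets (character vectors).
#' @param assoc An `association_map`.
#' @param n_simulations Number of null draws (>= 1); see
#'   [choose_simulations()].
#' @param rng_seed Integer seed.
#' @return Data frame (module, term, name, k, n, p_raw, p_corrected)
#'   where `module` indexes into `modules`.
#' @export
resampling_correction <- function(modules, assoc, n_simulations,
                                  rng_seed = 1L) {
  stopifnot(n_simulations >= 1L)
  observed <- lapply(modules, module_enrichment, assoc = assoc)
  sizes <- vapply(modules, function(m) length(unique(m)), integer(1))
  null_by_size <- with_seed(rng_seed, {
    out <- list()
    for (s in sort(unique(sizes))) {
      out[[as.character(s)]] <- sort(null_min_p(s, assoc, n_simulations))
    }
    out
  })
  res <- lapply(seq_along(modules), function(j) {
    obs <- observed[[j]]
    if (!nrow(obs)) return(NULL)
    nullp <- null_by_size[[as.character(sizes[j])]]
    cnt <- findInterval(obs$p_raw, nullp)   # draws with min-p <= p_raw
    obs$p_corrected <- (1 + cnt) / (1 + n_simulations)
    cbind(module = j, obs)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(module = integer(), term = character(),
                      name = character(), k = integer(), n = integer(),
                      p_raw = numeric(), p_corrected = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Enrichment parameters
#'
#' @param p_cutoff Corrected p-value cutoff; only terms at or below it
#'   are reported. Default 0.05.
#' @param genespace_mode `"input_genes"` (background = genes of the
#'   interaction data, the default) or `"all_species_genes"` (background
#'   = every gene in the association file's universe; the caller supplies
#'   that universe as the genespace).
#' @param n_simulations Number of null draws, or `NULL` to apply
#'   [choose_simulations()] to the number of modules tested.
#' @return An `enrichment_params` list.
#' @export
enrichment_params <- function(p_cutoff = 0.05,
                              genespace_mode = c("input_genes",
                                                 "all_species_genes"),
                              n_simulations = NULL) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1,
            is.null(n_simulations) || n_simulations >= 1)
  structure(list(p_cutoff = p_cutoff,
                 genespace_mode = match.arg(genespace_mode),
                 n_simulations = if (is.null(n_simulations)) NULL
                 else as.integer(n_simulations)),
            class = "enrichment_params")
}

#' GO enrichment of a BPM list
#'
#' Tests both modules of every BPM ([module_enrichment()]), corrects by
#' min-p resampling ([resampling_correction()]) with
#' `choose_simulations(2 * #BPMs)` draws unless overridden, keeps terms
#' with corrected p <= `p_cutoff`, and flags every BPM as dually enriched
#' (surviving terms in both modules), singly enriched (in exactly one),
#' or neither. Dual takes precedence over single.
#'
#' @param bpms List of [bpm()] objects.
#' @param assoc An `association_map`; all BPM genes must lie in its
#'   genespace.
#' @param params An [enrichment_params()] object.
#' @param rng_seed Integer seed for the resampling null.
#' @return An `enrichment_report`: list with `table` (bpm, module, term,
#'   name, k, n, ratio, p_raw, p_corrected), `flags` (bpm,
#'   dually_enriched, singly_enriched), `p_cutoff`, `n_simulations`.
#' @export
enrich_bpms <- function(bpms, assoc, params = enrichment_params(),
                        rng_seed = 1L) {
  stopifnot(length(bpms) >= 1L, inherits(params, "enrichment_params"))
  modules <- vector("list", 2L * length(bpms))
  bpm_id <- character(2L * length(bpms))
  mod_id <- character(2L * length(bpms))
  for (i in seq_along(bpms)) {
    modules[[2L * i - 1L]] <- bpms[[i]]$module1
    modules[[2L * i]] <- bpms[[i]]$module2
    bpm_id[(2L * i - 1L):(2L * i)] <- sprintf("bpm%d", i - 1L)
    mod_id[(2L * i - 1L):(2L * i)] <- c("module1", "module2")
  }
  nsim <- params$n_simulations %||% choose_simulations(length(modules))
  res <- resampling_correction(modules, assoc, nsim, rng_seed)
  res <- res[res$p_corrected <= params$p_cutoff, , drop = FALSE]
  table <- data.frame(bpm = bpm_id[res$module], module = mod_id[res$module],
                      term = res$term, name = res$name, k = res$k,
                      n = res$n, ratio = sprintf("%d/%d", res$k, res$n),
                      p_raw = res$p_raw, p_corrected = res$p_corrected,
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  enriched <- unique(table[c("bpm", "module")])
  nmod <- table(factor(enriched$bpm,
                       levels = sprintf("bpm%d", seq_along(bpms) - 1L)))
  flags <- data.frame(bpm = names(nmod),
                      dually_enriched = as.vector(nmod) == 2L,
                      singly_enriched = as.vector(nmod) == 1L,
                      stringsAsFactors = FALSE)
  structure(list(table = table, flags = flags, p_cutoff = params$p_cutoff,
                 n_simulations = nsim),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(paste0("enrichment report: %d term hits at corrected p <= ",
                     "%g (%d simulations)\n"),
              nrow(x$table), x$p_cutoff, x$n_simulations))
  cat(sprintf("  %d dually / %d singly enriched BPMs of %d\n",
              sum(x$flags$dually_enriched), sum(x$flags$singly_enriched),
              nrow(x$flags)))
  invisible(x)
}

#' Write an enrichment report as TSV
#'
#' Columns: bpm, module, term, name, k, n, ratio, p_raw, p_corrected.
#'
#' @param report An `enrichment_report`.
#' @param sink Path or connection.
#' @export
write_enrichment <- function(report, sink) {
  stopifnot(inherits(report, "enrichment_report"))
  write.table(report$table, sink, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
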