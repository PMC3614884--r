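# Reading, validating and writing genetic-interaction (GI) tables and
# BPM files. GI input is tab-delimited: gene A, gene B, epistasis score
# (extra columns ignored). Identifiers are opaque, case-sensitive strings.

# Byte-wise (C-locale) sort so canonical order never depends on the
# session locale.
radix_sort <- function(x) sort(unique(x), method = "radix")

# Canonicalize unordered pairs: gene_a < gene_b byte-wise.
canonicalize_pairs <- function(gene_a, gene_b, weight) {
  lev <- radix_sort(c(gene_a, gene_b))
  ia <- match(gene_a, lev)
  ib <- match(gene_b, lev)
  swap <- ia > ib
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  data.frame(gene_a = a, gene_b = b, weight = weight,
             stringsAsFactors = FALSE)
}

new_interaction_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_a", "gene_b", "weight") %in% names(df)),
            nrow(df) > 0L)
  genes <- radix_sort(c(df$gene_a, df$gene_b))
  df <- df[order(match(df$gene_a, genes), match(df$gene_b, genes)), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, genes = genes,
            class = c("interaction_table", "data.frame"))
}

#' Genes covered by an interaction table
#'
#' @param table An `interaction_table`.
#' @return Character vector of gene identifiers in canonical (byte-wise
#'   sorted) order; every gene participates in at least one record.
#' @export
interaction_genes <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  attr(table, "genes")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction table: %d pairs over %d genes\n",
              nrow(x), length(attr(x, "genes"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Parse a genetic-interaction file
#'
#' Reads a tab-delimited interaction file (columns: gene A, gene B,
#' epistasis score; extra columns ignored) into a canonical, deduplicated
#' symmetric interaction table. Blank lines and lines starting with `#`
#' are skipped. A header is tolerated on the first data line only: if its
#' third field does not parse as a number it is skipped with a warning.
#'
#' Cleaning rules: self-pairs (gene A = gene B) are dropped with a
#' warning; rows touching an excluded gene are dropped; rows whose score
#' is blank or non-finite (`NA`, `NaN`, `Inf`) are dropped with a
#' warning; duplicate unordered pairs are merged by averaging their
#' scores, with a warning. Pairs are stored with `gene_a < gene_b`
#' (byte-wise) and rows sorted, so permuting the input lines yields an
#' identical table.
#'
#' @param source Path to a file, or a connection.
#' @param exclude Character vector of gene identifiers to drop (e.g. an
#'   essential-gene list; see [read_exclusions()]).
#' @return An `interaction_table`: a data frame with columns `gene_a`,
#'   `gene_b`, `weight` and a `genes` attribute.
#' @export
parse_interactions <- function(source, exclude = character()) {
  lines <- readLines(source, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) stop("no interaction rows found in input")

  # sentinel keeps trailing empty fields (strsplit drops them otherwise)
  fields <- lapply(strsplit(paste0(lines, "\t."), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nf <- lengths(fields)
  f3 <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[[3L]])
               else NA_character_, character(1))
  blankish <- !is.na(f3) & (f3 == "" | toupper(f3) %in% c("NA", "NAN"))
  w <- suppressWarnings(as.numeric(replace(f3, blankish, NA)))

  # header: first data line whose third field is not a number
  if (nf[1L] >= 3L && is.na(w[1L]) && !blankish[1L]) {
    warning("skipping apparent header on line ", lineno[1L], ": ",
            lines[1L], call. = FALSE)
    fields <- fields[-1L]; nf <- nf[-1L]; w <- w[-1L]
    blankish <- blankish[-1L]; lineno <- lineno[-1L]
    if (!length(fields)) stop("no interaction rows found in input")
  }

  if (any(nf < 3L)) {
    stop("line ", lineno[which(nf < 3L)[1L]],
         ": expected at least 3 tab-separated fields")
  }
  unparseable <- is.na(w) & !blankish
  if (any(unparseable)) {
    i <- which(unparseable)[1L]
    stop("line ", lineno[i], ": interaction score ",
         sQuote(f3[i]), " is not a number")
  }

  gene_a <- trimws(vapply(fields, `[[`, character(1), 1L))
  gene_b <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (any(gene_a == "" | gene_b == "")) {
    i <- which(gene_a == "" | gene_b == "")[1L]
    stop("line ", lineno[i], ": empty gene identifier")
  }

  drop_missing <- blankish | !is.finite(w)
  if (any(drop_missing)) {
    warning("dropped ", sum(drop_missing),
            " row(s) with missing or non-finite scores", call. = FALSE)
  }
  drop_self <- gene_a == gene_b
  if (any(drop_self & !drop_missing)) {
    warning("dropped ", sum(drop_self & !drop_missing),
            " self-interaction row(s)", call. = FALSE)
  }
  drop_excl <- gene_a %in% exclude | gene_b %in% exclude
  keep <- !(drop_missing | drop_self | drop_excl)
  if (!any(keep)) stop("no interaction rows left after filtering")

  df <- canonicalize_pairs(gene_a[keep], gene_b[keep], w[keep])
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning("merged ", ndup, " duplicate gene-pair row(s) by averaging",
            call. = FALSE)
    mw <- tapply(df$weight, key, mean)
    df <- df[!duplicated(key), , drop = FALSE]
    df$weight <- as.numeric(mw[paste(df$gene_a, df$gene_b, sep = "\r")])
  }
  new_interaction_table(df)
}

#' Read a gene-exclusion list
#'
#' One identifier per line; blank lines and `#` comments skipped.
#'
#' @param source Path or connection.
#' @return Character vector of identifiers.
#' @export
read_exclusions <- function(source) {
  lines <- trimws(readLines(source, warn = FALSE))
  lines[!grepl("^(#|$)", lines)]
}

#' Transform interaction weights
#'
#' SGA-style scores are typically used as-is; E-MAP scores are often
#' squared while retaining their sign (`signed_square`, w -> sign(w) w^2),
#' which sharpens the separation between strong and weak interactions and
#' speeds convergence of the local search.
#'
#' @param table An `interaction_table`.
#' @param mode `"identity"` or `"signed_square"`.
#' @return The table with transformed weights (gene set unchanged).
#' @export
transform_weights <- function(table, mode = c("identity", "signed_square")) {
  stopifnot(inherits(table, "interaction_table"))
  mode <- match.arg(mode)
  if (mode == "signed_square") {
    table$weight <- sign(table$weight) * table$weight^2
  }
  table
}

# shortest decimal that round-trips the binary double exactly
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  redo <- as.numeric(out) != x
  if (any(redo)) out[redo] <- sprintf("%.17g", x[redo])
  out
}

#' Write an interaction table
#'
#' Emits the canonical 3-column tab-delimited GI format. Weights are
#' serialized with enough digits to round-trip exactly, so
#' `parse_interactions(write_interactions(x))` reproduces `x` bit for bit.
#'
#' @param table An `interaction_table`.
#' @param sink Path or connection.
#' @export
write_interactions <- function(table, sink) {
  stopifnot(inherits(table, "interaction_table"))
  writeLines(paste(table$gene_a, table$gene_b, fmt_num(table$weight),
                   sep = "\t"), sink)
  invisible(NULL)
}

#' Write BPMs to the two-lines-per-module-pair format
#'
#' The i-th BPM (0-based) produces the lines
#' `bpm<i>/module1<TAB>gene...` and `bpm<i>/module2<TAB>gene...`, the
#' gene order of each module preserved. This file is the input of the
#' enrichment stage (see [read_bpms()], [enrich_bpms()]).
#'
#' @param bpms Non-empty list of [bpm()] objects.
#' @param sink Path or connection.
#' @export
write_bpms <- function(bpms, sink) {
  if (!length(bpms)) stop("refusing to write an empty BPM list")
  stopifnot(all(vapply(bpms, inherits, logical(1), "bpm")))
  lines <- character(2L * length(bpms))
  for (i in seq_along(bpms)) {
    b <- bpms[[i]]
    lines[2L * i - 1L] <- paste(c(sprintf("bpm%d/module1", i - 1L),
                                  b$module1), collapse = "\t")
    lines[2L * i] <- paste(c(sprintf("bpm%d/module2", i - 1L),
                             b$module2), collapse = "\t")
  }
  writeLines(lines, sink)
  invisible(NULL)
}

#' Read a BPM file
#'
#' Inverse of [write_bpms()]. The file format does not record the
#' generating gene, so `generator` is `NA` on the returned objects.
#'
#' @param source Path or connection.
#' @return List of [bpm()] objects (empty list for an empty stream).
#' @export
read_bpms <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  if (length(lines) %% 2L != 0L) {
    stop("BPM file has an orphan module line (odd line count)")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  heads <- vapply(fields, `[[`, character(1), 1L)
  m <- regmatches(heads, regexec("^bpm([0-9]+)/module([12])$", heads))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    stop("malformed BPM line label: ", sQuote(heads[bad[1L]]))
  }
  ids <- vapply(m, function(x) as.integer(x[[2L]]), integer(1))
  mods <- vapply(m, function(x) as.integer(x[[3L]]), integer(1))
  n <- length(lines) / 2L
  out <- vector("list", n)
  for (j in seq_len(n)) {
    i1 <- 2L * j - 1L
    i2 <- 2L * j
    if (mods[i1] != 1L || mods[i2] != 2L || ids[i1] != ids[i2]) {
      stop("BPM lines ", i1, "-", i2,
           " do not pair up as module1/module2 with matching ids")
    }
    g1 <- fields[[i1]][-1L]
    g2 <- fields[[i2]][-1L]
    if (!length(g1) || !length(g2)) {
      stop("BPM ", ids[i1], " has an empty module")
    }
    out[[j]] <- bpm(g1, g2)
  }
  out
}
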