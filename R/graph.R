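# Steps 2-3: extract directed (k-1)-overlap edges from consecutive valid
# k-mers in reads (edge abundance CE = number of adjacent co-occurrences),
# then filter so each node keeps only its maximal-abundance 3'/5' candidates.
# The filtered graph drives clustering; contig extension itself ranks by node
# abundance, so edges serve cluster segregation only.

.EDGE_SEP <- "\t"

#' Edge table constructor
#'
#' Directed edges of the k-mer overlap graph: `suffix(source, k-1) ==
#' prefix(target, k-1)` for edges produced by [extract_edges()].  The
#' constructor itself is permissive (clustering and filtering are pure graph
#' operations), validation happens at extraction.
#'
#' @param source,target character vectors of node labels.
#' @param count positive integer edge abundances CE.
#' @param k k-mer length.
#' @param mode counting mode.
#' @return an `edge_table` (data.frame with class attribute).
#' @export
edge_table <- function(source, target, count, k = NA_integer_,
                       mode = "strand_specific") {
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   count = as.integer(count), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("source", "target")]))
    stop("duplicate (source, target) pairs in edge table")
  attr(df, "k") <- as.integer(k)
  attr(df, "mode") <- mode
  class(df) <- c("edge_table", "data.frame")
  df
}

#' @export
as.data.frame.edge_table <- function(x, ...) {
  data.frame(source = x$source, target = x$target, count = x$count,
             stringsAsFactors = FALSE)
}

#' @export
print.edge_table <- function(x, ...) {
  cat("<edge_table> ", nrow(x), " edge(s)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Extract overlap edges from reads
#'
#' One map/collate/reduce cycle: map emits one (source, target) pair for every
#' two *adjacent* read positions (i, i+1) that both yield valid k-mers — pairs
#' spanning an N contribute nothing — collate groups ordered pairs, reduce
#' counts occurrences (CE).  Edges whose endpoints did not survive in
#' `kmer_table` (e.g. removed by `min_kmer_cov`) are dropped.  Self-loops
#' (e.g. from homopolymer runs) are legitimate edges.  In double-stranded mode
#' the pair is recorded between canonical forms, in read orientation.
#'
#' @param reads as in [count_kmers()] (must be the same read set).
#' @param k k-mer length; must match `kmer_table`.
#' @param mode counting mode; must match `kmer_table`.
#' @param kmer_table a [kmer_table()] built from the same reads/parameters.
#' @param engine an [engine_config()].
#' @return an `edge_table` sorted by (source, target).
#' @examples
#' kt <- count_kmers("AAAAA", k = 3)
#' extract_edges("AAAAA", k = 3, kmer_table = kt)  # self-loop AAA->AAA, CE=2
#' @export
extract_edges <- function(reads, k = 25L, mode = "strand_specific",
                          kmer_table, engine = engine_config()) {
  mode <- .check_mode(mode)
  k <- as.integer(k)
  if (!inherits(kmer_table, "kmer_table"))
    stop("kmer_table must be a kmer_table")
  if (!is.na(attr(kmer_table, "k")) && length(kmer_table$kmer) &&
      attr(kmer_table, "k") != k)
    stop("k mismatch between kmer_table (", attr(kmer_table, "k"),
         ") and edge extraction (", k, ")")
  reads <- .as_read_df(reads)
  ds <- mode == "double_stranded"
  kv <- mr_map(as.list(reads$sequence), function(s) {
    w <- valid_kmers(s, k)
    if (nrow(w) < 2L) return(NULL)
    adj <- which(diff(w$position) == 1L)
    if (!length(adj)) return(NULL)
    src <- w$kmer[adj]
    tgt <- w$kmer[adj + 1L]
    if (ds) {
      src <- canonical_kmers(src)
      tgt <- canonical_kmers(tgt)
    }
    list(key = paste(src, tgt, sep = .EDGE_SEP), value = "1")
  }, engine)
  kmv <- mr_collate(kv, engine)
  out <- mr_reduce(kmv, function(keys, values) {
    list(key = keys, value = as.character(lengths(values)))
  }, engine, vectorized = TRUE)
  pairs <- kv_pairs(out)
  if (!nrow(pairs))
    return(edge_table(character(0), character(0), integer(0), k, mode))
  st <- strsplit(pairs$key, .EDGE_SEP, fixed = TRUE)
  src <- vapply(st, `[`, "", 1L)
  tgt <- vapply(st, `[`, "", 2L)
  keep <- src %in% kmer_table$kmer & tgt %in% kmer_table$kmer
  src <- src[keep]; tgt <- tgt[keep]
  ce <- as.integer(pairs$value)[keep]
  ord <- order(src, tgt, method = "radix")
  edge_table(src[ord], tgt[ord], ce[ord], k, mode)
}

#' Filter edges to per-node maximal-abundance candidates
#'
#' Keeps exactly the edges that are maximal among their source node's outgoing
#' (3') edges *and* among their target node's incoming (5') edges
#' (`rule = "and"`, the default); ties at the maximum are all retained.  The
#' node set is unchanged.  With `rule = "or"` an edge survives if it is
#' maximal at either endpoint — a milder variant that splits clusters less
#' aggressively.
#'
#' The filter is idempotent and is the identity on branch-free paths.
#'
#' @param edges an `edge_table`.
#' @param rule `"and"` (default) or `"or"`.
#' @return the filtered `edge_table`, original row order preserved.
#' @export
filter_edges <- function(edges, rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(inherits(edges, "edge_table"))
  if (!nrow(edges)) return(edges)
  out_max <- stats::ave(edges$count, edges$source, FUN = max)
  in_max <- stats::ave(edges$count, edges$target, FUN = max)
  keep <- if (rule == "and") {
    edges$count == out_max & edges$count == in_max
  } else {
    edges$count == out_max | edges$count == in_max
  }
  res <- edges[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "k") <- attr(edges, "k")
  attr(res, "mode") <- attr(edges, "mode")
  class(res) <- c("edge_table", "data.frame")
  res
}

#' Write / read an edge table as TSV
#'
#' Plain `source<TAB>target<TAB>count` rows, no header.
#'
#' @param x an `edge_table`.
#' @param path TSV path.
#' @export
write_edge_tsv <- function(x, path) {
  stopifnot(inherits(x, "edge_table"))
  utils::write.table(as.data.frame(x)[c("source", "target", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @param mode metadata to attach on read.
#' @export
read_edge_tsv <- function(path, mode = "strand_specific") {
  if (file.size(path) == 0)
    return(edge_table(character(0), character(0), integer(0), NA_integer_,
                      mode))
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("source", "target", "count"),
                          colClasses = c("character", "character", "integer"))
  edge_table(df$source, df$target, df$count, nchar(df$source[1L]), mode)
}
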