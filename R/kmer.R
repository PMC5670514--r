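# Step 1 of the pipeline: decompose reads into unique k-mers with abundances
# via one map/collate/reduce cycle.  k-mers are the nodes V of the de Bruijn
# graph, their abundance C the number of occurrences across all reads.

#' Valid k-mer windows of a read
#'
#' Enumerates every length-k window of a sequence containing only A/C/G/T,
#' left to right; windows containing N (or any other non-ACGT character) are
#' skipped.
#'
#' @param sequence a single read sequence (character scalar).
#' @param k window length (>= 1).
#' @return data.frame with `position` (0-based start) and `kmer`.
#' @examples
#' valid_kmers("ACNGT", 3)  # zero rows: every window spans the N
#' valid_kmers("ACGTA", 3)
#' @export
valid_kmers <- function(sequence, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  n <- nchar(sequence)
  if (n < k)
    return(data.frame(position = integer(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  data.frame(position = starts[ok] - 1L, kmer = kmers[ok],
             stringsAsFactors = FALSE)
}

#' Reverse complement
#'
#' @param x character vector of DNA strings over ACGTN.
#' @return reverse complements, same length.
#' @export
reverse_complement <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The lexicographic minimum of each k-mer and its reverse complement; the
#' standard folding used in non-strand-specific (double-stranded) mode.
#'
#' @param kmers character vector over ACGT.
#' @return canonical k-mers, same length.
#' @examples
#' canonical_kmers(c("TTT", "ACG"))
#' @export
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- reverse_complement(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

.check_mode <- function(mode) {
  match.arg(mode, c("strand_specific", "double_stranded"))
}

.as_read_df <- function(reads) {
  if (is.data.frame(reads)) return(reads)
  if (!is.character(reads))
    stop("reads must be a data.frame, a character vector of sequences, ",
         "or file path(s)")
  # bare sequences are ACGTN(U) strings; anything else is taken as a path
  is_seq <- length(reads) >= 1L && all(grepl("^[ACGTNUacgtnu]+$", reads)) &&
    !any(file.exists(reads))
  if (is_seq)
    return(data.frame(id = paste0("r", seq_along(reads)), sequence = reads,
                      stringsAsFactors = FALSE))
  missing <- reads[!file.exists(reads)]
  if (length(missing)) stop("no such read file: ", missing[1L])
  do.call(rbind, lapply(reads, read_sequences))
}

#' Count k-mers across reads
#'
#' One map/collate/reduce cycle: map emits one (k-mer, 1) pair per valid
#' window of each read, collate groups by k-mer, reduce counts occurrences and
#' drops entries below `min_kmer_cov`.  In `double_stranded` mode each window
#' is folded to its canonical form before counting.  The result is independent
#' of read order and of `n_workers`/`pagesize`.
#'
#' @param reads a data.frame from [read_sequences()], a character vector of
#'   sequences, or FASTA/FASTQ path(s).
#' @param k k-mer length (default 25, the usual choice for transcriptome
#'   assembly).
#' @param mode `"strand_specific"` (default) or `"double_stranded"`.
#' @param min_kmer_cov drop k-mers with abundance below this (default 1, i.e.
#'   keep everything).
#' @param engine an [engine_config()].
#' @return object of class `kmer_table`: list with `kmer` (sorted), `count`,
#'   and attributes `k`, `mode`, `min_kmer_cov`, `reads_skipped_short`.
#' @examples
#' count_kmers(c("ACG", "CGT", "ACG"), k = 3)
#' @export
count_kmers <- function(reads, k = 25L, mode = "strand_specific",
                        min_kmer_cov = 1L, engine = engine_config()) {
  mode <- .check_mode(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  min_kmer_cov <- as.integer(min_kmer_cov)
  reads <- .as_read_df(reads)
  skipped <- sum(nchar(reads$sequence) < k)
  ds <- mode == "double_stranded"
  kv <- mr_map(as.list(reads$sequence), function(s) {
    w <- valid_kmers(s, k)
    if (!nrow(w)) return(NULL)
    km <- if (ds) canonical_kmers(w$kmer) else w$kmer
    list(key = km, value = "1")
  }, engine)
  kmv <- mr_collate(kv, engine)
  out <- mr_reduce(kmv, function(keys, values) {
    counts <- lengths(values)
    keep <- counts >= min_kmer_cov
    if (!any(keep)) return(NULL)
    list(key = keys[keep], value = as.character(counts[keep]))
  }, engine, vectorized = TRUE)
  pairs <- kv_pairs(out)
  ord <- order(pairs$key, method = "radix")
  kmer_table(pairs$key[ord], as.integer(pairs$value[ord]), k = k, mode = mode,
             min_kmer_cov = min_kmer_cov, reads_skipped_short = skipped)
}

#' K-mer table constructor
#'
#' @param kmer character vector of distinct k-mers.
#' @param count positive integer abundances, same length.
#' @param k k-mer length.
#' @param mode counting mode.
#' @param min_kmer_cov abundance floor applied.
#' @param reads_skipped_short reads shorter than k that were skipped.
#' @return a `kmer_table`.
#' @export
kmer_table <- function(kmer, count, k, mode = "strand_specific",
                       min_kmer_cov = 1L, reads_skipped_short = 0L) {
  stopifnot(length(kmer) == length(count))
  structure(list(kmer = as.character(kmer), count = as.integer(count)),
            k = as.integer(k), mode = mode,
            min_kmer_cov = as.integer(min_kmer_cov),
            reads_skipped_short = as.integer(reads_skipped_short),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("<kmer_table> ", length(x$kmer), " unique ", attr(x, "k"), "-mer(s), ",
      attr(x, "mode"), " mode, total abundance ", sum(x$count), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.kmer_table <- function(x, ...) {
  data.frame(kmer = x$kmer, count = x$count, stringsAsFactors = FALSE)
}

#' Write / read a k-mer table as TSV
#'
#' Plain `kmer<TAB>count` rows sorted by k-mer, no header — the stage-wise
#' hand-off and inspection format.
#'
#' @param x a `kmer_table`.
#' @param path TSV path.
#' @return `path` (write) / a `kmer_table` (read; `mode` and `min_kmer_cov`
#'   must be re-supplied, they are not stored in the TSV).
#' @export
write_kmer_tsv <- function(x, path) {
  stopifnot(inherits(x, "kmer_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_tsv
#' @param mode,min_kmer_cov metadata to attach on read.
#' @export
read_kmer_tsv <- function(path, mode = "strand_specific", min_kmer_cov = 1L) {
  if (file.size(path) == 0)
    return(kmer_table(character(0), integer(0), k = 0L, mode = mode,
                      min_kmer_cov = min_kmer_cov))
  df <- utils::read.delim(path, header = FALSE, col.names = c("kmer", "count"),
                          colClasses = c("character", "integer"))
  ord <- order(df$kmer, method = "radix")
  kmer_table(df$kmer[ord], df$count[ord], k = nchar(df$kmer[1L]), mode = mode,
             min_kmer_cov = min_kmer_cov)
}
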