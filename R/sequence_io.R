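# FASTA/FASTQ ingest (plain or gzip), read-file sharding, contig FASTA output.
# Parsing itself is delegated to Biostrings; this layer adds format
# auto-detection, normalization to uppercase ACGTN (U -> T) and validation.

.detect_format <- function(path) {
  con <- gzfile(path, open = "rt")   # reads plain files too
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) return(NA_character_)
    if (nzchar(trimws(line))) break
  }
  first <- substr(trimws(line), 1L, 1L)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("cannot detect format of '", path,
       "': first record starts with '", first, "', expected '>' or '@'")
}

#' Read sequences from FASTA or FASTQ
#'
#' Auto-detects the format from the first record character ('>' FASTA,
#' '@' FASTQ); gzip compression is handled transparently.  Sequences are
#' uppercased, RNA U is mapped to T, and any character outside ACGTN is
#' rejected.  FASTQ qualities are parsed and discarded; multi-line FASTA is
#' concatenated.  Read ids are the header token up to the first whitespace.
#'
#' @param path input file (optionally .gz).
#' @return data.frame with columns `id` and `sequence`; zero rows (with a
#'   warning) for an empty file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgu"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- .detect_format(path)
  if (is.na(fmt)) {
    warning("empty sequence file: ", path)
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(Biostrings::readBStringSet(path, format = fmt),
                  error = function(e)
    stop("malformed ", toupper(fmt), " in '", path, "': ",
         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(chartr("u", "t", as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs) | !nzchar(seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed record '", ids[i], "' in '", path,
         "': sequence contains characters outside ACGTN (after uppercasing)")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

.wrap60 <- function(s) {
  n <- nchar(s)
  if (n <= 60L) return(s)
  starts <- seq(1L, n, by = 60L)
  paste(substring(s, starts, pmin(starts + 59L, n)), collapse = "\n")
}

.write_fasta <- function(ids, seqs, path) {
  if (!length(ids)) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(2L * length(ids))
  out[c(TRUE, FALSE)] <- paste0(">", ids)
  out[c(FALSE, TRUE)] <- vapply(seqs, .wrap60, "", USE.NAMES = FALSE)
  writeLines(out, path)
  invisible(path)
}

.write_fastq <- function(ids, seqs, path) {
  if (!length(ids)) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(4L * length(ids))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", ids)
  out[seq(2L, length(out), by = 4L)] <- seqs
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- strrep("I", nchar(seqs))
  writeLines(out, path)
  invisible(path)
}

#' Split a read file into balanced shards
#'
#' Distributes records round-robin by record index over `n_shards` output
#' files, so every read lands in exactly one shard, shard sizes differ by at
#' most one read, and record boundaries are never split.  Shards are written
#' in the input's dialect (FASTA or FASTQ; FASTQ shards carry dummy "I"
#' qualities since qualities are discarded on ingest).
#'
#' @param path input FASTA/FASTQ (optionally .gz).
#' @param n_shards number of shards (>= 1).
#' @param out_dir output directory, created if missing.
#' @return character vector of shard paths, length `n_shards`.
#' @export
split_reads <- function(path, n_shards, out_dir) {
  n_shards <- as.integer(n_shards)
  if (is.na(n_shards) || n_shards < 1L) stop("n_shards must be >= 1")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt <- .detect_format(path)
  reads <- read_sequences(path)
  ext <- if (identical(fmt, "fastq")) ".fq" else ".fa"
  base <- sub("\\.gz$", "", basename(path))
  base <- sub("\\.[^.]*$", "", base)
  paths <- file.path(out_dir, sprintf("%s.shard%03d%s", base,
                                      seq_len(n_shards) - 1L, ext))
  assign_to <- (seq_len(nrow(reads)) - 1L) %% n_shards + 1L
  for (s in seq_len(n_shards)) {
    sel <- assign_to == s
    if (identical(fmt, "fastq")) {
      .write_fastq(reads$id[sel], reads$sequence[sel], paths[s])
    } else {
      .write_fasta(reads$id[sel], reads$sequence[sel], paths[s])
    }
  }
  paths
}

#' Write contigs as FASTA
#'
#' One record per contig with header
#' `cluster<Z>_contig<i> len=<L> cov=<mean k-mer abundance, 2 decimals>`,
#' sequence wrapped at 60 columns.  Contig indices `<i>` are 0-based and
#' assigned per cluster in input order.
#'
#' @param contigs list of contigs as returned by [assemble_cluster()] /
#'   [run_pipeline()]: each a list with `sequence`, `zone`, `coverage`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  if (!length(contigs)) {
    ok <- file.create(path)
    if (!ok) stop("cannot write contig FASTA: ", path)
    return(invisible(path))
  }
  zones <- vapply(contigs, function(ct) ct$zone, 0L)
  idx <- stats::ave(zones, zones, FUN = seq_along) - 1L
  ids <- vapply(seq_along(contigs), function(i) {
    ct <- contigs[[i]]
    sprintf("cluster%d_contig%d len=%d cov=%.2f", ct$zone, idx[i],
            nchar(ct$sequence), mean(ct$coverage))
  }, "")
  seqs <- vapply(contigs, function(ct) ct$sequence, "")
  ok <- tryCatch({.write_fasta(ids, seqs, path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write contig FASTA: ", path)
  invisible(path)
}
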