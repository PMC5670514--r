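# Synthetic transcripts and reads with controlled structure, so every stage
# of the pipeline is testable without external data.  Randomness goes through
# R's standard RNG (Mersenne-Twister) seeded explicitly, which makes every
# fixture reproducible from its seed.

#' Generate random transcript sequences
#'
#' Uniform random ACGT sequences.  With `disjoint_spectra = TRUE` (the
#' interesting mode for end-to-end tests) each transcript is redrawn until it
#' contains no internal repeated k-mer and shares no k-mer with the
#' transcripts drawn before it, so the k-mer graph has exactly one linear
#' component per transcript.  This terminates quickly whenever
#' `n * length` is small against `4^k`; infeasible parameter combinations are
#' rejected up front.
#'
#' @param n number of transcripts.
#' @param length transcript length in nt (>= k).
#' @param k k-mer length the spectra refer to (default 25).
#' @param disjoint_spectra enforce pairwise-disjoint, internally
#'   repeat-free k-mer spectra (default TRUE).
#' @param seed integer RNG seed.
#' @return character vector of `n` sequences.
#' @export
generate_transcripts <- function(n, length, k = 25L, disjoint_spectra = TRUE,
                                 seed = 1L) {
  k <- as.integer(k)
  if (length < k) stop("transcript length must be >= k")
  total_kmers <- n * (length - k + 1)
  if (disjoint_spectra && total_kmers^2 > 0.25 * 4^k)
    stop("infeasible: expected k-mer collision load too high for n=", n,
         ", length=", length, ", k=", k,
         "; increase k or reduce n*length")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seen <- new.env(parent = emptyenv())
  out <- character(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(1000L)) {
      s <- paste(sample(bases, length, replace = TRUE), collapse = "")
      if (!disjoint_spectra) break
      starts <- seq_len(length - k + 1L)
      km <- substring(s, starts, starts + k - 1L)
      if (anyDuplicated(km)) next
      if (any(vapply(km, function(x) !is.null(seen[[x]]), TRUE))) next
      for (x in km) seen[[x]] <- TRUE
      break
    }
    if (attempt == 1000L && disjoint_spectra)
      stop("could not draw transcript ", i, " with a disjoint spectrum")
    out[i] <- s
  }
  out
}

#' Simulate reads from transcripts
#'
#' Reads are drawn at uniform random start positions from each transcript
#' until the target mean coverage is reached; substitution errors are applied
#' independently per base at `error_rate` (no indels).  With
#' `error_rate = 0` every read is an exact transcript substring.
#'
#' @param transcripts character vector of transcript sequences.
#' @param read_length read length (<= shortest transcript; default 100).
#' @param coverage target mean per-base coverage (default 30).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer RNG seed.
#' @return data.frame with `id` ("t<i>_r<j>") and `sequence`.
#' @export
simulate_reads <- function(transcripts, read_length = 100L, coverage = 30,
                           error_rate = 0, seed = 1L) {
  read_length <- as.integer(read_length)
  if (read_length > min(nchar(transcripts)))
    stop("read_length exceeds the shortest transcript")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out_id <- list(); out_seq <- list()
  for (i in seq_along(transcripts)) {
    tr <- transcripts[i]
    L <- nchar(tr)
    n_reads <- ceiling(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    seqs <- substring(tr, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        hit <- which(stats::runif(read_length) < error_rate)
        if (!length(hit)) return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    out_id[[i]] <- sprintf("t%d_r%d", i, seq_len(n_reads))
    out_seq[[i]] <- seqs
  }
  data.frame(id = unlist(out_id), sequence = unlist(out_seq),
             stringsAsFactors = FALSE)
}

#' Exhaustively tiling reads
#'
#' Deterministic companion to [simulate_reads()]: every start position of
#' every transcript is emitted exactly `times` times, error-free.  The k-mer
#' spectrum of the read set then equals the transcripts' spectrum exactly
#' (for any k <= read_length), which makes perfect-recovery tests
#' non-stochastic.
#'
#' @param transcripts character vector of transcript sequences.
#' @param read_length read length (default 100).
#' @param times copies of each start position (default 1).
#' @return data.frame with `id` and `sequence`.
#' @export
tile_reads <- function(transcripts, read_length = 100L, times = 1L) {
  read_length <- as.integer(read_length)
  if (read_length > min(nchar(transcripts)))
    stop("read_length exceeds the shortest transcript")
  out_id <- list(); out_seq <- list()
  for (i in seq_along(transcripts)) {
    tr <- transcripts[i]
    starts <- rep(seq_len(nchar(tr) - read_length + 1L), each = times)
    out_id[[i]] <- sprintf("t%d_p%d_c%d", i, starts - 1L,
                           rep(seq_len(times),
                               nchar(tr) - read_length + 1L))
    out_seq[[i]] <- substring(tr, starts, starts + read_length - 1L)
  }
  data.frame(id = unlist(out_id), sequence = unlist(out_seq),
             stringsAsFactors = FALSE)
}

#' Write transcripts as FASTA / reads as FASTQ
#'
#' Fixture output in standard formats: transcripts as FASTA records named
#' `transcript<i>`, reads as FASTQ with dummy "I" qualities.
#'
#' @param transcripts character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  .write_fasta(sprintf("transcript%d", seq_along(transcripts)), transcripts,
               path)
}

#' @rdname write_transcripts_fasta
#' @param reads data.frame with `id`, `sequence`.
#' @export
write_reads_fastq <- function(reads, path) {
  .write_fastq(reads$id, reads$sequence, path)
}

#' Which transcripts are recovered by a contig set?
#'
#' A transcript counts as recovered when some contig, after trimming at most
#' k-1 nt from each of its ends, is an exact substring of the transcript and
#' the matched length is at least `min_fraction` of the transcript length
#' minus the 2(k-1) nt end-truncation allowance.  Exact containment implies
#' 100% identity over the matched region; the truncation budget absorbs
#' uncovered transcript ends and short erroneous terminal k-mer chains.
#'
#' @param contigs contig list (as from [run_pipeline()]) or a character
#'   vector of contig sequences.
#' @param transcripts character vector of transcript sequences.
#' @param k k-mer length used in assembly.
#' @param min_fraction required fraction of the truncation-adjusted
#'   transcript length (default 0.99).
#' @return logical vector, one entry per transcript.
#' @export
transcript_recovery <- function(contigs, transcripts, k,
                                min_fraction = 0.99) {
  k <- as.integer(k)
  seqs <- if (is.character(contigs)) contigs
          else vapply(contigs, function(ct) ct$sequence, "")
  vapply(transcripts, function(tr) {
    need <- ceiling(min_fraction * (nchar(tr) - 2L * (k - 1L)))
    for (s in seqs) {
      if (nchar(s) < need) next
      hit <- FALSE
      for (a in 0:(k - 1L)) {
        if (nchar(s) - a < need) break
        # trim a from the left, then the smallest right trim that fits
        for (b in 0:(k - 1L)) {
          frag <- substr(s, a + 1L, nchar(s) - b)
          if (nchar(frag) < need) break
          if (grepl(frag, tr, fixed = TRUE)) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}
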