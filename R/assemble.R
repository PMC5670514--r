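# Step 5: regroup k-mers and abundances by zone and run greedy contig
# construction independently within each cluster.  Extension ranks candidates
# by node abundance (the classic greedy k-mer walk); the cluster's own k-mer
# map implicitly honours the filtered graph topology, since clustering decided
# which k-mers ended up together.

#' Group k-mers into per-zone clusters
#'
#' Two map/collate/reduce cycles, mirroring the regrouping a distributed run
#' performs: the zone assignment and the k-mer table are concatenated into one
#' store keyed by k-mer; after collating, each k-mer's (zone, abundance) pair
#' is re-emitted keyed by zone; a final collate gathers every zone's k-mer/
#' abundance list on one partition, distributing clusters across workers.
#'
#' @param zones a `zone_assignment`.
#' @param kmer_table a [kmer_table()] over the same k-mer set.
#' @param engine an [engine_config()].
#' @return list of clusters sorted by zone ID; each is a list with `zone`
#'   (integer) and `kmers` (named integer vector: k-mer -> abundance).
#' @export
group_by_zone <- function(zones, kmer_table, engine = engine_config()) {
  stopifnot(inherits(zones, "zone_assignment"),
            inherits(kmer_table, "kmer_table"))
  if (length(zones$kmer) != length(kmer_table$kmer) ||
      !setequal(zones$kmer, kmer_table$kmer))
    stop("zone assignment and k-mer table cover different k-mer sets")
  if (!length(zones$kmer)) return(list())
  batches <- list(list(kind = "zones"), list(kind = "counts"))
  kv <- mr_map(batches, function(b) {
    if (b$kind == "zones") {
      list(key = zones$kmer, value = paste0("Z", zones$zone))
    } else {
      list(key = kmer_table$kmer, value = paste0("C", kmer_table$count))
    }
  }, engine)
  kmv <- mr_collate(kv, engine)
  by_zone <- mr_reduce(kmv, function(keys, values) {
    zed <- vapply(values, function(v) {
      iz <- startsWith(v, "Z")
      if (sum(iz) != 1L || sum(!iz) != 1L)
        stop("k-mer missing zone or abundance record")
      paste0(substring(v[iz], 2L), "\t", substring(v[!iz], 2L))
    }, "")
    parts <- strsplit(zed, "\t", fixed = TRUE)
    list(key = vapply(parts, `[`, "", 1L),
         value = paste(keys, vapply(parts, `[`, "", 2L), sep = ":"))
  }, engine, vectorized = TRUE)
  grouped <- mr_collate(by_zone, engine)
  got <- kmv_pairs(grouped)
  ord <- order(as.integer(got$key))
  lapply(ord, function(i) {
    rec <- strsplit(got$values[[i]], ":", fixed = TRUE)
    kmers <- vapply(rec, `[`, "", 1L)
    counts <- as.integer(vapply(rec, `[`, "", 2L))
    o <- order(kmers, method = "radix")
    list(zone = as.integer(got$key[i]),
         kmers = stats::setNames(counts[o], kmers[o]))
  })
}

.other_orientation_lookup <- function(kmer, amap, ds) {
  # abundance of kmer in the cluster map, folding to canonical form in
  # double-stranded mode; NA if absent
  key <- if (ds) canonical_kmers(kmer) else kmer
  unname(amap[key])
}

#' Greedy extension of a seed or contig
#'
#' Repeatedly shifts the terminal k-mer of the growing sequence one base in
#' the given direction; among the <= 4 shifted candidates present in
#' `kmer_map` (and not globally used), the one with the highest abundance is
#' chosen (ties by lexicographically smallest appended base) and its new base
#' appended (3') or prepended (5').  Extension stops when no candidate exists
#' or the chosen candidate was already appended during this extension (loop
#' guard against cycles).
#'
#' @param seed sequence to extend (length >= k); its terminal k-mer should be
#'   in `kmer_map`.
#' @param kmer_map named integer vector: k-mer -> abundance (one cluster's
#'   map).
#' @param direction `"3prime"` (default) or `"5prime"`.
#' @param k k-mer length.
#' @param used optional character vector or environment of globally used
#'   k-mers to exclude as candidates.
#' @param mode `"strand_specific"` or `"double_stranded"` (candidates are
#'   looked up by canonical form).
#' @return the extended sequence.
#' @examples
#' m <- c(ACG = 10L, CGT = 8L, GTT = 5L, GTA = 2L)
#' extend_contig("ACG", m, "3prime", k = 3)  # "ACGTT"
#' @export
extend_contig <- function(seed, kmer_map, direction = c("3prime", "5prime"),
                          k, used = NULL, mode = "strand_specific") {
  direction <- match.arg(direction)
  mode <- .check_mode(mode)
  ds <- mode == "double_stranded"
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  seq <- seed
  local_used <- character(0)
  is_used <- function(km) {
    if (is.null(used)) return(FALSE)
    if (is.environment(used)) return(!is.null(used[[km]]))
    km %in% used
  }
  repeat {
    n <- nchar(seq)
    term <- if (direction == "3prime") substr(seq, n - k + 1L, n)
            else substr(seq, 1L, k)
    cand <- if (direction == "3prime") paste0(substr(term, 2L, k), bases)
            else paste0(bases, substr(term, 1L, k - 1L))
    keys <- if (ds) canonical_kmers(cand) else cand
    ab <- unname(kmer_map[keys])
    ok <- !is.na(ab) & !vapply(keys, is_used, TRUE)
    if (!any(ok)) break
    # highest abundance; ties -> lexicographically smallest appended base
    # (bases are iterated in ACGT order, which.max takes the first maximum)
    pick <- which(ok)[which.max(ab[ok])]
    chosen <- keys[pick]
    if (chosen %in% local_used) break
    local_used <- c(local_used, chosen)
    seq <- if (direction == "3prime") paste0(seq, substr(cand[pick], k, k))
           else paste0(substr(cand[pick], 1L, 1L), seq)
  }
  seq
}

# constituent k-mers of a contig, in position order (canonical in ds mode)
.contig_kmers <- function(sequence, k, ds) {
  starts <- seq_len(nchar(sequence) - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  if (ds) canonical_kmers(km) else km
}

#' Assemble one cluster into contigs
#'
#' Greedy seeding and bidirectional extension: the unused k-mer with highest
#' abundance (ties by lexicographically smallest k-mer) seeds a contig, which
#' is extended 3' then 5' through unused k-mers; all constituent k-mers are
#' then marked used, and the contig is reported if it reaches
#' `min_contig_length`.  Repeats until every k-mer has been consumed by
#' exactly one contig attempt.  Deterministic tie-breaks make the result
#' independent of the map's storage order.
#'
#' @param cluster a cluster from [group_by_zone()] (`zone` + `kmers`).
#' @param k k-mer length.
#' @param min_contig_length shortest contig reported (default 48 nt).
#' @param mode `"strand_specific"` or `"double_stranded"`.
#' @return list of contigs: each `list(sequence, zone, coverage)` where
#'   `coverage` holds the per-position constituent k-mer abundances
#'   (length `nchar(sequence) - k + 1`).
#' @export
assemble_cluster <- function(cluster, k, min_contig_length = 48L,
                             mode = "strand_specific") {
  mode <- .check_mode(mode)
  ds <- mode == "double_stranded"
  k <- as.integer(k)
  amap <- cluster$kmers
  if (!length(amap)) return(list())
  # seed order: decreasing abundance, ties by k-mer lexicographic order
  seed_order <- names(amap)[order(-amap, names(amap), method = "radix")]
  used <- new.env(parent = emptyenv(), size = length(amap))
  contigs <- list()
  for (seed in seed_order) {
    if (!is.null(used[[seed]])) next
    seq <- extend_contig(seed, amap, "3prime", k, used = used, mode = mode)
    seq <- extend_contig(seq, amap, "5prime", k, used = used, mode = mode)
    km <- .contig_kmers(seq, k, ds)
    for (x in unique(km)) used[[x]] <- TRUE
    if (nchar(seq) >= min_contig_length) {
      contigs[[length(contigs) + 1L]] <-
        list(sequence = seq, zone = as.integer(cluster$zone),
             coverage = unname(amap[km]))
    }
  }
  contigs
}

#' Run the full pipeline
#'
#' Composes all stages: read ingest, k-mer counting, edge extraction,
#' edge filtering, connected-component clustering, per-zone regrouping and
#' greedy assembly, then (optionally) contig FASTA output.  Per-step counters
#' are collected and logged.
#'
#' @param reads FASTA/FASTQ path(s) (shards are simply multiple paths), a
#'   data.frame of reads, or a character vector of sequences.
#' @param k k-mer length (default 25).
#' @param mode `"strand_specific"` (default) or `"double_stranded"`.
#' @param min_kmer_cov abundance floor for k-mers (default 1).
#' @param min_contig_length shortest contig reported (default 48 nt).
#' @param filter_rule edge filter combination rule, `"and"` or `"or"`.
#' @param engine an [engine_config()].
#' @param out optional path for the contig FASTA.
#' @param quiet suppress per-step log messages.
#' @return (invisibly) list with `contigs`, `kmer_table`, `edges`,
#'   `edges_filtered`, `zones`, `counters` (named numeric vector of per-step
#'   tallies and engine I/O).
#' @export
run_pipeline <- function(reads, k = 25L, mode = "strand_specific",
                         min_kmer_cov = 1L, min_contig_length = 48L,
                         filter_rule = "and", engine = engine_config(),
                         out = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[zoneworm] ", ...)
  reads <- .as_read_df(reads)
  say("reads: ", nrow(reads))
  kt <- count_kmers(reads, k = k, mode = mode, min_kmer_cov = min_kmer_cov,
                    engine = engine)
  say("unique k-mers: ", length(kt$kmer))
  ed <- extract_edges(reads, k = k, mode = mode, kmer_table = kt,
                      engine = engine)
  say("edges: ", nrow(ed))
  edf <- filter_edges(ed, rule = filter_rule)
  say("edges after filter: ", nrow(edf))
  zones <- find_connected_components(kt, edf, engine = engine)
  zs <- zone_summary(zones)
  say("zones: ", zones$n_zones, " (", zones$iterations_run,
      " iterations; cluster sizes min/median/max ", zs[["min_size"]], "/",
      zs[["median_size"]], "/", zs[["max_size"]], ")")
  clusters <- group_by_zone(zones, kt, engine = engine)
  contigs <- list()
  for (cl in clusters) {
    contigs <- c(contigs, assemble_cluster(cl, k = k,
                                           min_contig_length =
                                             min_contig_length, mode = mode))
  }
  say("contigs: ", length(contigs))
  cnt <- engine_counters(engine)
  say("engine: ", cnt[["pairs_emitted"]], " pairs emitted, ",
      cnt[["bytes_spilled"]], " bytes spilled in ",
      cnt[["pages_written"]], " pages")
  if (!is.null(out)) {
    write_contigs_fasta(contigs, out)
    say("wrote ", out)
  }
  .clean_spill(engine)
  invisible(list(contigs = contigs, kmer_table = kt, edges = ed,
                 edges_filtered = edf, zones = zones,
                 counters = c(n_reads = nrow(reads),
                              reads_skipped_short =
                                attr(kt, "reads_skipped_short"),
                              unique_kmers = length(kt$kmer),
                              edges_raw = nrow(ed),
                              edges_filtered = nrow(edf),
                              zones = zones$n_zones,
                              iterations = zones$iterations_run,
                              contigs = length(contigs), cnt)))
}
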