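# Step 4: connected components of the (undirected view of the) filtered
# overlap graph, by iterative zone-ID propagation expressed as map/collate/
# reduce cycles.  Every node starts in its own zone; each sweep a node adopts
# the minimum of its own zone and its neighbours' zones, so zone IDs are
# monotonically non-increasing and the iteration provably converges.  At the
# fixed point each component carries the minimum initial zone ID of its nodes.

#' Zone assignment constructor
#'
#' @param kmer character vector of node labels (sorted).
#' @param zone non-negative integer zone IDs, same length.
#' @param iterations_run sweeps performed (including the confirming one).
#' @return object of class `zone_assignment` with fields `kmer`, `zone`,
#'   `n_zones`, `iterations_run`.
#' @export
zone_assignment <- function(kmer, zone, iterations_run = 0L) {
  stopifnot(length(kmer) == length(zone))
  structure(list(kmer = as.character(kmer), zone = as.integer(zone),
                 n_zones = length(unique(zone)),
                 iterations_run = as.integer(iterations_run)),
            class = "zone_assignment")
}

#' @export
print.zone_assignment <- function(x, ...) {
  cat("<zone_assignment> ", length(x$kmer), " node(s), ", x$n_zones,
      " zone(s), ", x$iterations_run, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Initial zones: one distinct zone per node
#'
#' Zones 0..N-1 are assigned by the rank of each k-mer in lexicographic
#' order, so initialization is deterministic for a given node set.
#'
#' @param kmer_table a [kmer_table()].
#' @return a `zone_assignment` with all zones distinct.
#' @export
init_zones <- function(kmer_table) {
  stopifnot(inherits(kmer_table, "kmer_table"))
  km <- sort(kmer_table$kmer, method = "radix")
  zone_assignment(km, seq_along(km) - 1L, iterations_run = 0L)
}

#' One sweep of zone propagation
#'
#' Map emits, for every node, its own zone keyed by itself and, for every
#' edge, each endpoint's zone keyed by the *other* endpoint (both directions —
#' edge direction is ignored, connectivity is undirected).  Collate groups by
#' node; reduce assigns each node the minimum of the received zones.
#'
#' @param zones a `zone_assignment` covering all edge endpoints.
#' @param edges an `edge_table`.
#' @param engine an [engine_config()].
#' @return list with `zones` (updated `zone_assignment`) and `changed`
#'   (number of nodes whose zone decreased).
#' @export
propagate_zones_once <- function(zones, edges, engine = engine_config()) {
  stopifnot(inherits(zones, "zone_assignment"), inherits(edges, "edge_table"))
  z <- zones$zone
  names(z) <- zones$kmer
  if (nrow(edges)) {
    miss <- !(edges$source %in% zones$kmer) | !(edges$target %in% zones$kmer)
    if (any(miss))
      stop("edge endpoint missing from zone assignment: ",
           edges$source[which(miss)[1L]], " -> ",
           edges$target[which(miss)[1L]])
  }
  batches <- list(list(kind = "nodes"), list(kind = "edges"))
  kv <- mr_map(batches, function(b) {
    if (b$kind == "nodes") {
      list(key = zones$kmer, value = as.character(z))
    } else if (nrow(edges)) {
      list(key = c(edges$source, edges$target),
           value = as.character(c(z[edges$target], z[edges$source])))
    } else NULL
  }, engine)
  kmv <- mr_collate(kv, engine)
  out <- mr_reduce(kmv, function(keys, values) {
    list(key = keys,
         value = as.character(vapply(values,
                                     function(v) min(as.integer(v)), 0L)))
  }, engine, vectorized = TRUE)
  pairs <- kv_pairs(out)
  newz <- z
  newz[pairs$key] <- as.integer(pairs$value)
  changed <- sum(newz < z)
  list(zones = zone_assignment(zones$kmer, unname(newz),
                               zones$iterations_run + 1L),
       changed = as.integer(changed))
}

#' Connected components by iterated zone propagation
#'
#' Repeats [propagate_zones_once()] until a sweep changes nothing; the final
#' partition equals the connected components of the undirected graph, with
#' each component labelled by the minimum initial zone ID among its nodes.
#' Requires at most (maximum component diameter + 1) sweeps.
#'
#' @param kmer_table a [kmer_table()]: the node set.
#' @param edges an `edge_table` over those nodes (typically filtered).
#' @param engine an [engine_config()].
#' @param max_iter safety bound on sweeps (default 10000); the iteration is
#'   monotone and must converge, so exceeding this indicates a bug.
#' @return a `zone_assignment` at the fixed point.
#' @export
find_connected_components <- function(kmer_table, edges,
                                      engine = engine_config(),
                                      max_iter = 10000L) {
  if (max_iter < 1L) stop("max_iter must be >= 1")
  zones <- init_zones(kmer_table)
  if (!length(zones$kmer))
    return(zones)
  for (i in seq_len(max_iter)) {
    step <- propagate_zones_once(zones, edges, engine)
    zones <- step$zones
    if (step$changed == 0L) return(zones)
  }
  stop("zone propagation did not converge within ", max_iter,
       " iterations; this indicates an internal error")
}

#' Cluster size summary
#'
#' Number of zones and min/median/max cluster size — the balance figures that
#' matter for distributing per-cluster assembly work.
#'
#' @param zones a `zone_assignment`.
#' @return named numeric vector.
#' @export
zone_summary <- function(zones) {
  stopifnot(inherits(zones, "zone_assignment"))
  if (!length(zones$zone))
    return(c(n_zones = 0, min_size = 0, median_size = 0, max_size = 0))
  sizes <- table(zones$zone)
  c(n_zones = length(sizes), min_size = min(sizes),
    median_size = stats::median(as.numeric(sizes)), max_size = max(sizes))
}

#' Write / read a zone assignment as TSV
#'
#' Plain `kmer<TAB>zone` rows, no header.
#'
#' @param x a `zone_assignment`.
#' @param path TSV path.
#' @export
write_zone_tsv <- function(x, path) {
  stopifnot(inherits(x, "zone_assignment"))
  utils::write.table(data.frame(x$kmer, x$zone), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_zone_tsv
#' @export
read_zone_tsv <- function(path) {
  if (file.size(path) == 0)
    return(zone_assignment(character(0), integer(0)))
  df <- utils::read.delim(path, header = FALSE, col.names = c("kmer", "zone"),
                          colClasses = c("character", "integer"))
  ord <- order(df$kmer, method = "radix")
  zone_assignment(df$kmer[ord], df$zone[ord])
}
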