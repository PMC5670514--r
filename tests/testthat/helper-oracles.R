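# Independent brute-force oracles and random-input generators.  These
# deliberately avoid the package's own windowing/hashing/propagation code
# paths: plain dictionary counts, pair enumeration, and igraph components.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(s, i, i + k - 1L)
    if (!grepl("[^ACGT]", w)) out <- c(out, w)
  }
  out
}

# brute-force dictionary k-mer count
oracle_count_kmers <- function(seqs, k, mode = "strand_specific",
                               min_cov = 1L) {
  all <- unlist(lapply(seqs, oracle_windows, k = k))
  if (mode == "double_stranded" && length(all)) {
    rc <- oracle_revcomp(all)
    all <- ifelse(all <= rc, all, rc)
  }
  tab <- table(all)
  tab <- tab[tab >= min_cov]
  data.frame(kmer = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)[order(names(tab), method = "radix"), ,
                                       drop = FALSE]
}

# brute-force adjacent-pair edge enumeration (positions i, i+1 both valid)
oracle_edges <- function(seqs, k, mode = "strand_specific",
                         surviving_kmers = NULL) {
  src_all <- character(0); tgt_all <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k + 1L) next
    for (i in seq_len(n - k)) {
      a <- substr(s, i, i + k - 1L)
      b <- substr(s, i + 1L, i + k)
      if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
      if (mode == "double_stranded") {
        ra <- oracle_revcomp(a); rb <- oracle_revcomp(b)
        a <- min(a, ra); b <- min(b, rb)
      }
      src_all <- c(src_all, a); tgt_all <- c(tgt_all, b)
    }
  }
  if (!length(src_all))
    return(data.frame(source = character(0), target = character(0),
                      count = integer(0)))
  key <- paste(src_all, tgt_all, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  df <- data.frame(source = vapply(parts, `[`, "", 1L),
                   target = vapply(parts, `[`, "", 2L),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  if (!is.null(surviving_kmers))
    df <- df[df$source %in% surviving_kmers & df$target %in% surviving_kmers,
             , drop = FALSE]
  df <- df[order(df$source, df$target, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# connected-component membership oracle; returns a canonical partition label
# per node (the lexicographically smallest node of its component)
oracle_components <- function(nodes, src, tgt) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c(src, nodes), to = c(tgt, nodes)),
    directed = FALSE, vertices = data.frame(name = nodes))
  memb <- igraph::components(g)$membership[nodes]
  vapply(split(nodes, memb)[as.character(memb)], min, "")
}

# max over components of the unweighted diameter
oracle_max_diameter <- function(nodes, src, tgt) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c(src, nodes), to = c(tgt, nodes)),
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  max(vapply(seq_len(comp$no), function(i) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == i))
    igraph::diameter(sub, unconnected = FALSE)
  }, 0))
}

# canonical form of a partition for comparison: label each node by the
# smallest node sharing its class
canon_partition <- function(nodes, labels) {
  reps <- vapply(split(nodes, labels), min, "")
  unname(reps[as.character(labels)])
}

random_reads <- function(n, len = 100L, seed = 1L, with_n = TRUE,
                         homopolymer = FALSE) {
  set.seed(seed)
  alpha <- c("A", "C", "G", "T")
  reads <- vapply(seq_len(n), function(i) {
    s <- sample(alpha, len, replace = TRUE)
    if (with_n && i %% 5L == 0L)
      s[sample.int(len, 2L)] <- "N"
    if (homopolymer && i %% 3L == 0L) {
      p <- sample.int(len - 8L, 1L)
      s[p:(p + 7L)] <- "A"
    }
    paste(s, collapse = "")
  }, "")
  reads
}

# random directed graph as an edge_table over arbitrary distinct labels
random_edge_graph <- function(n_nodes, n_edges, seed = 1L, max_ce = 9L) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pick <- unique(data.frame(
    source = nodes[sample.int(n_nodes, n_edges, replace = TRUE)],
    target = nodes[sample.int(n_nodes, n_edges, replace = TRUE)],
    stringsAsFactors = FALSE))
  edge_table(pick$source, pick$target,
             sample.int(max_ce, nrow(pick), replace = TRUE))
}

fake_kmer_table <- function(nodes) {
  ord <- order(nodes, method = "radix")
  kmer_table(nodes[ord], rep(1L, length(nodes)), k = nchar(nodes[1L]))
}

tiny_engine <- function(...) engine_config(..., spill_dir = tempfile("sp"))
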