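# Per-zone regrouping and greedy contig construction.

test_that("group_by_zone partitions the k-mer table by zone", {
  kt <- kmer_table(c("AAA", "CCC", "GGG", "TTT", "ACG"),
                   c(5L, 4L, 3L, 2L, 1L), k = 3L)
  z <- zone_assignment(sort(kt$kmer), c(0L, 0L, 0L, 3L, 3L))
  cl <- group_by_zone(z, kt, tiny_engine(n_workers = 3))
  expect_length(cl, 2L)
  expect_equal(vapply(cl, function(x) x$zone, 0L), c(0L, 3L))
  expect_equal(sum(lengths(lapply(cl, `[[`, "kmers"))), 5L)
  # union of cluster maps reproduces the table exactly
  all_k <- unlist(lapply(cl, function(x) names(x$kmers)))
  all_c <- unlist(lapply(cl, function(x) unname(x$kmers)))
  ord <- order(all_k)
  expect_equal(all_k[ord], sort(kt$kmer))
  expect_equal(all_c[ord], kt$count[match(all_k[ord], kt$kmer)])

  single <- group_by_zone(zone_assignment(sort(kt$kmer), rep(0L, 5)), kt,
                          tiny_engine())
  expect_length(single, 1L)
  expect_equal(length(single[[1]]$kmers), 5L)

  bad <- zone_assignment(c("AAA", "CCC"), c(0L, 1L))
  expect_error(group_by_zone(bad, kt, tiny_engine()), "different k-mer sets")
})

test_that("cluster memberships agree with the components oracle end to end", {
  reads <- c(tile_reads(generate_transcripts(3, 80, k = 9, seed = 21),
                        read_length = 30)$sequence)
  kt <- count_kmers(reads, k = 9, engine = tiny_engine())
  ed <- filter_edges(extract_edges(reads, k = 9, kmer_table = kt,
                                   engine = tiny_engine()))
  z <- find_connected_components(kt, ed, tiny_engine())
  cl <- group_by_zone(z, kt, tiny_engine())
  want <- oracle_components(z$kmer, ed$source, ed$target)
  for (x in cl) {
    members <- names(x$kmers)
    expect_equal(length(unique(want[match(members, z$kmer)])), 1L)
  }
  expect_equal(length(cl), length(unique(want)))
})

test_that("greedy extension follows highest abundance with loop guard", {
  m <- c(ACG = 10L, CGT = 8L, GTT = 5L, GTA = 2L)
  expect_equal(extend_contig("ACG", m, "3prime", k = 3), "ACGTT")
  expect_equal(extend_contig("GTA", m, "5prime", k = 3), "ACGTA")
  expect_equal(extend_contig("ACG", c(ACG = 1L), "3prime", k = 3), "ACG")
  # loop guard: a self-overlapping k-mer extends exactly once
  expect_equal(extend_contig("AAA", c(AAA = 9L), "3prime", k = 3), "AAAA")
  # tie on abundance -> lexicographically smallest appended base
  tie <- c(ACG = 5L, CGA = 3L, CGT = 3L)
  expect_equal(extend_contig("ACG", tie, "3prime", k = 3), "ACGA")
  # globally used k-mers are not candidates
  expect_equal(extend_contig("ACG", m, "3prime", k = 3, used = "CGT"), "ACG")
})

test_that("assemble_cluster consumes every k-mer exactly once", {
  cl <- list(zone = 0L, kmers = c(ACG = 10L, CGT = 8L, GTT = 5L, GTA = 2L))
  got <- assemble_cluster(cl, k = 3, min_contig_length = 3)
  expect_equal(vapply(got, function(ct) ct$sequence, ""), c("ACGTT", "GTA"))
  expect_equal(got[[1]]$coverage, c(10, 8, 5))
  expect_equal(got[[2]]$coverage, 2)
  # single k-mer cluster (no self-overlap: no extension possible)
  one <- assemble_cluster(list(zone = 2L, kmers = c(GAC = 4L)), k = 3,
                          min_contig_length = 3)
  expect_equal(one[[1]]$sequence, "GAC")
  expect_equal(one[[1]]$zone, 2L)
  # min_contig_length suppresses short output but still consumes k-mers
  none <- assemble_cluster(cl, k = 3, min_contig_length = 10)
  expect_length(none, 0L)
})

test_that("an unbranched chain reassembles into exactly one contig", {
  tr <- generate_transcripts(1, 40, k = 11, seed = 5)
  km <- oracle_windows(tr, 11)
  cl <- list(zone = 0L, kmers = stats::setNames(rep(7L, length(km)), km))
  got <- assemble_cluster(cl, k = 11, min_contig_length = 11)
  expect_length(got, 1L)
  expect_equal(got[[1]]$sequence, tr)
  expect_equal(length(got[[1]]$coverage), nchar(tr) - 11L + 1L)
})

test_that("assembly output is invariant to kmer_map storage order", {
  tr <- generate_transcripts(1, 60, k = 7, seed = 9)
  km <- oracle_windows(tr, 7)
  counts <- stats::setNames(sample.int(20, length(km), TRUE), km)
  a <- assemble_cluster(list(zone = 0L, kmers = counts), k = 7,
                        min_contig_length = 7)
  sh <- sample(length(counts))
  b <- assemble_cluster(list(zone = 0L, kmers = counts[sh]), k = 7,
                        min_contig_length = 7)
  expect_equal(a, b)
})

test_that("contig k-mers stay within their cluster, each used at most once", {
  reads <- random_reads(40, 60, seed = 123, with_n = FALSE)
  kt <- count_kmers(reads, k = 9, engine = tiny_engine())
  ed <- filter_edges(extract_edges(reads, k = 9, kmer_table = kt,
                                   engine = tiny_engine()))
  z <- find_connected_components(kt, ed, tiny_engine())
  for (cl in group_by_zone(z, kt, tiny_engine())) {
    contigs <- assemble_cluster(cl, k = 9, min_contig_length = 9)
    used <- unlist(lapply(contigs, function(ct) {
      starts <- seq_len(nchar(ct$sequence) - 9L + 1L)
      substring(ct$sequence, starts, starts + 8L)
    }))
    per_contig_unique <- unlist(lapply(contigs, function(ct) {
      starts <- seq_len(nchar(ct$sequence) - 9L + 1L)
      unique(substring(ct$sequence, starts, starts + 8L))
    }))
    expect_true(all(used %in% names(cl$kmers)))
    expect_false(anyDuplicated(per_contig_unique) > 0)
  }
})

test_that("run_pipeline reconstructs single and disjoint transcripts", {
  tr <- generate_transcripts(1, 100, k = 25, seed = 31)
  reads <- tile_reads(tr, read_length = 50)
  res <- run_pipeline(reads, k = 25, quiet = TRUE, engine = tiny_engine())
  expect_equal(res$zones$n_zones, 1L)
  expect_length(res$contigs, 1L)
  expect_equal(res$contigs[[1]]$sequence, tr)

  tr2 <- generate_transcripts(2, 120, k = 25, seed = 32)
  res2 <- run_pipeline(tile_reads(tr2, read_length = 60), k = 25,
                       quiet = TRUE, engine = tiny_engine())
  expect_equal(res2$zones$n_zones, 2L)
  expect_setequal(vapply(res2$contigs, function(ct) ct$sequence, ""), tr2)
})

test_that("an empty read file flows through to an empty FASTA", {
  empty <- tempfile(fileext = ".fq")
  file.create(empty)
  out <- tempfile(fileext = ".fa")
  res <- suppressWarnings(run_pipeline(empty, k = 25, quiet = TRUE,
                                       engine = tiny_engine(), out = out))
  expect_equal(unname(res$counters["unique_kmers"]), 0)
  expect_equal(unname(res$counters["contigs"]), 0)
  expect_equal(file.size(out), 0)
})

test_that("double-stranded pipeline reconstructs a transcript up to strand", {
  tr <- generate_transcripts(1, 90, k = 15, seed = 41)
  reads <- tile_reads(tr, read_length = 45)
  # flip half the reads to the other strand
  flip <- seq_len(nrow(reads)) %% 2 == 0
  reads$sequence[flip] <- oracle_revcomp(reads$sequence[flip])
  res <- run_pipeline(reads, k = 15, mode = "double_stranded", quiet = TRUE,
                      engine = tiny_engine())
  expect_equal(res$zones$n_zones, 1L)
  best <- res$contigs[[which.max(vapply(res$contigs,
                                        function(ct) nchar(ct$sequence), 0))]]
  expect_true(best$sequence == tr || oracle_revcomp(best$sequence) == tr)
})
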