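# Connected components by min-label zone propagation, against igraph.

test_that("init_zones ranks nodes lexicographically with distinct zones", {
  kt <- fake_kmer_table(c("CGT", "ACG"))
  z <- init_zones(kt)
  expect_equal(z$kmer, c("ACG", "CGT"))
  expect_equal(z$zone, c(0L, 1L))
  expect_equal(init_zones(fake_kmer_table(character(0)))$n_zones, 0L)
  n <- 20
  z <- init_zones(fake_kmer_table(sprintf("x%02d", sample(n))))
  expect_equal(sort(z$zone), 0:(n - 1))
})

test_that("one sweep propagates one neighbour layer", {
  kt <- fake_kmer_table(c("A", "B", "C"))
  z0 <- init_zones(kt)                        # A:0 B:1 C:2
  ed <- edge_table(c("A", "B"), c("B", "C"), c(1L, 1L))
  step <- propagate_zones_once(z0, ed, tiny_engine())
  expect_equal(step$zones$zone, c(0L, 0L, 1L))
  expect_equal(step$changed, 2L)
  # fixed point: converged state reports changed = 0 and is unchanged
  z <- find_connected_components(kt, ed, tiny_engine())
  again <- propagate_zones_once(z, ed, tiny_engine())
  expect_equal(again$changed, 0L)
  expect_equal(again$zones$zone, z$zone)
})

test_that("isolated nodes keep their zone; missing endpoints are fatal", {
  kt <- fake_kmer_table(c("A", "B", "Z"))
  ed <- edge_table("A", "B", 1L)
  z <- find_connected_components(kt, ed, tiny_engine())
  expect_equal(z$zone[z$kmer == "Z"], 2L)
  expect_equal(z$n_zones, 2L)
  bad <- edge_table("A", "Q", 1L)
  expect_error(propagate_zones_once(init_zones(kt), bad, tiny_engine()),
               "missing")
})

test_that("no edges yields one singleton zone per node", {
  kt <- fake_kmer_table(sprintf("n%02d", 1:15))
  z <- find_connected_components(
    kt, edge_table(character(0), character(0), integer(0)), tiny_engine())
  expect_equal(z$n_zones, 15L)
  expect_equal(z$iterations_run, 1L)  # single confirming sweep
})

test_that("random graphs match the igraph components oracle", {
  for (i in 1:15) {
    set.seed(600 + i)
    n <- sample(20:120, 1)
    p <- 1.2 / n
    nodes <- sprintf("v%03d", seq_len(n))
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- stats::runif(nrow(pair)) < p
    src <- nodes[pair[on, 1]]; tgt <- nodes[pair[on, 2]]
    kt <- fake_kmer_table(nodes)
    ed <- edge_table(src, tgt, rep(1L, length(src)))
    z <- find_connected_components(kt, ed, tiny_engine(n_workers = 2))
    got <- canon_partition(z$kmer, z$zone)
    want <- oracle_components(z$kmer, src, tgt)
    expect_identical(got, unname(want))
    # iteration bound: at most max component diameter + 1 sweeps
    expect_lte(z$iterations_run, oracle_max_diameter(nodes, src, tgt) + 1)
    # each component's final zone is the minimum initial zone of its members
    init <- init_zones(kt)
    for (zz in unique(z$zone)) {
      members <- z$kmer[z$zone == zz]
      expect_equal(zz, min(init$zone[init$kmer %in% members]))
    }
  }
})

test_that("path, star and cycle families resolve to single components", {
  eng <- tiny_engine()
  n <- 40
  nodes <- sprintf("m%02d", seq_len(n))
  kt <- fake_kmer_table(nodes)
  path <- edge_table(nodes[-n], nodes[-1], rep(1L, n - 1))
  z <- find_connected_components(kt, path, eng)
  expect_equal(z$n_zones, 1L)
  expect_lte(z$iterations_run, n)      # <= diameter + 1 = n
  star <- edge_table(rep(nodes[1], n - 1), nodes[-1], rep(1L, n - 1))
  z <- find_connected_components(kt, star, eng)
  expect_equal(z$n_zones, 1L)
  expect_lte(z$iterations_run, 3L)     # diameter 2
  cycle <- edge_table(nodes, c(nodes[-1], nodes[1]), rep(1L, n))
  z <- find_connected_components(kt, cycle, eng)
  expect_equal(z$n_zones, 1L)
  expect_lte(z$iterations_run, n %/% 2 + 2L)
})

test_that("zone sum strictly decreases until convergence (monotonicity)", {
  set.seed(88)
  n <- 30
  nodes <- sprintf("q%02d", seq_len(n))
  kt <- fake_kmer_table(nodes)
  ed <- edge_table(nodes[-n], nodes[-1], rep(1L, n - 1))
  z <- init_zones(kt)
  prev_sum <- sum(z$zone)
  repeat {
    step <- propagate_zones_once(z, ed, tiny_engine())
    if (step$changed == 0L) {
      expect_equal(sum(step$zones$zone), prev_sum)
      break
    }
    expect_true(all(step$zones$zone <= z$zone))   # per-node monotone
    expect_lt(sum(step$zones$zone), prev_sum)
    prev_sum <- sum(step$zones$zone)
    z <- step$zones
  }
})

test_that("final partition is invariant to edge order and worker count", {
  set.seed(17)
  nodes <- sprintf("w%02d", 1:40)
  src <- nodes[sample.int(40, 50, TRUE)]
  tgt <- nodes[sample.int(40, 50, TRUE)]
  dup <- duplicated(paste(src, tgt))
  src <- src[!dup]; tgt <- tgt[!dup]
  kt <- fake_kmer_table(nodes)
  z1 <- find_connected_components(kt, edge_table(src, tgt,
                                                 rep(1L, length(src))),
                                  tiny_engine(n_workers = 1))
  perm <- sample(length(src))
  z2 <- find_connected_components(kt, edge_table(src[perm], tgt[perm],
                                                 rep(1L, length(src))),
                                  tiny_engine(n_workers = 5,
                                              pagesize = 4096))
  expect_identical(z1$zone, z2$zone)
})

test_that("zone TSV round-trips and zone_summary reports sizes", {
  z <- zone_assignment(c("AAA", "CCC", "GGG"), c(0L, 0L, 2L))
  path <- tempfile(fileext = ".tsv")
  write_zone_tsv(z, path)
  back <- read_zone_tsv(path)
  expect_equal(back$kmer, z$kmer)
  expect_equal(back$zone, z$zone)
  s <- zone_summary(z)
  expect_equal(unname(s[c("n_zones", "min_size", "max_size")]), c(2, 1, 2))
})
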