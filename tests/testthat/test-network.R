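mk_records <- function(...) {
  rows <- list(...)
  data.frame(gene_a = vapply(rows, `[[`, "", 1),
             gene_b = vapply(rows, `[[`, "", 2),
             relation = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

eq_clique <- function(genes) {
  pairs <- t(combn(genes, 2))
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             relation = "EQUIVALENT", stringsAsFactors = FALSE)
}

test_that("buildBIN stores nodes, canonical edges, rejects conflicts", {
  bin <- buildBIN(NULL, genes = c("a", "b", "c"))
  expect_identical(binNodes(bin), c("a", "b", "c"))
  expect_identical(nrow(binEdges(bin)), 0L)
  bin2 <- buildBIN(mk_records(c("z", "a", "EQUIVALENT")))
  expect_identical(binEdges(bin2)$gene_a, "a")   # canonicalized
  # both directions of one asymmetric relation are consistent
  ok <- buildBIN(mk_records(c("a", "b", "HIGH_HIGH"),
                            c("b", "a", "LOW_LOW")))
  expect_identical(nrow(binEdges(ok)), 2L)
  expect_error(buildBIN(mk_records(c("a", "b", "HIGH_HIGH"),
                                   c("b", "a", "HIGH_HIGH"))),
               "conflicting")
  d <- tiny_planted(seed = 3, n = 400, sizes = c(4, 4))
  recs <- run_discovery(d$expr, "network")$records
  bin3 <- buildBIN(recs)
  expect_identical(sort(binNodes(bin3)),
                   sort(unique(c(recs$gene_a, recs$gene_b))))
})

test_that("jaccardSimilarity uses closed equivalence neighborhoods", {
  # N[u] = {u,v,a,b}, N[v] = {u,v,a,c} -> 3/5
  bin <- buildBIN(mk_records(c("u", "v", "EQUIVALENT"),
                             c("a", "u", "EQUIVALENT"),
                             c("b", "u", "EQUIVALENT"),
                             c("a", "v", "EQUIVALENT"),
                             c("c", "v", "EQUIVALENT")))
  expect_equal(jaccardSimilarity("u", "v", bin), 3 / 5)
  # mutually equivalent pendant pair: identical closed neighborhoods
  bin2 <- buildBIN(mk_records(c("p", "q", "EQUIVALENT")))
  expect_equal(jaccardSimilarity("p", "q", bin2), 1)
  # no shared neighbors, no mutual edge
  bin3 <- buildBIN(mk_records(c("a", "b", "EQUIVALENT"),
                              c("c", "d", "EQUIVALENT")))
  expect_equal(jaccardSimilarity("a", "c", bin3), 0)
  expect_error(jaccardSimilarity("a", "a", bin3), "differ")
})

test_that("clusterEquivalences keeps cliques and cuts weak bridges", {
  # one 4-clique, pairwise jaccard 1 -> single cluster
  bin <- buildBIN(eq_clique(c("a1", "a2", "a3", "a4")))
  cb <- clusterEquivalences(bin)
  expect_identical(unname(geneClusters(cb)),
                   list(c("a1", "a2", "a3", "a4")))
  # two 4-cliques joined by one bridge (jaccard 2/8 < 0.7) -> two clusters
  recs <- rbind(eq_clique(paste0("a", 1:4)), eq_clique(paste0("b", 1:4)),
                mk_records(c("a1", "b1", "EQUIVALENT")))
  cb2 <- clusterEquivalences(buildBIN(recs))
  expect_identical(unname(geneClusters(cb2)),
                   list(paste0("a", 1:4), paste0("b", 1:4)))
  # isolated gene becomes its own representative
  cb3 <- clusterEquivalences(buildBIN(NULL, genes = "solo"))
  expect_identical(unname(representatives(cb3)), "solo")
})

test_that("raising jaccard_min only refines the partition", {
  set.seed(77)
  genes <- sprintf("g%02d", 1:14)
  pairs <- t(combn(genes, 2))
  take <- sample(nrow(pairs), 30)
  recs <- data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                     relation = "EQUIVALENT", stringsAsFactors = FALSE)
  bin <- buildBIN(recs)
  coarse <- geneClusters(clusterEquivalences(bin, clusterParams(jaccard_min = 0.2)))
  fine <- geneClusters(clusterEquivalences(bin, clusterParams(jaccard_min = 0.8)))
  for (cl in fine) {
    container <- vapply(coarse, function(big) all(cl %in% big), logical(1))
    expect_identical(sum(container), 1L)
  }
})

test_that("non-forest equivalence edges do not change the clustering", {
  # a 4-cycle plus a chord: dropping the chord leaves the same components
  recs <- mk_records(c("a", "b", "EQUIVALENT"), c("b", "c", "EQUIVALENT"),
                     c("c", "d", "EQUIVALENT"), c("a", "d", "EQUIVALENT"),
                     c("a", "c", "EQUIVALENT"))
  p <- clusterParams(jaccard_min = 0.3)
  full <- geneClusters(clusterEquivalences(buildBIN(recs), p))
  nochord <- geneClusters(clusterEquivalences(buildBIN(recs[1:4, ]), p))
  expect_identical(full, nochord)
})

test_that("linkClusters emits an edge only on an overwhelming majority", {
  recs <- rbind(eq_clique(c("a1", "a2")), eq_clique(paste0("b", 1:6)))
  clusters_only <- function(extra) {
    bin <- buildBIN(rbind(recs, extra))
    cb <- clusterEquivalences(bin)
    linkClusters(cb, bin, clusterParams(rng_seed = 4))
  }
  # all six pairs agree -> typed edge A -> B
  all6 <- do.call(mk_records, lapply(paste0("b", 1:6), function(b)
    c("a1", b, "HIGH_HIGH")))
  ed <- clusterEdges(clusters_only(all6))
  got <- ed[ed$cluster_a == "C01" & ed$cluster_b == "C02", ]
  expect_identical(got$relation, "HIGH_HIGH")
  expect_identical(got$support, 6L)
  # three of six below the 2/3 majority -> no edge
  three <- do.call(mk_records, lapply(paste0("b", 1:3), function(b)
    c("a1", b, "HIGH_HIGH")))
  ed2 <- clusterEdges(clusters_only(three))
  expect_false(any(ed2$cluster_a == "C01" & ed2$cluster_b == "C02"))
})

test_that("clustering and linking are bit-identical under a fixed seed", {
  d <- tiny_planted(seed = 19)
  recs <- run_discovery(d$expr, "network")$records
  bin <- buildBIN(recs)
  p <- clusterParams(rng_seed = 99)
  run <- function() {
    cb <- clusterEquivalences(bin, p)
    clusterEdges(linkClusters(cb, bin, p))
  }
  expect_identical(run(), run())
})

test_that("chartPaths enumerates simple paths like the DFS oracle", {
  edges <- data.frame(
    cluster_a = c("A", "B"), cluster_b = c("B", "C"),
    relation = c("HIGH_HIGH", "HIGH_LOW"),
    support = 6L, sampled = 6L, stringsAsFactors = FALSE)
  cb <- new("ClusteredBooleanNetwork",
            clusters = list(A = "g1", B = "g2", C = "g3"),
            representatives = c(A = "g1", B = "g2", C = "g3"),
            edges = edges)
  paths <- chartPaths(cb, "A", max_len = 2)
  expect_identical(lapply(paths, `[[`, "clusters"),
                   list(c("A", "B"), c("A", "B", "C")))
  expect_identical(paths[[2]]$relations, c("HIGH_HIGH", "HIGH_LOW"))
  expect_identical(paths[[2]]$weights, c(1, 1, 1))
  # single edge -> one length-1 path
  expect_length(chartPaths(cb, "B", max_len = 3), 1L)
  expect_error(chartPaths(cb, "Z"), "unknown seed")
  # planted 5-cluster DAG vs brute-force enumeration
  set.seed(55)
  ids <- LETTERS[1:5]
  all_pairs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$a < all_pairs$b, ]
  pick <- all_pairs[runif(nrow(all_pairs)) < 0.6, ]
  ed5 <- data.frame(cluster_a = pick$a, cluster_b = pick$b,
                    relation = "HIGH_HIGH", support = 6L, sampled = 6L,
                    stringsAsFactors = FALSE)
  cb5 <- new("ClusteredBooleanNetwork",
             clusters = setNames(as.list(paste0("g", 1:5)), ids),
             representatives = setNames(paste0("g", 1:5), ids),
             edges = ed5)
  for (ml in 1:4) {
    got <- lapply(chartPaths(cb5, "A", max_len = ml), `[[`, "clusters")
    expect_identical(got, oracle_paths(ed5, "A", ml))
  }
  got_end <- lapply(chartPaths(cb5, "A", end_cluster = "E", max_len = 4),
                    `[[`, "clusters")
  expect_identical(got_end, oracle_paths(ed5, "A", 4, end = "E"))
})

test_that("planted three-cluster chain is recovered end to end", {
  d <- tiny_planted(seed = 101)
  res <- run_discovery(d$expr, "network")
  bin <- buildBIN(res$records)
  cb <- linkClusters(clusterEquivalences(bin), bin, clusterParams(rng_seed = 101))
  planted <- lapply(split(names(d$truth$gene_cluster), d$truth$gene_cluster),
                    sort)
  expect_identical(unname(lapply(geneClusters(cb), sort)), unname(planted))
  ed <- clusterEdges(cb)
  expect_true(any(ed$cluster_a == "C01" & ed$cluster_b == "C02" &
                    ed$relation == "HIGH_HIGH"))
  expect_true(any(ed$cluster_a == "C02" & ed$cluster_b == "C03" &
                    ed$relation == "HIGH_LOW"))
})
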