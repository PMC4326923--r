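test_that("edge decisions follow the signed Pearson threshold", {
  x <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 4, 6, 8, 10),      # identical direction: r = 1
             c = c(5, 4, 3, 2, 1),       # anti-correlated: r = -1
             d = c(2, 2, 2, 2, 2))       # zero variance
  colnames(x) <- paste0("s", 1:5)
  net <- buildNetwork(x, rThreshold = 0.95)
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$gene_a, e$gene_b), c("a", "b"))
  expect_equal(e$r, 1, tolerance = 1e-12)
  expect_identical(net@excludedGenes, "d")
  # flipping a gene's sign redirects its edges to anti-correlated partners
  x2 <- x; x2["a", ] <- 100 - 7 * x["a", ]
  e2 <- networkEdges(buildNetwork(x2, rThreshold = 0.95))
  expect_identical(nrow(e2), 1L)
  expect_setequal(c(e2$gene_a, e2$gene_b), c("a", "c"))
  # positive affine rescaling leaves edge decisions unchanged
  x3 <- x; x3["a", ] <- 100 + 7 * x["a", ]
  e3 <- networkEdges(buildNetwork(x3, rThreshold = 0.95))
  expect_identical(e3[c("gene_a", "gene_b")], e[c("gene_a", "gene_b")])
  expect_equal(e3$r, e$r, tolerance = 1e-9)
})

test_that("thresholded edges match a naive double-loop oracle exactly", {
  set.seed(60)
  nG <- 50
  x <- matrix(rnorm(nG * 8), nrow = nG,
              dimnames = list(sprintf("g%02d", 1:nG), paste0("s", 1:8)))
  x[2, ] <- x[1, ] + rnorm(8, sd = 0.05)
  x[5, ] <- x[4, ] * 2 + rnorm(8, sd = 0.05)
  thr <- 0.6
  net <- buildNetwork(x, rThreshold = thr, blockSize = 7L)  # force tiling
  got <- networkEdges(net)
  want <- list()
  for (i in 1:(nG - 1)) for (j in (i + 1):nG) {
    r <- cor(x[i, ], x[j, ])
    if (r >= thr) want[[length(want) + 1L]] <-
        data.frame(gene_a = rownames(x)[i], gene_b = rownames(x)[j], r = r)
  }
  want <- do.call(rbind, want)
  ord <- order(got$gene_a, got$gene_b)
  expect_identical(got$gene_a[ord], want$gene_a)
  expect_identical(got$gene_b[ord], want$gene_b)
  expect_equal(got$r[ord], want$r, tolerance = 1e-12)
})

test_that("raising the threshold never adds edges", {
  set.seed(61)
  x <- matrix(rnorm(30 * 6), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  eLoose <- networkEdges(buildNetwork(x, rThreshold = 0.3))
  eTight <- networkEdges(buildNetwork(x, rThreshold = 0.7))
  keyL <- paste(eLoose$gene_a, eLoose$gene_b)
  keyT <- paste(eTight$gene_a, eTight$gene_b)
  expect_true(all(keyT %in% keyL))
  expect_gte(nrow(eLoose), nrow(eTight))
})

test_that("hub identification handles stars and ties", {
  # deterministic star: center at exact r = 0.96 with 5 satellites, so
  # satellite pairs sit at exactly 0.96^2 = 0.9216 < 0.95
  set.seed(62)
  n <- 8
  M <- scale(matrix(rnorm(n * 6), n), scale = FALSE)
  Q <- qr.Q(qr(M))                       # orthonormal, zero-mean columns
  a <- 0.96
  x <- t(cbind(Q[, 1],
               sapply(2:6, function(i) a * Q[, 1] + sqrt(1 - a^2) * Q[, i])))
  rownames(x) <- c("hub", paste0("sat", 1:5))
  colnames(x) <- paste0("s", 1:n)
  net <- buildNetwork(x, rThreshold = 0.95)
  rep <- hubReport(net)
  expect_identical(rep$hub, "hub")
  expect_identical(rep$degree, 5L)
  expect_identical(rep$neighborhoodNodes, 6L)
  expect_gte(rep$neighborhoodEdges, 5L)

  # two tied nodes: lexicographically smaller id wins, both reported
  xt <- rbind(aa = c(1, 2, 3, 4), ab = c(1, 2, 3, 4), zz = c(4, 3, 2, 1))
  colnames(xt) <- paste0("s", 1:4)
  nt <- buildNetwork(xt, rThreshold = 0.95)
  rt <- hubReport(nt)
  expect_identical(rt$hub, "aa")
  expect_setequal(rt$ties, c("aa", "ab"))
})

test_that("components match a union-find oracle and sort by size", {
  set.seed(63)
  nG <- 40
  x <- matrix(rnorm(nG * 6), nrow = nG,
              dimnames = list(sprintf("g%02d", 1:nG), paste0("s", 1:6)))
  net <- buildNetwork(x, rThreshold = 0.5)
  comps <- networkComponents(net)
  oracle <- unionFindComponents(networkNodes(net), networkEdges(net))
  expect_identical(comps, oracle)

  # two disjoint triangles
  tri <- function(base) rbind(base, base + rnorm(6, sd = 1e-3),
                              base + rnorm(6, sd = 1e-3))
  xt <- rbind(tri(seq(1, 6)), tri(c(2, 0, 5, 1, 4, 3)))
  rownames(xt) <- paste0("t", 1:6); colnames(xt) <- paste0("s", 1:6)
  ct <- networkComponents(buildNetwork(xt, rThreshold = 0.95))
  expect_identical(lengths(ct), c(3L, 3L))

  # no edges -> no nodes -> empty component list
  xe <- matrix(c(1, 2, 3, 4, 3, 1, 4, 2, 2, 4, 1, 3), nrow = 3,
               dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_identical(networkComponents(buildNetwork(xe, rThreshold = 0.99)),
                   list())
})

test_that("age-stratified networks are identical for identical strata", {
  # same per-age value block repeated at every age
  block <- matrix(rnorm(10 * 5), nrow = 10)
  vals <- cbind(block, block, block)
  rownames(vals) <- sprintf("g%02d", 1:10)
  colnames(vals) <- sprintf("s%02d", 1:15)
  ae <- valueExperiment(vals, ages = rep(c(5, 20, 39), each = 5))
  strat <- ageStratifiedNetworks(ae, rThreshold = 0.6)
  expect_identical(names(strat$networks), c("5", "20", "39"))
  expect_true(all(strat$jaccard == 1))

  # independent noise strata: jaccard near the null edge-density level
  set.seed(64)
  vals2 <- matrix(rnorm(40 * 15), nrow = 40,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("s%02d", 1:15)))
  ae2 <- valueExperiment(vals2, ages = rep(c(5, 20, 39), each = 5))
  strat2 <- ageStratifiedNetworks(ae2, rThreshold = 0.9)
  off <- strat2$jaccard[upper.tri(strat2$jaccard)]
  expect_true(all(off < 0.2))

  # cluster-label composition is tabulated per component
  labels <- setNames(rep(c("c1", "c2"), each = 5), rownames(vals))
  strat3 <- ageStratifiedNetworks(ae, rThreshold = 0.6,
                                  clusterLabels = labels)
  expect_identical(names(strat3$composition), c("5", "20", "39"))
})

test_that("graphs round-trip through the TSV edge list and GraphML", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 4), c = c(1, 2.1, 3, 4),
             d = c(4, 3, 2, 1), e = c(4, 3, 2.2, 1.2))
  colnames(x) <- paste0("s", 1:4)
  net <- buildNetwork(x, rThreshold = 0.9)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "edges.tsv"); gml <- file.path(dir, "net.graphml")
  writeGraph(net, graphmlFile = gml, tsvFile = tsv)
  back <- readGraphTsv(tsv)
  expect_setequal(igraph::V(back)$name, networkNodes(net))
  expect_identical(igraph::gsize(back), igraph::gsize(networkGraph(net)))
  gml2 <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::gsize(gml2), igraph::gsize(networkGraph(net)))
})
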