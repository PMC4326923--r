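test_that("hypergeometric p-values match exhaustive enumeration", {
  # N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 5/210
  sets <- list(S = paste0("g", 1:5))
  bg <- paste0("g", 1:10)
  res <- hypergeomEnrich(paste0("g", c(1:4)), sets, bg)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, enumHyperUpper(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(res$fold, (4 / 4) / (5 / 10))

  # enumeration agreement on an assortment of small urns
  for (prm in list(c(8, 3, 4, 2), c(12, 6, 5, 3), c(15, 7, 6, 1))) {
    N <- prm[1]; K <- prm[2]; n <- prm[3]; k <- prm[4]
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p, enumHyperUpper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment edge cases: saturated queries, skips, validation", {
  bg <- paste0("g", 1:20)
  sets <- list(A = bg[1:8], B = c("x1", "x2"), C = bg[9:10])
  res <- hypergeomEnrich(bg, sets, bg)       # query = background
  expect_equal(res$p, rep(1, 2))
  expect_equal(res$fold, rep(1, 2))
  expect_identical(attr(res, "skipped"), "B")
  # k at its expectation gives fold exactly 1
  res2 <- hypergeomEnrich(bg[seq(1, 20, by = 2)], list(A = bg[1:8]), bg)
  expect_equal(res2$fold, 1)
  expect_error(hypergeomEnrich(character(), sets, bg), "empty")
  expect_error(hypergeomEnrich("zz", sets, bg), "missing from background")
  # monotonicity: more overlap can only lower the p-value
  p <- sapply(0:5, function(k) stats::phyper(k - 1, 5, 15, 5,
                                             lower.tail = FALSE))
  expect_true(all(diff(p) < 0))
})

test_that("Fisher 2x2 matches enumeration and the reference implementation", {
  expect_equal(fisherExact2x2(rbind(c(4, 0), c(0, 4))), 2 / 70,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(rbind(c(3, 6), c(2, 4))), 1)  # equal proportions
  expect_equal(fisherExact2x2(rbind(c(0, 0), c(3, 4))), 1)  # zero margin
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  # one-sided upper tail equals the hypergeometric urn p-value
  tab <- rbind(c(3, 2), c(4, 11))
  expect_equal(fisherExact2x2(tab, alternative = "greater"),
               stats::phyper(2, 5, 15, 7, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("kappa grouping follows single linkage over membership agreement", {
  bg <- paste0("g", 1:40)
  sets <- list(A = bg[1:10], A2 = bg[1:10], D = bg[30:35])
  enr <- hypergeomEnrich(bg[1:10], sets, bg)
  grp <- kappaGroup(enr, sets, bg, kappaThreshold = 0.4)
  kap <- attr(grp, "kappa")
  expect_equal(kap["A", "A2"], 1)
  expect_lt(kap["A", "D"], 0)   # disjoint sets disagree beyond chance
  expect_identical(length(unique(grp$group[grp$set %in% c("A", "A2")])), 1L)
  expect_false(grp$group[grp$set == "D"] %in%
                 grp$group[grp$set %in% c("A", "A2")])

  # chain A~B, B~C without A~C still forms one group (single linkage)
  sets2 <- list(A = bg[1:12], B = bg[5:16], C = bg[9:20])
  enr2 <- hypergeomEnrich(bg[1:16], sets2, bg)
  grp2 <- kappaGroup(enr2, sets2, bg, kappaThreshold = 0.5)
  kap2 <- attr(grp2, "kappa")
  expect_gte(kap2["A", "B"], 0.5)
  expect_gte(kap2["B", "C"], 0.5)
  expect_lt(kap2["A", "C"], 0.5)
  expect_identical(length(unique(grp2$group)), 1L)
  # representative carries the largest query overlap
  expect_identical(unique(grp2$representative),
                   grp2$set[which.max(grp2$k)])

  # input order invariance
  enr2r <- enr2[rev(seq_len(nrow(enr2))), ]
  grp2r <- kappaGroup(enr2r, sets2, bg, kappaThreshold = 0.5)
  expect_identical(length(unique(grp2r$group)), 1L)
  expect_setequal(grp2r$set, grp2$set)
})

test_that("term-list intersections report counts and percent of second list", {
  resA <- data.frame(set = paste0("s", 1:8),
                     q = c(rep(0.01, 4), rep(0.5, 4)))
  resB <- data.frame(set = paste0("s", 1:8),
                     q = c(0.5, 0.5, rep(0.01, 6)))
  tab <- intersectTermLists(resA, resB)
  expect_identical(tab$n_a, 4L)       # s1..s4
  expect_identical(tab$n_b, 6L)       # s3..s8
  expect_identical(tab$n_intersection, 2L)
  expect_equal(tab$pct_of_b, 100 * 2 / 6, tolerance = 0.05)

  same <- intersectTermLists(resA, resA)
  expect_equal(same$pct_of_b, 100)
  disj <- intersectTermLists(resA, data.frame(set = paste0("s", 1:8),
                                              q = c(rep(0.5, 4),
                                                    rep(0.01, 4))))
  expect_identical(disj$n_intersection, 0L)
  expect_error(intersectTermLists(resA, data.frame(set = "zz", q = 0.01)),
               "share no gene-set names")
})

test_that("archetype sets enrich in their clusters, random sets stay null", {
  sim <- simulateAgingCounts(simConfig(genesPerArchetype =
    c(flat = 150, rapid_decay = 80, linear_up = 80)), seed = 51)
  sets <- simulateGeneSets(sim$truth, nRandomSets = 50, seed = 51)
  bg <- sim$truth$gene_id
  query <- sim$truth$gene_id[sim$truth$archetype == "rapid_decay"]
  res <- hypergeomEnrich(query, sets, bg)
  expect_lt(res$q[res$set == "SET_rapid_decay"], 0.05)
  expect_gt(res$q[res$set == "SET_linear_up"], 0.5)
  falsePos <- sum(res$q[startsWith(res$set, "RANDOM")] < 0.05)
  expect_lte(falsePos, 2.5)
})
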