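test_that("standardization centers, scales, excludes constants, is idempotent", {
  vals <- rbind(g1 = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
                g2 = rep(7, 10),
                g3 = c(2, 0, 1, 3, 1, 1, 3, 5, 4, 6))
  colnames(vals) <- paste0("s", 1:10)
  ae <- valueExperiment(vals, ages = rep(c(5, 12, 20, 27, 39), each = 2))
  prof <- standardizeProfiles(ae, assay = "logrpkm")
  # per-age means (1..5) -> centered (-2..2) / sd sqrt(2.5)
  expect_equal(unname(prof["g1", ]), c(-2, -1, 0, 1, 2) / sqrt(2.5))
  expect_identical(attr(prof, "excluded"), "g2")
  expect_equal(unname(rowMeans(prof)), rep(0, nrow(prof)), tolerance = 1e-9)
  expect_equal(unname(apply(prof, 1, sd)), rep(1, nrow(prof)),
               tolerance = 1e-9)
  # standardizing an already standardized profile changes nothing
  restd <- t(apply(prof, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(restd, prof, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(standardizeProfiles(ae, genes = "missing"), "absent")
})

test_that("fcm on separated clouds reproduces the nearest-centroid partition", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40 * 3, mean = 0, sd = 0.1), ncol = 3),
             matrix(rnorm(40 * 3, mean = 5, sd = 0.1), ncol = 3))
  rownames(x) <- sprintf("p%02d", 1:80)
  fit <- fcmFit(x, 2, seed = 1)
  expect_equal(unname(rowSums(membership(fit))), rep(1, 80), tolerance = 1e-9)
  expect_true(all(diff(fit@objectivePath) <= 1e-8))
  # brute-force nearest-centroid oracle
  d2 <- as.matrix(dist(rbind(x, centroids(fit))))[1:80, 81:82]
  expect_identical(unname(hardLabels(fit)),
                   unname(max.col(-d2, ties.method = "first")))
  truth <- rep(1:2, each = 40)
  expect_gte(matchAccuracy(hardLabels(fit), truth), 1)
})

test_that("a profile coinciding with a centroid gets full membership", {
  # two clouds of identical points: centroids land exactly on the points
  x <- rbind(matrix(rep(c(0, 0, 0), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(8, 8, 8), 10), ncol = 3, byrow = TRUE))
  fit <- fcmFit(x, 2, seed = 2)
  expect_equal(max(abs(membership(fit) - round(membership(fit)))), 0,
               tolerance = 1e-9)
  expect_equal(sort(unique(hardLabels(fit))), 1:2)
})

test_that("duplicating every profile leaves centroids unchanged", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 3)
  f1 <- fcmFit(x, 3, seed = 8, nStarts = 10)
  f2 <- fcmFit(rbind(x, x), 3, seed = 8, nStarts = 10)
  # compare centroid sets after matching by nearest distance
  d <- as.matrix(dist(rbind(centroids(f1), centroids(f2))))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 1e-3)
})

test_that("fcm agrees with an independent implementation on clean data", {
  skip_if_not_installed("e1071")
  set.seed(11)
  x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 3),
             matrix(rnorm(60, 4, 0.3), ncol = 3),
             matrix(rnorm(60, -4, 0.3), ncol = 3))
  fit <- fcmFit(x, 3, seed = 1, nStarts = 10)
  ref <- e1071::cmeans(x, 3, m = 2, iter.max = 500)
  d <- as.matrix(dist(rbind(centroids(fit), ref$centers)))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 0.05)
  expect_equal(matchAccuracy(hardLabels(fit), ref$cluster), 1)
})

test_that("near-crisp fcm reproduces the k-means partition", {
  set.seed(12)
  x <- rbind(matrix(rnorm(50 * 2, 0, 0.2), ncol = 2),
             matrix(rnorm(50 * 2, 3, 0.2), ncol = 2))
  fit <- fcmFit(x, 2, m = 1.05, seed = 3, nStarts = 10)
  km <- kmeans(x, 2, nstart = 20, algorithm = "Lloyd", iter.max = 100)
  expect_equal(matchAccuracy(hardLabels(fit), km$cluster), 1)
})

test_that("validity vote recovers clear structure and flags unclustered data", {
  set.seed(13)
  proto <- rbind(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2), c(-1, 1, 2, 1, -1))
  x <- proto[rep(1:3, each = 60), ] + matrix(rnorm(180 * 5, sd = 0.15),
                                             ncol = 5)
  x <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  fit <- validityVote(x, kRange = 2:6, nStarts = 10, seed = 1)
  expect_identical(chosenK(fit), 3L)
  expect_identical(nrow(validityTable(fit)), 5L)

  # a single Gaussian blob: Xie-Beni degrades as k grows
  blob <- matrix(rnorm(150 * 5), ncol = 5)
  vb <- validityVote(blob, kRange = 2:6, nStarts = 5, seed = 2)
  xb <- as.numeric(validityTable(vb)[validityTable(vb)$index == "xie_beni",
                                     paste0("k", 2:6)])
  expect_gt(cor(2:6, xb, method = "spearman"), 0)
  expect_gt(xb[5], xb[1])
})

test_that("cluster summaries report size order, monotonicity and direction", {
  # construct profiles with known hard structure: 70 decreasing, 30 inverted
  dec <- c(1, 0.5, 0, -0.5, -1); inv <- c(-1, 0, 1, 0.5, -0.5)
  x <- rbind(matrix(rep(dec, 70), ncol = 5, byrow = TRUE) +
               matrix(rnorm(350, sd = 0.05), ncol = 5),
             matrix(rep(inv, 30), ncol = 5, byrow = TRUE) +
               matrix(rnorm(150, sd = 0.05), ncol = 5))
  fit <- fcmFit(x, 2, seed = 5, nStarts = 10)
  s <- summarizeClusters(fit, x)
  expect_equal(s$summary$n_members, c(70, 30))
  expect_equal(s$summary$pct_members, c(70, 30))
  expect_equal(sum(s$summary$pct_members), 100, tolerance = 0.1)
  big <- s$summary[1, ]; small <- s$summary[2, ]
  expect_true(big$monotonic);  expect_identical(big$initial_direction, "down")
  expect_false(small$monotonic); expect_identical(small$initial_direction, "up")
  # CI envelopes bracket the means
  expect_true(all(s$lower <= s$means & s$means <= s$upper))
})

test_that("cluster summary contents are invariant to label permutation", {
  set.seed(6)
  x <- matrix(rnorm(200), ncol = 5)
  fit <- fcmFit(x, 3, seed = 6, nStarts = 5)
  s1 <- summarizeClusters(fit, x)
  perm <- c(3L, 1L, 2L)
  fit2 <- fit
  fit2@membership <- fit@membership[, order(perm)]
  fit2@centroids <- fit@centroids[order(perm), ]
  fit2@hardLabels <- perm[fit@hardLabels]
  sizes <- tabulate(fit2@hardLabels, 3)
  fit2@clusterOrder <- order(sizes, decreasing = TRUE)
  s2 <- summarizeClusters(fit2, x)
  canon <- function(s) {
    o <- order(s$summary$n_members, round(s$means[, 1], 6))
    list(n = s$summary$n_members[o], m = s$means[o, , drop = FALSE])
  }
  expect_equal(canon(s1)$n, canon(s2)$n)
  expect_equal(canon(s1)$m, canon(s2)$m, tolerance = 1e-9)
})

test_that("group trajectories recover the simulated percent change", {
  # flat-dominated background keeps the RPKM totals composition-stable, as
  # for a minority gene family in a real transcriptome
  cfg <- simConfig(genesPerArchetype = c(flat = 400, linear_up = 20),
                   archetypes = defaultArchetypes())
  cfg$archetypes$linear_up$amplitude <- 0.47
  sim <- simulateAgingCounts(cfg, seed = 31)
  ae <- logTransform(rpkm(sim$experiment))
  up <- sim$truth$gene_id[sim$truth$archetype == "linear_up"]
  traj <- groupAverageTrajectory(ae, up)
  expect_equal(traj$pctChange, 47, tolerance = 10)
  expect_true(all(diff(traj$mean) > 0))

  flat <- sim$truth$gene_id[sim$truth$archetype == "flat"]
  trajFlat <- groupAverageTrajectory(ae, flat)
  expect_lt(abs(trajFlat$pctChange), 10)

  one <- groupAverageTrajectory(ae, up[1])
  profOne <- standardizeProfiles(ae, up[1])
  expect_equal(unname(one$mean), unname(profOne[1, ]), tolerance = 1e-9)
  expect_error(groupAverageTrajectory(ae, character()), "empty")
  expect_error(groupAverageTrajectory(ae, "nope"), "nope")
})
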