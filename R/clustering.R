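#' @include AllClasses.R AllGenerics.R
NULL

#' Standardized temporal profiles
#'
#' Averages each gene's normalized expression over replicates within each
#' age group, then centers the resulting per-age vector to mean 0 and
#' scales it to variance 1 — the representation clustered by fuzzy
#' c-means. Genes whose per-age profile is constant (zero variance) cannot
#' be standardized; they are dropped and listed in
#' `attr(result, "excluded")`.
#'
#' @param ae an [AgingExperiment-class].
#' @param genes character vector of gene ids (default: all genes).
#' @param assay assay to profile, normally `"logrpkm"`.
#' @return numeric matrix, genes x age groups (columns named by age, in
#'   increasing order), each row mean 0 / variance 1.
#' @export
standardizeProfiles <- function(ae, genes = rownames(ae),
                                assay = "logrpkm") {
  x <- assayMatrix(ae, assay)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("genes absent from the experiment: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- x[genes, , drop = FALSE]
  ages <- ageWeeks(ae)
  groups <- sort(unique(ages))
  prof <- vapply(groups, function(a)
    rowMeans(x[, ages == a, drop = FALSE]), numeric(nrow(x)))
  if (!is.matrix(prof)) prof <- matrix(prof, nrow = 1,
                                       dimnames = list(genes, NULL))
  colnames(prof) <- as.character(groups)
  sds <- apply(prof, 1L, stats::sd)
  excluded <- rownames(prof)[sds == 0]
  keep <- sds > 0
  out <- (prof[keep, , drop = FALSE] - rowMeans(prof[keep, , drop = FALSE])) /
    sds[keep]
  attr(out, "excluded") <- excluded
  attr(out, "ages") <- groups
  out
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Minimizes the fuzzy objective `J = sum_ij u_ij^m d^2(x_j, v_i)`
#' (Euclidean distance) by alternating the standard update equations
#' `v_i = sum_j u_ij^m x_j / sum_j u_ij^m` and
#' `u_ij = 1 / sum_l (d_ij / d_lj)^(2/(m-1))`; a profile coinciding with a
#' centroid receives full membership in that centroid's cluster. The best
#' of `nStarts` random initializations (by final objective) is returned;
#' iteration stops when the maximum membership change falls below `tol`.
#' Deterministic given `seed`.
#'
#' @param x numeric matrix of profiles (genes x ages), e.g. from
#'   [standardizeProfiles()].
#' @param k number of clusters, `2 <= k < nrow(x)`.
#' @param m fuzzifier (> 1); 2 is conventional.
#' @param tol convergence tolerance on the membership change.
#' @param maxIter iteration cap per start.
#' @param nStarts random restarts.
#' @param seed integer seed.
#' @return a [FuzzyClustering-class] object.
#' @export
fcmFit <- function(x, k, m = 2, tol = 1e-6, maxIter = 500, nStarts = 20,
                   seed = 1) {
  x <- as.matrix(x)
  if (k < 2L) stop("k must be at least 2")
  if (k >= nrow(x)) stop("k must be smaller than the number of profiles")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nStarts)) {
    fit <- .fcmSingle(x, k, m, tol, maxIter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  hard <- max.col(best$u, ties.method = "first")
  sizes <- tabulate(hard, nbins = k)
  methods::new("FuzzyClustering", k = as.integer(k), m = m,
               membership = best$u, centroids = best$v,
               objective = best$objective, objectivePath = best$path,
               hardLabels = as.integer(hard),
               clusterOrder = order(sizes, decreasing = TRUE),
               validity = data.frame(), chosenK = NA_integer_)
}

# one FCM run from a random membership initialization
.fcmSingle <- function(x, k, m, tol, maxIter) {
  n <- nrow(x)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  path <- numeric(0)
  for (iter in seq_len(maxIter)) {
    um <- u^m
    v <- (t(um) %*% x) / colSums(um)
    d2 <- .sqDistToCentroids(x, v)
    path <- c(path, sum(um * d2))
    uNew <- .fcmMembership(d2, m)
    delta <- max(abs(uNew - u))
    u <- uNew
    if (delta < tol) break
  }
  um <- u^m
  v <- (t(um) %*% x) / colSums(um)
  d2 <- .sqDistToCentroids(x, v)
  obj <- sum(um * d2)
  path <- c(path, obj)
  list(u = u, v = v, objective = obj, path = path)
}

.sqDistToCentroids <- function(x, v) {
  d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * x %*% t(v)
  pmax(d2, 0)
}

.fcmMembership <- function(d2, m) {
  pw <- d2^(-1 / (m - 1))
  zero <- d2 < 1e-300
  hasZero <- rowSums(zero) > 0
  u <- pw / rowSums(pw)
  if (any(hasZero)) {
    u[hasZero, ] <- 0
    u[hasZero, ] <- zero[hasZero, , drop = FALSE] /
      rowSums(zero[hasZero, , drop = FALSE])
  }
  u
}

#' @rdname FuzzyClustering-accessors
#' @export
setMethod("membership", "FuzzyClustering", function(x) x@membership)
#' @rdname FuzzyClustering-accessors
#' @export
setMethod("centroids", "FuzzyClustering", function(x) x@centroids)
#' Accessors for FuzzyClustering
#'
#' @param x a [FuzzyClustering-class] object.
#' @return the corresponding slot.
#' @name FuzzyClustering-accessors
#' @export
setMethod("hardLabels", "FuzzyClustering", function(x) x@hardLabels)
#' @rdname FuzzyClustering-accessors
#' @export
setMethod("chosenK", "FuzzyClustering", function(x) x@chosenK)
#' @rdname FuzzyClustering-accessors
#' @export
setMethod("validityTable", "FuzzyClustering", function(x) x@validity)

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering: k =", object@k, ", m =", object@m,
      ",", nrow(object@membership), "profiles\n")
  cat("  objective:", format(object@objective, digits = 6),
      "after", length(object@objectivePath), "iterations\n")
  sz <- tabulate(object@hardLabels, nbins = object@k)
  cat("  hard cluster sizes (descending):",
      paste(sort(sz, decreasing = TRUE), collapse = ", "), "\n")
  if (!is.na(object@chosenK))
    cat("  validity vote chose k =", object@chosenK, "\n")
})

#' Choose the number of clusters by a validity-index vote
#'
#' Fits fuzzy c-means for each candidate `k` and scores every fit with five
#' cluster validity indices capturing different aspects of partition
#' quality: the modified partition coefficient (maximized; Dave's
#' correction of the raw coefficient, whose monotone k-bias would
#' otherwise always favor the smallest candidate), the normalized
#' partition entropy (minimized; entropy divided by `log k`, same
#' rationale), Xie-Beni (minimized), Fukuyama-Sugeno (minimized) and the
#' fuzzy silhouette (maximized). Each index casts one vote for its optimal
#' `k`; the modal vote wins, with ties broken toward the smaller `k`
#' (parsimony).
#'
#' @inheritParams fcmFit
#' @param kRange candidate cluster numbers (at least two candidates, each
#'   `< nrow(x)`).
#' @return the fitted [FuzzyClustering-class] at the chosen `k`, with the
#'   validity table (`index` x `k`, plus each index's vote) in
#'   `validityTable()` and the vote in `chosenK()`.
#' @export
validityVote <- function(x, kRange = 2:10, m = 2, nStarts = 20, seed = 1,
                         tol = 1e-6, maxIter = 500) {
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) < 2L) stop("kRange must contain at least two values")
  if (any(kRange < 2L) || any(kRange >= nrow(x)))
    stop("kRange must lie within [2, nrow(x) - 1]")
  fits <- lapply(seq_along(kRange), function(i)
    fcmFit(x, kRange[i], m = m, tol = tol, maxIter = maxIter,
           nStarts = nStarts, seed = seed + i - 1L))
  dx <- stats::dist(x)
  idx <- vapply(fits, function(f) .validityIndices(x, f, dx), numeric(5))
  rownames(idx) <- c("modified_partition_coefficient",
                     "normalized_partition_entropy",
                     "xie_beni", "fukuyama_sugeno", "fuzzy_silhouette")
  direction <- c(modified_partition_coefficient = 1,
                 normalized_partition_entropy = -1,
                 xie_beni = -1, fukuyama_sugeno = -1, fuzzy_silhouette = 1)
  votes <- vapply(rownames(idx), function(r)
    kRange[which.max(direction[r] * idx[r, ])], integer(1))
  tab <- table(factor(votes, levels = kRange))
  winner <- as.integer(names(tab)[tab == max(tab)][1L])  # ties: smaller k
  chosen <- fits[[match(winner, kRange)]]
  vt <- data.frame(index = rownames(idx), idx, vote = votes,
                   row.names = NULL, check.names = FALSE)
  colnames(vt)[2:(1 + length(kRange))] <- paste0("k", kRange)
  chosen@validity <- vt
  chosen@chosenK <- winner
  methods::validObject(chosen)
  chosen
}

# the five-index electorate for one fitted clustering; the partition
# coefficient and entropy are the k-bias-corrected variants (Dave's
# modification, entropy normalized by log k) — the raw forms are monotone
# in k and would always vote for the smallest candidate
.validityIndices <- function(x, fit, dx = stats::dist(x)) {
  u <- fit@membership; v <- fit@centroids; m <- fit@m
  n <- nrow(u); k <- ncol(u)
  d2 <- .sqDistToCentroids(x, v)
  um <- u^m
  pc <- sum(u^2) / n
  mpc <- 1 - k / (k - 1) * (1 - pc)
  pe <- -sum(ifelse(u > 0, u * log(u), 0)) / n
  pen <- pe / log(k)
  sepV <- .sqDistToCentroids(v, v)
  diag(sepV) <- Inf
  xb <- sum(um * d2) / (n * min(sepV))
  xbar <- colMeans(x)
  fs <- sum(um * d2) - sum(um * matrix(rowSums(t(t(v) - xbar)^2),
                                       n, k, byrow = TRUE))
  fsil <- .fuzzySilhouette(dx, u, fit@hardLabels)
  c(mpc, pen, xb, fs, fsil)
}

# Campello-Hruschka fuzzy silhouette: crisp silhouettes weighted by the
# margin between the two largest memberships
.fuzzySilhouette <- function(dx, u, labels, alpha = 1) {
  dm <- as.matrix(dx)
  n <- nrow(dm)
  k <- ncol(u)
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(Z)
  S <- dm %*% Z                                # total distance to each cluster
  ownSize <- sizes[labels]
  a <- ifelse(ownSize > 1, S[cbind(seq_len(n), labels)] / (ownSize - 1), 0)
  Mb <- sweep(S, 2L, pmax(sizes, 1), "/")
  Mb[, sizes == 0] <- Inf
  Mb[cbind(seq_len(n), labels)] <- Inf
  b <- apply(Mb, 1L, min)
  denom <- pmax(a, b)
  sil <- ifelse(is.finite(b) & denom > 0, (b - a) / denom, 0)
  topTwo <- apply(u, 1L, function(r) sort(r, decreasing = TRUE)[1:2])
  w <- (topTwo[1L, ] - topTwo[2L, ])^alpha
  if (sum(w) == 0) return(0)
  sum(w * sil) / sum(w)
}

#' Per-cluster summaries of a fitted clustering
#'
#' Reports, for each cluster in decreasing size order: the mean profile
#' over its hard members, a 95% confidence envelope per age
#' (`mean +/- 1.96 * sd / sqrt(n)`), member counts and percentages, whether
#' the mean profile is monotonic (consecutive differences of a single
#' sign), and its initial direction. Empty clusters are reported with
#' `n = 0` and undefined flags.
#'
#' @param fit a [FuzzyClustering-class].
#' @param x the profile matrix the fit was computed on.
#' @return list with `summary` (data.frame: `cluster`, `n_members`,
#'   `pct_members`, `monotonic`, `initial_direction`), `means`, `lower`,
#'   `upper` (cluster x age matrices, rows in size order).
#' @export
summarizeClusters <- function(fit, x) {
  x <- as.matrix(x)
  k <- fit@k
  labels <- fit@hardLabels
  ord <- fit@clusterOrder
  nAges <- ncol(x)
  means <- lower <- upper <- matrix(NA_real_, k, nAges,
                                    dimnames = list(NULL, colnames(x)))
  n <- integer(k)
  mono <- logical(k); dir <- character(k)
  for (c in seq_len(k)) {
    mem <- which(labels == c)
    n[c] <- length(mem)
    if (!length(mem)) { mono[c] <- NA; dir[c] <- NA_character_; next }
    xs <- x[mem, , drop = FALSE]
    mu <- colMeans(xs)
    sdv <- apply(xs, 2L, stats::sd)
    sdv[is.na(sdv)] <- 0
    means[c, ] <- mu
    lower[c, ] <- mu - 1.96 * sdv / sqrt(n[c])
    upper[c, ] <- mu + 1.96 * sdv / sqrt(n[c])
    d <- diff(mu)
    mono[c] <- all(d >= 0) || all(d <= 0)
    dir[c] <- if (d[1L] >= 0) "up" else "down"
  }
  summary <- data.frame(
    cluster = ord, n_members = n[ord],
    pct_members = 100 * n[ord] / sum(n),
    monotonic = mono[ord], initial_direction = dir[ord],
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, means = means[ord, , drop = FALSE],
       lower = lower[ord, , drop = FALSE],
       upper = upper[ord, , drop = FALSE])
}

#' Average standardized trajectory of a gene group
#'
#' For a list of genes (e.g. all ribosomal-protein genes), computes the
#' groupwise mean and standard deviation of the standardized per-age
#' profiles, plus the percent change of the group's unstandardized mean
#' expression between the first and last age
#' (`100 * (last - first) / first`).
#'
#' @param ae an [AgingExperiment-class].
#' @param genes non-empty character vector of gene ids.
#' @param assay assay used for the standardized profiles; the percent
#'   change is always computed on the `"rpkm"` scale.
#' @return list with `ages`, `mean`, `sd` (per-age group statistics of the
#'   standardized profiles) and `pctChange`.
#' @export
groupAverageTrajectory <- function(ae, genes, assay = "logrpkm") {
  if (!length(genes)) stop("gene list is empty")
  missing <- setdiff(genes, rownames(ae))
  if (length(missing))
    stop("genes absent from the experiment: ",
         paste(missing, collapse = ", "))
  prof <- standardizeProfiles(ae, genes, assay = assay)
  ages <- attr(prof, "ages")
  rk <- assayMatrix(ae, "rpkm")[genes, , drop = FALSE]
  aw <- ageWeeks(ae)
  rawByAge <- vapply(ages, function(a)
    mean(rowMeans(rk[, aw == a, drop = FALSE])), numeric(1))
  pct <- 100 * (rawByAge[length(rawByAge)] - rawByAge[1L]) / rawByAge[1L]
  list(ages = ages,
       mean = colMeans(prof),
       sd = apply(prof, 2L, stats::sd),
       pctChange = unname(pct))
}
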