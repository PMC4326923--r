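#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio between its counts
#' and the per-gene geometric mean, computed over genes detected in every
#' sample. Robust to composition effects and the standard normalization for
#' bulk count matrices. Falls back to relative library sizes if no gene is
#' detected everywhere.
#'
#' @param counts numeric matrix of counts, genes x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
medianOfRatios <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) {
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(x) exp(stats::median(log(x) - logGeo[use])))
  unname(sf)
}

#' Negative-binomial Wald test for one gene
#'
#' Tests for a difference in mean expression between two groups of counts
#' under a negative-binomial model. Counts are normalized by the supplied
#' size factors; a common dispersion is estimated by method of moments from
#' the within-group means and variances (floored at `1e-8`); the Wald
#' statistic on the difference of log group means is referred to a t
#' distribution with `nA + nB - 2` degrees of freedom. Genes that are zero
#' in both groups return `p = 1` by convention.
#'
#' @param a,b numeric count vectors for the two groups (>= 2 each).
#' @param sfA,sfB size factors for the corresponding samples (default 1).
#' @return two-sided p-value in `[0, 1]`.
#' @export
nbWaldTest <- function(a, b, sfA = rep(1, length(a)),
                       sfB = rep(1, length(b))) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicates")
  .nbWaldMatrix(matrix(a, nrow = 1), matrix(b, nrow = 1), sfA, sfB)
}

# vectorized over genes (rows)
.nbWaldMatrix <- function(A, B, sfA, sfB) {
  yA <- sweep(A, 2L, sfA, "/"); yB <- sweep(B, 2L, sfB, "/")
  nA <- ncol(yA); nB <- ncol(yB)
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- .rowVars(yA); vB <- .rowVars(yB)
  aA <- ifelse(mA > 0, (vA - mA) / mA^2, NA_real_)
  aB <- ifelse(mB > 0, (vB - mB) / mB^2, NA_real_)
  alpha <- rowMeans(cbind(aA, aB), na.rm = TRUE)
  alpha[!is.finite(alpha)] <- 1e-8
  alpha <- pmax(alpha, 1e-8)
  # half-a-normalized-count continuity shift keeps zero-mean groups finite
  mAt <- mA + 0.5 / nA; mBt <- mB + 0.5 / nB
  delta <- log(mAt) - log(mBt)
  se <- sqrt((1 / mAt + alpha) / nA + (1 / mBt + alpha) / nB)
  p <- 2 * stats::pt(-abs(delta / se), df = nA + nB - 2L)
  p[mA == 0 & mB == 0] <- 1
  pmin(pmax(p, 0), 1)
}

.rowVars <- function(x) {
  n <- ncol(x)
  (rowSums(x^2) - n * rowMeans(x)^2) / (n - 1L)
}

#' Two-sided rank-sum test
#'
#' Wilcoxon-Mann-Whitney test on normalized expression values. Without ties
#' the exact two-sided p-value is computed from the Wilcoxon distribution;
#' with ties (or large samples) a normal approximation with midranks, tie
#' variance correction and continuity correction is used. Values constant
#' across both groups give `p = 1`.
#'
#' @param a,b numeric vectors for the two groups (>= 2 each).
#' @param exactMax use the exact distribution when `length(a) + length(b)`
#'   is at most this and there are no ties.
#' @return two-sided p-value.
#' @export
rankSumTest <- function(a, b, exactMax = 20) {
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 replicates")
  z <- c(a, b)
  if (max(z) == min(z)) return(1)
  r <- rank(z)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (!ties && (nA + nB) <= exactMax) {
    p <- if (U > nA * nB / 2)
      stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE)
    else stats::pwilcox(U, nA, nB)
    return(min(1, 2 * p))
  }
  n <- nA + nB
  tieTab <- table(z)
  sigma2 <- (nA * nB / 12) * ((n + 1) - sum(tieTab^3 - tieTab) /
                                (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  d <- U - nA * nB / 2
  d <- d - sign(d) * 0.5                      # continuity correction
  min(1, 2 * stats::pnorm(-abs(d) / sqrt(sigma2)))
}

#' Permutation test on the log2 fold change
#'
#' Compares the observed absolute difference of group means (computed on
#' log2-normalized values, i.e. the absolute log2 fold change) with its
#' permutation distribution under relabeling. When the number of distinct
#' group assignments is at most `nPerm` the full enumeration is used and
#' the result is seed-independent; otherwise `nPerm` random assignments are
#' drawn without replacement within each draw and the add-one estimator
#' `p = (1 + #{|t*| >= |t|}) / (1 + nPerm)` is returned.
#'
#' @param a,b numeric vectors of log2-normalized values (>= 2 each).
#' @param nPerm number of Monte-Carlo permutations (>= 100).
#' @param seed integer seed (Monte-Carlo mode only).
#' @param exhaustive force (`TRUE`)/suppress (`FALSE`) enumeration;
#'   default: enumerate when `choose(n, nA) <= nPerm`.
#' @return p-value in `(0, 1]`.
#' @export
permFoldChangeTest <- function(a, b, nPerm = 10000, seed = 1,
                               exhaustive = NULL) {
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 replicates")
  if (nPerm < 100) stop("nPerm must be at least 100")
  x <- c(a, b)
  if (max(x) == min(x)) return(1)
  nSplits <- choose(nA + nB, nA)
  if (is.null(exhaustive)) exhaustive <- nSplits <= nPerm
  obs <- abs(mean(a) - mean(b))
  if (exhaustive) {
    W <- .splitWeights(nA, nB)
    stat <- abs(as.vector(x %*% W))
    mean(stat >= obs - 1e-12)
  } else {
    set.seed(as.integer(seed))
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      idx <- sample.int(nA + nB, nA)
      if (abs(mean(x[idx]) - mean(x[-idx])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    (1 + cnt) / (1 + nPerm)
  }
}

# n x choose(n, nA) matrix of contrast weights (+1/nA for group A,
# -1/nB for group B) over all assignments
.splitWeights <- function(nA, nB) {
  n <- nA + nB
  idx <- utils::combn(n, nA)
  W <- matrix(-1 / nB, nrow = n, ncol = ncol(idx))
  W[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = nA))] <- 1 / nA
  W
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegating to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes across all pairwise age comparisons
#'
#' For every pair of age groups, computes three independent per-gene tests —
#' a parametric negative-binomial Wald test on counts ([nbWaldTest()]), a
#' nonparametric rank-sum test ([rankSumTest()]) and a resampling
#' permutation test on the log2 fold change ([permFoldChangeTest()]), the
#' latter two on `log2(RPKM + pseudocount)` values — and adjusts each test's
#' p-values by Benjamini-Hochberg within the comparison. A gene is called
#' differentially expressed when all three q-values fall below `alpha` in
#' at least one comparison; no effect-size cutoff is applied. Genes with
#' zero counts in every sample are dropped before testing and reported.
#'
#' @param ae an [AgingExperiment-class].
#' @param alpha FDR level in (0, 1).
#' @param nPerm permutations for the fold-change test (exhaustive
#'   enumeration is used automatically when cheaper).
#' @param seed integer seed for the permutation test.
#' @param pseudocount pseudocount for the log2 RPKM values.
#' @return list with elements
#'   `results` (data.frame, one row per gene x comparison: `gene`, `age_a`,
#'   `age_b`, `log2fc`, `p_nb`, `p_rank`, `p_perm`, `q_nb`, `q_rank`,
#'   `q_perm`), `calls` (data.frame: `gene`, `is_deg`, `n_support`,
#'   `supporting`, `best_comparison`), `zeroGenes` (character),
#'   `sizeFactors`, and `alpha`.
#' @export
callDegs <- function(ae, alpha = 0.05, nPerm = 10000, seed = 1,
                     pseudocount = 1) {
  stopifnot(methods::is(ae, "AgingExperiment"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  counts <- SummarizedExperiment::assay(ae, "counts")
  zero <- rownames(counts)[rowSums(counts) == 0]
  keep <- setdiff(rownames(counts), zero)
  counts <- counts[keep, , drop = FALSE]
  logm <- assayMatrix(ae, "logrpkm", pseudocount = pseudocount)[keep, ,
                                                               drop = FALSE]
  ages <- ageWeeks(ae)
  groups <- sort(unique(ages))
  reps <- table(ages)
  if (any(reps < 2L))
    stop("age group ", names(reps)[reps < 2L][1L],
         " has fewer than 2 replicates")
  sf <- medianOfRatios(counts)
  pairs <- utils::combn(groups, 2L)
  res <- vector("list", ncol(pairs))
  for (ci in seq_len(ncol(pairs))) {
    aAge <- pairs[1L, ci]; bAge <- pairs[2L, ci]
    ia <- which(ages == aAge); ib <- which(ages == bAge)
    pNb <- .nbWaldMatrix(counts[, ia, drop = FALSE],
                         counts[, ib, drop = FALSE], sf[ia], sf[ib])
    pRank <- vapply(seq_len(nrow(logm)), function(g)
      rankSumTest(logm[g, ia], logm[g, ib]), numeric(1))
    pPerm <- .permMatrix(logm[, ia, drop = FALSE],
                         logm[, ib, drop = FALSE], nPerm = nPerm,
                         seed = seed + ci)
    l2fc <- rowMeans(logm[, ia, drop = FALSE]) -
      rowMeans(logm[, ib, drop = FALSE])
    res[[ci]] <- data.frame(
      gene = keep, age_a = aAge, age_b = bAge, log2fc = l2fc,
      p_nb = pNb, p_rank = pRank, p_perm = pPerm,
      q_nb = benjaminiHochberg(pNb),
      q_rank = benjaminiHochberg(pRank),
      q_perm = benjaminiHochberg(pPerm),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  hit <- results$q_nb < alpha & results$q_rank < alpha &
    results$q_perm < alpha
  worstQ <- pmax(results$q_nb, results$q_rank, results$q_perm)
  cmpNames <- paste0(pairs[1L, ], "-", pairs[2L, ])
  # comparison blocks share the gene order, so reshape gene x comparison
  hitM <- matrix(hit, nrow = length(keep))
  wqM <- matrix(worstQ, nrow = length(keep))
  calls <- data.frame(
    gene = keep,
    is_deg = rowSums(hitM) > 0L,
    n_support = rowSums(hitM),
    supporting = apply(hitM, 1L, function(h)
      paste(cmpNames[h], collapse = ";")),
    best_comparison = cmpNames[max.col(-wqM, ties.method = "first")],
    row.names = NULL, stringsAsFactors = FALSE)
  list(results = results, calls = calls, zeroGenes = zero,
       sizeFactors = sf, alpha = alpha)
}

# vectorized permutation fold-change test across gene rows; exhaustive when
# the assignment count fits in nPerm
.permMatrix <- function(A, B, nPerm = 10000, seed = 1) {
  nA <- ncol(A); nB <- ncol(B)
  X <- cbind(A, B)
  obs <- abs(rowMeans(A) - rowMeans(B))
  constant <- .rowMax(X) == .rowMin(X)
  nSplits <- choose(nA + nB, nA)
  if (nSplits <= nPerm) {
    W <- .splitWeights(nA, nB)
    stat <- abs(X %*% W)
    p <- rowMeans(stat >= obs - 1e-12)
  } else {
    set.seed(as.integer(seed))
    cnt <- integer(nrow(X))
    for (i in seq_len(nPerm)) {
      idx <- sample.int(nA + nB, nA)
      stat <- abs(rowMeans(X[, idx, drop = FALSE]) -
                    rowMeans(X[, -idx, drop = FALSE]))
      cnt <- cnt + (stat >= obs - 1e-12)
    }
    p <- (1 + cnt) / (1 + nPerm)
  }
  p[constant] <- 1
  p
}

.rowMax <- function(x) do.call(pmax, as.data.frame(x))
.rowMin <- function(x) do.call(pmin, as.data.frame(x))
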