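# shared fixtures and independent oracles, all built in code

# deterministic toy experiment: nGenes x (2 ages x 3 reps), Poisson-ish counts
toyExperiment <- function(nGenes = 6, ages = c(5, 39), reps = 3, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(nGenes * length(ages) * reps, lambda = 60),
                   nrow = nGenes)
  rownames(counts) <- sprintf("g%02d", seq_len(nGenes))
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  AgingExperiment(counts, geneLengths = seq(500, by = 250,
                                            length.out = nGenes),
                  ageWeeks = rep(ages, each = reps),
                  replicate = rep(seq_len(reps), length(ages)))
}

# experiment whose logrpkm assay is replaced by arbitrary values
valueExperiment <- function(values, ages, reps = NULL) {
  nS <- ncol(values)
  if (is.null(reps)) reps <- as.integer(ave(seq_len(nS), ages, FUN = seq_along))
  counts <- matrix(10L, nrow(values), nS, dimnames = dimnames(values))
  ae <- AgingExperiment(counts, geneLengths = rep(1000, nrow(values)),
                        ageWeeks = ages, replicate = reps)
  ae <- logTransform(rpkm(ae))
  SummarizedExperiment::assay(ae, "logrpkm", withDimnames = FALSE) <- values
  ae
}

# optimal hard-label accuracy by exhaustive assignment over label permutations
matchAccuracy <- function(labels, truth) {
  tab <- unclass(table(factor(labels), factor(truth)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  n <- min(nrow(tab), ncol(tab))
  best <- 0
  for (p in perms(seq_len(ncol(tab))))
    best <- max(best, sum(tab[cbind(seq_len(n), p[seq_len(n)])]))
  best / length(labels)
}

# union-find oracle for connected components over an edge data.frame
unionFindComponents <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$gene_a[i]); rb <- find(edges$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  firsts <- vapply(comps, `[[`, character(1), 1L)
  unname(comps[order(-lengths(comps), firsts)])
}

# textbook pseudoinverse OLS oracle (svd-based)
pinvFit <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
  as.vector(sv$v[, keep, drop = FALSE] %*%
              ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
}

# exhaustive hypergeometric upper-tail oracle: enumerate all draws of size n
# from a universe of size N with K marked elements
enumHyperUpper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# exhaustive two-sided rank-sum oracle over all group assignments
enumRankSumTwoSided <- function(a, b) {
  x <- c(a, b); nA <- length(a)
  splits <- utils::combn(length(x), nA)
  r <- rank(x)
  obsU <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  Us <- apply(splits, 2L, function(ix) sum(r[ix]) - nA * (nA + 1) / 2)
  mu <- nA * (length(b)) / 2
  mean(abs(Us - mu) >= abs(obsU - mu))
}

# rigid Procrustes error after centering and optimal rotation/reflection
procrustesError <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$u %*% t(sv$v)
  sqrt(sum((Yc %*% R - Xc)^2))
}
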