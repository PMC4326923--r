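#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation in a query gene list against
#' a background universe (all expressed genes). Sets are intersected with
#' the background before the urn parameters are computed; sets that vanish
#' after intersection are skipped and listed in
#' `attr(result, "skipped")`. The upper-tail p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; q-values are
#' Benjamini-Hochberg across all tested sets; fold enrichment is
#' `(k/n) / (K/N)`.
#'
#' @param query character vector of genes of interest (must be contained in
#'   `background`).
#' @param sets named list of gene sets (see [readGmt()]).
#' @param background character vector, the expressed-gene universe.
#' @return data.frame sorted by `q`: `set`, `N`, `K`, `n`, `k`, `fold`,
#'   `p`, `q`.
#' @export
hypergeomEnrich <- function(query, sets, background) {
  if (!length(query)) stop("query gene list is empty")
  if (!length(background)) stop("background gene universe is empty")
  background <- unique(background)
  query <- unique(query)
  out <- setdiff(query, background)
  if (length(out))
    stop("query genes missing from background: ",
         paste(utils::head(out, 5L), collapse = ", "))
  N <- length(background); n <- length(query)
  K <- vapply(sets, function(s) length(intersect(s, background)), integer(1))
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  skipped <- names(sets)[K == 0L]
  keep <- K > 0L
  p <- stats::phyper(k[keep] - 1L, K[keep], N - K[keep], n,
                     lower.tail = FALSE)
  res <- data.frame(set = names(sets)[keep], N = N, K = K[keep], n = n,
                    k = k[keep], fold = (k[keep] / n) / (K[keep] / N),
                    p = p, q = benjaminiHochberg(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$set), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing, over the hypergeometric support
#' at fixed margins, the probabilities of all tables at most as probable as
#' the observed one. A zero margin gives `p = 1` by convention. The
#' one-sided upper tail coincides with the hypergeometric enrichment
#' p-value on the matching urn.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default) or `"greater"` (upper tail).
#' @return p-value.
#' @export
fisherExact2x2 <- function(tab, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) ||
      any(tab != round(tab)) || anyNA(tab))
    stop("tab must be a 2x2 matrix of non-negative integers")
  m <- sum(tab[1L, ]); n2 <- sum(tab[2L, ])
  cs <- colSums(tab)
  if (m == 0 || n2 == 0 || any(cs == 0)) return(1)
  k <- cs[1L]                     # first-column total
  x <- tab[1L, 1L]
  support <- max(0L, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  if (alternative == "greater")
    return(sum(dens[support >= x]))
  rel <- 1 + 1e-7                 # tolerance for equal-probability tables
  min(1, sum(dens[dens <= dens[support == x] * rel]))
}

#' Group enriched terms by gene-membership agreement (Cohen's kappa)
#'
#' Computes Cohen's kappa between every pair of enriched sets, comparing
#' their gene-membership indicator vectors over the background universe,
#' and forms single-linkage groups from pairs with
#' `kappa >= kappaThreshold`. Terms sharing a significant number of genes
#' therefore collapse into one group, represented by the member with the
#' largest query overlap `k` — the convention used for redundancy reduction
#' of enriched annotation terms.
#'
#' @param enrichment data.frame from [hypergeomEnrich()] (typically after
#'   filtering to `q < 0.05`); needs columns `set` and `k`.
#' @param sets the gene-set collection the results came from.
#' @param background the background universe used for the enrichment.
#' @param kappaThreshold linkage threshold (0.4 is the conventional
#'   default).
#' @return data.frame with columns `group`, `set`, `k`,
#'   `representative`; the pairwise kappa matrix is attached as
#'   `attr(result, "kappa")`.
#' @export
kappaGroup <- function(enrichment, sets, background, kappaThreshold = 0.4) {
  if (!nrow(enrichment)) stop("no enriched sets to group")
  background <- unique(background)
  nm <- enrichment$set
  M <- vapply(nm, function(s)
    as.numeric(background %in% sets[[s]]), numeric(length(background)))
  kap <- .pairwiseKappa(M)
  adj <- kap >= kappaThreshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(seq_along(nm), comp)
  res <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    ix <- groups[[gi]]
    rep <- nm[ix][which.max(enrichment$k[ix])]
    data.frame(group = gi, set = nm[ix], k = enrichment$k[ix],
               representative = rep, stringsAsFactors = FALSE)
  }))
  # stable ordering: groups by size then representative name
  ord <- order(-ave(res$group, res$group, FUN = length), res$representative,
               res$set)
  res <- res[ord, ]
  res$group <- match(res$representative, unique(res$representative))
  rownames(res) <- NULL
  attr(res, "kappa") <- kap
  res
}

# Cohen's kappa between all columns of a 0/1 matrix
.pairwiseKappa <- function(M) {
  N <- nrow(M)
  a <- crossprod(M)                       # both present
  cs <- colSums(M)
  b <- outer(cs, cs, function(x, y) x) - a  # in i only
  cC <- outer(cs, cs, function(x, y) y) - a # in j only
  d <- N - a - b - cC
  po <- (a + d) / N
  pe <- (((a + b) / N) * ((a + cC) / N)) + (((cC + d) / N) * ((b + d) / N))
  kap <- ifelse(abs(1 - pe) < 1e-12, 1, (po - pe) / (1 - pe))
  dimnames(kap) <- dimnames(a)
  kap
}

#' Intersect significant terms from two enrichment analyses
#'
#' Compares the sets called significant (`q < qThreshold`) in two
#' enrichment result tables over a shared gene-set naming, optionally per
#' category family (a prefix or a supplied mapping), and reports counts in
#' each analysis, the intersection, and the intersection as a percentage of
#' the second analysis' terms.
#'
#' @param resA,resB data.frames from [hypergeomEnrich()].
#' @param qThreshold significance cutoff on `q`.
#' @param family optional named character vector mapping set names to
#'   category families; one row per family is then reported.
#' @return data.frame with columns `family`, `n_a`, `n_b`,
#'   `n_intersection`, `pct_of_b`.
#' @export
intersectTermLists <- function(resA, resB, qThreshold = 0.05,
                               family = NULL) {
  if (!length(intersect(resA$set, resB$set)))
    stop("the two result tables share no gene-set names")
  sigA <- resA$set[resA$q < qThreshold]
  sigB <- resB$set[resB$q < qThreshold]
  fam <- function(x) {
    if (is.null(family)) rep("all", length(x)) else unname(family[x])
  }
  fams <- sort(unique(c(fam(sigA), fam(sigB), if (is.null(family)) "all")))
  do.call(rbind, lapply(fams, function(f) {
    A <- sigA[fam(sigA) == f]; B <- sigB[fam(sigB) == f]
    inter <- intersect(A, B)
    data.frame(family = f, n_a = length(A), n_b = length(B),
               n_intersection = length(inter),
               pct_of_b = if (length(B)) 100 * length(inter) / length(B)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
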