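#' @include AllClasses.R AllGenerics.R
NULL

#' Build a thresholded Pearson coexpression network
#'
#' Computes pairwise Pearson correlations of gene expression across the
#' selected samples and connects gene pairs with `r >= threshold`
#' (positive correlations only: the threshold selects coregulation, and
#' anti-correlated pairs are never edges). Genes with zero variance over
#' the subset are excluded beforehand and recorded. For large gene sets
#' the correlation matrix is computed in tiles so memory stays linear in
#' the block size; the result is identical to the naive double loop.
#'
#' @param ae an [AgingExperiment-class], or a plain numeric matrix of
#'   expression values (genes x samples) to correlate as-is.
#' @param rThreshold correlation cutoff (default 0.95).
#' @param genes gene ids to include (default all).
#' @param samples sample ids to correlate over (default all); at least 3.
#' @param assay assay to use; correlations on `"logrpkm"` by default (set
#'   `assay = "rpkm"` for literal RPKM-scale correlation).
#' @param blockSize tile width for the blocked computation.
#' @return a [CorrelationNetwork-class] object.
#' @export
buildNetwork <- function(ae, rThreshold = 0.95, genes = rownames(ae),
                         samples = colnames(ae), assay = "logrpkm",
                         blockSize = 2000L) {
  vals <- if (is.matrix(ae)) ae else assayMatrix(ae, assay)
  x <- vals[genes, samples, drop = FALSE]
  if (ncol(x) < 3L) stop("at least 3 samples are required")
  v <- .rowVars(x)
  excluded <- rownames(x)[v == 0]
  x <- x[v > 0, , drop = FALSE]
  edges <- .thresholdEdges(t(x), rThreshold, blockSize)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  methods::new("CorrelationNetwork", graph = g, threshold = rThreshold,
               sampleSubset = samples, excludedGenes = excluded)
}

# edge list (gene_a, gene_b, r) with r >= threshold; x is samples x genes
.thresholdEdges <- function(x, threshold, blockSize = 2000L) {
  nG <- ncol(x)
  ids <- colnames(x)
  starts <- seq(1L, nG, by = blockSize)
  res <- list()
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]; i1 <- min(i0 + blockSize - 1L, nG)
    for (bj in bi:length(starts)) {
      j0 <- starts[bj]; j1 <- min(j0 + blockSize - 1L, nG)
      r <- stats::cor(x[, i0:i1, drop = FALSE], x[, j0:j1, drop = FALSE])
      hit <- which(r >= threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        gi <- i0 + hit[, 1L] - 1L
        gj <- j0 + hit[, 2L] - 1L
        keep <- gi < gj
        if (any(keep))
          res[[length(res) + 1L]] <- data.frame(
            gene_a = ids[gi[keep]], gene_b = ids[gj[keep]],
            r = r[hit][keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' @rdname CorrelationNetwork-accessors
#' @export
setMethod("networkGraph", "CorrelationNetwork", function(x) x@graph)

#' Accessors for CorrelationNetwork
#'
#' `networkGraph()` returns the underlying igraph object,
#' `networkEdges()` a three-column edge data.frame (`gene_a`, `gene_b`,
#' `r`), and `networkNodes()` the incident gene ids.
#'
#' @param x a [CorrelationNetwork-class].
#' @name CorrelationNetwork-accessors
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x) {
  e <- igraph::as_data_frame(x@graph, what = "edges")
  names(e) <- c("gene_a", "gene_b", "r")
  e
})

#' @rdname CorrelationNetwork-accessors
#' @export
setMethod("networkNodes", "CorrelationNetwork", function(x) {
  igraph::V(x@graph)$name
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork: r >=", object@threshold, "over",
      length(object@sampleSubset), "samples\n")
  cat(" ", igraph::gorder(object@graph), "nodes,",
      igraph::gsize(object@graph), "edges;",
      length(object@excludedGenes), "zero-variance genes excluded\n")
})

#' Identify the network hub and its first-neighbor subnetwork
#'
#' The hub is the node of maximal degree; ties are broken toward the
#' lexicographically smallest gene id (all tied genes are reported). The
#' first-neighbor subnetwork is the induced subgraph on the hub and its
#' direct neighbors.
#'
#' @param net a non-empty [CorrelationNetwork-class].
#' @return list with `hub`, `degree`, `ties` (all max-degree nodes),
#'   `neighborhoodNodes`, `neighborhoodEdges`.
#' @export
hubReport <- function(net) {
  g <- networkGraph(net)
  if (igraph::gorder(g) == 0L) stop("network is empty")
  deg <- igraph::degree(g)
  ties <- sort(names(deg)[deg == max(deg)])
  hub <- ties[1L]
  nb <- igraph::neighbors(g, hub)$name
  sub <- igraph::induced_subgraph(g, c(hub, nb))
  list(hub = hub, degree = as.integer(max(deg)), ties = ties,
       neighborhoodNodes = as.integer(igraph::gorder(sub)),
       neighborhoodEdges = as.integer(igraph::gsize(sub)))
}

#' Connected components of a coexpression network
#'
#' @param net a [CorrelationNetwork-class].
#' @return list of character vectors of gene ids, sorted by component size
#'   (descending), then by the lexicographically smallest member.
#' @export
networkComponents <- function(net) {
  g <- networkGraph(net)
  if (igraph::gorder(g) == 0L) return(list())
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  firsts <- vapply(sets, `[[`, character(1), 1L)
  unname(sets[order(-lengths(sets), firsts)])
}

#' Age-stratified coexpression networks
#'
#' Rebuilds the thresholded correlation network separately within each age
#' group's replicates (strata with fewer than 3 samples are skipped with a
#' warning), then compares the strata by the Jaccard index of their edge
#' sets. When per-gene cluster labels are supplied, the composition of
#' each component of each stratum network is tabulated against them —
#' revealing, e.g., disconnected groups of down- vs re-upregulated genes
#' at the oldest age. With only a handful of replicates per stratum the
#' correlation estimates are heavy-tailed, so stratum networks are sparser
#' and noisier than the all-sample network at the same threshold; the
#' threshold is deliberately not recalibrated.
#'
#' @inheritParams buildNetwork
#' @param clusterLabels optional named vector (gene id -> label).
#' @return list with `networks` (one [CorrelationNetwork-class] per age),
#'   `jaccard` (age x age matrix of edge-set Jaccard indices), and
#'   `composition` (per age, a list of per-component label tables; `NULL`
#'   when no labels were given).
#' @export
ageStratifiedNetworks <- function(ae, rThreshold = 0.95,
                                  genes = rownames(ae), assay = "logrpkm",
                                  clusterLabels = NULL) {
  ages <- ageWeeks(ae)
  groups <- sort(unique(ages))
  nets <- list()
  for (a in groups) {
    sel <- colnames(ae)[ages == a]
    if (length(sel) < 3L) {
      warning("age stratum ", a, " has fewer than 3 samples; skipped")
      next
    }
    nets[[as.character(a)]] <- buildNetwork(ae, rThreshold, genes = genes,
                                            samples = sel, assay = assay)
  }
  edgeKeys <- lapply(nets, function(nt) {
    e <- networkEdges(nt)
    paste(e$gene_a, e$gene_b, sep = "|")
  })
  nA <- length(nets)
  jac <- matrix(NA_real_, nA, nA, dimnames = list(names(nets), names(nets)))
  for (i in seq_len(nA)) for (j in seq_len(nA)) {
    un <- union(edgeKeys[[i]], edgeKeys[[j]])
    jac[i, j] <- if (length(un))
      length(intersect(edgeKeys[[i]], edgeKeys[[j]])) / length(un)
    else 1
  }
  composition <- NULL
  if (!is.null(clusterLabels)) {
    composition <- lapply(nets, function(nt) {
      lapply(networkComponents(nt), function(comp)
        table(clusterLabels[comp], useNA = "ifany"))
    })
  }
  list(networks = nets, jaccard = jac, composition = composition)
}

#' Export and re-import a network
#'
#' Writes both a GraphML file and a three-column TSV edge list
#' (`gene_a`, `gene_b`, `r`); `readGraphTsv()` reconstructs the igraph
#' object from the TSV so that node and edge sets round-trip exactly.
#'
#' @param net a [CorrelationNetwork-class].
#' @param graphmlFile,tsvFile output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
writeGraph <- function(net, graphmlFile = NULL, tsvFile = NULL) {
  written <- character()
  if (!is.null(graphmlFile)) {
    igraph::write_graph(networkGraph(net), graphmlFile, format = "graphml")
    written <- c(written, graphmlFile)
  }
  if (!is.null(tsvFile)) {
    .writeTsv(networkEdges(net), tsvFile)
    written <- c(written, tsvFile)
  }
  invisible(written)
}

#' @rdname writeGraph
#' @param path TSV edge-list path.
#' @export
readGraphTsv <- function(path) {
  e <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = FALSE)
}
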