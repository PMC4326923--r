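#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' AgingExperiment: a count matrix over an age-structured design
#'
#' `AgingExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with the constraints of a
#' cross-sectional aging design: an integer `"counts"` assay, a positive
#' per-gene transcript length in `rowData(x)$gene_length`, and per-sample
#' `age_weeks` and `replicate` columns in `colData`. At least two distinct
#' age groups with at least two replicates each are required, so that every
#' pairwise age-group comparison is testable.
#'
#' Normalized representations are carried as additional assays: [rpkm()]
#' adds a `"rpkm"` assay (reads per kilobase per million mapped reads) and
#' [logTransform()] a `"logrpkm"` assay (log2 of RPKM plus a pseudocount).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [AgingExperiment()] for construction from matrices,
#'   [readAgingExperiment()] for construction from TSV files.
#' @export
setClass("AgingExperiment", contains = "SummarizedExperiment")

.validAgingExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and sample identifiers (dimnames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated gene id: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample id: %s",
                          colnames(object)[duplicated(colnames(object))][1L]))
  if (anyNA(cts) || any(cts < 0) || any(abs(cts - round(cts)) > 1e-8))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene_length" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'gene_length' is required")
  } else if (anyNA(rd$gene_length) || any(rd$gene_length <= 0)) {
    msg <- c(msg, "gene_length must be strictly positive")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("age_weeks", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData columns 'age_weeks' and 'replicate' are required")
  } else {
    if (anyNA(cd$age_weeks) || any(cd$age_weeks <= 0))
      msg <- c(msg, "age_weeks must be positive")
    if (anyNA(cd$replicate) || any(cd$replicate < 1) ||
        any(cd$replicate != round(cd$replicate)))
      msg <- c(msg, "replicate must be a positive integer")
    tab <- table(cd$age_weeks)
    if (length(tab) < 2L)
      msg <- c(msg, "at least 2 distinct age groups are required")
    if (length(tab) >= 2L && any(tab < 2L))
      msg <- c(msg, sprintf("age group %s has fewer than 2 replicates",
                            names(tab)[tab < 2L][1L]))
  }
  if (length(msg)) msg else TRUE
}
setValidity("AgingExperiment", .validAgingExperiment)

#' Construct an AgingExperiment
#'
#' @param counts integer matrix of read counts, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param geneLengths numeric vector of transcript lengths in bases, one per
#'   gene, in row order of `counts`.
#' @param ageWeeks numeric vector of sample ages in weeks, one per column.
#' @param replicate integer vector of replicate indices within age group.
#'
#' @return A validated [AgingExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(60, 50), nrow = 6,
#'               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' ae <- AgingExperiment(cts, geneLengths = rep(1000, 6),
#'                       ageWeeks = rep(c(5, 39), each = 5),
#'                       replicate = rep(1:5, 2))
#' ae
#' @export
AgingExperiment <- function(counts, geneLengths, ageWeeks, replicate) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = as.numeric(geneLengths),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(age_weeks = as.numeric(ageWeeks),
                                   replicate = as.integer(replicate),
                                   row.names = colnames(counts)))
  methods::new("AgingExperiment", se)
}

#' FuzzyClustering: a fitted fuzzy c-means partition of temporal profiles
#'
#' Holds the soft membership matrix, the cluster centroids over the ordered
#' age groups, the final objective value and its per-iteration trajectory,
#' plus (after [validityVote()]) the validity-index table and the voted
#' number of clusters. Membership rows sum to one; the objective is
#' non-increasing over iterations; `clusterOrder` sorts clusters by hard
#' member count, largest first.
#'
#' @slot k integer, number of clusters.
#' @slot m numeric, fuzzifier exponent (> 1).
#' @slot membership numeric matrix, genes x k, rows summing to 1.
#' @slot centroids numeric matrix, k x ages.
#' @slot objective numeric, final value of the fuzzy objective.
#' @slot objectivePath numeric vector, objective per iteration of the best
#'   start.
#' @slot hardLabels integer vector, argmax membership per gene.
#' @slot clusterOrder integer permutation sorting clusters by size.
#' @slot validity data.frame of validity-index values per candidate k (may
#'   be empty when the fit was for a single k).
#' @slot chosenK integer, modal vote of the validity indices (NA when no
#'   vote was run).
#' @export
setClass("FuzzyClustering",
  representation(k = "integer", m = "numeric",
                 membership = "matrix", centroids = "matrix",
                 objective = "numeric", objectivePath = "numeric",
                 hardLabels = "integer", clusterOrder = "integer",
                 validity = "data.frame", chosenK = "integer"))

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  u <- object@membership
  if (ncol(u) != object@k) msg <- c(msg, "membership must have k columns")
  if (any(u < -1e-9) || any(u > 1 + 1e-9))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (any(abs(rowSums(u) - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (object@m <= 1) msg <- c(msg, "fuzzifier m must exceed 1")
  op <- object@objectivePath
  if (length(op) > 1L && any(diff(op) > 1e-8 * max(1, op[1L])))
    msg <- c(msg, "objective must be non-increasing over iterations")
  sz <- tabulate(object@hardLabels, nbins = object@k)
  if (is.unsorted(rev(sz[object@clusterOrder])))
    msg <- c(msg, "clusterOrder must sort clusters by size, descending")
  if (length(msg)) msg else TRUE
})

#' CorrelationNetwork: a thresholded Pearson coexpression graph
#'
#' An undirected graph over genes in which an edge joins two genes whose
#' Pearson correlation across the selected samples is at least `threshold`
#' (positive correlations only). Genes without any edge are not nodes.
#'
#' @slot graph an [igraph::igraph] object with edge attribute `r`.
#' @slot threshold numeric, the correlation cutoff used.
#' @slot sampleSubset character, the sample ids the correlations were
#'   computed over.
#' @slot excludedGenes character, zero-variance genes dropped before
#'   correlation.
#' @export
setClass("CorrelationNetwork",
  representation(graph = "ANY", threshold = "numeric",
                 sampleSubset = "character", excludedGenes = "character"))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::gsize(g) > 0) {
    w <- igraph::edge_attr(g, "r")
    if (is.null(w)) msg <- c(msg, "edges must carry attribute 'r'")
    else if (any(w < object@threshold - 1e-12))
      msg <- c(msg, "all edge weights must reach the threshold")
  }
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-edges are not allowed")
  if (igraph::gorder(g) > 0 && any(igraph::degree(g) == 0))
    msg <- c(msg, "isolated nodes must be excluded")
  if (length(msg)) msg else TRUE
})
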