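#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for AgingExperiment metadata
#'
#' `geneLengths()` returns per-gene transcript lengths (bases);
#' `ageWeeks()` and `replicateIndex()` the per-sample design columns;
#' `ageGroups()` the sorted unique ages.
#'
#' @param x an [AgingExperiment-class] object.
#' @return numeric (or integer) vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneLengths", "AgingExperiment", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$gene_length, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("ageWeeks", "AgingExperiment", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$age_weeks, colnames(x))
})

#' @rdname accessors
#' @export
setMethod("replicateIndex", "AgingExperiment", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$replicate, colnames(x))
})

#' @rdname accessors
#' @export
setMethod("ageGroups", "AgingExperiment", function(x) {
  sort(unique(SummarizedExperiment::colData(x)$age_weeks))
})

setMethod("show", "AgingExperiment", function(object) {
  ages <- table(SummarizedExperiment::colData(object)$age_weeks)
  cat("AgingExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  age groups (weeks):",
      paste0(names(ages), " (n=", as.integer(ages), ")", collapse = ", "),
      "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' RPKM normalization
#'
#' Computes reads per kilobase of transcript per million mapped reads,
#' `rpkm(g, s) = counts(g, s) * 1e9 / (length(g) * librarySize(s))`, where the
#' library size is the column total of the count matrix itself. The result is
#' stored as assay `"rpkm"`. Zeros are preserved exactly.
#'
#' @param x an [AgingExperiment-class] object with a `"counts"` assay.
#' @param ... unused.
#' @return `x` with an added (or replaced) `"rpkm"` assay.
#' @examples
#' # one gene of 1 kb carrying 10 of 1e6 reads has RPKM 10
#' @rdname rpkm
#' @export
setMethod("rpkm", "AgingExperiment", function(x, ...) {
  cts <- SummarizedExperiment::assay(x, "counts")
  libSize <- colSums(cts)
  if (any(libSize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(x)[libSize == 0], collapse = ", "))
  vals <- cts * 1e9 / outer(geneLengths(x), libSize)
  SummarizedExperiment::assay(x, "rpkm", withDimnames = FALSE) <- vals
  x
})

#' Log2 transformation of a normalized assay
#'
#' Applies `log2(value + pseudocount)` elementwise to the `"rpkm"` assay
#' (computing it first if absent) and stores the result as assay
#' `"logrpkm"`. The default pseudocount of 1 keeps zero RPKM at exactly 0.
#'
#' @param x an [AgingExperiment-class] object.
#' @param pseudocount positive real added before taking logs.
#' @param ... unused.
#' @return `x` with an added `"logrpkm"` assay.
#' @rdname logTransform
#' @export
setMethod("logTransform", "AgingExperiment",
          function(x, pseudocount = 1, ...) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (!"rpkm" %in% SummarizedExperiment::assayNames(x)) x <- rpkm(x)
  vals <- log2(SummarizedExperiment::assay(x, "rpkm") + pseudocount)
  SummarizedExperiment::assay(x, "logrpkm", withDimnames = FALSE) <- vals
  x
})

#' Retrieve a normalized matrix, computing it on demand
#'
#' @param x an [AgingExperiment-class] object.
#' @param assay one of `"counts"`, `"rpkm"`, `"logrpkm"`.
#' @param pseudocount passed to [logTransform()] when `"logrpkm"` must be
#'   computed.
#' @return a numeric matrix with gene rownames and sample colnames.
#' @export
assayMatrix <- function(x, assay = c("logrpkm", "rpkm", "counts"),
                        pseudocount = 1) {
  assay <- match.arg(assay)
  if (!assay %in% SummarizedExperiment::assayNames(x)) {
    x <- switch(assay,
      rpkm = rpkm(x),
      logrpkm = logTransform(x, pseudocount = pseudocount),
      stop("assay '", assay, "' not present"))
  }
  SummarizedExperiment::assay(x, assay)
}
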