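#' Read a count TSV and a sample sheet into an AgingExperiment
#'
#' The count file is tab-separated with a header row: column 1 the gene id,
#' column 2 the transcript length in bases, then one integer column per
#' sample. The sample sheet is tab-separated with columns `sample_id`,
#' `age_weeks`, `replicate` and must cover every count column exactly once.
#'
#' @param countFile path to the count TSV.
#' @param sampleFile path to the sample sheet TSV.
#' @return An [AgingExperiment-class] object with rows and columns in file
#'   order.
#' @export
readAgingExperiment <- function(countFile, sampleFile) {
  cm <- readCountTable(countFile)
  sheet <- readSampleSheet(sampleFile)
  missing <- setdiff(colnames(cm$counts), sheet$sample_id)
  extra <- setdiff(sheet$sample_id, colnames(cm$counts))
  if (length(missing) || length(extra))
    stop("sample sheet does not match count columns; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), ]
  AgingExperiment(cm$counts, geneLengths = cm$gene_lengths,
                  ageWeeks = sheet$age_weeks, replicate = sheet$replicate)
}

#' Read the raw count table
#'
#' @param path path to a count TSV (gene id, length, then sample columns).
#' @return list with elements `counts` (numeric matrix with dimnames) and
#'   `gene_lengths` (named numeric vector).
#' @export
readCountTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("count file needs a gene id column, a length column and at least ",
         "one sample column")
  if (nrow(df) == 0L) stop("no genes in count file '", path, "'")
  gid <- as.character(df[[1L]])
  if (anyDuplicated(gid))
    stop("duplicated gene id: ", gid[duplicated(gid)][1L])
  len <- df[[2L]]
  if (anyNA(len) || !is.numeric(len) || any(len <= 0))
    stop("gene lengths must be strictly positive numbers")
  cts <- as.matrix(df[, -(1:2), drop = FALSE])
  if (anyDuplicated(colnames(cts)))
    stop("duplicated sample id: ",
         colnames(cts)[duplicated(colnames(cts))][1L])
  bad <- which(is.na(cts) | cts < 0 | abs(cts - round(cts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-integer count at gene '%s', sample '%s'",
                 gid[bad[1L, 1L]], colnames(cts)[bad[1L, 2L]]))
  rownames(cts) <- gid
  list(counts = cts, gene_lengths = stats::setNames(as.numeric(len), gid))
}

#' Read a sample sheet TSV
#'
#' @param path path to a TSV with columns `sample_id`, `age_weeks`,
#'   `replicate`.
#' @return data.frame with those columns, in file order.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_weeks", "replicate")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  df$sample_id <- as.character(df$sample_id)
  df$age_weeks <- as.numeric(df$age_weeks)
  df$replicate <- as.integer(df$replicate)
  df[need]
}

#' Write an AgingExperiment back to its two TSV files
#'
#' Inverse of [readAgingExperiment()]: `readAgingExperiment()` applied to the
#' written files reproduces the object (round-trip identity on valid input).
#' Files are UTF-8 with Unix newlines and '.' as the decimal separator.
#'
#' @param x an [AgingExperiment-class] object.
#' @param countFile,sampleFile output paths.
#' @return invisibly, the two paths.
#' @export
writeAgingExperiment <- function(x, countFile, sampleFile) {
  cts <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(x),
                   length = unname(geneLengths(x)),
                   cts, check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, countFile)
  sheet <- data.frame(sample_id = colnames(x),
                      age_weeks = unname(ageWeeks(x)),
                      replicate = unname(replicateIndex(x)),
                      stringsAsFactors = FALSE)
  .writeTsv(sheet, sampleFile)
  invisible(c(countFile, sampleFile))
}

.writeTsv <- function(df, path, comments = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n", useBytes = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' A GMT line is `name<TAB>description<TAB>member1<TAB>member2...`. The
#' returned collection is a named list of character vectors with the
#' per-set descriptions kept in `attr(x, "descriptions")` — the lightweight
#' convention used by enrichment tooling.
#'
#' @param path path to a GMT file.
#' @return named list of member vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in '", path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene-set name: ", nm[duplicated(nm)][1L])
  short <- lengths(parts) < 3L
  if (any(short)) stop("empty gene set: ", nm[short][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors; descriptions taken from
#'   `attr(sets, "descriptions")` when present.
#' @export
writeGmt <- function(sets, path) {
  if (!length(sets) || is.null(names(sets)))
    stop("'sets' must be a non-empty named list")
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
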