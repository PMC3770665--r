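#' Read an expression-style TSV matrix
#'
#' Expects a header of sample names and a first column of probe ids.
#' Duplicate probe ids, non-numeric cells (reported with their row and
#' column) and empty files are errors.
#'
#' @param path path to a tab-separated file.
#' @return Numeric matrix with probe ids as rownames.
#' @examples
#' f <- tempfile(); writeExpressionTsv(matrix(1:6, 1,
#'   dimnames = list("p1", flowConditions())), f)
#' readExpressionTsv(f)
#' @export
readExpressionTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("empty input file (header only): ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probe ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], colnames(vals)[j], vals[[j]][bad[1L]]))
    m[, j] <- v
  }
  if (anyNA(m)) stop("missing values in matrix: ", path)
  m
}

#' Write a matrix as an expression-style TSV
#'
#' @param x numeric matrix with rownames (probe ids) and colnames (samples).
#' @param path output path.
#' @param id_column name of the first (probe id) column.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path, id_column = "probe_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a FlowExperiment as plain-text TSV files
#'
#' Writes `intensities.tsv`, `detection.tsv`, `annotations.tsv` and (when
#' ground truth is present) `truth.tsv` into a directory.
#'
#' @param x a [FlowExperiment-class].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @seealso [readFlowData()]
#' @export
writeFlowData <- function(x, dir) {
  stopifnot(is(x, "FlowExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTsv(intensities(x), file.path(dir, "intensities.tsv"))
  writeExpressionTsv(detectionP(x), file.path(dir, "detection.tsv"))
  ann <- data.frame(probe_id = rownames(x), symbol = geneSymbols(x),
                    stringsAsFactors = FALSE)
  write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- simTruth(x)
  if (!is.null(tr)) {
    trd <- data.frame(probe_id = rownames(x), as.data.frame(tr),
                      stringsAsFactors = FALSE)
    write.table(trd, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a FlowExperiment from TSV files
#'
#' Counterpart of [writeFlowData()]; also accepts explicit file paths for
#' data produced elsewhere.
#'
#' @param dir directory containing `intensities.tsv`, `detection.tsv`,
#'   `annotations.tsv` and optionally `truth.tsv`; or `NULL` when the three
#'   file arguments are given.
#' @param intensities_file,detection_file,annotations_file explicit paths
#'   (override `dir`).
#' @return A [FlowExperiment-class].
#' @export
readFlowData <- function(dir = NULL, intensities_file = NULL,
                         detection_file = NULL, annotations_file = NULL) {
  if (!is.null(dir)) {
    intensities_file <- intensities_file %||% file.path(dir, "intensities.tsv")
    detection_file <- detection_file %||% file.path(dir, "detection.tsv")
    annotations_file <- annotations_file %||% file.path(dir, "annotations.tsv")
  }
  ints <- readExpressionTsv(intensities_file)
  dp <- readExpressionTsv(detection_file)
  ann <- read.delim(annotations_file, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("probe_id", "symbol") %in% colnames(ann)))
    stop("annotations file needs columns 'probe_id' and 'symbol'")
  if (!identical(rownames(ints), ann$probe_id))
    stop("annotation probe ids do not match the intensity matrix")
  truth <- NULL
  truth_file <- if (!is.null(dir)) file.path(dir, "truth.tsv") else NULL
  if (!is.null(truth_file) && file.exists(truth_file)) {
    td <- read.delim(truth_file, header = TRUE, sep = "\t")
    truth <- td[, setdiff(colnames(td), "probe_id"), drop = FALSE]
  }
  FlowExperiment(ints, dp, ann$symbol, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
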