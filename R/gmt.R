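#' Read a GMT gene-set file
#'
#' GMT is tab-separated, one set per line: name, description, then member
#' genes. Members are deduplicated per set; duplicate set names, lines with
#' fewer than three fields, and empty sets are errors.
#'
#' @param path path to a GMT file.
#' @param universe optional universe to harmonize against (see
#'   [geneSets()]); defaults to the union of all set members.
#' @return A [GeneSets-class] collection; set descriptions are kept in
#'   `metadata`-style attribute `"descriptions"`.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SETX\tdesc\tA\tB\tA", f)
#' setList(readGmt(f))
#' @export
readGmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- setNames(lapply(fields, function(f) unique(f[-c(1L, 2L)])), nm)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gs <- geneSets(sets, universe)
  attr(gs, "descriptions") <- setNames(desc, nm)
  gs
}

#' Write a gene-set collection as GMT
#'
#' @param x a [GeneSets-class] collection, or a named list of character
#'   vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeGmt(list(S1 = c("A", "B")), f)
#' readLines(f)
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
  sets <- if (is(x, "GeneSets")) setList(x) else x
  if (is.null(descriptions)) {
    descriptions <- attr(x, "descriptions")
    if (is.null(descriptions))
      descriptions <- setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
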