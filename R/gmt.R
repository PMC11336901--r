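#' Read a GMT gene-set file
#'
#' GMT is the tab-delimited gene-set format: one set per line —
#' set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors (descriptions kept as the
#'   `"description"` attribute of each element).
#' @export
read_gmt <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    check_that(length(f) >= 3, "malformed GMT line (need name, desc, genes)")
    structure(unique(f[-(1:2)]), description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  check_that(!anyDuplicated(names(sets)), "duplicated gene-set name in GMT")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors; an optional
#'   `"description"` attribute per element is written to column 2.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  check_that(is.list(sets) && !is.null(names(sets)),
             "sets must be a named list")
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(d)) nm else d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
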