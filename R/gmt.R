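#' Read a GMT gene-set collection
#'
#' Parses the MSigDB-style GMT dialect: one gene set per line,
#' `name TAB description TAB gene1 TAB gene2 ...`. The description column
#' is discarded; duplicate genes within a line are deduplicated keeping
#' first occurrence; lines with fewer than three fields are skipped with a
#' warning, as are sets that end up empty.
#'
#' @param path GMT file
#' @param name collection name (defaults to the file name without extension)
#' @return a `PathwayCollection`: a named list of character gene vectors,
#'   with the collection name as attribute `"name"`
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      warning("skipping GMT line ", i, " (fewer than 3 fields)")
      next
    }
    genes <- unique(fields[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("dropping empty gene set '", fields[1L], "' (line ", i, ")")
      next
    }
    sets[[fields[1L]]] <- genes
  }
  if (!length(sets)) stop("no usable gene sets in ", path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  pathway_collection(sets, name)
}

#' Construct a pathway collection from a named list of gene sets
#' @param sets named list, pathway name -> character vector of gene ids
#' @param name collection name
#' @return a `PathwayCollection`
#' @export
pathway_collection <- function(sets, name = "pathways") {
  if (!length(sets)) stop("empty pathway collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every pathway needs a name")
  }
  if (anyDuplicated(names(sets))) stop("pathway names must be unique")
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set in collection")
  structure(lapply(sets, as.character), name = name,
            class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  sizes <- vapply(x, length, 1L)
  cat(sprintf("PathwayCollection '%s': %d sets, %d-%d genes each\n",
              attr(x, "name"), length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Write a pathway collection as GMT
#' @param p a `PathwayCollection`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(p, path) {
  lines <- vapply(names(p), function(nm) {
    paste(c(nm, "na", p[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
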