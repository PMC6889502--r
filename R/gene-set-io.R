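#' Write a signature as a pair of GRP tag files
#'
#' GRP dialect: one identifier per line, `#` lines are comments. The pair is
#' written as `<name>_up.grp` and `<name>_down.grp` under `dir`.
#'
#' @param sig a [gene_signature()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths (up, down).
#' @export
write_signature_grp <- function(sig, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  up_path <- file.path(dir, paste0(sig$name, "_up.grp"))
  dn_path <- file.path(dir, paste0(sig$name, "_down.grp"))
  writeLines(c(paste0("# ", sig$name, " up tags"), sig$up_tags), up_path)
  writeLines(c(paste0("# ", sig$name, " down tags"), sig$down_tags), dn_path)
  invisible(c(up = up_path, down = dn_path))
}

#' Read one GRP tag file
#'
#' @param path path to a GRP file (one identifier per line; `#` comments and
#'   blank lines ignored).
#' @return character vector of identifiers.
#' @export
read_grp <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a signature from a pair of GRP files
#'
#' @param up_path,down_path paths to the up and down tag files.
#' @param name signature label; defaults to the shared file-name stem.
#' @return a [gene_signature()].
#' @export
read_signature_grp <- function(up_path, down_path, name = NULL) {
  if (is.null(name)) {
    name <- sub("_up\\.grp$", "", basename(up_path))
  }
  gene_signature(name, read_grp(up_path), read_grp(down_path))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members...
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(!is.null(names(sets)), "sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
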