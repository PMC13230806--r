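#' Read a wide abundance TSV
#'
#' Expects a tab-separated file whose first column holds sample ids and
#' whose header names the aptamers. Duplicate ids and non-numeric cells are
#' rejected with the offending row/column named.
#'
#' @param path file path.
#' @return An [abundance_matrix()] with an empty transform ledger.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed abundance file: fewer than 2 columns")
  apt <- header[-1]
  if (anyDuplicated(apt))
    stop("duplicate aptamer column(s): ",
         paste(unique(apt[duplicated(apt)]), collapse = ", "))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                          check.names = FALSE, data.table = FALSE)
  sid <- dt[[1]]
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(dt), length(apt), dimnames = list(sid, apt))
  for (j in seq_along(apt)) {
    v <- suppressWarnings(as.numeric(dt[[j + 1L]]))
    bad <- which(is.na(v) & !(dt[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (sample %s), column %s",
                   dt[[j + 1L]][bad[1]], bad[1], sid[bad[1]], apt[j]))
    vals[, j] <- v
  }
  abundance_matrix(vals)
}

#' Write a wide abundance TSV at full precision
#'
#' @param matrix an `AbundanceMatrix` or numeric matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_abundance <- function(matrix, path) {
  m <- as_abundance(matrix)$values
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read sample metadata / aptamer annotation TSVs
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  md
}

#' @rdname read_metadata
#' @export
read_annotation <- function(path) {
  an <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("aptamer_id", "gene", "intracellular")
  miss <- setdiff(need, names(an))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  an$intracellular <- as.logical(an$intracellular)
  an
}

#' Read / write gene sets in GMT format
#'
#' Standard 3+ column tab-separated format: set name, description, then one
#' gene per remaining field.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (needs name, description, >=1 gene): ", ln)
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  if (length(sets) && is.null(names(sets))) stop("gene sets must be named")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
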