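#' Abundance matrix with a transform ledger
#'
#' Container for a samples x aptamers abundance matrix. Each preprocessing
#' step appends its name to an ordered ledger so that pipeline order
#' (natural log before standardisation, batch adjustment before residual
#' adjustment for the intracellular protein score) can be enforced rather
#' than assumed.
#'
#' @param values numeric matrix, samples in rows and aptamers in columns;
#'   must carry unique row and column names.
#' @param ledger character vector of transforms already applied, in order.
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values` (the matrix) and `ledger`.
#' @export
abundance_matrix <- function(values, ledger = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample (row) and aptamer (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate aptamer ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, ledger = as.character(ledger)),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d samples x %d aptamers\n",
              nrow(x$values), ncol(x$values)))
  cat("transforms applied:",
      if (length(x$ledger)) paste(x$ledger, collapse = " -> ") else "(none)", "\n")
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' @export
as.matrix.AbundanceMatrix <- function(x, ...) x$values

## Accept either an AbundanceMatrix or a bare matrix; returns AbundanceMatrix.
as_abundance <- function(x, default_ledger = character()) {
  if (inherits(x, "AbundanceMatrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("A", seq_len(ncol(x)))
    return(abundance_matrix(x, default_ledger))
  }
  stop("expected an AbundanceMatrix or a numeric matrix")
}

has_transform <- function(x, what) what %in% x$ledger

require_transform <- function(x, what, op) {
  if (!has_transform(x, what))
    stop(sprintf("%s requires '%s' to have been applied first (ledger: %s)",
                 op, what,
                 if (length(x$ledger)) paste(x$ledger, collapse = " -> ") else "empty"),
         call. = FALSE)
  invisible(TRUE)
}

forbid_transform <- function(x, what, op) {
  if (has_transform(x, what))
    stop(sprintf("%s: '%s' already applied (ledger: %s)", op, what,
                 paste(x$ledger, collapse = " -> ")), call. = FALSE)
  invisible(TRUE)
}

add_transform <- function(x, what) {
  x$ledger <- c(x$ledger, what)
  x
}
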