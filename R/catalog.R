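#' Build a drug catalog
#'
#' A catalog is the ordered set of drug identifiers that fixes the row (and
#' column) order of every matrix in an analysis.  All files exchange
#' identifiers, never positional indices.
#'
#' @param ids Character vector of drug identifiers (e.g. DrugBank accessions).
#' @return A character vector of unique, non-empty identifiers, in the order
#'   first supplied, with class `drug_catalog`.
#' @examples
#' drug_catalog(c("DB00001", "DB00002"))
#' @export
drug_catalog <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) == 0) stop("catalog must contain at least one identifier")
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("drug identifiers must be non-empty strings")
  }
  ids <- ids[!duplicated(ids)]
  structure(ids, class = "drug_catalog")
}

#' Position of identifiers in a catalog
#'
#' @param catalog A [drug_catalog()] (or plain character vector).
#' @param ids Identifiers to look up.
#' @return Integer positions; an error names any identifier absent from the
#'   catalog.
#' @export
catalog_index <- function(catalog, ids) {
  idx <- match(ids, catalog)
  if (anyNA(idx)) {
    stop("unknown drug identifier(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("<drug_catalog> ", length(x), " drugs: ",
      paste(utils::head(x, 5), collapse = ", "),
      if (length(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

## internal validators shared by readers and the fitters ----------------------

# checks an interaction matrix: square, binary, symmetric, zero diagonal
validate_network <- function(J, require_edge = FALSE) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) {
    stop("interaction matrix must be square")
  }
  if (!all(J %in% c(0, 1))) stop("interaction matrix entries must be 0/1")
  if (any(diag(J) != 0)) stop("interaction matrix must have a zero diagonal")
  if (!isTRUE(all.equal(J, t(J)))) stop("interaction matrix must be symmetric")
  if (require_edge && sum(J) == 0) {
    stop("interaction network has no known interactions")
  }
  invisible(J)
}

# checks one binary drug x descriptor incidence matrix against a catalog
validate_features <- function(H, catalog = NULL) {
  if (!is.matrix(H)) stop("feature matrix must be a matrix")
  if (!all(H %in% c(0, 1))) stop("feature matrix entries must be 0/1")
  if (!is.null(catalog)) {
    if (nrow(H) != length(catalog) ||
        !identical(as.character(rownames(H)), as.character(catalog))) {
      stop("feature matrix rows are not aligned to the catalog")
    }
  }
  invisible(H)
}

# checks that a list of feature matrices shares one catalog with the network
validate_inputs <- function(features, network) {
  validate_network(network)
  ids <- rownames(network)
  if (is.null(ids)) stop("interaction matrix must carry drug ids as dimnames")
  if (!is.list(features) || length(features) == 0) {
    stop("`features` must be a non-empty list of feature matrices")
  }
  for (H in features) validate_features(H, ids)
  invisible(ids)
}
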