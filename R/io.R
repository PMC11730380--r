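# Readers and writers for the plain-text shapes the tool exchanges:
# interaction edge lists, binary feature tables (long or wide), SMI files,
# and ranked prediction tables.

# guesses the field delimiter of a line: tab, comma, or whitespace
sniff_delim <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "[[:space:]]+"
}

split_fields <- function(lines, delim) {
  lapply(strsplit(lines, delim), function(x) trimws(x[nzchar(trimws(x))]))
}

#' Read a drug-drug interaction edge list
#'
#' Each row lists one interacting pair of drug identifiers (tab- or
#' comma-separated; the delimiter is detected from the first line).  Edges
#' are unordered: an edge in either direction sets both `J[i, j]` and
#' `J[j, i]`.  Self-pairs are dropped with a warning.
#'
#' @param path Path to the edge list.
#' @param catalog Optional [drug_catalog()] fixing the row order.  When
#'   absent, a catalog is built from the union of identifiers in
#'   first-appearance order.
#' @return A binary symmetric interaction matrix with drug identifiers as
#'   dimnames and attribute `"catalog"` carrying the catalog.
#' @export
read_interactions <- function(path, catalog = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty interaction file: ", path)
  delim <- sniff_delim(lines[[1]])
  rows <- split_fields(lines, delim)
  bad <- which(vapply(rows, length, 1L) < 2)
  if (length(bad)) {
    stop("row ", bad[1], " of ", path, " has fewer than 2 identifier fields")
  }
  a <- vapply(rows, `[[`, "", 1L)
  b <- vapply(rows, `[[`, "", 2L)
  if (is.null(catalog)) {
    catalog <- drug_catalog(as.vector(rbind(a, b)))
  }
  ia <- catalog_index(catalog, a)
  ib <- catalog_index(catalog, b)
  self <- ia == ib
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped from ", path)
    ia <- ia[!self]; ib <- ib[!self]
  }
  n <- length(catalog)
  J <- matrix(0, n, n, dimnames = list(as.character(catalog),
                                       as.character(catalog)))
  J[cbind(ia, ib)] <- 1
  J[cbind(ib, ia)] <- 1
  attr(J, "catalog") <- catalog
  J
}

#' Read a binary drug-feature table
#'
#' Accepts two shapes.  Long form: two columns `drug_id, descriptor_id`, one
#' incidence per row, no header.  Wide form: a header row of descriptor
#' labels followed by rows of `drug_id` plus 0/1 cells.  A file whose rows
#' carry more than two fields is treated as wide; two-field files are long.
#'
#' Drugs in the catalog but absent from the file get all-zero rows (logged
#' via `message()`), mirroring ragged database exports.
#'
#' @param path Path to the table.
#' @param catalog A [drug_catalog()]; rows of the result follow its order.
#' @param feature_name Label for the feature space (e.g. `"pathway"`).
#' @param strict Error on drug identifiers not in the catalog instead of
#'   skipping them.
#' @return Binary matrix (drugs x descriptors) with attribute
#'   `"feature_name"`.
#' @export
read_feature_table <- function(path, catalog, feature_name = basename(path),
                               strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty feature file: ", path)
  delim <- sniff_delim(lines[[1]])
  rows <- split_fields(lines, delim)
  wide <- length(rows[[1]]) > 2
  ids <- as.character(catalog)
  if (wide) {
    descriptors <- rows[[1]]
    # tolerate a leading id-column name in the header
    body <- rows[-1]
    ncell <- length(descriptors)
    if (all(vapply(body, length, 1L) == ncell + 1L)) {
      # header holds descriptor labels only
    } else if (all(vapply(body, length, 1L) == ncell)) {
      descriptors <- descriptors[-1]   # first header field names the id column
    } else {
      stop("ragged wide-form feature table: ", path)
    }
    H <- matrix(0, length(ids), length(descriptors),
                dimnames = list(ids, descriptors))
    seen <- character(0)
    for (r in body) {
      id <- r[[1]]
      cells <- r[-1]
      if (!all(cells %in% c("0", "1"))) {
        stop("wide-form cell not in {0,1} for drug ", id, " in ", path)
      }
      if (!id %in% ids) {
        if (strict) stop("unknown drug identifier in feature table: ", id)
        next
      }
      H[id, ] <- as.numeric(cells)
      seen <- c(seen, id)
    }
  } else {
    a <- vapply(rows, `[[`, "", 1L)
    d <- vapply(rows, function(r) if (length(r) >= 2) r[[2]] else "", "")
    if (any(!nzchar(d))) stop("long-form row with fewer than 2 fields in ", path)
    known <- a %in% ids
    if (any(!known)) {
      if (strict) {
        stop("unknown drug identifier in feature table: ",
             paste(unique(a[!known]), collapse = ", "))
      }
      message(sum(!known), " incidence row(s) for drugs outside the catalog ",
              "skipped in ", basename(path))
      a <- a[known]; d <- d[known]
    }
    descriptors <- unique(d)
    H <- matrix(0, length(ids), length(descriptors),
                dimnames = list(ids, descriptors))
    H[cbind(a, d)] <- 1
    seen <- unique(a)
  }
  missing <- setdiff(ids, seen)
  if (length(missing)) {
    message(length(missing), " catalog drug(s) absent from ",
            basename(path), "; rows left all-zero")
  }
  attr(H, "feature_name") <- feature_name
  H
}

#' Read a SMILES (SMI) file
#'
#' Standard SMI convention is one record per line, `SMILES<ws>identifier`.
#' Two-column `identifier<delim>SMILES` tables are supported with
#' `id_first = TRUE`.  Blank lines are skipped; a duplicated identifier is
#' overridden by its last record with a warning.
#'
#' @param path Path to the SMI file.
#' @param id_first The identifier precedes the SMILES string on each line.
#' @return Named character vector, identifier -> SMILES.
#' @export
read_smiles <- function(path, id_first = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty SMILES file: ", path)
  rows <- split_fields(lines, if (id_first) sniff_delim(lines[[1]])
                       else "[[:space:]]+")
  if (any(vapply(rows, length, 1L) < 2)) {
    stop("SMILES record with a missing field in ", path)
  }
  smi <- vapply(rows, `[[`, "", if (id_first) 2L else 1L)
  id <- vapply(rows, `[[`, "", if (id_first) 1L else 2L)
  if (any(!nzchar(smi))) stop("empty SMILES field in ", path)
  dup <- duplicated(id, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate identifier(s) in ", basename(path),
            "; later records override: ",
            paste(unique(id[dup]), collapse = ", "))
  }
  stats::setNames(smi[!dup], id[!dup])
}

#' Write a ranked prediction table
#'
#' Rows are sorted by descending score; ties break on
#' `(drug_a, drug_b)` lexicographically.  Scores are written with 8
#' significant digits.
#'
#' @param predictions Data frame with columns `drug_a`, `drug_b`, `score`,
#'   and optionally `severity_score` and `severity_level`.
#' @param path Output CSV path.
#' @return The sorted data frame, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  req <- c("drug_a", "drug_b", "score")
  if (!all(req %in% names(predictions))) {
    stop("predictions need columns: ", paste(req, collapse = ", "))
  }
  if (!all(is.finite(predictions$score))) stop("scores must be finite")
  ord <- order(-predictions$score, predictions$drug_a, predictions$drug_b)
  out <- predictions[ord, , drop = FALSE]
  keep <- intersect(c(req, "severity_score", "severity_level",
                      "severity_flag"), names(out))
  out <- out[, keep, drop = FALSE]
  fmt <- out
  fmt$score <- sprintf("%.8g", out$score)
  if ("severity_score" %in% keep) {
    fmt$severity_score <- ifelse(is.na(out$severity_score), "NA",
                                 sprintf("%.8g", out$severity_score))
  }
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path CSV path.
#' @return Data frame with at least `drug_a`, `drug_b`, `score`.
#' @export
read_predictions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$score <- as.numeric(out$score)
  out
}

#' Chemical-substructure descriptor labels
#'
#' The packaged 881-entry descriptor label list for the chemical
#' substructure feature space, matching the dimensionality of the standard
#' PubChem substructure fingerprint.  Labels are positional
#' (`PCFP0000` ... `PCFP0880`); the substructure definitions themselves are
#' not bundled.
#'
#' @return Character vector of 881 labels.
#' @export
substructure_descriptors <- function() {
  path <- system.file("extdata", "substructure_descriptors.txt",
                      package = "ddilearn", mustWork = TRUE)
  readLines(path)
}
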