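# Severity grading of predicted interactions.
#
# Molecular structure similarity is a weighted blend of Tanimoto, Dice and
# cosine coefficients over hashed binary fingerprints.  A predicted
# interaction (C, B) inherits a 1-100 severity score from the known
# interactors A of B, weighted by the structural similarity of C to each A,
# and the score is banded into MINOR / MODERATE / MAJOR.

#' Construct a fingerprint from explicit bit positions
#'
#' @param bits Integer vector of set-bit positions in `[0, nbits)`.
#' @param nbits Fingerprint length.
#' @param source Optional provenance tag (e.g. the SMILES string).
#' @return Object of class `ddi_fingerprint`.
#' @export
bit_fingerprint <- function(bits, nbits = 1024, source = "synthetic") {
  bits <- sort(unique(as.integer(bits)))
  if (nbits < 1) stop("nbits must be >= 1")
  if (length(bits) && (min(bits) < 0 || max(bits) >= nbits)) {
    stop("bit positions must lie in [0, nbits)")
  }
  structure(list(bits = bits, nbits = as.integer(nbits), source = source),
            class = "ddi_fingerprint")
}

#' @export
print.ddi_fingerprint <- function(x, ...) {
  cat("<ddi_fingerprint> ", length(x$bits), "/", x$nbits, " bits set (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Hashed structural fingerprints from SMILES strings
#'
#' Parses each SMILES string and computes the 1024-bit path-based FP2
#' fingerprint via Open Babel (through ChemmineR/ChemmineOB).  The
#' fingerprint is a function of the molecular graph, so different spellings
#' of the same molecule give identical bit sets.
#'
#' @param smiles Named character vector of SMILES strings (names become the
#'   fingerprint identifiers).
#' @return Named list of [bit_fingerprint()] objects (nbits = 1024).
#' @export
smiles_fingerprint <- function(smiles) {
  smiles <- unlist(smiles)
  if (is.null(names(smiles))) names(smiles) <- paste0("mol", seq_along(smiles))
  if (any(!nzchar(smiles))) stop("empty SMILES string supplied")
  out <- vector("list", length(smiles))
  names(out) <- names(smiles)
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
      error = function(e) stop("unparsable SMILES for '", names(smiles)[i],
                               "': ", smiles[[i]], call. = FALSE))
    if (!ChemmineR::validSDF(sdf)) {
      # path fingerprints need at least one bond; single-heavy-atom
      # molecules (e.g. methane) have none
      stop("cannot fingerprint '", names(smiles)[i], "' (", smiles[[i]],
           "): no bonded heavy-atom structure", call. = FALSE)
    }
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
    row <- methods::slot(fp, "fpma")[1, ]
    out[[i]] <- bit_fingerprint(which(row != 0) - 1L, nbits = length(row),
                                source = unname(smiles[i]))
  }
  out
}

#' Weighted molecular structure similarity
#'
#' Blends three set statistics of two binary fingerprints:
#' \deqn{\alpha \frac{|A \cap B|}{|A \cup B|} +
#'       \beta \frac{2|A \cap B|}{|A| + |B|} +
#'       (1 - \alpha - \beta) \frac{|A \cap B|}{\sqrt{|A||B|}}}
#' (Tanimoto, Dice, and cosine on the 0/1 bit vectors).  Symmetric in its
#' arguments and bounded in \[0, 1\] whenever the weights are non-negative
#' and sum to at most 1.
#'
#' @param a,b [bit_fingerprint()] objects of equal length, each with at
#'   least one bit set.
#' @param alpha,beta Tanimoto and Dice weights (defaults 0.5 and 0.2; the
#'   cosine weight is `1 - alpha - beta`).
#' @return Similarity in \[0, 1\].
#' @examples
#' a <- bit_fingerprint(c(1, 2), 8)
#' b <- bit_fingerprint(c(2, 3), 8)
#' fingerprint_similarity(a, b)  # 0.5/3 + 0.2/2 + 0.3/2
#' @export
fingerprint_similarity <- function(a, b, alpha = 0.5, beta = 0.2) {
  if (!inherits(a, "ddi_fingerprint") || !inherits(b, "ddi_fingerprint")) {
    stop("both arguments must be ddi_fingerprint objects")
  }
  if (a$nbits != b$nbits) stop("fingerprints have different lengths")
  if (length(a$bits) == 0 || length(b$bits) == 0) {
    stop("similarity undefined for an all-zero fingerprint")
  }
  if (alpha < 0 || beta < 0 || alpha + beta > 1) {
    stop("need alpha, beta >= 0 and alpha + beta <= 1")
  }
  inter <- length(intersect(a$bits, b$bits))
  na <- length(a$bits)
  nb <- length(b$bits)
  union_ <- na + nb - inter
  alpha * inter / union_ + beta * 2 * inter / (na + nb) +
    (1 - alpha - beta) * inter / sqrt(na * nb)
}

#' Severity score bands
#'
#' The 1-100 score scale maps to three levels: 1-30 MINOR, 31-60 MODERATE,
#' 61-100 MAJOR.
#'
#' @return Data frame with columns `lower`, `upper`, `level`.
#' @export
severity_bands <- function() {
  data.frame(lower = c(1, 31, 61), upper = c(30, 60, 100),
             level = c("MINOR", "MODERATE", "MAJOR"),
             stringsAsFactors = FALSE)
}

#' Severity level of a score
#'
#' Scores are real-valued; banding applies to the half-up rounded integer.
#'
#' @param score Numeric score(s) in \[1, 100\].
#' @param bands Band table as from [severity_bands()].
#' @return Character vector of levels.
#' @export
severity_level <- function(score, bands = severity_bands()) {
  if (any(!is.finite(score)) || any(score < 1) || any(score > 100)) {
    stop("severity scores must lie in [1, 100]")
  }
  rounded <- floor(score + 0.5)
  vapply(rounded, function(s) {
    bands$level[bands$lower <= s & s <= bands$upper][1]
  }, "")
}

#' Infer the severity of a predicted interaction
#'
#' For a predicted pair (C, B), takes the known interactors A of B together
#' with their recorded 1-100 severity scores against B, and transfers a
#' score to (C, B) as the similarity-weighted average over neighbours whose
#' structural similarity to C reaches `sim_cutoff`.  If no neighbour passes
#' the cutoff, the single most similar neighbour is used and the result is
#' flagged low-confidence.
#'
#' @param drug_c Identifier of the new partner C.
#' @param known Data frame with columns `drug` (the A identifiers) and
#'   `score` (their severity against B, in \[1, 100\]).
#' @param fingerprints Named list of [bit_fingerprint()] objects covering
#'   `drug_c` and every neighbour.
#' @param sim_cutoff Similarity threshold for a neighbour to contribute.
#' @param alpha,beta Similarity weights (see [fingerprint_similarity()]).
#' @param bands Band table for the level assignment.
#' @return Object of class `ddi_severity`: `score`, `level`,
#'   `low_confidence`, and `neighbors` (data frame of drug, similarity,
#'   known score, used flag).
#' @export
infer_severity <- function(drug_c, known, fingerprints, sim_cutoff = 0.5,
                           alpha = 0.5, beta = 0.2,
                           bands = severity_bands()) {
  if (nrow(known) == 0) stop("no known interactors with recorded severity")
  if (is.null(fingerprints[[drug_c]])) {
    stop("no fingerprint available for ", drug_c)
  }
  sims <- vapply(known$drug, function(a) {
    if (is.null(fingerprints[[a]])) return(NA_real_)
    fingerprint_similarity(fingerprints[[drug_c]], fingerprints[[a]],
                           alpha, beta)
  }, 0)
  ok <- !is.na(sims)
  if (!any(ok)) stop("no neighbour of ", drug_c, " has a fingerprint")
  known <- known[ok, , drop = FALSE]
  sims <- sims[ok]
  use <- sims >= sim_cutoff
  low_confidence <- FALSE
  if (!any(use)) {
    use <- seq_along(sims) == which.max(sims)
    low_confidence <- TRUE
  }
  if (sum(sims[use]) == 0) {
    # zero total similarity: fall back to the plain mean of the used scores
    score <- mean(known$score[use])
  } else {
    score <- sum(sims[use] * known$score[use]) / sum(sims[use])
  }
  # a weighted mean lies inside the neighbour range; clamp roundoff drift
  score <- min(max(score, min(known$score[use])), max(known$score[use]))
  score <- min(100, max(1, score))
  structure(list(
    score = score,
    level = severity_level(score, bands),
    low_confidence = low_confidence,
    neighbors = data.frame(drug = known$drug, similarity = sims,
                           known_score = known$score, used = use,
                           stringsAsFactors = FALSE)
  ), class = "ddi_severity")
}

#' @export
print.ddi_severity <- function(x, ...) {
  cat("<ddi_severity> score ", format(x$score, digits = 4), " -> ", x$level,
      if (x$low_confidence) " (low confidence)" else "",
      "; ", sum(x$neighbors$used), " neighbour(s) used\n", sep = "")
  invisible(x)
}

#' Annotate a prediction table with severity scores and levels
#'
#' For each predicted pair, known severities of interactions involving
#' either endpoint supply the neighbours: partners of `drug_b` are compared
#' structurally with `drug_a` (and, if none are available, partners of
#' `drug_a` with `drug_b`).  Pairs with no usable neighbours or missing
#' fingerprints get `NA` with a flag rather than being dropped.
#'
#' @param predictions Data frame with `drug_a`, `drug_b` (and typically
#'   `score`).
#' @param fingerprints Named list of fingerprints (see
#'   [smiles_fingerprint()]).
#' @param known_severity Data frame with `drug_a`, `drug_b`, `score`
#'   (recorded severities on the 1-100 scale).
#' @param sim_cutoff,alpha,beta Passed to [infer_severity()].
#' @return `predictions` with columns `severity_score`, `severity_level`,
#'   `severity_flag` appended.
#' @export
annotate_severity <- function(predictions, fingerprints, known_severity,
                              sim_cutoff = 0.5, alpha = 0.5, beta = 0.2) {
  neighbours_of <- function(b) {
    hit_a <- known_severity$drug_b == b
    hit_b <- known_severity$drug_a == b
    data.frame(drug = c(known_severity$drug_a[hit_a],
                        known_severity$drug_b[hit_b]),
               score = c(known_severity$score[hit_a],
                         known_severity$score[hit_b]),
               stringsAsFactors = FALSE)
  }
  n <- nrow(predictions)
  sev_score <- rep(NA_real_, n)
  sev_level <- rep(NA_character_, n)
  flag <- rep("", n)
  for (r in seq_len(n)) {
    a <- predictions$drug_a[r]
    b <- predictions$drug_b[r]
    attempt <- function(C, B) {
      kn <- neighbours_of(B)
      kn <- kn[kn$drug != C, , drop = FALSE]
      if (nrow(kn) == 0 || is.null(fingerprints[[C]])) return(NULL)
      tryCatch(infer_severity(C, kn, fingerprints, sim_cutoff, alpha, beta),
               error = function(e) NULL)
    }
    res <- attempt(a, b)
    if (is.null(res)) res <- attempt(b, a)
    if (is.null(res)) {
      flag[r] <- "no_reference"
    } else {
      sev_score[r] <- res$score
      sev_level[r] <- res$level
      if (res$low_confidence) flag[r] <- "low_confidence"
    }
  }
  predictions$severity_score <- sev_score
  predictions$severity_level <- sev_level
  predictions$severity_flag <- flag
  predictions
}
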