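# Synthetic benchmark generator.
#
# Drugs carry a non-negative low-rank latent factor matrix U (each drug has
# one dominant latent group plus weak background loadings, with
# heterogeneous loading magnitudes).  Feature matrices are binarized random
# non-negative mixtures of U, and the interaction network is the
# symmetrized top-density quantile of U U^T, so features and interactions
# share latent structure and the predictor has recoverable signal.

#' Generate a synthetic multi-feature interaction dataset
#'
#' @param n Number of drugs (>= 10).
#' @param m Number of feature spaces.
#' @param dims Descriptor counts, one per feature space.
#' @param rank Latent rank (number of planted groups); must be below
#'   `min(dims)`.
#' @param density Target interaction density over unordered pairs, in
#'   (0, 0.5).
#' @param noise Per-cell bit-flip probability applied to the feature
#'   matrices, in \[0, 0.5).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   parameters and the seed.
#' @return Object of class `ddi_simulation`: `catalog`, `features` (named
#'   list of binary matrices), `network`, `latent` (the factor matrix `U`),
#'   `params`.
#' @examples
#' sim <- simulate_ddi_data(n = 40, m = 2, dims = c(25, 30), rank = 4,
#'                          density = 0.1, noise = 0, seed = 7)
#' sum(sim$network) / 2  # planted edge count
#' @export
simulate_ddi_data <- function(n = 200, m = 4, dims = c(120, 100, 150, 300),
                              rank = 10, density = 0.05, noise = 0.05,
                              seed = 1) {
  if (n < 10) stop("need n >= 10")
  if (length(dims) != m) stop("`dims` must list one descriptor count per feature space")
  if (rank >= min(dims)) stop("rank must be below min(dims)")
  if (density <= 0 || density >= 0.5) stop("density must lie in (0, 0.5)")
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)")
  set.seed(seed)
  catalog <- drug_catalog(sprintf("SYN%04d", seq_len(n)))
  ids <- as.character(catalog)
  group <- sample(rep_len(seq_len(rank), n))
  loading <- stats::runif(n, 0.5, 1.5)
  U <- matrix(stats::runif(n * rank, 0, 0.05), n, rank)
  U[cbind(seq_len(n), group)] <- loading
  gram <- tcrossprod(U)
  ut <- gram[upper.tri(gram)]
  n_edges <- max(1L, round(density * length(ut)))
  thr <- sort(ut, decreasing = TRUE)[n_edges]
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  J[upper.tri(J)] <- as.numeric(ut >= thr)
  J <- J + t(J)
  features <- lapply(seq_len(m), function(i) {
    d <- dims[i]
    W <- matrix(stats::rexp(rank * d), rank, d) *
      (matrix(stats::runif(rank * d), rank, d) < 0.3)
    X <- U %*% W
    H <- (X > stats::quantile(X, 0.8)) * 1
    if (noise > 0) {
      flips <- matrix(stats::runif(n * d) < noise, n, d)
      H <- abs(H - flips)
    }
    dimnames(H) <- list(ids, sprintf("F%d_%04d", i, seq_len(d)))
    attr(H, "feature_name") <- paste0("feature", i)
    H
  })
  names(features) <- paste0("feature", seq_len(m))
  structure(list(catalog = catalog, features = features, network = J,
                 latent = U,
                 params = list(n = n, m = m, dims = dims, rank = rank,
                               density = density, noise = noise,
                               seed = seed)),
            class = "ddi_simulation")
}

#' @export
print.ddi_simulation <- function(x, ...) {
  p <- x$params
  cat("<ddi_simulation> ", p$n, " drugs, ", p$m, " feature space(s) [",
      paste(p$dims, collapse = ", "), "], ", sum(x$network) / 2,
      " interactions (density ", format(p$density), ", noise ",
      format(p$noise), ", seed ", p$seed, ")\n", sep = "")
  invisible(x)
}

#' Hold out a drug subset for cold-start experiments
#'
#' Removes a random fraction of drugs from the dataset and returns the
#' induced training data together with each held-out drug's feature vectors
#' and its true interaction labels against the training drugs.
#'
#' @param sim A [simulate_ddi_data()] result.
#' @param fraction Fraction of drugs to hold out, in (0, 0.5).
#' @param seed Integer seed for the drug draw.
#' @return List with `train` (a reduced `ddi_simulation`) and `holdout`
#'   (list per held-out drug: `id`, `features` (named list of binary
#'   vectors), `labels` (named 0/1 vector over the training drugs)).
#' @export
holdout_drugs <- function(sim, fraction = 0.2, seed = 1) {
  if (fraction <= 0 || fraction >= 0.5) stop("fraction must lie in (0, 0.5)")
  ids <- sim$catalog
  n <- length(ids)
  n_out <- round(fraction * n)
  if (n - n_out < 10) stop("holdout would leave fewer than 10 training drugs")
  set.seed(seed)
  out_ids <- sample(ids, n_out)
  tr_ids <- setdiff(ids, out_ids)
  tr <- match(tr_ids, ids)
  train <- sim
  train$catalog <- drug_catalog(tr_ids)
  train$network <- sim$network[tr, tr]
  train$features <- lapply(sim$features, function(H) H[tr, , drop = FALSE])
  train$latent <- sim$latent[tr, , drop = FALSE]
  train$params$n <- length(tr_ids)
  holdout <- lapply(out_ids, function(d) {
    list(id = d,
         features = lapply(sim$features, function(H) H[d, ]),
         labels = sim$network[d, tr_ids])
  })
  names(holdout) <- out_ids
  list(train = train, holdout = holdout)
}

# drug-like ring scaffolds used as starting points for toy molecules
toy_scaffolds <- c(
  "c1ccccc1",          # benzene
  "c1ccncc1",          # pyridine
  "c1ccc2ccccc2c1",    # naphthalene
  "C1CCCCC1",          # cyclohexane
  "c1ccoc1",           # furan
  "c1ccsc1",           # thiophene
  "C1CCNCC1",          # piperidine
  "c1ccc(cc1)O"        # phenol
)

#' Generate toy drug-like SMILES strings
#'
#' Draws a ring scaffold and appends a random short heteroatom-bearing
#' chain, yielding valid, parsable SMILES for exercising the fingerprint
#' and severity machinery without external structure files.
#'
#' @param count Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `count` SMILES strings named `TOY0001`, ...
#' @export
simulate_smiles <- function(count, seed = 1) {
  if (count < 1) stop("count must be >= 1")
  set.seed(seed)
  atoms <- c("C", "O", "N", "CC", "C(C)C", "CO", "CN")
  out <- vapply(seq_len(count), function(i) {
    scaffold <- sample(toy_scaffolds, 1)
    tail_len <- sample(0:3, 1)
    tail <- paste(sample(atoms, tail_len, replace = TRUE), collapse = "")
    paste0(scaffold, tail)
  }, "")
  stats::setNames(out, sprintf("TOY%04d", seq_len(count)))
}

#' Write a simulated dataset in the package's file formats
#'
#' Emits the interaction edge list (`interactions.tsv`), one long-form
#' feature table per feature space (`<name>.tsv`), and a SMILES file
#' (`molecules.smi`) for the catalog drugs, all readable by the package's
#' readers.
#'
#' @param sim A [simulate_ddi_data()] result.
#' @param dir Output directory (created if needed).
#' @param smiles Optional named SMILES vector; defaults to toy molecules,
#'   one per drug.
#' @return Named list of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, smiles = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  J <- sim$network
  idx <- which(upper.tri(J) & J == 1)
  edges <- data.frame(a = rownames(J)[row(J)[idx]],
                      b = colnames(J)[col(J)[idx]])
  paths$interactions <- file.path(dir, "interactions.tsv")
  utils::write.table(edges, paths$interactions, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (nm in names(sim$features)) {
    H <- sim$features[[nm]]
    hit <- which(H == 1, arr.ind = TRUE)
    long <- data.frame(drug = rownames(H)[hit[, 1]],
                       descriptor = colnames(H)[hit[, 2]])
    long <- long[order(long$drug, long$descriptor), ]
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(long, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (is.null(smiles)) {
    smiles <- simulate_smiles(length(sim$catalog), seed = sim$params$seed)
    names(smiles) <- sim$catalog
  }
  paths$smiles <- file.path(dir, "molecules.smi")
  writeLines(paste(smiles, names(smiles)), paths$smiles)
  invisible(paths)
}
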