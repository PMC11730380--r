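# Multi-view feature projection into the interaction space.
#
# Each binary feature matrix H^i (drugs x descriptors) is mapped by a
# non-negative projection Z^i (descriptors x drugs) so that H^i Z^i
# approximates both the common score matrix S and the known interaction
# matrix J.  S itself stays close to J and is tied to the learned relation
# structure M through the relation-regularization penalty.  The joint
# objective is
#
#   theta * sum_i ( ||S - H^i Z^i||_F^2 + ||J - H^i Z^i||_F^2 )
#   + lambda * sum_i ( tr((Z^i)^T O Z^i) + tr((H^i)^T O H^i) )
#   + ||S - J||_F^2 + sigma * tr(((I - M) S)^T M S)
#
# with Z^i >= 0, where O is the all-ones matrix (the sparsity term is the
# squared column-sum form the solver algebra uses).  The H terms are data
# constants.  Optimization alternates an exact linear solve for S with one
# multiplicative sweep over the Z^i.

#' Default hyperparameters for the two prediction goals
#'
#' Goal 1 (pairs among networked drugs): `(lambda, theta, sigma) =
#' (1e-1, 1e-5, 1e-3)`.  Goal 2 (cold-start drugs): `(1e-3, 1e-2, 0)` --
#' new drugs have no edges, so the relation term is switched off.
#'
#' @param goal 1 or 2.
#' @return Named list with `lambda`, `theta`, `sigma`.
#' @export
ddi_defaults <- function(goal = 1) {
  if (goal == 1) list(lambda = 1e-1, theta = 1e-5, sigma = 1e-3)
  else if (goal == 2) list(lambda = 1e-3, theta = 1e-2, sigma = 0)
  else stop("goal must be 1 or 2")
}

# symmetric system matrix of the S-stationarity condition:
# (1 + m*theta) I + (sigma/2) (G + G^T),  G = (I - M)^T M
score_system_matrix <- function(M, m, theta, sigma) {
  n <- nrow(M)
  A <- (1 + m * theta) * diag(n)
  if (sigma > 0) {
    G <- crossprod(diag(n) - M, M)
    A <- A + (sigma / 2) * (G + t(G))
  }
  A
}

# lambda * sum_i tr((H^i)^T O H^i): the data-constant part of the sparsity
# term, included in reported objectives, excluded from convergence ratios
sparsity_constant <- function(features, lambda) {
  lambda * sum(vapply(features, function(H) sum(colSums(H)^2), 0))
}

#' Joint objective of the projection model
#'
#' Evaluates the full objective (see the package vignette for the model) at
#' a given score matrix `S` and projection list.  With
#' `include_constants = FALSE` the data-constant feature-sparsity term is
#' dropped; this is the quantity convergence is measured on.
#'
#' @param features List of m binary feature matrices (drugs x descriptors).
#' @param projections List of m non-negative projection matrices
#'   (descriptors x drugs).
#' @param S Score matrix (drugs x drugs).
#' @param network Binary symmetric interaction matrix `J`.
#' @param M Relation matrix (use a zero matrix when `sigma = 0`).
#' @param lambda,theta,sigma Non-negative weights of the sparsity,
#'   projection-error and relation-regularization terms.
#' @param include_constants Include the `H`-dependent constant.
#' @return Scalar objective value.
#' @export
full_objective <- function(features, projections, S, network, M,
                           lambda, theta, sigma, include_constants = TRUE) {
  m <- length(features)
  if (length(projections) != m) stop("one projection per feature matrix")
  v <- sum((S - network)^2)
  if (sigma > 0) v <- v + sigma * drr_penalty(M, S)
  for (i in seq_len(m)) {
    HZ <- features[[i]] %*% projections[[i]]
    if (any(dim(HZ) != dim(S))) stop("shape mismatch in feature space ", i)
    v <- v + theta * (sum((S - HZ)^2) + sum((network - HZ)^2)) +
      lambda * sum(colSums(projections[[i]])^2)
  }
  if (include_constants) v <- v + sparsity_constant(features, lambda)
  v
}

#' Closed-form score matrix given fixed projections
#'
#' Solves the stationarity condition of the joint objective in `S`:
#' \deqn{\big((1 + m\theta) I + \tfrac{\sigma}{2}(G + G^T)\big) S =
#'       \theta \sum_i H^i Z^i + J, \quad G = (I - M)^T M,}
#' by a linear solve (never an explicit inverse).  The system matrix is the
#' exact gradient coefficient of the relation-regularized objective, so the
#' numerical gradient of [full_objective()] vanishes at the returned `S`.
#'
#' @inheritParams full_objective
#' @return The score matrix `S`.
#' @export
solve_scores <- function(features, projections, network, M,
                         theta, sigma) {
  m <- length(features)
  A <- score_system_matrix(M, m, theta, sigma)
  rc <- rcond(A)
  if (rc < .Machine$double.eps * 100) {
    stop("singular score system (reciprocal condition number ",
         format(rc, digits = 3), "); reduce sigma")
  }
  rhs <- network
  for (i in seq_len(m)) {
    rhs <- rhs + theta * (features[[i]] %*% projections[[i]])
  }
  S <- solve(A, rhs)
  dimnames(S) <- dimnames(network)
  S
}

#' Reduced objective in the projections only
#'
#' The joint objective with `S` eliminated by its closed form
#' ([solve_scores()]), up to the data-constant sparsity term: differences of
#' this function between two projection settings equal differences of
#' [full_objective()] evaluated at the corresponding optimal `S`.
#'
#' @inheritParams full_objective
#' @return Scalar value.
#' @export
reduced_objective <- function(features, projections, network, M,
                              lambda, theta, sigma) {
  S <- solve_scores(features, projections, network, M, theta, sigma)
  full_objective(features, projections, S, network, M, lambda, theta, sigma,
                 include_constants = FALSE)
}

#' One multiplicative sweep over the projection matrices
#'
#' For each feature space i in turn, the stationarity condition of the
#' reduced objective in `Z^i` is the linear form `C Z^i = B` with
#' \deqn{C = 2\theta (H^i)^T H^i - \theta^2 (H^i)^T Y H^i + \lambda O,
#'       \qquad B = \theta (H^i)^T ( Y R_{-i} + J ),}
#' where `Y` is the inverse of the score system matrix and
#' \eqn{R_{-i} = J + \theta\sum_{j \neq i} H^j Z^j}.  The update applies the
#' sign-split multiplicative rule
#' `Z <- Z * (C^- Z + B^+) / (C^+ Z + B^-)` (with `X^+ = (|X|+X)/2`,
#' `X^- = (|X|-X)/2`), which preserves non-negativity; entries with a zero
#' denominator are left unchanged.
#'
#' @inheritParams full_objective
#' @return The updated projection list.
#' @export
update_projections <- function(features, projections, network, M,
                               lambda, theta, sigma) {
  m <- length(features)
  A <- score_system_matrix(M, m, theta, sigma)
  Y <- solve(A)
  update_projections_sweep(features, projections, network, Y, lambda, theta)
}

# sweep with a precomputed resolvent Y (reused across iterations in ddi_fit)
update_projections_sweep <- function(features, projections, network, Y,
                                     lambda, theta) {
  m <- length(features)
  HZ <- Map(`%*%`, features, projections)
  for (i in seq_len(m)) {
    H <- features[[i]]
    Z <- projections[[i]]
    YH <- Y %*% H
    Cmat <- 2 * theta * crossprod(H) - theta * theta * crossprod(H, YH)
    Cmat <- Cmat + lambda  # + lambda * O (all-ones): constant shift
    Rmi <- network
    for (j in seq_len(m)) if (j != i) Rmi <- Rmi + theta * HZ[[j]]
    B <- theta * crossprod(H, Y %*% Rmi + network)
    Cp <- pmax(Cmat, 0); Cn <- pmax(-Cmat, 0)
    num <- Cn %*% Z + pmax(B, 0)
    den <- Cp %*% Z + pmax(-B, 0)
    upd <- num / den
    upd[den == 0] <- 1
    Z <- Z * upd
    projections[[i]] <- Z
    HZ[[i]] <- H %*% Z
  }
  projections
}

#' Fit the interaction-prediction model
#'
#' Learns the relation structure from the training network (when
#' `sigma > 0`), initializes seeded non-negative projections, and alternates
#' the exact score solve with one multiplicative projection sweep per
#' iteration until the relative change of the (constant-free) objective
#' falls below `tol` or `max_iter` is reached.
#'
#' @param features Named list of binary feature matrices, rows aligned to
#'   the network's drug identifiers.
#' @param network Binary symmetric interaction matrix with drug identifiers
#'   as dimnames.
#' @param goal 1 or 2; selects default `(lambda, theta, sigma)` via
#'   [ddi_defaults()] for any of the three left `NULL`.
#' @param lambda,theta,sigma Model weights (see [full_objective()]).
#' @param theta_drr Row-sum penalty weight passed to [learn_relation()].
#' @param max_iter,tol Outer-iteration budget and relative-change threshold.
#' @param seed Integer seed governing projection initialization and the
#'   relation-structure start.
#' @param goal2_denominator `"m+1"` (default) or `"m"`: divisor of the
#'   cold-start score formula in [predict_new_drug()].
#' @param relation Optional pre-fitted [learn_relation()] result to reuse.
#' @return Object of class `ddi_model` with elements `projections` (the
#'   `Z^i`), `S` (fitted score matrix), `M`, `relation`, `hyperparams`,
#'   `objective_history` (full objective, constants included, one value per
#'   outer iteration starting at initialization), `converged_at`,
#'   `converged`, `catalog`, `feature_names`, `dims` and the training
#'   `network`.
#' @examples
#' sim <- simulate_ddi_data(n = 30, m = 2, dims = c(15, 20), rank = 3,
#'                          density = 0.1, noise = 0, seed = 1)
#' fit <- ddi_fit(sim$features, sim$network, goal = 1, seed = 1)
#' fit$converged_at
#' @export
ddi_fit <- function(features, network, goal = 1, lambda = NULL, theta = NULL,
                    sigma = NULL, theta_drr = 1e-2, max_iter = 100,
                    tol = 1e-4, seed = 1,
                    goal2_denominator = c("m+1", "m"), relation = NULL) {
  ids <- validate_inputs(features, network)
  goal2_denominator <- match.arg(goal2_denominator)
  defaults <- ddi_defaults(goal)
  if (is.null(lambda)) lambda <- defaults$lambda
  if (is.null(theta)) theta <- defaults$theta
  if (is.null(sigma)) sigma <- defaults$sigma
  if (min(lambda, theta, sigma, theta_drr) < 0 || max_iter < 1 || tol <= 0) {
    stop("weights must be non-negative, max_iter >= 1, tol > 0")
  }
  n <- length(ids)
  m <- length(features)
  if (sigma > 0) {
    if (is.null(relation)) {
      relation <- learn_relation(network, theta_drr, seed = seed)
    }
    M <- relation$M
  } else {
    relation <- NULL
    M <- matrix(0, n, n)
  }
  A <- score_system_matrix(M, m, theta, sigma)
  rc <- rcond(A)
  if (rc < .Machine$double.eps * 100) {
    stop("singular score system (reciprocal condition number ",
         format(rc, digits = 3), "); reduce sigma")
  }
  Y <- solve(A)   # fixed across iterations; factor once
  set.seed(seed + 1L)
  projections <- lapply(features, function(H) {
    matrix(stats::runif(ncol(H) * n), ncol(H), n) / sqrt(ncol(H))
  })
  hconst <- sparsity_constant(features, lambda)
  solve_now <- function(Zs) {
    rhs <- network
    for (i in seq_len(m)) rhs <- rhs + theta * (features[[i]] %*% Zs[[i]])
    Y %*% rhs
  }
  S <- solve_now(projections)
  f_prev <- full_objective(features, projections, S, network, M,
                           lambda, theta, sigma, include_constants = FALSE)
  history <- f_prev + hconst
  converged_at <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    projections <- update_projections_sweep(features, projections, network,
                                            Y, lambda, theta)
    S <- solve_now(projections)
    f <- full_objective(features, projections, S, network, M,
                        lambda, theta, sigma, include_constants = FALSE)
    history <- c(history, f + hconst)
    if (abs(f_prev - f) < tol * max(abs(f_prev), .Machine$double.eps)) {
      converged_at <- it
      converged <- TRUE
      f_prev <- f
      break
    }
    f_prev <- f
  }
  dimnames(S) <- list(ids, ids)
  structure(list(
    projections = projections,
    S = S,
    M = M,
    relation = relation,
    hyperparams = list(lambda = lambda, theta = theta, sigma = sigma,
                       theta_drr = theta_drr, max_iter = max_iter, tol = tol,
                       seed = seed, goal2_denominator = goal2_denominator),
    objective_history = history,
    converged_at = converged_at,
    converged = converged,
    catalog = ids,
    feature_names = if (!is.null(names(features))) names(features)
                    else paste0("feature", seq_len(m)),
    dims = vapply(features, ncol, 0L),
    descriptors = lapply(features, colnames),
    network = network
  ), class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  hp <- x$hyperparams
  cat("<ddi_model> ", length(x$catalog), " drugs, ",
      length(x$projections), " feature space(s) [",
      paste(x$feature_names, collapse = ", "), "]\n",
      "  (lambda, theta, sigma) = (", hp$lambda, ", ", hp$theta, ", ",
      hp$sigma, "); ",
      if (x$converged) paste0("converged at iteration ", x$converged_at)
      else paste0("not converged within ", hp$max_iter, " iterations"),
      "\n  final objective ",
      format(utils::tail(x$objective_history, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Score drug pairs inside the network
#'
#' Returns the symmetrized interaction score `(S[i,j] + S[j,i]) / 2` for
#' each requested unordered pair.  Self-pairs are rejected; pairs already
#' interacting in the training network are flagged.
#'
#' @param model A fitted [ddi_fit()] model.
#' @param pairs Two-column data frame or character matrix of drug
#'   identifiers.
#' @return Data frame with `drug_a`, `drug_b`, `score`, `known`.
#' @export
predict_within <- function(model, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop("`pairs` needs two identifier columns")
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  ia <- catalog_index(model$catalog, a)
  ib <- catalog_index(model$catalog, b)
  if (any(ia == ib)) {
    stop("self-interaction is undefined for drug(s): ",
         paste(unique(a[ia == ib]), collapse = ", "))
  }
  score <- (model$S[cbind(ia, ib)] + model$S[cbind(ib, ia)]) / 2
  data.frame(drug_a = a, drug_b = b, score = score,
             known = model$network[cbind(ia, ib)] == 1,
             stringsAsFactors = FALSE)
}

#' Score a cold-start drug against the network
#'
#' A drug outside the training network, described by one binary feature
#' vector per feature space, is scored against every catalog drug as
#' \deqn{J^* = \frac{\sum_{i=1}^m H^{*i} Z^i}{m + 1}}
#' (denominator `m` available via the model's `goal2_denominator` setting).
#' A feature space missing from `new_features` contributes a zero vector
#' (logged via `message()`).
#'
#' @param model A fitted [ddi_fit()] model.
#' @param new_features Named list (or single named numeric vector wrapped in
#'   a list) of binary feature vectors; names must match the model's
#'   feature names, lengths the corresponding descriptor counts.
#' @return Named non-negative score vector over the catalog.
#' @export
predict_new_drug <- function(model, new_features) {
  m <- length(model$projections)
  n <- length(model$catalog)
  acc <- numeric(n)
  for (i in seq_len(m)) {
    nm <- model$feature_names[i]
    h <- new_features[[nm]]
    if (is.null(h)) {
      message("no '", nm, "' feature vector supplied; using zeros")
      next
    }
    if (length(h) != model$dims[i]) {
      stop("feature vector '", nm, "' has length ", length(h),
           ", expected ", model$dims[i])
    }
    acc <- acc + as.numeric(h %*% model$projections[[i]])
  }
  denom <- if (model$hyperparams$goal2_denominator == "m+1") m + 1 else m
  stats::setNames(acc / denom, model$catalog)
}

#' Persist a fitted model
#'
#' Writes a single JSON archive holding the catalog, feature names and
#' dimensions, projection matrices, score and relation matrices,
#' hyperparameters and objective history.
#'
#' @param model A `ddi_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_ddi_model <- function(model, path) {
  payload <- list(
    format = "ddilearn-model",
    version = 1L,
    catalog = model$catalog,
    feature_names = model$feature_names,
    dims = unname(model$dims),
    hyperparams = model$hyperparams,
    objective_history = model$objective_history,
    converged_at = model$converged_at,
    converged = model$converged,
    descriptors = model$descriptors,
    projections = lapply(model$projections, unname),
    S = unname(model$S),
    M = unname(model$M),
    network = unname(model$network)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a model written by [write_ddi_model()]
#'
#' @param path JSON model path.
#' @return A `ddi_model`.
#' @export
read_ddi_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ddilearn-model")) {
    stop(path, " is not a ddilearn model archive")
  }
  ids <- p$catalog
  as_mat <- function(x) matrix(unlist(x), nrow = length(x), byrow = TRUE)
  to_mat <- function(x) if (is.matrix(x)) x else as_mat(x)
  S <- to_mat(p$S); dimnames(S) <- list(ids, ids)
  J <- to_mat(p$network); dimnames(J) <- list(ids, ids)
  projections <- lapply(p$projections, to_mat)
  structure(list(
    projections = projections,
    S = S,
    M = to_mat(p$M),
    relation = NULL,
    hyperparams = as.list(p$hyperparams),
    objective_history = as.numeric(p$objective_history),
    converged_at = as.integer(p$converged_at),
    converged = isTRUE(p$converged),
    catalog = ids,
    feature_names = p$feature_names,
    dims = as.integer(p$dims),
    descriptors = p$descriptors,
    network = J
  ), class = "ddi_model")
}
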