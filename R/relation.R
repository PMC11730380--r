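# Self-representation of the known interaction network.
#
# Each drug's row of the interaction matrix J is reconstructed as a
# non-negative combination of the other drugs' rows: J ~ (N * M) J, where N
# masks the diagonal so no drug represents itself, subject to M >= 0 and
# unit row sums of N * M.  The learned M is later used to regularize
# predicted interaction scores so that the relational structure of the
# known network carries over to unseen pairs.

# off-diagonal mask N (0 on the diagonal, 1 elsewhere)
offdiag_mask <- function(n) {
  N <- matrix(1, n, n)
  diag(N) <- 0
  N
}

#' Self-representation objective for the interaction network
#'
#' Evaluates
#' \deqn{\tfrac12\|(N \odot M)J - J\|_F^2 + \tfrac12\|NJ - J\|_F^2 +
#'       \tfrac{\theta}{2}\|(N \odot M)e\|_2^2}
#' where \eqn{N} is the off-diagonal mask, \eqn{e} the all-ones vector and
#' \eqn{\theta} (`theta_drr`) weighs the row-sum penalty.  The middle term
#' does not depend on `M`.
#'
#' @param M Non-negative square matrix (diagonal ignored).
#' @param network Binary symmetric interaction matrix `J`.
#' @param theta_drr Non-negative row-sum penalty weight.
#' @return Scalar objective value.
#' @export
drr_objective <- function(M, network, theta_drr = 1e-2) {
  n <- nrow(network)
  if (!is.matrix(M) || any(dim(M) != n)) {
    stop("M must be ", n, " x ", n, " to match the network")
  }
  N <- offdiag_mask(n)
  A <- N * M
  NJ <- N %*% network
  0.5 * sum((A %*% network - network)^2) +
    0.5 * sum((NJ - network)^2) +
    theta_drr / 2 * sum(rowSums(A)^2)
}

#' One multiplicative update of the self-representation matrix
#'
#' Applies the non-negativity-preserving rule
#' \deqn{M_{ij} \leftarrow M_{ij}\,
#'   \frac{(\mu\, ee^T(I + JJ^T) + JJ^T)_{ij}}
#'        {\big((N \odot M)(\theta ee^T + \theta ee^T JJ^T + JJ^T)\big)_{ij}}}
#' for \eqn{i \neq j}, with the diagonal pinned to zero.  Entries whose
#' denominator is zero (isolated drugs) are left unchanged.  The multiplier
#' \eqn{\mu} of the row-sum constraint defaults to `theta_drr`; the
#' constraint itself is enforced by row rescaling in [learn_relation()].
#'
#' @inheritParams drr_objective
#' @param multiplier Scalar weight of the constant numerator term.
#' @return Updated matrix, non-negative with zero diagonal.
#' @export
drr_update <- function(M, network, theta_drr = 1e-2, multiplier = theta_drr) {
  n <- nrow(network)
  if (!is.matrix(M) || any(dim(M) != n)) stop("M/network shape mismatch")
  JJt <- tcrossprod(network)
  # ee^T X has identical rows equal to colSums(X)
  num <- multiplier * matrix(colSums(diag(n) + JJt), n, n, byrow = TRUE) + JJt
  A <- offdiag_mask(n) * M
  den <- A %*% (theta_drr * (matrix(1, n, n) +
                             matrix(colSums(JJt), n, n, byrow = TRUE)) + JJt)
  upd <- num / den
  upd[den == 0] <- 1
  out <- M * upd
  diag(out) <- 0
  out
}

#' Learn the relation structure of a known interaction network
#'
#' Iterates [drr_update()] from a seeded strictly positive start, rescaling
#' each positive row of the (masked) matrix to unit sum after every sweep so
#' that the constraint \eqn{(N \odot M)e = e} holds exactly for drugs with
#' known interactions.  A sweep is accepted only if it lowers the
#' constrained objective; the iteration stops at the first non-improving
#' sweep or when the relative improvement falls below `tol`, keeping the
#' best iterate.  The recorded objective history is therefore
#' non-increasing.
#'
#' @param network Binary symmetric interaction matrix with at least one edge.
#' @param theta_drr Row-sum penalty weight (default `1e-2`).
#' @param max_iter Maximum number of sweeps.
#' @param tol Relative-improvement stopping threshold.
#' @param seed Integer seed for the random start.
#' @return Object of class `ddi_relation`: list with elements `M` (the
#'   fitted matrix), `theta_drr`, `iterations_run`, `residual_history`
#'   (objective after each accepted sweep, starting at the initial value)
#'   and `active_rows` (drugs with at least one known interaction, the rows
#'   on which the unit-row-sum constraint applies).
#' @export
learn_relation <- function(network, theta_drr = 1e-2, max_iter = 200,
                           tol = 1e-6, seed = 1) {
  validate_network(network, require_edge = TRUE)
  n <- nrow(network)
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  diag(M) <- 0
  M <- M / rowSums(M)
  active <- rowSums(network) > 0
  best <- drr_objective(M, network, theta_drr)
  history <- best
  iters <- 0L
  for (it in seq_len(max_iter)) {
    cand <- drr_update(M, network, theta_drr)
    rs <- rowSums(cand)
    pos <- rs > 0
    cand[pos, ] <- cand[pos, ] / rs[pos]
    f <- drr_objective(cand, network, theta_drr)
    if (f > best) break
    M <- cand
    history <- c(history, f)
    iters <- it
    if ((best - f) < tol * max(abs(best), .Machine$double.eps)) {
      best <- f
      break
    }
    best <- f
  }
  structure(list(M = M, theta_drr = theta_drr, iterations_run = iters,
                 residual_history = history, active_rows = active),
            class = "ddi_relation")
}

#' @export
print.ddi_relation <- function(x, ...) {
  cat("<ddi_relation> ", nrow(x$M), " drugs, ", x$iterations_run,
      " sweep(s), objective ",
      format(utils::tail(x$residual_history, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Relation-regularization penalty on a score matrix
#'
#' Computes \eqn{\mathrm{tr}\big(((I - M)S)^T M S\big)}: the agreement
#' between each drug's predicted score profile and its reconstruction from
#' the other drugs' profiles under the learned relation structure.
#'
#' @param M Relation matrix (or a `ddi_relation` object).
#' @param S Square score matrix of matching order.
#' @return Scalar penalty value.
#' @export
drr_penalty <- function(M, S) {
  if (inherits(M, "ddi_relation")) M <- M$M
  if (!is.matrix(M) || !is.matrix(S) || any(dim(M) != dim(S)) ||
      nrow(S) != ncol(S)) {
    stop("M and S must be square matrices of the same order")
  }
  sum(((diag(nrow(M)) - M) %*% S) * (M %*% S))
}
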