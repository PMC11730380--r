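# Independent brute-force oracles: plain loops, no matrix shortcuts, kept
# deliberately separate from the package's vectorized implementations.

# relation-structure objective by elementwise loops
oracle_drr_objective <- function(M, J, theta_drr) {
  n <- nrow(J)
  v <- 0
  # || (N*M) J - J ||_F^2 / 2
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(n)) if (l != i) acc <- acc + M[i, l] * J[l, j]
    v <- v + 0.5 * (acc - J[i, j])^2
  }
  # || N J - J ||^2 / 2  (constant in M)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(n)) if (l != i) acc <- acc + J[l, j]
    v <- v + 0.5 * (acc - J[i, j])^2
  }
  # theta/2 * || (N*M) e ||_2^2
  for (i in seq_len(n)) {
    rs <- 0
    for (l in seq_len(n)) if (l != i) rs <- rs + M[i, l]
    v <- v + theta_drr / 2 * rs^2
  }
  v
}

# one multiplicative relation update by elementwise loops
oracle_drr_update <- function(M, J, theta_drr, multiplier = theta_drr) {
  n <- nrow(J)
  JJt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (l in seq_len(n)) JJt[i, j] <- JJt[i, j] + J[i, l] * J[j, l]
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0
    for (l in seq_len(n)) {
      num <- num + multiplier * (as.numeric(l == j) + JJt[l, j])
    }
    num <- num + JJt[i, j]
    den <- 0
    for (l in seq_len(n)) {
      if (l == i) next
      coef <- theta_drr
      for (q in seq_len(n)) coef <- coef + theta_drr * JJt[q, j]
      den <- den + M[i, l] * (coef + JJt[l, j])
    }
    out[i, j] <- if (den == 0) M[i, j] else M[i, j] * num / den
  }
  out
}

# joint projection objective by elementwise loops (column-sum sparsity form)
oracle_full_objective <- function(features, Zs, S, J, M, lambda, theta,
                                  sigma, include_constants = TRUE) {
  n <- nrow(J)
  v <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) v <- v + (S[i, j] - J[i, j])^2
  for (f in seq_along(features)) {
    H <- features[[f]]; Z <- Zs[[f]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      hz <- 0
      for (l in seq_len(ncol(H))) hz <- hz + H[i, l] * Z[l, j]
      v <- v + theta * ((S[i, j] - hz)^2 + (J[i, j] - hz)^2)
    }
    for (j in seq_len(n)) {
      cs <- 0
      for (l in seq_len(nrow(Z))) cs <- cs + Z[l, j]
      v <- v + lambda * cs^2
    }
    if (include_constants) {
      for (j in seq_len(ncol(H))) {
        cs <- 0
        for (i in seq_len(n)) cs <- cs + H[i, j]
        v <- v + lambda * cs^2
      }
    }
  }
  if (sigma > 0) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ims <- 0; ms <- 0
      for (l in seq_len(n)) {
        ims <- ims + (as.numeric(i == l) - M[i, l]) * S[l, j]
        ms <- ms + M[i, l] * S[l, j]
      }
      v <- v + sigma * ims * ms
    }
  }
  v
}

# central-difference gradient of a scalar function of a matrix
numerical_gradient <- function(fn, X, h = 1e-6) {
  g <- X * 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    g[i, j] <- (fn(Xp) - fn(Xm)) / (2 * h)
  }
  g
}

# AUC by exhaustive positive/negative pair comparison
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUPR by evaluating precision/recall at every distinct threshold
oracle_aupr <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# small aligned random instance for projection tests
random_instance <- function(n = 8, m = 2, dims = c(6, 7), density = 0.25,
                            seed = 1) {
  set.seed(seed)
  ids <- sprintf("D%02d", seq_len(n))
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(J))
  on <- sample(ut, max(1, round(density * length(ut))))
  J[on] <- 1
  J <- J + t(J)
  J[J > 1] <- 1
  features <- lapply(dims, function(d) {
    H <- matrix(rbinom(n * d, 1, 0.3), n, d,
                dimnames = list(ids, sprintf("x%03d", seq_len(d))))
    H
  })
  names(features) <- paste0("feature", seq_along(features))
  Zs <- lapply(dims, function(d) matrix(runif(d * n), d, n))
  M <- matrix(runif(n * n), n, n)
  diag(M) <- 0
  M <- M / rowSums(M)
  list(J = J, features = features, Zs = Zs, M = M, ids = ids)
}

# writes lines to a temp file and returns its path
tmpfile_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
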