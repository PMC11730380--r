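test_that("joint objective matches the loop-based oracle", {
  inst <- random_instance(n = 6, m = 2, dims = c(4, 5), seed = 2)
  S <- matrix(rnorm(36), 6, 6)
  got <- full_objective(inst$features, inst$Zs, S, inst$J, inst$M,
                        lambda = 0.05, theta = 0.1, sigma = 0.02)
  want <- oracle_full_objective(inst$features, inst$Zs, S, inst$J, inst$M,
                                0.05, 0.1, 0.02)
  expect_equal(got, want, tolerance = 1e-9)

  # plug-in anchors
  zeroZ <- lapply(inst$Zs, function(Z) Z * 0)
  v <- full_objective(inst$features, zeroZ, inst$J, inst$J, inst$M,
                      lambda = 0.05, theta = 0.1, sigma = 0,
                      include_constants = FALSE)
  expect_equal(v, 0.1 * 2 * 2 * sum(inst$J^2))  # theta * sum_i 2 * ||J||_F^2
  zf <- lapply(inst$features, function(H) H * 0)
  expect_equal(full_objective(zf, zeroZ, inst$J * 0, inst$J * 0,
                              inst$M * 0, 0.05, 0.1, 0), 0)
})

test_that("score solve hits trivial fixed points and the exact residual", {
  inst <- random_instance(n = 7, m = 2, dims = c(5, 6), seed = 3)
  # theta = 0, sigma = 0: S = J exactly
  S <- solve_scores(inst$features, inst$Zs, inst$J, inst$M, 0, 0)
  expect_equal(S, inst$J, tolerance = 1e-12)
  # sigma = 0, m = 1, H Z = J  =>  S = J
  n <- nrow(inst$J)
  S2 <- solve_scores(list(inst$J), list(diag(n)), inst$J, inst$M, 0.3, 0)
  expect_equal(S2, inst$J, tolerance = 1e-12)
  # linear-system residual against the stationarity system matrix
  theta <- 0.05; sigma <- 0.02
  S3 <- solve_scores(inst$features, inst$Zs, inst$J, inst$M, theta, sigma)
  G <- crossprod(diag(n) - inst$M, inst$M)
  A <- (1 + 2 * theta) * diag(n) + sigma / 2 * (G + t(G))
  rhs <- inst$J + theta * Reduce(`+`, Map(`%*%`, inst$features, inst$Zs))
  expect_lt(norm(A %*% S3 - rhs, "F"), 1e-8 * norm(rhs, "F"))
})

test_that("solved scores are stationary points of the joint objective", {
  for (seed in 1:5) {
    inst <- random_instance(n = 8, m = 2, dims = c(6, 7), seed = seed)
    S <- solve_scores(inst$features, inst$Zs, inst$J, inst$M, 0.05, 0.01)
    g <- numerical_gradient(function(X) {
      full_objective(inst$features, inst$Zs, X, inst$J, inst$M,
                     0.02, 0.05, 0.01)
    }, S)
    expect_lt(max(abs(g)), 1e-5)
  }
})

test_that("reduced objective differences equal full-objective differences", {
  inst <- random_instance(n = 6, m = 2, dims = c(4, 5), seed = 9)
  lambda <- 0.02; theta <- 0.05; sigma <- 0.01
  set.seed(10)
  Za <- lapply(inst$Zs, function(Z) Z * matrix(runif(length(Z)), nrow(Z)))
  Zb <- lapply(inst$Zs, function(Z) Z * matrix(runif(length(Z)), nrow(Z)))
  red <- function(Zs) reduced_objective(inst$features, Zs, inst$J, inst$M,
                                        lambda, theta, sigma)
  fullat <- function(Zs) {
    S <- solve_scores(inst$features, Zs, inst$J, inst$M, theta, sigma)
    full_objective(inst$features, Zs, S, inst$J, inst$M, lambda, theta, sigma)
  }
  expect_equal(red(Za) - red(Zb), fullat(Za) - fullat(Zb), tolerance = 1e-7)
  # and the offset is exactly the data-constant sparsity term
  expect_equal(fullat(Za) - red(Za),
               lambda * sum(vapply(inst$features,
                                   function(H) sum(colSums(H)^2), 0)))
})

test_that("projection updates preserve non-negativity and zero absorption", {
  inst <- random_instance(n = 6, m = 2, dims = c(4, 5), seed = 4)
  zeroZ <- lapply(inst$Zs, function(Z) Z * 0)
  upd0 <- update_projections(inst$features, zeroZ, inst$J, inst$M,
                             0.02, 0.05, 0.01)
  expect_true(all(vapply(upd0, function(Z) all(Z == 0), TRUE)))
  upd <- update_projections(inst$features, inst$Zs, inst$J, inst$M,
                            0.02, 0.05, 0.01)
  expect_true(all(vapply(upd, function(Z) all(Z >= 0), TRUE)))
})

test_that("alternating sweeps never increase the objective", {
  for (seed in 1:6) {
    inst <- random_instance(n = 6, m = 2, dims = c(4, 5), seed = seed)
    Zs <- inst$Zs
    red <- function(Zs) reduced_objective(inst$features, Zs, inst$J, inst$M,
                                          0.02, 0.05, 0.01)
    f <- red(Zs)
    for (sweep in 1:5) {
      Zs <- update_projections(inst$features, Zs, inst$J, inst$M,
                               0.02, 0.05, 0.01)
      f2 <- red(Zs)
      expect_lte(f2, f + 1e-8 * max(1, abs(f)))
      f <- f2
    }
  }
})

test_that("fitting is deterministic and its history is monotone", {
  sim <- simulate_ddi_data(n = 30, m = 2, dims = c(15, 20), rank = 3,
                           density = 0.1, noise = 0, seed = 5)
  f1 <- ddi_fit(sim$features, sim$network, goal = 1, seed = 3)
  f2 <- ddi_fit(sim$features, sim$network, goal = 1, seed = 3)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$projections, f2$projections)
  h <- f1$objective_history
  expect_true(all(diff(h) <= 1e-8 * pmax(1, abs(h[-length(h)]))))
  expect_lte(f1$converged_at, f1$hyperparams$max_iter)
})

test_that("the relation term vanishes continuously as sigma tends to zero", {
  sim <- simulate_ddi_data(n = 25, m = 2, dims = c(12, 15), rank = 3,
                           density = 0.12, noise = 0, seed = 8)
  f0 <- ddi_fit(sim$features, sim$network, goal = 1, sigma = 0, seed = 2)
  feps <- ddi_fit(sim$features, sim$network, goal = 1, sigma = 1e-12,
                  seed = 2)
  o0 <- utils::tail(f0$objective_history, 1)
  oe <- utils::tail(feps$objective_history, 1)
  expect_lt(abs(o0 - oe) / abs(o0), 1e-6)
})

test_that("within-network scoring symmetrizes and flags known pairs", {
  sim <- simulate_ddi_data(n = 30, m = 2, dims = c(15, 20), rank = 3,
                           density = 0.1, noise = 0, seed = 5)
  model <- ddi_fit(sim$features, sim$network, goal = 1, sigma = 0, seed = 1)
  ids <- as.character(sim$catalog)
  pr <- predict_within(model, data.frame(a = ids[1], b = ids[2]))
  expect_equal(pr$score, (model$S[1, 2] + model$S[2, 1]) / 2)
  known_pair <- which(sim$network == 1, arr.ind = TRUE)[1, ]
  pr2 <- predict_within(model, data.frame(a = ids[known_pair[1]],
                                          b = ids[known_pair[2]]))
  expect_true(pr2$known)
  expect_error(predict_within(model, data.frame(a = ids[1], b = ids[1])),
               "self-interaction")
  expect_error(predict_within(model, data.frame(a = "nope", b = ids[1])),
               "unknown")
})

test_that("planted interactions outscore cross-structure pairs", {
  sim <- simulate_ddi_data(n = 40, m = 2, dims = c(25, 30), rank = 4,
                           density = 0.1, noise = 0, seed = 7)
  model <- ddi_fit(sim$features, sim$network, goal = 1, sigma = 0, seed = 1)
  Ssym <- (model$S + t(model$S)) / 2
  pos <- Ssym[upper.tri(Ssym) & sim$network == 1]
  neg <- Ssym[upper.tri(Ssym) & sim$network == 0]
  expect_gt(mean(pos), mean(neg))
})

test_that("cold-start scores follow the averaged projection formula", {
  sim <- simulate_ddi_data(n = 25, m = 1, dims = 15, rank = 3,
                           density = 0.12, noise = 0, seed = 6)
  model <- ddi_fit(sim$features, sim$network, goal = 2, seed = 1)
  # all-zero feature vectors give the zero score vector
  z <- predict_new_drug(model, list(feature1 = numeric(15)))
  expect_equal(unname(z), numeric(25))
  # m = 1 and H* = row k of H: J* = (H Z)[k, ] / 2
  k <- 4
  got <- predict_new_drug(model, list(feature1 = sim$features[[1]][k, ]))
  want <- (sim$features[[1]] %*% model$projections[[1]])[k, ] / 2
  expect_equal(unname(got), unname(want))
  expect_true(all(got >= 0))
  # a missing feature space contributes zeros, with a log message
  expect_message(predict_new_drug(model, list()), "using zeros")
  expect_error(predict_new_drug(model, list(feature1 = numeric(3))),
               "length 3")
})

test_that("held-out drugs rank their true interactors first", {
  sim <- simulate_ddi_data(n = 100, m = 2, dims = c(40, 50), rank = 5,
                           density = 0.08, noise = 0, seed = 11)
  ho <- holdout_drugs(sim, fraction = 0.2, seed = 2)
  model <- ddi_fit(ho$train$features, ho$train$network, goal = 2, seed = 1)
  hits <- vapply(ho$holdout, function(d) {
    sc <- predict_new_drug(model, d$features)
    y <- d$labels
    if (sum(y) == 0 || sum(y) == length(y)) return(NA)
    mean(sc[y == 1]) > mean(sc[y == 0])
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("models persist through the JSON archive unchanged", {
  sim <- simulate_ddi_data(n = 20, m = 2, dims = c(10, 12), rank = 3,
                           density = 0.15, noise = 0, seed = 9)
  model <- ddi_fit(sim$features, sim$network, goal = 1, seed = 4)
  path <- tempfile(fileext = ".json")
  write_ddi_model(model, path)
  back <- read_ddi_model(path)
  expect_equal(back$S, model$S)
  expect_equal(back$projections, lapply(model$projections, unname))
  expect_equal(back$hyperparams$lambda, model$hyperparams$lambda)
  expect_equal(back$objective_history, model$objective_history)
  expect_equal(back$catalog, model$catalog)
  sc1 <- predict_new_drug(model, list(feature1 = sim$features[[1]][1, ]))
  sc2 <- predict_new_drug(back, list(feature1 = sim$features[[1]][1, ]))
  expect_equal(sc1, sc2)
})
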