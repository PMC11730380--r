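test_that("confusion counts follow the threshold rule", {
  expect_equal(confusion_counts(c(0.9, 0.1), c(1, 0), 0.5),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  # everything predicted positive leaves no negatives or misses below
  cm <- confusion_counts(c(0.9, 0.8, 0.7), c(1, 0, 1), 0)
  expect_equal(cm[["tn"]], 0L)
  expect_equal(cm[["fn"]], 0L)
  # six-element hand count
  cm2 <- confusion_counts(c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1),
                          c(1, 0, 1, 1, 0, 0), 0.5)
  expect_equal(cm2, c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  expect_error(confusion_counts(numeric(0), integer(0), 0.5), "empty")
  expect_error(confusion_counts(1, 2, 0.5), "binary")
})

test_that("classification metrics compute the four standard ratios", {
  perfect <- classification_metrics(c(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))
  expect_warning(
    deg <- classification_metrics(c(tp = 0, fp = 0, tn = 5, fn = 0)),
    "undefined")
  expect_equal(deg[["recall"]], 0)
  got <- classification_metrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(unname(got), c(0.6, 0.75, 2 * 0.75 * 0.6 / 1.35, 0.7),
               tolerance = 1e-12)
})

test_that("AUC equals exhaustive pairwise comparison on all small inputs", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.9), c(1, 1, 0)), 0)
  set.seed(42)
  for (len in 2:12) {
    for (rep in 1:20) {
      labels <- sample(c(0, 1), len, replace = TRUE)
      if (sum(labels) %in% c(0, len)) next
      scores <- sample(seq(0, 1, 0.25), len, replace = TRUE)  # forces ties
      expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
    }
  }
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUPR equals the threshold-sweep oracle on all small inputs", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  # constant scores collapse to a single PR point at the prevalence
  expect_equal(aupr_score(rep(0.5, 8), c(1, 0, 0, 0, 1, 0, 0, 0)), 0.25)
  set.seed(24)
  for (len in 2:12) {
    for (rep in 1:20) {
      labels <- sample(c(0, 1), len, replace = TRUE)
      if (sum(labels) == 0) next
      scores <- sample(seq(0, 1, 0.25), len, replace = TRUE)
      expect_equal(aupr_score(scores, labels), oracle_aupr(scores, labels))
    }
  }
  expect_error(aupr_score(c(1, 2), c(0, 0)), "positive")
})

test_that("ranking metrics are invariant to permutation of the pairs", {
  set.seed(7)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  perm <- sample(30)
  expect_equal(auc_score(scores, labels),
               auc_score(scores[perm], labels[perm]))
  expect_equal(aupr_score(scores, labels),
               aupr_score(scores[perm], labels[perm]))
})

test_that("pair folds partition the known interactions evenly", {
  sim <- simulate_ddi_data(n = 20, m = 1, dims = 12, rank = 2,
                           density = 0.06, noise = 0, seed = 13)
  J <- sim$network
  n_pairs <- sum(J) / 2
  folds <- split_goal1(J, k = 5, seed = 1)
  expect_equal(nrow(folds$pairs), n_pairs)
  sizes <- table(folds$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # union of folds is exactly the known pair set
  got <- folds$pairs[order(folds$pairs[, 1], folds$pairs[, 2]), ]
  idx <- which(upper.tri(J) & J == 1)
  want <- cbind(row(J)[idx], col(J)[idx])
  expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ]))
  expect_error(split_goal1(J, k = n_pairs + 1), "fewer known pairs")
})

test_that("drug folds and the case-study preset partition the catalog", {
  folds <- split_goal2(sprintf("D%02d", 1:10), k = 5, seed = 2)
  expect_equal(as.vector(table(folds$fold)), rep(2L, 5))
  cs <- case_study_split(sprintf("D%02d", 1:12), seed = 3)
  expect_equal(length(cs$train), 8)    # 66.67 %
  expect_equal(length(cs$validation), 2)
  expect_equal(length(cs$test), 2)
  expect_setequal(c(cs$train, cs$validation, cs$test), sprintf("D%02d", 1:12))
})

test_that("cross-validation is reproducible and beats chance on planted data", {
  sim <- simulate_ddi_data(n = 40, m = 2, dims = c(25, 30), rank = 4,
                           density = 0.1, noise = 0, seed = 7)
  cv1 <- suppressWarnings(
    ddi_crossval(sim$features, sim$network, goal = 1, k = 5, seed = 3))
  cv2 <- suppressWarnings(
    ddi_crossval(sim$features, sim$network, goal = 1, k = 5, seed = 3))
  expect_identical(cv1$metrics, cv2$metrics)
  mean_row <- cv1$metrics[cv1$metrics$fold == "mean", ]
  n_cand <- choose(40, 2) - sum(sim$network) / 2 + sum(sim$network) / 2 / 5
  prevalence <- (sum(sim$network) / 2 / 5) / n_cand
  expect_gt(mean_row$aupr, prevalence)
  expect_true(all(cv1$metrics$aupr >= 0 & cv1$metrics$aupr <= 1))

  cvg2 <- suppressWarnings(
    ddi_crossval(sim$features, sim$network, goal = 2, k = 5, seed = 3))
  expect_gt(cvg2$metrics[cvg2$metrics$fold == "mean", "auc"], 0.5)
})

test_that("an unpredictable network scores at the chance baseline", {
  # features carry planted structure but the network is rewired at random,
  # so cross-validated AUPR should sit at the candidate prevalence
  sim <- simulate_ddi_data(n = 60, m = 2, dims = c(25, 30), rank = 4,
                           density = 0.1, noise = 0, seed = 21)
  set.seed(99)
  n <- 60
  J <- matrix(0, n, n, dimnames = dimnames(sim$network))
  idx <- sample(which(upper.tri(J)), sum(sim$network) / 2)
  J[idx] <- 1
  J <- J + t(J)
  cv <- suppressWarnings(
    ddi_crossval(sim$features, J, goal = 1, k = 5, seed = 4))
  per_fold <- cv$metrics[cv$metrics$fold %in% as.character(1:5), "aupr"]
  n_pairs <- choose(n, 2)
  held <- sum(J) / 2 / 5
  prevalence <- held / (n_pairs - sum(J) / 2 + held)
  expect_lt(abs(mean(per_fold) - prevalence),
            3 * max(stats::sd(per_fold), 0.005))
})

test_that("cross-validation reports serialize to CSV and JSON", {
  sim <- simulate_ddi_data(n = 25, m = 1, dims = 15, rank = 3,
                           density = 0.12, noise = 0, seed = 5)
  cv <- suppressWarnings(
    ddi_crossval(sim$features, sim$network, goal = 1, k = 3, seed = 1))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_cv_report(cv, csv = csv, json = js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 5)   # 3 folds + mean + sd
  expect_true(all(c("recall", "aupr") %in% names(back)))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$goal, 1)
})

test_that("the tuning grid sweeps all requested weight combinations", {
  sim <- simulate_ddi_data(n = 25, m = 1, dims = 15, rank = 3,
                           density = 0.12, noise = 0, seed = 5)
  res <- suppressWarnings(
    tune_ddi(sim$features, sim$network, goal = 1,
             values = c(1e-3, 1e-1), k = 2, seed = 1, max_iter = 10))
  expect_equal(nrow(res), 8)    # 2^3 combinations
  expect_true(!is.unsorted(rev(res$aupr)))
  res2 <- suppressWarnings(
    tune_ddi(sim$features, sim$network, goal = 2,
             values = c(1e-3, 1e-1), k = 2, seed = 1, max_iter = 10))
  expect_equal(nrow(res2), 4)   # sigma pinned to 0
  expect_true(all(res2$sigma == 0))
})
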