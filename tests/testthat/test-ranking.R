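test_that("consensus aggregation pools, sorts and deduplicates by best rank", {
  l1 <- candidate_list("cpd", c("g2", "g1", "g3", "g4"), c(0.9, 0.8, 0.7, 0.6), "A", "shRNA")
  l2 <- candidate_list("cpd", c("g1", "g5"), c(0.95, 0.1), "B", "cDNA")
  cons <- consensus_aggregate(list(l1, l2))
  expect_equal(cons$entries$gene, c("g2", "g1", "g3", "g4", "g5"))
  expect_equal(cons$entries$normalized_rank, c(0.25, 0.5, 0.75, 1, 1))
  expect_true(all(diff(cons$entries$normalized_rank) >= 0))

  # single list: consensus preserves it
  single <- consensus_aggregate(list(l1))
  expect_equal(single$entries$gene, l1$entries$gene)
  expect_equal(single$entries$normalized_rank, l1$entries$normalized_rank)

  expect_error(consensus_aggregate(list()), "no candidate lists")
  l3 <- candidate_list("other", "g1", 0.5)
  expect_error(consensus_aggregate(list(l1, l3)), "one compound")
})

test_that("consensus rank equals the minimum normalized rank across lists", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:30)
  for (rep_i in 1:5) {
    lists <- lapply(1:4, function(j) {
      gs <- sample(genes, sample(5:20, 1))
      candidate_list("cpd", gs, runif(length(gs)), paste0("CL", j), "shRNA")
    })
    cons <- consensus_aggregate(lists)
    # oracle: per-gene minimum of O_g / n over the lists that contain it
    pool <- do.call(rbind, lapply(lists, function(l) l$entries))
    oracle <- tapply(pool$normalized_rank, pool$gene, min)
    expect_equal(cons$entries$normalized_rank,
                 as.numeric(oracle[cons$entries$gene]))
  }
})

test_that("candidate lists sort by probability with id tie-break", {
  cl <- candidate_list("c", c("gB", "gA", "gC"), c(0.5, 0.5, 0.9))
  expect_equal(cl$entries$gene, c("gC", "gA", "gB"))
  expect_error(candidate_list("c", c("g1", "g1"), c(0.1, 0.2)), "unique")
})

test_that("odds-ratio feature matches the printed mapping", {
  expect_equal(odds_ratio_feature(0.5), 1)
  expect_equal(odds_ratio_feature(0.05), 19)
  expect_equal(odds_ratio_feature(1), 0)
  expect_error(odds_ratio_feature(0), "0, 1")
})

test_that("activity-profile feature takes the maximum reference correlation", {
  mat <- rbind(q = c(1, 2, 3, 4), r1 = c(1, 2, 3, 4), r2 = c(4, 3, 2, 1),
               r3 = c(1, 2, 2.5, 5))
  refs <- list(T1 = c("r1"), T2 = c("r1", "r2", "r3"), T3 = c("r2"), T4 = "absent")
  expect_equal(max_profile_correlation("q", "T1", mat, refs), 1)
  expect_equal(max_profile_correlation("q", "T2", mat, refs), 1)
  expect_equal(max_profile_correlation("q", "T3", mat, refs), -1)
  expect_true(is.na(max_profile_correlation("q", "T4", mat, refs)))
  expect_true(is.na(max_profile_correlation("q", "T5", mat, refs)))
  # insufficient shared assays flags missing
  mat_na <- rbind(q = c(1, 2, NA, NA), r1 = c(NA, NA, 3, 4))
  expect_true(is.na(max_profile_correlation("q", "T1", mat_na, list(T1 = "r1"))))
})

test_that("logistic predictions follow the sigmoid and are monotone", {
  m <- structure(list(weights = 1, bias = 0), class = "logistic_model")
  expect_equal(lr_predict(m, 19), 1 / (1 + exp(-19)), tolerance = 1e-8)
  m0 <- structure(list(weights = 0, bias = 0), class = "logistic_model")
  expect_equal(lr_predict(m0, c(-5, 0, 7)), rep(0.5, 3))
  xs <- seq(-3, 3, length.out = 25)
  expect_true(all(diff(lr_predict(m, xs)) >= 0))
})

test_that("constrained weighted logistic fit honors w >= 0 and class weighting", {
  # perfectly separated positive-direction signal
  set.seed(41)
  x <- c(runif(30, -3, -1), runif(30, 1, 3))
  y <- rep(c(0, 1), each = 30)
  fit <- lr_fit(matrix(x), y, lambda_grid = c(1e-3, 1e-1), n_outer = 3L, n_inner = 3L)
  expect_gt(fit$weights, 0)
  pred <- lr_predict(fit, matrix(x)) > 0.5
  expect_equal(mean(pred == y), 1)

  # anti-predictive feature is pinned at zero; prediction collapses to the prior
  fit_neg <- lr_fit(matrix(-x), y, lambda_grid = c(1e-3, 1e-1),
                    n_outer = 3L, n_inner = 3L)
  expect_equal(fit_neg$weights, 0, tolerance = 1e-6)
  expect_equal(unname(lr_predict(fit_neg, matrix(0))), 0.5, tolerance = 0.02)

  # duplicating every record leaves the class-weighted fit unchanged at fixed lambda
  fit1 <- lr_fit(matrix(x), y, lambda_grid = 0.01, n_outer = 2L, n_inner = 2L)
  fit_dup <- lr_fit(matrix(c(x, x)), c(y, y), lambda_grid = 0.01,
                    n_outer = 2L, n_inner = 2L)
  expect_equal(fit_dup$weights, fit1$weights, tolerance = 1e-6)
  expect_equal(fit_dup$bias, fit1$bias, tolerance = 1e-6)

  # class imbalance: weighting keeps the boundary at the balanced point
  x_im <- c(rnorm(200, -1), rnorm(20, 1))
  y_im <- rep(c(0, 1), c(200, 20))
  fit_im <- lr_fit(matrix(x_im), y_im, lambda_grid = 1e-3, n_outer = 2L, n_inner = 2L)
  expect_gt(lr_predict(fit_im, matrix(0.9)), 0.5)

  expect_warning(f0 <- lr_fit(matrix(0, 20, 1), rep(c(0, 1), 10)), "intercept-only")
  expect_equal(f0$weights, 0)
})

test_that("balanced metrics reduce to plain metrics on balanced data", {
  m <- balanced_metrics(tp = 1, fp = 49, tn = 49, fn = 1, n_p = 2, n_n = 98)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)

  # balanced classes: weighted = plain
  mb <- balanced_metrics(tp = 30, fp = 10, tn = 40, fn = 20, n_p = 50, n_n = 50)
  expect_equal(mb$precision, 30 / 40)
  expect_equal(mb$recall, 30 / 50)

  mp <- balanced_metrics(tp = 10, fp = 0, tn = 90, fn = 0, n_p = 10, n_n = 90)
  expect_equal(mp$precision, 1); expect_equal(mp$recall, 1)
  expect_equal(mp$f1, 1); expect_equal(mp$mcc, 1)

  expect_error(balanced_metrics(1, 1, 1, 1, 0, 2), "positive")
  expect_error(balanced_metrics(2, 1, 1, 1, 5, 2), "inconsistent")
})

test_that("weighted AUC equals the rank statistic and behaves at the extremes", {
  sc <- c(0.9, 0.8, 0.3, 0.1)
  y <- c(1, 1, 0, 0)
  a <- weighted_auc(sc, y)
  expect_equal(a$roc_auc, 1)
  expect_equal(weighted_auc(rev(sc), y)$roc_auc, 0)
  set.seed(9)
  sc2 <- runif(200); y2 <- rbinom(200, 1, 0.3)
  w <- weighted_auc(sc2, y2)
  expect_true(w$roc_auc > 0.3 && w$roc_auc < 0.7)
  expect_true(w$pr_auc >= 0 && w$pr_auc <= 1)
})

test_that("recall at the top 5% applies the strict boundary rule", {
  mk_rank <- function(cp, genes, ranks) {
    structure(list(compound_id = cp,
                   entries = data.frame(gene = genes, normalized_rank = ranks)),
              class = "consensus_ranking")
  }
  r1 <- mk_rank("c1", sprintf("g%03d", 1:100), (1:100) / 100)
  expect_equal(as.numeric(recall_at_percent(list(c1 = r1), list(c1 = "g001"))), 1)
  # exactly at the boundary counts; just above it does not
  r2 <- mk_rank("c2", c("hit", "x"), c(0.05, 0.9))
  r3 <- mk_rank("c3", c("hit", "x"), c(0.051, 0.9))
  expect_equal(as.numeric(recall_at_percent(list(c2 = r2), list(c2 = "hit"))), 1)
  expect_equal(as.numeric(recall_at_percent(list(c3 = r3), list(c3 = "hit"))), 0)
  # missing compounds are excluded and counted
  out <- recall_at_percent(list(c2 = r2), list(c2 = "hit", c9 = "g1"))
  expect_equal(attr(out, "n_excluded"), 1L)

  # Monte-Carlo null: uniform rankings of 200 candidates recall ~5%
  set.seed(12)
  genes <- sprintf("g%03d", 1:200)
  rankings <- lapply(1:200, function(i)
    mk_rank(paste0("c", i), sample(genes), (1:200) / 200))
  names(rankings) <- paste0("c", 1:200)
  known <- stats::setNames(as.list(sample(genes, 200, replace = TRUE)),
                           paste0("c", 1:200))
  null_recall <- as.numeric(recall_at_percent(rankings, known))
  expect_lt(abs(null_recall - 0.05), 0.05)
})

test_that("network export applies the probability and rank thresholds", {
  edges <- data.frame(
    compound_id = c("c1", "c1", "c2", "c3"),
    gene = c("g1", "g2", "g3", "g4"),
    probability = c(0.95, 0.85, 0.7, 0.9),
    normalized_rank = c(0.01, 0.2, 0.01, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  net <- export_network(edges, path)
  expect_equal(net$gene, c("g1", "g4"))
  expect_true(file.exists(paste0(path, ".json")))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_edges, 2L)
})
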