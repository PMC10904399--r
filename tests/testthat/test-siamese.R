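test_that("forward pass is symmetric, calibrated at zero, and matches a hand oracle", {
  p <- siamese_params(4L, hidden1 = 6L, hidden2 = 3L, seed = 2)
  # zeroed parameters give sigmoid(0) = 0.5 for every pair
  p0 <- p
  p0$W1[] <- 0; p0$W2[] <- 0; p0$W3[] <- 0
  expect_equal(siamese_forward(p0, rnorm(4), rnorm(4)), 0.5)

  # input-swap symmetry
  set.seed(8)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(siamese_forward(p, a, b), siamese_forward(p, b, a), tolerance = 1e-12)

  # explicit affine/relu/sigmoid oracle
  relu <- function(x) pmax(x, 0)
  sig <- function(x) 1 / (1 + exp(-x))
  h1a <- relu(drop(a %*% p$W1) + p$b1)
  h1b <- relu(drop(b %*% p$W1) + p$b1)
  h2 <- relu(drop((h1a * h1b) %*% p$W2) + p$b2)
  o <- sig(drop(h2 %*% p$W3) + p$b3)
  expect_equal(siamese_forward(p, a, b), o, tolerance = 1e-12)

  expect_error(siamese_forward(p, rnorm(3), rnorm(4)), "dimension mismatch")
})

test_that("cross-entropy loss matches the printed arithmetic", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(0.5, 0), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), 0.1054 + 0.2231, tolerance = 1e-4)
})

test_that("balanced sampling yields an exact per-gene 1:1 ratio with exclusions", {
  pos <- data.frame(
    compound_id = c("c1", "c2", "c3", "c1", "c4"),
    target_gene = c("gA", "gA", "gA", "gB", "gB"),
    stringsAsFactors = FALSE)
  ann <- pos
  cands <- sprintf("c%d", 1:10)
  out <- balanced_pair_sampling(pos, ann, cands, seed = 3)
  tab <- table(out$target_gene, out$label)
  expect_equal(unname(tab[, "1"]), unname(tab[, "0"]))
  expect_equal(sum(out$label == 1), sum(out$label == 0))
  # a compound annotated to a gene never appears as its negative
  negA <- out$compound_id[out$label == 0 & out$target_gene == "gA"]
  expect_false(any(negA %in% c("c1", "c2", "c3")))

  # gene with no eligible negative errors by name
  expect_error(
    balanced_pair_sampling(pos, ann, c("c1", "c2", "c3"), seed = 1),
    "gA")
})

test_that("training separates planted co-targeting pairs and applies the target filter", {
  # synthetic vectors: co-targeting pairs share a latent direction
  set.seed(21)
  d <- 12L
  n_targets <- 12L; n_cpd <- 30L
  dirs <- matrix(rnorm(n_targets * d), n_targets, d)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tg <- sprintf("T%02d", 1:n_targets)
  cp <- sprintf("c%02d", 1:n_cpd)
  cpd_target <- sample(tg, n_cpd, replace = TRUE)
  gvec <- dirs + matrix(rnorm(n_targets * d, sd = 0.2), n_targets, d)
  rownames(gvec) <- tg
  cvec <- dirs[match(cpd_target, tg), ] + matrix(rnorm(n_cpd * d, sd = 0.2), n_cpd, d)
  rownames(cvec) <- cp
  ann <- data.frame(compound_id = cp, target_gene = cpd_target,
                    stringsAsFactors = FALSE)
  pairs <- balanced_pair_sampling(ann, ann, cp, seed = 4)
  fold <- compound_folds(pairs$compound_id, 5L, seed = 6)
  tr <- fold != 1L
  ens <- train_cotarget_model(pairs[tr, ], cvec, gvec, annotations = ann,
                              epochs = 60L, n_models = 3L,
                              hidden1 = 64L, hidden2 = 16L, seed = 5)
  te <- pairs[!tr, ]
  pr <- predict_cotarget(ens, cvec[te$compound_id, , drop = FALSE],
                         gvec[te$target_gene, , drop = FALSE])
  expect_gt(mean(pr[te$label == 1]), mean(pr[te$label == 0]))

  # trained model keeps the input-swap symmetry (square inputs of equal dim)
  m1 <- ens$members[[1]]
  v1 <- cvec[1, ]; v2 <- gvec[1, ]
  expect_equal(siamese_forward(m1, v1, v2), siamese_forward(m1, v2, v1),
               tolerance = 1e-12)

  # polypharmacology filter: a compound with six annotated targets is dropped
  ann6 <- rbind(ann, data.frame(compound_id = "c01",
                                target_gene = sprintf("X%d", 1:6)))
  ens6 <- train_cotarget_model(pairs[tr, ], cvec, gvec, annotations = ann6,
                               epochs = 1L, n_models = 1L,
                               hidden1 = 8L, hidden2 = 4L, seed = 1)
  expect_true("c01" %in% ens6$excluded_compounds)
  expect_equal(ens6$n_excluded, 1L)

  # single-member ensemble equals the bare model output
  ens1 <- train_cotarget_model(pairs[tr, ], cvec, gvec,
                               epochs = 2L, n_models = 1L,
                               hidden1 = 8L, hidden2 = 4L, seed = 11)
  pr_ens <- predict_cotarget(ens1, cvec[1:3, ], gvec[1:3, ])
  pr_raw <- as.numeric(siamese_forward(ens1$members[[1]], cvec[1:3, ], gvec[1:3, ]))
  expect_equal(pr_ens, pr_raw)
})

test_that("model checkpoints round-trip through the JSON container", {
  set.seed(30)
  cvec <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("c", 1:5), NULL))
  gvec <- matrix(rnorm(16), 4, 4, dimnames = list(paste0("T", 1:4), NULL))
  pairs <- data.frame(compound_id = rep(paste0("c", 1:5), 2),
                      target_gene = sample(paste0("T", 1:4), 10, replace = TRUE),
                      label = rep(c(1, 0), each = 5))
  ens <- train_cotarget_model(pairs, cvec, gvec, epochs = 3L, n_models = 2L,
                              hidden1 = 8L, hidden2 = 4L, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cotarget_model(ens, path)
  back <- read_cotarget_model(path)
  p1 <- predict_cotarget(ens, cvec, gvec[c(1, 2, 3, 4, 1), ])
  p2 <- predict_cotarget(back, cvec, gvec[c(1, 2, 3, 4, 1), ])
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("compound-wise folds never split a compound across train and validation", {
  ids <- rep(sprintf("c%02d", 1:20), times = sample(1:4, 20, replace = TRUE))
  f <- compound_folds(ids, 5L, seed = 3)
  expect_true(all(tapply(f, ids, function(x) length(unique(x))) == 1L))
  expect_equal(sort(unique(f)), 1:5)
})
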