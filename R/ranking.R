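#' Candidate target list for one compound in one context
#'
#' Orders candidate genes by decreasing predicted probability (ties broken by
#' gene id) and records each gene's normalized rank \eqn{O_g / n}.
#'
#' @param compound_id string.
#' @param genes character vector of candidate genes (unique).
#' @param probabilities numeric vector of predicted co-targeting
#'   probabilities, one per gene.
#' @param cell_line,perturbagen_type context labels.
#' @return Object of class `candidate_list` with a data.frame `entries`
#'   (gene, probability, rank, normalized_rank).
#' @export
candidate_list <- function(compound_id, genes, probabilities,
                           cell_line = "NA", perturbagen_type = "shRNA") {
  stopifnot(length(genes) == length(probabilities))
  if (anyDuplicated(genes)) stop("candidate genes must be unique within a list")
  ord <- order(-probabilities, genes)
  n <- length(genes)
  entries <- data.frame(gene = genes[ord], probability = probabilities[ord],
                        rank = seq_len(n), normalized_rank = seq_len(n) / n,
                        stringsAsFactors = FALSE)
  structure(list(compound_id = compound_id, cell_line = cell_line,
                 perturbagen_type = perturbagen_type, entries = entries, n = n),
            class = "candidate_list")
}

#' Consensus target ranking across contexts
#'
#' Pools (gene, normalized rank) entries from every per-cell-line /
#' per-perturbagen-type list of one compound, sorts ascending by normalized
#' rank (stable, ties by gene id), and keeps the first occurrence of each
#' gene — equivalently each gene retains its minimum normalized rank.
#'
#' @param lists list of `candidate_list` objects for one compound.
#' @return Object of class `consensus_ranking` with data.frame `entries`
#'   (gene, normalized_rank), non-decreasing down the list.
#' @export
consensus_aggregate <- function(lists) {
  if (!length(lists)) stop("no candidate lists supplied")
  stopifnot(all(vapply(lists, inherits, TRUE, "candidate_list")))
  cmp <- unique(vapply(lists, `[[`, "", "compound_id"))
  if (length(cmp) != 1L) stop("all lists must belong to one compound")
  pooled <- do.call(rbind, lapply(lists, function(l)
    l$entries[, c("gene", "normalized_rank")]))
  pooled <- pooled[order(pooled$normalized_rank, pooled$gene), ]
  keep <- !duplicated(pooled$gene)
  entries <- pooled[keep, ]
  rownames(entries) <- NULL
  structure(list(compound_id = cmp, entries = entries),
            class = "consensus_ranking")
}

#' Odds-ratio feature of a normalized rank
#'
#' \eqn{x = (1 - r)/r}: the best possible rank gives a large feature, the
#' worst (r = 1) gives 0.
#'
#' @param r normalized rank(s) in (0, 1].
#' @return numeric feature value(s).
#' @export
odds_ratio_feature <- function(r) {
  if (any(r <= 0)) stop("normalized rank must be in (0, 1]")
  (1 - r) / r
}

#' Maximum activity-profile correlation feature
#'
#' Pearson correlation between the query compound's activity profile and
#' each reference compound annotated to the target, over the assays both
#' share; the maximum over references is the feature. Returns `NA` (flagged
#' missing) when no reference exists or fewer than `min_shared` assays are
#' jointly observed.
#'
#' @param query compound id (row of `mat`).
#' @param target gene id (key of `reference_map`).
#' @param mat compounds x assays numeric matrix (may contain NA).
#' @param reference_map named list: target gene -> character vector of
#'   reference compound ids.
#' @param min_shared minimum jointly observed assays (default 3).
#' @return scalar feature or `NA`.
#' @export
max_profile_correlation <- function(query, target, mat, reference_map, min_shared = 3L) {
  refs <- reference_map[[target]]
  if (is.null(refs) || !length(refs)) return(NA_real_)
  refs <- setdiff(intersect(refs, rownames(mat)), query)
  if (!length(refs)) return(NA_real_)
  qv <- mat[query, ]
  qs <- numeric(0)
  for (r in refs) {
    rv <- mat[r, ]
    ok <- !is.na(qv) & !is.na(rv)
    if (sum(ok) < min_shared) next
    qs <- c(qs, suppressWarnings(stats::cor(qv[ok], rv[ok])))
  }
  qs <- qs[!is.na(qs)]
  if (!length(qs)) return(NA_real_)
  max(qs)
}

#' Logistic model prediction
#'
#' \eqn{p = 1/(1 + \exp(-b - w \cdot x))}. With the non-negativity
#' constraint on `w` enforced at fitting time, predictions are monotone
#' non-decreasing in every feature.
#'
#' @param model a `logistic_model` from [lr_fit()] (or a list with `weights`
#'   and `bias`).
#' @param x numeric feature vector or matrix (rows = records).
#' @return probability (vector).
#' @export
lr_predict <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = length(model$weights))
  if (ncol(X) != length(model$weights))
    stop("feature count mismatch: model has ", length(model$weights))
  .sigmoid(drop(X %*% model$weights) + model$bias)
}

# Weighted negative log-likelihood + L2 penalty on weights (not on bias).
.lr_objective <- function(theta, X, y, lambda) {
  b <- theta[1L]; w <- theta[-1L]
  n_p <- sum(y == 1); n_n <- sum(y == 0)
  eta <- drop(X %*% w) + b
  p <- .sigmoid(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  nll <- -(sum(log(p[y == 1])) / n_p + sum(log(1 - p[y == 0])) / n_n)
  nll + lambda * sum(w^2)
}

.lr_gradient <- function(theta, X, y, lambda) {
  b <- theta[1L]; w <- theta[-1L]
  n_p <- sum(y == 1); n_n <- sum(y == 0)
  sw <- ifelse(y == 1, 1 / n_p, 1 / n_n)
  p <- .sigmoid(drop(X %*% w) + b)
  resid <- sw * (p - y)
  c(sum(resid), drop(crossprod(X, resid)) + 2 * lambda * w)
}

.lr_solve <- function(X, y, lambda) {
  theta0 <- numeric(ncol(X) + 1L)
  fit <- stats::optim(theta0, .lr_objective, .lr_gradient, X = X, y = y,
                      lambda = lambda, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, ncol(X))),
                      control = list(maxit = 500L))
  list(bias = fit$par[1L], weights = fit$par[-1L], value = fit$value)
}

#' Fit class-weighted logistic regression with non-negative weights
#'
#' Minimizes the class-balanced negative log-likelihood (positives weighted
#' 1/n_p, negatives 1/n_n) plus an L2 penalty \eqn{\lambda \|w\|^2}, subject
#' to \eqn{w \ge 0} (bias unconstrained). The penalty strength is chosen by
#' inner cross-validation over `lambda_grid`; an outer five-fold loop
#' reports held-out performance. Records with all-zero features fit an
#' intercept-only model with a warning.
#'
#' @param features numeric matrix (records x features; `NA` not allowed).
#' @param labels binary labels.
#' @param lambda_grid candidate penalties (default decade steps 1e-3..1e3).
#' @param n_outer,n_inner fold counts (default 5 each).
#' @param seed integer seed for fold assignment.
#' @return Object of class `logistic_model`: `weights` (all >= 0), `bias`,
#'   `lambda`, `outer_cv` data.frame of per-fold weighted log-loss.
#' @export
lr_fit <- function(features, labels, lambda_grid = 10^(-3:3),
                   n_outer = 5L, n_inner = 5L, seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (anyNA(X)) stop("features contain missing values; filter or impute upstream")
  if (all(X == 0)) {
    warning("all features are zero; fitting intercept-only model")
    fit <- .lr_solve(matrix(0, nrow(X), 1L), y, 0)
    return(structure(list(weights = rep(0, ncol(X)), bias = fit$bias,
                          lambda = NA_real_, outer_cv = NULL),
                     class = "logistic_model"))
  }

  cv_lambda <- function(Xtr, ytr, folds) {
    losses <- sapply(lambda_grid, function(lm) {
      mean(sapply(unique(folds), function(f) {
        tr <- folds != f
        if (length(unique(ytr[tr])) < 2L || length(unique(ytr[!tr])) < 2L)
          return(NA_real_)
        fit <- .lr_solve(Xtr[tr, , drop = FALSE], ytr[tr], lm)
        .lr_objective(c(fit$bias, fit$weights), Xtr[!tr, , drop = FALSE],
                      ytr[!tr], 0)
      }), na.rm = TRUE)
    })
    lambda_grid[which.min(losses)]
  }

  stratified_folds <- function(yy, k, seed_off) {
    set.seed(seed + seed_off)
    f <- integer(length(yy))
    for (cls in unique(yy)) {
      idx <- which(yy == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  }

  outer_folds <- stratified_folds(y, n_outer, 0L)
  outer_cv <- data.frame(fold = integer(), lambda = numeric(), loss = numeric())
  for (f in seq_len(n_outer)) {
    tr <- outer_folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
    inner <- stratified_folds(y[tr], n_inner, f)
    lam <- cv_lambda(X[tr, , drop = FALSE], y[tr], inner)
    fit <- .lr_solve(X[tr, , drop = FALSE], y[tr], lam)
    loss <- .lr_objective(c(fit$bias, fit$weights), X[!tr, , drop = FALSE], y[!tr], 0)
    outer_cv <- rbind(outer_cv, data.frame(fold = f, lambda = lam, loss = loss))
  }
  lam_final <- cv_lambda(X, y, stratified_folds(y, n_inner, 1000L))
  fit <- .lr_solve(X, y, lam_final)
  structure(list(weights = fit$weights, bias = fit$bias, lambda = lam_final,
                 outer_cv = outer_cv),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model: bias", signif(x$bias, 4), "weights",
      paste(signif(x$weights, 4), collapse = ", "),
      "lambda", x$lambda, "\n")
  invisible(x)
}

#' Imbalance-corrected (balanced) classification metrics
#'
#' Re-weights the confusion counts by 1/n_p (TP, FN) and 1/n_n (FP, TN) so
#' the metrics describe the classifier as if the classes were balanced 1:1,
#' then computes precision, recall, specificity, F1, accuracy and MCC from
#' the weighted counts.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @param n_p,n_n class sizes (positives, negatives); must be non-zero and
#'   consistent with the counts.
#' @return named list of weighted counts and metrics.
#' @export
balanced_metrics <- function(tp, fp, tn, fn, n_p, n_n) {
  if (n_p <= 0 || n_n <= 0) stop("both class sizes must be positive")
  if (tp + fn != n_p || fp + tn != n_n)
    stop("counts inconsistent with class sizes")
  TPw <- tp / n_p; FNw <- fn / n_p; FPw <- fp / n_n; TNw <- tn / n_n
  precision <- if (TPw + FPw > 0) TPw / (TPw + FPw) else NA_real_
  recall <- TPw / (TPw + FNw)
  specificity <- TNw / (TNw + FPw)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  denom <- sqrt((TPw + FPw) * (TPw + FNw) * (TNw + FPw) * (TNw + FNw))
  mcc <- if (denom > 0) (TPw * TNw - FPw * FNw) / denom else NA_real_
  list(tp_w = TPw, fp_w = FPw, tn_w = TNw, fn_w = FNw,
       precision = precision, recall = recall, specificity = specificity,
       f1 = f1, accuracy = (TPw + TNw) / (TPw + TNw + FPw + FNw), mcc = mcc)
}

#' Class-weighted ROC and precision-recall areas
#'
#' Sweeps all score thresholds with samples weighted 1/n_p and 1/n_n, giving
#' the areas the model would attain on a balanced 1:1 dataset.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @return list with `roc_auc` and `pr_auc`.
#' @export
weighted_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.numeric(labels)
  n_p <- sum(y == 1); n_n <- sum(y == 0)
  if (n_p == 0 || n_n == 0) stop("both classes must be present")
  ord <- order(-scores)
  y <- y[ord]
  # with per-sample weights 1/n_p, 1/n_n the weighted ROC AUC reduces to the
  # plain rank statistic (ties averaged)
  rnk <- rank(scores)
  auc <- (sum(rnk[labels == 1]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
  tp <- cumsum(y == 1) / n_p
  fp <- cumsum(y == 0) / n_n
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  rec <- tp
  pr <- sum(diff(c(0, rec)) * prec)
  list(roc_auc = auc, pr_auc = pr)
}

#' Recall at the top N% of consensus rankings
#'
#' Fraction of compounds with at least one known target at normalized
#' consensus rank \eqn{\le N/100} (strict boundary: a rank of exactly
#' N/100 counts, anything larger does not). Compounds in `known` missing
#' from `rankings` are excluded and counted.
#'
#' @param rankings named list of `consensus_ranking` objects keyed by
#'   compound id.
#' @param known named list: compound id -> character vector of known target
#'   genes.
#' @param percent cutoff N (default 5).
#' @return scalar recall with attribute `"n_excluded"`.
#' @export
recall_at_percent <- function(rankings, known, percent = 5) {
  cutoff <- percent / 100
  cmpds <- names(known)
  have <- cmpds %in% names(rankings)
  hits <- vapply(cmpds[have], function(cp) {
    e <- rankings[[cp]]$entries
    any(e$gene %in% known[[cp]] & e$normalized_rank <= cutoff)
  }, logical(1))
  out <- mean(hits)
  attr(out, "n_excluded") <- sum(!have)
  out
}

#' Export the predicted compound-target network
#'
#' Keeps edges with probability above `prob_cutoff` and normalized consensus
#' rank at or below `rank_cutoff` (defaults 0.8 and 0.05), writes a
#' tab-delimited edge list and a JSON summary.
#'
#' @param edges data.frame with columns `compound_id`, `gene`, `probability`,
#'   `normalized_rank` and optional evidence columns.
#' @param path output TSV path (summary written to `<path>.json`).
#' @param prob_cutoff,rank_cutoff inclusion thresholds.
#' @return the filtered data.frame, invisibly.
#' @export
export_network <- function(edges, path, prob_cutoff = 0.8, rank_cutoff = 0.05) {
  keep <- edges$probability > prob_cutoff & edges$normalized_rank <= rank_cutoff
  net <- edges[keep, , drop = FALSE]
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_edges = nrow(net),
         n_compounds = length(unique(net$compound_id)),
         n_targets = length(unique(net$gene)),
         prob_cutoff = prob_cutoff, rank_cutoff = rank_cutoff),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(net)
}
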