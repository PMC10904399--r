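#' Initialize Siamese classifier parameters
#'
#' A shared affine layer maps both signature vectors to a hidden space; the
#' two hidden vectors are combined by element-wise product (which makes the
#' classifier symmetric in its inputs), then a two-layer head with sigmoid
#' output scores the pair. Hidden activations are ReLU. Defaults follow the
#' 2048/512-unit architecture; tests use smaller layers.
#'
#' @param input_dim dimension of the signature vectors.
#' @param hidden1 shared-layer width (default 2048).
#' @param hidden2 classification-layer width (default 512).
#' @param seed integer seed for the (He-scaled) normal initialization.
#' @return Object of class `siamese_params`.
#' @export
siamese_params <- function(input_dim, hidden1 = 2048L, hidden2 = 512L, seed = 1L) {
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  structure(list(
    W1 = he(input_dim, hidden1), b1 = numeric(hidden1),
    W2 = he(hidden1, hidden2),  b2 = numeric(hidden2),
    W3 = he(hidden2, 1L),       b3 = 0,
    input_dim = input_dim, hidden1 = hidden1, hidden2 = hidden2, seed = seed
  ), class = "siamese_params")
}

.relu <- function(x) x * (x > 0)

# Forward pass on row-matrices of pairs; returns intermediates for backprop.
.siamese_forward_full <- function(params, Xc, Xg) {
  H1c <- .relu(sweep(Xc %*% params$W1, 2L, params$b1, "+"))
  H1g <- .relu(sweep(Xg %*% params$W1, 2L, params$b1, "+"))
  Mm <- H1c * H1g
  H2 <- .relu(sweep(Mm %*% params$W2, 2L, params$b2, "+"))
  o <- .sigmoid(drop(H2 %*% params$W3) + params$b3)
  list(H1c = H1c, H1g = H1g, M = Mm, H2 = H2, o = o)
}

#' Siamese forward pass
#'
#' Scores one or more (compound, gene) signature-vector pairs. The shared
#' layer is applied identically to both inputs and the element-wise product
#' makes the output invariant to swapping the two vectors.
#'
#' @param params a `siamese_params`.
#' @param compound_vec,gene_vec numeric vectors (or row-matrices of equal
#'   `nrow`) of dimension `params$input_dim`.
#' @return probability (or vector of probabilities) in (0, 1).
#' @export
siamese_forward <- function(params, compound_vec, gene_vec) {
  stopifnot(inherits(params, "siamese_params"))
  to_mat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1L)
  Xc <- to_mat(if (inherits(compound_vec, "signature_vector")) compound_vec$vector else compound_vec)
  Xg <- to_mat(if (inherits(gene_vec, "signature_vector")) gene_vec$vector else gene_vec)
  if (ncol(Xc) != params$input_dim || ncol(Xg) != params$input_dim)
    stop(sprintf("input dimension mismatch: expected %d, got %d / %d",
                 params$input_dim, ncol(Xc), ncol(Xg)))
  .siamese_forward_full(params, Xc, Xg)$o
}

#' Binary cross-entropy loss
#'
#' \eqn{-\sum_i (y_i \log o_i + (1 - y_i)\log(1 - o_i))}. Probabilities
#' outside (0, 1) are clipped to [1e-7, 1 - 1e-7].
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @return scalar total loss.
#' @export
bce_loss <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  -sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Balanced negative pair sampling
#'
#' For every target gene appearing in a positive (compound, gene) pair,
#' samples exactly as many negative pairs using compounds not annotated to
#' that gene, so each gene occurs in positive and negative pairs at a 1:1
#' ratio and the classifier is not biased towards popular targets.
#'
#' @param positives data.frame with columns `compound_id`, `target_gene`, and
#'   optionally `cell_line`.
#' @param annotations data.frame (`compound_id`, `target_gene`) giving all
#'   known compound-target links (used for the exclusion rule).
#' @param candidate_compounds character vector of compounds eligible as
#'   negatives.
#' @param seed integer seed.
#' @return data.frame of pairs with a `label` column (1 positive, 0 sampled
#'   negative); per gene, positives and negatives are equinumerous.
#' @export
balanced_pair_sampling <- function(positives, annotations, candidate_compounds, seed = 1L) {
  stopifnot(all(c("compound_id", "target_gene") %in% names(positives)))
  set.seed(seed)
  if (!"cell_line" %in% names(positives)) positives$cell_line <- "NA"
  negs <- lapply(split(positives, positives$target_gene), function(pp) {
    g <- pp$target_gene[1L]
    annotated <- unique(annotations$compound_id[annotations$target_gene == g])
    pool <- setdiff(candidate_compounds, annotated)
    if (!length(pool)) stop("no eligible negative compound for gene: ", g)
    data.frame(compound_id = sample(pool, nrow(pp), replace = TRUE),
               target_gene = g, cell_line = pp$cell_line,
               stringsAsFactors = FALSE)
  })
  negs <- do.call(rbind, negs)
  pos <- positives[, c("compound_id", "target_gene", "cell_line")]
  out <- rbind(cbind(pos, label = 1), cbind(negs, label = 0))
  rownames(out) <- NULL
  out
}

# One Adam-trained Siamese model on matrices of pair vectors.
.train_one_siamese <- function(Xc, Xg, y, hidden1, hidden2, epochs, batch_size,
                               learning_rate, seed) {
  params <- siamese_params(ncol(Xc), hidden1, hidden2, seed = seed)
  n <- nrow(Xc)
  adam <- lapply(params[c("W1", "b1", "W2", "b2", "W3", "b3")],
                 function(p) list(m = p * 0, v = p * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  loss_hist <- numeric(epochs)
  set.seed(seed + 104729L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      bXc <- Xc[idx, , drop = FALSE]; bXg <- Xg[idx, , drop = FALSE]
      by <- y[idx]; m <- length(idx)
      f <- .siamese_forward_full(params, bXc, bXg)
      ep_loss <- ep_loss + bce_loss(f$o, by)
      do <- (f$o - by) / m                         # d mean-BCE / d logit
      gW3 <- crossprod(f$H2, do); gb3 <- sum(do)
      dH2 <- (do %*% t(params$W3)) * (f$H2 > 0)
      gW2 <- crossprod(f$M, dH2); gb2 <- colSums(dH2)
      dM <- dH2 %*% t(params$W2)
      dH1c <- dM * f$H1g * (f$H1c > 0)
      dH1g <- dM * f$H1c * (f$H1g > 0)
      gW1 <- crossprod(bXc, dH1c) + crossprod(bXg, dH1g)
      gb1 <- colSums(dH1c) + colSums(dH1g)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
      step <- step + 1L
      for (nm in names(grads)) {
        st <- adam[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
        st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
        adam[[nm]] <- st
        upd <- learning_rate * (st$m / (1 - beta1^step)) /
          (sqrt(st$v / (1 - beta2^step)) + eps)
        params[[nm]] <- params[[nm]] - upd
      }
    }
    loss_hist[ep] <- ep_loss / n
  }
  attr(params, "loss_history") <- loss_hist
  params
}

#' Train the co-targeting Siamese ensemble
#'
#' Trains `n_models` Siamese classifiers (different seeds, same data) on
#' labelled (compound vector, gene vector) pairs; ensemble prediction is the
#' arithmetic mean of member probabilities. Compounds with more than
#' `max_targets` annotated targets are excluded from training (count
#' recorded). Cross-validation folds, when requested via `n_folds`, are
#' split by compound so no compound appears in both train and validation.
#'
#' @param pairs data.frame with columns `compound_id`, `target_gene`,
#'   `label` (and optionally `cell_line`).
#' @param compound_vecs,gene_vecs numeric matrices of signature vectors, rows
#'   named by compound id / target gene id.
#' @param annotations data.frame (`compound_id`, `target_gene`) used for the
#'   polypharmacology filter.
#' @param epochs training epochs per model (default 60).
#' @param n_models ensemble size (default 3).
#' @param hidden1,hidden2 layer widths (defaults 2048/512).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_targets polypharmacology cutoff (default 5).
#' @param seed integer seed.
#' @return Object of class `cotarget_ensemble` with members, the exclusion
#'   count, and the training configuration.
#' @export
train_cotarget_model <- function(pairs, compound_vecs, gene_vecs, annotations = NULL,
                                 epochs = 60L, n_models = 3L,
                                 hidden1 = 2048L, hidden2 = 512L,
                                 batch_size = 128L, learning_rate = 1e-3,
                                 max_targets = 5L, seed = 1L) {
  stopifnot(all(c("compound_id", "target_gene", "label") %in% names(pairs)))
  excluded <- character()
  if (!is.null(annotations)) {
    tcount <- table(unique(annotations[, c("compound_id", "target_gene")])$compound_id)
    excluded <- names(tcount)[tcount > max_targets]
    pairs <- pairs[!pairs$compound_id %in% excluded, , drop = FALSE]
  }
  if (length(unique(pairs$label)) < 2L)
    stop("training pairs must contain both labels")
  missing_c <- setdiff(pairs$compound_id, rownames(compound_vecs))
  missing_g <- setdiff(pairs$target_gene, rownames(gene_vecs))
  if (length(missing_c) || length(missing_g))
    stop("pairs reference vectors not provided: ",
         paste(utils::head(c(missing_c, missing_g), 5L), collapse = ", "))
  Xc <- compound_vecs[pairs$compound_id, , drop = FALSE]
  Xg <- gene_vecs[pairs$target_gene, , drop = FALSE]
  y <- pairs$label
  members <- lapply(seq_len(n_models), function(k)
    .train_one_siamese(Xc, Xg, y, hidden1, hidden2, epochs, batch_size,
                       learning_rate, seed = seed + k))
  structure(list(members = members, n_excluded = length(excluded),
                 excluded_compounds = excluded,
                 config = list(epochs = epochs, n_models = n_models,
                               hidden1 = hidden1, hidden2 = hidden2,
                               batch_size = batch_size,
                               learning_rate = learning_rate,
                               max_targets = max_targets, seed = seed)),
            class = "cotarget_ensemble")
}

#' Ensemble prediction for signature pairs
#'
#' @param ensemble a `cotarget_ensemble`.
#' @param compound_vec,gene_vec vectors or row-matrices of pair inputs.
#' @return mean member probability per pair.
#' @export
predict_cotarget <- function(ensemble, compound_vec, gene_vec) {
  stopifnot(inherits(ensemble, "cotarget_ensemble"))
  probs <- vapply(ensemble$members,
                  function(m) as.numeric(siamese_forward(m, compound_vec, gene_vec)),
                  numeric(if (is.matrix(compound_vec)) nrow(compound_vec) else 1L))
  if (is.matrix(probs)) rowMeans(probs) else mean(probs)
}

#' Compound-wise cross-validation folds
#'
#' Assigns each distinct compound to one of `n_folds` folds so that no
#' compound appears in both the training and validation side of a split.
#'
#' @param compound_ids character vector (one entry per pair).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return integer fold id per input entry.
#' @export
compound_folds <- function(compound_ids, n_folds = 5L, seed = 1L) {
  set.seed(seed)
  u <- unique(compound_ids)
  fold_of <- stats::setNames(sample(rep_len(seq_len(n_folds), length(u))), u)
  unname(fold_of[compound_ids])
}

#' Save / load a Siamese ensemble checkpoint
#'
#' Portable JSON container holding the configuration and all weight arrays;
#' round-trips exactly (weights serialized at full precision).
#'
#' @param ensemble a `cotarget_ensemble`.
#' @param path file path (JSON).
#' @export
write_cotarget_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cotarget_ensemble"))
  ser <- list(
    config = ensemble$config,
    n_excluded = ensemble$n_excluded,
    excluded_compounds = as.list(ensemble$excluded_compounds),
    members = lapply(ensemble$members, function(m)
      list(W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2, W3 = as.numeric(m$W3),
           b3 = m$b3, input_dim = m$input_dim, hidden1 = m$hidden1,
           hidden2 = m$hidden2, seed = m$seed))
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cotarget_model
#' @export
read_cotarget_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  members <- lapply(seq_along(ser$members), function(k) {
    m <- ser$members[[k]]
    structure(list(
      W1 = matrix(unlist(m$W1), m$input_dim, m$hidden1),
      b1 = as.numeric(unlist(m$b1)),
      W2 = matrix(unlist(m$W2), m$hidden1, m$hidden2),
      b2 = as.numeric(unlist(m$b2)),
      W3 = matrix(as.numeric(unlist(m$W3)), m$hidden2, 1L),
      b3 = as.numeric(m$b3),
      input_dim = as.integer(m$input_dim), hidden1 = as.integer(m$hidden1),
      hidden2 = as.integer(m$hidden2), seed = as.integer(m$seed)
    ), class = "siamese_params")
  })
  structure(list(members = members,
                 n_excluded = as.integer(ser$n_excluded),
                 excluded_compounds = as.character(unlist(ser$excluded_compounds)),
                 config = ser$config),
            class = "cotarget_ensemble")
}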