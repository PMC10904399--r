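#' Embedding matrix
#'
#' Per-gene real vectors for one modality (`"ontology"`, `"expression"`) or
#' their concatenation (`"concat"`, ordered [ontology, expression]).
#'
#' @param vectors numeric matrix, one row per gene, rownames = gene ids.
#' @param universe a `gene_universe` (row order must match).
#' @param modality one of `"ontology"`, `"expression"`, `"concat"`.
#' @param isolated optional logical flag per gene: zero vector carried for a
#'   gene with no edge membership in this modality.
#' @return Object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(vectors, universe, modality = c("ontology", "expression", "concat"),
                             isolated = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(universe, "gene_universe"), is.matrix(vectors))
  if (nrow(vectors) != length(universe$genes) ||
      !identical(rownames(vectors), universe$genes))
    stop("embedding rows must match the universe gene order")
  if (is.null(isolated)) isolated <- rep(FALSE, nrow(vectors))
  structure(list(vectors = vectors, universe = universe, modality = modality,
                 dim = ncol(vectors), isolated = isolated),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix [%s]: %d genes x %d dims\n",
              x$modality, nrow(x$vectors), x$dim))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

#' Contrastive negative-sampling loss for one anchor gene
#'
#' \eqn{-\sum_{v \in N(u)} \log \sigma(x_v \cdot x_u)
#'      -\sum_{z \in R(u)} \log \sigma(-x_z \cdot x_u)}.
#' Dot products are clamped to ±30 before the sigmoid for numerical
#' stability, so the loss is finite for finite embeddings.
#'
#' @param anchor gene id.
#' @param positives,negatives character vectors of sampled genes (multisets).
#' @param emb an `embedding_matrix`.
#' @return scalar loss.
#' @export
contrastive_loss <- function(anchor, positives, negatives, emb) {
  stopifnot(inherits(emb, "embedding_matrix"))
  all_g <- c(anchor, positives, negatives)
  unknown <- setdiff(all_g, rownames(emb$vectors))
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  xu <- emb$vectors[anchor, ]
  lp <- if (length(positives))
    sum(log(.sigmoid(emb$vectors[positives, , drop = FALSE] %*% xu))) else 0
  ln <- if (length(negatives))
    sum(log(.sigmoid(-(emb$vectors[negatives, , drop = FALSE] %*% xu)))) else 0
  -(lp + ln)
}

#' Train per-modality gene embeddings
#'
#' Learns an embedding of every non-isolated gene in the hypergraph so that
#' genes lying close under random walk with restart obtain similar vectors.
#' Each epoch resamples, per anchor gene, `n_pos` neighbors proportional to
#' the stationary distribution and `5 * n_pos` negatives inversely
#' proportional to it, and takes one Adam step on the negative-sampling
#' objective per anchor. Isolated genes keep a zero vector and are flagged.
#'
#' @param graph a weighted `functional_hypergraph`.
#' @param dim embedding dimension (default 256).
#' @param epochs training epochs (default 50).
#' @param n_pos positives per anchor per epoch (default 20).
#' @param restart_prob restart probability for the random walk (default 0.5).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param rwr_tol convergence threshold for the stationary matrix.
#' @param verbose print per-epoch mean loss.
#' @return An `embedding_matrix` with attribute `"loss_history"` (mean loss
#'   per epoch).
#' @export
train_embeddings <- function(graph, dim = 256L, epochs = 50L, n_pos = 20L,
                             restart_prob = 0.5, learning_rate = 1e-3,
                             seed = 1L, rwr_tol = 1e-6, verbose = FALSE) {
  stopifnot(inherits(graph, "functional_hypergraph"))
  active <- which(!graph$isolated)
  if (length(active) < 2L) stop("need at least 2 non-isolated genes to train")
  genes <- graph$universe$genes
  nV <- length(genes)

  model <- build_transition_matrix(graph, restart_prob = restart_prob)
  S <- stationary_matrix(model, tol = rwr_tol)

  set.seed(seed)
  X <- matrix(stats::rnorm(nV * dim, sd = 1 / sqrt(dim)), nV, dim,
              dimnames = list(genes, NULL))
  X[graph$isolated, ] <- 0
  # Adam state
  M <- matrix(0, nV, dim); Vv <- matrix(0, nV, dim)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  step <- 0L
  eps <- 1e-12
  loss_hist <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (ui in active) {
      s <- S[, ui]
      s[ui] <- 0
      s[graph$isolated] <- 0
      pos <- sample.int(nV, n_pos, replace = TRUE, prob = s + eps)
      wneg <- 1 / (s + eps)
      wneg[ui] <- 0; wneg[graph$isolated] <- 0
      neg <- sample.int(nV, 5L * n_pos, replace = TRUE, prob = wneg)

      xu <- X[ui, ]
      ctx <- c(pos, neg)
      sign_v <- c(rep(1, length(pos)), rep(-1, length(neg)))
      Xc <- X[ctx, , drop = FALSE]
      dots <- drop(Xc %*% xu)
      p <- .sigmoid(sign_v * dots)
      ep_loss <- ep_loss - sum(log(p))
      # d loss / d dot = -sign * (1 - sigma(sign * dot))
      g <- -sign_v * (1 - p)
      grad_u <- drop(crossprod(Xc, g))
      grad_ctx <- outer(g, xu)

      # accumulate sparse gradient into dense rows (anchor + contexts)
      rows <- c(ui, ctx)
      Gacc <- rbind(grad_u, grad_ctx)
      # duplicate context rows must sum: aggregate by row index
      agg <- rowsum(Gacc, group = rows)
      ridx <- as.integer(rownames(agg))

      step <- step + 1L
      M[ridx, ] <- beta1 * M[ridx, ] + (1 - beta1) * agg
      Vv[ridx, ] <- beta2 * Vv[ridx, ] + (1 - beta2) * agg^2
      mh <- M[ridx, , drop = FALSE] / (1 - beta1^step)
      vh <- Vv[ridx, , drop = FALSE] / (1 - beta2^step)
      X[ridx, ] <- X[ridx, , drop = FALSE] - learning_rate * mh / (sqrt(vh) + eps_adam)
    }
    loss_hist[ep] <- ep_loss / length(active)
    if (verbose) message(sprintf("epoch %d: mean loss %.4f", ep, loss_hist[ep]))
  }
  X[graph$isolated, ] <- 0
  modality <- if (graph$mode == "ontology") "ontology" else "expression"
  out <- embedding_matrix(X, graph$universe, modality, isolated = graph$isolated)
  attr(out, "loss_history") <- loss_hist
  out
}

#' Concatenate ontology and expression embeddings
#'
#' Joins the two per-modality embeddings gene-wise into a single
#' representation ordered [ontology, expression]. A gene isolated in one
#' modality contributes a zero block there and stays flagged.
#'
#' @param go_emb,expr_emb `embedding_matrix` objects over the same universe.
#' @return An `embedding_matrix` with `modality = "concat"` and attributes
#'   `"dim_go"`, `"dim_expr"` recording the block sizes.
#' @export
concat_modalities <- function(go_emb, expr_emb) {
  stopifnot(inherits(go_emb, "embedding_matrix"), inherits(expr_emb, "embedding_matrix"))
  if (!identical(go_emb$universe$genes, expr_emb$universe$genes)) {
    d1 <- setdiff(go_emb$universe$genes, expr_emb$universe$genes)
    d2 <- setdiff(expr_emb$universe$genes, go_emb$universe$genes)
    stop("universe mismatch; symmetric difference: ",
         paste(utils::head(c(d1, d2), 10L), collapse = ", "))
  }
  X <- cbind(go_emb$vectors, expr_emb$vectors)
  rownames(X) <- go_emb$universe$genes
  out <- embedding_matrix(X, go_emb$universe, "concat",
                          isolated = go_emb$isolated & expr_emb$isolated)
  attr(out, "dim_go") <- go_emb$dim
  attr(out, "dim_expr") <- expr_emb$dim
  attr(out, "isolated_go") <- go_emb$isolated
  attr(out, "isolated_expr") <- expr_emb$isolated
  out
}

#' Split a concatenated embedding back into its modality blocks
#'
#' @param emb a `"concat"` `embedding_matrix` produced by [concat_modalities()].
#' @return list with elements `ontology` and `expression`.
#' @export
split_modalities <- function(emb) {
  stopifnot(inherits(emb, "embedding_matrix"), emb$modality == "concat")
  d1 <- attr(emb, "dim_go"); d2 <- attr(emb, "dim_expr")
  if (is.null(d1) || is.null(d2)) stop("concat embedding lacks block size attributes")
  list(
    ontology = embedding_matrix(emb$vectors[, seq_len(d1), drop = FALSE],
                                emb$universe, "ontology",
                                isolated = attr(emb, "isolated_go")),
    expression = embedding_matrix(emb$vectors[, d1 + seq_len(d2), drop = FALSE],
                                  emb$universe, "expression",
                                  isolated = attr(emb, "isolated_expr"))
  )
}

#' Write / read an embedding table
#'
#' Tab-delimited: first column the gene id, then one column per dimension.
#' Round-trips to within 1e-8 (values written with full precision).
#'
#' @param emb an `embedding_matrix`.
#' @param path file path.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  df <- data.frame(gene = rownames(emb$vectors),
                   format(emb$vectors, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", paste0("d", seq_len(emb$dim)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @param modality modality label to attach on read.
#' @export
read_embedding <- function(path, modality = "ontology") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  mode(X) <- "numeric"
  rownames(X) <- df[[1]]
  uni <- gene_universe(df[[1]])
  embedding_matrix(X, uni, modality)
}
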