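#' Gene signature
#'
#' A perturbation-derived gene set plus its metadata: the perturbagen that
#' produced it, the perturbagen type, the cell line, and the Transcriptional
#' Activity Score (TAS) used to pick exemplar signatures.
#'
#' @param genes character vector of member genes (de-duplicated).
#' @param perturbagen_id,cell_line strings.
#' @param perturbagen_type one of `"compound"`, `"shRNA"`, `"cDNA"`.
#' @param tas non-negative Transcriptional Activity Score (metadata).
#' @param id optional signature id (defaults to perturbagen/cell-line).
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(genes, perturbagen_id, perturbagen_type = c("compound", "shRNA", "cDNA"),
                           cell_line = "NA", tas = 0, id = NULL) {
  perturbagen_type <- match.arg(perturbagen_type)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene signature is empty")
  if (is.na(tas) || tas < 0) stop("TAS must be a non-negative number")
  if (is.null(id)) id <- paste(perturbagen_id, cell_line, sep = ":")
  structure(list(genes = genes, perturbagen_id = perturbagen_id,
                 perturbagen_type = perturbagen_type, cell_line = cell_line,
                 tas = as.numeric(tas), id = id),
            class = "gene_signature")
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-normalize an embedding block; zero rows stay zero.
.unitize <- function(X) {
  n <- sqrt(rowSums(X^2))
  n[n == 0] <- 1
  X / n
}

#' Mean within-set embedding similarity of one gene
#'
#' \eqn{r_u = \frac{1}{|G|} \sum_{v \in G} \cos(x_u, x_v)}; the sum includes
#' \eqn{v = u}, so a singleton set gives \eqn{r_u = 1}. Cosine against a
#' zero-norm vector is defined as 0.
#'
#' @param gene a gene id in `genes`.
#' @param genes the signature's member genes (character vector).
#' @param emb a per-modality `embedding_matrix`.
#' @return scalar mean cosine.
#' @export
within_set_similarity <- function(gene, genes, emb) {
  stopifnot(inherits(emb, "embedding_matrix"))
  if (!gene %in% genes) stop("gene not in the signature")
  U <- .unitize(emb$vectors[genes, , drop = FALSE])
  mean(drop(U %*% U[match(gene, genes), ]))
}

#' Genome-background moments of a gene's cosine similarities
#'
#' Mean and standard deviation of \eqn{\cos(x_u, x_v)} over all genes
#' \eqn{v \ne u} in the universe, per modality. Computed exactly for every
#' gene in one matrix product and intended to be cached.
#'
#' @param emb a per-modality `embedding_matrix`.
#' @return data.frame with columns `gene`, `mean`, `sd`.
#' @export
background_moments <- function(emb) {
  stopifnot(inherits(emb, "embedding_matrix"))
  U <- .unitize(emb$vectors)
  n <- nrow(U)
  if (n < 3L) stop("universe too small for background moments (need >= 3 genes)")
  C <- U %*% t(U)
  # exclude the self-cosine from row moments
  m <- (rowSums(C) - diag(C)) / (n - 1)
  ss <- rowSums(C^2) - diag(C)^2
  v <- pmax(ss / (n - 1) - m^2, 0)
  data.frame(gene = rownames(U), mean = m, sd = sqrt(v * (n - 1) / (n - 2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Z-score a within-set similarity against the genome background
#'
#' \eqn{z = (r - \mu_u)/\sigma_u} with the moments of the gene's cosine to
#' all other genes in the universe. A zero background s.d. yields z = 0.
#'
#' @param gene gene id.
#' @param r within-set mean similarity from [within_set_similarity()].
#' @param emb per-modality `embedding_matrix` (used when `moments` missing).
#' @param moments optional cached result of [background_moments()].
#' @return scalar z.
#' @export
zscore_vs_genome <- function(gene, r, emb = NULL, moments = NULL) {
  if (is.null(moments)) moments <- background_moments(emb)
  row <- moments[moments$gene == gene, ]
  if (nrow(row) != 1L) stop("gene absent from background moments: ", gene)
  if (row$sd == 0) return(0)
  (r - row$mean) / row$sd
}

#' Per-gene aggregation weight
#'
#' \eqn{w_u = \min(\max(z^{GO}_u, z^{expr}_u, 0), 1)}: a gene whose
#' within-set similarity is not above genome background in either modality
#' gets weight 0; strong coherence saturates at 1.
#'
#' @param z_go,z_expr modality z-scores (may be `-Inf` for a missing block).
#' @return weight in [0, 1].
#' @export
gene_weight <- function(z_go, z_expr) {
  pmin(pmax(pmax(z_go, z_expr), 0), 1)
}

#' Aggregate a gene signature into its consensus embedding
#'
#' Computes, for every member gene, its within-set mean cosine in each
#' modality, z-scores those against the genome background, converts to
#' weights \eqn{w_u \in [0,1]}, and returns
#' \eqn{x_G = \frac{1}{|G|}\sum_u w_u x_u} over the concatenated embedding.
#' Genes absent from the universe are dropped (count recorded); a gene with
#' a zero block in one modality is scored by the other modality alone. If
#' every weight is zero the unweighted mean is used with a warning.
#'
#' @param sig a `gene_signature` (or plain character vector of genes).
#' @param emb a `"concat"` `embedding_matrix` from [concat_modalities()].
#' @param moments_go,moments_expr optional cached [background_moments()]
#'   for the two blocks.
#' @return Object of class `signature_vector`: `vector` (concat dim),
#'   `per_gene` ledger data.frame (gene, r_go, r_expr, z_go, z_expr, weight),
#'   `n_dropped`, `signature` metadata.
#' @export
aggregate_signature <- function(sig, emb, moments_go = NULL, moments_expr = NULL) {
  stopifnot(inherits(emb, "embedding_matrix"), emb$modality == "concat")
  if (is.character(sig)) sig <- gene_signature(sig, perturbagen_id = "adhoc")
  parts <- split_modalities(emb)
  genes <- intersect(sig$genes, emb$universe$genes)
  n_dropped <- length(sig$genes) - length(genes)
  if (!length(genes)) stop("no signature gene is present in the embedding universe")
  genes <- sort(genes)  # order-invariant aggregation

  if (is.null(moments_go)) moments_go <- background_moments(parts$ontology)
  if (is.null(moments_expr)) moments_expr <- background_moments(parts$expression)

  score_block <- function(block, moments, iso) {
    U <- .unitize(block$vectors[genes, , drop = FALSE])
    r <- rowMeans(U %*% t(U))
    mi <- match(genes, moments$gene)
    z <- ifelse(moments$sd[mi] == 0, 0, (r - moments$mean[mi]) / moments$sd[mi])
    z[iso[emb$universe$index[genes]]] <- -Inf  # missing modality: other one decides
    list(r = r, z = z)
  }
  go <- score_block(parts$ontology, moments_go, attr(emb, "isolated_go"))
  ex <- score_block(parts$expression, moments_expr, attr(emb, "isolated_expr"))

  w <- gene_weight(go$z, ex$z)
  X <- emb$vectors[genes, , drop = FALSE]
  if (all(w == 0)) {
    warning("all aggregation weights are zero; falling back to unweighted mean")
    vec <- colMeans(X)
  } else {
    vec <- drop(crossprod(X, w)) / length(genes)
  }
  structure(
    list(vector = vec,
         per_gene = data.frame(gene = genes, r_go = go$r, r_expr = ex$r,
                               z_go = go$z, z_expr = ex$z, weight = w,
                               row.names = NULL, stringsAsFactors = FALSE),
         n_dropped = n_dropped,
         signature = sig[c("perturbagen_id", "perturbagen_type", "cell_line", "tas", "id")]),
    class = "signature_vector"
  )
}

#' @export
print.signature_vector <- function(x, ...) {
  cat(sprintf("signature_vector: %s (%s, %s), %d genes (%d dropped), dim %d\n",
              x$signature$perturbagen_id, x$signature$perturbagen_type,
              x$signature$cell_line, nrow(x$per_gene), x$n_dropped,
              length(x$vector)))
  invisible(x)
}

#' Cosine similarity between two signature vectors
#'
#' Standard cosine in [-1, 1]; a zero vector yields 0.
#'
#' @param a,b `signature_vector` objects (or plain numeric vectors) of the
#'   same dimension.
#' @return scalar cosine.
#' @export
cosine_signature_similarity <- function(a, b) {
  va <- if (inherits(a, "signature_vector")) a$vector else a
  vb <- if (inherits(b, "signature_vector")) b$vector else b
  if (length(va) != length(vb)) stop("signature vectors differ in dimension")
  .cosine(va, vb)
}

#' Export a signature vector with its per-gene weight ledger
#'
#' Writes the aggregated vector as one tab-delimited row and the per-gene
#' weights as a `<path>.weights.tsv` sidecar.
#'
#' @param sv a `signature_vector`.
#' @param path output file path.
#' @export
write_signature_vector <- function(sv, path) {
  stopifnot(inherits(sv, "signature_vector"))
  vec <- data.frame(id = sv$signature$id, t(sv$vector))
  names(vec) <- c("id", paste0("d", seq_along(sv$vector)))
  utils::write.table(vec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sv$per_gene, paste0(path, ".weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
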