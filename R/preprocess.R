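#' Normalize a raw expression count matrix
#'
#' Applies the standard bulk-RNA-seq pipeline used to derive differential
#' gene sets: log2(x + 1) transformation, quantile normalization (all
#' columns mapped onto the pooled sorted-mean reference distribution, ties
#' averaged), then per-gene Z-scoring across samples. Genes constant across
#' samples get Z = 0 (count recorded in attribute `"n_constant"`).
#'
#' @param mat numeric genes x samples matrix of non-negative counts.
#' @return Z-scored matrix of the same shape with attribute `"stage"` set to
#'   `"zscored"`.
#' @export
preprocess_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (any(mat < 0)) stop("raw counts must be non-negative")
  lg <- log2(mat + 1)
  qn <- limma::normalizeQuantiles(lg, ties = TRUE)
  mu <- rowMeans(qn)
  sd <- apply(qn, 1L, stats::sd)
  constant <- sd == 0 | is.na(sd)
  sd[constant] <- 1
  z <- (qn - mu) / sd
  z[constant, ] <- 0
  dimnames(z) <- dimnames(mat)
  attr(z, "stage") <- "zscored"
  attr(z, "n_constant") <- sum(constant)
  z
}

#' Differential gene sets from one sample's Z-scores
#'
#' Up-regulated genes are those ranked in the top `rank_cut` by Z and with
#' Z >= `z_cut`; down-regulated genes are the bottom `rank_cut` with
#' Z <= -`z_cut`. Both the rank and the magnitude condition must hold, so
#' either set may be smaller than the rank cut (or empty). Rank ties are
#' broken stably by gene id.
#'
#' @param sample_z named numeric vector of per-gene Z-scores for one sample.
#' @param rank_cut rank threshold (default 100).
#' @param z_cut magnitude threshold (default 2).
#' @return list with character vectors `up` and `down`.
#' @export
differential_gene_set <- function(sample_z, rank_cut = 100L, z_cut = 2) {
  if (is.null(names(sample_z))) stop("sample_z must be named by gene")
  ord_up <- order(-sample_z, names(sample_z))
  ord_dn <- order(sample_z, names(sample_z))
  top <- names(sample_z)[utils::head(ord_up, rank_cut)]
  bot <- names(sample_z)[utils::head(ord_dn, rank_cut)]
  list(up = top[sample_z[top] >= z_cut],
       down = bot[sample_z[bot] <= -z_cut])
}

#' Select exemplar signatures by Transcriptional Activity Score
#'
#' Keeps, for every (perturbagen, cell line) group, the single signature
#' with the highest TAS; ties are broken by signature id.
#'
#' @param signatures list of `gene_signature` objects (TAS required on all).
#' @return filtered list, one exemplar per group.
#' @export
exemplar_by_tas <- function(signatures) {
  stopifnot(all(vapply(signatures, inherits, TRUE, "gene_signature")))
  tas <- vapply(signatures, `[[`, 0, "tas")
  if (anyNA(tas)) {
    bad <- which(is.na(tas))[1L]
    stop("missing TAS on signature: ", signatures[[bad]]$id)
  }
  key <- vapply(signatures, function(s) paste(s$perturbagen_id, s$cell_line, sep = "\r"), "")
  ids <- vapply(signatures, `[[`, "", "id")
  keep <- unlist(lapply(split(seq_along(signatures), key), function(idx) {
    idx[order(-tas[idx], ids[idx])][1L]
  }), use.names = FALSE)
  signatures[sort(keep)]
}
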