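#' Simulate a foreground/foreground/background signature triplet
#'
#' For a pathway gene set `W`, draws two independent 100-gene foreground
#' sets, each seeded with `lambda` genes sampled from `W` plus
#' `set_size - lambda` genes sampled outside `W`, and a 100-gene background
#' set disjoint from `W`. All draws are without replacement within a set;
#' the two foreground sets are independent and may overlap by chance.
#'
#' @param pathway character vector `W` of pathway genes.
#' @param lambda number of pathway genes planted per foreground set.
#' @param universe a `gene_universe` (or character vector).
#' @param seed integer seed.
#' @param set_size simulated signature size (default 100).
#' @return list with `S_fg`, `S_fg2`, `S_bg`, `lambda`, `seed`.
#' @export
simulate_signature_triplet <- function(pathway, lambda, universe, seed = 1L,
                                       set_size = 100L) {
  genes <- if (inherits(universe, "gene_universe")) universe$genes else as.character(universe)
  pathway <- intersect(pathway, genes)
  if (lambda < 0 || lambda > min(set_size, length(pathway)))
    stop("lambda must be between 0 and min(set_size, |pathway|)")
  outside <- setdiff(genes, pathway)
  if (length(outside) < set_size)
    stop("universe must contain at least ", set_size, " genes outside the pathway")
  set.seed(seed)
  draw_fg <- function() c(if (lambda > 0) sample(pathway, lambda) else character(),
                          sample(outside, set_size - lambda))
  list(S_fg = draw_fg(), S_fg2 = draw_fg(), S_bg = sample(outside, set_size),
       lambda = lambda, seed = seed)
}

#' Identity-overlap similarity by one-sided Fisher's exact test
#'
#' \eqn{-\log_{10}} of the one-sided (over-enrichment) Fisher's exact
#' p-value for the 2x2 overlap table of two gene sets, computed on the log
#' scale via the hypergeometric tail so extreme significance does not
#' underflow.
#'
#' @param A,B gene sets (character vectors).
#' @param universe_size size of the gene universe.
#' @return similarity score \eqn{\ge 0}.
#' @export
fisher_similarity <- function(A, B, universe_size) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) stop("gene sets must be non-empty")
  if (length(A) > universe_size || length(B) > universe_size)
    stop("set larger than the universe")
  k <- length(intersect(A, B))
  logp <- stats::phyper(k - 1, length(A), universe_size - length(A), length(B),
                        lower.tail = FALSE, log.p = TRUE)
  max(-logp / log(10), 0)
}

#' Paired one-sided Wilcoxon signed-rank separation score
#'
#' \eqn{-\log_{10}(p)} for the alternative that foreground-foreground
#' similarities exceed their paired foreground-background similarities.
#' Zero differences are dropped before ranking; the exact null distribution
#' is used for n <= 25 tie-free differences, the normal approximation with
#' continuity correction otherwise. If every difference is zero, p = 1 by
#' convention.
#'
#' @param fg_fg_scores,fg_bg_scores paired similarity scores (equal length,
#'   n >= 5).
#' @return separation score \eqn{\ge 0}.
#' @export
separation_score <- function(fg_fg_scores, fg_bg_scores) {
  if (length(fg_fg_scores) != length(fg_bg_scores))
    stop("paired score lists must have equal length")
  if (length(fg_fg_scores) < 5L) stop("need at least 5 pairs")
  d <- fg_fg_scores - fg_bg_scores
  d <- d[d != 0]
  if (!length(d)) return(0)
  use_exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", mu = 0,
                       exact = use_exact, correct = TRUE)$p.value
  )
  max(-log10(p), 0)
}

#' Run the signature-similarity sensitivity benchmark
#'
#' For every pathway and signal level `lambda`, repeats the triplet
#' simulation `n_reps` times, scores each triplet with every requested
#' method, and summarizes the paired foreground-foreground versus
#' foreground-background scores by the one-sided Wilcoxon signed-rank
#' separation. Methods: `"embedding"` (cosine of aggregated signature
#' vectors) and `"fisher"` (identity overlap).
#'
#' @param pathways named list of pathway gene sets.
#' @param emb a `"concat"` `embedding_matrix` over the benchmark universe
#'   (required for the embedding method).
#' @param lambda_values signal levels (default c(5, 10, 15, 20)).
#' @param n_reps simulations per (pathway, lambda) (default 200).
#' @param methods subset of c("embedding", "fisher").
#' @param seed integer seed.
#' @param set_size simulated signature size (default 100).
#' @param size_range eligible pathway size range (default c(50, 200));
#'   pathways outside it are skipped.
#' @return data.frame (pathway, lambda, method, n_reps, separation).
#' @export
run_benchmark_grid <- function(pathways, emb = NULL,
                               lambda_values = c(5L, 10L, 15L, 20L),
                               n_reps = 200L,
                               methods = c("embedding", "fisher"),
                               seed = 1L, set_size = 100L,
                               size_range = c(50L, 200L)) {
  methods <- match.arg(methods, several.ok = TRUE)
  sizes <- lengths(pathways)
  pathways <- pathways[sizes >= size_range[1L] & sizes <= size_range[2L]]
  if (!length(pathways)) stop("no eligible pathways supplied")
  if ("embedding" %in% methods && is.null(emb))
    stop("embedding method requires an embedding matrix")
  universe <- if (!is.null(emb)) emb$universe else
    gene_universe(unique(unlist(pathways)))
  if ("embedding" %in% methods) {
    parts <- split_modalities(emb)
    mom_go <- background_moments(parts$ontology)
    mom_ex <- background_moments(parts$expression)
  }
  agg_cache <- new.env(parent = emptyenv())
  agg_vec <- function(genes) {
    key <- paste(genes, collapse = "|")
    if (!is.null(agg_cache[[key]])) return(agg_cache[[key]])
    v <- suppressWarnings(
      aggregate_signature(genes, emb, moments_go = mom_go, moments_expr = mom_ex)$vector)
    agg_cache[[key]] <- v
    v
  }

  out <- list()
  for (pi in seq_along(pathways)) {
    W <- pathways[[pi]]
    pname <- names(pathways)[pi]
    for (lam in lambda_values) {
      scores <- lapply(methods, function(m) list(ff = numeric(n_reps), fb = numeric(n_reps)))
      names(scores) <- methods
      for (rep_i in seq_len(n_reps)) {
        tri <- simulate_signature_triplet(
          W, lam, universe,
          seed = seed + 7919L * pi + 911L * match(lam, lambda_values) + rep_i,
          set_size = set_size)
        if ("embedding" %in% methods) {
          v_fg <- agg_vec(tri$S_fg); v_fg2 <- agg_vec(tri$S_fg2); v_bg <- agg_vec(tri$S_bg)
          scores$embedding$ff[rep_i] <- .cosine(v_fg, v_fg2)
          scores$embedding$fb[rep_i] <- .cosine(v_fg, v_bg)
        }
        if ("fisher" %in% methods) {
          N <- length(universe$genes)
          scores$fisher$ff[rep_i] <- fisher_similarity(tri$S_fg, tri$S_fg2, N)
          scores$fisher$fb[rep_i] <- fisher_similarity(tri$S_fg, tri$S_bg, N)
        }
      }
      for (m in methods) {
        out[[length(out) + 1L]] <- data.frame(
          pathway = pname, lambda = lam, method = m, n_reps = n_reps,
          separation = separation_score(scores[[m]]$ff, scores[[m]]$fb),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Tail probability of the overlap of two random pathway subsamples
#'
#' Exact \eqn{P(X \ge k)} where X is the overlap between two independent
#' draws of `draw_size` genes (without replacement) from the same
#' `pathway_size`-gene pathway: X ~ Hypergeometric(pathway_size, draw_size,
#' draw_size).
#'
#' @param pathway_size number of genes in the pathway (K).
#' @param draw_size genes sampled per draw (n).
#' @param universe_size total genes (validated bound, K <= N).
#' @param min_overlap threshold k.
#' @return exact tail probability.
#' @export
random_overlap_tail <- function(pathway_size, draw_size, universe_size, min_overlap) {
  if (min_overlap < 0 || draw_size > pathway_size || pathway_size > universe_size)
    stop("require 0 <= k <= n <= K <= N")
  if (min_overlap > draw_size) return(0)
  if (min_overlap == 0) return(1)
  stats::phyper(min_overlap - 1, draw_size, pathway_size - draw_size, draw_size,
                lower.tail = FALSE)
}

#' Z-score for 1-nearest-neighbor label enrichment
#'
#' \eqn{(\mu - \mu_0)/\delta}: observed mean fraction of 1-NNs sharing the
#' label, its chance expectation, and the standard error of the mean.
#'
#' @param mu observed mean 1-NN agreement.
#' @param mu0 chance agreement (label prevalence).
#' @param delta standard error of `mu` (> 0).
#' @return scalar Z-score.
#' @export
knn_label_zscore <- function(mu, mu0, delta) {
  if (delta <= 0) stop("delta must be positive")
  (mu - mu0) / delta
}

#' Standard error of a confirmation rate
#'
#' Binomial standard error \eqn{\sqrt{R_c (1 - R_c)/n}}.
#'
#' @param rate confirmation rate in [0, 1].
#' @param n sample size (>= 1).
#' @return scalar standard error.
#' @export
confirmation_rate_se <- function(rate, n) {
  stopifnot(rate >= 0, rate <= 1, n >= 1)
  sqrt(rate * (1 - rate) / n)
}

#' Fold enrichment of confirmation between predicted and negative arms
#'
#' Ratio of confirmation rates between the predicted and negative arms,
#' with a one-sided chi-square p-value on the 2x2 table (Pearson statistic
#' without continuity correction, halved in the enrichment direction).
#'
#' @param confirmed_pred,total_pred confirmed / tested counts, predicted arm.
#' @param confirmed_neg,total_neg confirmed / tested counts, negative arm.
#' @return list with `fold` (Inf flagged when the negative arm has zero
#'   confirmations), `p`, and the two `rate`s.
#' @export
fold_enrichment <- function(confirmed_pred, total_pred, confirmed_neg, total_neg) {
  if (total_pred < 1 || total_neg < 1) stop("totals must be >= 1")
  if (confirmed_pred > total_pred || confirmed_neg > total_neg)
    stop("confirmed counts cannot exceed totals")
  rate_pred <- confirmed_pred / total_pred
  rate_neg <- confirmed_neg / total_neg
  fold <- if (confirmed_neg == 0) Inf else rate_pred / rate_neg
  tab <- matrix(c(confirmed_pred, total_pred - confirmed_pred,
                  confirmed_neg, total_neg - confirmed_neg), 2L, byrow = TRUE)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p <- if (rate_pred >= rate_neg) chi$p.value / 2 else 1 - chi$p.value / 2
  list(fold = fold, p = p, rate_pred = rate_pred, rate_neg = rate_neg,
       infinite_fold = is.infinite(fold))
}
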