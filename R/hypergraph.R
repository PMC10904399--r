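#' Gene universe
#'
#' An ordered collection of unique gene identifiers with a gene <-> position
#' index. All hypergraphs, embeddings and signatures in the package are
#' expressed against a universe.
#'
#' @param genes character vector of gene identifiers.
#' @return An object of class `gene_universe` with elements `genes` and
#'   `index` (named integer vector mapping gene id to position).
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("universe must contain at least one gene")
  if (anyNA(genes) || any(!nzchar(genes))) stop("gene identifiers must be non-empty")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  structure(
    list(genes = genes, index = stats::setNames(seq_along(genes), genes)),
    class = "gene_universe"
  )
}

#' @export
length.gene_universe <- function(x) length(x$genes)

#' @export
print.gene_universe <- function(x, ...) {
  cat("gene_universe with", length(x$genes), "genes\n")
  invisible(x)
}

#' Hyperedge collection
#'
#' Builds a collection of hyperedges, one per annotation term or per
#' expression-derived gene set. In ontology mode an edge may declare child
#' edges (term hierarchy); in expression mode `children` is empty.
#'
#' @param members named list; each element a character vector of member gene
#'   ids, names are edge ids.
#' @param children optional named list of character vectors of child edge ids;
#'   names must be edge ids present in `members`.
#' @param weights optional numeric vector of non-negative edge weights.
#' @return An object of class `hyperedge_set`: a list with `ids`, `members`,
#'   `children`, `weights`.
#' @export
hyperedge_set <- function(members, children = NULL, weights = NULL) {
  if (length(members) == 0L) stop("edge collection is empty")
  ids <- names(members)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("edge ids must be unique non-empty names of `members`")
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(vapply(members, length, 1L) == 0L))
    stop("every hyperedge must have at least one member gene")
  if (is.null(children)) children <- stats::setNames(vector("list", length(ids)), ids)
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (id in names(children)) {
    if (!id %in% ids) stop("children declared for unknown edge: ", id)
    kk <- as.character(children[[id]])
    if (!all(kk %in% ids))
      stop("unknown child edge ids for ", id, ": ",
           paste(setdiff(kk, ids), collapse = ", "))
    kids[[id]] <- kk
  }
  .check_acyclic(ids, kids)
  if (!is.null(weights)) {
    if (length(weights) != length(ids)) stop("one weight per edge required")
    if (any(weights < 0)) stop("edge weights must be non-negative")
    weights <- stats::setNames(as.numeric(weights), ids)
  }
  structure(list(ids = ids, members = members, children = kids, weights = weights),
            class = "hyperedge_set")
}

#' @export
length.hyperedge_set <- function(x) length(x$ids)

# DFS cycle check over the child relation; errors naming one cycle.
.check_acyclic <- function(ids, children) {
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 on stack, 2 done
  visit <- function(id, path) {
    if (state[[id]] == 1L) {
      cyc <- c(path[which(path == id)[1L]:length(path)], id)
      stop("cycle detected in edge hierarchy: ", paste(cyc, collapse = " -> "))
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (k in children[[id]]) visit(k, c(path, id))
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id, character())
  invisible(TRUE)
}

# All descendants of each edge present in the collection, plus the edge itself.
.descendant_closure <- function(edges) {
  memo <- stats::setNames(vector("list", length(edges$ids)), edges$ids)
  desc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    out <- id
    for (k in edges$children[[id]]) out <- c(out, desc(k))
    out <- unique(out)
    memo[[id]] <<- out
    out
  }
  for (id in edges$ids) desc(id)
  memo
}

#' Information-content weights for ontology hyperedges
#'
#' Assigns each edge the information content of its annotation term:
#' \eqn{w(e) = -\log_2 \big(\sum_{c \in C(e)} |c| \; / \; \sum_{e'} |e'|\big)},
#' where \eqn{C(e)} is the set of descendants of \eqn{e} present in the
#' collection plus \eqn{e} itself. Rarer, more specific terms receive larger
#' weights; a term whose descendant mass equals the total mass (a root)
#' receives weight 0.
#'
#' @param edges a `hyperedge_set` (children allowed).
#' @return The same `hyperedge_set` with `weights` filled in (bits).
#' @export
ic_weight_ontology <- function(edges) {
  stopifnot(inherits(edges, "hyperedge_set"))
  sizes <- vapply(edges$members, length, 1L)
  total <- sum(sizes)
  closure <- .descendant_closure(edges)
  w <- vapply(edges$ids, function(id) {
    mass <- sum(sizes[closure[[id]]])
    -log2(mass / total)
  }, numeric(1))
  w <- pmax(w, 0)  # guard tiny negative rounding at the root
  edges$weights <- stats::setNames(w, edges$ids)
  edges
}

#' Size-based weights for expression hyperedges
#'
#' Assigns each expression-derived gene set the weight
#' \eqn{w(e) = -\log_2(|e| / \sum_{e'} |e'|)}: smaller, more specific
#' differential gene sets receive larger weights.
#'
#' @param edges a `hyperedge_set` with no child relations.
#' @return The same `hyperedge_set` with `weights` filled in (bits).
#' @export
size_weight_expression <- function(edges) {
  stopifnot(inherits(edges, "hyperedge_set"))
  if (any(vapply(edges$children, length, 1L) > 0L))
    stop("expression-mode edges must not declare children")
  sizes <- vapply(edges$members, length, 1L)
  edges$weights <- stats::setNames(-log2(sizes / sum(sizes)), edges$ids)
  edges
}

#' Functional hypergraph
#'
#' Couples a gene universe with a weighted hyperedge collection. Genes that
#' belong to no edge are carried but flagged `isolated`; they take no part in
#' random walks or neighbor sampling.
#'
#' @param universe a `gene_universe`.
#' @param edges a weighted `hyperedge_set`; all members must be in `universe`.
#' @param mode `"ontology"` or `"expression"`.
#' @return Object of class `functional_hypergraph` with the incidence encoded
#'   as per-edge member index vectors, per-gene degree `d(u) = sum_{e ∋ u} w(e)`
#'   and the logical `isolated` flag.
#' @export
functional_hypergraph <- function(universe, edges, mode = c("ontology", "expression")) {
  mode <- match.arg(mode)
  stopifnot(inherits(universe, "gene_universe"), inherits(edges, "hyperedge_set"))
  if (is.null(edges$weights)) stop("edge weights not assigned; run ic_weight_ontology() or size_weight_expression()")
  unknown <- setdiff(unique(unlist(edges$members)), universe$genes)
  if (length(unknown))
    stop("edge members outside the universe: ", paste(utils::head(unknown, 5L), collapse = ", "))
  nV <- length(universe$genes)
  member_idx <- lapply(edges$members, function(m) unname(universe$index[m]))
  degree <- numeric(nV)
  for (j in seq_along(member_idx))
    degree[member_idx[[j]]] <- degree[member_idx[[j]]] + edges$weights[[j]]
  isolated <- rep(TRUE, nV)
  isolated[unique(unlist(member_idx))] <- FALSE
  structure(
    list(universe = universe, edges = edges, mode = mode,
         member_idx = member_idx, degree = degree, isolated = isolated),
    class = "functional_hypergraph"
  )
}

#' @export
print.functional_hypergraph <- function(x, ...) {
  cat(sprintf("functional_hypergraph (%s): %d genes (%d isolated), %d hyperedges\n",
              x$mode, length(x$universe$genes), sum(x$isolated), length(x$edges$ids)))
  invisible(x)
}

#' Random-walk transition matrix of a hypergraph
#'
#' Computes the transition probability matrix
#' \eqn{B(u,v) = \sum_e w(e) \frac{H(u,e)}{d(u)} \frac{H(v,e)}{|e|}}:
#' from gene \eqn{u}, pick an incident edge with probability proportional to
#' its weight, then a member of that edge uniformly. Rows over non-isolated
#' genes sum to one; self-transitions are permitted.
#'
#' @param graph a `functional_hypergraph`.
#' @param restart_prob restart probability \eqn{q \in (0, 1]} carried on the
#'   model for downstream random walks (default 0.5).
#' @return Object of class `transition_model` with fields `matrix` (dense
#'   |V| x |V|), `restart_prob`, `universe`, `isolated`.
#' @export
build_transition_matrix <- function(graph, restart_prob = 0.5) {
  stopifnot(inherits(graph, "functional_hypergraph"))
  if (restart_prob <= 0 || restart_prob > 1) stop("restart_prob must be in (0, 1]")
  nV <- length(graph$universe$genes)
  zero_deg <- which(graph$degree == 0 & !graph$isolated)
  if (length(zero_deg))
    stop("gene with zero degree outside the isolated set: ",
         graph$universe$genes[zero_deg[1L]])
  B <- matrix(0, nV, nV, dimnames = list(graph$universe$genes, graph$universe$genes))
  w <- graph$edges$weights
  for (j in seq_along(graph$member_idx)) {
    idx <- graph$member_idx[[j]]
    if (w[[j]] == 0) next
    # contribution w(e)/(d(u) |e|) for every (u, v) in e x e
    contrib <- w[[j]] / (graph$degree[idx] * length(idx))
    B[idx, idx] <- B[idx, idx] + contrib  # contrib recycles down columns = rows u
  }
  structure(list(matrix = B, restart_prob = restart_prob,
                 universe = graph$universe, isolated = graph$isolated),
            class = "transition_model")
}

#' Random walk with restart from one source gene
#'
#' Iterates the restart recursion until successive distributions differ by
#' less than `tol` (2-norm per source; the all-sources variant
#' [stationary_matrix()] uses the Frobenius norm of the matrix difference).
#' Probability mass flows along the row-stochastic transition matrix, so
#' every iterate is itself a probability distribution.
#'
#' @param model a `transition_model`.
#' @param source a gene id in the universe.
#' @param tol convergence threshold (default 1e-6).
#' @param max_iter iteration cap; reaching it without convergence is an error
#'   carrying the last residual.
#' @return Object of class `stationary_profile`: `source`, `distribution`
#'   (named, sums to one), `iterations`, `converged`.
#' @export
random_walk_restart <- function(model, source, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(model, "transition_model"))
  if (tol <= 0) stop("tol must be positive")
  i <- model$universe$index[source]
  if (is.na(i)) stop("unknown source gene: ", source)
  if (model$isolated[i]) {
    a <- numeric(length(model$universe$genes)); a[i] <- 1
    names(a) <- model$universe$genes
    return(structure(list(source = source, distribution = a,
                          iterations = 0L, converged = TRUE),
                     class = "stationary_profile"))
  }
  q <- model$restart_prob
  tB <- t(model$matrix)
  a <- numeric(nrow(tB)); a[i] <- 1
  s <- a
  for (it in seq_len(max_iter)) {
    s_new <- (1 - q) * drop(tB %*% s) + q * a
    res <- sqrt(sum((s_new - s)^2))
    s <- s_new
    if (res < tol) {
      names(s) <- model$universe$genes
      return(structure(list(source = source, distribution = s,
                            iterations = it, converged = TRUE),
                       class = "stationary_profile"))
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (last residual %.3g)",
               max_iter, res))
}

#' Stationary distribution matrix for all sources
#'
#' Runs the restart recursion simultaneously for every gene as source and
#' stops when the Frobenius norm of successive matrix differences drops below
#' `tol`. Column `u` is the stationary distribution of the walk restarted at
#' gene `u`; isolated genes keep their point-mass start.
#'
#' @inheritParams random_walk_restart
#' @return |V| x |V| matrix, columns indexed by source gene.
#' @export
stationary_matrix <- function(model, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(model, "transition_model"))
  q <- model$restart_prob
  tB <- t(model$matrix)
  nV <- nrow(tB)
  S <- diag(nV)
  iso <- model$isolated
  for (it in seq_len(max_iter)) {
    S_new <- (1 - q) * (tB %*% S) + q * diag(nV)
    if (any(iso)) S_new[, iso] <- S[, iso]  # isolated sources stay put
    res <- sqrt(sum((S_new - S)^2))
    S <- S_new
    if (res < tol) {
      dimnames(S) <- list(model$universe$genes, model$universe$genes)
      return(S)
    }
  }
  stop(sprintf("stationary matrix did not converge in %d iterations (last residual %.3g)",
               max_iter, res))
}

#' Closed-form stationary distribution
#'
#' Dense solve of \eqn{s = q (I - (1-q) B^\top)^{-1} a_u}; used as the
#' reference solution on small graphs.
#'
#' @inheritParams random_walk_restart
#' @return named numeric vector summing to one.
#' @export
stationary_closed_form <- function(model, source) {
  stopifnot(inherits(model, "transition_model"))
  i <- model$universe$index[source]
  if (is.na(i)) stop("unknown source gene: ", source)
  q <- model$restart_prob
  nV <- nrow(model$matrix)
  a <- numeric(nV); a[i] <- 1
  s <- drop(q * solve(diag(nV) - (1 - q) * t(model$matrix), a))
  names(s) <- model$universe$genes
  s
}

#' Sample positive and negative training genes for a source
#'
#' Draws `n_pos` neighbor genes with probability proportional to the
#' stationary distribution over genes other than the source, and
#' `5 * n_pos` negatives with probability inversely proportional to it
#' (weight \eqn{1/(s + \epsilon)}). Sampling is with replacement; isolated
#' genes never appear in either set.
#'
#' @param profile a `stationary_profile`.
#' @param n_pos number of positives (negatives are `5 * n_pos`).
#' @param isolated optional logical vector flagging isolated genes to exclude.
#' @param eps stabilizer for the inverse-probability weight (default 1e-12).
#' @return list with character vectors `positives` and `negatives`.
#' @export
sample_neighbors <- function(profile, n_pos, isolated = NULL, eps = 1e-12) {
  stopifnot(inherits(profile, "stationary_profile"), n_pos >= 1)
  s <- profile$distribution
  keep <- names(s) != profile$source
  if (!is.null(isolated)) keep <- keep & !isolated
  s <- s[keep]
  if (!length(s)) stop("no eligible genes to sample from")
  pos <- sample(names(s), n_pos, replace = TRUE, prob = s + eps)
  neg <- sample(names(s), 5L * n_pos, replace = TRUE, prob = 1 / (s + eps))
  list(positives = pos, negatives = neg)
}
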