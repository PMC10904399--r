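#' Specification for synthetic fixtures
#'
#' Collects the sizes, noise level and seed that the fixture generators use
#' to emit synthetic instances of every input the pipeline consumes: an
#' annotation hierarchy with planted functional clusters, and a compound /
#' shRNA / cDNA signature collection with planted co-targeting structure.
#'
#' @param n_genes universe size.
#' @param n_pathways number of planted functional modules.
#' @param pathway_size_range integer length-2 vector, module sizes drawn
#'   uniformly within it.
#' @param n_compounds,n_targets counts for the co-targeting fixture.
#' @param cotarget_effect module genes planted per signature (signal
#'   strength; 0 gives a null fixture).
#' @param signature_size genes per synthetic signature.
#' @param n_cell_lines cell lines per perturbagen.
#' @param max_targets_per_compound annotation cap (mirrors the training
#'   filter; default 5).
#' @param seed mandatory integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2400L, n_pathways = 20L,
                         pathway_size_range = c(50L, 50L),
                         n_compounds = 48L, n_targets = 40L,
                         cotarget_effect = 15L, signature_size = 30L,
                         n_cell_lines = 2L, max_targets_per_compound = 5L,
                         seed = 1L) {
  stopifnot(n_genes >= 1, n_pathways >= 1, n_compounds >= 1, n_targets >= 1,
            length(pathway_size_range) == 2L,
            pathway_size_range[1L] <= pathway_size_range[2L],
            !is.null(seed))
  if (cotarget_effect > pathway_size_range[1L])
    stop("cotarget_effect cannot exceed the smallest pathway size")
  structure(list(n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_compounds = as.integer(n_compounds), n_targets = as.integer(n_targets),
                 cotarget_effect = as.integer(cotarget_effect),
                 signature_size = as.integer(signature_size),
                 n_cell_lines = as.integer(n_cell_lines),
                 max_targets_per_compound = as.integer(max_targets_per_compound),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.fixture_genes <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic ontology fixture
#'
#' Draws `n_pathways` leaf terms with disjoint member modules (sizes uniform
#' in `pathway_size_range`), groups them pairwise under parent terms whose
#' members are the union of their children, and adds a root term covering
#' all annotated genes. The result is a DAG with nested membership and
#' planted functional clusters, deterministic for a given seed.
#'
#' @param spec a `fixture_spec`.
#' @return list with `universe` (`gene_universe`), `sets` (named member
#'   list), `hierarchy` (data.frame child/parent), `modules` (the planted
#'   leaf modules).
#' @export
generate_ontology_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- .fixture_genes(spec$n_genes)
  size_range <- seq.int(spec$pathway_size_range[1L], spec$pathway_size_range[2L])
  sizes <- size_range[sample.int(length(size_range), spec$n_pathways, replace = TRUE)]
  if (sum(sizes) > spec$n_genes)
    stop("infeasible nesting: module sizes exceed the universe")
  pool <- sample(genes)
  modules <- list()
  off <- 0L
  for (i in seq_len(spec$n_pathways)) {
    modules[[sprintf("leaf%02d", i)]] <- sort(pool[off + seq_len(sizes[i])])
    off <- off + sizes[i]
  }
  sets <- modules
  hierarchy <- data.frame(child = character(), parent = character(),
                          stringsAsFactors = FALSE)
  if (spec$n_pathways >= 2L) {
    grp <- ceiling(seq_len(spec$n_pathways) / 2)
    top_level <- character()
    for (g in unique(grp)) {
      kids <- names(modules)[grp == g]
      if (length(kids) < 2L) { top_level <- c(top_level, kids); next }
      pid <- sprintf("branch%02d", g)
      sets[[pid]] <- sort(unique(unlist(modules[kids])))
      hierarchy <- rbind(hierarchy, data.frame(child = kids, parent = pid,
                                               stringsAsFactors = FALSE))
      top_level <- c(top_level, pid)
    }
    root_kids <- top_level
    sets[["root"]] <- sort(unique(unlist(sets[root_kids])))
    hierarchy <- rbind(hierarchy, data.frame(child = root_kids, parent = "root",
                                             stringsAsFactors = FALSE))
  }
  list(universe = gene_universe(genes), sets = sets, hierarchy = hierarchy,
       modules = modules)
}

#' Generate a synthetic co-targeting fixture
#'
#' Emulates an L1000-style signature collection with planted ground truth:
#' each target gene belongs to a functional module; its shRNA and cDNA
#' signatures draw `cotarget_effect` genes from the module plus random
#' noise genes, and every compound annotated to that target draws its
#' signatures the same way, so annotated pairs share module-coherent genes
#' at a configurable strength. With `cotarget_effect = 0` co-targeting
#' pairs are indistinguishable from random pairs.
#'
#' @param spec a `fixture_spec`.
#' @param modules named list of planted modules (defaults to the modules of
#'   [generate_ontology_fixture()] run on `spec`).
#' @return list with `signatures` (list of `gene_signature`), `annotations`
#'   (data.frame compound_id/target_gene), `target_module` (named vector),
#'   `universe`, `cell_lines`.
#' @export
generate_cotarget_fixture <- function(spec, modules = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(modules)) modules <- generate_ontology_fixture(spec)$modules
  set.seed(spec$seed + 1L)
  genes <- .fixture_genes(spec$n_genes)
  cell_lines <- sprintf("CL%d", seq_len(spec$n_cell_lines))
  targets <- sprintf("T%03d", seq_len(spec$n_targets))
  target_module <- stats::setNames(
    sample(names(modules), spec$n_targets, replace = TRUE), targets)
  compounds <- sprintf("cpd%03d", seq_len(spec$n_compounds))
  annotations <- data.frame(
    compound_id = compounds,
    target_gene = sample(targets, spec$n_compounds, replace = TRUE),
    stringsAsFactors = FALSE)
  # enforce the annotation cap (holds trivially for 1 target per compound)
  cnt <- table(annotations$compound_id)
  stopifnot(all(cnt <= spec$max_targets_per_compound))

  draw_sig <- function(module_name) {
    mod <- modules[[module_name]]
    k <- min(spec$cotarget_effect, length(mod), spec$signature_size)
    core <- if (k > 0) sample(mod, k) else character()
    noise <- sample(setdiff(genes, core), spec$signature_size - k)
    c(core, noise)
  }
  sigs <- list()
  for (tg in targets) {
    for (cl in cell_lines) {
      for (ty in c("shRNA", "cDNA")) {
        sigs[[length(sigs) + 1L]] <- gene_signature(
          draw_sig(target_module[[tg]]), tg, ty, cl,
          tas = stats::runif(1, 0.3, 1))
      }
    }
  }
  for (i in seq_len(nrow(annotations))) {
    cp <- annotations$compound_id[i]
    mod <- target_module[[annotations$target_gene[i]]]
    for (cl in cell_lines) {
      sigs[[length(sigs) + 1L]] <- gene_signature(
        draw_sig(mod), cp, "compound", cl, tas = stats::runif(1, 0.3, 1))
    }
  }
  list(signatures = sigs, annotations = annotations,
       target_module = target_module, universe = gene_universe(genes),
       cell_lines = cell_lines)
}

#' Train benchmark embeddings on a fixture hypergraph
#'
#' Convenience wrapper used by the benchmark and the end-to-end tests:
#' builds ontology- and expression-weighted hypergraphs whose hyperedges are
#' the fixture gene sets, trains one embedding per modality (different
#' seeds), and concatenates them.
#'
#' @param fixture result of [generate_ontology_fixture()].
#' @param dim per-modality embedding dimension.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param ... passed to [train_embeddings()].
#' @return a `"concat"` `embedding_matrix`.
#' @export
fixture_embeddings <- function(fixture, dim = 32L, epochs = 15L, seed = 1L, ...) {
  edges_go <- ic_weight_ontology(
    edges_from_sets(fixture$sets, fixture$hierarchy))
  leaf_sets <- fixture$sets[!names(fixture$sets) %in%
                              unique(fixture$hierarchy$parent)]
  edges_ex <- size_weight_expression(hyperedge_set(leaf_sets))
  g_go <- functional_hypergraph(fixture$universe, edges_go, "ontology")
  g_ex <- functional_hypergraph(fixture$universe, edges_ex, "expression")
  emb_go <- train_embeddings(g_go, dim = dim, epochs = epochs, seed = seed, ...)
  emb_ex <- train_embeddings(g_ex, dim = dim, epochs = epochs, seed = seed + 1L, ...)
  concat_modalities(emb_go, emb_ex)
}
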