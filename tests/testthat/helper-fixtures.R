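# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Two planted 15-gene clusters in a 40-gene universe, trained concat embedding.
cluster_fixture <- function(seed = 3L) {
  memo(paste0("cluster", seed), function() {
    spec <- fixture_spec(n_genes = 40L, n_pathways = 2L,
                         pathway_size_range = c(15L, 15L),
                         cotarget_effect = 5L, seed = seed)
    fx <- generate_ontology_fixture(spec)
    emb <- fixture_embeddings(fx, dim = 16L, epochs = 30L, seed = seed)
    list(spec = spec, fx = fx, emb = emb)
  })
}

# Random small weighted hypergraph over n genes for property checks.
random_hypergraph <- function(n_genes, n_edges, seed, mode = "expression") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  members <- list()
  for (j in seq_len(n_edges)) {
    k <- sample(2:max(2, n_genes %/% 3), 1L)
    members[[sprintf("e%02d", j)]] <- sample(genes, k)
  }
  # guarantee full coverage so no gene is isolated
  members[["e_all"]] <- genes
  edges <- size_weight_expression(hyperedge_set(members))
  functional_hypergraph(gene_universe(genes), edges, mode)
}

# 1-NN cluster purity of an embedding restricted to labelled genes.
nn_purity <- function(vectors, labels) {
  keep <- !is.na(labels)
  U <- vectors[keep, , drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  C <- U %*% t(U)
  diag(C) <- -2
  nn <- apply(C, 1L, which.max)
  mean(labels[keep][nn] == labels[keep])
}

module_labels <- function(fx) {
  lab <- rep(NA_character_, length(fx$universe$genes))
  names(lab) <- fx$universe$genes
  for (nm in names(fx$modules)) lab[fx$modules[[nm]]] <- nm
  lab
}

# Exact one-sided signed-rank p-value by enumeration over all sign patterns.
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  mean(w_all >= w_obs)
}

# Benchmark-scale fixture: 2400-gene universe, 20 planted 50-gene pathways,
# trained concat embedding. Built once per run.
bench_fixture <- function() {
  memo("bench", function() {
    spec <- fixture_spec(seed = 11L)
    fx <- generate_ontology_fixture(spec)
    emb <- fixture_embeddings(fx, dim = 32L, epochs = 15L, seed = 2L)
    list(spec = spec, fx = fx, emb = emb)
  })
}

# End-to-end planted co-target evaluation: trains the Siamese ensemble on
# balanced pairs and returns held-out recall at the top 5%.
cotarget_recall <- function() {
  memo("cotarget", function() {
    spec <- fixture_spec(n_genes = 800L, n_pathways = 10L,
                         pathway_size_range = c(40L, 40L),
                         n_compounds = 60L, n_targets = 40L,
                         cotarget_effect = 12L, signature_size = 30L,
                         n_cell_lines = 2L, seed = 7L)
    fx <- generate_ontology_fixture(spec)
    emb <- fixture_embeddings(fx, dim = 24L, epochs = 12L, seed = 3L)
    ct <- generate_cotarget_fixture(spec, modules = fx$modules)
    parts <- split_modalities(emb)
    mg <- background_moments(parts$ontology)
    mx <- background_moments(parts$expression)
    svs <- lapply(ct$signatures, function(s)
      suppressWarnings(aggregate_signature(s, emb, mg, mx)))
    names(svs) <- vapply(ct$signatures, function(s)
      paste(s$perturbagen_id, s$perturbagen_type, s$cell_line, sep = "|"), "")
    cl_lines <- ct$cell_lines
    targets <- names(ct$target_module)
    vec_of <- function(id, type, cl) svs[[paste(id, type, cl, sep = "|")]]$vector
    gvecs <- lapply(cl_lines, function(cl)
      do.call(rbind, stats::setNames(lapply(targets, vec_of, "shRNA", cl), targets)))
    names(gvecs) <- cl_lines
    cvecs <- lapply(cl_lines, function(cl)
      do.call(rbind, stats::setNames(
        lapply(unique(ct$annotations$compound_id), vec_of, "compound", cl),
        unique(ct$annotations$compound_id))))
    names(cvecs) <- cl_lines

    pos <- ct$annotations
    pairs <- balanced_pair_sampling(pos, ct$annotations,
                                    unique(pos$compound_id), seed = 5L)
    fold <- compound_folds(pairs$compound_id, 5L, seed = 9L)
    tr <- fold != 1L
    ens <- lapply(cl_lines, function(cl)
      train_cotarget_model(pairs[tr, ], cvecs[[cl]], gvecs[[cl]],
                           annotations = ct$annotations, epochs = 60L,
                           n_models = 3L, hidden1 = 128L, hidden2 = 32L,
                           seed = 4L))
    names(ens) <- cl_lines
    test_cpds <- unique(pairs$compound_id[!tr])
    rankings <- lapply(test_cpds, function(cp) {
      lists <- lapply(cl_lines, function(cl) {
        pr <- predict_cotarget(ens[[cl]],
                               cvecs[[cl]][rep(cp, length(targets)), , drop = FALSE],
                               gvecs[[cl]])
        candidate_list(cp, targets, pr, cl, "shRNA")
      })
      consensus_aggregate(lists)
    })
    names(rankings) <- test_cpds
    known <- split(ct$annotations$target_gene, ct$annotations$compound_id)[test_cpds]
    list(recall = as.numeric(recall_at_percent(rankings, known, 5)),
         ens = ens, pairs = pairs, rankings = rankings, known = known,
         cvecs = cvecs, gvecs = gvecs)
  })
}
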