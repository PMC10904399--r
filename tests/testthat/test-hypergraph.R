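test_that("information-content weights match hand computation and handle roots", {
  e <- hyperedge_set(list(e1 = paste0("g", 1:3), e2 = paste0("g", 4:8)),
                     children = list(e2 = "e1"))
  e <- ic_weight_ontology(e)
  expect_equal(unname(e$weights["e1"]), -log2(3 / 8), tolerance = 1e-12)
  expect_equal(unname(e$weights["e2"]), 0)

  single <- ic_weight_ontology(hyperedge_set(list(only = c("a", "b"))))
  expect_equal(unname(single$weights), 0)
})

test_that("information-content weights agree with a brute-force descendant oracle", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:30)
  n_edges <- 20L
  members <- lapply(seq_len(n_edges), function(j) sample(genes, sample(2:8, 1)))
  names(members) <- sprintf("t%02d", seq_len(n_edges))
  # random DAG: edges only point from higher to lower index
  children <- list()
  for (j in 3:n_edges) {
    k <- sample(0:2, 1)
    if (k > 0) children[[names(members)[j]]] <- sample(names(members)[seq_len(j - 1)], k)
  }
  edges <- ic_weight_ontology(hyperedge_set(members, children))

  # oracle: expand descendants by fixpoint iteration, independent of the DFS code
  desc_oracle <- function(id) {
    out <- id
    repeat {
      nxt <- unique(c(out, unlist(children[out])))
      if (length(nxt) == length(out)) return(out)
      out <- nxt
    }
  }
  total <- sum(lengths(members))
  for (id in names(members)) {
    w_expected <- -log2(sum(lengths(members[desc_oracle(id)])) / total)
    expect_equal(unname(edges$weights[id]), max(w_expected, 0), tolerance = 1e-12)
  }
})

test_that("cycles in the edge hierarchy are rejected with the cycle named", {
  expect_error(
    hyperedge_set(list(a = "g1", b = "g2"), children = list(a = "b", b = "a")),
    "cycle.*a|b")
  expect_error(hyperedge_set(list()), "empty")
})

test_that("expression-mode size weights match hand computation", {
  e <- size_weight_expression(hyperedge_set(list(a = paste0("g", 1:2),
                                                 b = paste0("g", 3:8))))
  expect_equal(unname(e$weights), c(2, -log2(6 / 8)), tolerance = 1e-12)
  expect_equal(unname(size_weight_expression(hyperedge_set(list(x = "g1")))$weights), 0)
  four <- size_weight_expression(hyperedge_set(
    list(a = "g1", b = "g2", c = "g3", d = "g4")))
  expect_equal(unname(four$weights), rep(2, 4))
  expect_error(size_weight_expression(
    hyperedge_set(list(a = "g1", b = "g2"), children = list(b = "a"))),
    "children")
})

test_that("transition matrix matches hand computation and is row-stochastic", {
  uni <- gene_universe(c("u", "v", "z"))
  ed <- hyperedge_set(list(e1 = c("u", "v"), e2 = c("u", "v", "z")),
                      weights = c(1, 1))
  B <- build_transition_matrix(functional_hypergraph(uni, ed, "expression"))$matrix
  expect_equal(B["u", "v"], 5 / 12, tolerance = 1e-12)
  expect_equal(B["u", "u"], 5 / 12, tolerance = 1e-12)
  expect_equal(B["u", "z"], 1 / 6, tolerance = 1e-12)
  expect_equal(unname(rowSums(B)), rep(1, 3), tolerance = 1e-12)

  pairg <- functional_hypergraph(gene_universe(c("u", "v")),
                                 hyperedge_set(list(e = c("u", "v")), weights = 2.7),
                                 "expression")
  B2 <- build_transition_matrix(pairg)$matrix
  expect_equal(unname(B2["u", c("u", "v")]), c(0.5, 0.5))

  for (s in 1:3) {
    g <- random_hypergraph(15L, 8L, seed = s)
    Br <- build_transition_matrix(g)$matrix
    expect_equal(unname(rowSums(Br)), rep(1, 15), tolerance = 1e-12)
    expect_true(all(Br >= 0))
  }
})

test_that("raising one edge weight increases transitions along that edge", {
  base <- c(e1 = 1, e2 = 1)
  bump <- c(e1 = 3, e2 = 1)
  mk <- function(w) {
    ed <- hyperedge_set(list(e1 = c("u", "v"), e2 = c("u", "v", "z")), weights = w)
    build_transition_matrix(functional_hypergraph(gene_universe(c("u", "v", "z")),
                                                  ed, "expression"))$matrix
  }
  B0 <- mk(base); B1 <- mk(bump)
  expect_gt(B1["u", "v"], B0["u", "v"])  # v shares the up-weighted edge with u
})

test_that("random walk with restart matches the closed form and conserves mass", {
  # restart-only limit
  g <- random_hypergraph(10L, 5L, seed = 1)
  m1 <- build_transition_matrix(g, restart_prob = 1)
  p1 <- random_walk_restart(m1, "g001")
  expect_equal(unname(p1$distribution["g001"]), 1)

  # two-gene closed form
  uni <- gene_universe(c("u", "v"))
  ed <- hyperedge_set(list(e = c("u", "v")), weights = 1)
  m2 <- build_transition_matrix(functional_hypergraph(uni, ed, "expression"), 0.5)
  p2 <- random_walk_restart(m2, "u")
  expect_equal(unname(p2$distribution), c(0.75, 0.25), tolerance = 1e-6)

  # power iteration vs dense closed form on graphs up to 50 genes
  for (s in 1:3) {
    n <- c(20L, 35L, 50L)[s]
    g <- random_hypergraph(n, n %/% 2, seed = 10 + s)
    m <- build_transition_matrix(g, restart_prob = 0.5)
    src <- g$universe$genes[1L]
    p <- random_walk_restart(m, src, tol = 1e-8)
    cf <- stationary_closed_form(m, src)
    expect_lt(max(abs(p$distribution - cf)), 1e-6)
    expect_true(all(p$distribution >= 0))
    expect_equal(sum(p$distribution), 1, tolerance = 1e-8)
    S <- stationary_matrix(m, tol = 1e-8)
    expect_lt(max(abs(S[, src] - cf)), 1e-6)
  }

  g_big <- random_hypergraph(20L, 10L, seed = 44)
  m_big <- build_transition_matrix(g_big, 0.5)
  expect_error(random_walk_restart(m_big, "g001", tol = 1e-30, max_iter = 3L),
               "did not converge")
  expect_error(random_walk_restart(m2, "nope"), "unknown source")
})

test_that("neighbor sampling honors the 1:5 ratio and the target probabilities", {
  g <- random_hypergraph(12L, 6L, seed = 2)
  m <- build_transition_matrix(g, 0.5)
  prof <- random_walk_restart(m, "g001")
  for (np in c(1L, 7L, 20L)) {
    set.seed(1)
    s <- sample_neighbors(prof, np)
    expect_length(s$positives, np)
    expect_length(s$negatives, 5L * np)
    expect_false("g001" %in% c(s$positives, s$negatives))
  }

  # degenerate profile: all mass on one non-source gene
  deg <- structure(list(source = "g001",
                        distribution = stats::setNames(c(0, 1, rep(0, 10)),
                                                       g$universe$genes),
                        iterations = 1L, converged = TRUE),
                   class = "stationary_profile")
  set.seed(2)
  sd_ <- sample_neighbors(deg, 5L)
  expect_true(all(sd_$positives == "g002"))

  # empirical frequencies over 1e5 draws match the target within 3 SE
  set.seed(3)
  big <- sample_neighbors(prof, 100000L)
  p_target <- prof$distribution[names(prof$distribution) != "g001"]
  p_target <- p_target / sum(p_target)
  freq <- table(factor(big$positives, levels = names(p_target))) / 1e5
  se <- sqrt(p_target * (1 - p_target) / 1e5)
  expect_true(all(abs(freq - p_target) <= 3 * se + 1e-9))
})

test_that("isolated genes are flagged, excluded from walks, and zero-degree errors fire", {
  uni <- gene_universe(c("a", "b", "lonely"))
  ed <- hyperedge_set(list(e = c("a", "b")), weights = 1)
  g <- functional_hypergraph(uni, ed, "expression")
  expect_true(g$isolated[3L])
  m <- build_transition_matrix(g, 0.5)
  p <- random_walk_restart(m, "lonely")
  expect_true(p$converged)
  expect_equal(unname(p$distribution["lonely"]), 1)
  pa <- random_walk_restart(m, "a")
  expect_equal(unname(pa$distribution["lonely"]), 0)
})
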