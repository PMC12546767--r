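test_that("BLOSUM50 alignment scores match known values and symmetry", {
  # three A<->A matches at BLOSUM50 diagonal score 5
  expect_equal(pocket_alignment_score("AAA", "AAA"), 15)
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aa, 10, TRUE), collapse = "")
    b <- paste(sample(aa, 10, TRUE), collapse = "")
    expect_equal(pocket_alignment_score(a, b), pocket_alignment_score(b, a))
    # identity alignment is optimal for positive-diagonal matrices
    expect_gte(pocket_alignment_score(a, a), pocket_alignment_score(a, b))
  }
  expect_error(pocket_alignment_score("", "AAA"),
               class = "ligspace_domain_error")
  expect_warning(pocket_alignment_score("AZA", "AAA"), "unknown residue")
})

test_that("pocket-pocket edges follow the half-self-score criterion", {
  # self("AAAA") = 20; "AAAC" scores 5+5+5-1 = 14 > 10 -> edge;
  # "CCCC" scores -4 -> no edge
  tbl <- tibble::tibble(assay_id = c("A1", "A2", "A3"),
                        target_group_id = c("T1", "T2", "T3"),
                        ligand_id = c("l1", "l2", "l3"),
                        value = c(1, 1, 1), unit = "nM")
  pm <- tibble::tibble(assay_id = c("A1", "A2", "A3"),
                       pocket_id = c("pA", "pB", "pC"))
  reg <- tibble::tibble(pocket_id = c("pA", "pB", "pC"),
                        sequence = c("AAAA", "AAAC", "CCCC"))
  col <- ingest_assays(tbl, pocket_map = pm, pocket_registry = reg)
  g <- build_graph(col, label_activity(col))
  has_edge <- function(from, to) {
    any(g$pp_edges$from == from & g$pp_edges$to == to)
  }
  s_ab <- pocket_alignment_score("AAAA", "AAAC")
  expect_equal(s_ab, 14)
  expect_true(has_edge("pB", "pA"))   # 14 > 0.5 * 20
  # criterion is strict and asymmetric: self(AAAC) = 28, 14 > 14 fails
  expect_false(has_edge("pA", "pB"))
  expect_false(has_edge("pC", "pA"))
  expect_false(has_edge("pA", "pC"))
  # every active ligand points at its assay's pocket
  expect_equal(nrow(g$lp_edges), 3)
})

test_that("ligand edges cover exactly the labeled actives", {
  tbl <- tibble::tibble(assay_id = rep("A1", 8),
                        target_group_id = "T1",
                        ligand_id = paste0("l", 1:8),
                        value = c(1, 2, 3, 20, 30, 40, 50, 60),
                        unit = "uM")
  pm <- tibble::tibble(assay_id = "A1", pocket_id = "p1")
  reg <- tibble::tibble(pocket_id = "p1", sequence = "ACDEFGHIKL")
  col <- ingest_assays(tbl, pocket_map = pm, pocket_registry = reg)
  g <- build_graph(col, label_activity(col))
  expect_equal(sort(g$lp_edges$ligand_id), c("l1", "l2", "l3"))
})

test_that("attention weights form a convex combination", {
  hp <- init_hgnn_params(d = 6, seed = 2)
  q <- rnorm(6)
  # single neighbor: output is that neighbor's value
  v1 <- matrix(rnorm(6), 1)
  out1 <- attention_aggregate(q, v1, hp$agg_p)
  expect_equal(as.numeric(out1), as.numeric(v1))
  expect_equal(sum(attr(out1, "weights")), 1)

  # identical neighbors: output equals the shared value, weights 0.5/0.5
  v2 <- rbind(v1, v1)
  out2 <- attention_aggregate(q, v2, hp$agg_p)
  expect_equal(as.numeric(out2), as.numeric(v1))
  expect_equal(attr(out2, "weights"), c(0.5, 0.5))

  # random neighbors: weights nonnegative, sum 1, output in convex hull
  for (m in c(3, 7)) {
    V <- matrix(rnorm(m * 6), m)
    out <- attention_aggregate(q, V, hp$agg_p)
    w <- attr(out, "weights")
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(as.numeric(out), as.numeric(crossprod(V, w)))
  }
  # empty neighbor set falls back to the query
  expect_equal(as.numeric(attention_aggregate(q, matrix(numeric(0), 0, 6),
                                              hp$agg_p)), q)
  expect_error(attention_aggregate(q, matrix(1, 1, 3), hp$agg_p),
               class = "ligspace_contract_error")
})

test_that("two-hop neighbors follow the definition with best-path relations", {
  g <- empty_graph()
  g$pp_edges <- tibble::tibble(from = c("p1", "p3"), to = c("p2", "p2"),
                               score = c(10, 8), rel = c(0.9, 0.6))
  g$lp_edges <- tibble::tibble(ligand_id = c("l1", "l1", "l9"),
                               pocket_id = c("p1", "p3", "p9"))
  nb <- two_hop_ligand_neighbors(g, "p2")
  # l1 reachable through p1 and p3: deduplicated, best-scoring relation kept
  expect_equal(nb$ligand_id, "l1")
  expect_equal(nb$rel, 0.9)
  # pocket with no incoming pocket edges has an empty neighborhood
  expect_equal(nrow(two_hop_ligand_neighbors(g, "p1")), 0)
})

test_that("refinement is the stated convex combination", {
  d <- 4
  hp <- init_hgnn_params(d = d, seed = 3)
  p <- c(1, 0, 0, 0)
  pn <- c(0, 1, 0, 0)   # single pocket neighbor -> p_p = pn
  lg <- c(0, 0, 1, 0)   # single 2-hop ligand; identity Phi -> p_l = lg
  g <- empty_graph()
  g$pp_edges <- tibble::tibble(from = "pn", to = "q", score = 10, rel = 0.9)
  g$lp_edges <- tibble::tibble(ligand_id = "lg", pocket_id = "pn")
  pemb <- matrix(pn, 1, d, dimnames = list("pn", NULL))
  lemb <- matrix(lg, 1, d, dimnames = list("lg", NULL))

  hp0 <- set_refine_weights(hp, 0, 0)
  expect_equal(refine_pocket("q", p, g, pemb, lemb, hp0), p)

  hp1 <- set_refine_weights(hp, 1, 0)
  expect_equal(refine_pocket("q", p, g, pemb, lemb, hp1), lg,
               tolerance = 1e-9)

  hp25 <- set_refine_weights(hp, 0.25, 0.25)
  expect_equal(refine_pocket("q", p, g, pemb, lemb, hp25),
               0.25 * lg + 0.25 * pn + 0.5 * p, tolerance = 1e-9)
})

test_that("the identity-initialised Phi passes ligand embeddings through", {
  hp <- init_hgnn_params(d = 5, seed = 4)
  L <- matrix(rnorm(15), 3, 5)
  X <- cbind(L, hp$rel_table[c(1, 4, 8), ])
  expect_equal(ligspace:::phi_forward(hp$phi, X), L, tolerance = 1e-12)
})

test_that("graphs serialize to diffable TSVs and back", {
  w <- tiny_world()
  col <- sample_assays(w, 6, 8, unit_mix = c(nM = 1), seed = 1)
  g <- build_graph(col, label_activity(col))
  path <- file.path(withr::local_tempdir(), "kg")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_equal(as.data.frame(g2$lp_edges), as.data.frame(g$lp_edges))
  expect_equal(as.data.frame(g2$pp_edges), as.data.frame(g$pp_edges),
               tolerance = 1e-12)
})

test_that("edge counts grow as the alignment criterion is relaxed", {
  w <- tiny_world()
  col <- sample_assays(w, 6, 8, unit_mix = c(nM = 1), seed = 1)
  g <- build_graph(col, label_activity(col))
  # recompute edges under a stricter-than-half and a looser criterion
  n_at <- function(mult) {
    self <- setNames(g$pockets$self_score, g$pockets$pocket_id)
    sum(g$pp_edges$score > mult * self[g$pp_edges$to])
  }
  expect_lte(n_at(0.9), n_at(0.5))
  expect_lte(n_at(0.5), n_at(0.3))
})
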