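#' BLOSUM50 global alignment score between two pocket sequences
#'
#' Pocket-pocket similarity for the knowledge graph, computed as a global
#' (Needleman-Wunsch) alignment score under the BLOSUM50 substitution matrix
#' with affine gap penalties (open 11, extend 1 — a standard protein
#' default).  Unknown residue letters are mapped to `X` with a warning.
#'
#' @param seq_a,seq_b Nonempty amino-acid strings.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return Scalar alignment score (symmetric in its arguments).
#' @export
pocket_alignment_score <- function(seq_a, seq_b, gap_open = 11,
                                   gap_extend = 1) {
  clean <- function(s) {
    if (!nzchar(s)) abort("empty pocket sequence",
                          class = "ligspace_domain_error")
    s <- toupper(s)
    known <- "ACDEFGHIKLMNPQRSTVWYX"
    chars <- strsplit(s, "")[[1]]
    bad <- !chars %in% strsplit(known, "")[[1]]
    if (any(bad)) {
      warn(sprintf("mapping %d unknown residue letter(s) to X", sum(bad)))
      chars[bad] <- "X"
    }
    paste(chars, collapse = "")
  }
  a <- clean(seq_a); b <- clean(seq_b)
  data("BLOSUM50", package = "Biostrings", envir = environment())
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = get("BLOSUM50", envir = environment()),
    gapOpening = gap_open, gapExtension = gap_extend)))
}

#' Build the pocket-ligand knowledge graph
#'
#' Two edge types: a ligand points to a pocket when it is a labeled active
#' of the pocket's assay target; pocket B points to pocket A when the
#' alignment score between A and B exceeds half of A's self-alignment score
#' (note the criterion is asymmetric, so B to A may exist without A to B).
#' Pocket-pocket edges carry the alignment score and its value normalised by
#' the target pocket's self-score (the relation feature for the
#' pocket-ligand aggregator).
#'
#' @param collection An `assay_collection` whose pocket registry has a
#'   `sequence` column (pockets without sequences are excluded with a
#'   warning).
#' @param labels Activity labels from [label_activity()].
#' @return A `knowledge_graph`: `pockets` (tibble with self-alignment
#'   scores), `lp_edges` (`ligand_id`, `pocket_id`), `pp_edges` (`from`,
#'   `to`, `score`, `rel`).
#' @export
build_graph <- function(collection, labels) {
  stopifnot(inherits(collection, "assay_collection"))
  reg <- collection$pocket_registry
  if (!"sequence" %in% names(reg)) {
    abort("pocket registry has no 'sequence' column",
          class = "ligspace_validation_error")
  }
  keep <- !is.na(reg$sequence) & nzchar(reg$sequence)
  if (any(!keep)) {
    warn(sprintf("excluding %d pocket(s) without sequence", sum(!keep)))
  }
  reg <- reg[keep, , drop = FALSE]

  # ligand -> pocket edges: active ligand of an assay points at each of the
  # assay's pocket variants
  assay_pockets <- collection$assays |>
    select("assay_id", "target_group_id", "pocket_ids") |>
    tidyr::unnest("pocket_ids") |>
    rename(pocket_id = "pocket_ids")
  lp <- collection$measurements |>
    select("assay_id", "target_group_id", "ligand_id") |>
    left_join(labels, by = c("target_group_id", "ligand_id")) |>
    filter(.data$label == "active") |>
    left_join(assay_pockets, by = c("assay_id", "target_group_id"),
              relationship = "many-to-many") |>
    filter(.data$pocket_id %in% reg$pocket_id) |>
    distinct(.data$ligand_id, .data$pocket_id)

  # pocket -> pocket edges under the half-self-score criterion
  seqs <- setNames(reg$sequence, reg$pocket_id)
  n <- length(seqs)
  self_score <- vapply(seqs, function(s) pocket_alignment_score(s, s),
                       numeric(1))
  pp <- NULL
  if (n > 1) {
    data("BLOSUM50", package = "Biostrings", envir = environment())
    blosum <- get("BLOSUM50", envir = environment())
    score_mat <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) {
      sc <- Biostrings::score(Biostrings::pairwiseAlignment(
        rep(seqs[i], n - i), seqs[(i + 1):n], type = "global",
        substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1))
      score_mat[i, (i + 1):n] <- sc
      score_mat[(i + 1):n, i] <- sc
    }
    idx <- which(outer(rep(TRUE, n), rep(TRUE, n)) &
                   score_mat > 0.5 * matrix(self_score, n, n, byrow = FALSE) &
                   row(score_mat) != col(score_mat), arr.ind = TRUE)
    # criterion on target A (rows): score(A, B) > 0.5 self(A) adds edge B -> A
    if (nrow(idx) > 0) {
      pp <- tibble(from = names(seqs)[idx[, 2]],
                   to = names(seqs)[idx[, 1]],
                   score = score_mat[idx],
                   rel = score_mat[idx] / self_score[idx[, 1]]) |>
        arrange(.data$to, .data$from)
    }
  }
  if (is.null(pp)) pp <- tibble(from = character(), to = character(),
                                score = numeric(), rel = numeric())
  structure(list(pockets = tibble(pocket_id = names(seqs),
                                  sequence = unname(seqs),
                                  self_score = unname(self_score)),
                 lp_edges = arrange(lp, .data$pocket_id, .data$ligand_id),
                 pp_edges = pp),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d pockets, %d ligand->pocket edges, %d pocket->pocket edges\n",
              nrow(x$pockets), nrow(x$lp_edges), nrow(x$pp_edges)))
  invisible(x)
}

#' Empty knowledge graph (refinement degrades to the identity)
#' @return A `knowledge_graph` with no nodes or edges.
#' @export
empty_graph <- function() {
  structure(list(pockets = tibble(pocket_id = character(),
                                  sequence = character(),
                                  self_score = numeric()),
                 lp_edges = tibble(ligand_id = character(),
                                   pocket_id = character()),
                 pp_edges = tibble(from = character(), to = character(),
                                   score = numeric(), rel = numeric())),
            class = "knowledge_graph")
}

#' Serialize / read a knowledge graph as diffable edge-list TSVs
#' @param graph A `knowledge_graph`.
#' @param path Path prefix; writes `<path>.pockets.tsv`, `<path>.lp.tsv`,
#'   `<path>.pp.tsv`.
#' @export
write_graph <- function(graph, path) {
  readr::write_tsv(graph$pockets, paste0(path, ".pockets.tsv"))
  readr::write_tsv(graph$lp_edges, paste0(path, ".lp.tsv"))
  readr::write_tsv(graph$pp_edges, paste0(path, ".pp.tsv"))
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  structure(list(
    pockets = readr::read_tsv(paste0(path, ".pockets.tsv"),
                              show_col_types = FALSE),
    lp_edges = readr::read_tsv(paste0(path, ".lp.tsv"),
                               show_col_types = FALSE,
                               col_types = "cc"),
    pp_edges = readr::read_tsv(paste0(path, ".pp.tsv"),
                               show_col_types = FALSE)),
    class = "knowledge_graph")
}

#' Initialise H-GNN attention parameters
#'
#' Two independent attention aggregators (pocket-pocket and pocket-ligand),
#' a 2-layer perceptron `Phi` combining a ligand embedding with a relation
#' embedding (hidden size `2d`; initialised to pass the ligand embedding
#' through exactly, so an untrained aggregator already averages real ligand
#' embeddings), a bucketised relation-embedding table, and the simplex
#' logits for the final convex combination.
#'
#' @param d Embedding dimension.
#' @param d_h Attention hidden width.
#' @param n_bins Relation-score buckets.
#' @param seed Seed.
#' @return `hgnn_params` list.
#' @export
init_hgnn_params <- function(d, d_h = d, n_bins = 8, seed = 1) {
  mk_agg <- function(salt) {
    withr::with_seed(derive_seed(seed, salt), {
      list(W1 = matrix(rnorm(2 * d * d_h, sd = 1 / sqrt(2 * d)), 2 * d, d_h),
           b1 = rep(0, d_h),
           W2 = rnorm(d_h, sd = 1 / sqrt(d_h)))
    })
  }
  phi <- list(
    W1 = rbind(cbind(diag(d), -diag(d)), matrix(0, d, 2 * d)),
    b1 = rep(0, 2 * d),
    W2 = rbind(diag(d), -diag(d)),
    b2 = rep(0, d))
  rel_table <- withr::with_seed(derive_seed(seed, 31),
    matrix(rnorm(n_bins * d, sd = 0.1), n_bins, d))
  structure(list(agg_p = mk_agg(17), agg_l = mk_agg(19), phi = phi,
                 rel_table = rel_table, n_bins = n_bins, d = d, d_h = d_h,
                 gamma_logits = c(0, 0, 0)),
            class = "hgnn_params")
}

phi_forward <- function(phi, X) {
  h <- pmax(sweep(X %*% phi$W1, 2, phi$b1, "+"), 0)
  sweep(h %*% phi$W2, 2, phi$b2, "+")
}

refine_gammas <- function(params) {
  e <- exp(params$gamma_logits - max(params$gamma_logits))
  g <- e / sum(e)
  c(gamma1 = g[1], gamma2 = g[2])
}

#' Set the convex-combination weights of pocket refinement
#' @param params `hgnn_params`.
#' @param gamma1,gamma2 Weights in \[0,1\] with `gamma1 + gamma2 <= 1`.
#' @return Updated params (weights stored as simplex logits).
#' @export
set_refine_weights <- function(params, gamma1, gamma2) {
  stopifnot(gamma1 >= 0, gamma2 >= 0, gamma1 + gamma2 <= 1 + 1e-12)
  g3 <- max(1 - gamma1 - gamma2, 0)
  eps <- 1e-12
  params$gamma_logits <- log(c(gamma1, gamma2, g3) + eps)
  params
}

#' Attention aggregation over a neighbor set
#'
#' Weights are a softmax over `W2' ReLU(W1 [value_i | query] + b1)`; the
#' output is the weighted sum of neighbor values.  An empty neighbor set
#' falls back to the query embedding so downstream refinement degrades to
#' the identity rather than injecting zeros.
#'
#' @param query Query embedding (length d).
#' @param values Neighbor value matrix (m x d; may have zero rows).
#' @param agg One aggregator's parameter list (`W1`, `b1`, `W2`).
#' @return Aggregated embedding with attribute `"weights"`.
#' @export
attention_aggregate <- function(query, values, agg) {
  query <- as.numeric(query)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (nrow(values) == 0) {
    out <- query; attr(out, "weights") <- numeric(0); return(out)
  }
  if (ncol(values) != length(query)) {
    abort("neighbor/query dimension mismatch", class = "ligspace_contract_error")
  }
  X <- cbind(values, matrix(query, nrow(values), length(query), byrow = TRUE))
  if (ncol(X) != nrow(agg$W1)) {
    abort("attention parameter dimension mismatch",
          class = "ligspace_contract_error")
  }
  scores <- drop(pmax(sweep(X %*% agg$W1, 2, agg$b1, "+"), 0) %*% agg$W2)
  w <- exp(scores - max(scores)); w <- w / sum(w)
  out <- drop(crossprod(values, w))
  attr(out, "weights") <- w
  out
}

#' Two-hop ligand neighbors of a pocket
#'
#' Ligands active for some pocket that itself points at the query pocket.
#' Multi-path ligands are deduplicated keeping the relation of the
#' best-scoring connecting pocket edge; the set is capped (score-ranked) to
#' bound cost.
#'
#' @param graph A `knowledge_graph`.
#' @param pocket_id Query pocket.
#' @param cap Maximum neighbors returned.
#' @return Tibble `ligand_id`, `rel` (normalised connecting score), ordered
#'   by decreasing `rel` then id.
#' @export
two_hop_ligand_neighbors <- function(graph, pocket_id, cap = 64) {
  inn <- filter(graph$pp_edges, .data$to == !!pocket_id)
  hits <- inn |>
    left_join(graph$lp_edges, by = c(from = "pocket_id"),
              relationship = "many-to-many") |>
    filter(!is.na(.data$ligand_id))
  if (nrow(hits) == 0) return(tibble(ligand_id = character(), rel = numeric()))
  hits |>
    group_by(.data$ligand_id) |>
    summarise(rel = max(.data$rel), .groups = "drop") |>
    arrange(dplyr::desc(.data$rel), .data$ligand_id) |>
    head(cap)
}

#' Refine a query pocket embedding with the knowledge graph
#'
#' Convex combination of three signals: the attention-aggregated embeddings
#' of similar pockets, the attention-aggregated (relation-conditioned)
#' embeddings of those pockets' active ligands, and the pocket's own encoder
#' embedding: `p* = gamma1 p_l + gamma2 p_p + (1 - gamma1 - gamma2) p`.
#' With an empty graph (or an isolated pocket) both aggregators fall back to
#' the pocket's own embedding and refinement is the identity for every
#' gamma.
#'
#' @param pocket_id Query pocket id.
#' @param p Query pocket embedding (length d).
#' @param graph A `knowledge_graph`.
#' @param pocket_embeddings,ligand_embeddings Matrices with entity row
#'   names (graph neighbors are looked up here; missing entries are
#'   dropped).
#' @param params `hgnn_params`.
#' @param cap Two-hop neighbor cap.
#' @return Refined embedding (length d).
#' @export
refine_pocket <- function(pocket_id, p, graph, pocket_embeddings,
                          ligand_embeddings, params, cap = 64) {
  stopifnot(inherits(params, "hgnn_params"))
  p <- as.numeric(p)
  g <- refine_gammas(params)

  inn <- filter(graph$pp_edges, .data$to == !!pocket_id)
  inn <- inn[inn$from %in% rownames(pocket_embeddings), , drop = FALSE]
  p_p <- if (nrow(inn) > 0) {
    as.numeric(attention_aggregate(
      p, pocket_embeddings[inn$from, , drop = FALSE], params$agg_p))
  } else p

  nb <- two_hop_ligand_neighbors(graph, pocket_id, cap = cap)
  nb <- nb[nb$ligand_id %in% rownames(ligand_embeddings), , drop = FALSE]
  p_l <- if (nrow(nb) > 0) {
    bins <- pmin(pmax(ceiling(nb$rel * params$n_bins), 1), params$n_bins)
    X <- cbind(ligand_embeddings[nb$ligand_id, , drop = FALSE],
               params$rel_table[bins, , drop = FALSE])
    as.numeric(attention_aggregate(p, phi_forward(params$phi, X),
                                   params$agg_l))
  } else p

  g[["gamma1"]] * p_l + g[["gamma2"]] * p_p +
    (1 - g[["gamma1"]] - g[["gamma2"]]) * p
}

#' Fit the refinement combination weights on the training graph
#'
#' Desk-scale H-GNN training: with encoders frozen and attention parameters
#' at their seeded initialisation, the simplex weights `gamma1, gamma2` are
#' selected by grid search to maximise leave-own-edges-out retrieval.  For
#' each pocket with known actives, its own ligand edges are removed from the
#' graph (a cold-start surrogate), the pocket is refined, and recall@k of
#' its actives in the ligand pool is scored; the gammas with the best mean
#' recall win (ties prefer smaller weights for stability).
#'
#' @param graph Training `knowledge_graph`.
#' @param pocket_embeddings,ligand_embeddings Embedding matrices (entity
#'   ids in row names).
#' @param actives Named list: pocket_id -> character vector of its true
#'   active ligand ids.
#' @param params `hgnn_params`.
#' @param recall_k Retrieval depth.
#' @param grid_step Grid resolution on the simplex.
#' @return Updated `hgnn_params` with fitted gamma logits and attribute
#'   `"fit"` (the grid with mean recall per candidate).
#' @export
fit_refine_weights <- function(graph, pocket_embeddings, ligand_embeddings,
                               actives, params, recall_k = 10,
                               grid_step = 0.25) {
  cand <- tidyr::expand_grid(gamma1 = seq(0, 1, grid_step),
                             gamma2 = seq(0, 1, grid_step)) |>
    filter(.data$gamma1 + .data$gamma2 <= 1 + 1e-12)
  pool <- rownames(ligand_embeddings)
  eval_gamma <- function(g1, g2) {
    pr <- set_refine_weights(params, g1, g2)
    rec <- purrr::map_dbl(names(actives), function(pk) {
      truth <- intersect(actives[[pk]], pool)
      if (length(truth) == 0 || !pk %in% rownames(pocket_embeddings)) {
        return(NA_real_)
      }
      gsub <- graph
      gsub$lp_edges <- filter(gsub$lp_edges,
                              !.data$ligand_id %in% actives[[pk]])
      p_ref <- refine_pocket(pk, pocket_embeddings[pk, ], gsub,
                             pocket_embeddings, ligand_embeddings, pr)
      sc <- drop(cosine_matrix(matrix(p_ref, 1), ligand_embeddings))
      top <- pool[order(-sc, pool)][seq_len(min(recall_k, length(pool)))]
      topk_recall(top, truth)
    })
    mean(rec, na.rm = TRUE)
  }
  cand$recall <- purrr::map2_dbl(cand$gamma1, cand$gamma2, eval_gamma)
  best <- cand |>
    arrange(dplyr::desc(.data$recall), .data$gamma1 + .data$gamma2,
            .data$gamma1) |>
    dplyr::slice(1)
  out <- set_refine_weights(params, best$gamma1, best$gamma2)
  attr(out, "fit") <- cand
  out
}
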