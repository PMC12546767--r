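#' Training configuration
#'
#' @param seed Mandatory integer seed (no unseeded runs).
#' @param steps Optimisation steps.
#' @param batch_assays Assays sampled per step (capped at the collection
#'   size).
#' @param ligands_per_assay Ligands sampled per assay per step.
#' @param d Embedding dimension.
#' @param hidden Encoder hidden width (`NULL` = linear).
#' @param lr Adam learning rate.
#' @param tau_rank,tau_contrast Loss temperatures.
#' @param loss_weights Weights for (contrastive, ranking).
#' @param active_threshold_molar Activity boundary used for contrastive
#'   positives.
#' @return `train_config` list.
#' @export
train_config <- function(seed, steps = 500, batch_assays = 10,
                         ligands_per_assay = 10, d = 16, hidden = NULL,
                         lr = 0.03, tau_rank = 0.07, tau_contrast = 0.07,
                         loss_weights = c(1, 1),
                         active_threshold_molar = 1e-5) {
  if (missing(seed) || is.null(seed)) {
    abort("train_config requires an explicit seed",
          class = "ligspace_config_error")
  }
  stopifnot(steps >= 1, batch_assays >= 1, ligands_per_assay >= 1,
            d >= 1, lr > 0, tau_rank > 0, tau_contrast > 0)
  list(seed = as.integer(seed), steps = as.integer(steps),
       batch_assays = as.integer(batch_assays),
       ligands_per_assay = as.integer(ligands_per_assay),
       d = as.integer(d), hidden = hidden, lr = lr,
       tau_rank = tau_rank, tau_contrast = tau_contrast,
       loss_weights = loss_weights,
       active_threshold_molar = active_threshold_molar)
}

# ---- encoder forward/backward + Adam ---------------------------------------

encoder_forward <- function(params, side, X) {
  w <- params[[side]]
  H0 <- sweep(X %*% w$W1, 2, w$b1, "+")
  if (is.null(params$hidden)) return(list(E = H0))
  H <- pmax(H0, 0)
  list(E = sweep(H %*% w$W2, 2, w$b2, "+"), H0 = H0, H = H)
}

encoder_backprop <- function(params, side, X, fwd, gE) {
  w <- params[[side]]
  if (is.null(params$hidden)) {
    return(list(W1 = crossprod(X, gE), b1 = colSums(gE)))
  }
  gW2 <- crossprod(fwd$H, gE)
  gb2 <- colSums(gE)
  gH <- gE %*% t(w$W2)
  gH0 <- gH * (fwd$H0 > 0)
  list(W1 = crossprod(X, gH0), b1 = colSums(gH0), W2 = gW2, b2 = gb2)
}

adam_init <- function(params) {
  rapply(params[c("ligand", "pocket")],
         function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = c("matrix", "numeric", "array"))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (side in c("ligand", "pocket")) {
    for (nm in names(grads[[side]])) {
      g <- grads[[side]][[nm]]
      st <- state[[side]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[side]][[nm]] <- params[[side]][[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[side]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

# Per-assay training context derived once from a collection.
.assay_contexts <- function(collection, threshold_molar) {
  labels <- label_activity(collection, threshold_molar)
  purrr::pmap(collection$assays, function(assay_id, target_group_id, unit,
                                          n_ligands, pocket_ids) {
    m <- filter(collection$measurements, .data$assay_id == !!assay_id)
    pot <- to_potency(m$value, m$unit)
    lab <- labels |>
      filter(.data$target_group_id == !!target_group_id,
             .data$ligand_id %in% m$ligand_id)
    act <- setNames(lab$label == "active", lab$ligand_id)
    list(assay_id = assay_id, group = target_group_id,
         pocket_ids = pocket_ids, ligand_ids = m$ligand_id,
         potency = pot$potency, scale = pot$scale[1],
         active = unname(act[m$ligand_id]), n_ligands = n_ligands)
  })
}

#' Pre-train the shared-space encoders on an assay collection
#'
#' Gradient optimisation (Adam) of the combined contrastive + listwise
#' ranking loss.  Each step samples a batch of assays, one pocket-structure
#' variant per assay, and a ligand subset per assay; the negative mask
#' excludes cross-assay pairs sharing a target group.  Deterministic given
#' the config seed.
#'
#' @param collection An `assay_collection`.
#' @param features List with `pockets` and `ligands` feature matrices (row
#'   names = entity ids covering the collection's registries).
#' @param config A [train_config()].
#' @return A `ligspace_model`: encoder params, config, per-step loss log.
#' @export
pretrain <- function(collection, features, config) {
  stopifnot(inherits(collection, "assay_collection"))
  ctx <- .assay_contexts(collection, config$active_threshold_molar)
  if (!any(vapply(ctx, function(a) length(a$ligand_ids) >= 2, logical(1)))) {
    abort("no assay with at least 2 ligands; nothing to rank",
          class = "ligspace_config_error")
  }
  Xp <- features$pockets; Xl <- features$ligands
  missing_p <- setdiff(unique(unlist(purrr::map(ctx, "pocket_ids"))),
                       rownames(Xp))
  missing_l <- setdiff(unique(unlist(purrr::map(ctx, "ligand_ids"))),
                       rownames(Xl))
  if (length(missing_p) + length(missing_l) > 0) {
    abort("features missing for some pockets/ligands",
          class = "ligspace_contract_error")
  }
  params <- init_encoders(ncol(Xl), ncol(Xp), d = config$d,
                          hidden = config$hidden, seed = config$seed)
  state <- adam_init(params)
  log <- vector("list", config$steps)

  for (s in seq_len(config$steps)) {
    withr::with_seed(derive_seed(config$seed, 1000 + s), {
      take <- if (length(ctx) <= config$batch_assays) seq_along(ctx)
              else sample(seq_along(ctx), config$batch_assays)
      batch_ctx <- ctx[take]
      picks <- purrr::map(batch_ctx, function(a) {
        ligs <- if (length(a$ligand_ids) <= config$ligands_per_assay)
          seq_along(a$ligand_ids)
        else sample(seq_along(a$ligand_ids), config$ligands_per_assay)
        list(variant = if (length(a$pocket_ids) == 1) a$pocket_ids
                       else sample(a$pocket_ids, 1),
             ligs = sort(ligs))
      })
    })
    variants <- vapply(picks, `[[`, character(1), "variant")
    lig_ids <- unlist(purrr::map2(batch_ctx, picks,
                                  function(a, p) a$ligand_ids[p$ligs]))
    assay_of_ligand <- rep(seq_along(batch_ctx),
                           vapply(picks, function(p) length(p$ligs), integer(1)))
    potency <- unlist(purrr::map2(batch_ctx, picks,
                                  function(a, p) a$potency[p$ligs]))
    active <- unlist(purrr::map2(batch_ctx, picks,
                                 function(a, p) a$active[p$ligs]))
    Xp_b <- Xp[variants, , drop = FALSE]
    Xl_b <- Xl[lig_ids, , drop = FALSE]
    fwd_p <- encoder_forward(params, "pocket", Xp_b)
    fwd_l <- encoder_forward(params, "ligand", Xl_b)
    L <- fwd_l$E; rownames(L) <- lig_ids
    batch <- assay_batch(fwd_p$E, L, assay_of_ligand, potency, active,
                         pocket_groups = vapply(batch_ctx, `[[`,
                                                character(1), "group"),
                         ligand_groups = vapply(batch_ctx, `[[`,
                                                character(1), "group")[assay_of_ligand],
                         n_ligands = vapply(batch_ctx, `[[`, numeric(1),
                                            "n_ligands"))
    res <- .batch_loss_grad(batch, config$tau_rank, config$tau_contrast,
                            config$loss_weights)
    grads <- list(pocket = encoder_backprop(params, "pocket", Xp_b, fwd_p,
                                            res$gP),
                  ligand = encoder_backprop(params, "ligand", Xl_b, fwd_l,
                                            res$gL))
    upd <- adam_step(params, grads, state, config$lr, s)
    params <- upd$params; state <- upd$state
    log[[s]] <- tibble(step = s, loss = res$loss, loss_ranking = res$loss_r,
                       loss_contrastive = res$loss_c)
  }
  structure(list(params = params, config = config, log = bind_rows(log)),
            class = "ligspace_model")
}

#' @export
print.ligspace_model <- function(x, ...) {
  cat(sprintf("<ligspace_model> d = %d, %s encoders, %d training steps, final loss %.4f\n",
              x$params$d,
              if (is.null(x$params$hidden)) "linear" else "MLP",
              nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' Few-shot fine-tuning on one assay's support set
#'
#' Continues optimisation of the listwise ranking loss restricted to the
#' support measurements (the contrastive term is off by default: a single
#' assay supplies no meaningful in-batch negatives).  An empty support set
#' returns the parameters unchanged (the zero-shot path never mutates the
#' pretrained model).
#'
#' @param model A `ligspace_model`.
#' @param support Data frame `ligand_id`, `value`, `unit` (subset of one
#'   assay's measurements; may have zero rows).
#' @param pocket_feature Feature vector of the assay pocket.
#' @param ligand_features Feature matrix containing at least the support
#'   ligands (row names = ids).
#' @param steps,lr Optimisation settings (conservative defaults: few-shot support sets are tiny).
#' @return Updated `ligspace_model`.
#' @export
finetune <- function(model, support, pocket_feature, ligand_features,
                     steps = 100, lr = 0.005) {
  stopifnot(inherits(model, "ligspace_model"))
  if (nrow(support) == 0) return(model)
  missing_l <- setdiff(support$ligand_id, rownames(ligand_features))
  if (length(missing_l) > 0) {
    abort(paste0("support ligand(s) not in feature table: ",
                 paste(missing_l, collapse = ", ")),
          class = "ligspace_contract_error")
  }
  pot <- to_potency(support$value, support$unit)
  Xl <- ligand_features[support$ligand_id, , drop = FALSE]
  Xp <- matrix(pocket_feature, nrow = 1)
  params <- model$params
  state <- adam_init(params)
  tau <- model$config$tau_rank %||% 0.07
  for (s in seq_len(steps)) {
    fwd_p <- encoder_forward(params, "pocket", Xp)
    fwd_l <- encoder_forward(params, "ligand", Xl)
    P <- fwd_p$E; L <- fwd_l$E
    Pn <- row_normalize(P); Ln <- row_normalize(L)
    C <- Pn %*% t(Ln)
    rl <- .ranking_loss_grad(pot$potency, drop(C), tau,
                             ids = support$ligand_id)
    G <- matrix(rl$grad, nrow = 1)
    np <- sqrt(rowSums(P^2)); nl <- sqrt(rowSums(L^2))
    gP <- (G %*% Ln - rowSums(G * C) * Pn) / np
    Gt <- t(G)
    gL <- (Gt %*% Pn - rowSums(Gt * t(C)) * Ln) / nl
    grads <- list(pocket = encoder_backprop(params, "pocket", Xp, fwd_p, gP),
                  ligand = encoder_backprop(params, "ligand", Xl, fwd_l, gL))
    upd <- adam_step(params, grads, state, lr, s)
    params <- upd$params; state <- upd$state
  }
  model$params <- params
  model
}

#' Score a ligand library against a query pocket
#'
#' Embeds the pocket (optionally refining it through the knowledge graph)
#' and every library ligand, scores by cosine similarity, and returns the
#' ranked library.  Scores do not depend on library order; with no graph
#' (or an empty one) the raw pocket embedding is used.
#'
#' @param model A `ligspace_model`.
#' @param pocket_feature Query pocket feature vector.
#' @param library_features Ligand feature matrix (row names = ligand ids;
#'   nonempty).
#' @param labels Optional binary activity labels (named vector or vector
#'   aligned to rows) carried into the ranking for evaluation.
#' @param refine Optional list for graph refinement: `graph`
#'   (`knowledge_graph`), `pocket_id`, `hgnn` (`hgnn_params`), and
#'   optionally `pocket_features` for graph pockets (defaults to none).
#' @return A [screen_ranking()].
#' @export
screen <- function(model, pocket_feature, library_features, labels = NULL,
                   refine = NULL) {
  stopifnot(inherits(model, "ligspace_model"))
  if (is.null(dim(library_features)) || nrow(library_features) == 0) {
    abort("empty screening library", class = "ligspace_contract_error")
  }
  p <- drop(encode(model$params, matrix(pocket_feature, nrow = 1), "pocket"))
  L <- encode(model$params, library_features, "ligand")
  if (!is.null(refine)) {
    graph <- refine$graph
    pocket_emb <- if (!is.null(refine$pocket_features) &&
                      nrow(refine$pocket_features) > 0) {
      encode(model$params, refine$pocket_features, "pocket")
    } else matrix(numeric(0), 0, model$params$d)
    lig_emb <- if (!is.null(refine$ligand_features) &&
                   nrow(refine$ligand_features) > 0) {
      encode(model$params, refine$ligand_features, "ligand")
    } else L
    p <- refine_pocket(refine$pocket_id, p, graph, pocket_emb, lig_emb,
                       refine$hgnn)
  }
  scores <- drop(cosine_matrix(matrix(p, nrow = 1), L))
  lab <- if (is.null(labels)) rep(0L, nrow(L)) else {
    if (!is.null(names(labels))) as.integer(labels[rownames(L)])
    else as.integer(labels)
  }
  screen_ranking(tibble(ligand_id = rownames(library_features),
                        score = scores, label = lab))
}

#' Masking-based importance scores for one pocket-ligand pair
#'
#' For each maskable unit (a ligand feature/atom group or a pocket
#' residue/feature), the unit's feature contribution is zeroed, the entity
#' re-encoded, and the drop in predicted score recorded:
#' `delta = score(full) - score(masked)`.  The no-mask baseline delta is 0
#' by construction.
#'
#' @param model A `ligspace_model`.
#' @param pocket_feature,ligand_feature Feature vectors.
#' @param ligand_units,pocket_units Optional named list mapping unit name to
#'   feature indices; defaults to one unit per feature.
#' @return `importance_report` tibble: `side`, `unit`, `delta`, with the
#'   baseline row first.
#' @export
importance_scores <- function(model, pocket_feature, ligand_feature,
                              ligand_units = NULL, pocket_units = NULL) {
  stopifnot(inherits(model, "ligspace_model"))
  default_units <- function(v, prefix) {
    nm <- names(v) %||% sprintf("%s%03d", prefix, seq_along(v))
    setNames(as.list(seq_along(v)), nm)
  }
  ligand_units <- ligand_units %||% default_units(ligand_feature, "lf")
  pocket_units <- pocket_units %||% default_units(pocket_feature, "pf")
  p_full <- drop(encode(model$params, matrix(pocket_feature, 1), "pocket"))
  l_full <- drop(encode(model$params, matrix(ligand_feature, 1), "ligand"))
  s_full <- score_pair(p_full, l_full)
  mask_score <- function(side, fv, idx) {
    fv[idx] <- 0
    e <- drop(encode(model$params, matrix(fv, 1), side))
    if (all(e == 0)) return(NA_real_)
    if (side == "ligand") score_pair(p_full, e) else score_pair(e, l_full)
  }
  rows <- bind_rows(
    tibble(side = "none", unit = "(baseline)", delta = s_full - s_full),
    tibble(side = "ligand", unit = names(ligand_units),
           delta = unname(vapply(ligand_units, function(idx)
             s_full - mask_score("ligand", ligand_feature, idx), numeric(1)))),
    tibble(side = "pocket", unit = names(pocket_units),
           delta = unname(vapply(pocket_units, function(idx)
             s_full - mask_score("pocket", pocket_feature, idx), numeric(1)))))
  class(rows) <- c("importance_report", class(rows))
  rows
}

# ---- active learning --------------------------------------------------------

#' Model factories for the active-learning loop
#'
#' Each factory returns `function(labeled_ids, labeled_potency, seed)` which
#' fits a surrogate and returns a scoring function over the pool feature
#' matrix.  `al_model_reference` fine-tunes a pretrained shared-space model
#' on the labeled set (ranking loss); the baselines mirror the standard
#' comparison set for fingerprint-based lead optimisation (linear model,
#' random forest) plus a random scorer and a perfect oracle.
#'
#' @param model Pretrained `ligspace_model`.
#' @param pocket_feature Query pocket features.
#' @param steps,lr Fine-tuning settings per iteration.
#' @return A model factory function.
#' @export
al_model_reference <- function(model, pocket_feature, steps = 80, lr = 0.01) {
  function(labeled_ids, labeled_potency, features, seed) {
    support <- tibble(ligand_id = labeled_ids,
                      value = 10^(9 - labeled_potency), unit = "nM")
    ft <- finetune(model, support, pocket_feature, features,
                   steps = steps, lr = lr)
    function(X) {
      p <- drop(encode(ft$params, matrix(pocket_feature, 1), "pocket"))
      drop(cosine_matrix(matrix(p, 1), encode(ft$params, X, "ligand")))
    }
  }
}

#' @rdname al_model_reference
#' @export
al_model_random <- function() {
  function(labeled_ids, labeled_potency, features, seed) {
    function(X) withr::with_seed(derive_seed(seed, 404), runif(nrow(X)))
  }
}

#' @rdname al_model_reference
#' @export
al_model_linear <- function() {
  function(labeled_ids, labeled_potency, features, seed) {
    df <- as.data.frame(features[labeled_ids, , drop = FALSE])
    df$.y <- labeled_potency
    fit <- lm(.y ~ ., data = df)
    # tiny labeled sets make the fit rank-deficient by design; predictions
    # on the pool are still the baseline's defined behavior
    function(X) unname(suppressWarnings(stats::predict(fit, as.data.frame(X))))
  }
}

#' @rdname al_model_reference
#' @export
al_model_rf <- function(ntree = 200) {
  function(labeled_ids, labeled_potency, features, seed) {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      abort("randomForest not installed", class = "ligspace_config_error")
    }
    fit <- withr::with_seed(derive_seed(seed, 405),
      randomForest::randomForest(features[labeled_ids, , drop = FALSE],
                                 labeled_potency, ntree = ntree))
    function(X) unname(stats::predict(fit, X))
  }
}

#' @rdname al_model_reference
#' @param oracle Named potency vector over the pool.
#' @export
al_model_oracle <- function(oracle) {
  function(labeled_ids, labeled_potency, features, seed) {
    function(X) unname(oracle[rownames(X)])
  }
}

#' Run an active-learning campaign over a ligand pool
#'
#' Iteration 0 labels a random seed batch.  Each subsequent iteration fits
#' the surrogate on the labeled set, scores the unlabeled pool, selects a
#' batch (greedy: top predicted; exploration-exploitation: an
#' epsilon-fraction of diverse picks from unsampled scaffold clusters with
#' epsilon decaying from 0.5 to 0.1, remainder greedy), queries the oracle,
#' and records the top-k recall of the labeled set plus the surrogate's
#' r-squared over the whole pool.
#'
#' @param pool_features Feature matrix of the pool (row names = ligand
#'   ids; >= 100 rows).
#' @param oracle Named true-potency vector over the pool.
#' @param model_factory A factory from [al_model_reference()] and friends.
#' @param strategy `"greedy"` or `"explore-exploit"`.
#' @param batch_fraction Fraction of the pool labeled per iteration.
#' @param iterations Number of acquisition iterations.
#' @param seed Integer seed.
#' @param topk_fraction Ground-truth top set used for recall (default top
#'   2%).
#' @param clusters Optional named scaffold-cluster vector for diverse
#'   exploration picks.
#' @return An `al_state`: `labeled` (with acquisition iteration), `history`
#'   (per-iteration `recall`, `r_squared`, `n_labeled`), and the settings.
#' @export
active_learning_run <- function(pool_features, oracle, model_factory,
                                strategy = c("greedy", "explore-exploit"),
                                batch_fraction = 0.01, iterations = 5,
                                seed = 1, topk_fraction = 0.02,
                                clusters = NULL) {
  strategy <- match.arg(strategy)
  ids <- rownames(pool_features)
  N <- length(ids)
  if (N < 100) abort("pool must contain at least 100 ligands",
                     class = "ligspace_contract_error")
  stopifnot(all(ids %in% names(oracle)))
  truth <- ids[order(-oracle[ids], ids)][seq_len(max(1, ceiling(topk_fraction * N)))]
  batch <- max(1, ceiling(batch_fraction * N))
  labeled <- withr::with_seed(derive_seed(seed, 500),
                              sample(ids, batch))
  labeled_tbl <- tibble(ligand_id = labeled, potency = unname(oracle[labeled]),
                        iteration = 0L)
  history <- vector("list", iterations)
  for (t in seq_len(iterations)) {
    fit <- model_factory(labeled_tbl$ligand_id, labeled_tbl$potency,
                         pool_features, derive_seed(seed, 600 + t))
    scores <- fit(pool_features)
    names(scores) <- ids
    unl <- setdiff(ids, labeled_tbl$ligand_id)
    if (length(unl) == 0) break
    b <- batch
    if (b > length(unl)) {
      inform("final iteration truncated to remaining pool")
      b <- length(unl)
    }
    picked <- withr::with_seed(derive_seed(seed, 700 + t), {
      if (strategy == "greedy") {
        unl[order(-scores[unl], unl)][seq_len(b)]
      } else {
        eps <- 0.5 - (0.5 - 0.1) * (t - 1) / max(1, iterations - 1)
        n_explore <- round(eps * b)
        explore <- character(0)
        if (n_explore > 0) {
          cand <- unl
          if (!is.null(clusters)) {
            sampled_clusters <- unique(clusters[labeled_tbl$ligand_id])
            fresh <- cand[!clusters[cand] %in% sampled_clusters]
            if (length(fresh) > 0) cand <- fresh
          }
          explore <- sample(cand, min(n_explore, length(cand)))
        }
        rest <- setdiff(unl, explore)
        greedy <- rest[order(-scores[rest], rest)][seq_len(min(b - length(explore),
                                                               length(rest)))]
        c(explore, greedy)
      }
    })
    labeled_tbl <- bind_rows(labeled_tbl,
                             tibble(ligand_id = picked,
                                    potency = unname(oracle[picked]),
                                    iteration = t))
    r2 <- tryCatch(correlation_suite(unname(scores), unname(oracle[ids]))$r_squared,
                   error = function(e) NA_real_)
    history[[t]] <- tibble(iteration = t, n_labeled = nrow(labeled_tbl),
                           recall = topk_recall(labeled_tbl$ligand_id, truth),
                           r_squared = r2)
  }
  structure(list(labeled = labeled_tbl, history = bind_rows(history),
                 strategy = strategy, batch = batch,
                 topk_fraction = topk_fraction, seed = seed,
                 truth = truth),
            class = "al_state")
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<al_state> %s strategy, %d labeled after %d iterations, final recall %.3f\n",
              x$strategy, nrow(x$labeled), max(x$history$iteration),
              x$history$recall[nrow(x$history)]))
  invisible(x)
}
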