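#' Stepwise selection probability of a listwise ranking model
#'
#' The listwise ranking objective treats an observed within-assay ranking as
#' a sequence of softmax selections (a Plackett-Luce factorization): at each
#' step the chosen ligand competes against every ligand still in its
#' candidate set, with predicted scores divided by a temperature.
#'
#' @param scores Numeric scores of the candidate set (nonempty).
#' @param chosen Index (1-based) of the selected candidate.
#' @param tau Temperature (> 0).
#' @return Selection probability in (0, 1\].
#' @examples
#' step_selection_prob(c(2, 1, 0), 1)  # exp(2) / (exp(2)+exp(1)+exp(0))
#' @export
step_selection_prob <- function(scores, chosen, tau = 1) {
  if (length(scores) == 0) abort("empty candidate set",
                                 class = "ligspace_contract_error")
  if (tau <= 0) abort("tau must be > 0", class = "ligspace_config_error")
  stopifnot(chosen >= 1, chosen <= length(scores))
  z <- scores / tau
  z <- z - max(z)
  exp(z[chosen]) / sum(exp(z))
}

# Best-first ordering used throughout: decreasing potency, ties stable by id.
rank_order <- function(potency, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("%09d", seq_along(potency))
  order(-potency, ids)
}

#' Listwise pharmacophore-ranking loss for one assay
#'
#' Ligands are ordered best-first by potency; step `k` scores the `k`-th
#' ranked ligand against the candidate set of ligands with potency no
#' greater than its own (for strict orders, the ligands not yet selected;
#' tied ligands remain in each other's candidate sets).  The loss is the
#' weighted sum of negative log selection probabilities with decay
#' `mu_k = 1 / (n * log(k + 1))` (natural log): the `1/log(k+1)` factor
#' prioritises top-ranked ligands and `1/n` stops large assays from
#' dominating.  The loss depends on potencies only through their ordering,
#' so any strictly increasing transform of the potencies leaves it
#' unchanged.
#'
#' @param potency Numeric potencies (canonical larger-is-stronger scale, or
#'   any within-assay orderable values such as percent readouts).
#' @param scores Predicted scores (cosine similarities), same length.
#' @param tau Temperature (> 0).
#' @param ids Optional ligand ids for stable tie ordering.
#' @return Scalar loss (>= 0).
#' @export
ranking_loss <- function(potency, scores, tau = 0.07, ids = NULL) {
  .ranking_loss_grad(potency, scores, tau, ids, want_grad = FALSE)$loss
}

.ranking_loss_grad <- function(potency, scores, tau, ids = NULL,
                               want_grad = TRUE) {
  if (tau <= 0) abort("tau must be > 0", class = "ligspace_config_error")
  n <- length(potency)
  stopifnot(length(scores) == n, n >= 1)
  if (any(!is.finite(potency))) abort("non-finite potency",
                                      class = "ligspace_domain_error")
  ord <- rank_order(potency, ids)
  p <- unname(potency[ord]); s <- as.vector(scores)[ord] / tau
  # candidate set for step k: all j with potency <= potency[k]; with the
  # best-first sort this is tie_start(k)..n
  tie_start <- match(p, p)  # first index with the same potency value
  loss <- 0
  g <- numeric(n)
  for (k in seq_len(n)) {
    idx <- tie_start[k]:n
    mu <- 1 / (n * log(k + 1))
    z <- s[idx]; m <- max(z); w <- exp(z - m)
    loss <- loss + mu * (log(sum(w)) + m - s[k])
    if (want_grad) {
      q <- w / sum(w)
      g[idx] <- g[idx] + mu * q / tau
      g[k] <- g[k] - mu / tau
    }
  }
  grad <- numeric(n); grad[ord] <- g
  list(loss = loss, grad = grad)
}

#' Build the in-batch negative-usability mask
#'
#' A pocket from assay A and a ligand from assay B must not be used as a
#' contrastive negative when the two assays share a protein-identity group
#' (same UniProt-like key): such pairs are plausibly active and would be
#' false negatives.  The positive pair being scored is always retained in
#' its own softmax regardless of the mask.
#'
#' @param pocket_groups Character vector of target group ids, one per batch
#'   pocket (assay).
#' @param ligand_groups Character vector of target group ids, one per batch
#'   ligand (the group of the assay the ligand was measured in).
#' @return Logical matrix `length(pocket_groups) x length(ligand_groups)`;
#'   `TRUE` means the pair may serve as a negative.
#' @export
build_negative_mask <- function(pocket_groups, ligand_groups) {
  outer(as.character(pocket_groups), as.character(ligand_groups), "!=")
}

#' In-batch contrastive scaffold-discrimination loss
#'
#' For each assay's pocket, every active ligand of that assay is a positive;
#' the loss pushes its similarity above all unmasked batch ligands
#' (pocket-to-ligand direction) and, symmetrically, above all unmasked batch
#' pockets (ligand-to-pocket direction).  Per-assay sums are normalised by
#' the number of active ligands and weighted by `gamma_i = 1/|L_i|` so
#' ligand-rich assays do not dominate; the batch loss is the mean over
#' assays.  Assays contributing no active ligand add 0.
#'
#' @param sim Similarity matrix, pockets (assays) in rows, batch ligands in
#'   columns.
#' @param active Logical vector per ligand: is it an active of its assay.
#' @param assay_of_ligand Integer row index of each ligand's own assay
#'   (`NA` for foreign ligands that only serve as negatives).
#' @param mask Logical negative-usability matrix from
#'   [build_negative_mask()]; defaults to all-usable except own-assay
#'   columns.
#' @param n_ligands Per-assay ligand-count context `|L_i|` (defaults to the
#'   batch count, with foreign-only assays counted 1).
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(sim, active, assay_of_ligand, mask = NULL,
                             n_ligands = NULL, tau = 0.07) {
  .contrastive_loss_grad(sim, active, assay_of_ligand, mask, n_ligands, tau,
                         want_grad = FALSE)$loss
}

.contrastive_loss_grad <- function(sim, active, assay_of_ligand, mask = NULL,
                                   n_ligands = NULL, tau = 0.07,
                                   want_grad = TRUE) {
  if (tau <= 0) abort("tau must be > 0", class = "ligspace_config_error")
  n_p <- nrow(sim); n_l <- ncol(sim)
  stopifnot(length(active) == n_l, length(assay_of_ligand) == n_l)
  if (is.null(mask)) {
    mask <- matrix(TRUE, n_p, n_l)
    for (j in seq_len(n_l)) if (!is.na(assay_of_ligand[j]))
      mask[assay_of_ligand[j], j] <- FALSE
  }
  if (is.null(n_ligands)) {
    n_ligands <- vapply(seq_len(n_p), function(i)
      max(1L, sum(assay_of_ligand == i, na.rm = TRUE)), integer(1))
  }
  S <- unname(sim) / tau
  G <- matrix(0, n_p, n_l)
  total <- 0
  n_assays_counted <- 0
  for (i in seq_len(n_p)) {
    own <- which(!is.na(assay_of_ligand) & assay_of_ligand == i)
    pos <- own[active[own]]
    n_assays_counted <- n_assays_counted + 1
    if (length(pos) == 0) next
    gamma <- 1 / n_ligands[i]
    li <- 0
    for (k in pos) {
      # pocket -> ligand: positive + unmasked ligand columns of row i
      neg <- setdiff(which(mask[i, ]), k)
      idx <- c(k, neg)
      z <- S[i, idx]; m <- max(z); w <- exp(z - m); q <- w / sum(w)
      li <- li + (log(sum(w)) + m - S[i, k])
      if (want_grad) {
        G[i, idx] <- G[i, idx] + (gamma / length(pos)) * q / tau
        G[i, k] <- G[i, k] - (gamma / length(pos)) / tau
      }
      # ligand -> pocket: positive + unmasked pocket rows of column k
      negp <- setdiff(which(mask[, k]), i)
      idxp <- c(i, negp)
      zp <- S[idxp, k]; mp <- max(zp); wp <- exp(zp - mp); qp <- wp / sum(wp)
      li <- li + (log(sum(wp)) + mp - S[i, k])
      if (want_grad) {
        G[idxp, k] <- G[idxp, k] + (gamma / length(pos)) * qp / tau
        G[i, k] <- G[i, k] - (gamma / length(pos)) / tau
      }
    }
    total <- total + gamma * li / length(pos)
  }
  denom <- max(1, n_assays_counted)
  list(loss = total / denom, grad = G / denom)
}

#' Combined pre-training loss
#'
#' The unified objective is the unit-weighted sum of the contrastive
#' scaffold-discrimination loss and the listwise pharmacophore-ranking loss
#' evaluated on one batch of assays.
#'
#' @param batch An [assay_batch()].
#' @param tau_rank,tau_contrast Temperatures of the two components.
#' @param weights Length-2 weights for (contrastive, ranking); default
#'   `c(1, 1)`.
#' @return List with `total`, `contrastive`, `ranking`.
#' @export
combined_loss <- function(batch, tau_rank = 0.07, tau_contrast = 0.07,
                          weights = c(1, 1)) {
  res <- .batch_loss_grad(batch, tau_rank, tau_contrast, weights,
                          want_grad = FALSE)
  list(total = res$loss, contrastive = res$loss_c, ranking = res$loss_r)
}

#' Assemble a batch of assays for the training losses
#'
#' @param P Raw pocket embedding matrix, one row per assay (the pocket
#'   variant sampled for this step).
#' @param L Raw ligand embedding matrix, one row per batch ligand.
#' @param assay_of_ligand Integer index into the rows of `P` (`NA` for
#'   foreign negatives).
#' @param potency Per-ligand within-assay potency (any orderable scale).
#' @param active Logical per ligand.
#' @param pocket_groups,ligand_groups Target-group ids for the negative
#'   mask.
#' @param n_ligands Optional per-assay `|L_i|` context.
#' @return An `assay_batch` list.
#' @export
assay_batch <- function(P, L, assay_of_ligand, potency, active,
                        pocket_groups, ligand_groups, n_ligands = NULL) {
  stopifnot(nrow(L) == length(assay_of_ligand),
            length(potency) == nrow(L), length(active) == nrow(L),
            length(pocket_groups) == nrow(P),
            length(ligand_groups) == nrow(L))
  structure(list(P = P, L = L, assay_of_ligand = assay_of_ligand,
                 potency = potency, active = active,
                 pocket_groups = pocket_groups,
                 ligand_groups = ligand_groups,
                 n_ligands = n_ligands),
            class = "assay_batch")
}

# Loss and gradients w.r.t. the raw embeddings of a batch.
.batch_loss_grad <- function(batch, tau_rank = 0.07, tau_contrast = 0.07,
                             weights = c(1, 1), want_grad = TRUE,
                             use_contrastive = TRUE, use_ranking = TRUE) {
  P <- batch$P; L <- batch$L
  Pn <- row_normalize(P); Ln <- row_normalize(L)
  C <- Pn %*% t(Ln)
  n_p <- nrow(P)
  G <- matrix(0, nrow(C), ncol(C))

  loss_r <- 0
  if (use_ranking) {
    n_rank_assays <- 0
    Gr <- matrix(0, nrow(C), ncol(C))
    for (i in seq_len(n_p)) {
      own <- which(!is.na(batch$assay_of_ligand) & batch$assay_of_ligand == i)
      if (length(own) == 0) next
      n_rank_assays <- n_rank_assays + 1
      rl <- .ranking_loss_grad(batch$potency[own], C[i, own], tau_rank,
                               ids = rownames(L)[own], want_grad = want_grad)
      loss_r <- loss_r + rl$loss
      if (want_grad) Gr[i, own] <- Gr[i, own] + rl$grad
    }
    if (n_rank_assays > 0) {
      loss_r <- loss_r / n_rank_assays
      if (want_grad) G <- G + weights[2] * Gr / n_rank_assays
    }
  }

  loss_c <- 0
  if (use_contrastive) {
    mask <- build_negative_mask(batch$pocket_groups, batch$ligand_groups)
    cl <- .contrastive_loss_grad(C, batch$active, batch$assay_of_ligand,
                                 mask = mask, n_ligands = batch$n_ligands,
                                 tau = tau_contrast, want_grad = want_grad)
    loss_c <- cl$loss
    if (want_grad) G <- G + weights[1] * cl$grad
  }

  out <- list(loss = weights[1] * loss_c + weights[2] * loss_r,
              loss_r = loss_r, loss_c = loss_c)
  if (want_grad) {
    # chain rule through row-normalised cosine:
    # dL/dP_i = (G Ln - diag(rowSums(G*C)) Pn)_i / |P_i|
    np <- sqrt(rowSums(P^2)); nl <- sqrt(rowSums(L^2))
    gP <- (G %*% Ln - rowSums(G * C) * Pn) / np
    Gt <- t(G)
    gL <- (Gt %*% Pn - rowSums(Gt * t(C)) * Ln) / nl
    out$gP <- gP; out$gL <- gL
  }
  out
}

#' Regression baseline loss (direct affinity regression)
#'
#' The regression variant of the shared-space model predicts absolute
#' potency by an affine calibration of the cosine score and minimises mean
#' squared error.  It is the ablation baseline for the ranking objective and
#' is undefined for rank-only (percent-unit) assays.
#'
#' @param predicted Cosine scores.
#' @param potency Absolute-scale potencies.
#' @param scale Measurement scale of the assay; `"rank_only"` raises a
#'   contract error.
#' @param coef Optional fixed calibration `c(intercept, slope)`; when `NULL`
#'   the affine map is fit by least squares.
#' @return Scalar mean squared error.
#' @export
regression_baseline_loss <- function(predicted, potency, scale = "molar",
                                     coef = NULL) {
  if (identical(scale, "rank_only")) {
    abort("regression is undefined for rank-only (percent-unit) assays",
          class = "ligspace_contract_error")
  }
  stopifnot(length(predicted) == length(potency))
  if (is.null(coef)) {
    if (stats::var(predicted) == 0) {
      coef <- c(mean(potency), 0)
    } else {
      fit <- lm(potency ~ predicted)
      coef <- unname(stats::coef(fit))
    }
  }
  mean((coef[1] + coef[2] * predicted - potency)^2)
}
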