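test_that("stepwise selection probabilities follow the tempered softmax", {
  expect_equal(step_selection_prob(c(2, 1, 0), 1),
               exp(2) / (exp(2) + exp(1) + exp(0)), tolerance = 1e-12)
  # symmetry: equal scores give 1/m for any chosen index
  for (m in 2:5) {
    expect_equal(step_selection_prob(rep(0.3, m), sample(m, 1)), 1 / m)
  }
  expect_equal(step_selection_prob(5, 1), 1)
  expect_error(step_selection_prob(numeric(0), 1),
               class = "ligspace_contract_error")
  expect_error(step_selection_prob(c(1, 2), 1, tau = 0),
               class = "ligspace_config_error")
})

test_that("ranking loss matches hand computations", {
  # single ligand: only single-candidate steps
  expect_equal(ranking_loss(9, 0.4), 0)
  # 2 ligands, equal scores: mu_1 * ln 2 = [1/(2 ln 2)] * ln 2 = 0.5 exactly
  expect_equal(ranking_loss(c(9, 6), c(0.3, 0.3), tau = 1), 0.5)
  expect_equal(ranking_loss(c(9, 6), c(0, 0), tau = 0.07), 0.5)
})

test_that("ranking loss depends on potencies only through their ordering", {
  set.seed(21)
  for (i in 1:10) {
    pot <- rnorm(6, 6); sc <- rnorm(6)
    l1 <- ranking_loss(pot, sc, tau = 0.2)
    expect_equal(ranking_loss(exp(pot), sc, tau = 0.2), l1, tolerance = 1e-12)
    expect_equal(ranking_loss(pot * 100 - 3, sc, tau = 0.2), l1,
                 tolerance = 1e-12)
    # joint permutation of ligand indexing
    perm <- sample(6)
    expect_equal(ranking_loss(pot[perm], sc[perm], tau = 0.2), l1,
                 tolerance = 1e-12)
  }
})

test_that("correctly ordered scores are locally optimal on 3-ligand instances", {
  pot <- c(9, 7, 5)
  grid <- expand.grid(s1 = seq(-1, 1, 0.5), s2 = seq(-1, 1, 0.5),
                      s3 = seq(-1, 1, 0.5))
  grid <- grid[grid$s1 > grid$s2 & grid$s2 > grid$s3, ]
  for (i in seq_len(nrow(grid))) {
    s <- as.numeric(grid[i, ])
    base <- ranking_loss(pot, s, tau = 0.5)
    expect_lte(base, ranking_loss(pot, s[c(2, 1, 3)], tau = 0.5))
    expect_lte(base, ranking_loss(pot, s[c(1, 3, 2)], tau = 0.5))
  }
})

test_that("the negative mask enumerates shared-target exclusions", {
  m <- build_negative_mask(c("X", "X", "Y"), c("X", "X", "X", "X", "Y"))
  # pockets from group X cannot use group-X ligands as negatives
  expect_false(any(m[1:2, 1:4]))
  expect_true(all(m[1:2, 5]))
  expect_true(all(m[3, 1:4]))
  expect_false(m[3, 5])
})

test_that("contrastive loss matches the single-foreign-negative hand value", {
  # one assay (group X): one active ligand at sim 0; one foreign unmasked
  # ligand (group Y) at sim 0; tau = 1
  sim <- matrix(c(0, 0), 1, 2)
  mask <- build_negative_mask("X", c("X", "Y"))
  loss <- contrastive_loss(sim, active = c(TRUE, FALSE),
                           assay_of_ligand = c(1L, NA), mask = mask,
                           tau = 1)
  expect_equal(loss, log(2), tolerance = 1e-12)

  # masking the foreign ligand (shared target group) removes the only
  # negative: loss collapses to 0
  mask2 <- build_negative_mask("X", c("X", "X"))
  expect_equal(contrastive_loss(sim, c(TRUE, FALSE), c(1L, NA), mask2,
                                tau = 1), 0)

  # lone assay with its single active and no other entities
  expect_equal(contrastive_loss(matrix(0, 1, 1), TRUE, 1L, tau = 1), 0)
})

test_that("contrastive loss decreases as a positive pair's similarity grows", {
  set.seed(3)
  sim <- matrix(rnorm(6, sd = 0.2), 2, 3)
  active <- c(TRUE, TRUE, FALSE)
  aol <- c(1L, 2L, NA)
  mask <- build_negative_mask(c("X", "Y"), c("X", "Y", "Z"))
  base <- contrastive_loss(sim, active, aol, mask, tau = 0.5)
  up <- sim; up[1, 1] <- up[1, 1] + 0.05
  expect_lt(contrastive_loss(up, active, aol, mask, tau = 0.5), base)
})

test_that("losses are invariant to batch reordering", {
  set.seed(14)
  P <- matrix(rnorm(8), 2, 4)
  L <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("l", 1:5), NULL))
  aol <- c(1L, 1L, 2L, 2L, NA)
  pot <- c(9, 7, 8, 6, 5)
  act <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  b1 <- assay_batch(P, L, aol, pot, act, c("X", "Y"),
                    c("X", "X", "Y", "Y", "Z"))
  l1 <- combined_loss(b1, 0.3, 0.3)
  perm <- c(4, 1, 5, 3, 2)
  # reorder ligands and swap the two pockets, remapping assay indices
  aol2 <- aol[perm]
  aol2 <- ifelse(is.na(aol2), NA, 3L - aol2)
  b2 <- assay_batch(P[2:1, ], L[perm, ], aol2, pot[perm], act[perm],
                    c("Y", "X"), c("X", "X", "Y", "Y", "Z")[perm])
  l2 <- combined_loss(b2, 0.3, 0.3)
  expect_equal(l2$total, l1$total, tolerance = 1e-12)
  expect_equal(l2$ranking, l1$ranking, tolerance = 1e-12)
  expect_equal(l2$contrastive, l1$contrastive, tolerance = 1e-12)
})

test_that("combined loss is the exact sum with summed gradients", {
  set.seed(5)
  P <- matrix(rnorm(4), 1, 4)
  L <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("l", 1:3), NULL))
  b <- assay_batch(P, L, c(1L, 1L, 1L), c(9, 7, 5),
                   c(TRUE, TRUE, FALSE), "X", c("X", "X", "X"))
  parts <- combined_loss(b, 0.3, 0.3)
  expect_equal(parts$total, parts$contrastive + parts$ranking)

  # gradient of the sum equals the numerical gradient (3-ligand toy)
  res <- ligspace:::.batch_loss_grad(b, 0.3, 0.3)
  f <- function(Lm) {
    bb <- assay_batch(P, Lm, c(1L, 1L, 1L), c(9, 7, 5),
                      c(TRUE, TRUE, FALSE), "X", c("X", "X", "X"))
    ligspace:::.batch_loss_grad(bb, 0.3, 0.3, want_grad = FALSE)$loss
  }
  eps <- 1e-6
  for (i in 1:3) for (j in 1:4) {
    Lp <- L; Lp[i, j] <- Lp[i, j] + eps
    Lm <- L; Lm[i, j] <- Lm[i, j] - eps
    expect_equal(unname(res$gL[i, j]), unname((f(Lp) - f(Lm)) / (2 * eps)),
                 tolerance = 1e-5)
  }
})

test_that("assays with no active ligands contribute only ranking signal", {
  set.seed(6)
  P <- matrix(rnorm(4), 1, 4)
  L <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  b <- assay_batch(P, L, c(1L, 1L), c(9, 7), c(FALSE, FALSE), "X",
                   c("X", "X"))
  parts <- combined_loss(b, 0.3, 0.3)
  expect_equal(parts$contrastive, 0)
  expect_gt(parts$ranking, 0)
})

test_that("regression baseline behaves like a calibrated MSE", {
  pot <- c(9, 8, 7, 6)
  expect_equal(regression_baseline_loss(pot, pot, coef = c(0, 1)), 0)
  # frozen calibration, constant offset c -> c^2
  expect_equal(regression_baseline_loss(pot - 2, pot, coef = c(0, 1)), 4)
  # fitted calibration absorbs affine error entirely
  expect_equal(regression_baseline_loss(0.1 * pot + 3, pot), 0,
               tolerance = 1e-20)
  expect_error(regression_baseline_loss(pot, pot, scale = "rank_only"),
               class = "ligspace_contract_error")
})
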