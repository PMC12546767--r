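test_that("pretraining is bit-reproducible from its seed", {
  w <- tiny_world()
  col <- sample_assays(w, 6, 8, unit_mix = c(nM = 1), seed = 2)
  feats <- world_features(w)
  cfg <- train_config(seed = 5, steps = 25, d = 8)
  m1 <- pretrain(col, feats, cfg)
  m2 <- pretrain(col, feats, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("training requires a seed and a rankable assay", {
  expect_error(train_config(), class = "ligspace_config_error")
  tbl <- tibble::tibble(assay_id = "A1", target_group_id = "T1",
                        ligand_id = "l1", value = 1, unit = "nM")
  col <- ingest_assays(tbl)
  feats <- list(pockets = matrix(rnorm(4), 1, 4,
                                 dimnames = list("pocket:T1", NULL)),
                ligands = matrix(rnorm(4), 1, 4, dimnames = list("l1", NULL)))
  expect_error(pretrain(col, feats, train_config(seed = 1, steps = 5)),
               class = "ligspace_config_error")
})

test_that("zero-shot path leaves pretrained parameters untouched", {
  run <- small_training_run()
  ser <- make_congeneric_series(run$world, "P002", seed = 5)
  ft <- finetune(run$model, ser$measurements[0, ],
                 run$world$pocket_factors["P002", ], ser$features)
  expect_identical(ft$params, run$model$params)
})

test_that("fine-tuning rejects support ligands without features", {
  run <- small_training_run()
  ser <- make_congeneric_series(run$world, "P002", seed = 5)
  bad <- ser$measurements[1:3, ]
  bad$ligand_id[1] <- "nope"
  expect_error(finetune(run$model, bad, run$world$pocket_factors["P002", ],
                        ser$features),
               class = "ligspace_contract_error")
})

test_that("fine-tuning on the full series improves its within-series fit", {
  run <- small_training_run()
  ser <- make_congeneric_series(run$world, "P002", seed = 5)
  pf <- run$world$pocket_factors["P002", ]
  fit_of <- function(mod) {
    p <- drop(encode(mod$params, matrix(pf, 1), "pocket"))
    s <- drop(ligspace:::cosine_matrix(
      matrix(p, 1), encode(mod$params, ser$features, "ligand")))
    correlation_suite(s, ser$truth$potency_true)$spearman
  }
  ft <- finetune(run$model, ser$measurements, pf, ser$features)
  expect_gt(fit_of(ft), fit_of(run$model))
})

test_that("screening is invariant to library order and to an empty graph", {
  run <- small_training_run()
  lib <- make_screening_library(run$world, "P001", n_actives = 4, ratio = 30,
                                seed = 6)
  X <- run$feats$ligands[lib$ligand_id, ]
  labels <- setNames(lib$label, lib$ligand_id)
  r1 <- screen(run$model, run$feats$pockets["P001", ], X, labels = labels)
  perm <- sample(nrow(X))
  r2 <- screen(run$model, run$feats$pockets["P001", ], X[perm, ],
               labels = labels)
  expect_equal(as.data.frame(r2), as.data.frame(r1))

  r3 <- screen(run$model, run$feats$pockets["P001", ], X, labels = labels,
               refine = list(graph = empty_graph(), pocket_id = "P001",
                             hgnn = init_hgnn_params(d = 8, seed = 1)))
  expect_equal(r3$score, r1$score, tolerance = 1e-12)
  expect_error(screen(run$model, run$feats$pockets["P001", ],
                      run$feats$ligands[0, , drop = FALSE]),
               class = "ligspace_contract_error")
})

test_that("masking nothing yields a zero delta and symmetric units tie", {
  p <- init_encoders(4, 4, d = 4, seed = 1, init = "identity")
  model <- structure(list(params = p,
                          config = list(tau_rank = 0.07),
                          log = tibble::tibble(step = 1, loss = 0,
                                               loss_ranking = 0,
                                               loss_contrastive = 0)),
                     class = "ligspace_model")
  # features 2 and 3 contribute identically
  rep <- importance_scores(model, c(2, 1, 1, 0), c(3, 1, 1, 0))
  expect_equal(rep$delta[rep$side == "none"], 0)
  lig <- rep[rep$side == "ligand", ]
  expect_equal(lig$delta[2], lig$delta[3], tolerance = 1e-12)
})

test_that("a planted dominant feature earns the largest masking drop", {
  p <- init_encoders(5, 5, d = 5, seed = 1, init = "identity")
  model <- structure(list(params = p, config = list(),
                          log = tibble::tibble(step = 1, loss = 0,
                                               loss_ranking = 0,
                                               loss_contrastive = 0)),
                     class = "ligspace_model")
  pocket <- c(10, 0.3, 0.2, 0.1, 0.2)
  ligand <- c(8, 0.2, 0.3, 0.2, 0.1)
  rep <- importance_scores(model, pocket, ligand)
  lig <- rep[rep$side == "ligand", ]
  expect_equal(which.max(lig$delta), 1L)
  pk <- rep[rep$side == "pocket", ]
  expect_equal(which.max(pk$delta), 1L)
})

test_that("a perfect oracle surrogate recovers the full top set in one step", {
  w <- tiny_world(seed = 21)
  feats <- world_features(w)
  oracle <- setNames(oracle_potency(w, "P001", w$ligand_ids), w$ligand_ids)
  st <- active_learning_run(feats$ligands, oracle, al_model_oracle(oracle),
                            strategy = "greedy", batch_fraction = 0.02,
                            iterations = 2, seed = 1, topk_fraction = 0.02)
  expect_equal(st$history$recall[1], 1)
  # labeled-set bookkeeping: seed batch + t * batch
  expect_equal(st$history$n_labeled,
               ceiling(0.02 * 300) * (2:3))
  expect_true(all(table(st$labeled$ligand_id) == 1))
})

test_that("random surrogates recall at the labeled-fraction rate", {
  w <- tiny_world(seed = 22)
  feats <- world_features(w)
  oracle <- setNames(oracle_potency(w, "P002", w$ligand_ids), w$ligand_ids)
  N <- 300; b <- ceiling(0.02 * N); K <- ceiling(0.02 * N)
  recalls <- vapply(1:20, function(s) {
    st <- active_learning_run(feats$ligands, oracle, al_model_random(),
                              strategy = "greedy", batch_fraction = 0.02,
                              iterations = 1, seed = s,
                              topk_fraction = 0.02)
    st$history$recall[1]
  }, numeric(1))
  n_lab <- 2 * b
  expected <- n_lab / N
  # hypergeometric standard error of the mean over 20 seeds
  var1 <- n_lab * (K / N) * (1 - K / N) * (N - n_lab) / (N - 1) / K^2
  se <- sqrt(var1 / 20)
  expect_lt(abs(mean(recalls) - expected), 3 * se + 1e-9)
})

test_that("explore-exploit acquisition stays seeded and covers new clusters", {
  w <- tiny_world(seed = 23)
  feats <- world_features(w)
  oracle <- setNames(oracle_potency(w, "P003", w$ligand_ids), w$ligand_ids)
  st1 <- active_learning_run(feats$ligands, oracle, al_model_linear(),
                             strategy = "explore-exploit",
                             batch_fraction = 0.02, iterations = 3, seed = 4,
                             clusters = w$scaffold_of)
  st2 <- active_learning_run(feats$ligands, oracle, al_model_linear(),
                             strategy = "explore-exploit",
                             batch_fraction = 0.02, iterations = 3, seed = 4,
                             clusters = w$scaffold_of)
  expect_identical(st1$labeled, st2$labeled)
  expect_equal(nrow(st1$history), 3)
  expect_s3_class(glance(st1), "tbl_df")
})

test_that("model accessors tidy and plot without error", {
  run <- small_training_run()
  td <- tidy(run$model)
  expect_equal(nrow(td), 80)
  gl <- glance(run$model)
  expect_equal(gl$steps, 80)
  expect_s3_class(autoplot(run$model), "ggplot")
  lib <- make_screening_library(run$world, "P001", n_actives = 4, ratio = 30,
                                seed = 6)
  r <- screen(run$model, run$feats$pockets["P001", ],
              run$feats$ligands[lib$ligand_id, ],
              labels = setNames(lib$label, lib$ligand_id))
  expect_s3_class(autoplot(r), "ggplot")
})
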