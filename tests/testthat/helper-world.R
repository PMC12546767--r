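# Shared fixtures, built in code.  Heavy objects (trained reference model)
# are cached per test run.

toy_assay_table <- function() {
  tibble::tibble(
    assay_id = c("A1", "A1", "A2", "A2"),
    target_group_id = c("T1", "T1", "T2", "T2"),
    ligand_id = c("l1", "l2", "l3", "l4"),
    value = c(1, 100, 5, 50),
    unit = "nM")
}

tiny_world <- function(seed = 11, ...) {
  generate_world(world_config(n_pockets = 6, n_ligands = 300, latent_dim = 6,
                              n_scaffold_clusters = 8, seed = seed, ...))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reference study conditions: 25 pockets, 2000 ligands, latent dim 8,
# 20 assays x 15 ligands in molar units, linear encoders, 500 steps, seed 42.
reference_run <- function(noise_sd = 0) {
  key <- paste0("ref_", noise_sd)
  cached(key, function() {
    w <- generate_world(world_config(n_pockets = 25, n_ligands = 2000,
                                     latent_dim = 8, noise_sd = noise_sd,
                                     seed = 42))
    feats <- world_features(w)
    train <- sample_assays(w, 20, 15, unit_mix = c(nM = 1), seed = 42)
    model <- pretrain(train, feats,
                      train_config(seed = 42, steps = 500, batch_assays = 10,
                                   ligands_per_assay = 10, d = 16, lr = 0.03))
    list(world = w, features = feats, train = train, model = model)
  })
}

# Held-out within-assay Spearman: fresh assays from the same world, scored
# against noiseless oracle potency.
heldout_spearman <- function(run, n_assays = 8, seed = 4242) {
  ev <- sample_assays(run$world, n_assays, 15, unit_mix = c(nM = 1),
                      seed = seed, noise_sd = 0)
  vapply(seq_len(nrow(ev$assays)), function(i) {
    a <- ev$assays$assay_id[i]
    mm <- dplyr::filter(ev$measurements, assay_id == a)
    pk <- ev$assays$pocket_ids[[i]][1]
    p <- drop(encode(run$model$params,
                     matrix(run$features$pockets[pk, ], 1), "pocket"))
    L <- encode(run$model$params,
                run$features$ligands[mm$ligand_id, , drop = FALSE], "ligand")
    s <- drop(ligspace:::cosine_matrix(matrix(p, 1), L))
    cor(s, oracle_potency(run$world, pk, mm$ligand_id), method = "spearman")
  }, numeric(1))
}

# All k-permutations (full) of 1..n as a matrix, one permutation per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Independent Plackett-Luce probability of ranking perm (best first) given
# item scores: closed form with suffix-sum denominators.
pl_probability <- function(scores, perm, tau = 1) {
  w <- exp(scores[perm] / tau)
  prod(w / rev(cumsum(rev(w))))
}

# A minimal PDB file with a reference heteroatom and residues at controlled
# distances from it.
write_toy_pdb <- function(path, shift = c(0, 0, 0), dists = c(4, 5, 9)) {
  fmt <- function(serial, name, resname, chain, resno, x, y, z, type = "ATOM") {
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial, name, resname, chain, resno,
            x + shift[1], y + shift[2], z + shift[3],
            substr(trimws(name), 1, 1))
  }
  lines <- c(
    fmt(1, "C1", "LIG", "A", 100, 0, 0, 0, type = "HETATM"),
    fmt(2, "CA", "ALA", "A", 1, dists[1], 0, 0),
    fmt(3, "CA", "GLY", "A", 2, 0, dists[2], 0),
    fmt(4, "CA", "LEU", "A", 3, 0, 0, dists[3]),
    "END")
  writeLines(lines, path)
  path
}

# Small trained run shared across test files.
small_training_run <- function() {
  cached("small_run", function() {
    w <- tiny_world()
    col <- sample_assays(w, 8, 10, unit_mix = c(nM = 1), seed = 2)
    feats <- world_features(w)
    m <- pretrain(col, feats, train_config(seed = 3, steps = 80, d = 8))
    list(world = w, col = col, feats = feats, model = m)
  })
}

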