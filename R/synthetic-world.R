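#' Configuration for a synthetic affinity landscape
#'
#' The generator manufactures a ground-truth world whose structure matches
#' what the model family assumes: pockets and ligands carry latent factors,
#' true potency is an affine function of their inner product (ligand factors
#' are unit length, so within-assay ranking by inner product coincides with
#' ranking by cosine similarity), ligands fall into scaffold clusters, and
#' every pocket has several slightly perturbed structure variants, mirroring
#' real affinity databases where each assay is tied to multiple pocket
#' structures.
#'
#' @param n_pockets,n_ligands,latent_dim,n_scaffold_clusters Positive counts.
#' @param noise_sd Measurement noise added per assay reading, in p-scale
#'   units (pIC50-like; 0.3 is a realistic inter-replicate spread).
#' @param active_fraction_target Fraction of pocket-ligand pairs whose true
#'   potency falls above the 10 uM activity boundary.
#' @param n_pocket_variants Structure variants per pocket.
#' @param variant_sd Factor perturbation applied to each variant.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the config.
#' @return A `world_config` list.
#' @export
world_config <- function(n_pockets = 25, n_ligands = 2000, latent_dim = 8,
                         n_scaffold_clusters = 25, noise_sd = 0.3,
                         active_fraction_target = 0.3,
                         n_pocket_variants = 3, variant_sd = 0.1, seed = 1) {
  cfg <- list(n_pockets = n_pockets, n_ligands = n_ligands,
              latent_dim = latent_dim,
              n_scaffold_clusters = n_scaffold_clusters,
              noise_sd = noise_sd,
              active_fraction_target = active_fraction_target,
              n_pocket_variants = n_pocket_variants,
              variant_sd = variant_sd, seed = as.integer(seed))
  counts <- c(n_pockets, n_ligands, latent_dim, n_scaffold_clusters,
              n_pocket_variants)
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("counts must be positive integers", class = "ligspace_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "ligspace_config_error")
  if (active_fraction_target <= 0 || active_fraction_target >= 1) {
    abort("active_fraction_target must lie in (0,1)",
          class = "ligspace_config_error")
  }
  structure(cfg, class = "world_config")
}

# p-scale activity boundary: 10 uM  <=>  -log10(1e-5) = 5
.active_boundary_p <- 5

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Generate a synthetic affinity world
#'
#' True potency is `a * <pocket_factor, ligand_factor> + b` with the affine
#' calibration chosen so that the configured fraction of all pocket-ligand
#' pairs lies above the 10 uM boundary (p-scale 5).  Scaffold clusters are a
#' k-means partition of the unit-norm ligand factors.  Pocket variants share
#' the parent's factor plus a small perturbation; each variant also carries a
#' synthetic amino-acid sequence derived from the parent's by point
#' mutations, so sequence alignment recovers the variant family structure.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` with factor matrices, scaffold assignments,
#'   pocket variants (factors and sequences) and the affine oracle
#'   coefficients.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(config$seed, {
    pk_ids <- sprintf("P%03d", seq_len(config$n_pockets))
    lig_ids <- sprintf("L%05d", seq_len(config$n_ligands))
    pocket_factors <- matrix(rnorm(config$n_pockets * config$latent_dim),
                             nrow = config$n_pockets,
                             dimnames = list(pk_ids, NULL))
    ligand_factors <- row_normalize(
      matrix(rnorm(config$n_ligands * config$latent_dim),
             nrow = config$n_ligands, dimnames = list(lig_ids, NULL)))

    km <- kmeans(ligand_factors,
                 centers = min(config$n_scaffold_clusters, config$n_ligands),
                 nstart = 3, iter.max = 50)
    scaffold_of <- setNames(km$cluster, lig_ids)

    ip <- pocket_factors %*% t(ligand_factors)
    slope <- 2 / stats::sd(ip)
    intercept <- .active_boundary_p -
      slope * unname(quantile(ip, 1 - config$active_fraction_target))

    variants <- purrr::map(seq_len(config$n_pockets), function(i) {
      v <- matrix(rep(pocket_factors[i, ], config$n_pocket_variants),
                  nrow = config$n_pocket_variants, byrow = TRUE)
      v + matrix(rnorm(length(v), sd = config$variant_sd), nrow = nrow(v))
    })
    variant_ids <- purrr::map(seq_len(config$n_pockets), function(i) {
      sprintf("%s.v%d", pk_ids[i], seq_len(config$n_pocket_variants))
    })
    for (i in seq_along(variants)) rownames(variants[[i]]) <- variant_ids[[i]]

    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    parent_seq <- vapply(pk_ids, function(p) {
      paste(sample(aa, 40, replace = TRUE), collapse = "")
    }, character(1))
    variant_seqs <- unlist(purrr::map(seq_len(config$n_pockets), function(i) {
      vapply(seq_len(config$n_pocket_variants), function(v) {
        s <- strsplit(parent_seq[i], "")[[1]]
        pos <- sample(seq_along(s), 2)
        s[pos] <- sample(aa, 2, replace = TRUE)
        paste(s, collapse = "")
      }, character(1))
    }))
    names(variant_seqs) <- unlist(variant_ids)

    structure(list(config = config,
                   pocket_ids = pk_ids, ligand_ids = lig_ids,
                   pocket_factors = pocket_factors,
                   ligand_factors = ligand_factors,
                   scaffold_of = scaffold_of,
                   pocket_variants = variants,
                   variant_ids = variant_ids,
                   pocket_sequences = c(parent_seq, variant_seqs),
                   oracle = list(slope = slope, intercept = intercept),
                   potency = slope * ip + intercept,
                   seed = config$seed),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d pockets (x%d variants), %d ligands,",
                     " %d scaffold clusters, active fraction %.3f\n"),
              length(x$pocket_ids), x$config$n_pocket_variants,
              length(x$ligand_ids), length(unique(x$scaffold_of)),
              mean(x$potency >= .active_boundary_p)))
  invisible(x)
}

strip_variant <- function(pocket_id) sub("\\.v[0-9]+$", "", pocket_id)

#' True potency of pocket-ligand pairs
#'
#' Deterministic ground-truth oracle on the p-scale.  Variant pocket ids
#' (`"P001.v2"`) resolve to their parent pocket.
#'
#' @param world A `synthetic_world`.
#' @param pocket_id,ligand_id Character vectors (recycled).
#' @return Numeric potency vector.
#' @export
oracle_potency <- function(world, pocket_id, ligand_id) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- strip_variant(pocket_id)
  pi <- match(p, world$pocket_ids)
  li <- match(ligand_id, world$ligand_ids)
  if (any(is.na(pi))) abort("unknown pocket id", class = "ligspace_domain_error")
  if (any(is.na(li))) abort("unknown ligand id", class = "ligspace_domain_error")
  world$potency[cbind(pi, li)]
}

#' Feature matrices for a synthetic world
#'
#' Synthetic entities are featurized by their latent factors (the
#' pass-through mode of [featurize()]).  Pocket rows cover parents and all
#' variants.
#'
#' @param world A `synthetic_world`.
#' @return List with `pockets` and `ligands` feature matrices (row names are
#'   entity ids).
#' @export
world_features <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  pk <- rbind(world$pocket_factors, do.call(rbind, world$pocket_variants))
  list(pockets = pk, ligands = world$ligand_factors)
}

# Assay-specific strictly increasing map onto [0, 100] for percent units.
percent_transform <- function(p_range) {
  gaps <- runif(5, 0.2, 1)
  y <- 100 * cumsum(gaps) / sum(gaps)
  y <- c(0, y[-5] * 0.99, 100)  # strictly increasing knots incl. endpoints
  x <- seq(p_range[1] - 1e-9, p_range[2] + 1e-9, length.out = length(y))
  function(p) stats::approx(x, y, xout = pmin(pmax(p, x[1]), x[length(x)]),
                            ties = "ordered")$y
}

#' Sample an assay collection from a synthetic world
#'
#' Each assay draws one pocket (listing a random nonempty subset of its
#' structure variants), samples ligands without replacement, and reports
#' oracle potency plus Gaussian noise pushed through an assay-specific
#' strictly monotone unit transform: molar units report the concentration
#' `10^-p`, density units the mass concentration, and percent units a random
#' increasing piecewise-linear map onto \[0, 100\].
#'
#' @param world A `synthetic_world`.
#' @param n_assays,ligands_per_assay Counts.
#' @param unit_mix Named probability weights over units
#'   (`nM`, `uM`, `mM`, `M`, `ug/mL`, `%`).
#' @param seed Integer seed.
#' @param noise_sd Measurement noise; defaults to the world's configured
#'   value.
#' @return An [ingest_assays()] collection whose pocket registry carries the
#'   variant factors.
#' @export
sample_assays <- function(world, n_assays, ligands_per_assay,
                          unit_mix = c(nM = 0.6, uM = 0.2, `%` = 0.1,
                                       `ug/mL` = 0.1),
                          seed = world$seed, noise_sd = world$config$noise_sd) {
  stopifnot(inherits(world, "synthetic_world"))
  if (ligands_per_assay > length(world$ligand_ids)) {
    abort("ligands_per_assay exceeds world size", class = "ligspace_config_error")
  }
  bad <- setdiff(names(unit_mix), .all_units)
  if (length(bad) > 0) abort(paste0("unknown unit in mix: ", bad),
                             class = "ligspace_config_error")
  withr::with_seed(derive_seed(seed, 101), {
    rows <- purrr::map(seq_len(n_assays), function(a) {
      pid <- sample(world$pocket_ids, 1)
      pidx <- match(pid, world$pocket_ids)
      n_var <- world$config$n_pocket_variants
      vars <- sort(sample(world$variant_ids[[pidx]], sample.int(n_var, 1)))
      ligs <- sort(sample(world$ligand_ids, ligands_per_assay))
      unit <- sample(names(unit_mix), 1, prob = unname(unit_mix))
      p <- oracle_potency(world, pid, ligs) + rnorm(length(ligs), sd = noise_sd)
      value <- switch(unit_class(unit),
        molar = 10^(-p) / unname(.molar_units[unit]),
        density = 10^(-p) / unname(.density_units[unit]),
        percent = percent_transform(range(p))(p))
      list(tbl = tibble(assay_id = sprintf("A%04d", a),
                        target_group_id = pid,
                        ligand_id = ligs, value = value, unit = unit,
                        measurement_kind = "synthetic"),
           pockets = tibble(assay_id = sprintf("A%04d", a), pocket_id = vars))
    })
    tbl <- bind_rows(purrr::map(rows, "tbl"))
    pocket_map <- bind_rows(purrr::map(rows, "pockets"))
    feats <- world_features(world)
    ligand_registry <- tibble(ligand_id = world$ligand_ids,
                              scaffold_cluster = unname(world$scaffold_of))
    pocket_registry <- tibble(pocket_id = rownames(feats$pockets),
                              parent = strip_variant(rownames(feats$pockets)),
                              sequence = unname(
                                world$pocket_sequences[rownames(feats$pockets)]))
    ingest_assays(tbl, pocket_map = pocket_map,
                  ligand_registry = ligand_registry,
                  pocket_registry = pocket_registry)
  })
}

#' Build a screening library with a fixed active:inactive ratio
#'
#' Mirrors realistic screening decks where actives are rare (default 1:200;
#' public experimental benchmarks go as far as 1:1,000).  Actives are world
#' ligands whose true potency for the pocket lies above the 10 uM boundary;
#' decoys lie below it.  With `scaffold_disjoint_decoys` the decoys are drawn
#' only from scaffold clusters containing no selected active, emulating
#' decoy sets curated to avoid analogue leakage.
#'
#' @param world A `synthetic_world`.
#' @param pocket_id Parent pocket (or variant) id.
#' @param n_actives Number of actives.
#' @param ratio Decoys per active.
#' @param seed Integer seed.
#' @param scaffold_disjoint_decoys Logical.
#' @param max_fresh Cap on freshly generated ligands when the world's pool
#'   is too small; requests needing more raise a generation error.
#' @return Tibble `ligand_id`, `label` (1 active / 0 decoy), `potency_true`,
#'   `scaffold_cluster`, ordered actives first then decoys, with attribute
#'   `"features"`: the library's ligand feature matrix (world factors plus
#'   any freshly generated ones).
#' @export
make_screening_library <- function(world, pocket_id, n_actives = 5,
                                   ratio = 200, seed = world$seed,
                                   scaffold_disjoint_decoys = FALSE,
                                   max_fresh = 10000) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- oracle_potency(world, pocket_id, world$ligand_ids)
  pf <- world$pocket_factors[strip_variant(pocket_id), ]
  nearest_cluster <- function(feats) {
    centers <- rowsum(world$ligand_factors, world$scaffold_of) /
      as.vector(table(world$scaffold_of))
    d2 <- outer(rowSums(feats^2), rowSums(centers^2), "+") -
      2 * feats %*% t(centers)
    as.integer(rownames(centers))[max.col(-d2)]
  }
  # rejection-sample fresh unit-norm ligands on the requested side of the
  # activity boundary when the world's own pool runs short
  sample_fresh <- function(n_needed, side, salt) {
    got <- matrix(numeric(0), 0, ncol(world$ligand_factors))
    tries <- 0
    while (nrow(got) < n_needed) {
      tries <- tries + 1
      if (tries > 200) {
        abort("cannot generate enough fresh ligands for this request",
              class = "ligspace_generation_error")
      }
      cand <- row_normalize(matrix(rnorm(5000 * ncol(world$ligand_factors)),
                                   nrow = 5000))
      pot <- drop(cand %*% pf) * world$oracle$slope + world$oracle$intercept
      keep <- if (side == "active") pot >= .active_boundary_p
              else pot < .active_boundary_p
      got <- rbind(got, cand[keep, , drop = FALSE])
    }
    got[seq_len(n_needed), , drop = FALSE]
  }
  n_decoys <- n_actives * ratio
  if (n_actives + n_decoys - length(world$ligand_ids) > max_fresh) {
    abort("request exceeds the fresh-ligand generation cap",
          class = "ligspace_generation_error")
  }
  withr::with_seed(derive_seed(seed, 202), {
    act_pool <- world$ligand_ids[p >= .active_boundary_p]
    dec_pool <- world$ligand_ids[p < .active_boundary_p]
    fresh <- list()
    actives <- sort(sample(act_pool, min(n_actives, length(act_pool))))
    act_clusters <- unique(world$scaffold_of[actives])
    if (length(actives) < n_actives) {
      fa <- sample_fresh(n_actives - length(actives), "active", 1)
      rownames(fa) <- sprintf("XA%05d", seq_len(nrow(fa)))
      fresh$act <- fa
    }
    if (scaffold_disjoint_decoys) {
      dec_pool <- dec_pool[!world$scaffold_of[dec_pool] %in% act_clusters]
    }
    decoys <- sort(sample(dec_pool, min(n_decoys, length(dec_pool))))
    if (length(decoys) < n_decoys) {
      fd <- sample_fresh(n_decoys - length(decoys), "decoy", 2)
      rownames(fd) <- sprintf("XD%05d", seq_len(nrow(fd)))
      if (scaffold_disjoint_decoys) {
        fd <- fd[!nearest_cluster(fd) %in% act_clusters, , drop = FALSE]
        while (nrow(fd) < n_decoys - length(decoys)) {
          extra <- sample_fresh(n_decoys - length(decoys) - nrow(fd),
                                "decoy", 3)
          extra <- extra[!nearest_cluster(extra) %in% act_clusters, ,
                         drop = FALSE]
          fd <- rbind(fd, extra)
        }
        fd <- fd[seq_len(n_decoys - length(decoys)), , drop = FALSE]
        rownames(fd) <- sprintf("XD%05d", seq_len(nrow(fd)))
      }
      fresh$dec <- fd
    }
  })
  fresh_mat <- do.call(rbind, fresh)
  all_act <- c(actives, rownames(fresh$act))
  all_dec <- c(decoys, rownames(fresh$dec))
  ids <- c(all_act, all_dec)
  world_ids <- ids[ids %in% world$ligand_ids]
  feats <- rbind(world$ligand_factors[world_ids, , drop = FALSE], fresh_mat)
  feats <- feats[ids, , drop = FALSE]
  pot_of <- function(id_set, m) {
    vapply(id_set, function(i) {
      if (i %in% world$ligand_ids) oracle_potency(world, pocket_id, i)
      else drop(m[i, ] %*% pf) * world$oracle$slope + world$oracle$intercept
    }, numeric(1))
  }
  cl <- rep(NA_integer_, length(ids))
  in_world <- ids %in% world$ligand_ids
  cl[in_world] <- unname(world$scaffold_of[ids[in_world]])
  if (any(!in_world)) {
    cl[!in_world] <- nearest_cluster(feats[!in_world, , drop = FALSE])
  }
  out <- tibble(ligand_id = ids,
                label = rep(c(1L, 0L), c(length(all_act), length(all_dec))),
                potency_true = unname(pot_of(ids, feats)),
                scaffold_cluster = cl)
  attr(out, "features") <- feats
  out
}

#' Manufacture a congeneric ligand series for one pocket
#'
#' A congeneric series models hit-to-lead chemistry: all members share one
#' scaffold and differ by small substituents.  Members are small
#' perturbations of a potent parent ligand's factor (renormalized to unit
#' length), all assigned the parent's scaffold cluster; true potencies are
#' read from the oracle, and measurements add the world's assay noise on the
#' p-scale, reported in nM.
#'
#' @param world A `synthetic_world`.
#' @param pocket_id Pocket the series is optimized against.
#' @param n_ligands Series size (default 29, a typical per-target count in
#'   hit-to-lead benchmark sets).
#' @param seed Integer seed.
#' @param perturb_sd Factor perturbation scale (controls how congeneric the
#'   series is; pairwise cosine stays above ~0.9 at the default).
#' @param local_sar_sd Strength (p-scale standard deviation) of the
#'   series-specific structure-activity component: a linear response to the
#'   substituent perturbations along a random pocket-specific direction,
#'   added on top of the global landscape.  Real congeneric SAR is exactly
#'   this kind of fine-grained signal a globally trained model cannot know
#'   zero-shot but can pick up from a few measured members; set to 0 for a
#'   series fully determined by the global oracle.
#' @param cosine_floor Minimum pairwise feature cosine among members;
#'   perturbations are shrunk deterministically until the floor holds.
#' @return A `congeneric_series`: list with `measurements` (assay table
#'   rows), `features` (member factor matrix), `truth` (tibble with true
#'   potencies), `scaffold_cluster`, `pocket_id`.
#' @export
make_congeneric_series <- function(world, pocket_id, n_ligands = 29,
                                   seed = world$seed, perturb_sd = 0.15,
                                   local_sar_sd = 1, cosine_floor = 0.8) {
  stopifnot(inherits(world, "synthetic_world"))
  if (n_ligands < 2) abort("a series needs at least 2 ligands",
                           class = "ligspace_config_error")
  p_all <- oracle_potency(world, pocket_id, world$ligand_ids)
  # parent: a clearly active hit (90th percentile potency for this pocket)
  parent_id <- world$ligand_ids[which.min(abs(p_all - quantile(p_all, 0.9)))]
  parent <- world$ligand_factors[parent_id, ]
  withr::with_seed(derive_seed(seed, 303), {
    base <- matrix(rep(parent, n_ligands), nrow = n_ligands, byrow = TRUE)
    eps <- matrix(rnorm(n_ligands * length(parent), sd = perturb_sd),
                  nrow = n_ligands)
    feats <- row_normalize(base + eps)
    # enforce the congeneric cosine floor by shrinking the perturbations
    repeat {
      cc <- cosine_matrix(feats, feats)
      if (all(cc[upper.tri(cc)] > cosine_floor)) break
      eps <- eps * 0.8
      feats <- row_normalize(base + eps)
    }
    rownames(feats) <- sprintf("%s.s%02d", parent_id, seq_len(n_ligands))
    pf <- world$pocket_factors[strip_variant(pocket_id), ]
    p_true <- drop(feats %*% pf) * world$oracle$slope + world$oracle$intercept
    if (local_sar_sd > 0) {
      v <- rnorm(length(parent)); v <- v / sqrt(sum(v^2))
      local <- drop((feats - matrix(parent, n_ligands, length(parent),
                                    byrow = TRUE)) %*% v)
      if (sd(local) > 0) local <- local / sd(local) * local_sar_sd
      p_true <- p_true + local
    }
    value_nM <- 10^(9 - (p_true + rnorm(n_ligands, sd = world$config$noise_sd)))
  })
  structure(list(
    measurements = tibble(assay_id = paste0("series:", pocket_id),
                          target_group_id = strip_variant(pocket_id),
                          ligand_id = rownames(feats),
                          value = value_nM, unit = "nM",
                          measurement_kind = "synthetic-series"),
    features = feats,
    truth = tibble(ligand_id = rownames(feats), potency_true = p_true),
    scaffold_cluster = unname(world$scaffold_of[parent_id]),
    pocket_id = pocket_id), class = "congeneric_series")
}
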