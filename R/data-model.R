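#' Ingest an assay table into a validated collection
#'
#' Affinity data are organised by assay: one experimental procedure measuring
#' several ligands against a single protein target.  Values are comparable
#' only within an assay (assay formats, conditions and measurement kinds
#' differ), so the collection keeps measurements grouped by `assay_id` and all
#' downstream ranking is within-assay.
#'
#' @param raw_table Data frame with columns `assay_id`, `target_group_id`,
#'   `ligand_id`, `value`, `unit` and optionally `relation` and
#'   `measurement_kind`.  `unit` must be one of `nM`, `uM`, `mM`, `M`,
#'   `ug/mL`, `%`.  Rows with a qualified relation (`"<"` or `">"`) are
#'   dropped with a warning; only exact (`"="` or missing) values enter the
#'   collection.
#' @param pocket_map Optional data frame `assay_id`, `pocket_id` listing the
#'   pocket-structure variants tied to each assay.  When absent every assay
#'   is assigned a single placeholder pocket named after its target group.
#' @param ligand_registry,pocket_registry Optional tibbles keyed by
#'   `ligand_id` / `pocket_id` carrying structure records (e.g. `smiles`,
#'   `sequence`, feature columns).  Registries are checked for coverage.
#'
#' @return An `assay_collection`: list with `measurements` (tibble),
#'   `assays` (one row per assay: `assay_id`, `target_group_id`, `unit`,
#'   `pocket_ids` list-column, `n_ligands`), `ligand_registry`,
#'   `pocket_registry`.
#' @export
ingest_assays <- function(raw_table, pocket_map = NULL,
                          ligand_registry = NULL, pocket_registry = NULL) {
  required <- c("assay_id", "target_group_id", "ligand_id", "value", "unit")
  missing_cols <- setdiff(required, names(raw_table))
  if (length(missing_cols) > 0) {
    abort(paste0("assay table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ligspace_schema_error")
  }
  tbl <- as_tibble(raw_table)
  if (nrow(tbl) == 0) {
    abort("assay table has no rows", class = "ligspace_schema_error")
  }
  tbl <- mutate(tbl,
                assay_id = as.character(.data$assay_id),
                target_group_id = as.character(.data$target_group_id),
                ligand_id = as.character(.data$ligand_id),
                value = as.numeric(.data$value),
                unit = as.character(.data$unit))
  if (!"measurement_kind" %in% names(tbl)) tbl$measurement_kind <- NA_character_

  if ("relation" %in% names(tbl)) {
    rel <- ifelse(is.na(tbl$relation) | tbl$relation == "", "=", tbl$relation)
    qualified <- rel != "="
    if (any(qualified)) {
      warn(sprintf("dropping %d row(s) with qualified relations ('<'/'>')",
                   sum(qualified)))
      tbl <- tbl[!qualified, , drop = FALSE]
    }
    tbl$relation <- NULL
    if (nrow(tbl) == 0) {
      abort("no exact-valued rows remain after dropping qualified relations",
            class = "ligspace_validation_error")
    }
  }

  bad_unit <- setdiff(unique(tbl$unit), .all_units)
  if (length(bad_unit) > 0) {
    abort(paste0("unknown unit(s): ", paste(bad_unit, collapse = ", ")),
          class = "ligspace_validation_error")
  }
  if (any(!is.finite(tbl$value))) {
    abort("non-finite affinity values present", class = "ligspace_validation_error")
  }
  bad_molar <- unit_class(tbl$unit) %in% c("molar", "density") & tbl$value <= 0
  if (any(bad_molar)) {
    abort("molar/density values must be strictly positive",
          class = "ligspace_validation_error")
  }

  dup <- tbl |>
    dplyr::count(.data$assay_id, .data$ligand_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (assay, ligand) pair(s): ",
                 paste(paste0(dup$assay_id, "/", dup$ligand_id), collapse = ", ")),
          class = "ligspace_validation_error")
  }

  unit_check <- tbl |>
    group_by(.data$assay_id) |>
    summarise(n_units = dplyr::n_distinct(.data$unit),
              unit = .data$unit[1],
              target_group_id = .data$target_group_id[1],
              n_ligands = n(), .groups = "drop")
  mixed <- filter(unit_check, .data$n_units > 1)
  if (nrow(mixed) > 0) {
    abort(paste0("mixed units within assay(s): ",
                 paste(mixed$assay_id, collapse = ", ")),
          class = "ligspace_validation_error")
  }

  if (is.null(pocket_map)) {
    pocket_map <- unit_check |>
      mutate(pocket_id = paste0("pocket:", .data$target_group_id)) |>
      select("assay_id", "pocket_id")
  } else {
    pocket_map <- as_tibble(pocket_map) |>
      mutate(assay_id = as.character(.data$assay_id),
             pocket_id = as.character(.data$pocket_id)) |>
      distinct()
    uncovered <- setdiff(unit_check$assay_id, pocket_map$assay_id)
    if (length(uncovered) > 0) {
      abort(paste0("assay(s) without any pocket: ",
                   paste(uncovered, collapse = ", ")),
            class = "ligspace_validation_error")
    }
  }

  assays <- unit_check |>
    select("assay_id", "target_group_id", "unit", "n_ligands") |>
    left_join(pocket_map |> group_by(.data$assay_id) |>
                summarise(pocket_ids = list(sort(unique(.data$pocket_id))),
                          .groups = "drop"),
              by = "assay_id") |>
    arrange(.data$assay_id)

  if (is.null(ligand_registry)) {
    ligand_registry <- tibble(ligand_id = sort(unique(tbl$ligand_id)))
  } else {
    ligand_registry <- as_tibble(ligand_registry)
    missing_lig <- setdiff(unique(tbl$ligand_id), ligand_registry$ligand_id)
    if (length(missing_lig) > 0) {
      abort(paste0("ligand(s) missing from registry: ",
                   paste(head(missing_lig, 5), collapse = ", ")),
            class = "ligspace_validation_error")
    }
  }
  all_pockets <- unique(unlist(assays$pocket_ids))
  if (is.null(pocket_registry)) {
    pocket_registry <- tibble(pocket_id = sort(all_pockets))
  } else {
    pocket_registry <- as_tibble(pocket_registry)
    missing_p <- setdiff(all_pockets, pocket_registry$pocket_id)
    if (length(missing_p) > 0) {
      abort(paste0("pocket(s) missing from registry: ",
                   paste(head(missing_p, 5), collapse = ", ")),
            class = "ligspace_validation_error")
    }
  }

  structure(list(measurements = arrange(tbl, .data$assay_id, .data$ligand_id),
                 assays = assays,
                 ligand_registry = ligand_registry,
                 pocket_registry = pocket_registry),
            class = "assay_collection")
}

#' @export
print.assay_collection <- function(x, ...) {
  cat(sprintf("<assay_collection> %d assays, %d measurements, %d ligands, %d pockets\n",
              nrow(x$assays), nrow(x$measurements),
              nrow(x$ligand_registry), nrow(x$pocket_registry)))
  invisible(x)
}

#' Convert reported affinity values to the canonical potency scale
#'
#' The internal canonical scale is "larger = stronger": molar-class values
#' (IC50/Ki/Kd concentrations) map to p-scale `-log10(mol/L)`; density values
#' map to `-log10(g/L)` and are flagged `density` (orderable within an assay,
#' no molar threshold without a molecular weight); percent readouts keep their
#' reported value and are flagged `rank_only` (ordering only, no absolute
#' scale).
#'
#' @param value Numeric vector of reported values.
#' @param unit Character vector (recycled) of units.
#' @return Tibble with `value`, `unit`, `potency`, `scale` in
#'   `c("molar", "density", "rank_only")`.
#' @examples
#' to_potency(c(1, 10), c("nM", "uM"))  # 9 and 5
#' @export
to_potency <- function(value, unit) {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  cls <- unit_class(unit)
  if (any(is.na(cls))) {
    abort(paste0("unknown unit(s): ",
                 paste(unique(unit[is.na(cls)]), collapse = ", ")),
          class = "ligspace_validation_error")
  }
  if (any(cls %in% c("molar", "density") & (!is.finite(value) | value <= 0))) {
    abort("molar/density values must be finite and strictly positive",
          class = "ligspace_domain_error")
  }
  potency <- rep(NA_real_, n)
  m <- cls == "molar"
  potency[m] <- -log10(value[m] * unname(.molar_units[unit[m]]))
  d <- cls == "density"
  potency[d] <- -log10(value[d] * unname(.density_units[unit[d]]))
  p <- cls == "percent"
  potency[p] <- value[p]
  tibble(value = value, unit = unit, potency = potency,
         scale = dplyr::if_else(m, "molar", dplyr::if_else(d, "density", "rank_only")))
}

#' Label target-ligand pairs active or inactive at a molar threshold
#'
#' A measured pocket-group/ligand pair is active when its strongest
#' molar-class measurement is at or below the threshold concentration
#' (default 10 uM, boundary inclusive).  Percent- and density-unit
#' measurements never yield an absolute label; the corresponding pairs are
#' reported `unlabeled`.  Labels depend only on the (target group, ligand)
#' measurements, never on assay membership.
#'
#' @param collection An `assay_collection`.
#' @param threshold_molar Activity boundary in mol/L (default `1e-5`).
#' @return Tibble `target_group_id`, `ligand_id`, `label` with label in
#'   `c("active", "inactive", "unlabeled")`, one row per measured pair.
#' @export
label_activity <- function(collection, threshold_molar = 1e-5) {
  stopifnot(inherits(collection, "assay_collection"))
  thr_p <- -log10(threshold_molar)
  pot <- to_potency(collection$measurements$value, collection$measurements$unit)
  collection$measurements |>
    mutate(potency = pot$potency, scale = pot$scale) |>
    group_by(.data$target_group_id, .data$ligand_id) |>
    summarise(best = if (any(.data$scale == "molar"))
                max(.data$potency[.data$scale == "molar"]) else NA_real_,
              .groups = "drop") |>
    mutate(label = dplyr::case_when(
      is.na(.data$best) ~ "unlabeled",
      .data$best >= thr_p - 1e-9 ~ "active",  # boundary inclusive (<= 10 uM)
      TRUE ~ "inactive")) |>
    select("target_group_id", "ligand_id", "label")
}

#' Rank the ligands of one assay best-first
#'
#' Ligands are ordered by decreasing potency on the canonical scale (percent
#' readouts order by reported value, higher = more inhibition).  Ligands with
#' exactly equal values form one tie group; order within a tie group is
#' stable by `ligand_id` so rankings are deterministic.
#'
#' @param assay Data frame with columns `ligand_id`, `value`, `unit` (one
#'   assay's measurements), or an `assay_collection` plus `assay_id`.
#' @param assay_id When `assay` is a collection, which assay to rank.
#' @return Tibble `ligand_id`, `potency`, `scale`, `rank`, `tie_group`,
#'   ordered best-first.
#' @export
rank_ligands <- function(assay, assay_id = NULL) {
  if (inherits(assay, "assay_collection")) {
    stopifnot(!is.null(assay_id))
    assay <- filter(assay$measurements, .data$assay_id == !!assay_id)
    if (nrow(assay) == 0) abort(paste0("no such assay: ", assay_id),
                                class = "ligspace_validation_error")
  }
  stopifnot(nrow(assay) >= 1)
  if (length(unique(assay$unit)) > 1) {
    abort("assay mixes units; values are not orderable",
          class = "ligspace_validation_error")
  }
  pot <- to_potency(assay$value, assay$unit)
  if (any(!is.finite(pot$potency))) {
    abort("non-finite potency", class = "ligspace_domain_error")
  }
  out <- tibble(ligand_id = as.character(assay$ligand_id),
                potency = pot$potency, scale = pot$scale) |>
    arrange(dplyr::desc(.data$potency), .data$ligand_id) |>
    mutate(rank = row_number(),
           tie_group = match(.data$potency, unique(.data$potency)))
  out
}

#' Serialize / read back an assay collection
#'
#' Canonical CSV round-trip for the measurement table (sorted rows, full
#' float precision) plus the assay-to-pocket map.
#'
#' @param collection An `assay_collection`.
#' @param path Output CSV path for measurements; the pocket map is written to
#'   `<path>.pockets.csv`.
#' @return `write_assay_collection` returns `path` invisibly;
#'   `read_assay_collection` returns an `assay_collection`.
#' @export
write_assay_collection <- function(collection, path) {
  stopifnot(inherits(collection, "assay_collection"))
  readr::write_csv(collection$measurements, path)
  pm <- collection$assays |>
    select("assay_id", "pocket_ids") |>
    tidyr::unnest("pocket_ids") |>
    rename(pocket_id = "pocket_ids")
  readr::write_csv(pm, paste0(path, ".pockets.csv"))
  invisible(path)
}

#' @rdname write_assay_collection
#' @export
read_assay_collection <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           value = readr::col_double(),
                           .default = readr::col_character()))
  pm_path <- paste0(path, ".pockets.csv")
  pm <- if (file.exists(pm_path)) {
    readr::read_csv(pm_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else NULL
  ingest_assays(tbl, pocket_map = pm)
}
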