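#' Read a ligand registry from a SMILES list or SDF file
#'
#' `.smi` files are whitespace-delimited `id SMILES` lines (blank lines and
#' `#` comments skipped); `.sdf` files are parsed with ChemmineR and keyed
#' by molecule name.  Every structure is validated; parse failures are
#' collected and reported in a single warning, duplicate ids are an error,
#' and a file with zero valid ligands is an error.
#'
#' @param path Input file (`.smi`/`.txt` or `.sdf`).
#' @return Tibble `ligand_id`, `smiles` with attribute `"failures"`
#'   (character vector of failed ids).
#' @export
read_ligands <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "ligspace_input_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    if (!requireNamespace("ChemmineR", quietly = TRUE)) {
      abort("ChemmineR is required to read SDF files",
            class = "ligspace_config_error")
    }
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    valid <- ChemmineR::validSDF(sdf)
    tbl <- tibble(ligand_id = as.character(ids),
                  smiles = NA_character_, ok = valid)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) abort("empty ligand file",
                                  class = "ligspace_input_error")
    parts <- strsplit(lines, "[ \t]+")
    tbl <- tibble(ligand_id = vapply(parts, `[`, character(1), 1),
                  smiles = vapply(parts, function(p)
                    if (length(p) >= 2) p[2] else NA_character_, character(1)))
    tbl$ok <- !is.na(tbl$smiles) &
      vapply(tbl$smiles, function(s)
        isTRUE(tryCatch({ validate_smiles(s); TRUE },
                        error = function(e) FALSE)), logical(1))
  }
  dup <- tbl$ligand_id[duplicated(tbl$ligand_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate ligand id(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "ligspace_input_error")
  }
  failures <- tbl$ligand_id[!tbl$ok]
  if (length(failures) > 0) {
    warn(paste0("failed to parse ligand(s): ",
                paste(failures, collapse = ", ")))
  }
  out <- tbl |> filter(.data$ok) |> select("ligand_id", "smiles")
  if (nrow(out) == 0) abort("no valid ligands in file",
                            class = "ligspace_input_error")
  attr(out, "failures") <- failures
  out
}

#' Extract a binding pocket from a PDB structure
#'
#' The pocket is the set of residues with any heavy atom within `radius`
#' angstroms of any heavy atom of the reference (a bound ligand residue
#' name, e.g. a HET code, or an explicit residue list which bypasses the
#' distance rule).  Coordinates and residue numbering follow the source
#' PDB; the rule is invariant under rigid motion of all coordinates.
#'
#' @param pdb_path Path to a PDB file.
#' @param reference Either a character HET residue name present in the file
#'   or a data frame with columns `chain`, `resno` selecting residues
#'   explicitly.
#' @param radius Heavy-atom distance cutoff in angstroms (default 6).
#' @param pocket_id Identifier for the extracted pocket.
#' @return A `pocket_structure`: `pocket_id`, `residues` tibble (`chain`,
#'   `resno`, `resid`, one row per residue), `sequence` (one-letter),
#'   `atoms` tibble of pocket heavy atoms, `source`.
#' @export
extract_pocket <- function(pdb_path, reference, radius = 6,
                           pocket_id = basename(pdb_path)) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- as_tibble(pdb$atom)
  heavy <- at |> filter(toupper(.data$elesy) != "H" | is.na(.data$elesy))
  if (is.data.frame(reference)) {
    res <- heavy |>
      dplyr::semi_join(as_tibble(reference) |>
                         mutate(chain = as.character(.data$chain),
                                resno = as.integer(.data$resno)),
                       by = c("chain", "resno"))
    if (nrow(res) == 0) abort("explicit residue list matches nothing",
                              class = "ligspace_input_error")
    pocket_atoms <- res
  } else {
    ref <- heavy |> filter(.data$resid == reference)
    if (nrow(ref) == 0) {
      abort(paste0("reference residue '", reference, "' absent from file"),
            class = "ligspace_input_error")
    }
    prot <- heavy |> filter(.data$type == "ATOM")
    if (nrow(prot) == 0) abort("no protein atoms in file",
                               class = "ligspace_input_error")
    d2 <- outer(prot$x, ref$x, "-")^2 + outer(prot$y, ref$y, "-")^2 +
      outer(prot$z, ref$z, "-")^2
    near <- apply(d2 <= radius^2, 1, any)
    sel <- prot[near, , drop = FALSE] |> distinct(.data$chain, .data$resno)
    pocket_atoms <- prot |> dplyr::semi_join(sel, by = c("chain", "resno"))
  }
  residues <- pocket_atoms |>
    distinct(.data$chain, .data$resno, .data$resid) |>
    arrange(.data$chain, .data$resno)
  if (nrow(residues) == 0) abort("empty pocket (no residues within radius)",
                                 class = "ligspace_input_error")
  seq1 <- paste(bio3d::aa321(residues$resid), collapse = "")
  seq1 <- gsub("[^A-Z]", "X", seq1)
  structure(list(pocket_id = pocket_id,
                 residues = residues,
                 sequence = seq1,
                 atoms = pocket_atoms |>
                   select("chain", "resno", "resid", "elety", "x", "y", "z"),
                 source = pdb_path),
            class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat(sprintf("<pocket_structure> %s: %d residues, sequence %s\n",
              x$pocket_id, nrow(x$residues), x$sequence))
  invisible(x)
}
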