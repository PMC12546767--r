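#' Featurize a ligand or pocket record
#'
#' Deterministic front-end of the reference encoders.  Three modes:
#' \describe{
#'   \item{synthetic factor}{a record with a `factor` field passes its latent
#'     factor through unchanged;}
#'   \item{ligand SMILES}{a record with a `smiles` field is validated
#'     (Open Babel via ChemmineR when available, otherwise a syntactic
#'     check), canonicalized, and hashed into substructure k-gram counts;}
#'   \item{pocket sequence/residues}{a record with a `sequence` (or residue
#'     table) yields residue composition plus hashed dipeptide counts.}
#' }
#'
#' @param entity A list-like record with `ligand_id` or `pocket_id` and one
#'   of `factor`, `smiles`, `sequence`.
#' @param n_bits Width of the hashed count block (ligand and dipeptide
#'   features).
#' @return Named numeric feature vector with attribute `entity_id`.
#' @export
featurize <- function(entity, n_bits = 64) {
  id <- entity$ligand_id %||% entity$pocket_id %||% entity$id
  if (is.null(id)) abort("entity has no id", class = "ligspace_input_error")
  if (!is.null(entity$factor)) {
    v <- as.numeric(entity$factor)
  } else if (!is.null(entity$smiles)) {
    v <- fingerprint_smiles(entity$smiles, id = id, n_bits = n_bits)
  } else if (!is.null(entity$sequence) || !is.null(entity$residues)) {
    seqc <- entity$sequence %||% paste(entity$residues$aa, collapse = "")
    v <- pocket_composition_features(seqc, n_bits = n_bits)
  } else {
    abort(sprintf("entity '%s' has no featurizable field", id),
          class = "ligspace_input_error")
  }
  if (any(!is.finite(v))) abort("non-finite features",
                                class = "ligspace_input_error")
  attr(v, "entity_id") <- as.character(id)
  v
}

# Syntactic SMILES sanity check: balanced (), [], valid characters,
# nonempty, no dangling bond/open branch.
smiles_syntax_ok <- function(smiles) {
  if (!nzchar(smiles)) return(FALSE)
  chars <- strsplit(smiles, "")[[1]]
  # POSIX bracket expression: ']' first, '-' last, backslash literal
  if (grepl("[^][A-Za-z0-9@+=#$/\\%*:.()-]", smiles)) return(FALSE)
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") { depth <- depth - 1; if (depth < 0) return(FALSE) }
  }
  if (depth != 0) return(FALSE)
  br <- cumsum((chars == "[") - (chars == "]"))
  if (any(br > 1) || any(br < 0) || br[length(br)] != 0) return(FALSE)
  if (grepl("[(=#]$", smiles)) return(FALSE)
  TRUE
}

# Validate and canonicalize in one pass.  Syntactic screening first; when
# Open Babel (ChemmineOB) is available it is the authority: an invalid
# SMILES converts to an empty canonical string.
validate_smiles <- function(smiles, id = smiles) {
  invisible(canonical_smiles(smiles, id = id))
}

canonical_smiles <- function(smiles, id = smiles) {
  fail <- function() {
    abort(sprintf("unparseable SMILES for ligand '%s': %s", id, smiles),
          class = "ligspace_input_error")
  }
  if (!smiles_syntax_ok(smiles)) fail()
  if (requireNamespace("ChemmineOB", quietly = TRUE)) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
      error = function(e) "")
    can <- strsplit(trimws(out), "[ \t\n]")[[1]][1]
    if (is.na(can) || !nzchar(can)) fail()
    return(can)
  }
  smiles
}

# Hashed k-gram (k = 1..3) counts over the canonical SMILES string: a cheap,
# deterministic stand-in for substructure fingerprints.
hash_string <- function(s, n_bits) {
  codes <- utf8ToInt(s)
  (sum(codes * 31^(seq_along(codes) - 1) %% 1e9) %% n_bits) + 1
}

fingerprint_smiles <- function(smiles, id = smiles, n_bits = 64) {
  can <- canonical_smiles(smiles, id = id)
  chars <- strsplit(can, "")[[1]]
  v <- numeric(n_bits)
  for (k in 1:3) {
    if (length(chars) < k) break
    for (i in seq_len(length(chars) - k + 1)) {
      g <- paste(chars[i:(i + k - 1)], collapse = "")
      j <- hash_string(g, n_bits)
      v[j] <- v[j] + 1
    }
  }
  names(v) <- sprintf("fp%03d", seq_len(n_bits))
  v
}

pocket_composition_features <- function(sequence, n_bits = 64) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) abort("empty pocket sequence",
                                class = "ligspace_input_error")
  chars[!chars %in% aa] <- "X"
  comp <- vapply(aa, function(a) sum(chars == a), numeric(1)) / length(chars)
  v2 <- numeric(n_bits)
  if (length(chars) >= 2) {
    for (i in seq_len(length(chars) - 1)) {
      j <- hash_string(paste0(chars[i], chars[i + 1]), n_bits)
      v2[j] <- v2[j] + 1
    }
    v2 <- v2 / (length(chars) - 1)
  }
  out <- c(comp, v2)
  names(out) <- c(paste0("aa_", aa), sprintf("dp%03d", seq_len(n_bits)))
  out
}
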