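#' Persist and reload an embedding store
#'
#' Screening pre-computes and stores entity embeddings so that scoring a
#' library is a similarity lookup.  The store is a plain-text matrix (17
#' significant digits, bit-exact double round-trip) plus a JSON sidecar
#' recording entity ids, the embedding dimension and a hash of the encoder
#' parameters; reading into a different model context fails fast.
#'
#' @param path Store path prefix; writes `<path>.values.txt` and
#'   `<path>.json`.
#' @param embeddings Numeric matrix with entity ids as row names (may have
#'   zero rows).
#' @param params Encoder params (hashed into the sidecar) or a precomputed
#'   hash string.
#' @return `write_embedding_store` returns `path` invisibly.
#' @export
write_embedding_store <- function(path, embeddings, params) {
  stopifnot(is.matrix(embeddings))
  hash <- if (is.character(params)) params else params_hash(params)
  ids <- rownames(embeddings) %||% character(0)
  if (nrow(embeddings) > 0 && length(ids) != nrow(embeddings)) {
    abort("embeddings must carry entity ids as row names",
          class = "ligspace_contract_error")
  }
  lines <- apply(embeddings, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(as.character(lines), paste0(path, ".values.txt"))
  jsonlite::write_json(
    list(ids = ids, d = ncol(embeddings), n = nrow(embeddings),
         params_hash = hash),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding_store
#' @param expect_params Optional encoder params (or hash) the store must
#'   match; mismatch raises a stale-cache error.
#' @return `read_embedding_store` returns the embedding matrix with a
#'   `params_hash` attribute.
#' @export
read_embedding_store <- function(path, expect_params = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expect_params)) {
    want <- if (is.character(expect_params)) expect_params
            else params_hash(expect_params)
    if (!identical(want, meta$params_hash)) {
      abort(sprintf("stale embedding cache: store hash %s, expected %s",
                    meta$params_hash, want),
            class = "ligspace_stale_cache_error")
    }
  }
  lines <- readLines(paste0(path, ".values.txt"))
  m <- if (length(lines) == 0) {
    matrix(numeric(0), nrow = 0, ncol = meta$d)
  } else {
    do.call(rbind, lapply(strsplit(lines, " "), as.numeric))
  }
  rownames(m) <- if (meta$n > 0) meta$ids else NULL
  attr(m, "params_hash") <- meta$params_hash
  m
}
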