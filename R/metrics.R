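#' Construct a screening ranking
#'
#' Canonical container for virtual-screening evaluation: ligands sorted by
#' decreasing score, score ties broken stably by `ligand_id` (documented
#' because the enrichment factor at small fractions is tie-sensitive).
#'
#' @param x Data frame with columns `ligand_id`, `score` and binary `label`
#'   (1 = active).
#' @return A `screen_ranking` tibble with a `rank` column.
#' @export
screen_ranking <- function(x) {
  stopifnot(all(c("ligand_id", "score", "label") %in% names(x)))
  if (any(!is.finite(x$score))) abort("non-finite scores",
                                      class = "ligspace_domain_error")
  out <- as_tibble(x) |>
    mutate(ligand_id = as.character(.data$ligand_id),
           label = as.integer(.data$label)) |>
    arrange(dplyr::desc(.data$score), .data$ligand_id) |>
    mutate(rank = row_number())
  class(out) <- c("screen_ranking", class(out))
  out
}

#' Enrichment factor at a fraction of the ranked library
#'
#' Ratio of the active rate in the top `ceil(fraction * N)` ligands to the
#' library-wide active rate; 1 is random, `min(N/n, 1/fraction)` is the
#' ceiling.
#'
#' @param ranking A [screen_ranking()] (or coercible data frame).
#' @param fraction Top fraction in (0, 1\].
#' @return Scalar enrichment factor.
#' @export
enrichment_factor <- function(ranking, fraction = 0.01) {
  r <- if (inherits(ranking, "screen_ranking")) ranking else screen_ranking(ranking)
  stopifnot(fraction > 0, fraction <= 1)
  N <- nrow(r); n <- sum(r$label)
  if (n < 1) abort("ranking contains no actives", class = "ligspace_domain_error")
  top <- ceiling(fraction * N)
  (sum(r$label[seq_len(top)]) / top) / (n / N)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC in the standard
#' exponential-weighting closed form: the robust initial enhancement (RIE,
#' an exponentially weighted sum over active ranks) min-max normalised to
#' \[0, 1\].  Large `alpha` concentrates the weight on the earliest ranks;
#' the default 80.5 weights roughly the top 2%.
#'
#' @param ranking A [screen_ranking()].
#' @param alpha Early-recognition parameter (> 0).
#' @return BEDROC score in \[0, 1\].
#' @export
bedroc <- function(ranking, alpha = 80.5) {
  r <- if (inherits(ranking, "screen_ranking")) ranking else screen_ranking(ranking)
  stopifnot(alpha > 0)
  N <- nrow(r); n <- sum(r$label)
  if (n < 1) abort("ranking contains no actives", class = "ligspace_domain_error")
  if (n >= N) abort("ranking needs at least one inactive",
                    class = "ligspace_domain_error")
  ranks <- r$rank[r$label == 1L]
  ra <- n / N
  rie <- (sum(exp(-alpha * ranks / N)) / n) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  (rie - rie_min) / (rie_max - rie_min)
}

# Analytic expectation of BEDROC under a uniform random ranking: E[RIE] = 1.
bedroc_random_expectation <- function(n, N, alpha = 80.5) {
  ra <- n / N
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  (1 - rie_min) / (rie_max - rie_min)
}

#' Correlation suite for affinity prediction
#'
#' Spearman's rank correlation (average ranks on ties), Pearson's r, and
#' r-squared.  By convention in binding free-energy benchmarking r-squared
#' is the squared Pearson correlation; a coefficient-of-determination
#' variant (1 - SS_res/SS_tot on the identity fit) is available.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 3,
#'   non-constant).
#' @param r2_method `"pearson"` (squared correlation, default) or
#'   `"determination"`.
#' @return Tibble with `spearman`, `pearson`, `r_squared`.
#' @export
correlation_suite <- function(predicted, observed,
                              r2_method = c("pearson", "determination")) {
  r2_method <- match.arg(r2_method)
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (sd(predicted) == 0 || sd(observed) == 0) {
    abort("correlation undefined for constant input",
          class = "ligspace_domain_error")
  }
  rho <- cor(predicted, observed, method = "spearman")
  r <- cor(predicted, observed, method = "pearson")
  r2 <- if (r2_method == "pearson") r^2 else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  tibble(spearman = rho, pearson = r, r_squared = r2)
}

#' Recall of a ground-truth top set
#'
#' Fraction of the true top-k% ligands recovered by a selected set; the
#' headline metric of active-learning lead optimisation.
#'
#' @param selected Character vector of selected ligand ids.
#' @param truth Character vector of ground-truth top ligand ids (nonempty).
#' @return Recall in \[0, 1\].
#' @export
topk_recall <- function(selected, truth) {
  if (length(truth) == 0) abort("empty truth set",
                                class = "ligspace_domain_error")
  length(intersect(unique(selected), unique(truth))) / length(unique(truth))
}

#' Metric report for a screening run
#'
#' @param ranking A [screen_ranking()].
#' @param ef_fractions Enrichment-factor fractions.
#' @param alpha BEDROC alpha.
#' @return Tibble of named metrics with their parameters.
#' @export
metric_report <- function(ranking, ef_fractions = c(0.01, 0.05), alpha = 80.5) {
  r <- if (inherits(ranking, "screen_ranking")) ranking else screen_ranking(ranking)
  ef <- tibble(metric = sprintf("EF%g%%", 100 * ef_fractions),
               parameter = ef_fractions,
               value = vapply(ef_fractions, function(f)
                 enrichment_factor(r, f), numeric(1)))
  bind_rows(ef, tibble(metric = "BEDROC", parameter = alpha,
                       value = bedroc(r, alpha)))
}
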