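#' Candidate rate-order motifs for model discrimination
#'
#' Builds the default candidate set: each candidate applies one
#' (aromatic order, nucleophile order) pair to all four substitution steps,
#' with orders in 0..2. The all-second-order motif (1, 1) is the reference
#' candidate.
#'
#' @param orders A data frame / tibble with columns `aromatic` and
#'   `nucleophile`; default covers the standard set of plausible motifs.
#' @return Tibble of candidates with a `label` column.
#' @export
candidate_motifs <- function(orders = NULL) {
  if (is.null(orders)) {
    orders <- tibble::tribble(
      ~aromatic, ~nucleophile,
      1, 1,
      1, 0,
      0, 1,
      2, 1,
      1, 2
    )
  }
  orders <- tibble::as_tibble(orders)
  if (!all(unlist(orders[c("aromatic", "nucleophile")]) %in% 0:2)) {
    abort_config("Candidate orders must be integers in 0..2.")
  }
  orders$label <- sprintf("arom^%d nuc^%d", orders$aromatic, orders$nucleophile)
  orders
}

#' Rank candidate rate-order motifs against a campaign table
#'
#' Fits every candidate motif globally and ranks the candidates by SSE and by
#' the small-sample corrected Akaike criterion
#' `AICc = n log(SSE/n) + 2p + 2p(p+1)/(n-p-1)`. Candidates whose fit fails
#' are kept in the report, flagged, and ranked last.
#'
#' @param table A campaign sample table.
#' @param candidates Tibble from [candidate_motifs()].
#' @param spec A [fit_spec()] applied to every candidate.
#' @param nucleophile_stoich_factor Passed to [snar_scheme()].
#' @return Tibble with one row per candidate: `label`, `aromatic`,
#'   `nucleophile`, `converged`, `sse`, `aicc`, `rank`, and a list column
#'   `fit` holding each [fit_kinetics()] result (or `NULL`).
#' @export
rank_rate_orders <- function(table, candidates = candidate_motifs(),
                             spec = fit_spec(),
                             nucleophile_stoich_factor = 1) {
  if (nrow(candidates) < 1) abort_config("At least one candidate is required.")
  fits <- purrr::pmap(candidates, function(aromatic, nucleophile, label) {
    sc <- snar_scheme(aromatic_order = aromatic, nucleophile_order = nucleophile,
      nucleophile_stoich_factor = nucleophile_stoich_factor)
    tryCatch(fit_kinetics(table, sc, spec), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  sse <- vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$sse else NA_real_, numeric(1))
  n <- vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$n_obs else NA_real_, numeric(1))
  p <- vapply(seq_along(fits), function(i) if (ok[i]) fits[[i]]$n_par else NA_real_, numeric(1))
  aicc <- n * log(sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  out <- dplyr::mutate(candidates,
    converged = ok, sse = sse, aicc = aicc,
    fit = lapply(seq_along(fits), function(i) if (ok[i]) fits[[i]] else NULL))
  out$rank <- rank(ifelse(out$converged, out$aicc, Inf), ties.method = "first")
  dplyr::arrange(out, .data$rank)
}
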