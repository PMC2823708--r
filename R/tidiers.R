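#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an unmixing fit into a long fraction table
#'
#' @param x A `"mix_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, component):
#'   `sample_id`, `component`, `fraction`.
#' @export
tidy.mix_fit <- function(x, ...) {
  tibble::as_tibble(x$fractions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "fraction")
}

#' One-row summary of an unmixing fit
#'
#' @param x A `"mix_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_genes`, `n_samples`, `volume`,
#'   `restart`, `n_restarts`, `min_fraction` (most negative fraction, a
#'   containment diagnostic), `fractions_space`.
#' @export
glance.mix_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_genes = nrow(x$components), n_samples = nrow(x$fractions),
    volume = x$volume, restart = x$restart, n_restarts = x$n_restarts,
    min_fraction = min(x$fractions), fractions_space = x$fractions_space)
}

#' Tidy a component phylogeny into an edge table
#'
#' @param x A `"mix_phylogeny"`.
#' @param ... Unused.
#' @return A tibble with one row per tree edge: `component_a`,
#'   `component_b`, `similarity`, and `confidence` when bootstrapped.
#' @export
tidy.mix_phylogeny <- function(x, ...) {
  out <- tibble::tibble(
    component_a = x$component_ids[x$edges[, 1]],
    component_b = x$component_ids[x$edges[, 2]],
    similarity = x$similarity[x$edges])
  if (!is.null(x$edge_confidence)) out$confidence <- x$edge_confidence
  out
}

#' One-row summary of a component phylogeny
#'
#' @param x A `"mix_phylogeny"`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_edges`, `total_similarity`,
#'   `min_confidence`/`mean_confidence` and bootstrap accounting when
#'   present.
#' @export
glance.mix_phylogeny <- function(x, ...) {
  tibble::tibble(
    k = length(x$component_ids), n_edges = nrow(x$edges),
    total_similarity = sum(x$similarity[x$edges]),
    min_confidence = if (is.null(x$edge_confidence)) NA_real_
                     else min(x$edge_confidence),
    mean_confidence = if (is.null(x$edge_confidence)) NA_real_
                      else mean(x$edge_confidence),
    n_replicates = x$n_replicates %||% NA_integer_,
    n_skipped = x$n_skipped %||% NA_integer_)
}
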