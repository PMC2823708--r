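#' Read an expression matrix from tab-delimited text
#'
#' Expects a header row of sample identifiers and a gene-identifier first
#' column; remaining cells are linear-scale expression values. Cells given
#' as `NA` (or empty) are recorded in a `"missing"` attribute (a logical
#' matrix) and left as `NA` in the values; downstream unmixing rejects
#' non-finite values unless [preprocess_log_to_linear()] is applied first.
#'
#' @param path Path to a TSV file.
#' @return A `d x n` numeric matrix with gene rownames, sample colnames and
#'   attribute `"missing"`.
#' @export
load_expression <- function(path) {
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  if (length(hdr) < 2) stop("expression file needs a gene-ID column and at ",
                            "least one sample column")
  types <- do.call(readr::cols, c(
    stats::setNames(list(readr::col_character()), hdr[1]),
    list(.default = readr::col_double())))
  # suppress readr's generic parsing-issue warning; problems() is inspected
  # below and turned into a specific error
  df <- suppressWarnings(readr::read_tsv(path, col_types = types,
                                         progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    stop("malformed expression file at line(s) ",
         paste(unique(probs$row), collapse = ", "), ": ",
         probs$expected[1], " vs ", probs$actual[1])
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L  # +1 for the header row
    stop("duplicate gene ID '", ids[duplicated(ids)][1], "' at line ", line)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  attr(m, "missing") <- is.na(m)
  m
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [load_expression()]: gene IDs in the first column
#' (`gene_id`), one column per sample.
#'
#' @param M Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(M, path) {
  df <- tibble::as_tibble(M, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert log-scale microarray values to clipped linear scale
#'
#' The mixing model is linear in expression, so log-ratio microarray values
#' must be exponentiated before unmixing: each value `x` becomes `base^x`
#' (default `2^x`), missing cells are assigned linear level
#' `missing_value` (default 1, i.e. log-ratio 0), and results are clamped
#' to `[clip_low, clip_high]` (default `[2^-5, 2^5]`) so a few extreme
#' values -- likely assay failures -- cannot dominate the linear-scale fit.
#' Total function: never errors. Not idempotent unless values are already
#' linear and inside the clip range.
#'
#' @param M Numeric matrix of log-scale values (`NA` allowed).
#' @param base Log base of the input; default 2.
#' @param missing_value Linear value substituted for missing cells.
#' @param clip_low,clip_high Clamp range on the linear scale.
#' @return Linear-scale matrix of the same shape, all values finite.
#' @export
preprocess_log_to_linear <- function(M, base = 2, missing_value = 1,
                                     clip_low = 2^-5, clip_high = 2^5) {
  out <- base^M
  out[is.na(out)] <- missing_value
  out[out < clip_low] <- clip_low
  out[out > clip_high] <- clip_high
  attr(out, "missing") <- NULL
  out
}

#' Average mixture fractions by sample label
#'
#' Summarizes a fraction matrix over a sample-to-type labelling (e.g.
#' clinical subtypes): for each label, the arithmetic mean of the fraction
#' rows of its samples. Unlabelled samples are excluded; labels naming
#' samples absent from the matrix are an error.
#'
#' @param f `n x k` fraction matrix with sample rownames, or a `"mix_fit"`.
#' @param labels Data frame with columns `sample_id` and `type` (or a named
#'   character vector `sample_id -> type`).
#' @return A tibble: `type`, `n_samples`, one column per component.
#' @export
summarize_fractions_by_type <- function(f, labels) {
  if (inherits(f, "mix_fit")) f <- f$fractions
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(sample_id = names(labels),
                             type = unname(labels))
  }
  stopifnot(all(c("sample_id", "type") %in% names(labels)))
  missing <- setdiff(labels$sample_id, rownames(f))
  if (length(missing) > 0)
    stop("labelled samples not in the fraction matrix: ",
         paste(missing, collapse = ", "))
  tibble::as_tibble(f, rownames = "sample_id") |>
    dplyr::inner_join(labels, by = "sample_id") |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     dplyr::across(dplyr::where(is.numeric), mean)) |>
    dplyr::arrange(.data$type)
}

#' Rank genes by relative expression within each component
#'
#' Reports, per component, every gene's expression relative to its mean
#' across samples (`C - offset`), sorted within each component in
#' decreasing order of relative expression (ties broken by gene ID). This
#' is the marker-gene view of a fit: the genes most over-expressed in a
#' component relative to the cohort average.
#'
#' @param C `d x k` component matrix, or a `"mix_fit"` (offset taken from
#'   its reduction).
#' @param offset Per-gene mean expression (length `d`); ignored when `C` is
#'   a `"mix_fit"`.
#' @param descriptions Optional named character vector of gene descriptions
#'   (absent genes get an empty string).
#' @return A tibble: `component`, `gene_id`, `description`,
#'   `relative_expression`, ordered by component then decreasing relative
#'   expression.
#' @export
sorted_component_gene_table <- function(C, offset = NULL,
                                        descriptions = NULL) {
  if (inherits(C, "mix_fit")) {
    offset <- C$reduced$offset
    C <- C$components
  }
  if (is.null(offset)) stop("offset (per-gene mean) is required")
  stopifnot(nrow(C) == length(offset))
  rel <- C - offset
  ids <- rownames(C)
  if (is.null(ids)) ids <- gene_ids(nrow(C))
  desc <- if (is.null(descriptions)) rep("", length(ids)) else {
    d <- unname(descriptions[ids]); d[is.na(d)] <- ""; d
  }
  tibble::as_tibble(rel, rownames = NULL) |>
    stats::setNames(colnames(rel) %||% component_ids(ncol(rel))) |>
    dplyr::mutate(gene_id = ids, description = desc) |>
    tidyr::pivot_longer(cols = -c("gene_id", "description"),
                        names_to = "component",
                        values_to = "relative_expression") |>
    dplyr::arrange(.data$component,
                   dplyr::desc(.data$relative_expression), .data$gene_id) |>
    dplyr::select("component", "gene_id", "description",
                  "relative_expression")
}

#' Write the outputs of an unmixing fit to a directory
#'
#' Writes `components.tsv` (relative expression, i.e. `C` minus the
#' per-gene mean), `fractions.tsv` (`sample_id` x component) and
#' `run_info.txt` (plain `key: value` metadata: seed, k, restarts,
#' tolerance, selected volume).
#'
#' @param fit A `"mix_fit"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mix_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "mix_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- fit$components - fit$reduced$offset
  readr::write_tsv(tibble::as_tibble(rel, rownames = "gene_id"),
                   file.path(dir, "components.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(fit$fractions, rownames = "sample_id"),
                   file.path(dir, "fractions.tsv"), progress = FALSE)
  info <- c(k = fit$k, n_restarts = fit$n_restarts,
            seed = fit$seed %||% "NULL", volume = format(fit$volume),
            restart = fit$restart, fractions_space = fit$fractions_space)
  writeLines(paste0(names(info), ": ", info), file.path(dir, "run_info.txt"))
  invisible(dir)
}

#' Write a component phylogeny as a TSV edge list
#'
#' Columns: `component_a`, `component_b`, `similarity` and (when bootstrap
#' confidences are present) `confidence`.
#'
#' @param phy A `"mix_phylogeny"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path) {
  stopifnot(inherits(phy, "mix_phylogeny"))
  readr::write_tsv(tidy(phy), path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
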