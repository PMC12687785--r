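#' Completeness and unique-value count of one attribute column
#'
#' Two of the four harmonization quality metrics. Completeness is the
#' proportion of non-missing cells. Unique values (the consolidation metric)
#' counts distinct non-missing cells by default; `mode = "token"` counts
#' distinct tokens after delimiter splitting, for multi-valued attributes.
#'
#' @param x Character vector (one attribute column, non-empty).
#' @param delimiter Token delimiter for `mode = "token"`.
#' @param mode `"cell"` (default) or `"token"`.
#' @return A one-row tibble `completeness`, `unique_values`.
#' @export
attribute_metrics <- function(x, delimiter = ";", mode = c("cell", "token")) {
  mode <- match.arg(mode)
  if (!length(x)) stop("zero rows", call. = FALSE)
  x <- as.character(x)
  nonna <- x[!is.na(x)]
  uniq <- if (mode == "cell") length(unique(nonna)) else {
    toks <- trimws(unlist(strsplit(nonna, delimiter, fixed = TRUE)))
    length(unique(toks[nzchar(toks)]))
  }
  tibble::tibble(completeness = length(nonna) / length(x), unique_values = uniq)
}

#' Correction rate of a curated attribute
#'
#' The proportion of originally present values that were updated during
#' curation: over rows where the original is non-missing, the fraction whose
#' curated cell differs from the *cleaned* original cell (exact string
#' inequality after trimming), so whitespace/NA normalization alone does not
#' count as a correction. The metric is only meaningful for one-to-one
#' original-to-curated pairings; under a many-to-many merging plan it is not
#' applicable and `NA` is returned.
#'
#' @param original,curated Aligned character vectors.
#' @param many_to_many Is the pairing many-to-many? If `TRUE`, returns `NA`.
#' @return A single double in \[0, 1\], or `NA`.
#' @export
correction_rate <- function(original, curated, many_to_many = FALSE) {
  if (length(original) != length(curated)) stop("length mismatch", call. = FALSE)
  if (many_to_many) return(NA_real_)
  keep <- !is.na(original)
  if (!any(keep)) return(NA_real_)
  o <- trimws(original[keep])
  c2 <- curated[keep]
  mean(is.na(c2) | o != trimws(c2))
}

#' Per-attribute harmonization quality metrics
#'
#' Computes the four quality metrics for each curated attribute of a plan:
#' compression (number of original attributes merged into the curated one),
#' consolidation (unique values before and after), correction rate, and
#' completeness before and after.
#'
#' @param original_data Raw metadata tibble.
#' @param harmonized_data Harmonized tibble carrying `curated_*` columns.
#' @param plan Tibble of edges `original_attribute`, `curated_attribute`.
#' @param delimiter Token delimiter.
#' @return An `attribute_metrics_tbl` tibble, one row per curated attribute:
#'   `attribute`, `compression`, `unique_original` (pooled over sources),
#'   `unique_curated`, `correction_rate` (`NA` when the attribute has several
#'   sources or the plan is many-to-many), `completeness_original` (best
#'   single source), `completeness_curated`.
#' @export
harmonization_metrics <- function(original_data, harmonized_data, plan,
                                  delimiter = ";") {
  plan <- tibble::as_tibble(plan)
  many <- anyDuplicated(plan$original_attribute) > 0L
  rows <- purrr::map(split(plan, plan$curated_attribute), function(edges) {
    cur <- edges$curated_attribute[[1]]
    col <- if (cur %in% names(harmonized_data)) cur else paste0("curated_", cur)
    if (!col %in% names(harmonized_data)) {
      stop("curated column absent: ", col, call. = FALSE)
    }
    orig_cols <- edges$original_attribute
    missing <- setdiff(orig_cols, names(original_data))
    if (length(missing)) {
      stop("plan edge references absent column: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    pooled <- unlist(original_data[orig_cols], use.names = FALSE)
    om <- attribute_metrics(pooled, delimiter)
    cm <- attribute_metrics(harmonized_data[[col]], delimiter)
    cr <- if (many || length(orig_cols) > 1L) NA_real_ else
      correction_rate(original_data[[orig_cols]], harmonized_data[[col]])
    comp_orig <- max(purrr::map_dbl(orig_cols, function(oc)
      attribute_metrics(original_data[[oc]], delimiter)$completeness))
    tibble::tibble(
      attribute = cur,
      compression = length(orig_cols),
      unique_original = om$unique_values,
      unique_curated = cm$unique_values,
      correction_rate = cr,
      completeness_original = comp_orig,
      completeness_curated = cm$completeness
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("attribute_metrics_tbl", class(out))
  out
}

#' Unique-value reduction achieved by harmonization
#'
#' Two renderings of the consolidation effect: `per_attribute` averages the
#' per-attribute relative reductions `1 - unique_curated / unique_original`;
#' `pooled` compares total pooled unique counts across attributes. Both are
#' reported because either convention is defensible for a summary statistic.
#'
#' @param metrics An `attribute_metrics_tbl` from [harmonization_metrics()].
#' @return A one-row tibble `per_attribute`, `pooled` (fractions in \[0, 1\]).
#' @export
unique_value_reduction <- function(metrics) {
  keep <- metrics$unique_original > 0
  tibble::tibble(
    per_attribute = mean(1 - metrics$unique_curated[keep] /
                           metrics$unique_original[keep]),
    pooled = 1 - sum(metrics$unique_curated) / sum(metrics$unique_original)
  )
}

#' Build a merging schema table
#'
#' Records, for every plan edge, how an original attribute fed a curated one,
#' with completeness and unique-value counts on both sides. The long form has
#' one row per edge (the many-to-many rendering); `collapse = TRUE` emits one
#' row per original field, valid only when the plan maps each original to a
#' single curated attribute.
#'
#' @inheritParams harmonization_metrics
#' @param collapse Collapse to one row per original field (requires a
#'   functional plan).
#' @return Tibble with the six schema columns: `original_field`,
#'   `original_field_completeness`, `original_field_unique_values`,
#'   `curated_field`, `curated_field_completeness`,
#'   `curated_field_unique_values`.
#' @export
build_merging_schema <- function(plan, original_data, harmonized_data,
                                 delimiter = ";", collapse = FALSE) {
  plan <- tibble::as_tibble(plan)
  if (collapse && anyDuplicated(plan$original_attribute)) {
    stop("collapse requires each original attribute to map to one curated attribute",
         call. = FALSE)
  }
  side <- function(data, col) {
    if (!col %in% names(data)) stop("plan edge references absent column: ", col,
                                    call. = FALSE)
    attribute_metrics(data[[col]], delimiter)
  }
  rows <- purrr::pmap(plan[, c("original_attribute", "curated_attribute")],
    function(original_attribute, curated_attribute) {
      cc <- if (curated_attribute %in% names(harmonized_data)) curated_attribute
            else paste0("curated_", curated_attribute)
      om <- side(original_data, original_attribute)
      cm <- side(harmonized_data, cc)
      tibble::tibble(
        original_field = original_attribute,
        original_field_completeness = om$completeness,
        original_field_unique_values = om$unique_values,
        curated_field = curated_attribute,
        curated_field_completeness = cm$completeness,
        curated_field_unique_values = cm$unique_values
      )
    })
  dplyr::bind_rows(rows)
}

#' Plot harmonization quality metrics
#'
#' Dot plot comparing each curated attribute's completeness (and unique-value
#' count, log scale) before and after harmonization.
#'
#' @param object An `attribute_metrics_tbl` from [harmonization_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attribute_metrics_tbl
#' @export
autoplot.attribute_metrics_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "attribute",
                  original = "completeness_original",
                  curated = "completeness_curated"),
    cols = c("original", "curated"),
    names_to = "stage", values_to = "completeness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribute, y = .data$completeness,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "completeness (non-NA fraction)",
                  colour = NULL,
                  title = "Attribute completeness before and after harmonization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
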