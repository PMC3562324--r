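#' Normalise per-category counts to percent of the per-category maximum
#'
#' For each category (row), counts across species are rescaled so the
#' largest count becomes 100%; ties at the maximum all map to 100. Rows
#' whose maximum is 0 become all 0. This is the display normalisation used
#' for cross-species functional-category comparisons.
#'
#' @param counts Data frame whose first column is the category label and
#'   whose remaining columns are non-negative species counts, or a numeric
#'   matrix with category rownames.
#' @return Tibble of the same shape with counts replaced by percentages.
#' @export
#' @examples
#' percent_of_max(tibble::tibble(term = "glycolysis", a = 5, b = 10, c = 2))
percent_of_max <- function(counts) {
  if (is.matrix(counts)) {
    counts <- tibble::as_tibble(counts, rownames = "category")
  }
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 2) stop("need at least one species column",
                             call. = FALSE)
  vals <- as.matrix(counts[, -1])
  if (!is.numeric(vals)) stop("species columns must be numeric",
                              call. = FALSE)
  if (any(vals < 0)) stop("negative counts", call. = FALSE)
  rmax <- apply(vals, 1, max)
  scale <- ifelse(rmax > 0, 100 / rmax, 0)
  counts[, -1] <- vals * scale
  counts
}

#' Tabulate enzyme-category counts and family diversity per species
#'
#' Given one gene-category table per species (the layout read by
#' [read_category_table()]), counts labelled genes and distinct CAZy
#' families per (category, species). Category labels outside the expected
#' vocabulary are bucketed as `"other"` with a warning.
#'
#' @param gene_tables Named list (species -> data frame with
#'   `pcwde_category`, `cazy_families`) or named character vector of TSV
#'   paths.
#' @param vocabulary Accepted category labels.
#' @return Long tibble: `category`, `species`, `n_genes`, `n_families`.
#' @export
tabulate_categories <- function(gene_tables,
                                vocabulary = c("cellulase", "hemicellulase",
                                               "beta-glucosidase",
                                               "pectinase", "expansin-like",
                                               "tannase",
                                               "cellobiose-dehydrogenase")) {
  if (is.character(gene_tables)) {
    gene_tables <- purrr::map(gene_tables, read_category_table)
  }
  if (is.null(names(gene_tables)) || any(names(gene_tables) == "")) {
    stop("gene_tables must be named by species", call. = FALSE)
  }
  purrr::imap_dfr(gene_tables, function(tbl, species) {
    tbl <- tibble::as_tibble(tbl) |>
      dplyr::filter(!is.na(.data$pcwde_category) &
                      .data$pcwde_category != "")
    unknown <- setdiff(unique(tbl$pcwde_category), vocabulary)
    if (length(unknown) > 0) {
      warning("unknown category label(s) in ", species, ": ",
              paste(unknown, collapse = ", "), " — bucketed as \"other\"",
              call. = FALSE)
      tbl$pcwde_category[tbl$pcwde_category %in% unknown] <- "other"
    }
    tbl |>
      dplyr::group_by(category = .data$pcwde_category) |>
      dplyr::summarise(
        n_genes = dplyr::n(),
        n_families = dplyr::n_distinct(
          setdiff(unlist(strsplit(.data$cazy_families, ";")), "")
        ),
        .groups = "drop"
      ) |>
      dplyr::mutate(species = species, .after = "category")
  })
}
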