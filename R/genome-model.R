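#' Build an in-memory genome model from tidy component tables
#'
#' A genome model bundles everything the downstream analyses consume: a gene
#' table with per-scaffold ordinals and CAZyme / plant cell wall-degrading
#' enzyme (PCWDE) flags, a scaffold table with lengths, and (optionally)
#' scaffold sequences and an exon table for annotation statistics.
#'
#' Coordinates are 0-based half-open throughout the package; conversion from
#' the 1-based closed GFF3 convention happens once, in [read_annotation()].
#' Ordinals rank genes within a scaffold by `(start, end, gene_id)`, so every
#' scaffold's ordinals are `0..n-1` with no gaps.
#'
#' @param genes Data frame with columns `gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand`; optional `is_cazyme`, `cazy_families`, `is_pcwde`,
#'   `pcwde_category`. Missing flag columns are filled with all-negative
#'   defaults. Ordinals are (re)assigned here.
#' @param scaffolds Optional data frame with `scaffold_id` and `length`.
#'   Scaffolds absent from it but present in `genes` are added with length
#'   equal to the maximum gene end.
#' @param sequences Optional named character vector of scaffold DNA sequences
#'   (uppercase ACGTN). Names must match scaffold IDs.
#' @param exons Optional data frame with `gene_id`, `mrna_id`, `start`, `end`
#'   (0-based half-open), used only by [compute_stats()].
#'
#' @return An object of class `genome_model`: a list with elements `genes`,
#'   `scaffolds`, `sequences`, `exons`, and the census counts `n_genes`,
#'   `k_cazyme`, `k_pcwde` that parameterise the hypergeometric background.
#' @seealso [read_annotation()], [simulate_genome()]
#' @export
#' @examples
#' g <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3"), scaffold_id = "s1",
#'   start = c(0L, 500L, 900L), end = c(300L, 800L, 1200L), strand = "+",
#'   is_cazyme = c(TRUE, FALSE, TRUE)
#' )
#' gm <- genome_model(g)
#' gm$k_cazyme
genome_model <- function(genes, scaffolds = NULL, sequences = NULL,
                         exons = NULL) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "scaffold_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    dups <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene IDs: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end][1]
    stop("gene ", bad, " has start >= end", call. = FALSE)
  }
  if (!"is_cazyme" %in% names(genes)) genes$is_cazyme <- FALSE
  if (!"cazy_families" %in% names(genes)) genes$cazy_families <- ""
  if (!"is_pcwde" %in% names(genes)) genes$is_pcwde <- FALSE
  if (!"pcwde_category" %in% names(genes)) genes$pcwde_category <- NA_character_
  genes$cazy_families[is.na(genes$cazy_families)] <- ""
  if (any(genes$is_pcwde & is.na(genes$pcwde_category))) {
    stop("PCWDE-flagged genes must carry a pcwde_category", call. = FALSE)
  }

  genes <- assign_ordinals(genes)

  obs <- genes |>
    dplyr::count(.data$scaffold_id, name = "n_genes") |>
    dplyr::left_join(
      genes |>
        dplyr::group_by(.data$scaffold_id) |>
        dplyr::summarise(max_end = max(.data$end), .groups = "drop"),
      by = "scaffold_id"
    )
  if (is.null(scaffolds)) {
    scaffolds <- tibble::tibble(scaffold_id = obs$scaffold_id,
                                length = obs$max_end)
  } else {
    scaffolds <- tibble::as_tibble(scaffolds)
    stopifnot(all(c("scaffold_id", "length") %in% names(scaffolds)))
    scaffolds <- scaffolds[, setdiff(names(scaffolds), "n_genes")]
    extra <- obs[!obs$scaffold_id %in% scaffolds$scaffold_id, ]
    if (nrow(extra) > 0) {
      scaffolds <- dplyr::bind_rows(
        scaffolds,
        tibble::tibble(scaffold_id = extra$scaffold_id, length = extra$max_end)
      )
    }
  }
  scaffolds <- scaffolds |>
    dplyr::left_join(obs[, c("scaffold_id", "n_genes")], by = "scaffold_id") |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))

  chk <- dplyr::left_join(
    genes |>
      dplyr::group_by(.data$scaffold_id) |>
      dplyr::summarise(max_end = max(.data$end), .groups = "drop"),
    scaffolds, by = "scaffold_id"
  )
  if (any(chk$max_end > chk$length)) {
    bad <- chk$scaffold_id[chk$max_end > chk$length][1]
    stop("genes on scaffold ", bad, " extend past its stated length",
         call. = FALSE)
  }

  if (!is.null(sequences)) {
    sequences <- toupper(unlist(sequences))
    unknown <- setdiff(names(sequences), scaffolds$scaffold_id)
    if (length(unknown) > 0) {
      sequences <- sequences[!names(sequences) %in% unknown]
    }
    have <- intersect(scaffolds$scaffold_id, names(sequences))
    lens <- unname(nchar(sequences[have]))
    stated <- scaffolds$length[match(have, scaffolds$scaffold_id)]
    if (any(lens != stated)) {
      # FASTA is the authority on physical length when both are present
      scaffolds$length[match(have, scaffolds$scaffold_id)] <- lens
    }
  }
  if (!is.null(exons)) {
    exons <- tibble::as_tibble(exons)
    stopifnot(all(c("gene_id", "mrna_id", "start", "end") %in% names(exons)))
  }

  structure(
    list(
      genes = genes,
      scaffolds = scaffolds,
      sequences = sequences,
      exons = exons,
      n_genes = nrow(genes),
      k_cazyme = sum(genes$is_cazyme),
      k_pcwde = sum(genes$is_pcwde)
    ),
    class = "genome_model"
  )
}

# Rank genes within each scaffold by (start, end, gene_id); 0-based ordinals.
assign_ordinals <- function(genes) {
  genes |>
    dplyr::arrange(.data$scaffold_id, .data$start, .data$end, .data$gene_id) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(ordinal = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::relocate("ordinal", .after = "strand")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat("  scaffolds: ", nrow(x$scaffolds),
      if (!is.null(x$sequences)) " (with sequences)" else "", "\n", sep = "")
  cat("  genes:     ", x$n_genes, "\n", sep = "")
  cat("  CAZymes:   ", x$k_cazyme, "\n", sep = "")
  cat("  PCWDEs:    ", x$k_pcwde, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genome model into its gene table
#'
#' @param x A `genome_model`.
#' @param ... Unused.
#' @return The gene tibble, one row per gene, ordered by scaffold and ordinal.
#' @method tidy genome_model
#' @export
tidy.genome_model <- function(x, ...) {
  x$genes
}

#' One-row census summary of a genome model
#'
#' @param x A `genome_model`.
#' @param ... Unused.
#' @return A one-row tibble with scaffold, gene, CAZyme and PCWDE counts and
#'   the total assembled length.
#' @method glance genome_model
#' @export
glance.genome_model <- function(x, ...) {
  tibble::tibble(
    n_scaffolds = nrow(x$scaffolds),
    total_length_bp = sum(x$scaffolds$length),
    n_genes = x$n_genes,
    k_cazyme = x$k_cazyme,
    k_pcwde = x$k_pcwde
  )
}

# Label flag column for a label keyword ("cazyme" or "pcwde").
label_column <- function(label) {
  label <- match.arg(label, c("cazyme", "pcwde"))
  c(cazyme = "is_cazyme", pcwde = "is_pcwde")[[label]]
}

# Total label-positive genes for a label keyword.
label_total <- function(genome, label) {
  switch(match.arg(label, c("cazyme", "pcwde")),
         cazyme = genome$k_cazyme,
         pcwde = genome$k_pcwde)
}
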