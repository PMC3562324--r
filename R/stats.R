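#' Genome annotation summary statistics
#'
#' Computes the usual genome-report table: assembled size, GC content,
#' gene counts, average gene/exon/intron lengths and introns per gene.
#' Introns are the gaps between consecutive exons of the same mRNA; for
#' genes with several isoforms the representative mRNA is the one with the
#' largest total exon length. Gene length is the annotated gene span
#' (`end - start`), so UTRs are included when annotated. The protein-length
#' gene count uses total exon bp / 3 as a proxy for protein length, since
#' the model carries no CDS features.
#'
#' GC percentages are computed over A/C/G/T only (N excluded from the
#' denominator). All averages are returned unrounded; see
#' [genome_stats_table()] for presentation rounding.
#'
#' @param genome A [genome_model()] with an exon table (see
#'   [read_annotation()]); sequences may live in the model or be passed
#'   separately.
#' @param sequences Optional named character vector overriding
#'   `genome$sequences`.
#' @param min_protein_len_aa Threshold for the "genes of at least this
#'   protein length" count, default 60.
#' @return One-row tibble: `assembled_size_bp`, `gc_pct`, `n_genes`,
#'   `n_genes_ge_min_len`, `coding_gc_pct`, `avg_gene_length_bp`,
#'   `avg_introns_per_gene`, `n_genes_with_intron`, `avg_intron_bp`,
#'   `avg_exon_bp`.
#' @export
compute_stats <- function(genome, sequences = NULL,
                          min_protein_len_aa = 60L) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(sequences)) sequences <- genome$sequences
  genes <- genome$genes

  assembled <- sum(genome$scaffolds$length)
  gc_pct <- NA_real_
  if (!is.null(sequences)) {
    gc_pct <- gc_percent(paste(sequences, collapse = ""))
  }

  exon_stats <- list(
    n_with_intron = NA_integer_, avg_introns = NA_real_,
    avg_intron_bp = NA_real_, avg_exon_bp = NA_real_,
    coding_gc = NA_real_, n_ge_min = NA_integer_
  )
  if (!is.null(genome$exons) && nrow(genome$exons) > 0) {
    exon_stats <- exon_intron_stats(genome, sequences, min_protein_len_aa)
  }

  tibble::tibble(
    assembled_size_bp = assembled,
    gc_pct = gc_pct,
    n_genes = nrow(genes),
    n_genes_ge_min_len = exon_stats$n_ge_min,
    coding_gc_pct = exon_stats$coding_gc,
    avg_gene_length_bp = mean(genes$end - genes$start),
    avg_introns_per_gene = exon_stats$avg_introns,
    n_genes_with_intron = exon_stats$n_with_intron,
    avg_intron_bp = exon_stats$avg_intron_bp,
    avg_exon_bp = exon_stats$avg_exon_bp
  )
}

gc_percent <- function(seq) {
  counts <- table(strsplit(seq, NULL)[[1]])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  100 * sum(counts[names(counts) %in% c("G", "C")]) / acgt
}

exon_intron_stats <- function(genome, sequences, min_protein_len_aa) {
  exons <- genome$exons
  # representative mRNA per gene: largest total exon bp
  rep_mrna <- exons |>
    dplyr::group_by(.data$gene_id, .data$mrna_id) |>
    dplyr::summarise(exon_bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$exon_bp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ex <- exons |>
    dplyr::semi_join(rep_mrna, by = c("gene_id", "mrna_id")) |>
    dplyr::arrange(.data$gene_id, .data$start)

  by_gene <- ex |> dplyr::group_by(.data$gene_id)
  overlap <- by_gene |>
    dplyr::summarise(
      bad = dplyr::n() > 1 && any(.data$start[-1] < .data$end[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    stop("overlapping exons within mRNA of gene ",
         overlap$gene_id[overlap$bad][1], call. = FALSE)
  }
  introns <- by_gene |>
    dplyr::summarise(
      n_introns = dplyr::n() - 1L,
      intron_bp = sum(.data$start[-1] - .data$end[-dplyr::n()]),
      exon_bp = sum(.data$end - .data$start),
      .groups = "drop"
    )
  # genes absent from the exon table contribute zero introns
  n_genes <- nrow(genome$genes)
  total_introns <- sum(introns$n_introns)

  coding_gc <- NA_real_
  if (!is.null(sequences)) {
    exs <- ex |>
      dplyr::left_join(
        genome$genes[, c("gene_id", "scaffold_id")], by = "gene_id"
      ) |>
      dplyr::filter(.data$scaffold_id %in% names(sequences))
    if (nrow(exs) > 0) {
      pieces <- substring(sequences[exs$scaffold_id], exs$start + 1, exs$end)
      coding_gc <- gc_percent(paste(pieces, collapse = ""))
    }
  }

  list(
    n_with_intron = sum(introns$n_introns > 0),
    avg_introns = total_introns / n_genes,
    avg_intron_bp = if (total_introns > 0) {
      sum(introns$intron_bp) / total_introns
    } else NA_real_,
    avg_exon_bp = sum(introns$exon_bp) / sum(introns$n_introns + 1L),
    coding_gc = coding_gc,
    n_ge_min = sum(introns$exon_bp / 3 >= min_protein_len_aa)
  )
}

#' Presentation table of genome statistics
#'
#' Applies the customary rounding (lengths to whole bp, introns per gene to
#' two decimals, percentages to one decimal) and returns a two-column
#' statistic/value tibble suitable for printing.
#'
#' @param stats One-row tibble from [compute_stats()].
#' @return Tibble with columns `statistic`, `value`.
#' @export
genome_stats_table <- function(stats) {
  fmt <- function(x, digits = 0) {
    if (is.na(x)) NA_character_ else format(round(x, digits), nsmall = digits)
  }
  tibble::tibble(
    statistic = c(
      "Size of assembled genome (bp)", "GC content of assembled genome (%)",
      "All protein-coding genes", "Protein-coding genes (>= min length)",
      "GC content of protein-coding region (%)", "Average gene length (bp)",
      "Average number of introns per gene", "Genes with intron",
      "Average intron size (bp)", "Average exon size (bp)"
    ),
    value = c(
      fmt(stats$assembled_size_bp), fmt(stats$gc_pct, 1),
      fmt(stats$n_genes), fmt(stats$n_genes_ge_min_len),
      fmt(stats$coding_gc_pct, 1), fmt(stats$avg_gene_length_bp),
      fmt(stats$avg_introns_per_gene, 2), fmt(stats$n_genes_with_intron),
      fmt(stats$avg_intron_bp), fmt(stats$avg_exon_bp)
    )
  )
}
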