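#' Read a GFF3 annotation and a gene-category table into a genome model
#'
#' The GFF3 supplies gene coordinates (and, when present, mRNA/exon features
#' used by [compute_stats()]); the tab-separated category table is the single
#' source of truth for CAZyme and plant cell wall-degrading enzyme (PCWDE)
#' labels — no domain annotation is performed here. GFF3 1-based closed
#' coordinates are converted to the package's internal 0-based half-open
#' convention at this boundary.
#'
#' The category table must have a header with columns `gene_id`, `is_cazyme`,
#' `cazy_families` (semicolon-separated, may be empty) and `pcwde_category`
#' (empty when the gene is not a PCWDE). Genes absent from the table get
#' all-negative flags; table rows whose `gene_id` is not in the GFF3 are
#' dropped with a warning.
#'
#' @param gff3_path Path to a GFF3 file with `gene` features carrying unique
#'   `ID` attributes (mRNA/exon features optional).
#' @param category_table_path Path to the category TSV (`NULL` to skip
#'   labelling).
#' @param fasta_path Optional scaffold FASTA; supplies sequences and
#'   authoritative scaffold lengths.
#' @return A [genome_model()].
#' @export
read_annotation <- function(gff3_path, category_table_path = NULL,
                            fasta_path = NULL) {
  if (!file.exists(gff3_path)) {
    stop("GFF3 not found: ", gff3_path, call. = FALSE)
  }
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", gff3_path, call. = FALSE)
  gene_ids <- as.character(meta$ID[is_gene])
  if (anyNA(gene_ids) || any(gene_ids == "")) {
    stop("gene feature without an ID attribute in ", gff3_path, call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs in ", gff3_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- tibble::tibble(
    gene_id = gene_ids,
    scaffold_id = as.character(GenomeInfoDb::seqnames(gr))[is_gene],
    start = BiocGenerics::start(gr)[is_gene] - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr)[is_gene],
    strand = as.character(BiocGenerics::strand(gr))[is_gene]
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  exons <- NULL
  is_mrna <- type == "mRNA"
  is_exon <- type == "exon"
  if (any(is_mrna) && any(is_exon)) {
    mrna_parent <- vapply(meta$Parent[is_mrna], function(p) p[1], character(1))
    mrna_ids <- as.character(meta$ID[is_mrna])
    exon_parent <- vapply(meta$Parent[is_exon], function(p) p[1], character(1))
    exons <- tibble::tibble(
      mrna_id = exon_parent,
      start = BiocGenerics::start(gr)[is_exon] - 1L,
      end = BiocGenerics::end(gr)[is_exon]
    ) |>
      dplyr::left_join(
        tibble::tibble(mrna_id = mrna_ids, gene_id = mrna_parent),
        by = "mrna_id"
      ) |>
      dplyr::filter(!is.na(.data$gene_id)) |>
      dplyr::select("gene_id", "mrna_id", "start", "end")
  }

  if (!is.null(category_table_path)) {
    cats <- read_category_table(category_table_path)
    orphan <- setdiff(cats$gene_id, genes$gene_id)
    if (length(orphan) > 0) {
      warning(length(orphan), " category row(s) with gene_id absent from ",
              "the GFF3 were ignored (e.g. ", orphan[1], ")", call. = FALSE)
      cats <- cats[!cats$gene_id %in% orphan, ]
    }
    genes <- genes |>
      dplyr::left_join(cats, by = "gene_id") |>
      dplyr::mutate(
        is_cazyme = dplyr::coalesce(.data$is_cazyme, FALSE),
        cazy_families = dplyr::coalesce(.data$cazy_families, ""),
        is_pcwde = dplyr::coalesce(.data$is_pcwde, FALSE)
      )
  }

  # scaffold lengths from ##sequence-region directives (1-based closed)
  scaffolds <- NULL
  directives <- grep("^##sequence-region",
                     readLines(gff3_path, warn = FALSE), value = TRUE)
  if (length(directives) > 0) {
    parts <- strsplit(trimws(directives), "\\s+")
    scaffolds <- tibble::tibble(
      scaffold_id = vapply(parts, `[`, character(1), 2),
      length = as.integer(vapply(parts, `[`, character(1), 4))
    )
  }

  sequences <- NULL
  if (!is.null(fasta_path)) {
    sequences <- read_fasta(fasta_path)
    scaffolds <- tibble::tibble(scaffold_id = names(sequences),
                                length = unname(nchar(sequences)))
  }

  genome_model(genes, scaffolds = scaffolds, sequences = sequences,
               exons = exons)
}

#' Read the gene-category TSV
#'
#' @param path TSV with header `gene_id`, `is_cazyme`, `cazy_families`,
#'   `pcwde_category`.
#' @return A tibble with logical flags; `is_pcwde` is derived from a
#'   non-empty `pcwde_category`.
#' @export
read_category_table <- function(path) {
  if (!file.exists(path)) stop("category table not found: ", path,
                               call. = FALSE)
  cats <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    is_cazyme = readr::col_logical(),
    cazy_families = readr::col_character(),
    pcwde_category = readr::col_character()
  ), na = c("NA"))
  if (anyDuplicated(cats$gene_id)) {
    stop("duplicate gene IDs in category table: ",
         paste(unique(cats$gene_id[duplicated(cats$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  cats |>
    dplyr::mutate(
      cazy_families = dplyr::coalesce(.data$cazy_families, ""),
      pcwde_category = dplyr::if_else(
        is.na(.data$pcwde_category) | .data$pcwde_category == "",
        NA_character_, .data$pcwde_category
      ),
      is_pcwde = !is.na(.data$pcwde_category)
    )
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; record IDs are truncated at the first
#' whitespace, matching common scaffold-naming practice.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence IDs in ", path, call. = FALSE)
  }
  seqs
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences (uppercased, IDs
#'   truncated at whitespace).
#' @export
read_protein_fasta <- function(path) {
  read_fasta(path)
}

#' Write enriched regions as a BED file
#'
#' BED uses 0-based half-open coordinates, which is also the package's
#' internal convention, so coordinates pass through unchanged. The score
#' column is `-10 * log10(min_p)` capped at 1000, the usual BED score range.
#'
#' @param regions Region tibble from [merge_regions()] (columns
#'   `region_id`, `scaffold_id`, `start`, `end`, `min_p`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(round(-10 * log10(pmax(regions$min_p, 1e-300))), 1000)
  bed <- tibble::tibble(
    chrom = regions$scaffold_id,
    start = regions$start,
    end = regions$end,
    name = regions$region_id,
    score = as.integer(score),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a gene table in the category-TSV layout plus coordinates
#'
#' Round-trips through [read_annotation()]'s conventions: a companion of the
#' simulator and of result export.
#'
#' @param genes Gene tibble (as in `genome_model$genes`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}
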