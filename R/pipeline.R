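#' Configuration for a full pipeline run
#'
#' Bundles input paths, stage parameters and the output directory. A YAML
#' file with the same field names can be loaded with [read_pipeline_config()].
#'
#' @param gff3 Path to the gene annotation GFF3.
#' @param categories Path to the gene-category TSV.
#' @param fasta Optional scaffold FASTA (enables telomere scanning,
#'   sub-telomeric calls on real chromosome ends, and GC statistics).
#' @param proteins Optional protein FASTA (enables the paralogy filter).
#' @param out_dir Output directory for the result bundle.
#' @param enrichment An [enrichment_params()].
#' @param telomere A [telomere_params()].
#' @param paralogy A [paralogy_params()].
#' @param adjacency_label Label for adjacent-run detection, default
#'   `"pcwde"`.
#' @param subtelomeric_cutoff_bp Distance cutoff for sub-telomeric calls.
#' @param top_regions Optional cap on reported regions (smallest p first).
#' @param seed Seed recorded in the bundle (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3, categories, fasta = NULL, proteins = NULL,
                            out_dir, enrichment = enrichment_params(),
                            telomere = telomere_params(),
                            paralogy = paralogy_params(),
                            adjacency_label = "pcwde",
                            subtelomeric_cutoff_bp = 200000L,
                            top_regions = NULL, seed = 1L) {
  structure(
    list(gff3 = gff3, categories = categories, fasta = fasta,
         proteins = proteins, out_dir = out_dir, enrichment = enrichment,
         telomere = telomere, paralogy = paralogy,
         adjacency_label = adjacency_label,
         subtelomeric_cutoff_bp = as.integer(subtelomeric_cutoff_bp),
         top_regions = top_regions, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognised fields mirror the arguments of [pipeline_config()]; nested
#' `enrichment`, `telomere` and `paralogy` mappings override individual
#' parameter defaults.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  enr <- do.call(enrichment_params, y$enrichment %||% list())
  tel <- do.call(telomere_params, y$telomere %||% list())
  par <- do.call(paralogy_params, y$paralogy %||% list())
  pipeline_config(
    gff3 = y$gff3, categories = y$categories,
    fasta = y$fasta, proteins = y$proteins,
    out_dir = out_dir %||% y$out_dir,
    enrichment = enr, telomere = tel, paralogy = par,
    adjacency_label = y$adjacency_label %||% "pcwde",
    subtelomeric_cutoff_bp = y$subtelomeric_cutoff_bp %||% 200000L,
    top_regions = y$top_regions,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full genome-architecture pipeline
#'
#' Reads the annotated genome, scans telomeres (when sequences are
#' available), enumerates and tests CAZyme-bounded clusters, merges
#' significant clusters into regions, classifies regions as sub-telomeric,
#' finds adjacent labelled gene runs (with the paralogy filter when
#' proteins are available), computes genome statistics, and writes the
#' whole bundle: candidate/region/telomere/run/stats TSVs, a regions BED, a
#' JSON summary and a parameter log. Identical inputs and configuration
#' produce a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every result table plus `files` (named
#'   paths of the written bundle).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("gff3", "categories", "fasta", "proteins")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input stage: missing ", f, " file: ", p, call. = FALSE)
    }
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  genome <- read_annotation(config$gff3, config$categories,
                            fasta_path = config$fasta)

  chrom <- classify_chromosomes(genome, config$telomere)
  telo <- telomere_hits(genome, config$telomere)
  scaffolds <- dplyr::left_join(
    genome$scaffolds,
    chrom[, c("scaffold_id", "is_putative_chromosome")],
    by = "scaffold_id"
  )

  fit <- enrich_clusters(genome, config$enrichment,
                         top_regions = config$top_regions)
  regions <- subtelomeric_classify(fit$regions, scaffolds,
                                   cutoff_bp = config$subtelomeric_cutoff_bp)

  runs <- find_adjacent_runs(genome, label = config$adjacency_label)
  if (!is.null(config$proteins)) {
    prots <- read_protein_fasta(config$proteins)
    runs <- flag_paralogous_runs(runs, prots, config$paralogy)
  }

  stats <- compute_stats(genome)

  files <- c(
    candidates = file.path(out, "candidates.tsv"),
    regions = file.path(out, "regions.tsv"),
    regions_bed = file.path(out, "regions.bed"),
    telomeres = file.path(out, "telomeres.tsv"),
    chromosomes = file.path(out, "chromosomes.tsv"),
    runs = file.path(out, "adjacent_runs.tsv"),
    stats = file.path(out, "genome_stats.tsv"),
    summary = file.path(out, "summary.json"),
    log = file.path(out, "run_log.txt")
  )
  readr::write_tsv(fit$candidates, files[["candidates"]])
  readr::write_tsv(regions, files[["regions"]])
  write_regions_bed(fit$regions, files[["regions_bed"]])
  readr::write_tsv(telo, files[["telomeres"]])
  readr::write_tsv(chrom, files[["chromosomes"]])
  runs_flat <- runs |>
    dplyr::mutate(gene_ids = vapply(.data$gene_ids, paste,
                                    character(1), collapse = ";"))
  readr::write_tsv(runs_flat, files[["runs"]])
  readr::write_tsv(genome_stats_table(stats), files[["stats"]])

  summary <- list(
    n_genes = genome$n_genes,
    k_cazyme = genome$k_cazyme,
    k_pcwde = genome$k_pcwde,
    n_candidates = nrow(fit$candidates),
    n_significant_clusters = nrow(fit$significant),
    n_regions = nrow(fit$regions),
    n_subtelomeric_regions = sum(regions$is_subtelomeric),
    n_putative_chromosomes = sum(chrom$is_putative_chromosome,
                                 na.rm = TRUE),
    n_adjacent_runs = nrow(runs),
    n_pairs = sum(runs$run_length == 2),
    n_triplets = sum(runs$run_length == 3),
    n_paralogous_runs = if ("contains_paralog_pair" %in% names(runs)) {
      sum(runs$contains_paralog_pair, na.rm = TRUE)
    } else NA,
    region_summary = as.list(fit$summary),
    seed = config$seed
  )
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  log_lines <- c(
    "cazclust pipeline run",
    paste0("gff3: ", config$gff3),
    paste0("categories: ", config$categories),
    paste0("fasta: ", config$fasta %||% "(none)"),
    paste0("proteins: ", config$proteins %||% "(none)"),
    paste0("label: ", config$enrichment$label),
    paste0("alpha: ", config$enrichment$alpha),
    paste0("max_window_genes: ", config$enrichment$max_window_genes),
    paste0("min_hits: ", config$enrichment$min_hits),
    paste0("bonferroni: ", config$enrichment$bonferroni),
    paste0("telomere_motif: ", config$telomere$motif),
    paste0("telomere_window_bp: ", config$telomere$window_bp),
    paste0("telomere_min_copies: ", config$telomere$min_copies),
    paste0("paralogy_min_identity_pct: ", config$paralogy$min_identity_pct),
    paste0("paralogy_min_coverage_pct: ", config$paralogy$min_coverage_pct),
    paste0("adjacency_label: ", config$adjacency_label),
    paste0("subtelomeric_cutoff_bp: ", config$subtelomeric_cutoff_bp),
    paste0("top_regions: ",
           if (is.null(config$top_regions)) "(all)" else config$top_regions),
    paste0("seed: ", config$seed)
  )
  writeLines(log_lines, files[["log"]])

  invisible(list(
    genome = genome, fit = fit, regions = regions, telomeres = telo,
    chromosomes = chrom, runs = runs, stats = stats, summary = summary,
    files = files
  ))
}
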