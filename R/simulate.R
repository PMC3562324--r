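#' Specification for a synthetic genome annotation
#'
#' Describes a multi-scaffold genome with uniformly scattered background
#' CAZyme labels, optional planted high-density clusters, terminal telomeric
#' repeat arrays, and injected near-identical protein pairs standing in for
#' paralogs. Defaults emulate a ~30 Mb filamentous-fungus assembly: nine
#' scaffolds, ~10,013 genes in total, a background CAZyme rate of
#' 371/10,013, telomere arrays at both ends of eight of the nine scaffolds,
#' and an intron structure giving ~78% of genes at least one intron with a
#' mean near 1.95 introns per gene and ~118 bp introns.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param genes_per_scaffold Genes per scaffold (scalar or vector of length
#'   `n_scaffolds`).
#' @param gene_len_bp Two-element range gene spans are drawn from
#'   (uniformly), default 500-3000.
#' @param intergenic_bp Range for intergenic gaps, default 100-2000.
#' @param background_label_rate Per-gene probability of a background CAZyme
#'   label outside planted windows.
#' @param pcwde_rate_given_cazyme Probability a CAZyme gene is also flagged
#'   as a plant cell wall-degrading enzyme (default 114/371, the observed
#'   PCWDE share of the CAZyme census).
#' @param planted_clusters Data frame with columns `scaffold` (1-based
#'   index), `start_ordinal`, `window_genes`, `label_genes`, or `NULL`.
#'   Each planted window gets exactly `label_genes` labelled genes, with
#'   the window's first and last gene labelled.
#' @param telomere_arrays Data frame with columns `scaffold`,
#'   `five_copies`, `three_copies`; defaults to arrays of
#'   `telomere_copies` at both ends of the first
#'   `min(8, n_scaffolds)` scaffolds (none on the rest).
#' @param telomere_motif Repeat unit, default `TTAGGGG`.
#' @param telomere_copies Default copy number for defaulted arrays.
#' @param paralog_injections Data frame with columns `scaffold`,
#'   `source_ordinal`, `target_ordinal`, `mutation_rate`: the target gene's
#'   protein becomes a mutated copy of the source gene's.
#' @param intron_p Probability a gene has any intron (default 0.776).
#' @param intron_extra_lambda Poisson mean for introns beyond the first
#'   (default 1.513, giving an overall mean near 1.95).
#' @param intron_len_bp Range for intron lengths, default 50-190.
#' @param with_sequences Generate scaffold DNA (needed for telomere and GC
#'   analyses; skip for large label-only simulations).
#' @param with_exons Generate mRNA/exon structure (needed for annotation
#'   statistics; skip for label-only simulations).
#' @param with_proteins Generate per-gene proteins (needed for the paralogy
#'   filter).
#' @param seed Integer seed; every simulation is reproducible given the
#'   spec.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_scaffolds = 9L,
                                  genes_per_scaffold = 1113L,
                                  gene_len_bp = c(500L, 3000L),
                                  intergenic_bp = c(100L, 2000L),
                                  background_label_rate = 371 / 10013,
                                  pcwde_rate_given_cazyme = 114 / 371,
                                  planted_clusters = NULL,
                                  telomere_arrays = NULL,
                                  telomere_motif = "TTAGGGG",
                                  telomere_copies = 8L,
                                  paralog_injections = NULL,
                                  intron_p = 0.776,
                                  intron_extra_lambda = 1.513,
                                  intron_len_bp = c(50L, 190L),
                                  with_sequences = TRUE,
                                  with_exons = TRUE,
                                  with_proteins = TRUE,
                                  seed = 1L) {
  stopifnot(n_scaffolds >= 1,
            background_label_rate >= 0, background_label_rate <= 1,
            length(gene_len_bp) == 2, length(intergenic_bp) == 2)
  genes_per_scaffold <- rep_len(as.integer(genes_per_scaffold), n_scaffolds)
  if (is.null(telomere_arrays)) {
    k <- min(8L, n_scaffolds)
    telomere_arrays <- tibble::tibble(
      scaffold = seq_len(k),
      five_copies = as.integer(telomere_copies),
      three_copies = as.integer(telomere_copies)
    )
  } else {
    telomere_arrays <- tibble::as_tibble(telomere_arrays)
  }
  if (!is.null(planted_clusters)) {
    planted_clusters <- tibble::as_tibble(planted_clusters)
    fits <- planted_clusters$start_ordinal + planted_clusters$window_genes <=
      genes_per_scaffold[planted_clusters$scaffold]
    if (!all(fits)) stop("planted cluster does not fit in its scaffold",
                         call. = FALSE)
    if (any(planted_clusters$label_genes > planted_clusters$window_genes) ||
        any(planted_clusters$label_genes < 2)) {
      stop("planted label_genes must be in [2, window_genes]", call. = FALSE)
    }
  }
  if (!is.null(paralog_injections)) {
    paralog_injections <- tibble::as_tibble(paralog_injections)
  }
  structure(
    list(n_scaffolds = as.integer(n_scaffolds),
         genes_per_scaffold = genes_per_scaffold,
         gene_len_bp = as.integer(gene_len_bp),
         intergenic_bp = as.integer(intergenic_bp),
         background_label_rate = background_label_rate,
         pcwde_rate_given_cazyme = pcwde_rate_given_cazyme,
         planted_clusters = planted_clusters,
         telomere_arrays = telomere_arrays,
         telomere_motif = toupper(telomere_motif),
         paralog_injections = paralog_injections,
         intron_p = intron_p,
         intron_extra_lambda = intron_extra_lambda,
         intron_len_bp = as.integer(intron_len_bp),
         with_sequences = isTRUE(with_sequences),
         with_exons = isTRUE(with_exons) || isTRUE(with_proteins),
         with_proteins = isTRUE(with_proteins),
         seed = as.integer(seed)),
    class = "synthetic_genome_spec"
  )
}

# Run code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]], n,
               replace = TRUE), collapse = "")
}

cazy_family_pool <- c("GH1", "GH3", "GH5", "GH6", "GH7", "GH10", "GH11",
                      "GH12", "GH28", "GH43", "GH61", "GH74", "CE1", "CE5",
                      "PL1", "PL3", "CBM1", "GT2")

pcwde_vocab <- c("cellulase", "hemicellulase", "beta-glucosidase",
                 "pectinase", "expansin-like", "tannase",
                 "cellobiose-dehydrogenase")

#' Generate a synthetic genome with recorded ground truth
#'
#' Produces an in-memory genome model (gene table, exon table, optional
#' scaffold sequences), per-gene proteins, and a truth record of every
#' planted feature, sufficient to score each downstream analysis stage.
#' Byte-identical outputs are guaranteed for identical specs.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list of class `synthetic_genome`: `genome` (a
#'   [genome_model()]), `proteins` (named character vector or `NULL`),
#'   `truth` (list with `planted_clusters`, `telomere_arrays`,
#'   `paralog_pairs`, `seed`).
#' @seealso [write_genome_files()] to serialise to GFF3/FASTA/TSV/JSON.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  scaff_ids <- sprintf("scaffold_%d", seq_len(spec$n_scaffolds))
  motif <- spec$telomere_motif
  mlen <- nchar(motif)

  genes_list <- list()
  exons_list <- list()
  seqs <- if (spec$with_sequences) character(0) else NULL
  scaff_len <- integer(spec$n_scaffolds)

  for (s in seq_len(spec$n_scaffolds)) {
    g <- spec$genes_per_scaffold[s]
    arr <- spec$telomere_arrays[spec$telomere_arrays$scaffold == s, ]
    span5 <- if (nrow(arr) > 0 && arr$five_copies[1] > 0) {
      arr$five_copies[1] * mlen
    } else 0L
    span3 <- if (nrow(arr) > 0 && arr$three_copies[1] > 0) {
      arr$three_copies[1] * mlen
    } else 0L

    gene_len <- sample(spec$gene_len_bp[1]:spec$gene_len_bp[2], g,
                       replace = TRUE)
    gaps <- sample(spec$intergenic_bp[1]:spec$intergenic_bp[2], g + 1,
                   replace = TRUE)
    # terminal gaps must clear any telomere array plus a margin
    gaps[1] <- max(gaps[1], span5 + 50L)
    gaps[g + 1] <- max(gaps[g + 1], span3 + 50L)
    starts <- if (g == 1) gaps[1] else {
      cumsum(c(gaps[1], gene_len[-g] + gaps[2:g]))
    }
    ends <- starts + gene_len
    total_len <- ends[g] + gaps[g + 1]
    scaff_len[s] <- total_len

    gid <- sprintf("PDE_%d%04d", s, seq_len(g) - 1L)
    genes_list[[s]] <- tibble::tibble(
      gene_id = gid,
      scaffold_id = scaff_ids[s],
      start = as.integer(starts),
      end = as.integer(ends),
      strand = sample(c("+", "-"), g, replace = TRUE)
    )

    if (spec$with_exons) {
      exons_list[[s]] <- purrr::map_dfr(seq_len(g), function(i) {
        make_exons(gid[i], starts[i], ends[i], spec)
      })
    }

    if (spec$with_sequences) {
      sq <- rand_dna(total_len)
      if (span5 > 0) {
        arr5 <- strrep(revcomp(motif), arr$five_copies[1])
        substr(sq, 1L, span5) <- arr5
      }
      if (span3 > 0) {
        arr3 <- strrep(motif, arr$three_copies[1])
        substr(sq, total_len - span3 + 1L, total_len) <- arr3
      }
      seqs[scaff_ids[s]] <- sq
    }
  }

  genes <- dplyr::bind_rows(genes_list)
  exons <- if (spec$with_exons) dplyr::bind_rows(exons_list) else NULL

  # --- labels ----------------------------------------------------------
  genes$is_cazyme <- FALSE
  genes$ordinal_tmp <- unlist(lapply(spec$genes_per_scaffold,
                                     function(g) seq_len(g) - 1L))
  planted_truth <- NULL
  in_planted <- rep(FALSE, nrow(genes))
  if (!is.null(spec$planted_clusters)) {
    planted_truth <- purrr::pmap_dfr(
      spec$planted_clusters,
      function(scaffold, start_ordinal, window_genes, label_genes, ...) {
        sid <- scaff_ids[scaffold]
        win <- start_ordinal:(start_ordinal + window_genes - 1L)
        sel <- which(genes$scaffold_id == sid &
                       genes$ordinal_tmp %in% win)
        in_planted[sel] <<- TRUE
        # first and last gene of the window are labelled; the rest drawn
        ends_win <- range(win)
        interior <- setdiff(win, ends_win)
        extra <- if (label_genes > 2 && length(interior) > 0) {
          # index-based draw: sample(x, n) misbehaves for scalar x
          sort(interior[sample.int(length(interior), label_genes - 2L)])
        } else integer(0)
        lab <- sort(c(ends_win, extra))
        hit <- which(genes$scaffold_id == sid & genes$ordinal_tmp %in% lab)
        genes$is_cazyme[hit] <<- TRUE
        tibble::tibble(
          scaffold_id = sid, start_ordinal = ends_win[1],
          end_ordinal = ends_win[2], window_genes = window_genes,
          label_genes = label_genes, label_ordinals = list(lab)
        )
      }
    )
  }
  bg <- !in_planted
  genes$is_cazyme[bg] <- stats::runif(sum(bg)) < spec$background_label_rate

  caz <- which(genes$is_cazyme)
  genes$cazy_families <- ""
  genes$cazy_families[caz] <- sample(cazy_family_pool, length(caz),
                                     replace = TRUE)
  genes$is_pcwde <- FALSE
  genes$pcwde_category <- NA_character_
  is_pc <- caz[stats::runif(length(caz)) < spec$pcwde_rate_given_cazyme]
  genes$is_pcwde[is_pc] <- TRUE
  genes$pcwde_category[is_pc] <- sample(pcwde_vocab, length(is_pc),
                                        replace = TRUE)
  genes$ordinal_tmp <- NULL

  # --- proteins --------------------------------------------------------
  proteins <- NULL
  paralog_truth <- NULL
  if (spec$with_proteins) {
    exon_bp <- exons |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(bp = sum(.data$end - .data$start), .groups = "drop")
    plen <- pmax(floor(exon_bp$bp[match(genes$gene_id,
                                        exon_bp$gene_id)] / 3), 30)
    proteins <- vapply(plen, rand_protein, character(1))
    names(proteins) <- genes$gene_id
    if (!is.null(spec$paralog_injections)) {
      ord_tbl <- assign_ordinals(genes)
      paralog_truth <- purrr::pmap_dfr(
        spec$paralog_injections,
        function(scaffold, source_ordinal, target_ordinal, mutation_rate,
                 ...) {
          sid <- scaff_ids[scaffold]
          src <- ord_tbl$gene_id[ord_tbl$scaffold_id == sid &
                                   ord_tbl$ordinal == source_ordinal]
          tgt <- ord_tbl$gene_id[ord_tbl$scaffold_id == sid &
                                   ord_tbl$ordinal == target_ordinal]
          proteins[[tgt]] <<- mutate_protein(proteins[[src]], mutation_rate)
          tibble::tibble(scaffold_id = sid, source_gene = src,
                         target_gene = tgt, mutation_rate = mutation_rate)
        }
      )
    }
  }

  scaffolds <- tibble::tibble(scaffold_id = scaff_ids, length = scaff_len)
  genome <- genome_model(genes, scaffolds = scaffolds, sequences = seqs,
                         exons = exons)

  telo_truth <- spec$telomere_arrays |>
    dplyr::mutate(scaffold_id = scaff_ids[.data$scaffold],
                  motif = motif, .before = 1) |>
    dplyr::select("scaffold_id", "motif", "five_copies", "three_copies")

  structure(
    list(genome = genome, proteins = proteins,
         truth = list(planted_clusters = planted_truth,
                      telomere_arrays = telo_truth,
                      paralog_pairs = paralog_truth,
                      seed = spec$seed)),
    class = "synthetic_genome"
  )
}

# Exon/intron structure for one gene: introns are gaps between exons.
make_exons <- function(gene_id, start, end, spec) {
  span <- end - start
  n_introns <- 0L
  if (stats::runif(1) < spec$intron_p) {
    n_introns <- 1L + stats::rpois(1, spec$intron_extra_lambda)
  }
  repeat {
    if (n_introns == 0L) {
      intron_len <- integer(0)
      break
    }
    intron_len <- sample(spec$intron_len_bp[1]:spec$intron_len_bp[2],
                         n_introns, replace = TRUE)
    if (sum(intron_len) <= span - 30L * (n_introns + 1L)) break
    n_introns <- n_introns - 1L
  }
  exon_total <- span - sum(intron_len)
  n_exons <- n_introns + 1L
  # random composition of exon_total into n_exons parts, each >= 30
  free <- exon_total - 30L * n_exons
  cuts <- sort(sample.int(free + 1L, n_exons - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, free)) + 30L
  exon_starts <- start + cumsum(c(0L, parts[-n_exons] +
                                    intron_len))
  tibble::tibble(
    gene_id = gene_id,
    mrna_id = paste0(gene_id, ".t1"),
    start = as.integer(exon_starts),
    end = as.integer(exon_starts + parts)
  )
}

mutate_protein <- function(seq, rate) {
  aa <- strsplit(seq, NULL)[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) {
    aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> seed =", x$truth$seed, "\n")
  print(x$genome)
  invisible(x)
}

#' Serialise a synthetic genome to standard on-disk formats
#'
#' Writes GFF3 (gene/mRNA/exon features, 1-based closed coordinates with
#' `##sequence-region` directives), scaffold FASTA, the gene-category TSV,
#' a protein FASTA, and a JSON ground-truth record.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths: `gff3`, `fasta`, `categories`,
#'   `proteins`, `truth` (FASTA/protein entries `NA` when not generated).
#' @export
write_genome_files <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- sim$genome

  gff3 <- file.path(dir, "genome.gff3")
  write_gff3(gm, gff3)

  fasta <- NA_character_
  if (!is.null(gm$sequences)) {
    fasta <- file.path(dir, "genome.fasta")
    ss <- Biostrings::DNAStringSet(gm$sequences)
    Biostrings::writeXStringSet(ss, fasta, width = 80)
  }

  categories <- file.path(dir, "categories.tsv")
  gm$genes |>
    dplyr::select("gene_id", "is_cazyme", "cazy_families",
                  "pcwde_category") |>
    readr::write_tsv(categories)

  proteins <- NA_character_
  if (!is.null(sim$proteins)) {
    proteins <- file.path(dir, "proteins.faa")
    aa <- Biostrings::AAStringSet(sim$proteins)
    Biostrings::writeXStringSet(aa, proteins, width = 80)
  }

  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  c(gff3 = gff3, fasta = fasta, categories = categories,
    proteins = proteins, truth = truth)
}

# Write gene/mRNA/exon features back to 1-based closed GFF3.
write_gff3 <- function(gm, path) {
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      gm$scaffolds$scaffold_id, gm$scaffolds$length))
  g <- gm$genes
  gene_lines <- sprintf("%s\tcazclust\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$scaffold_id, g$start + 1L, g$end, g$strand,
                        g$gene_id)
  feature_order <- g$gene_id
  mrna_lines <- character(0)
  exon_lines <- character(0)
  if (!is.null(gm$exons) && nrow(gm$exons) > 0) {
    ex <- gm$exons |>
      dplyr::left_join(g[, c("gene_id", "scaffold_id", "strand")],
                       by = "gene_id")
    mr <- ex |>
      dplyr::group_by(.data$gene_id, .data$mrna_id, .data$scaffold_id,
                      .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
    mrna_lines <- sprintf(
      "%s\tcazclust\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      mr$scaffold_id, mr$start + 1L, mr$end, mr$strand, mr$mrna_id,
      mr$gene_id)
    names(mrna_lines) <- mr$gene_id
    exon_lines <- sprintf(
      "%s\tcazclust\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      ex$scaffold_id, ex$start + 1L, ex$end, ex$strand, ex$mrna_id)
    names(exon_lines) <- ex$gene_id
  }
  body <- unlist(lapply(feature_order, function(id) {
    c(gene_lines[match(id, g$gene_id)],
      unname(mrna_lines[names(mrna_lines) == id]),
      unname(exon_lines[names(exon_lines) == id]))
  }))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Permute label flags uniformly across all genes
#'
#' Null generator for calibration: label columns (CAZyme flag, families,
#' PCWDE flag and category) are moved jointly to a uniformly random
#' permutation of gene positions. Counts are conserved exactly.
#'
#' @param genome A [genome_model()].
#' @param seed Integer seed.
#' @return A new [genome_model()] with permuted labels.
#' @export
permute_labels <- function(genome, seed) {
  stopifnot(inherits(genome, "genome_model"))
  genes <- genome$genes
  perm <- with_seed(seed, sample.int(nrow(genes)))
  cols <- c("is_cazyme", "cazy_families", "is_pcwde", "pcwde_category")
  genes[, cols] <- genes[perm, cols]
  genome_model(genes, scaffolds = genome$scaffolds,
               sequences = genome$sequences, exons = genome$exons)
}
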