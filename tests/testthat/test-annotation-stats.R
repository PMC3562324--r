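toy_stats_genome <- function() {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), scaffold_id = "s1",
    start = c(0L, 400L), end = c(100L, 700L), strand = "+"
  )
  exons <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    mrna_id = c("g1.t1", "g2.t1", "g2.t1"),
    start = c(0L, 400L, 600L), end = c(100L, 500L, 700L)
  )
  genome_model(genes,
               scaffolds = tibble::tibble(scaffold_id = "s1", length = 800L),
               exons = exons)
}

test_that("gene, exon and intron averages follow the gap rule", {
  gm <- toy_stats_genome()
  st <- compute_stats(gm)
  expect_equal(st$avg_gene_length_bp, mean(c(100, 300)))
  # g2 has exons [400,500) and [600,700): one intron of 100 bp
  expect_equal(st$n_genes_with_intron, 1L)
  expect_equal(st$avg_introns_per_gene, 0.5)
  expect_equal(st$avg_intron_bp, 100)
  expect_equal(st$avg_exon_bp, (100 + 100 + 100) / 3)
  # 100 bp and 200 bp of exon -> 33 aa and 66 aa at 3 bp per residue
  expect_equal(compute_stats(gm, min_protein_len_aa = 60)$n_genes_ge_min_len,
               1L)
  expect_equal(compute_stats(gm, min_protein_len_aa = 30)$n_genes_ge_min_len,
               2L)
})

test_that("GC is computed over ACGT only", {
  gm <- toy_stats_genome()
  seqs <- c(s1 = paste0(strrep("GGCCAATT", 100)))  # 50% GC, 800 bp
  st <- compute_stats(gm, sequences = seqs)
  expect_equal(st$gc_pct, 50)
  # Ns are excluded from the denominator
  seqs_n <- c(s1 = paste0(strrep("GGCCAATT", 50), strrep("N", 400)))
  expect_equal(compute_stats(gm, sequences = seqs_n)$gc_pct, 50)
})

test_that("exon + intron lengths add up to the mRNA span", {
  set.seed(19)
  spec <- synthetic_genome_spec(n_scaffolds = 2, genes_per_scaffold = 30,
                                with_sequences = FALSE,
                                with_proteins = FALSE, seed = 19)
  sim <- simulate_genome(spec)
  ex <- sim$genome$exons
  spans <- ex |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(
      span = max(.data$end) - min(.data$start),
      exon_bp = sum(.data$end - .data$start),
      intron_bp = sum(dplyr::lead(.data$start) - .data$end, na.rm = TRUE),
      .groups = "drop"
    )
  expect_equal(spans$exon_bp + spans$intron_bp, spans$span)
})

test_that("overlapping exons are fatal", {
  genes <- tibble::tibble(gene_id = "g1", scaffold_id = "s1",
                          start = 0L, end = 500L, strand = "+")
  exons <- tibble::tibble(gene_id = "g1", mrna_id = "g1.t1",
                          start = c(0L, 80L), end = c(100L, 200L))
  gm <- genome_model(genes, exons = exons)
  expect_error(compute_stats(gm), "overlapping exons.*g1")
})

test_that("simulator output reproduces its own intron parameters", {
  spec <- synthetic_genome_spec(n_scaffolds = 3, genes_per_scaffold = 400,
                                with_sequences = FALSE,
                                with_proteins = FALSE, seed = 23)
  sim <- simulate_genome(spec)
  st <- compute_stats(sim$genome)
  n <- sim$genome$n_genes
  # fraction of genes with an intron ~ 0.776 (binomial 3 SE band)
  p <- spec$intron_p
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(st$n_genes_with_intron / n - p), 3 * se + 0.02)
  # mean introns per gene ~ 0.776 * (1 + 1.513), minus feasibility clipping
  expect_gt(st$avg_introns_per_gene, 1.6)
  expect_lt(st$avg_introns_per_gene, 2.2)
  # intron length uniform on [50, 190] -> mean 120
  expect_gt(st$avg_intron_bp, 110)
  expect_lt(st$avg_intron_bp, 130)
})

test_that("presentation table applies the customary rounding", {
  gm <- toy_stats_genome()
  tab <- genome_stats_table(compute_stats(gm))
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$value[tab$statistic == "Average number of introns per gene"],
               "0.50")
  expect_equal(tab$value[tab$statistic == "Average gene length (bp)"], "200")
})
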