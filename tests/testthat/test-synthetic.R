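test_that("identical specs give byte-identical serialised outputs", {
  spec <- synthetic_genome_spec(n_scaffolds = 3, genes_per_scaffold = 25,
                                seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_genome_files(simulate_genome(spec), d1)
  f2 <- write_genome_files(simulate_genome(spec), d2)
  for (nm in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])),
                     label = nm)
  }
})

test_that("zero background rate with one planted cluster conserves labels", {
  spec <- synthetic_genome_spec(
    n_scaffolds = 1, genes_per_scaffold = 50, background_label_rate = 0,
    planted_clusters = tibble::tibble(scaffold = 1, start_ordinal = 10,
                                      window_genes = 12, label_genes = 10),
    with_sequences = FALSE, with_proteins = FALSE, seed = 5
  )
  sim <- simulate_genome(spec)
  expect_equal(sim$genome$k_cazyme, 10L)
  lab_ords <- sim$genome$genes$ordinal[sim$genome$genes$is_cazyme]
  # the window's first and last genes are labelled, all labels inside it
  expect_true(all(lab_ords >= 10 & lab_ords <= 21))
  expect_true(all(c(10, 21) %in% lab_ords))
  expect_equal(sort(unlist(sim$truth$planted_clusters$label_ordinals)),
               sort(lab_ords))
})

test_that("paper-scale background label count sits in the binomial band", {
  spec <- synthetic_genome_spec(with_sequences = FALSE,
                                with_proteins = FALSE, seed = 101)
  sim <- simulate_genome(spec)
  n <- sim$genome$n_genes
  p <- 371 / 10013
  expect_equal(n, 9 * 1113)
  sd <- sqrt(n * p * (1 - p))
  expect_lt(abs(sim$genome$k_cazyme - n * p), 3 * sd)
})

test_that("generated files round-trip losslessly through the io module", {
  spec <- synthetic_genome_spec(n_scaffolds = 2, genes_per_scaffold = 15,
                                seed = 7)
  sim <- simulate_genome(spec)
  files <- write_genome_files(sim, withr::local_tempdir())
  gm <- read_annotation(files[["gff3"]], files[["categories"]],
                        fasta_path = files[["fasta"]])
  orig <- sim$genome
  cols <- c("gene_id", "scaffold_id", "start", "end", "strand", "ordinal",
            "is_cazyme", "cazy_families", "is_pcwde", "pcwde_category")
  expect_equal(as.data.frame(gm$genes[, cols]),
               as.data.frame(orig$genes[, cols]))
  expect_equal(gm$scaffolds$length, orig$scaffolds$length)
  expect_equal(gm$sequences, orig$sequences)
  key <- function(e) e[order(e$gene_id, e$start), c("gene_id", "mrna_id",
                                                    "start", "end")]
  expect_equal(as.data.frame(key(gm$exons)), as.data.frame(key(orig$exons)))

  prots <- read_protein_fasta(files[["proteins"]])
  expect_equal(sort(names(prots)), sort(names(sim$proteins)))
})

test_that("telomere arrays are planted verbatim at the termini", {
  spec <- synthetic_genome_spec(n_scaffolds = 2, genes_per_scaffold = 10,
                                telomere_arrays = tibble::tibble(
                                  scaffold = 1, five_copies = 4,
                                  three_copies = 6),
                                seed = 13, with_proteins = FALSE)
  sim <- simulate_genome(spec)
  s1 <- sim$genome$sequences[["scaffold_1"]]
  expect_equal(substr(s1, 1, 28), strrep("CCCCTAA", 4))
  expect_equal(substr(s1, nchar(s1) - 41, nchar(s1)), strrep("TTAGGGG", 6))
  # scaffold 2 has no arrays
  s2 <- sim$genome$sequences[["scaffold_2"]]
  expect_false(startsWith(s2, "CCCCTAA"))
})

test_that("infeasible planted clusters are rejected", {
  expect_error(
    synthetic_genome_spec(
      n_scaffolds = 1, genes_per_scaffold = 10,
      planted_clusters = tibble::tibble(scaffold = 1, start_ordinal = 5,
                                        window_genes = 12, label_genes = 5)
    ),
    "does not fit"
  )
  expect_error(
    synthetic_genome_spec(
      n_scaffolds = 1, genes_per_scaffold = 30,
      planted_clusters = tibble::tibble(scaffold = 1, start_ordinal = 0,
                                        window_genes = 10, label_genes = 1)
    ),
    "label_genes"
  )
})

test_that("label permutation conserves counts and varies with the seed", {
  spec <- synthetic_genome_spec(n_scaffolds = 2, genes_per_scaffold = 100,
                                with_sequences = FALSE,
                                with_proteins = FALSE, seed = 31)
  gm <- simulate_genome(spec)$genome
  p1 <- permute_labels(gm, seed = 1)
  p2 <- permute_labels(gm, seed = 2)
  expect_equal(p1$k_cazyme, gm$k_cazyme)
  expect_equal(p1$k_pcwde, gm$k_pcwde)
  expect_false(identical(p1$genes$is_cazyme, p2$genes$is_cazyme))
  # flags move jointly: every permuted PCWDE keeps a category
  expect_true(all(!p1$genes$is_pcwde | !is.na(p1$genes$pcwde_category)))

  # a label-free genome is invariant
  empty <- genome_model(dplyr::mutate(gm$genes, is_cazyme = FALSE,
                                      cazy_families = "", is_pcwde = FALSE,
                                      pcwde_category = NA_character_))
  expect_equal(permute_labels(empty, 3)$genes, empty$genes)
})

test_that("truth record is sufficient to score planted-cluster detection", {
  spec <- synthetic_genome_spec(
    n_scaffolds = 1, genes_per_scaffold = 300,
    background_label_rate = 0.03,
    planted_clusters = tibble::tibble(scaffold = 1, start_ordinal = 100,
                                      window_genes = 12, label_genes = 10),
    with_sequences = FALSE, with_proteins = FALSE, seed = 55
  )
  sim <- simulate_genome(spec)
  fit <- enrich_clusters(sim$genome, enrichment_params())
  truth <- sim$truth$planted_clusters
  covered <- any(fit$significant$first_ordinal <= truth$start_ordinal &
                   fit$significant$last_ordinal >= truth$end_ordinal)
  expect_true(covered)
})
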