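test_that("run detection finds maximal runs only", {
  gm <- genome_model(genes_from_pattern("P,P,N,P,P,P"))
  runs <- find_adjacent_runs(gm, label = "pcwde")
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$run_length, c(2L, 3L))
  expect_equal(runs$start_ordinal, c(0L, 3L))

  expect_equal(nrow(find_adjacent_runs(
    genome_model(genes_from_pattern("P,N,P,N")), "pcwde")), 0L)

  quad <- find_adjacent_runs(
    genome_model(genes_from_pattern("P,P,P,P")), "pcwde")
  expect_equal(nrow(quad), 1L)
  expect_equal(quad$run_length, 4L)
})

test_that("runs are disjoint and never exceed the label census", {
  set.seed(9)
  for (rep in 1:10) {
    pat <- paste(sample(c("P", "N"), 40, replace = TRUE, prob = c(0.4, 0.6)),
                 collapse = ",")
    gm <- genome_model(genes_from_pattern(pat))
    runs <- find_adjacent_runs(gm, "pcwde")
    if (nrow(runs) == 0) next
    expect_lte(sum(runs$run_length), gm$k_pcwde)
    ords <- unlist(purrr::map2(runs$start_ordinal, runs$end_ordinal, `:`))
    expect_equal(anyDuplicated(ords), 0L)
    # maximality: flanking ordinals are label-negative or absent
    flags <- gm$genes$is_pcwde[order(gm$genes$ordinal)]
    for (i in seq_len(nrow(runs))) {
      lo <- runs$start_ordinal[i]
      hi <- runs$end_ordinal[i]
      if (lo > 0) expect_false(flags[lo])           # ordinal lo-1 (1-based)
      if (hi < length(flags) - 1) expect_false(flags[hi + 2])
    }
  }
})

test_that("alignment identity handles the canonical cases", {
  p <- paralogy_params()
  ident <- global_identity("MKVLIT", "MKVLIT", p)
  expect_equal(ident$identity_pct, 100)
  expect_equal(ident$coverage_pct, 100)

  one_sub <- global_identity("ACDEFG", "ACDQFG", p)
  expect_equal(one_sub$identity_pct, 100 * 5 / 6, tolerance = 1e-12)

  disjoint <- global_identity("AAAA", "CCCC", p)
  expect_equal(disjoint$identity_pct, 0)

  expect_error(global_identity("", "ACD", p), "empty")
})

test_that("alignment score equals exhaustive path enumeration (len <= 8)", {
  set.seed(14)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  for (rep in 1:15) {
    a <- paste(sample(aas, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:8, 1), replace = TRUE), collapse = "")
    got <- global_identity(a, b)$score
    expect_equal(got, nw_score_exhaustive(a, b),
                 label = paste(a, "vs", b))
  }
})

test_that("alignment score matches Biostrings on longer random pairs", {
  set.seed(15)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  mat <- matrix(-1, 20, 20, dimnames = list(aas, aas))
  diag(mat) <- 1
  for (rep in 1:3) {
    a <- paste(sample(aas, 60, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE
    )
    expect_equal(global_identity(a, b)$score, ref)
  }
})

test_that("identity is symmetric in its arguments", {
  set.seed(16)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  for (rep in 1:5) {
    a <- paste(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    ab <- global_identity(a, b)
    ba <- global_identity(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct, tolerance = 1e-9)
    expect_equal(ab$coverage_pct, ba$coverage_pct, tolerance = 1e-9)
  }
})

test_that("paralogy flagging separates duplicates from unrelated proteins", {
  gm <- genome_model(genes_from_pattern("P,P,N,P,P"))
  runs <- find_adjacent_runs(gm, "pcwde")
  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  rand_prot <- function(n) paste(sample(aas, n, replace = TRUE),
                                 collapse = "")
  dup <- rand_prot(200)
  proteins <- c(
    s1_g01 = dup, s1_g02 = dup,           # identical pair -> paralogs
    s1_g04 = rand_prot(200), s1_g05 = rand_prot(200)  # unrelated
  )
  flagged <- flag_paralogous_runs(runs, proteins)
  expect_equal(flagged$contains_paralog_pair, c(TRUE, FALSE))
  expect_lt(flagged$max_identity_pct[2], 30)

  # missing protein -> unknown with note
  partial <- flag_paralogous_runs(runs, proteins[-1])
  expect_true(is.na(partial$contains_paralog_pair[1]))
  expect_match(partial$note[1], "missing")
})

test_that("a shared paralog group overrides alignment", {
  gm <- genome_model(genes_from_pattern("P,P"))
  runs <- find_adjacent_runs(gm, "pcwde")
  proteins <- c(s1_g01 = "MKVLIT", s1_g02 = "WWWWWW")
  groups <- tibble::tibble(gene_id = c("s1_g01", "s1_g02"),
                           group_id = "fam1")
  flagged <- flag_paralogous_runs(runs, proteins, paralog_groups = groups)
  expect_true(flagged$contains_paralog_pair)
  expect_match(flagged$note, "shared paralog group")
})

test_that("simulator-injected adjacent duplicates are the only flagged run", {
  spec <- synthetic_genome_spec(
    n_scaffolds = 1, genes_per_scaffold = 40,
    background_label_rate = 0, pcwde_rate_given_cazyme = 1,
    planted_clusters = tibble::tibble(
      scaffold = 1, start_ordinal = c(5, 25), window_genes = c(2, 3),
      label_genes = c(2, 3)
    ),
    paralog_injections = tibble::tibble(
      scaffold = 1, source_ordinal = 5, target_ordinal = 6,
      mutation_rate = 0.05
    ),
    telomere_arrays = tibble::tibble(scaffold = integer(),
                                     five_copies = integer(),
                                     three_copies = integer()),
    with_sequences = FALSE, seed = 77
  )
  sim <- simulate_genome(spec)
  runs <- find_adjacent_runs(sim$genome, "pcwde")
  expect_equal(nrow(runs), 2L)
  flagged <- flag_paralogous_runs(runs, sim$proteins)
  expect_equal(sum(flagged$contains_paralog_pair), 1L)
  hit <- flagged[flagged$contains_paralog_pair, ]
  expect_setequal(unlist(hit$gene_ids),
                  c(sim$truth$paralog_pairs$source_gene,
                    sim$truth$paralog_pairs$target_gene))
})
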