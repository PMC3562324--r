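test_that("candidate enumeration matches brute force on label pairs", {
  gm <- genome_with_labels(10, c(2, 5, 7))
  cand <- enumerate_candidates(gm)
  expect_equal(nrow(cand), 3L)
  expect_equal(cand$first_ordinal, c(2L, 2L, 5L))
  expect_equal(cand$last_ordinal, c(5L, 7L, 7L))
  expect_equal(cand$n_window, c(4L, 6L, 3L))
  expect_equal(cand$k_hits, c(2L, 3L, 2L))

  brute <- candidates_brute(gm)
  expect_equal(cand$p_value, brute$p_value, tolerance = 1e-12)
})

test_that("enumeration honours the window cap and degenerate scaffolds", {
  gm <- genome_with_labels(70, c(0, 60))
  expect_equal(nrow(enumerate_candidates(gm)), 0L)  # window cap 50

  expect_equal(nrow(enumerate_candidates(genome_with_labels(10, 3))), 0L)
  expect_equal(nrow(enumerate_candidates(genome_with_labels(10, integer(0)))),
               0L)
})

test_that("enumeration matches brute force on random multi-scaffold genomes", {
  set.seed(11)
  for (rep in 1:4) {
    genes <- dplyr::bind_rows(lapply(c("sA", "sB", "sC"), function(sid) {
      n <- sample(20:60, 1)
      starts <- (seq_len(n) - 1L) * 1500L
      tibble::tibble(
        gene_id = sprintf("%s_g%03d", sid, seq_len(n)),
        scaffold_id = sid, start = starts, end = starts + 1000L,
        strand = "+", is_cazyme = runif(n) < 0.2
      )
    }))
    gm <- genome_model(genes)
    params <- enrichment_params(max_window_genes = 15)
    cand <- enumerate_candidates(gm, params)
    brute <- candidates_brute(gm, max_window = 15)
    expect_equal(nrow(cand), nrow(brute))
    if (nrow(cand) > 0) {
      key <- function(d) d[order(d$scaffold_id, d$first_ordinal,
                                 d$last_ordinal), ]
      expect_equal(key(cand)$p_value, key(brute)$p_value,
                   tolerance = 1e-12)
      expect_equal(key(cand)$k_hits, key(brute)$k_hits)
    }
  }
})

test_that("significance threshold is inclusive and order-preserving", {
  cand <- tibble::tibble(
    scaffold_id = "s1", first_ordinal = c(1L, 5L, 9L),
    last_ordinal = c(3L, 8L, 12L), n_window = 3L, k_hits = 2L,
    p_value = c(0.001, 0.0011, 1e-6)
  )
  sig <- significant_clusters(cand, enrichment_params(alpha = 0.001))
  expect_equal(sig$p_value, c(0.001, 1e-6))  # 0.001 retained, 0.0011 dropped
  expect_equal(nrow(significant_clusters(cand[0, ], enrichment_params())), 0L)
})

test_that("bonferroni option tightens the threshold", {
  cand <- tibble::tibble(
    scaffold_id = "s1", first_ordinal = 1:10, last_ordinal = 2:11,
    n_window = 2L, k_hits = 2L, p_value = rep(5e-4, 10)
  )
  expect_equal(nrow(significant_clusters(cand, enrichment_params())), 10L)
  expect_equal(
    nrow(significant_clusters(cand, enrichment_params(bonferroni = TRUE))),
    0L  # 5e-4 > 0.001/10
  )
})

test_that("overlapping and abutting clusters merge; disjoint ones do not", {
  gm <- genome_with_labels(60, c(10, 15, 20, 30, 40, 45))
  sig <- tibble::tibble(
    scaffold_id = "s1",
    first_ordinal = c(10L, 15L, 40L),
    last_ordinal = c(20L, 30L, 45L),
    n_window = c(11L, 16L, 6L), k_hits = c(3L, 3L, 2L),
    p_value = c(1e-5, 1e-7, 1e-4)
  )
  regions <- merge_regions(sig, gm)
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$first_ordinal, c(10L, 40L))
  expect_equal(regions$last_ordinal, c(30L, 45L))
  expect_equal(regions$min_p, c(1e-7, 1e-4))
  expect_equal(regions$n_clusters, c(2L, 1L))
  # bp bounds from member gene coordinates
  g <- gm$genes
  expect_equal(regions$start[1], g$start[g$ordinal == 10])
  expect_equal(regions$end[1], g$end[g$ordinal == 30])
  expect_equal(regions$length_bp, regions$end - regions$start)
  # labelled genes inside each ordinal span
  expect_equal(regions$n_label_genes, c(4L, 2L))
})

test_that("clusters on different scaffolds never merge", {
  genes <- dplyr::bind_rows(
    genes_from_pattern("P,P,P,N", "sA"),
    genes_from_pattern("P,P,N,N", "sB")
  )
  gm <- genome_model(genes)
  sig <- tibble::tibble(
    scaffold_id = c("sA", "sB"), first_ordinal = 0L, last_ordinal = 1L,
    n_window = 2L, k_hits = 2L, p_value = 1e-5
  )
  expect_equal(nrow(merge_regions(sig, gm)), 2L)
})

test_that("region summary reproduces printed-percentage arithmetic", {
  # region totalling 0.72 Mb on a 30.19 Mb genome holding 31 of 114 genes
  regions <- tibble::tibble(
    region_id = "R001", scaffold_id = "s1", start = 0L, end = 720000L,
    length_bp = 720000L, n_label_genes = 31L, min_p = 1e-9
  )
  s <- summarize_regions(regions, genome_size_bp = 30.19e6, k_label = 114)
  expect_equal(s$genome_fraction_pct, 2.4)
  expect_equal(s$label_gene_fraction_pct, 27.2)

  s0 <- summarize_regions(regions[0, ], genome_size_bp = 1e6, k_label = 10)
  expect_equal(s0$total_length_bp, 0)
  expect_equal(s0$genome_fraction_pct, 0)
  expect_error(summarize_regions(regions, genome_size_bp = 0, k_label = 10))
})

test_that("enrichment fit object ties the stages together", {
  set.seed(3)
  gm <- genome_with_labels(200, c(50:59, 150))
  fit <- enrich_clusters(gm, enrichment_params())
  expect_s3_class(fit, "cluster_enrichment")
  expect_gt(nrow(fit$significant), 0)
  expect_equal(tidy(fit), fit$regions)
  gl <- glance(fit)
  expect_equal(gl$n_candidates, nrow(fit$candidates))
  expect_equal(gl$n_regions, nrow(fit$regions))
  # a dense run of 10 labels among 200 genes must be significant
  expect_true(any(fit$regions$first_ordinal <= 50 &
                    fit$regions$last_ordinal >= 59))
})

test_that("region tables are deterministic for identical inputs", {
  gm <- genome_with_labels(100, c(10, 12, 14, 40, 70, 72))
  r1 <- tidy(enrich_clusters(gm))
  r2 <- tidy(enrich_clusters(gm))
  expect_identical(r1, r2)
})
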