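# Fixture builders and independent oracles shared across the suite.

# Gene table on one scaffold from a label pattern string like "P,P,N,P":
# genes 1 kb long, 500 bp apart, CAZyme and PCWDE flags both following the
# pattern (PCWDE genes get a fixed category).
genes_from_pattern <- function(pattern, scaffold_id = "s1") {
  flags <- strsplit(pattern, ",")[[1]] == "P"
  n <- length(flags)
  starts <- (seq_len(n) - 1L) * 1500L
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", scaffold_id, seq_len(n)),
    scaffold_id = scaffold_id,
    start = starts,
    end = starts + 1000L,
    strand = "+",
    is_cazyme = flags,
    is_pcwde = flags,
    pcwde_category = ifelse(flags, "cellulase", NA_character_)
  )
}

# Genome with labels at given ordinals on a single scaffold of n genes.
genome_with_labels <- function(n, label_ordinals, scaffold_id = "s1") {
  starts <- (seq_len(n) - 1L) * 1500L
  g <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    scaffold_id = scaffold_id,
    start = starts,
    end = starts + 1000L,
    strand = "+",
    is_cazyme = (seq_len(n) - 1L) %in% label_ordinals
  )
  cazclust::genome_model(g)
}

# Exact hypergeometric upper tail by direct binomial-coefficient
# arithmetic; exact in double precision for N <= 25 (all terms < 2^53).
hg_tail_exact <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force candidate enumeration: every pair of label-positive ordinals
# within the window cap, scored with stats::phyper (independent of the
# package's log-space path).
candidates_brute <- function(genome, label = "cazyme", max_window = 50,
                             min_hits = 2) {
  col <- if (label == "cazyme") "is_cazyme" else "is_pcwde"
  N <- genome$n_genes
  K <- sum(genome$genes[[col]])
  out <- list()
  for (sid in unique(genome$genes$scaffold_id)) {
    g <- genome$genes[genome$genes$scaffold_id == sid, ]
    g <- g[order(g$ordinal), ]
    lab <- g$ordinal[g[[col]]]
    if (length(lab) < 2) next
    for (a in seq_along(lab)) {
      for (b in seq_along(lab)) {
        if (b <= a) next
        nw <- lab[b] - lab[a] + 1
        if (nw > max_window) next
        kh <- b - a + 1
        if (kh < min_hits) next
        out[[length(out) + 1]] <- tibble::tibble(
          scaffold_id = sid, first_ordinal = lab[a], last_ordinal = lab[b],
          n_window = nw, k_hits = kh,
          p_value = stats::phyper(kh - 1, K, N - K, nw, lower.tail = FALSE)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# Naive quadratic tandem-repeat scan over a window string: exact matching.
naive_tandem_copies <- function(window, motif) {
  L <- nchar(motif)
  best <- 0L
  for (p in seq_len(max(nchar(window) - L + 1, 0))) {
    c <- 0L
    q <- p
    while (q + L - 1 <= nchar(window) &&
           substr(window, q, q + L - 1) == motif) {
      c <- c + 1L
      q <- q + L
    }
    best <- max(best, c)
  }
  best
}

# Exhaustive global-alignment score by path enumeration (sequences <= 8).
nw_score_exhaustive <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Write a small GFF3 + category TSV fixture; returns the two paths.
write_toy_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                 genes = NULL) {
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene_id = c("gA", "gB", "gC"),
      scaffold_id = "s1",
      start1 = c(1L, 1001L, 2001L),  # 1-based closed, as in the file
      end1 = c(300L, 1500L, 2600L),
      strand = c("+", "-", "+"),
      is_cazyme = c(TRUE, FALSE, TRUE),
      cazy_families = c("GH5;CBM1", "", "GH7"),
      pcwde_category = c("cellulase", NA, "cellulase")
    )
  }
  gff <- file.path(dir, "toy.gff3")
  lines <- c(
    "##gff-version 3",
    "##sequence-region s1 1 5000",
    sprintf("s1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$start1, genes$end1, genes$strand, genes$gene_id)
  )
  writeLines(lines, gff)
  tsv <- file.path(dir, "toy_categories.tsv")
  readr::write_tsv(
    tibble::tibble(gene_id = genes$gene_id, is_cazyme = genes$is_cazyme,
                   cazy_families = genes$cazy_families,
                   pcwde_category = genes$pcwde_category),
    tsv
  )
  list(gff3 = gff, categories = tsv, genes = genes)
}
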