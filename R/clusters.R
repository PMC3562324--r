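#' Parameters for CAZyme cluster enrichment
#'
#' @param alpha Significance threshold on the raw hypergeometric tail
#'   probability; the threshold is inclusive (`p <= alpha`). Default 0.001.
#' @param max_window_genes Largest candidate window, in genes. Candidate
#'   enumeration is quadratic in the number of labelled genes per scaffold
#'   without a cap; enzyme-dense regions observed in fungal genomes span at
#'   most a few tens of genes. Default 50.
#' @param min_hits Minimum labelled genes per candidate; 2 means the two
#'   distinct bounding genes. Default 2.
#' @param label Which label defines the analysis universe: `"cazyme"` (all
#'   carbohydrate-active enzymes) or `"pcwde"` (plant cell wall-degrading
#'   enzymes only).
#' @param bonferroni If `TRUE`, [significant_clusters()] divides `alpha` by
#'   the number of candidates tested. Off by default: the headline analysis
#'   uses the raw threshold.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(alpha = 0.001, max_window_genes = 50L,
                              min_hits = 2L, label = c("cazyme", "pcwde"),
                              bonferroni = FALSE) {
  label <- match.arg(label)
  stopifnot(alpha > 0, alpha < 1, min_hits >= 2, max_window_genes >= 2)
  structure(
    list(alpha = alpha, max_window_genes = as.integer(max_window_genes),
         min_hits = as.integer(min_hits), label = label,
         bonferroni = isTRUE(bonferroni)),
    class = "enrichment_params"
  )
}

#' Enumerate candidate label-bounded gene clusters
#'
#' A candidate cluster is any ordinal interval `[i, j]`, `i < j`, on one
#' scaffold whose first and last genes both carry the label, containing at
#' most `max_window_genes` genes. Each candidate is scored with
#' [hypergeom_tail()] against the genome-wide background (`N` = all genes,
#' `K` = all labelled genes).
#'
#' @param genome A [genome_model()].
#' @param params An [enrichment_params()].
#' @return Tibble of candidates ordered by scaffold, then first, then last
#'   ordinal, with columns `scaffold_id`, `first_ordinal`, `last_ordinal`,
#'   `first_gene`, `last_gene`, `n_window`, `k_hits`, `p_value`.
#' @export
enumerate_candidates <- function(genome, params = enrichment_params()) {
  stopifnot(inherits(genome, "genome_model"))
  col <- label_column(params$label)
  N <- genome$n_genes
  K <- label_total(genome, params$label)

  per_scaffold <- genome$genes |>
    dplyr::arrange(.data$scaffold_id, .data$ordinal) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::group_split()

  out <- purrr::map(per_scaffold, function(g) {
    lab_ord <- g$ordinal[g[[col]]]
    m <- length(lab_ord)
    if (m < 2) return(NULL)
    # all pairs of labelled ordinals within the window cap; hits between two
    # labelled endpoints = difference of their ranks in lab_ord + 1
    pairs <- purrr::map(seq_len(m - 1), function(a) {
      b <- (a + 1):m
      b <- b[lab_ord[b] - lab_ord[a] + 1 <= params$max_window_genes]
      if (length(b) == 0) return(NULL)
      tibble::tibble(a = a, b = b)
    })
    pairs <- dplyr::bind_rows(pairs)
    if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
    first_ord <- lab_ord[pairs$a]
    last_ord <- lab_ord[pairs$b]
    k_hits <- pairs$b - pairs$a + 1L
    keep <- k_hits >= params$min_hits
    if (!any(keep)) return(NULL)
    tibble::tibble(
      scaffold_id = g$scaffold_id[1],
      first_ordinal = first_ord[keep],
      last_ordinal = last_ord[keep],
      first_gene = g$gene_id[match(first_ord[keep], g$ordinal)],
      last_gene = g$gene_id[match(last_ord[keep], g$ordinal)],
      n_window = last_ord[keep] - first_ord[keep] + 1L,
      k_hits = k_hits[keep]
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      scaffold_id = character(), first_ordinal = integer(),
      last_ordinal = integer(), first_gene = character(),
      last_gene = character(), n_window = integer(), k_hits = integer(),
      p_value = numeric()
    ))
  }
  out$p_value <- hypergeom_tail(N, K, out$n_window, out$k_hits)
  dplyr::arrange(out, .data$scaffold_id, .data$first_ordinal,
                 .data$last_ordinal)
}

#' Filter candidates to statistically significant clusters
#'
#' Retains candidates with `p_value <= alpha` (inclusive). No
#' multiple-testing adjustment is applied by default; setting
#' `bonferroni = TRUE` in the params divides alpha by the number of
#' candidates.
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param params An [enrichment_params()].
#' @return The significant subset, input order preserved.
#' @export
significant_clusters <- function(candidates, params = enrichment_params()) {
  alpha <- params$alpha
  if (isTRUE(params$bonferroni) && nrow(candidates) > 0) {
    alpha <- alpha / nrow(candidates)
  }
  candidates[candidates$p_value <= alpha, , drop = FALSE]
}

#' Merge overlapping significant clusters into enzyme-dense regions
#'
#' Per scaffold, ordinal intervals that overlap or abut (share a gene or sit
#' on consecutive ordinals) are unioned transitively into maximal regions.
#' Region bp bounds run from the first member gene's start to the last
#' member gene's end.
#'
#' @param significant Tibble from [significant_clusters()].
#' @param genome The [genome_model()] the clusters were derived from.
#' @param label Label whose genes are counted in `n_label_genes`; defaults
#'   to `"cazyme"`.
#' @param top_regions Optional integer: keep only the `top_regions` regions
#'   with smallest `min_p` (ties by coordinate order).
#' @return Tibble of regions sorted by scaffold then start: `region_id`,
#'   `scaffold_id`, `first_ordinal`, `last_ordinal`, `start`, `end`,
#'   `length_bp`, `n_clusters`, `n_label_genes`, `min_p`.
#' @export
merge_regions <- function(significant, genome, label = "cazyme",
                          top_regions = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  col <- label_column(label)
  empty <- tibble::tibble(
    region_id = character(), scaffold_id = character(),
    first_ordinal = integer(), last_ordinal = integer(),
    start = integer(), end = integer(), length_bp = integer(),
    n_clusters = integer(), n_label_genes = integer(), min_p = numeric()
  )
  if (nrow(significant) == 0) return(empty)

  merged <- significant |>
    dplyr::arrange(.data$scaffold_id, .data$first_ordinal,
                   .data$last_ordinal) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(
      # a new component starts when this interval begins past the running
      # maximum end + 1 (ordinal space: +1 merges abutting intervals)
      comp = cumsum(.data$first_ordinal >
                      dplyr::lag(cummax(.data$last_ordinal + 1L),
                                 default = -1L))
    ) |>
    dplyr::group_by(.data$scaffold_id, .data$comp) |>
    dplyr::summarise(
      first_ordinal = min(.data$first_ordinal),
      last_ordinal = max(.data$last_ordinal),
      n_clusters = dplyr::n(),
      min_p = min(.data$p_value),
      .groups = "drop"
    )

  genes <- genome$genes
  merged <- merged |>
    dplyr::mutate(
      start = purrr::map2_int(.data$scaffold_id, .data$first_ordinal,
        function(s, o) {
          as.integer(genes$start[genes$scaffold_id == s & genes$ordinal == o])
        }),
      end = purrr::map2_int(.data$scaffold_id, .data$last_ordinal,
        function(s, o) {
          as.integer(genes$end[genes$scaffold_id == s & genes$ordinal == o])
        }),
      n_label_genes = purrr::pmap_int(
        list(.data$scaffold_id, .data$first_ordinal, .data$last_ordinal),
        function(s, i, j) {
          sum(genes[[col]][genes$scaffold_id == s &
                             genes$ordinal >= i & genes$ordinal <= j])
        }),
      length_bp = .data$end - .data$start
    ) |>
    dplyr::arrange(.data$scaffold_id, .data$start) |>
    dplyr::mutate(region_id = sprintf("R%03d", dplyr::row_number())) |>
    dplyr::select("region_id", "scaffold_id", "first_ordinal",
                  "last_ordinal", "start", "end", "length_bp", "n_clusters",
                  "n_label_genes", "min_p")

  if (!is.null(top_regions) && nrow(merged) > top_regions) {
    keep <- merged |>
      dplyr::arrange(.data$min_p, .data$scaffold_id, .data$start) |>
      dplyr::slice_head(n = top_regions)
    merged <- merged[merged$region_id %in% keep$region_id, , drop = FALSE]
  }
  merged
}

#' Summarise enzyme-dense regions against the genome
#'
#' Computes the headline fractions: total region length as a percentage of
#' the genome, and labelled genes inside regions as a percentage of all
#' labelled genes. Percentages are reported rounded to one decimal (the
#' customary printed precision) alongside the unrounded totals.
#'
#' @param regions Tibble from [merge_regions()] (needs `length_bp` and
#'   `n_label_genes`).
#' @param genome A [genome_model()], or `NULL` when `genome_size_bp` and
#'   `k_label` are given directly.
#' @param label Label universe for the gene fraction (used with `genome`).
#' @param genome_size_bp Override for the total genome length in bp.
#' @param k_label Override for the total number of labelled genes.
#' @return One-row tibble: `n_regions`, `total_length_bp`,
#'   `genome_fraction_pct`, `label_genes_in_regions`,
#'   `label_gene_fraction_pct`.
#' @export
summarize_regions <- function(regions, genome = NULL, label = "cazyme",
                              genome_size_bp = NULL, k_label = NULL) {
  if (is.null(genome_size_bp)) {
    stopifnot(inherits(genome, "genome_model"))
    genome_size_bp <- sum(genome$scaffolds$length)
  }
  if (is.null(k_label)) {
    stopifnot(inherits(genome, "genome_model"))
    k_label <- label_total(genome, label)
  }
  if (genome_size_bp <= 0) stop("genome length must be positive",
                                call. = FALSE)
  if (nrow(regions) == 0) {
    return(tibble::tibble(
      n_regions = 0L, total_length_bp = 0, genome_fraction_pct = 0,
      label_genes_in_regions = 0L, label_gene_fraction_pct = 0
    ))
  }
  total <- sum(regions$length_bp)
  in_regions <- sum(regions$n_label_genes)
  tibble::tibble(
    n_regions = nrow(regions),
    total_length_bp = total,
    genome_fraction_pct = round(100 * total / genome_size_bp, 1),
    label_genes_in_regions = in_regions,
    label_gene_fraction_pct =
      if (k_label > 0) round(100 * in_regions / k_label, 1) else 0
  )
}

#' Run the full cluster-enrichment fit on a genome
#'
#' Convenience wrapper chaining [enumerate_candidates()],
#' [significant_clusters()] and [merge_regions()] into one fitted object
#' with [tidy()] and [glance()] methods.
#'
#' @param genome A [genome_model()].
#' @param params An [enrichment_params()].
#' @param top_regions Passed to [merge_regions()].
#' @return An object of class `cluster_enrichment` holding `candidates`,
#'   `significant`, `regions`, `params` and the source genome's census.
#' @export
enrich_clusters <- function(genome, params = enrichment_params(),
                            top_regions = NULL) {
  candidates <- enumerate_candidates(genome, params)
  significant <- significant_clusters(candidates, params)
  regions <- merge_regions(significant, genome, label = params$label,
                           top_regions = top_regions)
  structure(
    list(candidates = candidates, significant = significant,
         regions = regions, params = params,
         summary = summarize_regions(regions, genome, label = params$label)),
    class = "cluster_enrichment"
  )
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat("<cluster_enrichment> label =", x$params$label,
      " alpha =", x$params$alpha, "\n")
  cat("  candidates:  ", nrow(x$candidates), "\n")
  cat("  significant: ", nrow(x$significant), "\n")
  cat("  regions:     ", nrow(x$regions), "\n")
  invisible(x)
}

#' Tidy a cluster-enrichment fit into its region table
#'
#' @param x A `cluster_enrichment` object.
#' @param ... Unused.
#' @return The merged-region tibble.
#' @method tidy cluster_enrichment
#' @export
tidy.cluster_enrichment <- function(x, ...) {
  x$regions
}

#' One-row summary of a cluster-enrichment fit
#'
#' @param x A `cluster_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble with candidate/significant/region counts and the
#'   region summary fractions.
#' @method glance cluster_enrichment
#' @export
glance.cluster_enrichment <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_candidates = nrow(x$candidates),
      n_significant = nrow(x$significant)
    ),
    x$summary
  )
}
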