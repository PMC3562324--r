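#' Classify enriched regions as sub-telomeric
#'
#' A region is sub-telomeric when its nearest edge lies within `cutoff_bp`
#' of a putative chromosome end (inclusive): any overlap of the terminal
#' window counts. Distance is measured to the scaffold end, i.e.
#' `min(start, scaffold_length - end)`. Regions on scaffolds not flagged as
#' putative chromosomes are returned with `is_subtelomeric = FALSE` and an
#' explanatory note — chromosome ends are only meaningful on scaffolds
#' whose termini are telomere-bounded.
#'
#' @param regions Region tibble from [merge_regions()] (`region_id`,
#'   `scaffold_id`, `start`, `end`).
#' @param scaffolds Either a [genome_model()] or a data frame with
#'   `scaffold_id`, `length` and optionally `is_putative_chromosome`
#'   (assumed `TRUE` when the column is absent, e.g. for ad-hoc use on a
#'   known chromosome).
#' @param cutoff_bp Inclusive distance cutoff, default 200,000 bp.
#' @return `regions` with added columns `distance_to_nearest_end`,
#'   `is_subtelomeric`, `cutoff_bp`, `note`.
#' @export
subtelomeric_classify <- function(regions, scaffolds, cutoff_bp = 200000L) {
  if (inherits(scaffolds, "genome_model")) scaffolds <- scaffolds$scaffolds
  scaffolds <- tibble::as_tibble(scaffolds)
  stopifnot(all(c("scaffold_id", "length") %in% names(scaffolds)))
  if (!"is_putative_chromosome" %in% names(scaffolds)) {
    scaffolds$is_putative_chromosome <- TRUE
  }
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, distance_to_nearest_end = integer(),
                         is_subtelomeric = logical(),
                         cutoff_bp = integer(), note = character()))
  }
  idx <- match(regions$scaffold_id, scaffolds$scaffold_id)
  if (anyNA(idx)) {
    stop("region on unknown scaffold: ",
         regions$scaffold_id[is.na(idx)][1], call. = FALSE)
  }
  slen <- scaffolds$length[idx]
  if (any(regions$start < 0 | regions$end > slen)) {
    bad <- which(regions$start < 0 | regions$end > slen)[1]
    stop("region ", regions$region_id[bad], " lies outside its scaffold",
         call. = FALSE)
  }
  is_chrom <- scaffolds$is_putative_chromosome[idx]
  is_chrom[is.na(is_chrom)] <- FALSE
  dist <- pmin(regions$start, slen - regions$end)
  regions |>
    dplyr::mutate(
      distance_to_nearest_end = as.integer(dist),
      is_subtelomeric = is_chrom & dist <= cutoff_bp,
      cutoff_bp = as.integer(cutoff_bp),
      note = dplyr::if_else(is_chrom, "",
                            "scaffold not a putative chromosome")
    )
}
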