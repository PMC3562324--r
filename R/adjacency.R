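#' Parameters for the paralogy filter on adjacent gene runs
#'
#' Two proteins are called paralogous when a global alignment reaches both
#' the identity and the coverage threshold. The scoring scheme is a simple
#' fully disclosed one — match +1, mismatch -1, linear gap -2 — because the
#' filter is a coarse duplicate detector, not a homology search.
#'
#' @param min_identity_pct Identity threshold over aligned columns (gap
#'   columns included in the denominator), default 30.
#' @param min_coverage_pct Fraction of the shorter protein aligned to a
#'   residue of the other, default 50.
#' @param match_score,mismatch_score,gap_penalty Alignment scores.
#' @return A list of class `paralogy_params`.
#' @export
paralogy_params <- function(min_identity_pct = 30, min_coverage_pct = 50,
                            match_score = 1, mismatch_score = -1,
                            gap_penalty = -2) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_coverage_pct > 0, min_coverage_pct <= 100)
  structure(
    list(min_identity_pct = min_identity_pct,
         min_coverage_pct = min_coverage_pct,
         match_score = match_score, mismatch_score = mismatch_score,
         gap_penalty = gap_penalty),
    class = "paralogy_params"
  )
}

#' Find maximal runs of adjacent labelled genes
#'
#' A run is a maximal set of consecutive ordinals on one scaffold whose
#' genes all carry the label; runs of length >= 2 are reported once (a
#' triplet is one run, not two pairs). Adjacency is purely positional:
#' intergenic distance and strand play no role.
#'
#' @param genome A [genome_model()].
#' @param label `"pcwde"` (default — the analysis of interest) or
#'   `"cazyme"`.
#' @return Tibble sorted by scaffold and start: `scaffold_id`,
#'   `start_ordinal`, `end_ordinal`, `run_length`, `gene_ids` (list column).
#' @export
find_adjacent_runs <- function(genome, label = "pcwde") {
  stopifnot(inherits(genome, "genome_model"))
  col <- label_column(label)
  genome$genes |>
    dplyr::arrange(.data$scaffold_id, .data$ordinal) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(run = cumsum(!.data[[col]] |
                                 dplyr::lag(!.data[[col]], default = TRUE))) |>
    dplyr::filter(.data[[col]]) |>
    dplyr::group_by(.data$scaffold_id, .data$run) |>
    dplyr::summarise(
      start_ordinal = min(.data$ordinal),
      end_ordinal = max(.data$ordinal),
      run_length = dplyr::n(),
      gene_ids = list(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$run_length >= 2) |>
    dplyr::arrange(.data$scaffold_id, .data$start_ordinal) |>
    dplyr::select(-"run")
}

#' Global protein alignment identity and coverage
#'
#' Needleman-Wunsch global alignment with linear gap penalties and a
#' deterministic traceback (ties prefer diagonal, then up, then left).
#' Identity is matches over all aligned columns including gap columns;
#' coverage is the fraction of the shorter sequence aligned opposite a
#' residue (not a gap) of the other.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (20-letter alphabet
#'   plus X).
#' @param params A [paralogy_params()].
#' @return One-row tibble: `identity_pct`, `coverage_pct`, `score`,
#'   `aligned_columns`.
#' @export
global_identity <- function(seq_a, seq_b, params = paralogy_params()) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  a <- strsplit(seq_a, NULL)[[1]]
  b <- strsplit(seq_b, NULL)[[1]]
  la <- length(a)
  lb <- length(b)
  gp <- params$gap_penalty
  ms <- params$match_score
  xs <- params$mismatch_score

  score <- matrix(0, la + 1, lb + 1)
  # pointers: 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  ptr <- matrix(0L, la + 1, lb + 1)
  score[, 1] <- gp * 0:la
  score[1, ] <- gp * 0:lb
  ptr[2:(la + 1), 1] <- 2L
  ptr[1, 2:(lb + 1)] <- 3L
  for (i in seq_len(la)) {
    sub <- ifelse(b == a[i], ms, xs)
    for (j in seq_len(lb)) {
      d <- score[i, j] + sub[j]
      u <- score[i, j + 1] + gp
      l <- score[i + 1, j] + gp
      best <- max(d, u, l)
      score[i + 1, j + 1] <- best
      ptr[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }

  i <- la + 1
  j <- lb + 1
  matches <- 0L
  cols <- 0L
  both <- 0L
  while (i > 1 || j > 1) {
    p <- ptr[i, j]
    cols <- cols + 1L
    if (p == 1L) {
      both <- both + 1L
      if (a[i - 1] == b[j - 1]) matches <- matches + 1L
      i <- i - 1
      j <- j - 1
    } else if (p == 2L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  tibble::tibble(
    identity_pct = 100 * matches / cols,
    coverage_pct = 100 * both / min(la, lb),
    score = score[la + 1, lb + 1],
    aligned_columns = cols
  )
}

#' Flag adjacent runs containing a paralogous gene pair
#'
#' Aligns every within-run protein pair and flags the run when any pair
#' reaches both the identity and coverage thresholds — such a run can be
#' explained by tandem duplication rather than functional clustering. A
#' precomputed paralog-group table, when supplied, overrides alignment:
#' two run members sharing a group are paralogs regardless of the scores.
#'
#' @param runs Tibble from [find_adjacent_runs()].
#' @param proteins Named character vector, gene ID -> protein sequence.
#' @param params A [paralogy_params()].
#' @param paralog_groups Optional data frame with columns `gene_id`,
#'   `group_id`.
#' @return `runs` with columns `contains_paralog_pair` (NA when a protein
#'   was missing), `max_identity_pct`, `note`.
#' @export
flag_paralogous_runs <- function(runs, proteins,
                                 params = paralogy_params(),
                                 paralog_groups = NULL) {
  if (nrow(runs) == 0) {
    return(dplyr::mutate(runs, contains_paralog_pair = logical(),
                         max_identity_pct = numeric(), note = character()))
  }
  res <- purrr::map(runs$gene_ids, function(ids) {
    missing <- setdiff(ids, names(proteins))
    if (length(missing) > 0) {
      return(list(flag = NA, max_id = NA_real_,
                  note = paste0("missing protein(s): ",
                                paste(missing, collapse = ","))))
    }
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    if (!is.null(paralog_groups)) {
      grp <- paralog_groups$group_id[match(ids, paralog_groups$gene_id)]
      names(grp) <- ids
      shared <- any(vapply(pairs, function(p) {
        !is.na(grp[p[1]]) && !is.na(grp[p[2]]) && grp[p[1]] == grp[p[2]]
      }, logical(1)))
      if (shared) {
        return(list(flag = TRUE, max_id = NA_real_,
                    note = "shared paralog group"))
      }
    }
    aligned <- purrr::map(pairs, function(p) {
      global_identity(proteins[[p[1]]], proteins[[p[2]]], params)
    })
    hit <- vapply(aligned, function(al) {
      al$identity_pct >= params$min_identity_pct &&
        al$coverage_pct >= params$min_coverage_pct
    }, logical(1))
    list(flag = any(hit),
         max_id = max(vapply(aligned, function(al) al$identity_pct,
                             numeric(1))),
         note = "")
  })
  runs |>
    dplyr::mutate(
      contains_paralog_pair = vapply(res, function(r) r$flag, logical(1)),
      max_identity_pct = vapply(res, function(r) r$max_id, numeric(1)),
      note = vapply(res, function(r) r$note, character(1))
    )
}
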