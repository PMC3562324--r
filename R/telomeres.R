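#' Parameters for terminal telomere-repeat scanning
#'
#' @param motif Telomeric repeat unit read 5'->3' on the top strand, default
#'   `TTAGGGG` (the heptamer found at fungal chromosome ends in this group
#'   of species). The forward motif is sought near the 3' terminus and its
#'   reverse complement near the 5' terminus.
#' @param window_bp Length of the terminal window searched at each end,
#'   default 500 bp. Telomeric arrays sit at the very ends of assembled
#'   scaffolds; a wider window admits arrays behind short terminal gaps.
#' @param min_copies Minimum head-to-tail copies to call an array, default 3
#'   (a single motif occurrence arises by chance in ~16 kb of random
#'   sequence; three tandem copies essentially never do).
#' @param max_mismatch_per_copy Mismatches tolerated within each copy,
#'   default 0 (exact matching). `N` bases never match.
#' @return A list of class `telomere_params`.
#' @export
telomere_params <- function(motif = "TTAGGGG", window_bp = 500L,
                            min_copies = 3L, max_mismatch_per_copy = 0L) {
  motif <- toupper(motif)
  if (nchar(motif) == 0 || grepl("[^ACGT]", motif)) {
    stop("motif must be non-empty over A/C/G/T", call. = FALSE)
  }
  stopifnot(min_copies >= 1, max_mismatch_per_copy >= 0)
  if (window_bp < nchar(motif) * min_copies) {
    stop("window_bp must fit at least min_copies motif copies",
         call. = FALSE)
  }
  structure(
    list(motif = motif, window_bp = as.integer(window_bp),
         min_copies = as.integer(min_copies),
         max_mismatch_per_copy = as.integer(max_mismatch_per_copy)),
    class = "telomere_params"
  )
}

# Reverse complement over ACGTN.
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, NULL), function(ch) {
           paste(rev(ch), collapse = "")
         }, character(1)))
}

# Longest head-to-tail tandem run of `motif` anywhere in `window` (a plain
# character string). Returns list(copies, offset) with offset 0-based into
# the window, or NULL. N counts as a mismatch always.
longest_tandem_run <- function(window, motif, max_mismatch) {
  w <- utf8ToInt(window)
  m <- utf8ToInt(motif)
  L <- length(m)
  W <- length(w)
  if (W < L) return(NULL)
  n_int <- utf8ToInt("N")
  # mism[p] = mismatches of the motif against window starting at position p
  n_anchor <- W - L + 1L
  mism <- integer(n_anchor)
  for (i in seq_len(L)) {
    block <- w[seq.int(i, i + n_anchor - 1L)]
    mism <- mism + as.integer(block != m[i] | block == n_int)
  }
  ok <- mism <= max_mismatch
  if (!any(ok)) return(NULL)
  # copies starting at p = 1 + copies starting at p + L (suffix recursion)
  copies <- integer(n_anchor)
  for (p in n_anchor:1) {
    if (!ok[p]) next
    nxt <- p + L
    copies[p] <- 1L + if (nxt <= n_anchor) copies[nxt] else 0L
  }
  best <- which.max(copies)
  list(copies = copies[best], offset = best - 1L)
}

#' Scan one scaffold terminus for a telomeric tandem array
#'
#' Searches the terminal window for the longest run of head-to-tail motif
#' copies: the forward motif near the 3' end, its reverse complement near
#' the 5' end (telomeres read outward on both strands).
#'
#' @param sequence Scaffold DNA string (A/C/G/T/N).
#' @param terminus `"five_prime"` or `"three_prime"`.
#' @param params A [telomere_params()].
#' @return One-row tibble (`terminus`, `motif`, `copies`, `span_start`,
#'   `span_end`; 0-based half-open scaffold coordinates) or `NULL` when no
#'   array of at least `min_copies` copies is present.
#' @export
scan_terminus <- function(sequence, terminus = c("five_prime", "three_prime"),
                          params = telomere_params()) {
  terminus <- match.arg(terminus)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  slen <- nchar(sequence)
  w <- min(params$window_bp, slen)
  if (terminus == "three_prime") {
    window <- substr(sequence, slen - w + 1L, slen)
    base <- slen - w  # 0-based start of window
    probe <- params$motif
  } else {
    window <- substr(sequence, 1L, w)
    base <- 0L
    probe <- revcomp(params$motif)
  }
  run <- longest_tandem_run(window, probe, params$max_mismatch_per_copy)
  if (is.null(run) || run$copies < params$min_copies) return(NULL)
  span_start <- base + run$offset
  tibble::tibble(
    terminus = terminus,
    motif = params$motif,
    copies = run$copies,
    span_start = as.integer(span_start),
    span_end = as.integer(span_start + run$copies * nchar(params$motif))
  )
}

#' Classify scaffolds as putative chromosomes by two-ended telomere arrays
#'
#' A scaffold carrying a telomeric tandem array at both termini is called a
#' putative chromosome. Scaffolds without sequence are classified `NA`.
#'
#' @param genome A [genome_model()] with sequences, or a named character
#'   vector of scaffold sequences.
#' @param params A [telomere_params()].
#' @return Tibble, one row per scaffold: `scaffold_id`,
#'   `five_prime_copies`, `three_prime_copies` (NA when no array),
#'   `is_putative_chromosome` (logical, NA without sequence).
#' @export
classify_chromosomes <- function(genome, params = telomere_params()) {
  if (inherits(genome, "genome_model")) {
    ids <- genome$scaffolds$scaffold_id
    seqs <- genome$sequences
  } else {
    seqs <- genome
    ids <- names(seqs)
  }
  purrr::map_dfr(ids, function(id) {
    s <- if (!is.null(seqs) && id %in% names(seqs)) seqs[[id]] else NA
    if (is.na(s)) {
      return(tibble::tibble(
        scaffold_id = id, five_prime_copies = NA_integer_,
        three_prime_copies = NA_integer_, is_putative_chromosome = NA
      ))
    }
    h5 <- scan_terminus(s, "five_prime", params)
    h3 <- scan_terminus(s, "three_prime", params)
    tibble::tibble(
      scaffold_id = id,
      five_prime_copies = if (is.null(h5)) NA_integer_ else h5$copies,
      three_prime_copies = if (is.null(h3)) NA_integer_ else h3$copies,
      is_putative_chromosome = !is.null(h5) && !is.null(h3)
    )
  })
}

#' Full telomere report for a genome
#'
#' One row per detected array (rather than per scaffold), convenient for
#' export.
#'
#' @inheritParams classify_chromosomes
#' @return Tibble with `scaffold_id`, `terminus`, `motif`, `copies`,
#'   `span_start`, `span_end`.
#' @export
telomere_hits <- function(genome, params = telomere_params()) {
  if (inherits(genome, "genome_model")) {
    seqs <- genome$sequences
  } else {
    seqs <- genome
  }
  if (is.null(seqs)) {
    return(tibble::tibble(
      scaffold_id = character(), terminus = character(),
      motif = character(), copies = integer(), span_start = integer(),
      span_end = integer()
    ))
  }
  purrr::map_dfr(names(seqs), function(id) {
    hits <- dplyr::bind_rows(
      scan_terminus(seqs[[id]], "five_prime", params),
      scan_terminus(seqs[[id]], "three_prime", params)
    )
    if (nrow(hits) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(scaffold_id = id), hits)
  })
}
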