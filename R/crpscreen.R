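## Kyte-Doolittle hydropathy scale; X (unknown residue) scores 0
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

check_protein_alphabet <- function(sequence, id) {
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), names(KD_SCALE))
  if (length(bad) > 0L) {
    stop("invalid residue(s) ", paste(bad, collapse = ""), " in `", id, "`",
         call. = FALSE)
  }
}

as_protein_tbl <- function(proteins) {
  if (is.character(proteins) && is.null(dim(proteins))) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  proteins <- tibble::as_tibble(proteins)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    stop("proteins need `id` and `sequence` columns", call. = FALSE)
  }
  proteins$sequence <- toupper(proteins$sequence)
  if (any(nchar(proteins$sequence) == 0L)) stop("empty sequence(s)", call. = FALSE)
  if (anyDuplicated(proteins$id)) stop("duplicate protein ids", call. = FALSE)
  if (!("length" %in% names(proteins))) proteins$length <- nchar(proteins$sequence)
  proteins
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first token of the header),
#'   `sequence` (uppercase) and `length`. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, call. = FALSE)
  }
  as_protein_tbl(tibble::tibble(id = ids, sequence = unname(as.character(set))))
}

#' Write proteins to FASTA
#'
#' @param proteins Tibble with `id` and `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @param width Sequence line wrap (default 60 columns).
#' @return `proteins`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  proteins <- as_protein_tbl(proteins)
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(proteins)
}

#' Keep small proteins
#'
#' Small proteins are defined as strictly shorter than `max_len` amino
#' acids (default 200), so a 200-residue protein is excluded.
#'
#' @param proteins Tibble with a `length` column, or with `sequence` from
#'   which lengths are derived.
#' @param max_len Strict upper bound on length (default 200).
#' @return The rows of `proteins` with `length < max_len`.
#' @export
filter_small <- function(proteins, max_len = 200) {
  proteins <- tibble::as_tibble(proteins)
  if (!("length" %in% names(proteins))) {
    proteins$length <- nchar(proteins$sequence)
  }
  proteins[proteins$length < max_len, , drop = FALSE]
}

#' Heuristic N-terminal secretion-signal prediction
#'
#' A transparent stand-in for neural signal-peptide predictors, modelling
#' the canonical signal-peptide anatomy: a charged n-region followed by a
#' hydrophobic h-region. A signal is called present when (a) at least one
#' K or R occurs within the first `n_region_window` residues and (b) some
#' window of `h_len` consecutive residues lying entirely within the first
#' `search_len` residues has mean Kyte-Doolittle hydropathy >=
#' `h_threshold`. Sequences shorter than `min_len` are called absent with
#' `too_short = TRUE`. Published predictions can be used instead via
#' [import_signal_calls()].
#'
#' @param proteins Tibble with `id` and `sequence` (or named character
#'   vector). `X` residues score 0 hydropathy; other non-standard letters
#'   are an error.
#' @param n_region_window Window at the N terminus searched for K/R
#'   (default 5).
#' @param h_len Length of the hydrophobic window (default 8).
#' @param h_threshold Minimum mean hydropathy of the best window
#'   (default 1.6).
#' @param search_len The h-window must end within this many residues of the
#'   N terminus (default 30).
#' @param min_len Minimum sequence length to attempt a call (default 15).
#' @return A tibble with one row per protein: `id`, `present`, `too_short`,
#'   `h_start`, `h_end` (1-based span of the best window), `score` (its
#'   mean hydropathy).
#' @export
predict_signal <- function(proteins, n_region_window = 5L, h_len = 8L,
                           h_threshold = 1.6, search_len = 30L, min_len = 15L) {
  proteins <- as_protein_tbl(proteins)
  rows <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    check_protein_alphabet(seq, id)
    L <- nchar(seq)
    if (L < min_len) {
      return(tibble::tibble(id = id, present = FALSE, too_short = TRUE,
                            h_start = NA_integer_, h_end = NA_integer_,
                            score = NA_real_))
    }
    aa <- strsplit(seq, "")[[1L]]
    charged <- any(aa[seq_len(min(n_region_window, L))] %in% c("K", "R"))
    kd <- KD_SCALE[aa[seq_len(min(search_len, L))]]
    n_win <- length(kd) - h_len + 1L
    means <- vapply(seq_len(n_win), function(i) mean(kd[i:(i + h_len - 1L)]),
                    double(1))
    best <- which.max(means)
    tibble::tibble(id = id, present = charged && means[best] >= h_threshold,
                   too_short = FALSE, h_start = as.integer(best),
                   h_end = as.integer(best + h_len - 1L),
                   score = means[best])
  })
  dplyr::bind_rows(rows)
}

#' Import precomputed signal-peptide calls
#'
#' Reads a two-column TSV (`id`, `signal`) of published predictions, where
#' `signal` is a residue span `"a-b"` (hyphen or en dash) or `"-"` for
#' absent, as printed in signal-prediction result tables.
#'
#' @param path Path to the TSV (header optional).
#' @return A tibble with `id`, `present`, `sig_start`, `sig_end`.
#' @export
import_signal_calls <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  has_header <- grepl("\\bid\\b", first)
  raw <- readr::read_tsv(path, col_names = has_header,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!has_header) names(raw)[1:2] <- c("id", "signal")
  parse_one <- function(id, s) {
    s <- trimws(s)
    if (s == "-" || s == "" || is.na(s)) {
      return(tibble::tibble(id = id, present = FALSE,
                            sig_start = NA_integer_, sig_end = NA_integer_))
    }
    parts <- strsplit(s, "–|-")[[1L]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
      stop("malformed signal span `", s, "` for `", id, "`", call. = FALSE)
    }
    a <- as.integer(parts[1L]); b <- as.integer(parts[2L])
    if (a < 1L || b < a) {
      stop("malformed signal span `", s, "` for `", id, "`", call. = FALSE)
    }
    tibble::tibble(id = id, present = TRUE, sig_start = a, sig_end = b)
  }
  dplyr::bind_rows(purrr::map2(raw$id, raw$signal, parse_one))
}

#' Count cysteines in the C-terminal region
#'
#' Counts `C` residues in the trailing fraction `frac` of the mature
#' sequence. The mature sequence starts at `mature_start` (1 for no signal;
#' one past the signal end after cleavage) and the region is residues
#' `ceil((1 - frac) * L) + 1 .. L` of it.
#'
#' @param sequence Amino-acid string(s).
#' @param frac Trailing fraction treated as the C-terminal region
#'   (default 0.5; `frac = 1` counts all cysteines).
#' @param mature_start 1-based start of the mature sequence (scalar or
#'   vector).
#' @return Integer count(s) of cysteines in the region.
#' @export
count_cterm_cys <- function(sequence, frac = 0.5, mature_start = 1L) {
  sequence <- toupper(sequence)
  mature_start <- rep_len(mature_start, length(sequence))
  mapply(function(seq, ms) {
    mature <- substr(seq, ms, nchar(seq))
    L <- nchar(mature)
    if (L <= 0L) return(0L)
    from <- ceiling((1 - frac) * L) + 1L
    if (from > L) return(0L)
    region <- substr(mature, from, L)
    sum(strsplit(region, "")[[1L]] == "C")
  }, sequence, mature_start, USE.NAMES = FALSE)
}

#' Classify small secreted cysteine-rich peptides
#'
#' A protein is called a CRP candidate when it is small (strictly shorter
#' than `max_len` residues), carries an N-terminal secretion signal, and
#' has an allowed number of cysteines in its C-terminal region (default
#' exactly 4, 6 or 8; set `min_cys` to relax this to "at least `min_cys`").
#' Signals come from [predict_signal()] unless precomputed calls are
#' supplied; with a predicted signal the mature sequence is taken to start
#' one past the hydrophobic window, with an imported call one past the
#' reported span end.
#'
#' @param proteins Tibble with `id` and `sequence` (or named character
#'   vector).
#' @param signals Optional tibble of signal calls from
#'   [import_signal_calls()] (columns `id`, `present`, `sig_end`) or
#'   [predict_signal()].
#' @param max_len Strict small-protein length bound (default 200).
#' @param allowed_cys Allowed C-terminal cysteine counts (default
#'   `c(4, 6, 8)`).
#' @param min_cys If set, overrides `allowed_cys` with the relaxed rule
#'   `n_cterm_cys >= min_cys`.
#' @param cterm_frac Trailing fraction of the mature sequence scanned for
#'   cysteines (default 0.5).
#' @param ... Further arguments passed to [predict_signal()].
#' @return A tibble with one row per protein: `id`, `length`, `is_small`,
#'   `signal_present`, `signal_end`, `n_cterm_cys`, `is_crp`.
#' @export
classify_crp <- function(proteins, signals = NULL, max_len = 200,
                         allowed_cys = c(4, 6, 8), min_cys = NULL,
                         cterm_frac = 0.5, ...) {
  proteins <- as_protein_tbl(proteins)
  if (is.null(signals)) signals <- predict_signal(proteins, ...)
  signals <- tibble::as_tibble(signals)
  end_col <- if ("sig_end" %in% names(signals)) "sig_end" else "h_end"
  idx <- match(proteins$id, signals$id)
  if (anyNA(idx)) {
    stop("no signal call for protein(s): ",
         paste(utils::head(proteins$id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  present <- signals$present[idx]
  sig_end <- signals[[end_col]][idx]
  mature_start <- ifelse(present & !is.na(sig_end), sig_end + 1L, 1L)
  n_cys <- count_cterm_cys(proteins$sequence, frac = cterm_frac,
                           mature_start = mature_start)
  is_small <- proteins$length < max_len
  cys_ok <- if (is.null(min_cys)) n_cys %in% allowed_cys else n_cys >= min_cys
  tibble::tibble(
    id = proteins$id,
    length = proteins$length,
    is_small = is_small,
    signal_present = present,
    signal_end = ifelse(present, sig_end, NA_integer_),
    n_cterm_cys = as.integer(n_cys),
    is_crp = is_small & present & cys_ok
  )
}

#' Packaged small-protein length table
#'
#' The packaged transcription of the published table of pistil-specific or
#' preferentially expressed small proteins: entry label, gene id, protein
#' length (aa) and the reported secretion-signal span (`"a-b"` or `"-"`).
#'
#' @return A tibble with columns `entry`, `gene_id`, `length` and `signal`.
#' @export
table2_lengths <- function() {
  path <- system.file("extdata", "table2_lengths.tsv", package = "pistilscreen",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    entry = readr::col_character(), gene_id = readr::col_character(),
    length = readr::col_integer(), signal = readr::col_character()
  ), progress = FALSE)
}
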