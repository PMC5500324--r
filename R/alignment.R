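#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment with linear gap cost and a
#' deterministic traceback (ties resolved diagonal > up > left). The
#' default scores (match 1, mismatch 0, gap -1) are chosen for
#' hand-checkability. Identity is the number of identical aligned residue
#' pairs divided by the number of aligned columns.
#'
#' @param a,b Non-empty amino-acid (or nucleotide) strings.
#' @param match,mismatch,gap Alignment scores.
#' @return A list with `n_identical`, `aligned_length`, `percent_identity`
#'   and the two gapped `alignment` strings.
#' @examples
#' pairwise_identity("ACDE", "ACDF")$percent_identity  # 75
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence", call. = FALSE)
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)

  score <- matrix(0, n + 1L, m + 1L)
  ## 0 = diagonal, 1 = up (gap in b), 2 = left (gap in a)
  move <- matrix(0L, n + 1L, m + 1L)
  score[, 1L] <- gap * (0:n)
  score[1L, ] <- gap * (0:m)
  move[, 1L] <- 1L
  move[1L, ] <- 2L
  for (i in seq_len(n)) {
    sub <- ifelse(x[i] == y, match, mismatch)
    for (j in seq_len(m)) {
      d <- score[i, j] + sub[j]
      u <- score[i, j + 1L] + gap
      l <- score[i + 1L, j] + gap
      best <- max(d, u, l)
      score[i + 1L, j + 1L] <- best
      move[i + 1L, j + 1L] <- if (d == best) 0L else if (u == best) 1L else 2L
    }
  }

  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- if (i == 1L) 2L else if (j == 1L) 1L else move[i, j]
    if (mv == 0L) {
      ai <- c(x[i - 1L], ai); bi <- c(y[j - 1L], bi); i <- i - 1L; j <- j - 1L
    } else if (mv == 1L) {
      ai <- c(x[i - 1L], ai); bi <- c("-", bi); i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(y[j - 1L], bi); j <- j - 1L
    }
  }
  identical_cols <- sum(ai == bi & ai != "-")
  cols <- length(ai)
  list(n_identical = identical_cols,
       aligned_length = cols,
       percent_identity = 100 * identical_cols / cols,
       alignment = c(paste(ai, collapse = ""), paste(bi, collapse = "")))
}

#' Alignment columns with a conserved cysteine
#'
#' Given equal-length aligned sequences, returns the 1-based column
#' positions at which every row carries a `C`.
#'
#' @param alignment Character vector of gapped, equal-length aligned
#'   sequences.
#' @return Integer vector of fully conserved cysteine columns.
#' @export
conserved_cys_columns <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  alignment <- toupper(alignment)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  which(apply(mat, 2L, function(col) all(col == "C")))
}
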