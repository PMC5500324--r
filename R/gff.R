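#' Gene lengths from a GFF3 gene model
#'
#' Computes, for every gene, the length in base pairs of the union of all
#' exon intervals over all of its transcripts -- the standard exon-model
#' length used in the RPKM denominator. GFF3 coordinates are 1-based
#' inclusive, so an exon `[a, b]` contributes `b - a + 1` bp before overlap
#' reduction.
#'
#' Exons are assigned to genes through their `Parent` attribute: a parent
#' that is itself an mRNA/transcript feature is followed up to its gene; a
#' `gene_id` attribute on the exon, when present, wins. Genes annotated in
#' the file but without any exon are dropped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id` and `length` (bp).
#' @export
gene_lengths_from_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  exons <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(exons) == 0L) {
    stop("no exon features in ", path, call. = FALSE)
  }

  ## transcript id -> gene id, for Parent chains exon -> mRNA -> gene
  tx_types <- c("mrna", "transcript")
  tx <- gr[tolower(as.character(gr$type)) %in% tx_types]
  tx_parent <- character(0)
  if (length(tx) > 0L && !is.null(tx$ID)) {
    tx_parent <- stats::setNames(first_parent(tx), tx$ID)
  }

  gene <- exon_gene_id(exons, tx_parent)
  if (anyNA(gene)) {
    stop("exon(s) without a resolvable gene parent in ", path, call. = FALSE)
  }

  reduced <- GenomicRanges::reduce(S4Vectors::split(exons, gene))
  lengths <- sum(IRanges::width(reduced))

  annotated <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(annotated) > 0L && !is.null(annotated$ID)) {
    no_exon <- setdiff(annotated$ID, names(lengths))
    if (length(no_exon) > 0L) {
      warning("gene(s) without exons omitted: ", paste(no_exon, collapse = ", "),
              call. = FALSE)
    }
  }
  tibble::tibble(gene_id = names(lengths), length = as.numeric(lengths))
}

first_parent <- function(gr) {
  p <- gr$Parent
  if (is.null(p)) return(rep(NA_character_, length(gr)))
  vapply(as.list(p), function(v) if (length(v) > 0L) v[[1L]] else NA_character_,
         character(1))
}

exon_gene_id <- function(exons, tx_parent) {
  gene <- rep(NA_character_, length(exons))
  if (!is.null(exons$gene_id)) {
    gene <- as.character(exons$gene_id)
  }
  parent <- first_parent(exons)
  need <- is.na(gene)
  ## Parent may point at a transcript (follow up one level) or at the gene
  via_tx <- tx_parent[parent[need]]
  gene[need] <- ifelse(is.na(via_tx), parent[need], via_tx)
  gene
}
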