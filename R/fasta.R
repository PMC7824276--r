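#' Read a mitogenome from FASTA plus a feature-table TSV
#'
#' The annotation side channel for bare FASTA input: a TSV with columns
#' `gene`, `strand` (`J`/`N`), `start`, `end` (1-based inclusive, GenBank
#' convention) and optionally `anticodon`. A feature wrapping the origin of
#' a circular molecule is given as `start > end`.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param features_path Path to the feature TSV.
#' @param circular Logical; is the molecule circular?
#' @return A [mitogenome()].
#' @export
read_fasta_annotation <- function(fasta_path, features_path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record in ", fasta_path, call. = FALSE)
  }
  id <- strsplit(names(seqs)[[1]], "[[:space:]]+")[[1]][[1]]
  sequence <- as.character(seqs[[1]])
  tab <- readr::read_tsv(features_path, show_col_types = FALSE)
  req <- c("gene", "strand", "start", "end")
  if (!all(req %in% names(tab))) {
    stop("feature table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"anticodon" %in% names(tab)) tab$anticodon <- NA_character_
  len <- nchar(sequence)
  spans <- purrr::pmap(list(tab$start, tab$end), function(s, e) {
    if (s <= e) {
      list(start = s - 1L, end = as.integer(e))
    } else {
      # wraps the origin
      list(start = c(s - 1L, 0L), end = c(len, as.integer(e)))
    }
  })
  gene <- suppressWarnings(normalize_gene_name(tab$gene, tab$anticodon))
  mitogenome(
    id = id,
    sequence = sequence,
    features = tibble::tibble(
      gene = gene,
      strand = tab$strand,
      start = purrr::map(spans, "start"),
      end = purrr::map(spans, "end"),
      anticodon = as.character(tab$anticodon),
      label = tab$gene
    ),
    circular = circular
  )
}

#' Write a mitogenome as FASTA plus a feature-table TSV
#'
#' Inverse of [read_fasta_annotation()]. Coordinates are written 1-based
#' inclusive; an origin-wrapping feature is written with `start > end`.
#'
#' @param genome A [mitogenome()].
#' @param fasta_path Output FASTA path.
#' @param features_path Output TSV path.
#' @return Invisibly, a list with both paths.
#' @export
write_fasta_annotation <- function(genome, fasta_path, features_path) {
  stopifnot(inherits(genome, "mitogenome"))
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  tab <- tibble::tibble(
    gene = dplyr::coalesce(genome$features$gene, genome$features$label),
    strand = genome$features$strand,
    start = purrr::map_int(genome$features$start, ~ as.integer(.x[[1]] + 1L)),
    end = purrr::map_int(genome$features$end, ~ as.integer(.x[[length(.x)]])),
    anticodon = genome$features$anticodon
  )
  readr::write_tsv(tab, features_path)
  invisible(list(fasta = fasta_path, features = features_path))
}
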