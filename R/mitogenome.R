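#' Construct an annotated mitogenome object
#'
#' The central container: a (usually circular) DNA sequence plus a feature
#' table mapped onto the canonical gene vocabulary. Strand labels follow the
#' majority-coding-strand convention: `"J"` is the strand that encodes
#' `cox1`, `"N"` the opposite strand. When a record is deposited with `cox1`
#' on the minus strand, the deposited plus strand is the N strand and
#' `j_is_plus` is `FALSE`; all analyses are invariant to this choice.
#'
#' Coordinates are 0-based half-open internally (converted from GenBank's
#' 1-based inclusive intervals at the I/O boundary). A feature may consist
#' of several spans, and spans may wrap the origin of a circular molecule.
#'
#' @param id Accession-like identifier string.
#' @param sequence IUPAC DNA string (deposited strand).
#' @param features A data frame with columns `gene` (canonical key or `NA`),
#'   `strand` (`"J"`/`"N"`), `start`, `end` (list-columns of 0-based
#'   half-open span vectors, one element per span, in annotation order),
#'   and optionally `anticodon` and `label` (the raw annotation string).
#' @param circular Logical; is the molecule circular?
#' @param organism Free-text organism name.
#' @param j_is_plus Logical; does the deposited plus strand encode `cox1`?
#' @param allow_duplicates `"error"` (default) or `"first"`: duplicated
#'   annotations for one gene key are surfaced as an error, or the first is
#'   kept with a warning (later copies are dropped).
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features, circular = TRUE,
                       organism = NA_character_, j_is_plus = TRUE,
                       allow_duplicates = c("error", "first")) {
  allow_duplicates <- match.arg(allow_duplicates)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  features <- tibble::as_tibble(features)
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  if (!"label" %in% names(features)) features$label <- features$gene
  if (!all(c("gene", "strand", "start", "end") %in% names(features))) {
    stop("features must have columns gene, strand, start, end", call. = FALSE)
  }
  if (!is.list(features$start)) features$start <- as.list(features$start)
  if (!is.list(features$end)) features$end <- as.list(features$end)
  bad <- !features$strand %in% c("J", "N")
  if (any(bad)) stop("feature strand must be 'J' or 'N'", call. = FALSE)
  len <- nchar(sequence)
  for (i in seq_len(nrow(features))) {
    s <- features$start[[i]]
    e <- features$end[[i]]
    if (length(s) == 0L || length(s) != length(e)) {
      stop("feature ", i, " has malformed spans", call. = FALSE)
    }
    if (any(s >= e)) stop("feature ", i, ": span start >= end", call. = FALSE)
    if (any(e > len) || any(s < 0)) {
      stop("feature '", features$label[[i]], "': coordinate beyond sequence length",
        call. = FALSE
      )
    }
  }
  mapped <- features$gene[!is.na(features$gene)]
  if (anyDuplicated(mapped)) {
    dup <- unique(mapped[duplicated(mapped)])
    if (allow_duplicates == "error") {
      stop("duplicate annotation for gene(s): ", paste(dup, collapse = ", "),
        call. = FALSE
      )
    }
    warning("duplicate annotation for gene(s): ", paste(dup, collapse = ", "),
      "; keeping first occurrence",
      call. = FALSE
    )
    keep <- is.na(features$gene) | !duplicated(features$gene, incomparables = NA)
    features <- features[keep, ]
  }
  structure(
    list(
      id = as.character(id),
      organism = organism,
      sequence = sequence,
      circular = isTRUE(circular),
      j_is_plus = isTRUE(j_is_plus),
      features = features,
      n_runs = count_n_runs(sequence)
    ),
    class = "mitogenome"
  )
}

count_n_runs <- function(sequence) {
  r <- rle(strsplit(sequence, "")[[1]] == "N")
  sum(r$values)
}

#' @export
print.mitogenome <- function(x, ...) {
  n_mapped <- sum(!is.na(x$features$gene))
  cat(
    "<mitogenome> ", x$id,
    if (!is.na(x$organism)) paste0(" (", x$organism, ")"), "\n",
    "  ", nchar(x$sequence), " bp, ",
    if (x$circular) "circular" else "linear", ", ",
    nrow(x$features), " features (", n_mapped, " mapped), ",
    x$n_runs, " N run(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.mitogenome <- function(x, ...) {
  paste0("<mitogenome> ", x$id, ": ", nchar(x$sequence), " bp")
}

feature_lengths <- function(genome) {
  purrr::map2_dbl(
    genome$features$start, genome$features$end,
    ~ sum(.y - .x)
  )
}

# linear start used for circular sorting (start of the first span)
feature_starts <- function(genome) {
  purrr::map_dbl(genome$features$start, 1)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the coding-sense sequence of an annotated gene
#'
#' Concatenates the feature's spans in annotation order and
#' reverse-complements the result when the gene lies on the strand opposite
#' to the deposited plus strand, so the returned string always reads in
#' mRNA sense (5'->3' of the encoded transcript).
#'
#' @param genome A [mitogenome()].
#' @param gene Canonical gene key.
#' @return A DNA string.
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 1))
#' substr(coding_sequence(g, "cox1"), 1, 3) # the start codon
#' @export
coding_sequence <- function(genome, gene) {
  stopifnot(inherits(genome, "mitogenome"))
  i <- match(gene, genome$features$gene)
  if (is.na(i)) stop("gene '", gene, "' not annotated in ", genome$id, call. = FALSE)
  s <- genome$features$start[[i]]
  e <- genome$features$end[[i]]
  seq <- paste0(
    purrr::map2_chr(s, e, ~ substr(genome$sequence, .x + 1L, .y)),
    collapse = ""
  )
  on_plus <- (genome$features$strand[[i]] == "J") == genome$j_is_plus
  if (!on_plus) seq <- revcomp(seq)
  seq
}
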