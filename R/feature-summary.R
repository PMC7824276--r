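#' Classify start and stop codons of the protein-coding genes
#'
#' For every annotated protein-coding gene the start codon is the first
#' three nucleotides of the mRNA-sense CDS. The stop codon is whatever
#' trails after removing complete internal codons: a CDS whose length is
#' congruent to 1 or 2 modulo 3 ends in a partial stop (`T` or `TA`),
#' completed to UAA by polyadenylation of the transcript — the standard
#' metazoan mitochondrial convention. Start classes follow mitogenome
#' practice: ATA/ATG (methionine) are canonical, TTG (leucine) is the
#' common alternative, ATT/ATC (isoleucine) are kept as their own class so
#' either roll-up is derivable.
#'
#' @param genome A [mitogenome()].
#' @return A tibble with one row per protein-coding gene: `genome_id`,
#'   `gene`, `start_codon`, `start_class` (`canonical_ATA_ATG`,
#'   `alternative_TTG`, `ATT_ATC`, `other`), `stop_codon` (1-3 nt),
#'   `stop_class` (`complete` for TAA/TAG, `partial` for T/TA, otherwise
#'   `other`) and `length` (CDS length in nt). Genes with a CDS shorter
#'   than 6 nt are skipped with a warning.
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 1))
#' classify_codons(g)
#' @export
classify_codons <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  pcg <- genome$features$gene[!is.na(genome$features$gene) &
    gene_class(genome$features$gene) == "PCG"]
  rows <- purrr::map(pcg, function(g) {
    cds <- coding_sequence(genome, g)
    n <- nchar(cds)
    if (n < 6L) {
      warning(genome$id, ": CDS of ", g, " shorter than 6 nt; skipped", call. = FALSE)
      return(NULL)
    }
    start <- substr(cds, 1L, 3L)
    r <- n %% 3L
    stop <- if (r == 0L) substr(cds, n - 2L, n) else substr(cds, n - r + 1L, n)
    tibble::tibble(
      genome_id = genome$id,
      gene = g,
      start_codon = start,
      start_class = dplyr::case_when(
        start %in% c("ATA", "ATG") ~ "canonical_ATA_ATG",
        start == "TTG" ~ "alternative_TTG",
        start %in% c("ATT", "ATC") ~ "ATT_ATC",
        TRUE ~ "other"
      ),
      stop_codon = stop,
      stop_class = dplyr::case_when(
        stop %in% c("TAA", "TAG") ~ "complete",
        stop %in% c("T", "TA") ~ "partial",
        TRUE ~ "other"
      ),
      length = n
    )
  })
  dplyr::bind_rows(rows)
}

#' Tabulate intergenic spacers and gene overlaps
#'
#' Features are sorted by circular start position; for each adjacent pair
#' (including the pair wrapping the origin) the gap between them is
#' reported as a spacer (positive gap) or an overlap (negative gap).
#' Zero-length junctions (abutting genes) produce no row. A feature nested
#' wholly inside its neighbour is reported as an overlap of the inner
#' feature's full length, with a warning.
#'
#' @param genome A [mitogenome()] with at least two features.
#' @return A tibble: `genome_id`, `left_gene`, `right_gene`, `kind`
#'   (`spacer`/`overlap`), `length` (bp, always >= 1).
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 1))
#' dplyr::slice_max(spacers_and_overlaps(g), length, n = 3)
#' @export
spacers_and_overlaps <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  f <- genome$features
  if (nrow(f) < 2L) stop("need at least two features", call. = FALSE)
  len <- nchar(genome$sequence)
  ext <- tibble::tibble(
    gene = dplyr::coalesce(f$gene, f$label),
    start = purrr::map_dbl(f$start, 1),
    end = purrr::map2_dbl(f$start, f$end, function(s, e) {
      # unwrapped linear end: a wrapping feature extends past the origin
      if (length(s) > 1L && s[[length(s)]] < s[[1]]) s[[1]] + sum(e - s) else max(e)
    }),
    flen = purrr::map2_dbl(f$start, f$end, ~ sum(.y - .x))
  )
  ext <- dplyr::arrange(ext, start, end)
  n <- nrow(ext)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ext[i, ]
    b <- if (i < n) ext[i + 1L, ] else ext[1L, ]
    gap <- if (i < n) b$start - a$end else b$start + len - a$end
    if (i < n && b$end <= a$end) {
      warning(
        genome$id, ": feature ", b$gene, " nested inside ", a$gene,
        call. = FALSE
      )
      gap <- -b$flen
    }
    if (gap == 0) next
    rows[[i]] <- tibble::tibble(
      genome_id = genome$id,
      left_gene = a$gene,
      right_gene = b$gene,
      kind = if (gap > 0) "spacer" else "overlap",
      length = abs(gap)
    )
  }
  dplyr::bind_rows(rows)
}

#' Whole-molecule base composition
#'
#' Counts A/C/G/T on the deposited strand of the whole molecule. IUPAC
#' ambiguity codes (including N) are excluded from the counts and from the
#' percentage denominator. Percentages are reported to one decimal, the
#' precision at which such values are conventionally quoted.
#'
#' @param genome A [mitogenome()], or a plain DNA string.
#' @return A one-row tibble: `genome_id`, counts `a`, `c`, `g`, `t`,
#'   percentages `a_pct`, `c_pct`, `g_pct`, `t_pct` and `at_pct`.
#' @examples
#' composition(simulate_genome(synthetic_spec(seed = 1)))
#' @export
composition <- function(genome) {
  if (inherits(genome, "mitogenome")) {
    id <- genome$id
    seq <- genome$sequence
  } else {
    stopifnot(is.character(genome), length(genome) == 1L)
    id <- NA_character_
    seq <- toupper(genome)
  }
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0L) stop("sequence contains no unambiguous bases", call. = FALSE)
  tibble::tibble(
    genome_id = id,
    a = as.integer(counts[["A"]]),
    c = as.integer(counts[["C"]]),
    g = as.integer(counts[["G"]]),
    t = as.integer(counts[["T"]]),
    a_pct = round(100 * a / tot, 1),
    c_pct = round(100 * c / tot, 1),
    g_pct = round(100 * g / tot, 1),
    t_pct = round(100 * t / tot, 1),
    at_pct = round(100 * (a + t) / tot, 1)
  )
}
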