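#' The default catalog of named Collembola gene-order models
#'
#' Named mitochondrial gene-order models described for springtails: the
#' ancestral Pancrustacea arrangement plus the derived models named after
#' the taxa in which they were first observed (Tetrodontophora, Podura,
#' Pseudachorutes, Sminthurinus, Sminthurus, Allacma, Lipothrix), four
#' metagenomic arrangements of unidentifiable species (GO A-D) and the
#' three arrangements recognised from re-annotated Seira-group genomes
#' (Trogolaphysa, Seira sp. 3, Seira paraibensis).
#'
#' Models whose complete arrangement follows from their description are
#' fully specified and eligible for exact matching. Models described only
#' by which genes moved (destinations unreported) carry an edit signature
#' instead: the sets of deleted / inverted / translocated genes expected
#' relative to the base order, with `sig_optional` genes allowed to appear
#' as either deleted or translocated (e.g. the unresolved trnY of the
#' Podura model). Where a textual description leaves freedom (destinations
#' of the Tetrodontophora translocations, strands of inverted blocks), one
#' concrete reading is encoded; see the package vignette.
#'
#' @return A tibble with columns `model`, `fully_specified`, `order`
#'   (space-separated signed gene tokens, `-` marking the N strand; `NA`
#'   for signature-only models), `sig_deleted`, `sig_inverted`,
#'   `sig_translocated`, `sig_optional`, `note`. The base model is row 1.
#' @export
default_catalog <- function() {
  base <- pancrustacea_order()
  as_order_string <- function(ord) paste(signed_tokens(ord), collapse = " ")

  # destinations are unreported in the literature; the pair is placed after
  # trnW, where the rearrangement signature is uniquely recoverable (placing
  # it next to trnI, trnQ's ancestral neighbour, leaves the moved set
  # ambiguous between {trnS2, trnQ} and {trnS2, trnI})
  tetro <- apply_edits(base, edit_script(
    edit_translocate("trnS2", after = "trnW"),
    edit_translocate("trnQ", after = "trnS2")
  ))
  sminthurinus <- apply_edits(base, edit_script(
    edit_invert("trnA", "trnR")
  ))
  go_d <- apply_edits(base, edit_script(
    edit_swap("trnM", "trnI")
  ))
  # GO A: trnQ-trnF-trnE-trnS1-trnS2 moved between the control region and
  # trnI, with the trnF-trnE-trnS1 block inverted
  go_a_genes <- c("trnQ", "trnF", "trnE", "trnS1", "trnS2")
  stripped <- base[!base$gene %in% go_a_genes, ]
  at <- match("CR", stripped$gene)
  go_a <- gene_order(
    append(stripped$gene, go_a_genes, after = at),
    append(stripped$strand, c("N", "J", "N", "N", "J"), after = at),
    genome_id = "GO A"
  )
  # Trogolaphysa: trnA-trnR-trnN-trnS1-trnE region rearranged (inversion
  # plus deletion of trnS1) into trnE-trnN-trnA-trnR
  seg <- c("trnA", "trnR", "trnN", "trnS1", "trnE")
  stripped <- base[!base$gene %in% seg, ]
  at <- match("nad3", stripped$gene)
  trogo <- gene_order(
    append(stripped$gene, c("trnE", "trnN", "trnA", "trnR"), after = at),
    append(stripped$strand, c("N", "N", "J", "J"), after = at),
    genome_id = "Trogolaphysa"
  )
  # Seira sp. 3: the same region translocated into trnN-trnS1-trnR-trnE-trnA
  stripped <- base[!base$gene %in% seg, ]
  seira3 <- gene_order(
    append(stripped$gene, c("trnN", "trnS1", "trnR", "trnE", "trnA"), after = at),
    append(stripped$strand, rep("J", 5L), after = at),
    genome_id = "Seira sp. 3"
  )

  full <- tibble::tibble(
    model = c(
      "Pancrustacea model", "Tetrodontophora model", "Sminthurinus model",
      "GO A", "GO D", "Trogolaphysa model", "Seira sp. 3 model"
    ),
    fully_specified = TRUE,
    order = vapply(
      list(base, tetro, sminthurinus, go_a, go_d, trogo, seira3),
      as_order_string, character(1)
    ),
    sig_deleted = NA_character_,
    sig_inverted = NA_character_,
    sig_translocated = NA_character_,
    sig_optional = NA_character_,
    note = c(
      "ancestral arrangement; reference for all comparisons",
      "trnS2 and trnQ translocated (destinations encoded after trnW)",
      "inversion of the trnA-trnR block",
      "five tRNAs moved between CR and trnI; trnF-trnE-trnS1 inverted",
      "reciprocal exchange of trnM and trnI",
      "trnE-trnN-trnA-trnR arrangement (inversion plus trnS1 deletion)",
      "trnN-trnS1-trnR-trnE-trnA arrangement (translocation)"
    )
  )

  sig <- tibble::tibble(
    model = c(
      "Podura model", "GO B", "GO C", "Sminthurus model", "Allacma model",
      "Lipothrix model", "Seira paraibensis model", "Pseudachorutes model"
    ),
    fully_specified = FALSE,
    order = NA_character_,
    sig_deleted = c(NA, NA, NA, NA, NA, NA, "rrnS", NA),
    sig_inverted = c(
      NA, NA, "trnP trnT", "trnP trnT", "trnP trnT", "trnP trnT", NA, NA
    ),
    sig_translocated = c(
      "trnC trnW", "trnC trnW", "trnD", "trnD trnF", "trnD trnY trnL2",
      "trnD trnQ trnY trnC trnI", "rrnL", NA
    ),
    sig_optional = c("trnY", NA, NA, NA, NA, NA, NA, NA),
    note = c(
      "trnC and trnW translocated; trnY lost or translocated",
      "trnW and trnC translocated to unreported positions",
      "putative Sminthuridae ancestral state: trnP/trnT inversion, trnD translocation",
      "Sminthuridae ancestral state plus a trnF translocation",
      "Sminthuridae ancestral state plus trnY and trnL2 translocations",
      "Sminthuridae ancestral state plus trnQ, trnY, trnC, trnI translocations",
      "rrnS deletion and rrnL translocation",
      "protein-coding gene translocations; arrangement unreported, never auto-matched"
    )
  )
  dplyr::bind_rows(full, sig)
}

#' Load a gene-order model catalog
#'
#' With no path, returns the built-in catalog of described springtail
#' gene-order models ([default_catalog()]). A user catalog is a TSV with
#' at least `model`, `fully_specified` and `order` columns (signed gene
#' tokens separated by spaces, `-` marking the N strand); the signature
#' columns of [default_catalog()] are optional.
#'
#' @param path Path to a catalog TSV, or `NULL` for the default.
#' @return A catalog tibble; the base (reference) model is the first row.
#' @examples
#' nrow(load_catalog()) # >= 13 described models
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) return(default_catalog())
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(tab) == 0L) stop("empty catalog: ", path, call. = FALSE)
  req <- c("model", "fully_specified", "order")
  if (!all(req %in% names(tab))) {
    stop("catalog needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  for (col in c("sig_deleted", "sig_inverted", "sig_translocated", "sig_optional", "note")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab$fully_specified <- as.logical(tab$fully_specified)
  for (i in seq_len(nrow(tab))) {
    toks <- c(
      if (!is.na(tab$order[[i]])) sub("^-", "", strsplit(tab$order[[i]], "[[:space:]]+")[[1]]),
      unlist(lapply(
        tab[i, c("sig_deleted", "sig_inverted", "sig_translocated", "sig_optional")],
        parse_sig_set
      ))
    )
    bad <- setdiff(toks, vocab_keys())
    if (length(bad) > 0L) {
      stop(
        "catalog line ", i, " (", tab$model[[i]], "): unknown gene token(s) ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tab
}

#' Write a gene-order model catalog as TSV
#'
#' @param catalog A catalog tibble ([load_catalog()] format).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}
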