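#' Construct a circular signed gene order
#'
#' A gene order is a circular sequence of (gene, strand) pairs, the unit of
#' comparison for rearrangement analysis. Orders are held in canonical
#' rotation: anchored at `cox1` (falling back to `cob`, then `rrnL`, then
#' the alphabetically first gene, with a message) and oriented so the
#' anchor lies on the J strand — if it does not, the whole order is
#' reversed and strand-flipped, which maps a genome deposited on the
#' opposite strand onto the same canonical order.
#'
#' @param genes Character vector of gene keys (no duplicates).
#' @param strands Character vector (`"J"`/`"N"`), recycled if length 1.
#' @param genome_id Identifier carried along in reports.
#' @param complete Logical; all 37 genes plus the control region present?
#'   Computed from `genes` when `NULL`.
#' @param validate Check keys against [gene_vocabulary()]?
#' @return An object of class `gene_order`: a tibble with columns `gene`
#'   and `strand` plus attributes `genome_id`, `complete` and `anchor`.
#' @examples
#' pancrustacea_order()
#' @export
gene_order <- function(genes, strands = "J", genome_id = NA_character_,
                       complete = NULL, validate = TRUE) {
  strands <- rep_len(strands, length(genes))
  stopifnot(all(strands %in% c("J", "N")))
  if (anyDuplicated(genes)) {
    stop("duplicated gene in order: ",
      paste(unique(genes[duplicated(genes)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (validate && !all(genes %in% vocab_keys())) {
    stop("unknown gene key(s): ",
      paste(setdiff(genes, vocab_keys()), collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(complete)) complete <- setequal(genes, vocab_keys())
  ord <- tibble::new_tibble(
    list(gene = as.character(genes), strand = strands),
    nrow = length(genes),
    class = "gene_order",
    genome_id = genome_id,
    complete = complete,
    anchor = NA_character_
  )
  canonicalize_order(ord)
}

#' @export
print.gene_order <- function(x, ...) {
  signed <- ifelse(x$strand == "J", x$gene, paste0("-", x$gene))
  cat(
    "<gene_order> ", attr(x, "genome_id"), ": ", nrow(x), " genes",
    if (isTRUE(attr(x, "complete"))) " (complete)", "\n  ",
    paste(signed, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

order_anchor <- function(genes) {
  for (a in c("cox1", "cob", "rrnL")) {
    if (a %in% genes) {
      if (a != "cox1") {
        message("anchor gene cox1 absent; anchoring at ", a)
      }
      return(a)
    }
  }
  a <- sort(genes)[[1]]
  message("no anchor gene (cox1/cob/rrnL) present; anchoring at ", a)
  a
}

#' Canonicalize a gene order's rotation and orientation
#'
#' @param order A `gene_order` (or tibble with `gene`, `strand`).
#' @param anchor Anchor gene; chosen by priority (`cox1`, `cob`, `rrnL`)
#'   when `NULL`.
#' @return The same order rotated so the anchor is first and oriented so
#'   the anchor is on the J strand.
#' @export
canonicalize_order <- function(order, anchor = NULL) {
  genes <- order$gene
  strands <- order$strand
  if (is.null(anchor)) anchor <- order_anchor(genes)
  i <- match(anchor, genes)
  if (is.na(i)) stop("anchor gene '", anchor, "' not in order", call. = FALSE)
  if (strands[[i]] == "N") {
    genes <- rev(genes)
    strands <- rev(ifelse(strands == "J", "N", "J"))
    i <- match(anchor, genes)
  }
  rot <- c(seq(i, length(genes)), seq_len(i - 1L))
  out <- tibble::new_tibble(
    list(gene = genes[rot], strand = strands[rot]),
    nrow = length(genes),
    class = "gene_order",
    genome_id = attr(order, "genome_id") %||% NA_character_,
    complete = attr(order, "complete") %||% setequal(genes, vocab_keys()),
    anchor = anchor
  )
  out
}

#' Extract the circular signed gene order of an annotated genome
#'
#' Mapped features are sorted by circular start coordinate (traversal
#' direction fixed so that the J strand reads forward) and reduced to their
#' (gene, strand) pairs, then canonicalized. Unmapped features are ignored.
#'
#' @param genome A [mitogenome()] with at least three mapped features.
#' @return A [gene_order()] with `complete = TRUE` when all 37 genes plus
#'   the control region are present.
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 1))
#' extract_gene_order(g)
#' @export
extract_gene_order <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  f <- genome$features[!is.na(genome$features$gene), ]
  if (nrow(f) < 3L) stop("fewer than three mapped features", call. = FALSE)
  ord <- order(purrr::map_dbl(f$start, 1))
  genes <- f$gene[ord]
  strands <- f$strand[ord]
  if (!genome$j_is_plus) {
    # deposited on the opposite strand: ascending coordinates traverse the
    # circle against the canonical (J-forward) direction
    genes <- rev(genes)
    strands <- rev(strands)
  }
  gene_order(genes, strands, genome_id = genome$id)
}

#' The ancestral Pancrustacea mitochondrial gene arrangement
#'
#' The plesiomorphic arrangement of the 37 mitochondrial genes and the
#' control region shared by most hexapods and crustaceans, used as the
#' reference (base) order for rearrangement detection.
#'
#' @return A [gene_order()] of all 38 elements.
#' @export
pancrustacea_order <- function() {
  j <- function(g) tibble::tibble(gene = g, strand = "J")
  n <- function(g) tibble::tibble(gene = g, strand = "N")
  ord <- dplyr::bind_rows(
    j(c("cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
        "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE")),
    n(c("trnF", "nad5", "trnH", "nad4", "nad4L")),
    j("trnT"),
    n("trnP"),
    j(c("nad6", "cob", "trnS2")),
    n(c("nad1", "trnL1", "rrnL", "trnV", "rrnS")),
    j("CR"),
    j("trnI"),
    n("trnQ"),
    j(c("trnM", "nad2", "trnW")),
    n(c("trnC", "trnY"))
  )
  gene_order(ord$gene, ord$strand, genome_id = "Pancrustacea")
}

signed_tokens <- function(order) {
  ifelse(order$strand == "J", order$gene, paste0("-", order$gene))
}

parse_signed_tokens <- function(tokens) {
  neg <- startsWith(tokens, "-")
  tibble::tibble(gene = sub("^-", "", tokens), strand = ifelse(neg, "N", "J"))
}

#' Compare two circular signed gene orders
#'
#' Detects the rearrangements separating a query order from a reference
#' order. Genes present in only one order are reported as deleted (in the
#' reference, absent from the query) or inserted. On the common gene set,
#' a longest common subsequence (LCS) of signed elements is computed over
#' the canonical rotation with the anchor gene held fixed; genes whose
#' strand differs between the orders are inverted, and genes outside the
#' LCS with unchanged strand are translocated. Ties between equally long
#' subsequences are broken deterministically: keep as many protein-coding
#' and rRNA genes as possible in the LCS, then choose the lexicographically
#' smallest displaced set. Breakpoints count the signed adjacencies of the
#' reference (on the common gene set) that are absent from the query.
#'
#' @param query,reference [gene_order()] objects (canonicalized on entry).
#' @return An object of class `rearrangement`: a list with fields
#'   `query_id`, `reference_id`, `deleted`, `inserted`, `inverted`,
#'   `translocated` (character vectors, sorted), `lcs_length`,
#'   `breakpoints` and `identical` (`TRUE` iff the orders are identical up
#'   to rotation). Use [generics::tidy()] / [generics::glance()] for
#'   tabular views.
#' @examples
#' base <- pancrustacea_order()
#' tet <- apply_edits(base, edit_script(
#'   edit_translocate("trnS2", after = "CR"),
#'   edit_translocate("trnQ", after = "trnS2")
#' ))
#' compare_orders(tet, base)
#' @export
compare_orders <- function(query, reference) {
  q <- canonicalize_order(query)
  r <- canonicalize_order(reference)
  deleted <- setdiff(r$gene, q$gene)
  inserted <- setdiff(q$gene, r$gene)
  # the control region is frequently unannotatable; never report it deleted
  deleted <- setdiff(deleted, "CR")
  common <- intersect(r$gene, q$gene)
  if (length(common) < 3L) {
    stop("fewer than three genes in common; comparison uninformative", call. = FALSE)
  }
  qc <- q[q$gene %in% common, ]
  rc <- r[r$gene %in% common, ]
  anchor <- order_anchor(common)
  qc <- canonicalize_order(qc, anchor = anchor)
  rc <- canonicalize_order(rc, anchor = anchor)

  qs <- stats::setNames(qc$strand, qc$gene)
  rs <- stats::setNames(rc$strand, rc$gene)
  inverted <- common[qs[common] != rs[common]]

  kept <- signed_lcs(rc, qc)
  displaced <- setdiff(common, kept)
  translocated <- setdiff(displaced, inverted)

  breakpoints <- count_breakpoints(rc, qc)
  identical_up_to_rotation <- length(deleted) == 0L && length(inserted) == 0L &&
    length(displaced) == 0L && length(inverted) == 0L

  structure(
    list(
      query_id = attr(q, "genome_id"),
      reference_id = attr(r, "genome_id"),
      deleted = sort(deleted),
      inserted = sort(inserted),
      inverted = sort(inverted),
      translocated = sort(translocated),
      lcs_length = length(kept),
      breakpoints = breakpoints,
      identical = identical_up_to_rotation
    ),
    class = "rearrangement"
  )
}

# Weighted LCS of signed sequences (anchor first in both, always matched).
# Additive per-match score, compared lexicographically:
#   1. number of matched genes,
#   2. matched PCG + rRNA genes,
#   3. -2^-rank(gene) summed over matches (rank = alphabetical position),
# Criterion 3 makes the *displaced* set lexicographically smallest: sums of
# distinct powers of two compare like sorted sets.
signed_lcs <- function(ref, qry) {
  a <- signed_tokens(ref)
  b <- signed_tokens(qry)
  n <- length(a)
  m <- length(b)
  genes_all <- sort(union(ref$gene, qry$gene))
  rank <- stats::setNames(seq_along(genes_all), genes_all)
  bonus_of <- function(g) {
    cl <- gene_class(g)
    as.numeric(!is.na(cl) & cl %in% c("PCG", "rRNA"))
  }
  # score components for matching a[i]
  w_len <- rep(1, n)
  w_bon <- vapply(ref$gene, bonus_of, numeric(1))
  w_tie <- -2^(-rank[ref$gene])

  L <- matrix(0, n + 1L, m + 1L) # matched count
  B <- matrix(0, n + 1L, m + 1L) # class bonus
  Tt <- matrix(0, n + 1L, m + 1L) # tie value
  for (i in seq_len(n)) {
    ai <- a[[i]]
    for (j in seq_len(m)) {
      best_l <- L[i, j + 1L]; best_b <- B[i, j + 1L]; best_t <- Tt[i, j + 1L]
      if (L[i + 1L, j] > best_l ||
        (L[i + 1L, j] == best_l && (B[i + 1L, j] > best_b ||
          (B[i + 1L, j] == best_b && Tt[i + 1L, j] > best_t)))) {
        best_l <- L[i + 1L, j]; best_b <- B[i + 1L, j]; best_t <- Tt[i + 1L, j]
      }
      if (ai == b[[j]]) {
        cl <- L[i, j] + w_len[[i]]
        cb <- B[i, j] + w_bon[[i]]
        ct <- Tt[i, j] + w_tie[[i]]
        if (cl > best_l ||
          (cl == best_l && (cb > best_b || (cb == best_b && ct > best_t)))) {
          best_l <- cl; best_b <- cb; best_t <- ct
        }
      }
      L[i + 1L, j + 1L] <- best_l
      B[i + 1L, j + 1L] <- best_b
      Tt[i + 1L, j + 1L] <- best_t
    }
  }
  # backtrack
  kept <- character(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[[i]] == b[[j]] &&
      L[i + 1L, j + 1L] == L[i, j] + w_len[[i]] &&
      B[i + 1L, j + 1L] == B[i, j] + w_bon[[i]] &&
      Tt[i + 1L, j + 1L] == Tt[i, j] + w_tie[[i]]) {
      kept <- c(ref$gene[[i]], kept)
      i <- i - 1L
      j <- j - 1L
    } else if (L[i, j + 1L] == L[i + 1L, j + 1L] &&
      B[i, j + 1L] == B[i + 1L, j + 1L] &&
      Tt[i, j + 1L] == Tt[i + 1L, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  kept
}

# signed circular adjacencies of x as "a|b" strings (gene with sign)
signed_adjacencies <- function(x) {
  tok <- signed_tokens(x)
  nxt <- c(tok[-1], tok[[1]])
  paste(tok, nxt, sep = " | ")
}

count_breakpoints <- function(ref, qry) {
  flip <- function(t) ifelse(startsWith(t, "-"), sub("^-", "", t), paste0("-", t))
  qtok <- signed_tokens(qry)
  qadj <- signed_adjacencies(qry)
  # an adjacency a|b is conserved if present as a|b, or as -b|-a
  qrev <- {
    ft <- flip(qtok)
    paste(c(ft[-1], ft[[1]]), ft, sep = " | ")
  }
  radj <- signed_adjacencies(ref)
  sum(!(radj %in% qadj | radj %in% qrev))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rearrangement report into one row per affected gene
#'
#' @param x A `rearrangement` from [compare_orders()].
#' @param ... Unused.
#' @return A tibble with columns `query_id`, `reference_id`, `gene`,
#'   `change` (`deleted`, `inserted`, `inverted`, `translocated`).
#' @method tidy rearrangement
#' @export
tidy.rearrangement <- function(x, ...) {
  changes <- c("deleted", "inserted", "inverted", "translocated")
  dplyr::bind_rows(purrr::map(changes, function(ch) {
    if (length(x[[ch]]) == 0L) return(NULL)
    tibble::tibble(
      query_id = x$query_id, reference_id = x$reference_id,
      gene = x[[ch]], change = ch
    )
  }))
}

#' One-row summary of a rearrangement report
#'
#' @param x A `rearrangement` from [compare_orders()].
#' @param ... Unused.
#' @return A one-row tibble with counts of each change class, the LCS
#'   length and the breakpoint count.
#' @method glance rearrangement
#' @export
glance.rearrangement <- function(x, ...) {
  tibble::tibble(
    query_id = x$query_id,
    reference_id = x$reference_id,
    n_deleted = length(x$deleted),
    n_inserted = length(x$inserted),
    n_inverted = length(x$inverted),
    n_translocated = length(x$translocated),
    lcs_length = x$lcs_length,
    breakpoints = x$breakpoints,
    identical = x$identical
  )
}

#' @export
print.rearrangement <- function(x, ...) {
  cat("<rearrangement> ", x$query_id, " vs ", x$reference_id, "\n", sep = "")
  if (x$identical) {
    cat("  identical up to rotation\n")
  } else {
    for (ch in c("deleted", "inserted", "inverted", "translocated")) {
      if (length(x[[ch]])) {
        cat("  ", ch, ": ", paste(x[[ch]], collapse = ", "), "\n", sep = "")
      }
    }
    cat("  breakpoints: ", x$breakpoints, "\n", sep = "")
  }
  invisible(x)
}

#' Classify a gene order against a catalog of named models
#'
#' Assignment mirrors curated gene-order tables: `exact` when the query
#' equals a fully specified model up to rotation; `compatible` when the
#' query is incomplete but deleting its missing genes from some model gives
#' equality (the model with fewest missing genes wins, ties going to the
#' base model and then to catalog order); `signature` when the
#' rearrangements relative to the base order match the described edit
#' signature of a partially specified model; otherwise `novel`. Genes
#' absent from an incomplete annotation are treated as missing, not as
#' deletions, and an unannotated control region is never counted missing.
#'
#' @param query A [gene_order()].
#' @param catalog A catalog tibble from [load_catalog()].
#' @return A one-row tibble: `genome_id`, `model`, `match` (`exact`,
#'   `compatible`, `signature`, `novel`) and `missing_genes` (list-column).
#' @examples
#' classify_order(pancrustacea_order(), load_catalog())
#' @export
classify_order <- function(query, catalog = load_catalog()) {
  q <- canonicalize_order(query)
  full <- catalog[catalog$fully_specified, ]
  result <- function(model, match, missing = character(0)) {
    tibble::tibble(
      genome_id = attr(q, "genome_id"),
      model = model,
      match = match,
      missing_genes = list(sort(missing))
    )
  }

  model_orders <- purrr::map(full$order, ~ {
    tok <- parse_signed_tokens(strsplit(.x, "[[:space:]]+")[[1]])
    gene_order(tok$gene, tok$strand, genome_id = NA_character_)
  })

  # exact: equality up to rotation (CR-insensitive when the query lacks it)
  for (k in seq_along(model_orders)) {
    if (orders_equal(q, model_orders[[k]])) {
      return(result(full$model[[k]], "exact"))
    }
  }

  # compatible: remove the query's missing genes from a model
  candidates <- purrr::map(seq_along(model_orders), function(k) {
    mo <- model_orders[[k]]
    missing <- setdiff(mo$gene, c(q$gene, "CR"))
    if (length(missing) == 0L) return(NULL)
    reduced <- mo[!mo$gene %in% missing, ]
    if (orders_equal(q, reduced)) {
      list(model = full$model[[k]], missing = missing, k = k)
    } else {
      NULL
    }
  })
  candidates <- purrr::compact(candidates)
  if (length(candidates) > 0L) {
    n_missing <- purrr::map_int(candidates, ~ length(.x$missing))
    is_base <- purrr::map_lgl(candidates, ~ .x$k == 1L)
    pick <- order(n_missing, !is_base, purrr::map_int(candidates, "k"))[[1]]
    return(result(candidates[[pick]]$model, "compatible", candidates[[pick]]$missing))
  }

  # signature: match described edits relative to the base order
  base <- model_orders[[1]]
  rep <- try(compare_orders(q, base), silent = TRUE)
  if (!inherits(rep, "try-error")) {
    sigs <- catalog[!catalog$fully_specified, ]
    for (k in seq_len(nrow(sigs))) {
      if (signature_matches(rep, sigs[k, ])) {
        return(result(sigs$model[[k]], "signature"))
      }
    }
  }
  result("novel", "novel")
}

orders_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    # tolerate only a missing control region
    if (!"CR" %in% a$gene && "CR" %in% b$gene) b <- b[b$gene != "CR", ]
    if (!"CR" %in% b$gene && "CR" %in% a$gene) a <- a[a$gene != "CR", ]
    if (nrow(a) != nrow(b)) return(FALSE)
  }
  if (!setequal(a$gene, b$gene)) return(FALSE)
  anchor <- order_anchor(a$gene)
  a <- canonicalize_order(a, anchor = anchor)
  b <- canonicalize_order(b, anchor = anchor)
  all(a$gene == b$gene) && all(a$strand == b$strand)
}

parse_sig_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "[[:space:],]+")[[1]]
}

signature_matches <- function(rep, sig_row) {
  sd <- parse_sig_set(sig_row$sig_deleted)
  si <- parse_sig_set(sig_row$sig_inverted)
  st <- parse_sig_set(sig_row$sig_translocated)
  so <- parse_sig_set(sig_row$sig_optional)
  if (length(c(sd, si, st, so)) == 0L) return(FALSE) # undescribed signature
  if (!setequal(rep$inverted, si)) return(FALSE)
  if (!all(sd %in% rep$deleted) || !all(st %in% rep$translocated)) return(FALSE)
  extras <- c(setdiff(rep$deleted, sd), setdiff(rep$translocated, st))
  length(setdiff(extras, so)) == 0L && length(rep$inserted) == 0L
}

#' Classify a set of genomes into gene-order models
#'
#' Batch wrapper around [extract_gene_order()] and [classify_order()],
#' producing the machine-readable twin of a curated "gene order" table.
#'
#' @param genomes A list of [mitogenome()] objects.
#' @param catalog A catalog tibble from [load_catalog()].
#' @return A tibble with one row per genome: `genome_id`, `model`, `match`,
#'   `missing_genes` (comma-separated string), `n_genes`.
#' @export
classify_genomes <- function(genomes, catalog = load_catalog()) {
  rows <- purrr::map(genomes, function(g) {
    ord <- extract_gene_order(g)
    cls <- classify_order(ord, catalog)
    cls$missing_genes <- paste(cls$missing_genes[[1]], collapse = ",")
    cls$n_genes <- nrow(ord)
    cls
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$genome_id)
}
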