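#' Edit-script constructors for gene-order rearrangements
#'
#' The rearrangement vocabulary of comparative mitogenomics, as operations
#' on a circular signed gene order: move a gene next to a new left
#' neighbour, flip a contiguous block onto the opposite strand (reversing
#' it), remove a gene, or exchange the positions of two genes.
#'
#' @param gene,gene_a,gene_b Canonical gene key(s) to edit.
#' @param after Gene key of the new left neighbour (translocation target).
#' @param from,to First and last gene of a contiguous block (inclusive) in
#'   the current canonical order.
#' @param ... For [edit_script()]: edits, in application order.
#' @return A single edit, or for [edit_script()] a list of edits.
#' @examples
#' edit_script(edit_delete("trnC"))
#' @name edits
NULL

#' @rdname edits
#' @export
edit_translocate <- function(gene, after) {
  structure(list(op = "translocate", gene = gene, after = after), class = "mito_edit")
}

#' @rdname edits
#' @export
edit_invert <- function(from, to = from) {
  structure(list(op = "invert", from = from, to = to), class = "mito_edit")
}

#' @rdname edits
#' @export
edit_delete <- function(gene) {
  structure(list(op = "delete", gene = gene), class = "mito_edit")
}

#' @rdname edits
#' @export
edit_swap <- function(gene_a, gene_b) {
  structure(list(op = "swap", gene_a = gene_a, gene_b = gene_b), class = "mito_edit")
}

#' @rdname edits
#' @export
edit_script <- function(...) {
  edits <- list(...)
  if (length(edits) == 1L && is.list(edits[[1]]) && !inherits(edits[[1]], "mito_edit")) {
    edits <- edits[[1]]
  }
  stopifnot(all(purrr::map_lgl(edits, inherits, "mito_edit")))
  structure(edits, class = "mito_edit_script")
}

#' Genes affected by an edit script
#'
#' @param edits An [edit_script()].
#' @return Sorted character vector of the gene keys an edit script touches
#'   (the translocated/deleted/swapped genes and all genes of inverted
#'   blocks, as they stand when each edit is applied to `order`).
#' @param order The order the script applies to (needed to resolve block
#'   extents).
#' @export
edited_genes <- function(edits, order) {
  affected <- character(0)
  cur <- canonicalize_order(order)
  for (e in edits) {
    affected <- c(affected, switch(e$op,
      translocate = e$gene,
      delete = e$gene,
      swap = c(e$gene_a, e$gene_b),
      invert = {
        i <- match(e$from, cur$gene)
        j <- match(e$to, cur$gene)
        cur$gene[seq(i, j)]
      }
    ))
    cur <- apply_edits(cur, edit_script(list(e)))
  }
  sort(unique(affected))
}

#' Apply an edit script to a gene order
#'
#' Edits are applied left to right; the result is re-canonicalized. An
#' edit referring to a gene absent from the (current) order is an error
#' naming the edit.
#'
#' @param order A [gene_order()].
#' @param edits An [edit_script()] (or a single edit).
#' @return The edited, canonicalized [gene_order()].
#' @examples
#' apply_edits(pancrustacea_order(), edit_script(edit_delete("trnC")))
#' @export
apply_edits <- function(order, edits) {
  if (inherits(edits, "mito_edit")) edits <- edit_script(edits)
  genes <- order$gene
  strands <- order$strand
  need <- function(g, e) {
    i <- match(g, genes)
    if (is.na(i)) {
      stop("edit ", e$op, ": gene '", g, "' not present in order", call. = FALSE)
    }
    i
  }
  for (e in edits) {
    if (e$op == "translocate") {
      i <- need(e$gene, e)
      st <- strands[[i]]
      genes <- genes[-i]
      strands <- strands[-i]
      j <- need(e$after, e)
      genes <- append(genes, e$gene, after = j)
      strands <- append(strands, st, after = j)
    } else if (e$op == "delete") {
      i <- need(e$gene, e)
      genes <- genes[-i]
      strands <- strands[-i]
    } else if (e$op == "swap") {
      i <- need(e$gene_a, e)
      j <- need(e$gene_b, e)
      genes[c(i, j)] <- genes[c(j, i)]
      strands[c(i, j)] <- strands[c(j, i)]
    } else if (e$op == "invert") {
      i <- need(e$from, e)
      j <- need(e$to, e)
      if (i > j) stop("edit invert: block ", e$from, "..", e$to,
        " does not read forward in the current order", call. = FALSE)
      seg <- seq(i, j)
      genes[seg] <- rev(genes[seg])
      strands[seg] <- rev(ifelse(strands[seg] == "J", "N", "J"))
    } else {
      stop("unknown edit op: ", e$op, call. = FALSE)
    }
  }
  gene_order(genes, strands,
    genome_id = attr(order, "genome_id"),
    validate = FALSE
  )
}

#' Draw a random edit script of well-separated edits
#'
#' Samples `n_edits` single-gene translocations, short block inversions
#' and/or single-gene deletions whose footprints are pairwise non-adjacent
#' in the starting order, never touch the anchor gene, and (for
#' translocations) move a gene by at least two positions. Under these
#' separation conditions the edits leave independent traces, so
#' [compare_orders()] of the edited order against the original recovers
#' exactly the edited genes.
#'
#' @param order The starting [gene_order()].
#' @param n_edits Number of edits (>= 1).
#' @param ops Edit types to draw from.
#' @param max_block Maximum inverted-block length.
#' @return An [edit_script()]. Uses the current RNG stream; seed it with
#'   [set.seed()] (or `withr::with_seed()`) for reproducibility.
#' @export
random_edit_script <- function(order, n_edits = 2L,
                               ops = c("translocate", "invert", "delete"),
                               max_block = 3L) {
  ord <- canonicalize_order(order)
  n <- nrow(ord)
  nbhd <- function(p) unique(c(p, (p %% n) + 1L, ((p - 2L) %% n) + 1L))
  repeat {
    chosen <- sample(ops, n_edits, replace = TRUE)
    edits <- list()
    # positions (in the starting order) that later edits must stay clear
    # of: edited genes, translocation destinations, and their neighbours;
    # the anchor at position 1 is never touched
    blocked <- nbhd(1L)
    ok <- TRUE
    for (op in chosen) {
      if (op == "invert") {
        len <- sample(seq_len(max_block), 1L)
        covers <- unique(unlist(lapply(seq_len(len) - 1L, function(k) {
          ((blocked - 1L - k) %% n) + 1L
        })))
        starts <- setdiff(seq_len(n), covers)
        starts <- starts[starts + len - 1L <= n]
        if (length(starts) == 0L) { ok <- FALSE; break }
        i <- sample(starts, 1L)
        block <- seq(i, i + len - 1L)
        edits <- c(edits, list(edit_invert(ord$gene[[i]], ord$gene[[i + len - 1L]])))
        blocked <- unique(c(blocked, unlist(lapply(block, nbhd))))
      } else {
        cand <- setdiff(seq_len(n), blocked)
        if (length(cand) == 0L) { ok <- FALSE; break }
        if (op == "delete") {
          # a deleted control region leaves no trace (it is never reported
          # deleted), so only real genes are deletion candidates
          cand <- cand[ord$gene[cand] != "CR"]
          if (length(cand) == 0L) { ok <- FALSE; break }
          i <- sample(cand, 1L)
          edits <- c(edits, list(edit_delete(ord$gene[[i]])))
          blocked <- unique(c(blocked, nbhd(i)))
        } else {
          i <- sample(cand, 1L)
          # destination: a left neighbour that moves the gene by at least
          # two positions and is clear of every other edit
          far <- setdiff(seq_len(n), unique(c(
            blocked, nbhd(i), ((i + 1L) %% n) + 1L, ((i - 3L) %% n) + 1L, n
          )))
          if (length(far) == 0L) { ok <- FALSE; break }
          j <- sample(far, 1L)
          edits <- c(edits, list(edit_translocate(ord$gene[[i]], ord$gene[[j]])))
          blocked <- unique(c(blocked, nbhd(i), nbhd(j)))
        }
      }
    }
    if (ok) return(edit_script(edits))
  }
}

class_probs <- function(at_share, at_skew, cg_skew) {
  c(
    A = at_share * (1 + at_skew) / 2,
    C = (1 - at_share) * (1 + cg_skew) / 2,
    G = (1 - at_share) * (1 - cg_skew) / 2,
    T = at_share * (1 - at_skew) / 2
  )
}

default_class_targets <- function() {
  tibble::tibble(
    class = site_classes(),
    at_share = c(0.55, 0.55, 0.60, 0.60, 0.70, 0.70, 0.75, 0.75),
    at_skew = c(0.10, -0.20, -0.37, -0.39, -0.05, -0.10, -0.10, -0.20),
    cg_skew = c(-0.05, -0.30, 0.27, 0.00, 0.45, -0.35, 0.30, -0.30)
  )
}

# internal codon counts per PCG (start and stop codons excluded), sized
# like a typical ~15 kb springtail mitogenome (~3700 codons in total)
default_codon_counts <- function() {
  c(
    cox1 = 512, cox2 = 227, cox3 = 261, cob = 378,
    nad1 = 311, nad2 = 324, nad3 = 117, nad4 = 446, nad4L = 95,
    nad5 = 571, nad6 = 165, atp6 = 224, atp8 = 52
  )
}

default_start_plan <- function() {
  c(
    cox2 = "ATG", cox3 = "ATG", cob = "ATG", nad2 = "ATG", nad4 = "ATG",
    nad5 = "ATG", nad4L = "TTG",
    cox1 = "ATT", nad1 = "ATT", nad3 = "ATT", nad6 = "ATT",
    atp6 = "ATT", atp8 = "ATT"
  )
}

default_stop_plan <- function() {
  c(
    cox1 = "T", cox2 = "T", cox3 = "T", nad1 = "T", nad2 = "T",
    nad3 = "T", nad4 = "T", nad5 = "TA", cob = "TA",
    nad4L = "TAA", nad6 = "TAA", atp6 = "TAA", atp8 = "TAG"
  )
}

default_rna_lengths <- function() {
  lens <- stats::setNames(
    rep(65L, 22L),
    grep("^trn", vocab_keys(), value = TRUE)
  )
  c(lens, rrnS = 779L, rrnL = 1277L, CR = 830L)
}

#' Specify a synthetic annotated mitogenome
#'
#' A full recipe for [simulate_genome()]: the gene order (a catalog model
#' name or an explicit [gene_order()], plus an optional edit script), the
#' number of internal codons per protein-coding gene, per-class base
#' composition targets, RNA/control-region lengths, a spacer/overlap plan,
#' start and stop codon plans, and the seed. Defaults emulate a typical
#' springtail mitogenome: the ancestral Pancrustacea arrangement, ~15.5 kb,
#' ~3700 codons, AT-rich composition with positive J-strand and negative
#' N-strand CG asymmetry at degenerate sites, one long intergenic spacer
#' ahead of nad1 and a 33 bp rrnL/trnV overlap.
#'
#' @param id Genome identifier (default derived from the seed).
#' @param organism Organism label written to output files.
#' @param base Catalog model name (see [load_catalog()]) or a
#'   [gene_order()].
#' @param edits An [edit_script()] applied to the base order.
#' @param codon_counts Named integer vector: internal codons per PCG.
#' @param class_targets Tibble with columns `class`, `at_share`,
#'   `at_skew`, `cg_skew` for the eight site classes (see
#'   [site_classes()]); targets are the distributions from which counted
#'   bases are drawn.
#' @param start_plan,stop_plan Named character vectors of start codons and
#'   stop codons (`TAA`/`TAG` complete, `T`/`TA` partial) per PCG.
#' @param rna_lengths Named lengths for tRNAs, rRNAs and the control
#'   region.
#' @param spacer_plan Named numeric vector: junction gap in bp, named by
#'   the left-hand gene; negative values are overlaps. Junctions without
#'   an entry get a small random spacer (0-12 bp).
#' @param noncoding_probs Base probabilities for RNA genes, spacers and
#'   the control region.
#' @param rotation Rotate the deposited sequence origin by this many bp
#'   (exercises origin-wrapping features).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `synthetic_spec` (a list).
#' @export
synthetic_spec <- function(id = NULL,
                           organism = "Synthetica exempli",
                           base = "Pancrustacea model",
                           edits = edit_script(),
                           codon_counts = default_codon_counts(),
                           class_targets = default_class_targets(),
                           start_plan = default_start_plan(),
                           stop_plan = default_stop_plan(),
                           rna_lengths = default_rna_lengths(),
                           spacer_plan = c(trnS2 = 592, rrnL = -33),
                           noncoding_probs = c(A = 0.36, C = 0.17, G = 0.12, T = 0.35),
                           rotation = 0L,
                           seed = 1L) {
  stopifnot(all(codon_counts >= 2), all(site_classes() %in% class_targets$class))
  if (is.null(id)) id <- sprintf("SYN%05d", as.integer(seed) %% 100000L)
  structure(
    list(
      id = id, organism = organism, base = base, edits = edits,
      codon_counts = codon_counts, class_targets = class_targets,
      start_plan = start_plan, stop_plan = stop_plan,
      rna_lengths = rna_lengths, spacer_plan = spacer_plan,
      noncoding_probs = noncoding_probs,
      rotation = as.integer(rotation), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

resolve_base_order <- function(base, catalog = load_catalog()) {
  if (inherits(base, "gene_order") || is.data.frame(base)) {
    return(canonicalize_order(base))
  }
  i <- match(base, catalog$model)
  if (is.na(i) || !isTRUE(catalog$fully_specified[[i]])) {
    stop("base order '", base, "' is not a fully specified catalog model",
      call. = FALSE
    )
  }
  tok <- parse_signed_tokens(strsplit(catalog$order[[i]], "[[:space:]]+")[[1]])
  gene_order(tok$gene, tok$strand, genome_id = base)
}

# Expected first/second-position marginals of the codon sampler, given
# sampling vectors q1/q2 and the two-fold third-position distribution r2.
# Stop-forming TA prefixes (prefix TA, third base a purine) are replaced
# by a redraw from the remaining two-fold prefixes, which depletes T at
# position 1 and A at position 2 relative to the raw product q1 x q2.
sampler_marginals <- function(q1, q2, r2) {
  bases <- c("A", "C", "G", "T")
  pref <- outer(q1, q2)
  prefixes <- outer(bases, bases, paste0)
  is4 <- prefixes %in% .fourfold_prefixes
  p_ag <- r2[["A"]] + r2[["G"]]
  pi4 <- sum(pref[is4])
  ta <- pref[!is4][match("TA", prefixes[!is4])]
  w <- pref
  denom <- (1 - pi4 - ta)
  w[!is4] <- (1 - p_ag) * pref[!is4] +
    if (denom > 0) p_ag * (1 - pi4) * pref[!is4] / denom else 0
  w[prefixes == "TA"] <- (1 - p_ag) * ta
  list(
    m1 = setNames(rowSums(w) / sum(w), bases),
    m2 = setNames(colSums(w) / sum(w), bases)
  )
}

# calibrate the sampling vectors so the realized position-1/2 marginals
# equal the targets in expectation (iterative proportional fitting)
calibrate_prefix_probs <- function(p1, p2, r2, iters = 25L) {
  q1 <- p1
  q2 <- p2
  for (it in seq_len(iters)) {
    m <- sampler_marginals(q1, q2, r2)
    if (any(m$m1 <= 0) || any(m$m2 <= 0)) break
    q1 <- q1 * p1 / m$m1
    q1 <- q1 / sum(q1)
    q2 <- q2 * p2 / m$m2
    q2 <- q2 / sum(q2)
  }
  list(p1 = q1, p2 = q2)
}

# draw n internal codons for one strand; third-position bases are exact
# iid draws from the class targets; stop-forming TA prefixes are replaced
# by a redraw of the prefix alone, with the prefix sampling vectors
# calibrated so position-1/2 compositions still match their targets
draw_codons <- function(n, strand, probs) {
  bases <- c("A", "C", "G", "T")
  p1 <- probs[[paste0(strand, "1")]]
  p2 <- probs[[paste0(strand, "2")]]
  r2 <- probs[[paste0("2", strand, "3")]]
  r4 <- probs[[paste0("4", strand, "3")]]
  cal <- calibrate_prefix_probs(p1, p2, r2)
  p1 <- cal$p1
  p2 <- cal$p2
  prefix_p <- outer(p1, p2)
  prefixes <- outer(bases, bases, paste0)
  is4 <- prefixes %in% .fourfold_prefixes
  p4 <- sum(prefix_p[is4])
  cls4 <- stats::runif(n) < p4
  z <- character(n)
  z[cls4] <- sample(bases, sum(cls4), TRUE, r4)
  z[!cls4] <- sample(bases, sum(!cls4), TRUE, r2)
  pre <- character(n)
  if (any(cls4)) {
    pre[cls4] <- sample(prefixes[is4], sum(cls4), TRUE, prefix_p[is4])
  }
  if (any(!cls4)) {
    pre[!cls4] <- sample(prefixes[!is4], sum(!cls4), TRUE, prefix_p[!is4])
  }
  # prevent stop codons: redraw the prefix where TA meets a purine
  bad <- pre == "TA" & z %in% c("A", "G")
  if (any(bad)) {
    ok2 <- !is4 & prefixes != "TA"
    pre[bad] <- sample(prefixes[ok2], sum(bad), TRUE, prefix_p[ok2])
  }
  paste0(pre, z)
}

random_dna <- function(n, probs) {
  paste(sample(names(probs), n, TRUE, probs), collapse = "")
}

#' Simulate an annotated mitogenome from a synthetic specification
#'
#' Lays the genes of the specified order onto a circular molecule with the
#' planned spacers and overlaps. Protein-coding genes are built codon-wise
#' in mRNA sense -- the planned start codon, internal codons drawn so that
#' first/second-position bases and degeneracy-stratified third-position
#' bases follow the class composition targets for the gene's strand (stop
#' codons never arise internally), and the planned complete or partial
#' stop. tRNAs, rRNAs and the control region are filled with random
#' sequence of the configured lengths; N-strand genes are
#' reverse-complemented into the deposited strand. Deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param catalog Catalog used to resolve a model-name `base`.
#' @return A [mitogenome()] with the spec attached as attribute `spec`.
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 42))
#' g
#' @export
simulate_genome <- function(spec, catalog = load_catalog()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(spec$seed)

  ord <- apply_edits(resolve_base_order(spec$base, catalog), spec$edits)
  probs <- stats::setNames(
    purrr::pmap(
      spec$class_targets[c("at_share", "at_skew", "cg_skew")],
      class_probs
    ),
    spec$class_targets$class
  )

  vocab <- gene_vocabulary()
  anticodons <- stats::setNames(vocab$anticodon, vocab$gene)

  # gene sequences in mRNA sense
  seqs <- stats::setNames(vector("list", nrow(ord)), ord$gene)
  for (i in seq_len(nrow(ord))) {
    g <- ord$gene[[i]]
    cls <- gene_class(g)
    if (cls == "PCG") {
      n <- spec$codon_counts[[g]]
      if (is.null(n)) stop("no codon count for ", g, call. = FALSE)
      seqs[[g]] <- paste0(
        spec$start_plan[[g]] %||% "ATG",
        paste(draw_codons(n, ord$strand[[i]], probs), collapse = ""),
        spec$stop_plan[[g]] %||% "TAA"
      )
    } else {
      len <- spec$rna_lengths[[g]]
      if (is.null(len)) stop("no length for ", g, call. = FALSE)
      seqs[[g]] <- random_dna(len, spec$noncoding_probs)
    }
  }

  # layout
  n_genes <- nrow(ord)
  lens <- purrr::map_int(seqs, nchar)[ord$gene]
  gaps <- vapply(seq_len(n_genes), function(i) {
    g <- ord$gene[[i]]
    if (!is.null(names(spec$spacer_plan)) && g %in% names(spec$spacer_plan)) {
      as.numeric(spec$spacer_plan[[g]])
    } else {
      sample(0:12, 1L)
    }
  }, numeric(1))
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    starts[[i]] <- pos
    pos <- pos + lens[[i]] + as.integer(gaps[[i]])
    if (i < n_genes && pos < starts[[i]] + 1L) {
      stop("infeasible plan: overlap after ", ord$gene[[i]],
        " exceeds gene length", call. = FALSE)
    }
  }
  total <- pos
  if (any(gaps[n_genes] < 0)) {
    stop("infeasible plan: the junction closing the circle cannot overlap",
      call. = FALSE
    )
  }

  # PCG footprints must not overlap each other
  is_pcg <- gene_class(ord$gene) == "PCG"
  ends <- starts + lens
  if (any(is_pcg)) {
    pi_ <- which(is_pcg)
    for (a in pi_) {
      for (b in pi_[pi_ > a]) {
        if (starts[[b]] < ends[[a]] && starts[[a]] < ends[[b]]) {
          stop("infeasible plan: protein-coding genes ", ord$gene[[a]],
            " and ", ord$gene[[b]], " overlap", call. = FALSE)
        }
      }
    }
  }

  seq_chars <- rep("A", total)
  # spacers first, then RNAs, then PCGs (later fills win inside overlaps)
  gap_fill <- strsplit(random_dna(total, spec$noncoding_probs), "")[[1]]
  seq_chars <- gap_fill
  fill <- function(chars, i) {
    s <- seqs[[ord$gene[[i]]]]
    on_plus <- ord$strand[[i]] == "J"
    if (!on_plus) s <- revcomp(s)
    chars[(starts[[i]] + 1L):ends[[i]]] <- strsplit(s, "")[[1]]
    chars
  }
  for (i in which(!is_pcg)) seq_chars <- fill(seq_chars, i)
  for (i in which(is_pcg)) seq_chars <- fill(seq_chars, i)
  sequence <- paste(seq_chars, collapse = "")

  # rotate the deposited origin
  r <- spec$rotation %% total
  if (r > 0L) {
    sequence <- paste0(substr(sequence, r + 1L, total), substr(sequence, 1L, r))
  }
  span_of <- function(s, e) {
    s2 <- (s - r) %% total
    if (s2 + (e - s) <= total) {
      list(start = s2, end = s2 + (e - s))
    } else {
      list(start = c(s2, 0L), end = c(total, s2 + (e - s) - total))
    }
  }
  spans <- purrr::map2(starts, ends, span_of)

  feats <- tibble::tibble(
    gene = ord$gene,
    strand = ord$strand,
    start = purrr::map(spans, ~ as.integer(.x$start)),
    end = purrr::map(spans, ~ as.integer(.x$end)),
    anticodon = unname(anticodons[ord$gene]),
    label = ord$gene
  )
  g <- mitogenome(
    id = spec$id, sequence = sequence, features = feats,
    circular = TRUE, organism = spec$organism, j_is_plus = TRUE
  )
  attr(g, "spec") <- spec
  g
}

#' Simulate a set of mitogenomes with between-genome skew variation
#'
#' Draws one genome per replicate from [synthetic_spec()] defaults, adding
#' zero-mean Gaussian jitter to the per-class skew targets with
#' class-specific spread, mimicking the empirical dispersion pattern in
#' which four-fold degenerate third positions vary most across taxa and
#' first positions least. Jittered skews are clamped to `[-0.9, 0.9]`.
#'
#' @param n Number of genomes.
#' @param seed Master seed; per-genome seeds are derived from it.
#' @param base_spec Template [synthetic_spec()].
#' @param jitter_sd Named numeric: skew jitter standard deviation for the
#'   class groups `p1`, `p2`, `p3_2fold`, `p3_4fold`.
#' @return A list of [mitogenome()] objects with ids `<id>_01`, ...
#' @export
simulate_genome_set <- function(n, seed = 1L, base_spec = synthetic_spec(),
                                jitter_sd = c(
                                  p1 = 0.03, p2 = 0.05,
                                  p3_2fold = 0.12, p3_4fold = 0.25
                                )) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1L, n)
  group_of <- c(
    J1 = "p1", N1 = "p1", J2 = "p2", N2 = "p2",
    `2J3` = "p3_2fold", `2N3` = "p3_2fold",
    `4J3` = "p3_4fold", `4N3` = "p3_4fold"
  )
  sds <- unname(jitter_sd[group_of[base_spec$class_targets$class]])
  purrr::map(seq_len(n), function(i) {
    ct <- base_spec$class_targets
    ct$at_skew <- pmin(0.9, pmax(-0.9, ct$at_skew + stats::rnorm(nrow(ct), 0, sds)))
    ct$cg_skew <- pmin(0.9, pmax(-0.9, ct$cg_skew + stats::rnorm(nrow(ct), 0, sds)))
    sp <- base_spec
    sp$class_targets <- ct
    sp$seed <- sub_seeds[[i]]
    sp$id <- sprintf("%s_%02d", base_spec$id, i)
    simulate_genome(sp)
  })
}
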