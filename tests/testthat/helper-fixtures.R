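# GenBank flat-file text for small hand-built records
gb_text <- function(sequence, features, id = "TEST0001", circular = TRUE) {
  origin <- mitorder:::format_origin(sequence)
  c(
    sprintf(
      "LOCUS       %-16s %11d bp    DNA     %-8s INV 01-JAN-2024",
      id, nchar(sequence), if (circular) "circular" else "linear"
    ),
    sprintf("DEFINITION  %s test record.", id),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    "                     /organism=\"Testus fixturae\"",
    features,
    "ORIGIN",
    origin,
    "//"
  )
}

gb_file <- function(sequence, features, id = "TEST0001", circular = TRUE) {
  path <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  writeLines(gb_text(sequence, features, id = id, circular = circular), path)
  path
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# a tiny annotated genome built directly (no parsing involved)
tiny_genome <- function(genes, strands, seqs, gaps = 5L, id = "TINY",
                        j_is_plus = TRUE) {
  gaps <- rep_len(gaps, length(genes))
  strands <- rep_len(strands, length(genes))
  pieces <- character(0)
  starts <- ends <- integer(length(genes))
  pos <- 0L
  spacer <- function(n) paste(rep("A", n), collapse = "")
  for (i in seq_along(genes)) {
    s <- seqs[[i]]
    deposited <- if ((strands[[i]] == "J") == j_is_plus) s else mitorder:::revcomp(s)
    starts[[i]] <- pos
    ends[[i]] <- pos + nchar(s)
    pieces <- c(pieces, deposited, spacer(gaps[[i]]))
    pos <- ends[[i]] + gaps[[i]]
  }
  mitogenome(
    id = id,
    sequence = paste(pieces, collapse = ""),
    features = tibble::tibble(
      gene = genes, strand = strands,
      start = as.list(starts), end = as.list(ends),
      anticodon = NA_character_, label = genes
    ),
    j_is_plus = j_is_plus
  )
}

# strand-flipped twin: reverse-complement the deposited sequence and remap
# the coordinates; the genome it describes is unchanged
flip_genome <- function(genome) {
  len <- nchar(genome$sequence)
  f <- genome$features
  f$start2 <- purrr::map2(f$start, f$end, ~ rev(len - .y))
  f$end2 <- purrr::map2(f$start, f$end, ~ rev(len - .x))
  f$start <- f$start2
  f$end <- f$end2
  f$start2 <- f$end2 <- NULL
  mitogenome(
    id = genome$id,
    sequence = mitorder:::revcomp(genome$sequence),
    features = f,
    circular = genome$circular,
    organism = genome$organism,
    j_is_plus = !genome$j_is_plus
  )
}

# a faster spec for tests where composition accuracy is irrelevant
quick_spec <- function(..., spacer_plan = c(trnS2 = 90, rrnL = -20)) {
  cc <- round(mitorder:::default_codon_counts() / 8)
  cc[cc < 2] <- 2
  synthetic_spec(
    codon_counts = cc,
    rna_lengths = c(
      stats::setNames(rep(30L, 22L), grep("^trn", gene_vocabulary()$gene, value = TRUE)),
      rrnS = 120L, rrnL = 180L, CR = 150L
    ),
    spacer_plan = spacer_plan,
    ...
  )
}

# expected deterministic start-codon contribution to the site classes:
# position 1/2 bases of each planned start codon, and its third base in
# the two-fold or four-fold class of its prefix
start_codon_counts <- function(spec, order) {
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG", "AG")
  tally <- matrix(0L, nrow = 8L, ncol = 4L,
    dimnames = list(site_classes(), c("A", "C", "G", "T"))
  )
  pcg <- order$gene[gene_class(order$gene) == "PCG"]
  for (g in pcg) {
    st <- order$strand[[match(g, order$gene)]]
    sc <- spec$start_plan[[g]]
    b <- strsplit(sc, "")[[1]]
    tally[paste0(st, "1"), b[[1]]] <- tally[paste0(st, "1"), b[[1]]] + 1L
    tally[paste0(st, "2"), b[[2]]] <- tally[paste0(st, "2"), b[[2]]] + 1L
    d <- if (substr(sc, 1, 2) %in% fourfold) "4" else "2"
    cl <- paste0(d, st, "3")
    tally[cl, b[[3]]] <- tally[cl, b[[3]]] + 1L
  }
  tally
}

# z-scores of observed class skews against spec targets, with the
# deterministic start-codon contribution removed before standardizing
skew_recovery_z <- function(genome) {
  spec <- attr(genome, "spec")
  ord <- suppressMessages(extract_gene_order(genome))
  adj <- start_codon_counts(spec, ord)
  counts <- partition_sites(genome)
  tg <- spec$class_targets
  purrr::pmap_dfr(counts, function(genome_id, class, a, c, g, t, ...) {
    cl <- as.character(class)
    a <- a - adj[cl, "A"]; c <- c - adj[cl, "C"]
    g <- g - adj[cl, "G"]; t <- t - adj[cl, "T"]
    row <- tg[tg$class == cl, ]
    n_at <- a + t
    n_cg <- c + g
    tibble::tibble(
      class = cl,
      z_at = ((a - t) / n_at - row$at_skew) / sqrt((1 - row$at_skew^2) / n_at),
      z_cg = ((c - g) / n_cg - row$cg_skew) / sqrt((1 - row$cg_skew^2) / n_cg)
    )
  })
}
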