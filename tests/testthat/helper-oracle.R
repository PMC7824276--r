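# Brute-force minimal-displacement oracle: the smallest set of non-anchor
# genes whose removal makes two signed circular orders identical up to
# rotation, tie-broken like the package (fewest PCG/rRNA genes removed,
# then lexicographically smallest set). Exponential; small orders only.
oracle_min_displaced <- function(query, ref, anchor = "cox1") {
  common <- intersect(ref$gene, query$gene)
  q <- canonicalize_order(query[query$gene %in% common, ], anchor = anchor)
  r <- canonicalize_order(ref[ref$gene %in% common, ], anchor = anchor)
  cand <- setdiff(common, anchor)
  equal_after <- function(rm) {
    qq <- canonicalize_order(q[!q$gene %in% rm, ], anchor = anchor)
    rr <- canonicalize_order(r[!r$gene %in% rm, ], anchor = anchor)
    all(qq$gene == rr$gene) && all(qq$strand == rr$strand)
  }
  vocab <- gene_vocabulary()
  cls <- stats::setNames(vocab$class, vocab$gene)
  for (k in 0:length(cand)) {
    sets <- if (k == 0) list(character(0)) else utils::combn(cand, k, simplify = FALSE)
    hits <- Filter(equal_after, sets)
    if (length(hits) > 0) {
      npr <- vapply(hits, function(s) sum(cls[s] %in% c("PCG", "rRNA")), numeric(1))
      hits <- hits[npr == min(npr)]
      # element-wise lexicographic comparison of the sorted sets
      rank <- stats::setNames(seq_along(sort(common)), sort(common))
      keys <- vapply(hits, function(s) {
        paste(sprintf("%02d", sort(rank[s])), collapse = "")
      }, character(1))
      return(sort(hits[[order(keys)[[1]]]]))
    }
  }
  stop("oracle: no removal set found")
}

# random signed circular order over the real vocabulary, anchored at cox1
random_signed_order <- function(n, id = "rand") {
  others <- setdiff(gene_vocabulary()$gene, c("cox1", "CR"))
  genes <- sample(c("cox1", sample(others, n - 1L)))
  strands <- sample(c("J", "N"), n, TRUE)
  strands[genes == "cox1"] <- "J"
  gene_order(genes, strands, genome_id = id)
}

# shuffled copy of an order (same genes, new arrangement and strands)
shuffle_order <- function(ord, id = "q") {
  n <- nrow(ord)
  perm <- sample(n)
  strands <- sample(c("J", "N"), n, TRUE)
  strands[ord$gene[perm] == "cox1"] <- "J"
  gene_order(ord$gene[perm], strands, genome_id = id)
}

# reference quartiles by explicit linear interpolation between order
# statistics, written out longhand (independent of stats::quantile)
oracle_quartile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
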