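test_that("the base arrangement has the canonical 38 elements", {
  base <- pancrustacea_order()
  expect_identical(nrow(base), 38L)
  expect_true(attr(base, "complete"))
  expect_identical(base$gene[[1]], "cox1")
  expect_identical(base$strand[[1]], "J")
  v <- gene_vocabulary()
  expect_identical(sum(gene_class(base$gene) == "PCG"), 13L)
  expect_identical(sum(gene_class(base$gene) == "tRNA"), 22L)
  expect_identical(sum(gene_class(base$gene) == "rRNA"), 2L)
})

test_that("extraction of a simulated base-model genome round-trips", {
  g <- simulate_genome(quick_spec(seed = 41))
  ord <- extract_gene_order(g)
  base <- pancrustacea_order()
  expect_identical(ord$gene, base$gene)
  expect_identical(ord$strand, base$strand)
  expect_true(attr(ord, "complete"))
})

test_that("a genome deposited on the opposite strand extracts the same order", {
  g <- simulate_genome(quick_spec(seed = 42))
  tw <- flip_genome(g)
  expect_false(tw$j_is_plus)
  o1 <- extract_gene_order(g)
  o2 <- extract_gene_order(tw)
  expect_identical(o1$gene, o2$gene)
  expect_identical(o1$strand, o2$strand)
})

test_that("an order is canonicalized regardless of input rotation/orientation", {
  base <- pancrustacea_order()
  rot <- c(17:38, 1:16)
  rotated <- gene_order(base$gene[rot], base$strand[rot], genome_id = "rot")
  expect_identical(rotated$gene, base$gene)
  # reversed-and-flipped encoding of the same circle
  flipped <- gene_order(
    rev(base$gene), rev(ifelse(base$strand == "J", "N", "J")),
    genome_id = "flip"
  )
  expect_identical(flipped$gene, base$gene)
  expect_identical(flipped$strand, base$strand)
})

test_that("comparison of identical orders is empty, with zero breakpoints", {
  catalog <- load_catalog()
  for (m in catalog$model[catalog$fully_specified]) {
    ord <- mitorder:::resolve_base_order(m, catalog)
    rep <- compare_orders(ord, ord)
    expect_true(rep$identical)
    expect_identical(rep$breakpoints, 0L)
    expect_length(c(rep$deleted, rep$inserted, rep$inverted, rep$translocated), 0L)
  }
})

test_that("comparison is invariant under rotation of either argument", {
  base <- pancrustacea_order()
  edited <- apply_edits(base, edit_script(
    edit_translocate("trnD", after = "nad6"),
    edit_invert("trnA", "trnR")
  ))
  rot <- function(ord, k) {
    idx <- c((k + 1):nrow(ord), 1:k)
    gene_order(ord$gene[idx], ord$strand[idx], genome_id = "r")
  }
  r1 <- compare_orders(edited, base)
  r2 <- compare_orders(rot(edited, 11), base)
  r3 <- compare_orders(edited, rot(base, 23))
  for (r in list(r2, r3)) {
    expect_identical(r$translocated, r1$translocated)
    expect_identical(r$inverted, r1$inverted)
    expect_identical(r$breakpoints, r1$breakpoints)
  }
  expect_identical(r1$translocated, "trnD")
  expect_identical(r1$inverted, c("trnA", "trnR"))
})

test_that("a double tRNA translocation is recovered exactly", {
  base <- pancrustacea_order()
  tet <- apply_edits(base, edit_script(
    edit_translocate("trnS2", after = "trnW"),
    edit_translocate("trnQ", after = "trnS2")
  ))
  rep <- compare_orders(tet, base)
  expect_identical(rep$translocated, c("trnQ", "trnS2"))
  expect_length(rep$inverted, 0L)
  expect_length(rep$deleted, 0L)
  expect_false(rep$identical)
  expect_gt(rep$breakpoints, 0L)

  # moving the pair next to trnQ's ancestral neighbour trnI leaves the
  # attribution ambiguous; the displaced set still has exactly two genes
  # and the tie resolves deterministically
  tet2 <- apply_edits(base, edit_script(
    edit_translocate("trnS2", after = "CR"),
    edit_translocate("trnQ", after = "trnS2")
  ))
  rep2 <- compare_orders(tet2, base)
  expect_length(c(rep2$inverted, rep2$translocated), 2L)
  expect_identical(rep2$translocated, sort(oracle_min_displaced(tet2, base)))
})

test_that("displacement ties break to the lexicographically smallest set", {
  # (cox1, trnA, trnC, trnD) vs (cox1, trnC, trnA, trnD): {trnA} or {trnC}
  # both minimal; the tie goes to trnA
  ref <- gene_order(c("cox1", "trnA", "trnC", "trnD"), "J", genome_id = "ref")
  qry <- gene_order(c("cox1", "trnC", "trnA", "trnD"), "J", genome_id = "qry")
  rep <- compare_orders(qry, ref)
  expect_identical(rep$translocated, "trnA")
  expect_identical(oracle_min_displaced(qry, ref), "trnA")
})

test_that("ties preserve protein-coding genes in the common subsequence", {
  # moving nad2 next to trnQ could equally be read as a trnM move; the
  # PCG-preserving reading wins
  base <- pancrustacea_order()
  qry <- apply_edits(base, edit_script(edit_translocate("trnM", after = "nad2")))
  rep <- compare_orders(qry, base)
  expect_identical(rep$translocated, "trnM")
})

test_that("deleted and inserted genes come from set differences", {
  base <- pancrustacea_order()
  del <- apply_edits(base, edit_script(edit_delete("trnC")))
  rep <- compare_orders(del, base)
  expect_identical(rep$deleted, "trnC")
  expect_length(rep$translocated, 0L)
  rep2 <- compare_orders(base, del)
  expect_identical(rep2$inserted, "trnC")
})

test_that("comparison requires a usable common gene set", {
  a <- gene_order(c("cox1", "trnA", "trnB" = "trnD"), "J", genome_id = "a")
  b <- gene_order(c("cox1", "trnW", "trnY"), "J", genome_id = "b")
  expect_error(compare_orders(a, b), "fewer than three genes in common")
})

test_that("the LCS displacement agrees with a brute-force minimal-edit oracle", {
  withr::local_seed(271828)
  for (i in 1:60) {
    n <- sample(4:8, 1L)
    ref <- random_signed_order(n, id = "ref")
    qry <- shuffle_order(ref, id = "qry")
    rep <- suppressMessages(compare_orders(qry, ref))
    got <- sort(c(rep$inverted, rep$translocated))
    expect_identical(got, oracle_min_displaced(qry, ref))
  }
})

test_that("tidy and glance views of a rearrangement are consistent", {
  base <- pancrustacea_order()
  ed <- apply_edits(base, edit_script(
    edit_delete("trnY"), edit_invert("trnA", "trnR")
  ))
  rep <- compare_orders(ed, base)
  td <- tidy(rep)
  expect_identical(sort(td$gene[td$change == "inverted"]), c("trnA", "trnR"))
  expect_identical(td$gene[td$change == "deleted"], "trnY")
  gl <- glance(rep)
  expect_identical(gl$n_deleted, 1L)
  expect_identical(gl$n_inverted, 2L)
  expect_identical(gl$n_translocated, 0L)
  expect_false(gl$identical)
})

test_that("classification distinguishes exact, compatible and novel", {
  catalog <- load_catalog()
  base <- pancrustacea_order()
  expect_identical(classify_order(base, catalog)$match, "exact")
  expect_identical(classify_order(base, catalog)$model, "Pancrustacea model")

  # an incomplete genome missing one tRNA is compatible with the base model
  tmix <- apply_edits(base, edit_script(edit_delete("trnC")))
  cls <- classify_order(tmix, catalog)
  expect_identical(cls$match, "compatible")
  expect_identical(cls$model, "Pancrustacea model")
  expect_identical(cls$missing_genes[[1]], "trnC")

  # an arrangement absent from the catalog is novel
  odd <- apply_edits(base, edit_script(edit_swap("nad2", "cob")))
  expect_identical(classify_order(odd, catalog)$match, "novel")
})

test_that("described edit signatures classify partially specified models", {
  catalog <- load_catalog()
  base <- pancrustacea_order()
  lipo <- apply_edits(base, edit_script(
    edit_invert("trnP"), edit_invert("trnT"),
    edit_translocate("trnD", after = "trnW"),
    edit_translocate("trnQ", after = "cox3"),
    edit_translocate("trnY", after = "nad3"),
    edit_translocate("trnC", after = "nad4L"),
    edit_translocate("trnI", after = "cob")
  ))
  cls <- classify_order(lipo, catalog)
  expect_identical(cls$model, "Lipothrix model")
  expect_identical(cls$match, "signature")

  pod <- apply_edits(base, edit_script(
    edit_translocate("trnC", after = "trnG"),
    edit_translocate("trnW", after = "nad3"),
    edit_delete("trnY")
  ))
  cls2 <- classify_order(pod, catalog)
  expect_identical(cls2$model, "Podura model")
})

test_that("an unannotated control region never blocks an exact match", {
  base <- pancrustacea_order()
  nocr <- base[base$gene != "CR", ]
  nocr <- gene_order(nocr$gene, nocr$strand, genome_id = "nocr")
  cls <- classify_order(nocr, load_catalog())
  expect_identical(cls$match, "exact")
  expect_identical(cls$model, "Pancrustacea model")
})

test_that("the default catalog covers the described models", {
  catalog <- load_catalog()
  expect_gte(nrow(catalog), 13L)
  expect_identical(catalog$model[[1]], "Pancrustacea model")
  expect_gte(sum(catalog$fully_specified), 5L)
  # every fully specified order uses the closed vocabulary, once per gene
  for (o in catalog$order[catalog$fully_specified]) {
    toks <- sub("^-", "", strsplit(o, " ")[[1]])
    expect_true(all(toks %in% gene_vocabulary()$gene))
    expect_false(anyDuplicated(toks) > 0)
  }
  # fully specified models are pairwise distinct arrangements
  orders <- lapply(catalog$order[catalog$fully_specified], function(o) {
    tok <- mitorder:::parse_signed_tokens(strsplit(o, " ")[[1]])
    gene_order(tok$gene, tok$strand)
  })
  for (i in seq_along(orders)) {
    for (j in seq_along(orders)) {
      if (i < j) expect_false(mitorder:::orders_equal(orders[[i]], orders[[j]]))
    }
  }
})

test_that("catalog files load, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(default_catalog(), path)
  cat2 <- load_catalog(path)
  expect_identical(nrow(cat2), nrow(default_catalog()))
  expect_identical(cat2$order, default_catalog()$order)

  # adding a model extends the catalog
  extra <- default_catalog()[1, ]
  extra$model <- "User model"
  extra$order <- sub("trnW -trnC", "-trnC trnW", extra$order)
  write_catalog(dplyr::bind_rows(default_catalog(), extra), path)
  expect_identical(nrow(load_catalog(path)), nrow(default_catalog()) + 1L)

  # unknown tokens are rejected with the offending line
  bad <- default_catalog()
  bad$order[[2]] <- paste(bad$order[[2]], "trnZ")
  write_catalog(bad, path)
  expect_error(load_catalog(path), "line 2.*trnZ")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("model\tfully_specified\torder", empty)
  expect_error(load_catalog(empty), "empty catalog")
})

test_that("anchor falls back along the priority list when cox1 is absent", {
  expect_message(
    ord <- gene_order(c("cob", "trnA", "trnW", "nad2"), "J"),
    "anchoring at cob"
  )
  expect_identical(ord$gene[[1]], "cob")
})
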