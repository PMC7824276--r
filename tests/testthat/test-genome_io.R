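test_that("a minimal GenBank record parses into a mapped mitogenome", {
  seq <- paste0("ATG", random_seq(24, 5), "TAA", random_seq(20, 6))
  path <- gb_file(seq, c(
    "     CDS             1..30",
    "                     /gene=\"COX1\""
  ))
  g <- read_genbank(path)
  expect_s3_class(g, "mitogenome")
  expect_identical(g$sequence, toupper(seq))
  expect_identical(nrow(g$features), 1L)
  expect_identical(g$features$gene[[1]], "cox1")
  expect_identical(g$features$strand[[1]], "J")
  expect_identical(g$features$start[[1]], 0L)
  expect_identical(g$features$end[[1]], 30L)
  expect_identical(g$organism, "Testus fixturae")
  expect_true(g$circular)
})

test_that("tRNA products are mapped through anticodons and family suffixes", {
  seq <- random_seq(200, 7)
  path <- gb_file(seq, c(
    "     tRNA            1..65",
    "                     /product=\"tRNA-Ser\"",
    "                     /anticodon=\"(pos:30..32,aa:Ser,seq:uga)\"",
    "     tRNA            71..135",
    "                     /product=\"tRNA-Leu (UUR)\"",
    "     tRNA            141..200",
    "                     /product=\"tRNA-Trp\""
  ))
  g <- read_genbank(path)
  expect_identical(g$features$gene, c("trnS2", "trnL2", "trnW"))
  expect_identical(g$features$anticodon[[1]], "uga")
})

test_that("complement and origin-wrapping join locations resolve to spans", {
  seq <- random_seq(15486, 8)
  path <- gb_file(seq, c(
    "     rRNA            complement(100..1300)",
    "                     /product=\"16S ribosomal RNA\"",
    "     CDS             join(14000..15486,1..200)",
    "                     /gene=\"cox1\"",
    "     tRNA            2000..2060",
    "                     /gene=\"trnM\""
  ))
  g <- read_genbank(path)
  cox1 <- g$features[g$features$gene == "cox1", ]
  expect_identical(cox1$start[[1]], c(13999L, 0L))
  expect_identical(cox1$end[[1]], c(15486L, 200L))
  expect_identical(sum(cox1$end[[1]] - cox1$start[[1]]), 1687L)
  # cox1 is on the plus strand, so minus-strand rrnL is N
  expect_identical(g$features$strand[g$features$gene == "rrnL"], "N")
  expect_true(g$j_is_plus)
})

test_that("malformed records fail loudly", {
  seq <- random_seq(100, 9)
  txt <- gb_text(seq, "     CDS             1..30\n                     /gene=\"cox1\"")
  no_origin <- txt[!grepl("^ORIGIN|^ {5,9}\\d|^//", txt)]
  f1 <- withr::local_tempfile(fileext = ".gb")
  writeLines(no_origin, f1)
  expect_error(read_genbank(f1), "ORIGIN")

  f2 <- gb_file(seq, c(
    "     CDS             50..150",
    "                     /gene=\"cox1\""
  ))
  expect_error(read_genbank(f2), "beyond sequence length")
})

test_that("duplicate annotations are an error, overridable to keep-first", {
  seq <- random_seq(300, 10)
  feats <- c(
    "     CDS             1..30",
    "                     /gene=\"cox1\"",
    "     CDS             101..130",
    "                     /gene=\"COI\""
  )
  path <- gb_file(seq, feats)
  expect_error(read_genbank(path), "duplicate")
  expect_warning(g <- read_genbank(path, allow_duplicates = "first"), "keeping first")
  expect_identical(nrow(g$features), 1L)
  expect_identical(g$features$start[[1]], 0L)
})

test_that("unmappable features are retained with a null gene and reported", {
  seq <- random_seq(300, 11)
  path <- gb_file(seq, c(
    "     CDS             1..30",
    "                     /gene=\"cox1\"",
    "     misc_feature    40..80",
    "                     /note=\"putative ORF of unknown function\"",
    "     tRNA            101..160",
    "                     /gene=\"trnI\"",
    "     tRNA            171..230",
    "                     /gene=\"trnM\""
  ))
  expect_message(g <- read_genbank(path), "not mapped")
  expect_identical(sum(is.na(g$features$gene)), 1L)
  expect_identical(nrow(g$features), 4L)
})

test_that("gene-name normalization maps synonyms and never guesses Leu/Ser", {
  cases <- tibble::tribble(
    ~raw, ~anticodon, ~want,
    "ND4L", NA, "nad4L",
    "nd2", NA, "nad2",
    "COI", NA, "cox1",
    "COIII", NA, "cox3",
    "CYTB", NA, "cob",
    "cytochrome b", NA, "cob",
    "ATPase6", NA, "atp6",
    "16S ribosomal RNA", NA, "rrnL",
    "l-rRNA", NA, "rrnL",
    "12S ribosomal RNA", NA, "rrnS",
    "D-loop", NA, "CR",
    "A+T-rich region", NA, "CR",
    "tRNA-Ala", NA, "trnA",
    "tRNA-Leu", "uaa", "trnL2",
    "tRNA-Leu", "uag", "trnL1",
    "tRNA-Ser", "gcu", "trnS1",
    "tRNA-Ser (UCN)", NA, "trnS2",
    "trnSuga", NA, "trnS2",
    "trnLuaa", NA, "trnL2"
  )
  got <- normalize_gene_name(cases$raw, cases$anticodon)
  expect_identical(got, cases$want)

  expect_warning(amb <- normalize_gene_name("tRNA-Leu"), "ambiguous")
  expect_identical(amb, NA_character_)
  expect_warning(amb2 <- normalize_gene_name("tRNA-Ser"), "ambiguous")
  expect_identical(amb2, NA_character_)
  expect_identical(normalize_gene_name("hypothetical protein"), NA_character_)
})

test_that("normalization is idempotent and closed over the vocabulary", {
  keys <- gene_vocabulary()$gene
  expect_identical(normalize_gene_name(keys), keys)
  mapped <- suppressWarnings(normalize_gene_name(c(
    keys, "COX2", "nd5", "cytb", "tRNA-Gly", "junk feature"
  )))
  expect_true(all(mapped[!is.na(mapped)] %in% keys))
})

test_that("coding_sequence honours strand and span order", {
  g <- tiny_genome(
    genes = c("cox1", "nad2", "trnM"),
    strands = c("J", "N", "J"),
    seqs = list("ATGAAATTTCCC", "AAACCC", "GGGGGG")
  )
  expect_identical(coding_sequence(g, "cox1"), "ATGAAATTTCCC")
  # the deposited strand holds the reverse complement of an N gene
  expect_identical(coding_sequence(g, "nad2"), "AAACCC")
  i <- match("nad2", g$features$gene)
  expect_identical(
    substr(g$sequence, g$features$start[[i]] + 1, g$features$end[[i]]),
    "GGGTTT"
  )
  expect_error(coding_sequence(g, "cob"), "not annotated")
})

test_that("a wrapping span concatenates across the origin in mRNA sense", {
  g <- simulate_genome(quick_spec(seed = 21, rotation = 500L))
  wrapped <- which(purrr::map_int(g$features$start, length) > 1L)
  expect_length(wrapped, 1L)
  gene <- g$features$gene[[wrapped]]
  cds <- coding_sequence(g, gene)
  expect_identical(
    nchar(cds),
    as.integer(sum(g$features$end[[wrapped]] - g$features$start[[wrapped]]))
  )
  # identical simulation without rotation yields the same sense sequence
  g0 <- simulate_genome(quick_spec(seed = 21))
  expect_identical(cds, coding_sequence(g0, gene))
})

test_that("GenBank round trip preserves sequence, features, strands, spans", {
  g <- simulate_genome(quick_spec(seed = 22, rotation = 700L))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(nrow(g2$features), nrow(g$features))
  k <- match(g$features$gene, g2$features$gene)
  expect_false(anyNA(k))
  expect_identical(g2$features$strand[k], g$features$strand)
  expect_true(all(purrr::map2_lgl(
    g$features$start, g2$features$start[k],
    ~ identical(as.integer(.x), as.integer(.y))
  )))
  expect_true(all(purrr::map2_lgl(
    g$features$end, g2$features$end[k],
    ~ identical(as.integer(.x), as.integer(.y))
  )))
})

test_that("FASTA plus feature-table side channel round trips", {
  g <- simulate_genome(quick_spec(seed = 23, rotation = 300L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_annotation(g, fa, tsv)
  g2 <- read_fasta_annotation(fa, tsv)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(nrow(g2$features), nrow(g$features))
  o1 <- suppressMessages(extract_gene_order(g))
  o2 <- suppressMessages(extract_gene_order(g2))
  expect_identical(o1$gene, o2$gene)
  expect_identical(o1$strand, o2$strand)
})

test_that("an independent GenBank implementation reads our files identically", {
  g <- simulate_genome(quick_spec(seed = 24))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "r = SeqIO.read(sys.argv[1], 'genbank')",
    "feats = [f for f in r.features if f.type in ('CDS','tRNA','rRNA','D-loop')]",
    "cox1 = [f for f in feats if f.qualifiers.get('gene', [''])[0] == 'cox1'][0]",
    "print(len(r.seq), len(feats), r.annotations['topology'],",
    "      str(cox1.extract(r.seq))[:3])",
    sep = "\n"
  )
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", c(py, path), stdout = TRUE, stderr = FALSE)
  fields <- strsplit(out[[length(out)]], " +")[[1]]
  expect_identical(as.integer(fields[[1]]), nchar(g$sequence))
  expect_identical(as.integer(fields[[2]]), nrow(g$features))
  expect_identical(fields[[3]], "circular")
  expect_identical(fields[[4]], substr(coding_sequence(g, "cox1"), 1, 3))
})
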