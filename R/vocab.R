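#' The canonical mitochondrial gene vocabulary
#'
#' Metazoan mitochondrial genomes carry a near-universal complement of 13
#' protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and one non-coding control
#' region (CR, also called the A+T-rich region). Annotations in public
#' records use wildly heterogeneous labels for these; everything downstream
#' of parsing works on the closed vocabulary returned here.
#'
#' The two leucine and two serine tRNAs are distinguished by codon family:
#' `trnL1` = Leu(CUN), anticodon `uag`; `trnL2` = Leu(UUR), anticodon `uaa`;
#' `trnS1` = Ser(AGN), anticodon `gcu`; `trnS2` = Ser(UCN), anticodon `uga`.
#'
#' @return A tibble with one row per canonical gene key: `gene` (key),
#'   `class` (`"PCG"`, `"tRNA"`, `"rRNA"` or `"control"`), `aa` (one-letter
#'   amino-acid code for tRNAs, otherwise `NA`) and `anticodon` (the
#'   canonical anticodon for the four codon-family-disambiguated tRNAs).
#' @examples
#' gene_vocabulary()
#' @export
gene_vocabulary <- function() {
  trna_aa <- c(
    trnA = "A", trnR = "R", trnN = "N", trnD = "D", trnC = "C", trnE = "E",
    trnQ = "Q", trnG = "G", trnH = "H", trnI = "I", trnK = "K", trnM = "M",
    trnF = "F", trnP = "P", trnT = "T", trnW = "W", trnY = "Y", trnV = "V",
    trnL1 = "L", trnL2 = "L", trnS1 = "S", trnS2 = "S"
  )
  pcg <- c(
    "atp6", "atp8", "cox1", "cox2", "cox3", "cob",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6"
  )
  tibble::tibble(
    gene = c(pcg, "rrnS", "rrnL", "CR", names(trna_aa)),
    class = c(
      rep("PCG", length(pcg)), "rRNA", "rRNA", "control",
      rep("tRNA", length(trna_aa))
    ),
    aa = c(rep(NA_character_, length(pcg) + 3), unname(trna_aa)),
    anticodon = dplyr::case_match(
      c(pcg, "rrnS", "rrnL", "CR", names(trna_aa)),
      "trnL1" ~ "uag", "trnL2" ~ "uaa", "trnS1" ~ "gcu", "trnS2" ~ "uga",
      .default = NA_character_
    )
  )
}

# internal fast lookups
.vocab_env <- new.env(parent = emptyenv())

vocab_keys <- function() {
  if (is.null(.vocab_env$keys)) .vocab_env$keys <- gene_vocabulary()$gene
  .vocab_env$keys
}

gene_class <- function(gene) {
  if (is.null(.vocab_env$class)) {
    v <- gene_vocabulary()
    .vocab_env$class <- stats::setNames(v$class, v$gene)
  }
  unname(.vocab_env$class[gene])
}

# amino-acid 3-letter -> canonical key (unambiguous tRNAs only)
.aa3_to_key <- c(
  ala = "trnA", arg = "trnR", asn = "trnN", asp = "trnD", cys = "trnC",
  glu = "trnE", gln = "trnQ", gly = "trnG", his = "trnH", ile = "trnI",
  lys = "trnK", met = "trnM", phe = "trnF", pro = "trnP", thr = "trnT",
  trp = "trnW", tyr = "trnY", val = "trnV"
)
.aa1_to_key <- stats::setNames(.aa3_to_key, c(
  "a", "r", "n", "d", "c", "e", "q", "g", "h", "i",
  "k", "m", "f", "p", "t", "w", "y", "v"
))

#' Normalize a raw annotation label to a canonical gene key
#'
#' Maps the common synonyms found in GenBank records (`COI`/`COX1`/`cox1`,
#' `CYTB`/`cob`, `ND4L`/`nad4L`, `16S`/`l-rRNA`/`rrnL`, `D-loop`/`A+T-rich
#' region`/`CR`, `tRNA-Xxx`, ...) onto the closed vocabulary of
#' [gene_vocabulary()]. Matching is case-insensitive. Leucine and serine
#' tRNAs are only resolved when an anticodon or a codon-family suffix
#' (`(UUR)`, `(CUN)`, `(AGN)`, `(UCN)`) disambiguates them; an ambiguous
#' leucine/serine label maps to `NA` with a warning rather than a guess.
#'
#' @param raw_label Character vector of raw annotation strings (a `/gene`
#'   or `/product` qualifier, say).
#' @param anticodon Optional character vector (recycled) of anticodon
#'   3-mers, e.g. `"uga"`.
#' @return Character vector of canonical gene keys; `NA` where no mapping
#'   applies. The mapping is idempotent on canonical keys.
#' @examples
#' normalize_gene_name(c("ND4L", "COI", "tRNA-Ser"), c(NA, NA, "uga"))
#' @export
normalize_gene_name <- function(raw_label, anticodon = NULL) {
  if (length(raw_label) == 0L) return(character(0))
  if (is.null(anticodon)) anticodon <- NA_character_
  anticodon <- rep_len(tolower(as.character(anticodon)), length(raw_label))
  vapply(seq_along(raw_label), function(i) {
    normalize_one(raw_label[[i]], anticodon[[i]])
  }, character(1))
}

normalize_one <- function(raw, anticodon) {
  if (is.na(raw) || !nzchar(raw)) return(NA_character_)
  lab <- tolower(trimws(raw))
  # already canonical (case-insensitive; nad4L needs its case restored)
  keys <- vocab_keys()
  hit <- match(lab, tolower(keys))
  if (!is.na(hit)) {
    key <- keys[[hit]]
    # trnL/trnS without index are not canonical; everything matched here is
    return(key)
  }
  lab2 <- gsub("[[:space:]_]+", " ", lab)

  # protein-coding synonyms
  pcg <- pcg_synonym(lab2)
  if (!is.na(pcg)) return(pcg)

  # rRNAs
  if (grepl("(^|[^0-9])16s|l-?rrna|large subunit ribosomal|rrn ?l", lab2)) return("rrnL")
  if (grepl("(^|[^0-9])12s|s-?rrna|small subunit ribosomal|rrn ?s", lab2)) return("rrnS")

  # control region
  if (grepl("d-?loop|control region|a\\+?t[- ]rich|at[- ]rich region|^cr$", lab2)) {
    return("CR")
  }

  # tRNAs
  if (grepl("^trna|^trn[- ]?[a-z]|^trn", lab2)) {
    return(normalize_trna(lab2, anticodon, raw))
  }
  NA_character_
}

pcg_synonym <- function(lab) {
  lab <- sub("^mt-?", "", lab)
  if (grepl("^co ?(i{1,3}|[1-3])$|^cox ?[1-3]$|^cox(i{1,3})$", lab)) {
    n <- if (grepl("3|iii", lab)) 3L else if (grepl("2|ii", lab)) 2L else 1L
    return(paste0("cox", n))
  }
  if (grepl("cytochrome c oxidase subunit", lab)) {
    n <- if (grepl("iii|3", lab)) 3L else if (grepl("ii|2", lab)) 2L else 1L
    return(paste0("cox", n))
  }
  if (grepl("^cytb$|^cyt ?b$|^cob$|cytochrome b", lab)) return("cob")
  if (grepl("^nd ?([1-6]|4l)$|^nad ?([1-6]|4l)$|nadh dehydrogenase subunit ?([1-6]|4l)", lab)) {
    n <- sub(".*?([1-6]l?|4l)$", "\\1", lab)
    n <- sub("^4l$", "4L", n)
    return(paste0("nad", n))
  }
  if (grepl("^atp ?(6|8)$|^atpase ?(6|8)$|atp synthase f0 subunit ?(6|8)", lab)) {
    n <- if (grepl("8", lab)) 8L else 6L
    return(paste0("atp", n))
  }
  NA_character_
}

normalize_trna <- function(lab, anticodon, raw) {
  # explicit codon-family suffix
  fam <- NA_character_
  if (grepl("\\(uur\\)|uur", lab)) fam <- "trnL2"
  if (grepl("\\(cun\\)|cun", lab)) fam <- "trnL1"
  if (grepl("\\(agn\\)|agn", lab)) fam <- "trnS1"
  if (grepl("\\(ucn\\)|ucn", lab)) fam <- "trnS2"
  # mitos-style trnl1/trns2 or paper-style trnluaa / trnsuga
  m <- regmatches(lab, regexec("^trn ?([ls])([12])", lab))[[1]]
  if (length(m) == 3L) {
    return(paste0("trn", toupper(m[[2]]), m[[3]]))
  }
  # amino acid identity
  aa <- NA_character_
  # paper-style compact labels like trnSuga / trnLuaa
  m <- regmatches(lab, regexec("^trn ?([ls])[- ]?(uaa|uag|gcu|uga|taa|tag|gct|tga)$", lab))[[1]]
  if (length(m) == 3L) {
    anticodon <- chartr("t", "u", m[[3]])
    aa <- c(l = "leu", s = "ser")[[m[[2]]]]
  }
  m <- regmatches(lab, regexec("^trna[- ]?([a-z]{3})", lab))[[1]]
  if (is.na(aa) && length(m) == 2L && m[[2]] %in% c(names(.aa3_to_key), "leu", "ser")) {
    aa <- m[[2]]
  } else if (is.na(aa)) {
    m <- regmatches(lab, regexec("^trn ?([a-z])$", lab))[[1]]
    if (length(m) == 2L) {
      aa1 <- m[[2]]
      if (aa1 %in% names(.aa1_to_key)) return(unname(.aa1_to_key[[aa1]]))
      if (aa1 %in% c("l", "s")) aa <- c(l = "leu", s = "ser")[[aa1]]
    }
  }
  if (is.na(aa) && is.na(fam)) return(NA_character_)
  if (!is.na(aa) && !aa %in% c("leu", "ser")) return(unname(.aa3_to_key[[aa]]))

  # leucine / serine: need family suffix or anticodon
  if (!is.na(fam)) return(fam)
  if (!is.na(anticodon) && nzchar(anticodon)) {
    ac <- chartr("t", "u", tolower(anticodon))
    key <- switch(ac,
      uag = "trnL1", uaa = "trnL2", gcu = "trnS1", uga = "trnS2",
      NA_character_
    )
    if (!is.na(key)) {
      # anticodon must be consistent with the amino acid when both given
      if (!is.na(aa) && substr(key, 4, 4) != toupper(substr(aa, 1, 1))) {
        warning("anticodon '", anticodon, "' inconsistent with label '",
          raw, "'; not mapped",
          call. = FALSE
        )
        return(NA_character_)
      }
      return(key)
    }
  }
  warning(
    "ambiguous leucine/serine tRNA label '", raw,
    "' (no anticodon or codon-family suffix); not mapped",
    call. = FALSE
  )
  NA_character_
}
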