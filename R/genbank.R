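#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the LOCUS line, the feature table and the ORIGIN sequence block of
#' a GenBank flat file. `CDS`, `tRNA`, `rRNA`, `D-loop` and `misc_feature`
#' entries are mapped onto the canonical vocabulary with
#' [normalize_gene_name()]; features that cannot be mapped are retained with
#' `gene = NA` and reported via a message. `join()` / `complement()`
#' locations are resolved to ordered spans (0-based half-open internally),
#' including spans that wrap the origin of a circular molecule.
#'
#' Strand labels are assigned relative to the majority strand: the strand
#' carrying `cox1` is labelled `"J"`. If a record is deposited with `cox1`
#' on the minus strand all labels are flipped accordingly (and
#' `j_is_plus = FALSE` is recorded), so downstream analyses see the same
#' genome regardless of which strand was deposited.
#'
#' @param path Path to a GenBank flat file.
#' @param allow_duplicates Passed to [mitogenome()]: `"error"` (default)
#'   rejects duplicate annotations for one gene key, `"first"` keeps the
#'   first with a warning.
#' @return A [mitogenome()].
#' @export
read_genbank <- function(path, allow_duplicates = c("error", "first")) {
  allow_duplicates <- match.arg(allow_duplicates)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path, call. = FALSE)

  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("no LOCUS line in ", path, call. = FALSE)
  locus_fields <- strsplit(trimws(locus[[1]]), "[[:space:]]+")[[1]]
  id <- locus_fields[[2]]
  circular <- any(grepl("circular", locus_fields, ignore.case = TRUE))

  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc) > 0L) {
    a <- strsplit(trimws(acc[[1]]), "[[:space:]]+")[[1]]
    if (length(a) >= 2L) id <- a[[2]]
  }

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("no ORIGIN block in ", path, call. = FALSE)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[[1]]][1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_at[[1]] + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence in ORIGIN block of ", path, call. = FALSE)

  feats <- parse_feature_table(lines, origin_at[[1]])
  organism <- NA_character_
  src <- feats[feats$type == "source", ]
  if (nrow(src) > 0L && !is.na(src$organism[[1]])) organism <- src$organism[[1]]
  feats <- feats[feats$type %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature"), ]

  if (nrow(feats) == 0L) {
    stop("no gene features found in ", path, call. = FALSE)
  }

  label <- dplyr::coalesce(feats$gene_q, feats$product, feats$note)
  gene <- ifelse(feats$type == "D-loop", "CR",
    suppressWarnings(normalize_gene_name(label, feats$anticodon))
  )
  # a misc_feature only maps if its label clearly names the control region
  # or a vocabulary gene; normalize_gene_name already handles both.
  unmapped <- is.na(gene) & !is.na(label)
  if (any(unmapped)) {
    message(
      id, ": ", sum(unmapped), " feature(s) not mapped to the vocabulary: ",
      paste(unique(label[unmapped]), collapse = ", ")
    )
  }

  # strand relative to cox1
  j_is_plus <- TRUE
  cox1_at <- which(gene == "cox1")
  if (length(cox1_at) > 0L && feats$minus[[cox1_at[[1]]]]) j_is_plus <- FALSE
  strand <- ifelse(feats$minus == !j_is_plus, "J", "N")

  mitogenome(
    id = id,
    sequence = sequence,
    features = tibble::tibble(
      gene = gene,
      strand = strand,
      start = feats$start,
      end = feats$end,
      anticodon = feats$anticodon,
      label = label
    ),
    circular = circular,
    organism = organism,
    j_is_plus = j_is_plus,
    allow_duplicates = allow_duplicates
  )
}

parse_feature_table <- function(lines, origin_at) {
  f_start <- grep("^FEATURES", lines)
  if (length(f_start) == 0L) stop("no FEATURES table", call. = FALSE)
  body <- lines[seq(f_start[[1]] + 1L, origin_at - 1L)]
  body <- body[nzchar(trimws(body))]
  # a new feature starts with a non-blank in column 6; qualifiers/continuations
  # are indented further
  is_head <- grepl("^ {1,10}[A-Za-z'_-]+[A-Za-z0-9'_-]* {2,}", body) &
    !grepl("^ {12,}", body)
  idx <- cumsum(is_head)
  out <- purrr::map(split(body, idx)[as.character(unique(idx[idx > 0]))], parse_one_feature)
  dplyr::bind_rows(out)
}

parse_one_feature <- function(chunk) {
  head_fields <- strsplit(trimws(chunk[[1]]), "[[:space:]]+")[[1]]
  type <- head_fields[[1]]
  rest <- chunk[-1]
  # location may continue over lines until the first qualifier
  qual_at <- grep("^[[:space:]]*/", rest)
  loc_extra <- if (length(qual_at)) rest[seq_len(qual_at[1] - 1L)] else rest
  location <- paste0(
    c(paste(head_fields[-1], collapse = ""), trimws(loc_extra)),
    collapse = ""
  )
  quals <- parse_qualifiers(if (length(qual_at)) rest[seq(qual_at[1], length(rest))] else character(0))
  loc <- parse_location(location)
  anticodon <- quals[["anticodon"]]
  if (!is.null(anticodon)) {
    m <- regmatches(anticodon, regexec("seq:([a-zA-Z]{3})", anticodon))[[1]]
    anticodon <- if (length(m) == 2L) tolower(m[[2]]) else tolower(gsub("[^a-zA-Z]", "", anticodon))
  }
  if (is.null(anticodon) && !is.null(quals[["note"]])) {
    m <- regmatches(quals[["note"]], regexec("anticodon[: ]([a-zA-Z]{3})", quals[["note"]]))[[1]]
    if (length(m) == 2L) anticodon <- tolower(m[[2]])
  }
  tibble::tibble(
    type = type,
    start = list(loc$start),
    end = list(loc$end),
    minus = loc$minus,
    gene_q = quals[["gene"]] %||% NA_character_,
    product = quals[["product"]] %||% NA_character_,
    note = quals[["note"]] %||% NA_character_,
    organism = quals[["organism"]] %||% NA_character_,
    anticodon = anticodon %||% NA_character_
  )
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  lines <- trimws(lines)
  starts <- grepl("^/", lines)
  merged <- character(0)
  for (i in seq_along(lines)) {
    if (starts[[i]] || length(merged) == 0L) {
      merged <- c(merged, lines[[i]])
    } else {
      merged[[length(merged)]] <- paste(merged[[length(merged)]], lines[[i]])
    }
  }
  out <- list()
  for (q in merged) {
    m <- regmatches(q, regexec("^/([a-zA-Z_]+)=?(.*)$", q))[[1]]
    if (length(m) == 3L) {
      val <- gsub('^"|"$', "", m[[3]])
      out[[m[[2]]]] <- val
    }
  }
  out
}

# GenBank location string -> 0-based half-open spans in annotation order
parse_location <- function(location) {
  loc <- gsub("[[:space:]<>]", "", location)
  minus <- FALSE
  if (grepl("^complement\\(", loc)) {
    minus <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  starts <- ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    rng <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1]]
    if (length(rng) == 0L) stop("cannot parse location '", location, "'", call. = FALSE)
    starts[[i]] <- as.integer(rng[[2]]) - 1L
    ends[[i]] <- if (nzchar(rng[[4]] %||% "")) as.integer(rng[[4]]) else as.integer(rng[[2]])
  }
  if (minus) {
    # complement(join(a..b,c..d)) reads d..c then b..a; keep annotation
    # (transcription) order for the spans
    starts <- rev(starts)
    ends <- rev(ends)
  }
  list(start = starts, end = ends, minus = minus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a minimal, deterministic GenBank flat file (fixed LOCUS date) with
#' `CDS`/`tRNA`/`rRNA`/`D-loop` features, `complement()`/`join()` locations,
#' and the full ORIGIN block, suitable for round-tripping through
#' [read_genbank()] and for consumption by standard toolchains.
#'
#' @param genome A [mitogenome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "mitogenome"))
  len <- nchar(genome$sequence)
  shape <- if (genome$circular) "circular" else "linear"
  out <- c(
    # fixed-column LOCUS line (name 12:28, length 29:40, topology 55:63)
    sprintf(
      "LOCUS       %-16s %11d bp    DNA     %-8s INV 01-JAN-2024",
      genome$id, len, shape
    ),
    sprintf(
      "DEFINITION  %s mitochondrion, complete genome.",
      if (is.na(genome$organism)) genome$id else genome$organism
    ),
    sprintf("ACCESSION   %s", genome$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"",
      if (is.na(genome$organism)) "synthetic construct" else genome$organism
    ),
    "                     /organelle=\"mitochondrion\""
  )
  vocab <- gene_vocabulary()
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    cls <- if (is.na(f$gene)) NA_character_ else gene_class(f$gene)
    type <- dplyr::case_match(cls,
      "PCG" ~ "CDS", "tRNA" ~ "tRNA", "rRNA" ~ "rRNA",
      "control" ~ "D-loop", .default = "misc_feature"
    )
    on_plus <- (f$strand == "J") == genome$j_is_plus
    loc <- format_location(f$start[[1]], f$end[[1]], !on_plus)
    out <- c(out, sprintf("     %-15s %s", type, loc))
    if (!is.na(f$gene) && cls != "control") {
      out <- c(out, sprintf("                     /gene=\"%s\"", f$gene))
    }
    lab <- f$label
    if (!is.na(lab) && (is.na(f$gene) || lab != f$gene)) {
      out <- c(out, sprintf("                     /product=\"%s\"", lab))
    }
    if (!is.na(f$anticodon)) {
      out <- c(out, sprintf(
        "                     /note=\"anticodon:%s\"", f$anticodon
      ))
    }
    if (type == "CDS") {
      out <- c(out, "                     /transl_table=5")
    }
  }
  out <- c(out, "ORIGIN", format_origin(genome$sequence), "//")
  writeLines(out, path)
  invisible(path)
}

format_location <- function(start, end, minus) {
  # 0-based half-open spans -> 1-based inclusive GenBank intervals
  ivs <- sprintf("%d..%d", start + 1L, end)
  if (minus) ivs <- rev(ivs)
  loc <- if (length(ivs) > 1L) paste0("join(", paste(ivs, collapse = ","), ")") else ivs
  if (minus) loc <- paste0("complement(", loc, ")")
  loc
}

format_origin <- function(sequence) {
  seq <- tolower(sequence)
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk))
    )
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}
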