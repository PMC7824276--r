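#' Site-class labels for skew analysis
#'
#' The eight strand-by-site classes: first and second codon positions of
#' J- and N-strand protein-coding genes (`J1`, `N1`, `J2`, `N2`) and third
#' codon positions stratified by synonymous-family size under the
#' invertebrate mitochondrial code (`2J3`, `2N3` for two-fold, `4J3`,
#' `4N3` for four-fold degenerate sites).
#'
#' @return Character vector of the eight class labels, in canonical order.
#' @export
site_classes <- function() c("J1", "N1", "J2", "N2", "2J3", "2N3", "4J3", "4N3")

# Two-base prefixes whose third-position synonymous family has size 4
# under the invertebrate mitochondrial code (translation table 5). Note
# AGN: AGA/AGG encode serine in this code, so the whole AGN box is one
# four-codon family (unlike the standard code).
.fourfold_prefixes <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG", "AG")

#' Third-position degeneracy of a codon under the invertebrate mitochondrial code
#'
#' Classifies codons by the size of the synonymous family sharing their
#' first two bases under translation table 5: `fourfold` when all four
#' third-position bases are synonymous, `twofold` otherwise, and `excluded`
#' for the stop codons (TAA, TAG) and for codons containing non-ACGT
#' characters. Families touching the stops (the TA box) contribute only
#' their sense codons.
#'
#' @param codon Character vector of 3-mers.
#' @return Character vector: `"twofold"`, `"fourfold"` or `"excluded"`.
#' @examples
#' degeneracy_class(c("CTA", "AGA", "TTT", "TAA"))
#' @export
degeneracy_class <- function(codon) {
  codon <- toupper(codon)
  ok <- nchar(codon) == 3L & !grepl("[^ACGT]", codon)
  prefix <- substr(codon, 1L, 2L)
  out <- ifelse(!ok | codon %in% c("TAA", "TAG"), "excluded",
    ifelse(prefix %in% .fourfold_prefixes, "fourfold", "twofold")
  )
  out
}

#' Partition the coding bases of a genome into the eight site classes
#'
#' Every annotated protein-coding gene is read codon-wise in mRNA sense.
#' The gene's strand selects the J or N classes; first- and second-position
#' bases accumulate into `J1`/`N1` and `J2`/`N2`, and third-position bases
#' into `2J3`/`2N3` or `4J3`/`4N3` according to [degeneracy_class()]. Stop
#' codons, codons containing ambiguous bases and incomplete trailing codons
#' contribute nothing (all their positions are excluded). Counts are pooled
#' across genes, giving one set of counts per genome and class.
#'
#' @param genome A [mitogenome()] with at least one annotated PCG.
#' @return A tibble with eight rows: `genome_id`, `class`, counts `a`,
#'   `c`, `g`, `t`, and `excluded_bases` (same value on every row: the
#'   number of coding bases excluded genome-wide, counting whole excluded
#'   codons and incomplete trailing codons).
#' @examples
#' g <- simulate_genome(synthetic_spec(seed = 1))
#' partition_sites(g)
#' @export
partition_sites <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  f <- genome$features
  pcg <- f$gene[!is.na(f$gene) & gene_class(f$gene) == "PCG"]
  if (length(pcg) == 0L) stop("no annotated protein-coding genes", call. = FALSE)

  tally <- matrix(0L, nrow = 8L, ncol = 4L,
    dimnames = list(site_classes(), c("A", "C", "G", "T"))
  )
  excluded <- 0L
  for (g in pcg) {
    strand <- f$strand[[match(g, f$gene)]]
    cds <- coding_sequence(genome, g)
    n3 <- nchar(cds) %/% 3L
    if (n3 == 0L) next
    codons <- substring(cds, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    dg <- degeneracy_class(codons)
    keep <- dg != "excluded"
    excluded <- excluded + 3L * sum(!keep) + nchar(cds) %% 3L
    if (!any(keep)) next
    codons <- codons[keep]
    dg <- dg[keep]
    p1 <- substr(codons, 1L, 1L)
    p2 <- substr(codons, 2L, 2L)
    p3 <- substr(codons, 3L, 3L)
    add <- function(class, bases) {
      tb <- table(factor(bases, levels = c("A", "C", "G", "T")))
      tally[class, ] <<- tally[class, ] + as.integer(tb)
    }
    add(paste0(strand, "1"), p1)
    add(paste0(strand, "2"), p2)
    add(paste0("2", strand, "3"), p3[dg == "twofold"])
    add(paste0("4", strand, "3"), p3[dg == "fourfold"])
  }
  tibble::tibble(
    genome_id = genome$id,
    class = factor(site_classes(), levels = site_classes()),
    a = tally[, "A"], c = tally[, "C"], g = tally[, "G"], t = tally[, "T"],
    excluded_bases = excluded
  )
}

#' AT and CG skews from site-class counts
#'
#' AT-skew = (A - T) / (A + T) and CG-skew = (C - G) / (C + G), the
#' standard measures of strand compositional asymmetry. A skew whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts A tibble with columns `a`, `c`, `g`, `t` (as produced by
#'   [partition_sites()]); any other columns are carried through.
#' @return The input with `at_skew` and `cg_skew` columns appended.
#' @examples
#' skew(tibble::tibble(a = 3, c = 2, g = 2, t = 1))
#' @export
skew <- function(counts) {
  counts <- tibble::as_tibble(counts)
  dplyr::mutate(
    counts,
    at_skew = dplyr::if_else(.data$a + .data$t > 0,
      (.data$a - .data$t) / (.data$a + .data$t), NA_real_
    ),
    cg_skew = dplyr::if_else(.data$c + .data$g > 0,
      (.data$c - .data$g) / (.data$c + .data$g), NA_real_
    )
  )
}

#' Per-genome, per-class skew table for a set of genomes
#'
#' Convenience wrapper: [partition_sites()] then [skew()] for each genome,
#' bound into one long table (the machine-readable twin of a per-class
#' skew scatter plot).
#'
#' @param genomes A list of [mitogenome()] objects.
#' @return A tibble: `genome_id`, `class`, counts, `at_skew`, `cg_skew`.
#' @export
skew_table <- function(genomes) {
  dplyr::bind_rows(purrr::map(genomes, ~ skew(partition_sites(.x))))
}

#' Detect outliers by the k x IQR rule
#'
#' Flags values lying beyond `k` times the interquartile range outside the
#' 25-75% quartiles: below Q1 - k*IQR or above Q3 + k*IQR. "Beyond" is
#' strict -- a value exactly on a fence is not flagged. Quartiles use
#' linear interpolation between order statistics (R's default quantile
#' type 7). Non-finite values are excluded; with fewer than four finite
#' values no outliers are reported and a warning is raised.
#'
#' @param values Named numeric vector (names are genome ids).
#' @param k IQR multiplier; 3 by default (far-out fences).
#' @return A one-row tibble: `n`, `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `outliers` (list-column of sorted names).
#' @examples
#' detect_outliers(c(a = 0, b = 0, c = 0, d = 10))
#' @export
detect_outliers <- function(values, k = 3) {
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 4L) {
    warning("fewer than 4 finite values; no outliers reported", call. = FALSE)
    return(tibble::tibble(
      n = length(v), q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
      lower_fence = NA_real_, upper_fence = NA_real_,
      outliers = list(character(0))
    ))
  }
  qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[[2]] - qs[[1]]
  lower <- qs[[1]] - k * iqr
  upper <- qs[[2]] + k * iqr
  out <- names(v)[v < lower | v > upper]
  tibble::tibble(
    n = length(v), q1 = qs[[1]], q3 = qs[[2]], iqr = iqr,
    lower_fence = lower, upper_fence = upper,
    outliers = list(sort(out %||% character(0)))
  )
}

#' Outlier report across site classes and skew metrics
#'
#' Applies [detect_outliers()] to every (class, metric) stratum of a skew
#' table. Undefined skews are excluded, not imputed.
#'
#' @param skews A skew table from [skew_table()].
#' @param k IQR multiplier (3 by default).
#' @return A tibble with one row per class and metric: the fence columns
#'   of [detect_outliers()] plus `class`, `metric` and `outliers`.
#' @export
skew_outliers <- function(skews, k = 3) {
  long <- tidyr::pivot_longer(
    dplyr::select(skews, "genome_id", "class", "at_skew", "cg_skew"),
    c("at_skew", "cg_skew"),
    names_to = "metric", values_to = "value"
  )
  long |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      detect_outliers(stats::setNames(d$value, d$genome_id), k = k)
    }) |>
    dplyr::ungroup()
}

#' AT% distribution over a set of genomes
#'
#' Whole-molecule AT percentage per genome (via [composition()]), for
#' comparison of a focal set against an optional background set.
#'
#' @param genomes A list of [mitogenome()] objects.
#' @return A tibble: `genome_id`, `at_pct`, sorted by id, with attributes
#'   `at_min` / `at_max` summarising the range.
#' @examples
#' gs <- lapply(1:2, function(s) simulate_genome(synthetic_spec(seed = s)))
#' at_percent_distribution(gs)
#' @export
at_percent_distribution <- function(genomes) {
  stopifnot(length(genomes) >= 1L)
  tab <- dplyr::bind_rows(purrr::map(genomes, composition))
  out <- dplyr::arrange(
    dplyr::select(tab, "genome_id", "at_pct"),
    .data$genome_id
  )
  attr(out, "at_min") <- min(out$at_pct)
  attr(out, "at_max") <- max(out$at_pct)
  out
}
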