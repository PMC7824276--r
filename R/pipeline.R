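#' @keywords internal
read_genome_any <- function(path) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    side <- sub("\\.[^.]+$", ".features.tsv", path)
    if (!file.exists(side)) {
      stop("no feature table (", basename(side), ") next to FASTA input", call. = FALSE)
    }
    read_fasta_annotation(path, side)
  } else {
    read_genbank(path)
  }
}

# read a batch, skipping (and logging) genomes that fail to parse
read_genome_batch <- function(inputs, log) {
  genomes <- list()
  for (p in inputs) {
    g <- tryCatch(
      withCallingHandlers(
        read_genome_any(p),
        message = function(m) {
          log(trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        },
        warning = function(w) {
          log(paste0("warning [", basename(p), "]: ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) {
        log(paste0("SKIPPED ", basename(p), ": ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(g)) genomes[[g$id]] <- g
  }
  genomes[order(names(genomes))]
}

make_logger <- function(out_dir, verbose) {
  log_path <- file.path(out_dir, "run.log")
  unlink(log_path)
  file.create(log_path)
  function(msg) {
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
}

#' Summarize genome architecture over a set of genomes
#'
#' Runs [classify_codons()], [spacers_and_overlaps()] and [composition()]
#' over every input genome and writes three TSV reports (`codons.tsv`,
#' `junctions.tsv`, `composition.tsv`) plus a `run.log` with per-genome
#' warnings. Genomes that fail to parse are skipped with a logged warning;
#' they never abort the batch.
#'
#' @param inputs Paths to GenBank (or FASTA + `.features.tsv`) files.
#' @param out_dir Output directory (created if needed).
#' @param verbose Echo log lines as messages?
#' @return Invisibly, a named list of the three tibbles.
#' @export
pipeline_summarize <- function(inputs, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(out_dir, verbose)
  genomes <- read_genome_batch(inputs, log)
  if (length(genomes) == 0L) stop("no readable genomes among inputs", call. = FALSE)
  grab <- function(f) {
    dplyr::bind_rows(purrr::map(genomes, function(g) {
      tryCatch(
        withCallingHandlers(f(g), warning = function(w) {
          log(paste0("warning [", g$id, "]: ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
        error = function(e) {
          log(paste0("SKIPPED ", g$id, ": ", conditionMessage(e)))
          NULL
        }
      )
    }))
  }
  out <- list(
    codons = grab(classify_codons),
    junctions = grab(spacers_and_overlaps),
    composition = grab(composition)
  )
  readr::write_tsv(out$codons, file.path(out_dir, "codons.tsv"))
  readr::write_tsv(out$junctions, file.path(out_dir, "junctions.tsv"))
  readr::write_tsv(out$composition, file.path(out_dir, "composition.tsv"))
  invisible(out)
}

#' Classify gene orders over a set of genomes
#'
#' Extracts every genome's circular signed gene order, classifies it
#' against the model catalog and reports the rearrangements relative to
#' the base (reference) model. Writes `classification.tsv` (one row per
#' genome: the machine-readable twin of a curated gene-order table) and
#' `rearrangements.tsv` (one row per affected gene), plus `run.log`.
#'
#' @inheritParams pipeline_summarize
#' @param catalog_path Optional path to a catalog TSV ([load_catalog()]).
#' @return Invisibly, a list with `classification` and `rearrangements`.
#' @export
pipeline_geneorder <- function(inputs, out_dir, catalog_path = NULL, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(out_dir, verbose)
  catalog <- load_catalog(catalog_path)
  genomes <- read_genome_batch(inputs, log)
  if (length(genomes) == 0L) stop("no readable genomes among inputs", call. = FALSE)
  base <- resolve_base_order(catalog$model[[1]], catalog)
  cls <- list()
  rearr <- list()
  for (g in genomes) {
    res <- tryCatch(
      {
        ord <- suppressMessages(extract_gene_order(g))
        c1 <- classify_order(ord, catalog)
        c1$missing_genes <- paste(c1$missing_genes[[1]], collapse = ",")
        c1$n_genes <- nrow(ord)
        rep1 <- suppressMessages(tidy(compare_orders(ord, base)))
        list(cls = c1, rearr = rep1)
      },
      error = function(e) {
        log(paste0("SKIPPED ", g$id, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) {
      cls[[g$id]] <- res$cls
      rearr[[g$id]] <- res$rearr
    }
  }
  out <- list(
    classification = dplyr::bind_rows(cls),
    rearrangements = dplyr::bind_rows(rearr)
  )
  readr::write_tsv(out$classification, file.path(out_dir, "classification.tsv"))
  readr::write_tsv(out$rearrangements, file.path(out_dir, "rearrangements.tsv"))
  invisible(out)
}

#' Skew and AT% analysis over a set of genomes
#'
#' Computes the per-genome, per-class skew table, the k x IQR outlier
#' report and the whole-molecule AT% distribution, writing `skews.tsv`,
#' `outliers.tsv` and `at_percent.tsv` plus `run.log`.
#'
#' @inheritParams pipeline_summarize
#' @param iqr_multiplier Fence multiplier for [skew_outliers()] (default 3).
#' @return Invisibly, a list with `skews`, `outliers`, `at_percent`.
#' @export
pipeline_skew <- function(inputs, out_dir, iqr_multiplier = 3, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(out_dir, verbose)
  genomes <- read_genome_batch(inputs, log)
  if (length(genomes) == 0L) stop("no readable genomes among inputs", call. = FALSE)
  skews <- skew_table(genomes)
  outliers <- suppressWarnings(skew_outliers(skews, k = iqr_multiplier))
  at <- at_percent_distribution(genomes)
  readr::write_tsv(skews, file.path(out_dir, "skews.tsv"))
  readr::write_tsv(
    dplyr::mutate(outliers,
      outliers = purrr::map_chr(.data$outliers, paste, collapse = ",")
    ),
    file.path(out_dir, "outliers.tsv")
  )
  readr::write_tsv(at, file.path(out_dir, "at_percent.tsv"))
  invisible(list(skews = skews, outliers = outliers, at_percent = at))
}

#' Simulate a fixture set of annotated genomes
#'
#' Writes one GenBank file, one FASTA and one feature TSV per simulated
#' genome into `out_dir`. Each fully specified catalog model can be
#' simulated, or several replicates of the base specification.
#'
#' @param out_dir Output directory.
#' @param n Replicates of the base spec (ignored when `models` given).
#' @param seed Master seed.
#' @param models Character vector of fully specified catalog model names
#'   to simulate (one genome each), or `NULL`.
#' @param verbose Echo log lines as messages?
#' @return Invisibly, the list of simulated [mitogenome()]s.
#' @export
pipeline_simulate <- function(out_dir, n = 3L, seed = 1L, models = NULL,
                              verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(out_dir, verbose)
  catalog <- load_catalog()
  if (is.null(models)) {
    specs <- purrr::map(seq_len(n), function(i) {
      synthetic_spec(seed = seed + i - 1L, id = sprintf("SYN%05d", seed + i - 1L))
    })
  } else {
    specs <- purrr::map(seq_along(models), function(i) {
      synthetic_spec(
        base = models[[i]], seed = seed + i - 1L,
        id = paste0("SYN_", gsub("[^A-Za-z0-9]+", "_", models[[i]]))
      )
    })
  }
  genomes <- purrr::map(specs, simulate_genome, catalog = catalog)
  for (g in genomes) {
    write_genbank(g, file.path(out_dir, paste0(g$id, ".gb")))
    write_fasta_annotation(
      g,
      file.path(out_dir, paste0(g$id, ".fasta")),
      file.path(out_dir, paste0(g$id, ".features.tsv"))
    )
    log(paste0("simulated ", g$id, " (", nchar(g$sequence), " bp)"))
  }
  invisible(genomes)
}

#' Merged per-genome report
#'
#' Runs the summarize, gene-order and skew stages and joins their
#' per-genome summaries into one table (`report.tsv`): genome length,
#' AT%, model assignment, codon-class counts and per-class skews in wide
#' form.
#'
#' @inheritParams pipeline_geneorder
#' @param iqr_multiplier Fence multiplier for the outlier stage.
#' @return Invisibly, the merged tibble.
#' @export
pipeline_report <- function(inputs, out_dir, catalog_path = NULL,
                            iqr_multiplier = 3, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- pipeline_summarize(inputs, out_dir, verbose = verbose)
  g <- pipeline_geneorder(inputs, out_dir, catalog_path = catalog_path, verbose = verbose)
  k <- pipeline_skew(inputs, out_dir, iqr_multiplier = iqr_multiplier, verbose = verbose)
  codon_counts <- s$codons |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarize(
      n_pcg = dplyr::n(),
      n_canonical_start = sum(.data$start_class == "canonical_ATA_ATG"),
      n_partial_stop = sum(.data$stop_class == "partial"),
      .groups = "drop"
    )
  skw <- k$skews |>
    dplyr::select("genome_id", "class", "at_skew", "cg_skew") |>
    tidyr::pivot_wider(
      names_from = "class",
      values_from = c("at_skew", "cg_skew")
    )
  merged <- s$composition |>
    dplyr::mutate(length = .data$a + .data$c + .data$g + .data$t) |>
    dplyr::select("genome_id", "length", "at_pct") |>
    dplyr::left_join(g$classification, by = "genome_id") |>
    dplyr::left_join(codon_counts, by = "genome_id") |>
    dplyr::left_join(skw, by = "genome_id") |>
    dplyr::arrange(.data$genome_id)
  readr::write_tsv(merged, file.path(out_dir, "report.tsv"))
  invisible(merged)
}
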