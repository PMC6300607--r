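#' Read gene models from a GTF file
#'
#' Parses exon features of a GTF file (GENCODE or Ensembl attribute dialect)
#' into a `gene_models` object: tidy tables of genes, transcripts and exons.
#' Transcript biotypes are read from the `transcript_type` attribute
#' (`dialect = "gencode"`) or `transcript_biotype` (`dialect = "ensembl"`);
#' a missing biotype is stored as `"unknown"`. Biotype strings are
#' normalised to lower case with spaces replaced by underscores, so
#' `"retained intron"` and `"retained_intron"` are equivalent.
#'
#' Records whose start exceeds their end are rejected with a warning and
#' counted in the `n_rejected` field; a structurally malformed line (wrong
#' field count, unparseable coordinates, missing `gene_id`/`transcript_id`)
#' raises an error naming the offending line number.
#'
#' @param path Path to a GTF file. Coordinates are 1-based inclusive.
#' @param dialect Attribute dialect, `"gencode"` (default) or `"ensembl"`.
#' @return A `gene_models` object: a list with tibbles `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`), `transcripts`
#'   (`transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`), `exons`
#'   (`chrom`, `start`, `end`, `strand`, `gene_id`, `transcript_id`,
#'   `exon_rank` ordered 5' to 3'), and the count `n_rejected`.
#' @seealso [build_splice_index()], [write_gtf()]
#' @export
read_gtf <- function(path, dialect = c("gencode", "ensembl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("GTF file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_gene_models(empty_exon_tbl(), n_rejected = 0L))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- line_no[which(nf != 9L)[1]]
    abort(paste0("malformed GTF record at line ", bad,
                 ": expected 9 tab-separated fields"))
  }
  feat <- vapply(fields, `[[`, character(1), 3L)
  is_exon <- feat == "exon"
  if (!any(is_exon)) {
    return(new_gene_models(empty_exon_tbl(), n_rejected = 0L))
  }
  fields <- fields[is_exon]
  line_no <- line_no[is_exon]

  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- line_no[which(is.na(starts) | is.na(ends))[1]]
    abort(paste0("malformed GTF record at line ", bad,
                 ": non-numeric coordinate"))
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  if (anyNA(gene_id) || anyNA(transcript_id)) {
    bad <- line_no[which(is.na(gene_id) | is.na(transcript_id))[1]]
    abort(paste0("malformed GTF attribute string at line ", bad,
                 ": gene_id and transcript_id are required"))
  }
  biotype_key <- if (dialect == "gencode") "transcript_type" else "transcript_biotype"
  biotype <- gtf_attr(attrs, biotype_key)
  biotype[is.na(biotype)] <- "unknown"
  biotype <- normalize_biotype(biotype)

  exons <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = starts,
    end = ends,
    strand = vapply(fields, `[[`, character(1), 7L),
    gene_id = gene_id,
    transcript_id = transcript_id,
    biotype = biotype
  )

  bad_coord <- exons$start > exons$end
  n_rejected <- sum(bad_coord)
  if (n_rejected > 0L) {
    warn(paste0(n_rejected, " exon record(s) with start > end rejected"))
    exons <- exons[!bad_coord, , drop = FALSE]
  }
  new_gene_models(exons, n_rejected = n_rejected)
}

gtf_attr <- function(attrs, key) {
  stringr::str_match(attrs, paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"'))[, 2]
}

normalize_biotype <- function(x) {
  gsub(" ", "_", tolower(x), fixed = TRUE)
}

empty_exon_tbl <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), gene_id = character(),
         transcript_id = character(), biotype = character())
}

# Construct a gene_models object from an exon table carrying per-exon
# biotype (replicated from its transcript). Ranks are assigned 5'->3'.
new_gene_models <- function(exons, n_rejected = 0L) {
  if (nrow(exons) > 0L) {
    exons <- exons |>
      group_by(.data$transcript_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(exon_rank = if (first(.data$strand) == "-") rev(row_number()) else row_number()) |>
      ungroup() |>
      arrange(.data$gene_id, .data$transcript_id, .data$start)
    transcripts <- exons |>
      distinct(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand,
               .data$biotype)
    genes <- exons |>
      group_by(.data$gene_id) |>
      summarise(chrom = first(.data$chrom), strand = first(.data$strand),
                start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    exons <- select(exons, -"biotype")
  } else {
    exons$exon_rank <- integer()
    exons <- select(exons, -"biotype")
    transcripts <- tibble(transcript_id = character(), gene_id = character(),
                          chrom = character(), strand = character(),
                          biotype = character())
    genes <- tibble(gene_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer())
  }
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         n_rejected = as.integer(n_rejected)),
    class = "gene_models"
  )
}

#' Build a gene_models object from tidy exon and transcript tables
#'
#' Programmatic constructor used by the simulator and by tests: supply an
#' exon table (`chrom`, `start`, `end`, `strand`, `gene_id`,
#' `transcript_id`) and a transcript biotype table (`transcript_id`,
#' `biotype`).
#'
#' @param exons Tibble of exons.
#' @param biotypes Tibble with `transcript_id` and `biotype`; transcripts
#'   absent from it get biotype `"unknown"`.
#' @return A `gene_models` object.
#' @export
gene_models <- function(exons, biotypes = NULL) {
  exons <- as_tibble(exons)
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id",
                  "transcript_id") %in% names(exons)))
  if (is.null(biotypes)) {
    exons$biotype <- "unknown"
  } else {
    exons <- left_join(exons, select(as_tibble(biotypes), "transcript_id", "biotype"),
                       by = "transcript_id")
    exons$biotype[is.na(exons$biotype)] <- "unknown"
  }
  exons$biotype <- normalize_biotype(exons$biotype)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  new_gene_models(exons)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$transcripts),
      " transcripts, ", nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' @export
format.gene_models <- function(x, ...) {
  paste0("<gene_models: ", nrow(x$genes), " genes>")
}

#' Write gene models back to GTF
#'
#' Emits one exon feature line per exon with `gene_id`, `transcript_id`,
#' the dialect's biotype attribute and `exon_number`, so that
#' [read_gtf()] on the output reproduces the models (round-trip safe).
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @param dialect Attribute dialect controlling the biotype key.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, dialect = c("gencode", "ensembl")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(models, "gene_models"))
  biotype_key <- if (dialect == "gencode") "transcript_type" else "transcript_biotype"
  ex <- left_join(models$exons,
                  select(models$transcripts, "transcript_id", "biotype"),
                  by = "transcript_id")
  if (nrow(ex) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; %s "%s"; exon_number %d;',
                   ex$gene_id, ex$transcript_id, biotype_key, ex$biotype,
                   ex$exon_rank)
  lines <- paste(ex$chrom, "spliceswitch", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attrs, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
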