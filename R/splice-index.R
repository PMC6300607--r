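#' Build a splice-site index from gene models
#'
#' Enumerates, per gene, the annotated donor and acceptor splice sites,
#' the annotated introns, the internal exons (exons that are neither first
#' nor last in their transcript) and the terminal-exon boundary
#' coordinates. Splice sites are stored as exon-boundary coordinates
#' (1-based, inclusive): for the + strand the donor of an intron is the
#' end of its upstream exon and the acceptor the start of its downstream
#' exon; on the - strand the roles swap ends. A junction stored as an
#' intron interval `[start, end]` therefore meets annotated sites at
#' `start - 1` (left boundary) and `end + 1` (right boundary).
#'
#' A boundary coordinate is flagged *terminal* when it lies on a
#' transcript's first or last exon in some transcript of the gene and is
#' never an internal-exon boundary in any transcript of that gene; these
#' flag candidate alternative transcript ends.
#'
#' @param models A `gene_models` object.
#' @return A `splice_index` object: list of tibbles `sites` (`gene_id`,
#'   `coord`, `role` in donor/acceptor, `strand`, list-column `biotypes`),
#'   `introns` (`gene_id`, `transcript_id`, `chrom`, `strand`, intron
#'   `start`/`end`), `internal_exons`, `terminal_sites` (`gene_id`,
#'   `coord`), and the `genes` table of `models`.
#' @export
build_splice_index <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- left_join(models$exons,
                  select(models$transcripts, "transcript_id", "biotype"),
                  by = "transcript_id")

  # consecutive exon pairs per transcript in genomic order
  ex_g <- ex |> arrange(.data$transcript_id, .data$start)
  pair_tbl <- ex_g |>
    group_by(.data$transcript_id) |>
    mutate(
      next_start = dplyr::lead(.data$start),
      n_ex = n(),
      idx = row_number()
    ) |>
    ungroup() |>
    filter(!is.na(.data$next_start))

  if (nrow(pair_tbl) > 0L) {
    introns <- pair_tbl |>
      transmute_intron()
    # per-intron boundary sites with strand-aware roles
    left_role <- ifelse(introns$strand == "+", "donor", "acceptor")
    right_role <- ifelse(introns$strand == "+", "acceptor", "donor")
    site_rows <- bind_rows(
      tibble(gene_id = introns$gene_id, coord = introns$start - 1L,
             role = left_role, strand = introns$strand,
             biotype = introns$biotype),
      tibble(gene_id = introns$gene_id, coord = introns$end + 1L,
             role = right_role, strand = introns$strand,
             biotype = introns$biotype)
    )
    sites <- site_rows |>
      group_by(.data$gene_id, .data$coord, .data$role, .data$strand) |>
      summarise(biotypes = list(sort(unique(.data$biotype))), .groups = "drop")
    introns <- distinct(select(introns, "gene_id", "transcript_id", "chrom",
                               "strand", "start", "end", "biotype"))
  } else {
    sites <- tibble(gene_id = character(), coord = integer(),
                    role = character(), strand = character(),
                    biotypes = list())
    introns <- tibble(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      biotype = character())
  }

  internal_exons <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(.pos = row_number(), .n = n()) |>
    ungroup() |>
    filter(.data$.pos > 1L, .data$.pos < .data$.n) |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end)

  # terminal-exon boundary coords: on a first/last exon of some transcript,
  # never on an internal exon of any transcript of the same gene
  flanks <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(.pos = row_number(), .n = n()) |>
    ungroup()
  term_coords <- flanks |>
    filter(.data$.pos == 1L | .data$.pos == .data$.n) |>
    tidyr::pivot_longer(cols = c("start", "end"), values_to = "coord") |>
    distinct(.data$gene_id, .data$coord)
  internal_coords <- flanks |>
    filter(.data$.pos > 1L, .data$.pos < .data$.n) |>
    tidyr::pivot_longer(cols = c("start", "end"), values_to = "coord") |>
    distinct(.data$gene_id, .data$coord)
  terminal_sites <- dplyr::anti_join(term_coords, internal_coords,
                                     by = c("gene_id", "coord"))

  structure(
    list(sites = sites, introns = introns, internal_exons = internal_exons,
         terminal_sites = terminal_sites, genes = models$genes),
    class = "splice_index"
  )
}

transmute_intron <- function(pair_tbl) {
  tibble(
    gene_id = pair_tbl$gene_id,
    transcript_id = pair_tbl$transcript_id,
    chrom = pair_tbl$chrom,
    strand = pair_tbl$strand,
    start = pair_tbl$end + 1L,
    end = pair_tbl$next_start - 1L,
    biotype = pair_tbl$biotype
  )
}

#' @export
print.splice_index <- function(x, ...) {
  cat("<splice_index> ", length(unique(x$sites$gene_id)), " genes, ",
      nrow(x$sites), " sites, ", nrow(distinct(x$introns, .data$gene_id,
      .data$start, .data$end)), " distinct introns\n", sep = "")
  invisible(x)
}

#' Find exons strictly inside a junction's intron interval
#'
#' Returns the annotated internal exons of the junction's gene that lie
#' strictly inside the intron interval (`exon_start > start` and
#' `exon_end < end`) — the "in-between" exons whose presence makes a
#' junction an exon-skipping/inclusion candidate.
#'
#' @param j A list or one-row data frame with `gene_id`, `start`, `end`
#'   (intron interval, first/last intronic base).
#' @param index A `splice_index`.
#' @return Tibble of distinct contained exons (`chrom`, `strand`, `start`,
#'   `end`).
#' @export
find_in_between_exons <- function(j, index) {
  stopifnot(inherits(index, "splice_index"))
  gid <- j$gene_id
  if (!gid %in% index$genes$gene_id) {
    abort(paste0("gene not present in splice index: ", gid))
  }
  index$internal_exons |>
    filter(.data$gene_id == gid, .data$start > j$start, .data$end < j$end) |>
    distinct(.data$chrom, .data$strand, .data$start, .data$end)
}

#' Biotypes owning a splice site
#'
#' Union of transcript biotypes of all transcripts of `gene_id` having an
#' annotated splice site (donor or acceptor) at the exon-boundary
#' coordinate `coord`; empty character vector when the coordinate is not
#' an annotated splice site of the gene.
#'
#' @param gene_id Gene identifier.
#' @param coord Exon-boundary coordinate (1-based).
#' @param index A `splice_index`.
#' @return Character vector of biotypes (possibly empty).
#' @export
site_biotypes <- function(gene_id, coord, index) {
  stopifnot(inherits(index, "splice_index"))
  if (!gene_id %in% index$genes$gene_id) {
    abort(paste0("gene not present in splice index: ", gene_id))
  }
  gid <- gene_id; cc <- coord
  hits <- filter(index$sites, .data$gene_id == gid, .data$coord == cc)
  sort(unique(as.character(unlist(hits$biotypes))))
}
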