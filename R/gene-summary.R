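#' Per-gene event summary
#'
#' Groups event calls by gene, counting events per category. Genes with
#' no calls are excluded. When gene-level test results are supplied, a
#' `significant` flag marks genes at `gene FDR <= gene_alpha`.
#'
#' @param calls An `event_calls` tibble from [classify_all()].
#' @param gene_results Optional tibble from [gene_level()].
#' @param gene_alpha Gene FDR threshold (default `0.0005`).
#' @return Tibble with `gene_id`, one count column per event category,
#'   `n_events`, and `significant` when `gene_results` is given.
#' @export
events_per_gene <- function(calls, gene_results = NULL,
                            gene_alpha = default_gene_alpha()) {
  calls <- as_tibble(calls)
  cats <- event_categories()
  if (nrow(calls) == 0L) {
    out <- tibble(gene_id = character())
    for (cc in cats) out[[cc]] <- integer()
    out$n_events <- integer()
    return(out)
  }
  wide <- calls |>
    count(.data$gene_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cc in setdiff(cats, names(wide))) wide[[cc]] <- 0L
  out <- wide |>
    select("gene_id", all_of(cats)) |>
    mutate(n_events = rowSums(across(all_of(cats)))) |>
    arrange(dplyr::desc(.data$n_events), .data$gene_id)
  if (!is.null(gene_results)) {
    out <- out |>
      left_join(select(gene_results, "gene_id", gene_FDR = "FDR"),
                by = "gene_id") |>
      mutate(significant = !is.na(.data$gene_FDR) &
               .data$gene_FDR <= gene_alpha)
  }
  out
}

#' Histogram of genes by number of events
#'
#' @param calls An `event_calls` tibble (or an [events_per_gene()]
#'   summary).
#' @return Tibble `n_events`, `n_genes`; the weighted sum
#'   `sum(n_events * n_genes)` equals the total number of calls.
#' @export
event_count_histogram <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) {
    return(tibble(n_events = integer(), n_genes = integer()))
  }
  per_gene <- if ("n_events" %in% names(calls)) {
    select(calls, "gene_id", "n_events")
  } else {
    count(calls, .data$gene_id, name = "n_events")
  }
  per_gene |>
    count(.data$n_events, name = "n_genes") |>
    arrange(.data$n_events)
}

#' Long/short isoform-switch score
#'
#' Quantifies a switch between two isoforms of one gene between
#' conditions: with per-condition summed marker abundances `L_c`, `S_c`
#' (pseudocount 0.5 each), the score is
#' `log2( (L_t/S_t) / (L_c/S_c) )` — positive when the long isoform is
#' enriched in the treated condition — and the total-abundance fold
#' change is `(L_t + S_t) / (L_c + S_c)`. A switch with score far from 0
#' but total FC near 1 mirrors an isoform switch that leaves overall
#' gene output unchanged.
#'
#' Marker abundances can be isoform-exclusive junction counts (RNA-seq)
#' or externally measured per-isoform quantities (qPCR); the score is
#' agnostic. When `lib_sizes` is supplied, each sample's counts are
#' rescaled to counts-per-million before condition summation, making the
#' score invariant to per-sample scaling.
#'
#' @param long_counts,short_counts Non-negative per-sample abundances of
#'   the long and short isoform markers (same length and order).
#' @param condition Character/factor of per-sample condition labels with
#'   exactly two levels.
#' @param treated The condition level treated as numerator; defaults to
#'   `"treated"` when present, else the second sorted level.
#' @param lib_sizes Optional per-sample library sizes for normalisation.
#' @param pseudocount Added to each isoform-condition sum (default 0.5).
#' @return One-row tibble: `score`, `total_fc`, and the per-condition
#'   sums `long_control`, `short_control`, `long_treated`,
#'   `short_treated`.
#' @export
switch_score <- function(long_counts, short_counts, condition,
                         treated = NULL, lib_sizes = NULL,
                         pseudocount = 0.5) {
  stopifnot(length(long_counts) == length(short_counts),
            length(condition) == length(long_counts),
            all(long_counts >= 0), all(short_counts >= 0))
  levels <- sort(unique(as.character(condition)))
  if (length(levels) != 2L) abort("exactly two condition levels required")
  if (is.null(treated)) {
    treated <- if ("treated" %in% levels) "treated" else levels[2]
  }
  control <- setdiff(levels, treated)
  if (!is.null(lib_sizes)) {
    stopifnot(length(lib_sizes) == length(long_counts), all(lib_sizes > 0))
    # CPM-style scaling to a fixed library size, so per-sample rescaling
    # of counts and library size together cancels exactly
    long_counts <- long_counts / lib_sizes * 1e6
    short_counts <- short_counts / lib_sizes * 1e6
  }
  sums <- function(x, lvl) sum(x[condition == lvl])
  L_c <- sums(long_counts, control); S_c <- sums(short_counts, control)
  L_t <- sums(long_counts, treated); S_t <- sums(short_counts, treated)
  if (L_c + S_c == 0 || L_t + S_t == 0) {
    abort("both isoform totals are zero in one condition; switch score undefined")
  }
  ratio_c <- (L_c + pseudocount) / (S_c + pseudocount)
  ratio_t <- (L_t + pseudocount) / (S_t + pseudocount)
  tibble(
    score = log2(ratio_t / ratio_c),
    total_fc = (L_t + S_t) / (L_c + S_c),
    long_control = L_c, short_control = S_c,
    long_treated = L_t, short_treated = S_t
  )
}

#' Isoform-exclusive marker junctions
#'
#' For two transcripts of one gene, returns the junctions (annotated
#' introns) exclusive to each: the set differences of their intron sets.
#' Counts over these junctions discriminate the isoforms in junction
#' data, e.g. a long isoform and a short isoform ending at an
#' alternative final exon.
#'
#' @param models A `gene_models` object.
#' @param gene_id Gene identifier.
#' @param long_id,short_id Transcript identifiers within the gene.
#' @return Tibble of junctions (`chrom`, `strand`, `start`, `end`) with
#'   an `isoform` column (`"long"` / `"short"`).
#' @export
isoform_marker_junctions <- function(models, gene_id, long_id, short_id) {
  stopifnot(inherits(models, "gene_models"))
  txs <- filter(models$transcripts, .data$gene_id == !!gene_id)
  for (tid in c(long_id, short_id)) {
    if (!tid %in% txs$transcript_id) {
      abort(paste0("transcript '", tid, "' not found in gene '", gene_id, "'"))
    }
  }
  tx_introns <- function(tid) {
    ex <- models$exons |>
      filter(.data$transcript_id == tid) |>
      arrange(.data$start)
    if (nrow(ex) < 2L) {
      return(tibble(chrom = character(), strand = character(),
                    start = integer(), end = integer()))
    }
    tibble(chrom = ex$chrom[-nrow(ex)], strand = ex$strand[-nrow(ex)],
           start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
  }
  long_i <- tx_introns(long_id)
  short_i <- tx_introns(short_id)
  key <- function(d) paste(d$chrom, d$start, d$end)
  bind_rows(
    mutate(long_i[!key(long_i) %in% key(short_i), , drop = FALSE],
           isoform = "long"),
    mutate(short_i[!key(short_i) %in% key(long_i), , drop = FALSE],
           isoform = "short")
  )
}
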