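#' Partner junctions sharing a splice site
#'
#' Returns the tested junctions of the same gene that share a splice site
#' with `j`: same chromosome and strand, and identical `start` (shared
#' donor-side boundary) or identical `end` (shared acceptor-side
#' boundary). `j` itself is excluded. The relation is symmetric.
#'
#' @param j A list or one-row data frame with `chrom`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @param tested A `usage_results` tibble (or any junction tibble with
#'   those columns).
#' @return The matching rows of `tested`.
#' @export
partners <- function(j, tested) {
  tested |>
    filter(.data$gene_id == j$gene_id,
           .data$chrom == j$chrom,
           .data$strand == j$strand,
           .data$start == j$start | .data$end == j$end,
           !(.data$start == j$start & .data$end == j$end))
}

event_categories <- function() {
  c("A5SS", "A3SS", "IR", "EI", "ES", "ATE", "UNCLASSIFIED")
}

ir_biotypes <- function() c("retained_intron", "nonsense_mediated_decay")

#' Classify one significant junction into an alternative-splicing event
#'
#' Applies the rule cascade to a tested junction, in precedence order:
#'
#' 1. **IR** — either boundary of the junction (`start - 1` or `end + 1`)
#'    equals an annotated splice site owned by a transcript of biotype
#'    `retained_intron` or `nonsense_mediated_decay`.
#' 2. **ES / EI** — the junction spans at least one annotated in-between
#'    (internal) exon; with `M` the mean fold change of the partner
#'    junctions sharing a splice site: `M > 1` and `FC < 1` gives ES
#'    (exon skipping), `M < 1` and `FC > 1` gives EI (exon inclusion);
#'    any other direction pattern — or an empty partner set, which leaves
#'    `M` undefined — falls through.
#' 3. **A5SS / A3SS** — the strand-aware donor boundary is not an
#'    annotated donor of the gene while the acceptor boundary is an
#'    annotated acceptor (A5SS), or conversely (A3SS).
#' 4. **ATE** — either boundary equals a terminal-exon-flagged coordinate
#'    (a first/last-exon boundary never used as an internal-exon boundary
#'    in any transcript of the gene); a heuristic, as no rule exists for
#'    alternative transcript ends.
#' 5. **UNCLASSIFIED** otherwise.
#'
#' Junctions with `FDR > alpha` are not classified (returns `NULL`).
#'
#' @param j A one-row data frame / list with `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `FC`, `FDR`.
#' @param index A `splice_index` covering `j`'s gene.
#' @param tested All tested junctions (`usage_results`), used for the
#'   partner mean in rule 2.
#' @param alpha Junction FDR gate; default `0.001`.
#' @param partner_mean `"arithmetic"` (default, the literal reading of
#'   the rule) or `"geometric"`.
#' @return A one-row tibble (`gene_id`, junction key, `category`, `FC`,
#'   `FDR`, list-column `evidence`) or `NULL` when not significant.
#' @export
classify_junction <- function(j, index, tested, alpha = default_junction_alpha(),
                              partner_mean = c("arithmetic", "geometric")) {
  partner_mean <- match.arg(partner_mean)
  stopifnot(inherits(index, "splice_index"))
  if (is.na(j$FDR) || j$FDR > alpha) return(NULL)
  if (!j$gene_id %in% index$genes$gene_id) {
    abort(paste0("gene not present in splice index: ", j$gene_id))
  }
  gid <- j$gene_id
  left_b <- j$start - 1L
  right_b <- j$end + 1L
  gsites <- filter(index$sites, .data$gene_id == gid)
  evidence <- list()

  # rule 1: intron retention via retained_intron / NMD splice sites
  ir_hits <- gsites |>
    filter(.data$coord %in% c(left_b, right_b),
           map_lgl(.data$biotypes, ~ any(.x %in% ir_biotypes())))
  if (nrow(ir_hits) > 0L) {
    evidence$matched_biotypes <-
      sort(unique(intersect(unlist(ir_hits$biotypes), ir_biotypes())))
    evidence$matched_sites <- unique(ir_hits$coord)
    return(event_row(j, "IR", evidence))
  }

  # rule 2: exon skipping / inclusion via in-between exon + partner FCs
  ibe <- find_in_between_exons(j, index)
  if (nrow(ibe) > 0L) {
    prt <- partners(j, tested)
    evidence$in_between_exons <- paste0(ibe$start, "-", ibe$end)
    if (nrow(prt) > 0L) {
      M <- if (partner_mean == "arithmetic") mean(prt$FC)
           else exp(mean(log(prt$FC)))
      evidence$partner_junctions <- paste0(prt$start, "-", prt$end)
      evidence$partner_mean_fc <- M
      if (M > 1 && j$FC < 1) return(event_row(j, "ES", evidence))
      if (M < 1 && j$FC > 1) return(event_row(j, "EI", evidence))
      evidence$es_ei_fallthrough <- "direction-condition-failed"
    } else {
      evidence$es_ei_fallthrough <- "no-partners-mean-undefined"
    }
  }

  # rule 3: alternative 5'/3' splice site (strand-aware roles)
  on_plus <- !identical(j$strand, "-")
  donor_b <- if (on_plus) left_b else right_b
  acceptor_b <- if (on_plus) right_b else left_b
  donors <- gsites$coord[gsites$role == "donor"]
  acceptors <- gsites$coord[gsites$role == "acceptor"]
  donor_known <- donor_b %in% donors
  acceptor_known <- acceptor_b %in% acceptors
  if (!donor_known && acceptor_known) return(event_row(j, "A5SS", evidence))
  if (donor_known && !acceptor_known) return(event_row(j, "A3SS", evidence))

  # rule 4: alternative transcript end (heuristic terminal-site match)
  term <- index$terminal_sites$coord[index$terminal_sites$gene_id == gid]
  if (left_b %in% term || right_b %in% term) {
    evidence$terminal_sites <- intersect(c(left_b, right_b), term)
    return(event_row(j, "ATE", evidence))
  }

  event_row(j, "UNCLASSIFIED", evidence)
}

event_row <- function(j, category, evidence) {
  tibble(
    gene_id = j$gene_id, chrom = j$chrom, start = j$start, end = j$end,
    strand = j$strand, category = category, FC = j$FC, FDR = j$FDR,
    evidence = list(evidence)
  )
}

#' Classify all significant junctions
#'
#' Runs [classify_junction()] over every tested junction at
#' `FDR <= alpha` and tabulates event-category frequencies. Junctions
#' whose gene is missing from the index are recorded as classification
#' errors and skipped; the pipeline continues.
#'
#' @param results A `usage_results` tibble from [usage_test()].
#' @param index A `splice_index`.
#' @param alpha Junction FDR gate (default `0.001`).
#' @param partner_mean Passed to [classify_junction()].
#' @return An `event_calls` tibble (one row per significant junction with
#'   `category` and `evidence`); the frequency table is in
#'   `attr(, "frequencies")` and via [event_frequencies()], classification
#'   errors in `attr(, "errors")`.
#' @export
classify_all <- function(results, index, alpha = default_junction_alpha(),
                         partner_mean = c("arithmetic", "geometric")) {
  partner_mean <- match.arg(partner_mean)
  sig <- which(!is.na(results$FDR) & results$FDR <= alpha)
  calls <- list()
  errors <- list()
  for (i in sig) {
    row <- results[i, , drop = FALSE]
    call <- tryCatch(
      classify_junction(row, index, results, alpha = alpha,
                        partner_mean = partner_mean),
      error = function(e) {
        errors[[length(errors) + 1L]] <<-
          tibble(gene_id = row$gene_id, chrom = row$chrom, start = row$start,
                 end = row$end, message = conditionMessage(e))
        NULL
      })
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  calls_tbl <- if (length(calls)) list_rbind(calls) else
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character(), category = character(),
           FC = numeric(), FDR = numeric(), evidence = list())
  freq <- tibble(category = event_categories()) |>
    left_join(count(calls_tbl, .data$category), by = "category") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(calls_tbl,
            class = c("event_calls", class(calls_tbl)),
            frequencies = freq,
            errors = if (length(errors)) list_rbind(errors) else NULL,
            alpha = alpha)
}

#' Event-type frequency table
#'
#' @param calls An `event_calls` tibble from [classify_all()].
#' @return Tibble `category`, `n` over all seven categories; counts sum
#'   to the number of classified significant junctions.
#' @export
event_frequencies <- function(calls) {
  attr(calls, "frequencies") %||%
    (tibble(category = event_categories()) |>
       left_join(count(as_tibble(calls), .data$category), by = "category") |>
       mutate(n = dplyr::coalesce(.data$n, 0L)))
}
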