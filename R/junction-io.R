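#' Read a STAR SJ.out.tab junction file
#'
#' Parses STAR's 9-column splice-junction table. Columns are: chromosome,
#' intron start (first intronic base, 1-based), intron end (last intronic
#' base), strand code (0 = unknown, 1 = +, 2 = -), intron motif,
#' annotation flag, uniquely-mapping read count, multi-mapping read count,
#' maximum overhang. The uniquely-mapping count (column 7) is the count
#' used downstream; columns 5, 6, 8, 9 are retained as metadata.
#'
#' @param path Path to an SJ.out.tab-dialect file (whitespace separated).
#' @return Tibble with `chrom`, `start`, `end`, `strand` (`+`, `-` or
#'   `?`), `count` (unique reads) and metadata columns `motif`,
#'   `annotated`, `multi_count`, `max_overhang`.
#' @export
read_star_sj <- function(path) {
  if (!file.exists(path)) abort(paste0("junction file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), count = integer(),
                  motif = integer(), annotated = integer(),
                  multi_count = integer(), max_overhang = integer()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    abort(paste0("malformed junction record at line ", bad,
                 ": expected 9 whitespace-separated columns, got ", nf[bad]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) {
      abort(paste0("malformed junction record at line ", which(is.na(v))[1],
                   ": non-integer value in column ", i))
    }
    v
  }
  strand_code <- num(4L)
  if (!all(strand_code %in% 0:2)) {
    abort("strand code must be 0 (unknown), 1 (+) or 2 (-)")
  }
  count <- num(7L)
  if (any(count < 0L)) {
    abort(paste0("malformed junction record at line ", which(count < 0L)[1],
                 ": negative read count"))
  }
  tibble(
    chrom = col(1L),
    start = num(2L),
    end = num(3L),
    strand = c("?", "+", "-")[strand_code + 1L],
    count = count,
    motif = num(5L),
    annotated = num(6L),
    multi_count = num(8L),
    max_overhang = num(9L)
  )
}

#' Write junctions in STAR SJ.out.tab dialect
#'
#' @param junctions Tibble with `chrom`, `start`, `end`, `strand`, `count`
#'   and optionally the metadata columns emitted by [read_star_sj()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(junctions, path) {
  j <- as_tibble(junctions)
  strand_code <- match(j$strand, c("?", "+", "-")) - 1L
  col_or <- function(nm, default) {
    if (nm %in% names(j)) j[[nm]] else rep(default, nrow(j))
  }
  motif <- col_or("motif", 0L)
  annotated <- col_or("annotated", 1L)
  multi <- col_or("multi_count", 0L)
  overhang <- col_or("max_overhang", 50L)
  lines <- paste(j$chrom, j$start, j$end, strand_code, motif, annotated,
                 j$count, multi, overhang, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

new_junction_matrix <- function(junctions, counts, samples) {
  stopifnot(nrow(junctions) == nrow(counts),
            nrow(samples) == ncol(counts))
  dimnames(counts) <- list(NULL, samples$sample_id)
  structure(list(junctions = junctions, counts = counts, samples = samples),
            class = "junction_matrix")
}

#' Assemble a junction-by-sample count matrix
#'
#' Takes per-sample junction count tables (as returned by
#' [read_star_sj()]) and a sample sheet, and assembles the union of
#' junctions into one integer count matrix; a junction absent from a
#' sample gets count 0. Junctions are ordered deterministically by
#' (chrom, start, end, strand).
#'
#' @param samples Named list of per-sample junction tibbles (each with
#'   `chrom`, `start`, `end`, `strand`, `count`); names are sample ids.
#' @param sheet Data frame with `sample_id` and `condition` columns;
#'   exactly two condition levels are required.
#' @return A `junction_matrix` object: list with tibble `junctions`
#'   (`chrom`, `start`, `end`, `strand`, `gene_id` = `NA` until
#'   [assign_junctions_to_genes()]), integer matrix `counts`, and tibble
#'   `samples` (`sample_id`, `condition`).
#' @export
assemble_matrix <- function(samples, sheet) {
  sheet <- as_tibble(sheet)
  stopifnot(all(c("sample_id", "condition") %in% names(sheet)))
  ids <- names(samples)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("`samples` must be a named list of per-sample junction tables")
  }
  missing_sheet <- setdiff(ids, sheet$sample_id)
  if (length(missing_sheet) > 0L) {
    abort(paste0("sample(s) absent from the sample sheet: ",
                 paste(missing_sheet, collapse = ", ")))
  }
  sheet <- filter(sheet, .data$sample_id %in% ids)
  levels <- sort(unique(sheet$condition))
  if (length(levels) != 2L) {
    abort(paste0("the design must have exactly two condition levels, got ",
                 length(levels), " (", paste(levels, collapse = ", "), ")"))
  }

  long <- imap(samples, function(tbl, id) {
    tbl <- as_tibble(tbl)
    tibble(chrom = tbl$chrom, start = as.integer(tbl$start),
           end = as.integer(tbl$end), strand = tbl$strand,
           sample_id = id, count = as.integer(tbl$count))
  }) |> list_rbind()

  junctions <- long |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  junctions$gene_id <- NA_character_

  key <- function(d) paste(d$chrom, d$start, d$end, d$strand, sep = ":")
  jkey <- key(junctions)
  counts <- matrix(0L, nrow = nrow(junctions), ncol = length(ids))
  for (s in seq_along(ids)) {
    rows <- long[long$sample_id == ids[s], , drop = FALSE]
    idx <- match(key(rows), jkey)
    counts[, s] <- 0L
    # duplicated junction records within a sample accumulate
    agg <- rowsum(rows$count, idx)
    counts[as.integer(rownames(agg)), s] <- as.integer(agg[, 1])
  }
  samples_tbl <- tibble(sample_id = ids) |>
    left_join(select(sheet, "sample_id", "condition"), by = "sample_id")
  new_junction_matrix(junctions, counts, samples_tbl)
}

#' @export
print.junction_matrix <- function(x, ...) {
  cat("<junction_matrix> ", nrow(x$junctions), " junctions x ",
      nrow(x$samples), " samples (conditions: ",
      paste(sort(unique(x$samples$condition)), collapse = " vs "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.junction_matrix <- function(x, ...) {
  bind_cols(x$junctions, as_tibble(x$counts, .name_repair = "minimal"))
}

#' Filter junctions on minimum count support
#'
#' Keeps junctions having `count >= min_count` in at least `min_samples`
#' samples; junction order is preserved and the operation is idempotent.
#'
#' @param m A `junction_matrix`.
#' @param min_count Minimum per-sample count (default 5).
#' @param min_samples Minimum number of samples meeting it; defaults to
#'   the size of the smaller condition group.
#' @return A filtered `junction_matrix`.
#' @export
filter_junctions <- function(m, min_count = 5L, min_samples = NULL) {
  stopifnot(inherits(m, "junction_matrix"), min_count >= 0)
  if (is.null(min_samples)) {
    min_samples <- min(table(m$samples$condition))
  }
  stopifnot(min_samples >= 1)
  keep <- rowSums(m$counts >= min_count) >= min_samples
  new_junction_matrix(m$junctions[keep, , drop = FALSE],
                      m$counts[keep, , drop = FALSE], m$samples)
}

#' Assign junctions to genes
#'
#' Maps each junction to the gene whose span contains the junction's
#' intron interval on a compatible strand (a junction of unknown strand
#' `?` is compatible with either). Ties between nested/overlapping
#' same-strand genes are broken by (1) preferring a gene with an
#' annotated splice site exactly matching one of the junction's boundary
#' coordinates, then (2) the smaller gene span, then (3) lexicographic
#' gene id. Junctions contained in no gene keep `gene_id = NA` and are
#' excluded from downstream testing.
#'
#' @param m A `junction_matrix`.
#' @param index A `splice_index` built from `models`.
#' @param models The `gene_models` the index was built from.
#' @return The `junction_matrix` with the `gene_id` column populated.
#' @export
assign_junctions_to_genes <- function(m, index, models) {
  stopifnot(inherits(m, "junction_matrix"), inherits(index, "splice_index"))
  genes <- models$genes
  j <- m$junctions
  site_key <- paste(index$sites$gene_id, index$sites$coord)
  gene_id <- rep(NA_character_, nrow(j))
  for (i in seq_len(nrow(j))) {
    cand <- genes[genes$chrom == j$chrom[i] &
                    genes$start <= j$start[i] & genes$end >= j$end[i], ,
                  drop = FALSE]
    if (j$strand[i] %in% c("+", "-")) {
      cand <- cand[cand$strand == j$strand[i], , drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    if (nrow(cand) > 1L) {
      has_site <- paste(cand$gene_id, j$start[i] - 1L) %in% site_key |
        paste(cand$gene_id, j$end[i] + 1L) %in% site_key
      ord <- order(-has_site, cand$end - cand$start, cand$gene_id)
      cand <- cand[ord, , drop = FALSE]
    }
    gene_id[i] <- cand$gene_id[1]
  }
  m$junctions$gene_id <- gene_id
  m
}
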