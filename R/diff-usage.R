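#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values in input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and contain no NA")
  }
  p.adjust(p, method = "BH")
}

# Beta-binomial log-likelihood of counts y out of totals n at proportion
# prob with intra-class correlation rho (rho <= 0 reduces to binomial).
ll_betabinom <- function(y, n, prob, rho) {
  if (rho <= 1e-12) {
    return(sum(stats::dbinom(y, n, prob, log = TRUE)))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

# Maximized beta-binomial log-likelihood over the proportion (1-D search).
ml_betabinom <- function(y, n, rho, tol = 1e-8) {
  tot <- sum(n)
  if (tot == 0) return(0)
  phat <- sum(y) / tot
  if (phat <= 0 || phat >= 1 || rho <= 1e-12) {
    # binomial MLE is closed-form; boundary MLEs coincide for beta-binomial
    return(ll_betabinom(y, n, min(max(phat, 1e-12), 1 - 1e-12), rho))
  }
  opt <- optimize(function(p) ll_betabinom(y, n, p, rho),
                  interval = c(1e-9, 1 - 1e-9), maximum = TRUE, tol = tol)
  opt$objective
}

# Method-of-moments dispersion evidence for one gene: chi-square-style
# statistic accumulated over junction x condition cells, using the
# condition-specific proportion estimate so genuine usage shifts do not
# inflate the estimate. Returns the accumulators so callers can pool or
# shrink across genes; `k` counts the cells used.
mom_rho_stats <- function(Y, totals, cond_idx) {
  x2 <- 0; df <- 0; B <- 0; k <- 0L
  for (jj in seq_len(nrow(Y))) {
    for (cells in cond_idx) {
      use <- cells[totals[cells] > 0]
      m <- length(use)
      if (m < 2L) next
      y <- Y[jj, use]; n <- totals[use]
      phat <- sum(y) / sum(n)
      if (phat <= 0 || phat >= 1) next
      x2 <- x2 + sum((y - n * phat)^2 / (n * phat * (1 - phat)))
      df <- df + (m - 1)
      B <- B + sum(n - 1) * (m - 1) / m
      k <- k + 1L
    }
  }
  list(x2 = x2, df = df, B = B, k = k)
}

mom_rho <- function(Y, totals, cond_idx) {
  s <- mom_rho_stats(Y, totals, cond_idx)
  if (s$B <= 0) return(0)
  max(0, (s$x2 - s$df) / s$B)
}

#' Per-junction differential relative-usage test
#'
#' For every junction of every gene with at least two tested junctions,
#' tests whether the junction's relative usage — its count divided by the
#' gene's total junction count in that sample — differs between the two
#' conditions. The test is a beta-binomial likelihood-ratio test: a
#' gene-pooled method-of-moments intra-class correlation captures
#' biological overdispersion of usage proportions (floored at 0, where
#' the test reduces to a binomial LRT), the proportion is profiled out by
#' 1-D golden-section likelihood maximisation, and the LRT statistic is
#' referred to a chi-squared distribution with 1 degree of freedom.
#'
#' The usage fold change is `FC = (mean treated proportion + eps) /
#' (mean control proportion + eps)` with pseudo-proportion
#' `eps = 0.5 / median gene total`. FDR is Benjamini-Hochberg across all
#' tested junctions.
#'
#' @param m A gene-assigned `junction_matrix` (see
#'   [assign_junctions_to_genes()]); junctions with `gene_id = NA` are
#'   skipped.
#' @param treated Condition level taken as "treated" (numerator of FC).
#'   Defaults to `"treated"` when present, else the second sorted level.
#' @return A `usage_results` tibble: `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `usage_control`, `usage_treated`, `FC`, `p`, `FDR`.
#'   Skipped junctions and their reasons are in `attr(, "skipped")`.
#' @export
usage_test <- function(m, treated = NULL) {
  stopifnot(inherits(m, "junction_matrix"))
  cond <- m$samples$condition
  levels <- sort(unique(cond))
  if (length(levels) != 2L) abort("exactly two condition levels required")
  if (is.null(treated)) {
    treated <- if ("treated" %in% levels) "treated" else levels[2]
  }
  if (!treated %in% levels) {
    abort(paste0("treated level '", treated, "' not among conditions: ",
                 paste(levels, collapse = ", ")))
  }
  control <- setdiff(levels, treated)
  is_trt <- cond == treated

  j <- m$junctions
  skipped <- list()
  out <- list()
  gene_ids <- unique(j$gene_id[!is.na(j$gene_id)])

  # pass 1: dispersion evidence per testable gene, pooled across genes
  # for empirical shrinkage of the noisy per-gene moment estimates
  gene_data <- list()
  pool <- list(x2 = 0, df = 0, B = 0)
  for (g in gene_ids) {
    rows <- which(!is.na(j$gene_id) & j$gene_id == g)
    if (length(rows) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        tibble(gene_id = g, n_junctions = length(rows),
               reason = "single-junction-gene")
      next
    }
    Y <- m$counts[rows, , drop = FALSE]
    totals <- colSums(Y)
    if (all(totals[!is_trt] == 0) || all(totals[is_trt] == 0)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(gene_id = g, n_junctions = length(rows),
               reason = "no-expression")
      next
    }
    s <- mom_rho_stats(Y, totals, list(which(!is_trt), which(is_trt)))
    pool$x2 <- pool$x2 + s$x2; pool$df <- pool$df + s$df
    pool$B <- pool$B + s$B
    gene_data[[g]] <- list(rows = rows, Y = Y, totals = totals, stats = s)
  }
  rho_pool <- if (pool$B > 0) max(0, (pool$x2 - pool$df) / pool$B) else 0
  prior_cells <- 30

  for (g in names(gene_data)) {
    gd <- gene_data[[g]]
    rows <- gd$rows; Y <- gd$Y; totals <- gd$totals; s <- gd$stats
    rho_gene <- if (s$B > 0) max(0, (s$x2 - s$df) / s$B) else rho_pool
    # shrink the per-gene moment estimate toward the dataset-wide value;
    # weight by the number of dispersion cells the gene contributed
    rho <- (s$k * rho_gene + prior_cells * rho_pool) / (s$k + prior_cells)
    rho <- min(rho, 0.95)
    med_total <- median(totals)
    eps <- 0.5 / max(med_total, 1)

    prop <- sweep(Y, 2, pmax(totals, 1), "/")
    prop[, totals == 0] <- NA_real_
    for (k in seq_along(rows)) {
      y <- Y[k, ]; n <- totals
      ll0 <- ml_betabinom(y, n, rho)
      ll1 <- ml_betabinom(y[!is_trt], n[!is_trt], rho) +
        ml_betabinom(y[is_trt], n[is_trt], rho)
      stat <- max(0, 2 * (ll1 - ll0))
      pval <- pchisq(stat, df = 1, lower.tail = FALSE)
      u_c <- mean(prop[k, !is_trt], na.rm = TRUE)
      u_t <- mean(prop[k, is_trt], na.rm = TRUE)
      out[[length(out) + 1L]] <- tibble(
        chrom = j$chrom[rows[k]], start = j$start[rows[k]],
        end = j$end[rows[k]], strand = j$strand[rows[k]], gene_id = g,
        usage_control = u_c, usage_treated = u_t,
        FC = (u_t + eps) / (u_c + eps), p = pval
      )
    }
  }
  res <- if (length(out)) list_rbind(out) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), gene_id = character(),
           usage_control = numeric(), usage_treated = numeric(),
           FC = numeric(), p = numeric())
  res$FDR <- bh_adjust(res$p)
  structure(res,
            class = c("usage_results", class(res)),
            skipped = if (length(skipped)) list_rbind(skipped) else
              tibble(gene_id = character(), n_junctions = integer(),
                     reason = character()),
            treated = treated, control = control)
}

#' Gene-level differential-splicing aggregation
#'
#' Aggregates per-junction p-values to one p-value per gene by the
#' Bonferroni-adjusted minimum, `p_gene = min(1, n_g * min(p))`, then
#' applies BH across genes. Genes at `FDR <= 0.0005` are the default
#' differential-splicing calls.
#'
#' @param results A `usage_results` tibble from [usage_test()].
#' @return Tibble with `gene_id`, `n_junctions`, `p`, `FDR`, ordered by
#'   `p`.
#' @export
gene_level <- function(results) {
  stopifnot(is.data.frame(results), all(c("gene_id", "p") %in% names(results)))
  out <- results |>
    group_by(.data$gene_id) |>
    summarise(n_junctions = n(),
              p = min(1, n() * min(.data$p)),
              .groups = "drop")
  out$FDR <- bh_adjust(out$p)
  arrange(out, .data$p, .data$gene_id)
}

#' @export
glance.usage_results <- function(x, alpha = default_junction_alpha(), ...) {
  tibble(
    n_junctions = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_id),
    n_significant = sum(x$FDR <= alpha),
    alpha = alpha,
    treated = attr(x, "treated"),
    control = attr(x, "control")
  )
}

#' @export
tidy.usage_results <- function(x, ...) {
  as_tibble(unclass_results(x))
}

unclass_results <- function(x) {
  class(x) <- setdiff(class(x), "usage_results")
  attr(x, "skipped") <- NULL
  attr(x, "treated") <- NULL
  attr(x, "control") <- NULL
  x
}
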