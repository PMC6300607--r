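# Shared toy fixtures, built in code.

# The canonical 3-exon toy gene: exons 1-100, 201-300, 401-500 on the +
# strand; introns (101,200) and (301,400).
toy_exons <- function(strand = "+") {
  data.frame(chrom = "chr1",
             start = c(1L, 201L, 401L), end = c(100L, 300L, 500L),
             strand = strand, gene_id = "G1", transcript_id = "G1.T1")
}

toy_models <- function(strand = "+") {
  gene_models(toy_exons(strand),
              data.frame(transcript_id = "G1.T1", biotype = "protein_coding"))
}

toy_gtf_lines <- function() {
  ex <- toy_exons()
  sprintf(paste0("chr1\ttoy\texon\t%d\t%d\t.\t+\t.\t",
                 "gene_id \"G1\"; transcript_id \"G1.T1\"; ",
                 "transcript_type \"protein_coding\";"),
          ex$start, ex$end)
}

write_tmp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A junction_matrix built directly from per-junction count rows.
# `counts` is a matrix with one row per junction.
make_matrix <- function(junctions, counts, conditions) {
  samples <- tibble::tibble(
    sample_id = paste0("s", seq_len(ncol(counts))),
    condition = conditions
  )
  spliceswitch:::new_junction_matrix(tibble::as_tibble(junctions),
                                     matrix(as.integer(counts),
                                            nrow = nrow(junctions)),
                                     samples)
}

# Brute-force Benjamini-Hochberg step-up: q_i = min_{j: p_j ranked >= i}
# n * p_(j) / j, computed literally from the definition with loops.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (jj in i:n) {
      best <- min(best, n * p[o[jj]] / jj)
    }
    q_sorted[i] <- min(1, best)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Exhaustive two-sided Fisher oracle from the margin-fixed table weights,
# using binomial coefficients directly.
fisher_brute <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  as <- max(0, c1 - r2):min(r1, c1)
  w <- choose(r1, as) * choose(r2, c1 - as) / choose(n, c1)
  obs <- w[match(t[1, 1], as)]
  sum(w[w <= obs * (1 + 1e-7)])
}
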