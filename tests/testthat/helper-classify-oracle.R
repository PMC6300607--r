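# Independent brute-force interpreter of the event-classification rules,
# written directly against raw exon/biotype tables with plain loops -- no
# package index structures. Used to cross-check classify_junction().

oracle_classify <- function(j, exons, biotypes, tested, alpha = 0.001) {
  if (is.na(j$FDR) || j$FDR > alpha) return(NA_character_)
  ex <- exons[exons$gene_id == j$gene_id, , drop = FALSE]
  bt <- setNames(biotypes$biotype, biotypes$transcript_id)
  left_b <- j$start - 1L
  right_b <- j$end + 1L

  # per-transcript sorted exons and splice sites
  tx_ids <- unique(ex$transcript_id)
  donor_sites <- integer(0); acceptor_sites <- integer(0)
  ir_sites <- integer(0)
  internal_ex <- list(); internal_coords <- integer(0)
  terminal_coords <- integer(0)
  for (tid in tx_ids) {
    te <- ex[ex$transcript_id == tid, , drop = FALSE]
    te <- te[order(te$start), , drop = FALSE]
    nE <- nrow(te)
    tx_sites <- integer(0)
    if (nE >= 2) {
      for (i in seq_len(nE - 1)) {
        left <- te$end[i]; right <- te$start[i + 1]
        if (te$strand[1] == "+") {
          donor_sites <- c(donor_sites, left)
          acceptor_sites <- c(acceptor_sites, right)
        } else {
          donor_sites <- c(donor_sites, right)
          acceptor_sites <- c(acceptor_sites, left)
        }
        tx_sites <- c(tx_sites, left, right)
      }
    }
    if (bt[[tid]] %in% c("retained_intron", "nonsense_mediated_decay")) {
      ir_sites <- c(ir_sites, tx_sites)
    }
    if (nE >= 3) {
      for (i in 2:(nE - 1)) {
        internal_ex[[length(internal_ex) + 1]] <- c(te$start[i], te$end[i])
        internal_coords <- c(internal_coords, te$start[i], te$end[i])
      }
    }
    terminal_coords <- c(terminal_coords, te$start[1], te$end[1],
                         te$start[nE], te$end[nE])
  }

  # rule 1: intron retention
  if (left_b %in% ir_sites || right_b %in% ir_sites) return("IR")

  # rule 2: exon skipping / inclusion
  has_ibe <- FALSE
  for (e in internal_ex) {
    if (e[1] > j$start && e[2] < j$end) { has_ibe <- TRUE; break }
  }
  if (has_ibe) {
    fcs <- numeric(0)
    for (i in seq_len(nrow(tested))) {
      t_i <- tested[i, ]
      if (t_i$gene_id == j$gene_id && t_i$chrom == j$chrom &&
          t_i$strand == j$strand &&
          (t_i$start == j$start || t_i$end == j$end) &&
          !(t_i$start == j$start && t_i$end == j$end)) {
        fcs <- c(fcs, t_i$FC)
      }
    }
    if (length(fcs) > 0) {
      M <- sum(fcs) / length(fcs)
      if (M > 1 && j$FC < 1) return("ES")
      if (M < 1 && j$FC > 1) return("EI")
    }
  }

  # rule 3: alternative 5'/3' splice site
  if (j$strand == "-") {
    donor_b <- right_b; acceptor_b <- left_b
  } else {
    donor_b <- left_b; acceptor_b <- right_b
  }
  d_known <- donor_b %in% donor_sites
  a_known <- acceptor_b %in% acceptor_sites
  if (!d_known && a_known) return("A5SS")
  if (d_known && !a_known) return("A3SS")

  # rule 4: alternative transcript end
  term <- setdiff(terminal_coords, internal_coords)
  if (left_b %in% term || right_b %in% term) return("ATE")

  "UNCLASSIFIED"
}

# Random toy locus generator for oracle-equivalence checks: a small gene
# with 1-3 transcripts (optionally retained_intron / NMD companions) and
# a handful of tested junctions -- annotated introns plus perturbed
# (novel-end) junctions -- with random fold changes and FDRs.
random_toy_locus <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(3:5, 1)
  ex_len <- sample(50:150, n_ex, replace = TRUE)
  in_len <- sample(60:400, n_ex - 1, replace = TRUE)
  starts <- 1000L + cumsum(c(0L, ex_len[-n_ex] + in_len))
  ends <- starts + ex_len - 1L

  exons <- data.frame(chrom = "chrT", start = starts, end = ends,
                      strand = strand, gene_id = "GX",
                      transcript_id = "GX.T1")
  biotypes <- data.frame(transcript_id = "GX.T1", biotype = "protein_coding")

  pick <- function(v) if (length(v) == 1) v else sample(v, 1)
  if (runif(1) < 0.5) {
    # skip variant (drops a random internal exon)
    k <- pick(2:(n_ex - 1))
    exons <- rbind(exons, data.frame(chrom = "chrT", start = starts[-k],
                                     end = ends[-k], strand = strand,
                                     gene_id = "GX", transcript_id = "GX.T2"))
    biotypes <- rbind(biotypes, data.frame(transcript_id = "GX.T2",
                                           biotype = "protein_coding"))
  }
  if (runif(1) < 0.4) {
    # retained-intron / NMD companion (merges a random adjacent pair)
    r <- pick(seq_len(n_ex - 1))
    exons <- rbind(exons, data.frame(chrom = "chrT", start = starts[-(r + 1)],
                                     end = ends[-r], strand = strand,
                                     gene_id = "GX", transcript_id = "GX.T3"))
    biotypes <- rbind(biotypes,
                      data.frame(transcript_id = "GX.T3",
                                 biotype = sample(c("retained_intron",
                                                    "nonsense_mediated_decay"), 1)))
  }

  # candidate junctions: all annotated intron intervals plus perturbations
  introns <- data.frame(start = ends[-n_ex] + 1L, end = starts[-1] - 1L)
  cand <- introns
  # exon-spanning junction (skip geometry) sometimes present in the data
  if (n_ex >= 3 && runif(1) < 0.7) {
    k <- pick(2:(n_ex - 1))
    cand <- rbind(cand, data.frame(start = ends[k - 1] + 1L,
                                   end = starts[k + 1] - 1L))
  }
  n_novel <- sample(0:3, 1)
  for (i in seq_len(n_novel)) {
    base <- introns[pick(seq_len(nrow(introns))), ]
    side <- sample(c("start", "end"), 1)
    shift <- sample(c(-30:-5, 5:30), 1)
    base[[side]] <- base[[side]] + shift
    if (base$start < base$end) cand <- rbind(cand, base)
  }
  cand <- unique(cand)
  n_j <- nrow(cand)
  tested <- data.frame(
    chrom = "chrT", start = as.integer(cand$start),
    end = as.integer(cand$end), strand = strand, gene_id = "GX",
    FC = exp(stats::rnorm(n_j, 0, 0.7)),
    FDR = ifelse(runif(n_j) < 0.6, runif(n_j, 0, 0.001), runif(n_j, 0.01, 1))
  )
  list(exons = exons, biotypes = biotypes, tested = tested)
}

# Run both classifier routes over a locus; returns a data.frame of
# per-junction categories from implementation and oracle.
compare_classifiers <- function(locus, alpha = 0.001) {
  models <- gene_models(locus$exons, locus$biotypes)
  index <- build_splice_index(models)
  tested <- tibble::as_tibble(locus$tested)
  out <- lapply(seq_len(nrow(tested)), function(i) {
    j <- tested[i, ]
    impl <- classify_junction(j, index, tested, alpha = alpha)
    impl_cat <- if (is.null(impl)) NA_character_ else impl$category
    orc <- oracle_classify(j, locus$exons, locus$biotypes, locus$tested,
                           alpha = alpha)
    data.frame(start = j$start, end = j$end, impl = impl_cat, oracle = orc)
  })
  do.call(rbind, out)
}
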