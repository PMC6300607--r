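toy_tested <- function(fc, fdr = rep(1e-4, length(fc))) {
  tibble::tibble(
    chrom = "chr1",
    start = c(101L, 101L, 301L)[seq_along(fc)],
    end = c(200L, 400L, 400L)[seq_along(fc)],
    strand = "+", gene_id = "G1", FC = fc, FDR = fdr)
}

test_that("partners share a splice-site end within the gene", {
  tested <- toy_tested(c(1.5, 0.5, 1.7))
  p <- partners(tested[2, ], tested)
  expect_equal(nrow(p), 2L)
  expect_setequal(paste(p$start, p$end), c("101 200", "301 400"))
  # symmetric relation
  for (i in 1:3) for (k in 1:3) {
    if (i == k) next
    in_ik <- nrow(dplyr::semi_join(partners(tested[i, ], tested),
                                   tested[k, ],
                                   by = c("start", "end"))) > 0
    in_ki <- nrow(dplyr::semi_join(partners(tested[k, ], tested),
                                   tested[i, ],
                                   by = c("start", "end"))) > 0
    expect_equal(in_ik, in_ki)
  }
  lone <- tibble::tibble(chrom = "chr1", start = 900L, end = 950L,
                         strand = "+", gene_id = "G1", FC = 1, FDR = 1e-4)
  expect_equal(nrow(partners(lone, tested)), 0L)
})

test_that("junctions above the FDR gate are not classified", {
  idx <- build_splice_index(toy_models())
  tested <- toy_tested(c(1.5, 0.5, 1.7), fdr = c(1e-4, 0.01, 1e-4))
  expect_null(classify_junction(tested[2, ], idx, tested, alpha = 0.001))
})

test_that("the exon-spanning junction classifies as ES or EI by direction", {
  idx <- build_splice_index(toy_models())
  # partners mean 1.6 > 1 and FC 0.5 < 1: exon skipping
  tested <- toy_tested(c(1.5, 0.5, 1.7))
  call <- classify_junction(tested[2, ], idx, tested)
  expect_equal(call$category, "ES")
  expect_equal(call$evidence[[1]]$partner_mean_fc, 1.6)
  expect_equal(call$evidence[[1]]$in_between_exons, "201-300")

  # converse direction: exon inclusion
  tested2 <- toy_tested(c(0.5, 2.0, 0.7))
  expect_equal(classify_junction(tested2[2, ], idx, tested2)$category, "EI")

  # direction condition failed on both sides: falls through (here to ATE,
  # since the junction ends on first/last-exon boundaries of the toy gene)
  tested3 <- toy_tested(c(1.5, 2.0, 1.7))
  call3 <- classify_junction(tested3[2, ], idx, tested3)
  expect_false(call3$category %in% c("ES", "EI"))
  expect_equal(call3$evidence[[1]]$es_ei_fallthrough,
               "direction-condition-failed")
})

test_that("retained-intron sites take precedence over exon geometry", {
  # add a retained_intron transcript sharing site 100 with the gene
  ex <- rbind(toy_exons(),
              data.frame(chrom = "chr1", start = c(1L, 401L),
                         end = c(300L, 500L), strand = "+", gene_id = "G1",
                         transcript_id = "G1.T2"))
  gm <- gene_models(ex, data.frame(
    transcript_id = c("G1.T1", "G1.T2"),
    biotype = c("protein_coding", "retained_intron")))
  idx <- build_splice_index(gm)
  # same geometry that classified ES above now hits rule 1 first:
  # the skip junction's left boundary (100) is a retained_intron site
  tested <- toy_tested(c(1.5, 0.5, 1.7))
  call <- classify_junction(tested[2, ], idx, tested)
  expect_equal(call$category, "IR")
  expect_true("retained_intron" %in% call$evidence[[1]]$matched_biotypes)
  # junction (101,200) touches no T2 splice site (T2's sites are 300 and
  # 401), so it is NOT flipped to IR by the companion
  call1 <- classify_junction(tested[1, ], idx, tested)
  expect_false(call1$category == "IR")
  # junction (301,400) has both boundaries on T2 sites: IR with the
  # companion, something else without it
  idx0 <- build_splice_index(toy_models())
  expect_equal(classify_junction(tested[3, ], idx, tested)$category, "IR")
  expect_false(classify_junction(tested[3, ], idx0, tested)$category == "IR")
})

test_that("novel donors with annotated acceptors classify as A5SS", {
  idx <- build_splice_index(toy_models())
  j <- tibble::tibble(chrom = "chr1", start = 150L, end = 400L,
                      strand = "+", gene_id = "G1", FC = 2, FDR = 1e-4)
  call <- classify_junction(j, idx, toy_tested(c(1, 1, 1)))
  expect_equal(call$category, "A5SS")
  # converse geometry on the acceptor side
  j2 <- tibble::tibble(chrom = "chr1", start = 101L, end = 250L,
                       strand = "+", gene_id = "G1", FC = 2, FDR = 1e-4)
  expect_equal(classify_junction(j2, idx, toy_tested(c(1, 1, 1)))$category,
               "A3SS")
})

test_that("classify_junction matches the brute-force rule interpreter", {
  for (s in 1:60) {
    cmp <- compare_classifiers(random_toy_locus(s))
    agree <- cmp$impl == cmp$oracle | (is.na(cmp$impl) & is.na(cmp$oracle))
    expect_true(all(agree),
                label = paste("locus seed", s, "junctions",
                              paste(cmp$start[!agree], collapse = ",")))
  }
})

test_that("reflecting a locus leaves event categories invariant", {
  for (s in 1:25) {
    locus <- random_toy_locus(s)
    M <- max(locus$exons$end) + 1000L
    refl <- locus
    refl$exons$start <- M - locus$exons$end
    refl$exons$end <- M - locus$exons$start
    refl$exons$strand <- ifelse(locus$exons$strand == "+", "-", "+")
    refl$tested$start <- M - locus$tested$end
    refl$tested$end <- M - locus$tested$start
    refl$tested$strand <- ifelse(locus$tested$strand == "+", "-", "+")
    c1 <- compare_classifiers(locus)
    c2 <- compare_classifiers(refl)
    c2 <- c2[match(paste(M - c1$end, M - c1$start),
                   paste(c2$start, c2$end)), ]
    expect_equal(c2$impl, c1$impl)
  }
})

test_that("classify_all partitions significant junctions into one category each", {
  cfg <- sim_config(n_genes = 40, n_es = 8, n_ir = 5, n_a5ss = 4, seed = 13)
  sim <- simulate_splicing_dataset(cfg)
  res <- usage_test(sim$matrix)
  calls <- classify_all(res, sim$index, alpha = 0.05)
  freq <- event_frequencies(calls)
  expect_equal(sum(freq$n), sum(res$FDR <= 0.05))
  expect_equal(sum(freq$n), nrow(calls))
  expect_setequal(freq$category,
                  c("A5SS", "A3SS", "IR", "EI", "ES", "ATE", "UNCLASSIFIED"))
  # no junction appears twice
  expect_equal(anyDuplicated(paste(calls$gene_id, calls$start, calls$end)), 0L)
})

test_that("classify_all on no significant junctions yields an all-zero table", {
  idx <- build_splice_index(toy_models())
  tested <- toy_tested(c(1.5, 0.5, 1.7), fdr = rep(0.5, 3))
  calls <- classify_all(tested, idx)
  expect_equal(nrow(calls), 0L)
  expect_equal(sum(event_frequencies(calls)$n), 0L)
})
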