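test_that("read_gtf parses the toy gene and handles both dialects", {
  path <- write_tmp_gtf(toy_gtf_lines())
  gm <- read_gtf(path)
  expect_equal(nrow(gm$genes), 1L)
  expect_equal(nrow(gm$transcripts), 1L)
  expect_equal(nrow(gm$exons), 3L)
  expect_equal(gm$transcripts$biotype, "protein_coding")
  expect_equal(gm$genes$start, 1L)
  expect_equal(gm$genes$end, 500L)

  # ensembl dialect reads transcript_biotype, with normalisation of the
  # biotype string
  lines <- sub('transcript_type "protein_coding"',
               'transcript_biotype "Retained Intron"', toy_gtf_lines())
  gm2 <- read_gtf(write_tmp_gtf(lines), dialect = "ensembl")
  expect_equal(gm2$transcripts$biotype, "retained_intron")
  # under the wrong dialect the attribute is absent
  gm3 <- read_gtf(write_tmp_gtf(lines), dialect = "gencode")
  expect_equal(gm3$transcripts$biotype, "unknown")
})

test_that("read_gtf returns an empty model set for an empty file", {
  gm <- read_gtf(write_tmp_gtf(character()))
  expect_s3_class(gm, "gene_models")
  expect_equal(nrow(gm$genes), 0L)
  expect_equal(nrow(gm$exons), 0L)
})

test_that("read_gtf flags retained_intron companion transcripts", {
  lines <- c(toy_gtf_lines(),
             paste0("chr1\ttoy\texon\t1\t300\t.\t+\t.\t",
                    'gene_id "G1"; transcript_id "G1.T2"; ',
                    'transcript_type "retained_intron";'))
  gm <- read_gtf(write_tmp_gtf(lines))
  expect_equal(nrow(gm$transcripts), 2L)
  expect_setequal(gm$transcripts$biotype,
                  c("protein_coding", "retained_intron"))
})

test_that("read_gtf rejects malformed records with line numbers and counts bad coordinates", {
  lines <- c(toy_gtf_lines(), "chr1\ttoy\texon\tnot-all-fields")
  expect_error(read_gtf(write_tmp_gtf(lines)), "line 4")

  lines2 <- c(toy_gtf_lines()[1],
              "chr1\ttoy\texon\t90\t110\t.\t+\t.\tno_ids_here")
  expect_error(read_gtf(write_tmp_gtf(lines2)), "line 2")

  # start > end: rejected with a warning, not an error
  bad <- sub("\t201\t300", "\t300\t201", toy_gtf_lines())
  expect_warning(gm <- read_gtf(write_tmp_gtf(bad)), "rejected")
  expect_equal(gm$n_rejected, 1L)
  expect_equal(nrow(gm$exons), 2L)
})

test_that("GTF round-trip preserves models", {
  cfg <- sim_config(n_genes = 8, n_es = 2, n_ir = 2, n_ate = 1, seed = 4)
  gm <- simulate_annotation(cfg)$models
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, path)
  gm2 <- read_gtf(path)
  expect_equal(gm2$exons, gm$exons)
  expect_equal(dplyr::arrange(gm2$transcripts, transcript_id),
               dplyr::arrange(gm$transcripts, transcript_id))
  expect_equal(gm2$genes, gm$genes)
})

test_that("build_splice_index enumerates donors, acceptors and introns", {
  idx <- build_splice_index(toy_models())
  donors <- idx$sites$coord[idx$sites$role == "donor"]
  acceptors <- idx$sites$coord[idx$sites$role == "acceptor"]
  expect_setequal(donors, c(100L, 300L))
  expect_setequal(acceptors, c(201L, 401L))
  expect_equal(nrow(idx$introns), 2L)
  expect_setequal(paste(idx$introns$start, idx$introns$end),
                  c("101 200", "301 400"))

  # minus strand: donor/acceptor roles swap ends
  idx_m <- build_splice_index(toy_models(strand = "-"))
  expect_setequal(idx_m$sites$coord[idx_m$sites$role == "donor"],
                  c(201L, 401L))
  expect_setequal(idx_m$sites$coord[idx_m$sites$role == "acceptor"],
                  c(100L, 300L))
})

test_that("single-exon transcripts yield no sites or introns", {
  gm <- gene_models(data.frame(chrom = "chr1", start = 1L, end = 500L,
                               strand = "+", gene_id = "G1",
                               transcript_id = "G1.T1"))
  idx <- build_splice_index(gm)
  expect_equal(nrow(idx$sites), 0L)
  expect_equal(nrow(idx$introns), 0L)
})

test_that("every intron boundary appears as a site with the correct role", {
  cfg <- sim_config(n_genes = 10, n_es = 3, n_ir = 2, seed = 9)
  gm <- simulate_annotation(cfg)$models
  idx <- build_splice_index(gm)
  site_key <- paste(idx$sites$gene_id, idx$sites$coord, idx$sites$role)
  for (i in seq_len(nrow(idx$introns))) {
    intr <- idx$introns[i, ]
    left_role <- if (intr$strand == "+") "donor" else "acceptor"
    right_role <- if (intr$strand == "+") "acceptor" else "donor"
    expect_true(paste(intr$gene_id, intr$start - 1L, left_role) %in% site_key)
    expect_true(paste(intr$gene_id, intr$end + 1L, right_role) %in% site_key)
  }
})

test_that("find_in_between_exons returns exons strictly inside the intron", {
  idx <- build_splice_index(toy_models())
  hit <- find_in_between_exons(list(gene_id = "G1", start = 101L, end = 400L),
                               idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 201L)
  expect_equal(hit$end, 300L)

  # an annotated intron contains no exon
  expect_equal(nrow(find_in_between_exons(
    list(gene_id = "G1", start = 101L, end = 200L), idx)), 0L)
  # an interval inside an exon contains none either
  expect_equal(nrow(find_in_between_exons(
    list(gene_id = "G1", start = 50L, end = 95L), idx)), 0L)
  expect_error(find_in_between_exons(
    list(gene_id = "nope", start = 1L, end = 2L), idx), "not present")
})

test_that("annotated introns never contain an in-between exon of their own transcript", {
  cfg <- sim_config(n_genes = 12, n_es = 3, n_ir = 3, n_ate = 2, seed = 21)
  gm <- simulate_annotation(cfg)$models
  idx <- build_splice_index(gm)
  intr <- idx$introns
  for (i in seq_len(nrow(intr))) {
    ibe <- find_in_between_exons(intr[i, ], idx)
    if (nrow(ibe) > 0) {
      # contained exons must come from other transcripts (skip variants),
      # never from the intron's own transcript
      own <- gm$exons[gm$exons$transcript_id == intr$transcript_id[i], ]
      expect_false(any(own$start > intr$start[i] & own$end < intr$end[i]))
    }
  }
})

test_that("site_biotypes unions biotypes across owning transcripts", {
  idx <- build_splice_index(toy_models())
  expect_equal(site_biotypes("G1", 100L, idx), "protein_coding")
  expect_equal(site_biotypes("G1", 12345L, idx), character(0))

  # site shared by protein_coding and retained_intron transcripts
  ex <- rbind(toy_exons(),
              data.frame(chrom = "chr1", start = c(1L, 401L),
                         end = c(300L, 500L), strand = "+", gene_id = "G1",
                         transcript_id = "G1.T2"))
  gm <- gene_models(ex, data.frame(transcript_id = c("G1.T1", "G1.T2"),
                                   biotype = c("protein_coding",
                                               "retained_intron")))
  idx2 <- build_splice_index(gm)
  expect_setequal(site_biotypes("G1", 300L, idx2),
                  c("protein_coding", "retained_intron"))
})
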