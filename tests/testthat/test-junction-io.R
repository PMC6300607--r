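test_that("read_star_sj maps the STAR columns and strand codes", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t1000\t1200\t1\t1\t1\t50\t3\t38",
               "chr2\t500\t900\t2\t2\t0\t7\t0\t21",
               "chr3\t10\t90\t0\t0\t0\t1\t0\t12"), path)
  sj <- read_star_sj(path)
  expect_equal(sj$chrom, c("chr1", "chr2", "chr3"))
  expect_equal(sj$start, c(1000L, 500L, 10L))
  expect_equal(sj$strand, c("+", "-", "?"))
  expect_equal(sj$count, c(50L, 7L, 1L))
  expect_equal(sj$multi_count, c(3L, 0L, 0L))
})

test_that("read_star_sj handles empty files and rejects malformed records", {
  empty <- withr::local_tempfile(); writeLines(character(), empty)
  expect_equal(nrow(read_star_sj(empty)), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t1\t2\t1\t1\t1\t5\t0\t10", "chr1\t1\t2\t1"), bad)
  expect_error(read_star_sj(bad), "line 2")

  neg <- withr::local_tempfile()
  writeLines("chr1\t1\t2\t1\t1\t1\t-5\t0\t10", neg)
  expect_error(read_star_sj(neg), "negative")
})

test_that("STAR junction files round-trip", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t1000\t1200\t1\t1\t1\t50\t3\t38",
               "chr2\t500\t900\t0\t2\t0\t7\t0\t21"), path)
  sj <- read_star_sj(path)
  out <- withr::local_tempfile()
  write_star_sj(sj, out)
  expect_equal(read_star_sj(out), sj)
})

sj_tbl <- function(chrom, start, end, strand, count) {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 count = count)
}

test_that("assemble_matrix unions junctions with zero fill and keeps count mass", {
  s1 <- sj_tbl("chr1", c(100L, 300L), c(200L, 400L), "+", c(10L, 20L))
  s2 <- sj_tbl("chr2", c(50L, 70L), c(60L, 90L), "-", c(5L, 7L))
  sheet <- data.frame(sample_id = c("a", "b"),
                      condition = c("control", "treated"))
  m <- assemble_matrix(list(a = s1, b = s2), sheet)
  expect_equal(nrow(m$junctions), 4L)
  expect_equal(sum(m$counts), 42L)
  # blocks: sample a's junctions zero in b and vice versa
  expect_equal(unname(m$counts[m$junctions$chrom == "chr1", "b"]), c(0L, 0L))
  expect_equal(unname(m$counts[m$junctions$chrom == "chr2", "a"]), c(0L, 0L))
  # deterministic order
  expect_true(!is.unsorted(order(m$junctions$chrom, m$junctions$start)))
})

test_that("assemble_matrix duplicates a sample supplied under two ids", {
  s1 <- sj_tbl("chr1", c(100L, 300L), c(200L, 400L), "+", c(10L, 20L))
  sheet <- data.frame(sample_id = c("a", "b"),
                      condition = c("control", "treated"))
  m <- assemble_matrix(list(a = s1, b = s1), sheet)
  expect_equal(unname(m$counts[, "a"]), unname(m$counts[, "b"]))
})

test_that("assemble_matrix validates the design", {
  s1 <- sj_tbl("chr1", 100L, 200L, "+", 10L)
  expect_error(
    assemble_matrix(list(a = s1, b = s1),
                    data.frame(sample_id = c("a", "b"),
                               condition = c("A", "A"))),
    "two condition levels")
  expect_error(
    assemble_matrix(list(a = s1, b = s1),
                    data.frame(sample_id = "a", condition = "A")),
    "absent from the sample sheet")
})

test_that("filter_junctions applies the support rule and is idempotent", {
  j <- tibble::tibble(chrom = "chr1", start = c(1L, 10L), end = c(5L, 20L),
                      strand = "+", gene_id = NA_character_)
  m <- make_matrix(j, rbind(c(0L, 0L, 0L, 12L), c(12L, 12L, 12L, 12L)),
                   c("control", "control", "treated", "treated"))
  expect_equal(nrow(filter_junctions(m, min_count = 0L)$junctions), 2L)
  expect_equal(nrow(filter_junctions(m, 10L, 1L)$junctions), 2L)
  expect_equal(filter_junctions(m, 10L, 2L)$junctions$start, 10L)
  f1 <- filter_junctions(m, 10L, 2L)
  expect_equal(filter_junctions(f1, 10L, 2L)$junctions, f1$junctions)
  # all junctions failing still yields a valid, empty matrix
  none <- filter_junctions(m, 100L, 4L)
  expect_s3_class(none, "junction_matrix")
  expect_equal(nrow(none$junctions), 0L)
})

test_that("assign_junctions_to_genes is strand-aware with deterministic tie-breaks", {
  # G1: + strand 1-500 (toy); G2 nested same strand 1-1000 with no
  # matching site; junction (101,200,+) sits in both
  ex <- rbind(toy_exons(),
              data.frame(chrom = "chr1", start = c(1L, 901L),
                         end = c(50L, 1000L), strand = "+", gene_id = "G2",
                         transcript_id = "G2.T1"))
  gm <- gene_models(ex)
  idx <- build_splice_index(gm)
  j <- tibble::tibble(chrom = "chr1",
                      start = c(101L, 101L, 2000L),
                      end = c(200L, 200L, 2100L),
                      strand = c("+", "-", "+"),
                      gene_id = NA_character_)
  m <- make_matrix(j, matrix(1L, 3, 2), c("control", "treated"))
  m <- assign_junctions_to_genes(m, idx, gm)
  # splice-site match prefers G1 over the (larger) G2 span
  expect_equal(m$junctions$gene_id[1], "G1")
  # wrong strand inside a +-only locus: unassigned
  expect_true(is.na(m$junctions$gene_id[2]))
  # outside all genes: unassigned
  expect_true(is.na(m$junctions$gene_id[3]))

  # without a site match the smaller span wins
  j2 <- tibble::tibble(chrom = "chr1", start = 120L, end = 180L,
                       strand = "+", gene_id = NA_character_)
  m2 <- make_matrix(j2, matrix(1L, 1, 2), c("control", "treated"))
  m2 <- assign_junctions_to_genes(m2, idx, gm)
  expect_equal(m2$junctions$gene_id, "G1")
})
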