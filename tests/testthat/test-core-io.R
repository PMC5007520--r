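test_that("FASTA reading preserves order, uppercases, and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "acdef", "ghikl",
               ">g2", "MKV"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("g1", "g2"))
  expect_identical(unname(recs[1]), "ACDEFGHIKL")
  expect_identical(unname(recs[2]), "MKV")

  fd <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "AAA", ">g1", "CCC"), fd)
  expect_error(read_fasta(fd), "g1")

  fe <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fe)
  expect_warning(out <- read_fasta(fe), "no records")
  expect_length(out, 0)
})

test_that("FASTA write-then-read round-trips records exactly", {
  set.seed(1)
  seqs <- setNames(vapply(1:5, function(i) rand_prot(30 + i), ""),
                   paste0("p", 1:5))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 17)   # odd wrap on purpose
  expect_identical(read_fasta(f), seqs)
})

test_that("GFF3 parsing assembles exons and stitches strand-aware CDS", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t11\t70\t.\t+\t.\tID=gp",
    "chr1\tx\tmRNA\t11\t70\t.\t+\t.\tID=gp.t1;Parent=gp",
    "chr1\tx\texon\t41\t70\t.\t+\t.\tParent=gp.t1",
    "chr1\tx\texon\t11\t16\t.\t+\t.\tParent=gp.t1",
    "chr1\tx\texon\t21\t32\t.\t+\t.\tParent=gp.t1",
    "chr1\tx\tCDS\t11\t16\t.\t+\t0\tParent=gp.t1",
    "chr1\tx\tCDS\t21\t32\t.\t+\t0\tParent=gp.t1",
    "chr1\tx\tCDS\t41\t70\t.\t+\t0\tParent=gp.t1",
    "chr2\tx\tgene\t5\t7\t.\t-\t.\tID=gm",
    "chr2\tx\tmRNA\t5\t7\t.\t-\t.\tID=gm.t1;Parent=gm",
    "chr2\tx\texon\t5\t7\t.\t-\t.\tParent=gm.t1",
    "chr2\tx\tCDS\t5\t7\t.\t-\t0\tParent=gm.t1"), gff)
  # chr2 forward 5..7 = TTT so the minus-strand CDS must read AAA
  genome <- c(chr1 = paste(rep("ACGTGA", 20), collapse = ""),
              chr2 = "ACGATTTGC")
  gm <- read_gff3(gff, genome = genome)
  expect_length(gm, 2)
  expect_equal(nrow(gm$gp$exons), 3)
  expect_true(!is.unsorted(gm$gp$exons[, 1]))
  expect_equal(nchar(gm$gp$cds_sequence), 6 + 12 + 30)
  expect_identical(gm$gm$cds_sequence, "AAA")
})

test_that("GFF3 structural violations are rejected", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t50\t.\t+\t.\tID=g",
    "chr1\tx\tmRNA\t1\t50\t.\t+\t.\tID=g.t1;Parent=g",
    "chr1\tx\texon\t1\t20\t.\t+\t.\tParent=g.t1",
    "chr1\tx\texon\t15\t40\t.\t+\t.\tParent=g.t1"), bad)
  expect_error(read_gff3(bad), "overlapping")

  out <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t10\t20\t.\t+\t.\tID=g",
    "chr1\tx\tmRNA\t10\t20\t.\t+\t.\tID=g.t1;Parent=g",
    "chr1\tx\texon\t5\t20\t.\t+\t.\tParent=g.t1"), out)
  expect_error(read_gff3(out), "outside gene span")
})

test_that("gene models written as GFF3 read back identically", {
  set.seed(7)
  sg <- suppressMessages(generate_family_genome(
    n_chromosomes = 2, n_family_genes = 4, n_decoys = 4,
    tandem_spec = list(),
    collinear_spec = list(n_blocks = 1, anchors_each = 2, intervening = 1),
    seed = 21))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sg$genes, f)
  back <- read_gff3(f, genome = sg$genome)
  expect_setequal(names(back), names(sg$genes))
  for (id in names(sg$genes)) {
    expect_equal(back[[id]]$exons, sg$genes[[id]]$exons,
                 ignore_attr = TRUE)
    expect_identical(back[[id]]$cds_sequence,
                     sg$genes[[id]]$cds_sequence)
    expect_identical(back[[id]]$strand, sg$genes[[id]]$strand)
  }
})

test_that("expression tables parse with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(1.5, 0, 2, 3.25, 10, 0.1, 7, 8, 0, 1, 2, 3), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  write_expression_table(m, f)
  back <- read_expression_table(f)
  expect_equal(back, m)

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1", "g1\t-1.0"), neg)
  expect_error(read_expression_table(neg), "negative")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1", "g1\t1", "g1\t2"), dup)
  expect_error(read_expression_table(dup), "g1")

  nn <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1\tc2", "g1\t1\tfoo"), nn)
  expect_error(read_expression_table(nn), "c2")
})

test_that("count summaries round half-up to one decimal", {
  expect_equal(summarize_counts(50, 73), 68.5)
  expect_equal(summarize_counts(74, 82), 90.2)
  expect_equal(summarize_counts(0, 94), 0.0)
  expect_equal(summarize_counts(1, 400), 0.3)  # 0.25 rounds half-UP
  expect_error(summarize_counts(5, 0), "whole")
  expect_error(summarize_counts(8, 5))
})

test_that("part and complement percentages always sum to 100 +/- 0.1", {
  set.seed(2)
  for (k in 1:300) {
    whole <- sample.int(10000, 1)
    part <- sample.int(whole + 1, 1) - 1
    s <- summarize_counts(part, whole) +
      summarize_counts(whole - part, whole)
    expect_true(abs(s - 100) <= 0.1)
  }
})

test_that("BED output converts 1-based inclusive to 0-based half-open", {
  iv <- data.frame(chromosome = c("c1", "c2"), start = c(1, 101),
                   end = c(100, 250), name = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, f)
  lines <- readLines(f)
  expect_identical(lines[1], "c1\t0\t100\ta")   # length preserved: 100
  expect_identical(lines[2], "c2\t100\t250\tb")
  # interval length is invariant under the conversion
  parts <- strsplit(lines, "\t")
  expect_equal(vapply(parts, function(p)
    as.integer(p[3]) - as.integer(p[2]), 1L), iv$end - iv$start + 1L)
})

test_that("cluster and block interval tables span their member genes", {
  mk <- function(id, chrom, start)
    gene_model(id, chrom, start, start + 999, "+",
               cbind(start, start + 999))
  genes <- list(a = mk("a", "c1", 1000), b = mk("b", "c1", 50000),
                x = mk("x", "c2", 500), y = mk("y", "c2", 9000))
  cl <- suppressMessages(detect_tandem_clusters(genes[c("a", "b")]))
  iv <- tandem_intervals(cl, genes)
  expect_equal(iv$start, 1000); expect_equal(iv$end, 50999)
  blocks <- list(list(chromosomes = c("c1", "c2"),
                      anchors = data.frame(gene_a = c("a", "b"),
                                           gene_b = c("x", "y")),
                      orientation = "forward"))
  bi <- block_intervals(blocks, genes)
  expect_equal(nrow(bi), 2)
  expect_equal(bi$start, c(1000, 500))
  expect_equal(bi$end, c(50999, 9999))
})

test_that("trees written as Newick read back with identical topology", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("g", "c", 10, 5, "+", cbind(10, 5)), "end < start")
  expect_error(gene_model("g", "c", 1, 100, "?", cbind(1, 50)), "strand")
  expect_error(gene_model("g", "c", 1, 100, "+", cbind(c(1, 20), c(30, 60))),
               "overlap")
  expect_error(gene_model("g", "c", 1, 100, "+", cbind(1, 30), "ATGTAATTT"),
               "stop")
  expect_error(gene_model("g", "c", 1, 100, "+", cbind(1, 30), "ATGC"),
               "multiple of 3")
  gm <- gene_model("g", "c", 1, 100, "+", cbind(c(1, 40), c(30, 60)),
                   "ATGAAATTT")
  expect_s3_class(gm, "gene_model")
})
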