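small_genome <- function(seed) {
  suppressMessages(generate_family_genome(
    n_chromosomes = 3, n_family_genes = 10, n_decoys = 10,
    tandem_spec = list(list(size = 2, spacing = 150000)),
    collinear_spec = list(n_blocks = 1, anchors_each = 3, intervening = 1),
    seed = seed))
}

test_that("identical seeds give byte-identical synthetic genomes", {
  a <- small_genome(101); b <- small_genome(101); c <- small_genome(102)
  expect_identical(a, b)
  expect_false(identical(a$genome, c$genome))
})

test_that("planted layout realizes the declared truth", {
  sg <- small_genome(103)
  tr <- sg$truth
  # the planted tandem cluster is exactly what tandem detection finds
  expect_length(tr$tandem_clusters, 1)
  ids <- tr$tandem_clusters[[1]]$gene_ids
  starts <- vapply(ids, function(id) sg$genes[[id]]$start, 1)
  expect_lte(max(starts) - min(starts), 200000)
  # family and decoy sets partition the genes
  expect_length(intersect(tr$family_gene_ids, tr$decoy_gene_ids), 0)
  expect_setequal(c(tr$family_gene_ids, tr$decoy_gene_ids),
                  names(sg$genes))
  # every family protein carries the domain at the recorded interval
  cons <- sg$domain_consensus
  for (i in seq_len(nrow(tr$domain_intervals))) {
    row <- tr$domain_intervals[i, ]
    dom <- substr(sg$proteins[[row$gene_id]], row$start, row$end)
    ident <- mean(strsplit(dom, "")[[1]] == strsplit(cons, "")[[1]])
    expect_gt(ident, 0.5)
  }
  # CDS translates to protein for every gene
  for (id in names(sg$genes))
    expect_identical(genefam:::translate_cds(sg$cds[[id]]),
                     sg$proteins[[id]])
  # pair params positive
  expect_true(all(tr$pair_params$true_ks >= 0))
  expect_true(all(tr$pair_params$true_omega > 0))
})

test_that("a decoy-only genome is valid with empty truth sets", {
  sg <- suppressMessages(generate_family_genome(
    n_chromosomes = 2, n_family_genes = 0, n_decoys = 6,
    tandem_spec = list(),
    collinear_spec = list(n_blocks = 0, anchors_each = 0, intervening = 0),
    seed = 104))
  expect_length(sg$truth$family_gene_ids, 0)
  expect_length(sg$genes, 6)
})

test_that("infeasible layouts and bad cluster specs are rejected", {
  expect_error(suppressMessages(generate_family_genome(
    n_chromosomes = 2, n_family_genes = 2, n_decoys = 2,
    tandem_spec = list(list(size = 2, spacing = 250000)),
    collinear_spec = list(n_blocks = 0, anchors_each = 0, intervening = 0),
    seed = 1)), "below the tandem window")
  expect_error(suppressMessages(generate_family_genome(
    n_chromosomes = 3, n_family_genes = 2, n_decoys = 10,
    seed = 1)), "too small")
  expect_error(suppressMessages(generate_family_genome(
    n_chromosomes = 3, n_family_genes = 30, n_decoys = 30,
    max_chromosome_length = 500000, seed = 1)), "infeasible")
})

test_that("codon-pair evolution hits its targets in the limiting cases", {
  set.seed(111)
  anc <- genefam:::reverse_translate(rand_prot(100))
  same <- evolve_codon_pair(anc, 0, 1, seed = 5)
  expect_identical(same$descendant_a, anc)
  expect_identical(same$descendant_b, anc)

  syn_only <- evolve_codon_pair(anc, 0.5, 0, seed = 6)
  expect_identical(genefam:::translate_cds(syn_only$descendant_a),
                   genefam:::translate_cds(anc))
  expect_identical(genefam:::translate_cds(syn_only$descendant_b),
                   genefam:::translate_cds(anc))
  expect_equal(sum(syn_only$counts$nonsynonymous), 0)
  ng <- nei_gojobori(list(a = syn_only$descendant_a,
                          b = syn_only$descendant_b))
  expect_equal(ng$Ka, 0)

  expect_error(evolve_codon_pair("ATGTAA", 0.1, 1), "stop")
  expect_error(evolve_codon_pair("ATGA", 0.1, 1), "multiple of 3")
  expect_error(evolve_codon_pair(anc, -1, 1), "target_Ks")
})

test_that("neutral evolution gives Ka approximately equal to Ks", {
  set.seed(112)
  anc <- genefam:::reverse_translate(rand_prot(3000))
  ratios <- vapply(1:8, function(r) {
    ev <- evolve_codon_pair(anc, 0.4, 1, seed = 200 + r)
    nei_gojobori(list(a = ev$descendant_a, b = ev$descendant_b))$ratio
  }, 1)
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("planted expression classes are reproduced by the calling rules", {
  genes <- paste0("g", 1:40)
  gx <- generate_expression_matrix(genes, noise_sd = 0, seed = 113)
  m <- gx$matrix
  for (s in colnames(gx$truth$stress_class)) {
    calls <- call_differential(m[, paste0(s, "_treatment")],
                               m[, paste0(s, "_control")])
    expect_identical(unname(calls),
                     unname(gx$truth$stress_class[, s]))
  }
  # tissue pattern consistency: "on" tissues expressed, "off" not
  ex <- suppressMessages(call_expressed(m[, c("root", "stem", "leaf")]))
  for (g in genes) {
    on <- gx$truth$tissue_pattern[[g]]
    expect_setequal(colnames(ex$flags)[ex$flags[g, ]], on)
  }
  expect_error(generate_expression_matrix(genes, noise_sd = 0.5,
                                          margin = 1.2, seed = 1),
               "incompatible")
})

test_that("noisy expression matrices keep calls inside the margins", {
  genes <- paste0("g", 1:30)
  gx <- generate_expression_matrix(genes, noise_sd = 0.05, margin = 1.5,
                                   seed = 114)
  m <- gx$matrix
  mismatch <- 0
  for (s in colnames(gx$truth$stress_class)) {
    calls <- call_differential(m[, paste0(s, "_treatment")],
                               m[, paste0(s, "_control")])
    mismatch <- mismatch + sum(calls != gx$truth$stress_class[, s])
  }
  expect_lte(mismatch, 1)
})

test_that("two planted tissue patterns are recovered by clustering", {
  genes <- paste0("g", 1:20)
  patterns <- c(lapply(1:10, function(i) "root"),
                lapply(1:10, function(i) "leaf"))
  names(patterns) <- genes
  gx <- generate_expression_matrix(genes, tissues = c("root", "leaf"),
                                   tissue_pattern = patterns,
                                   noise_sd = 0.05, seed = 117)
  m <- gx$matrix[, c("root", "leaf")]
  cl <- suppressWarnings(cluster_expression_patterns(m, threshold = 0.5))
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(cl$clusters[genes], truth), 1)
})

test_that("Ct tables invert the 2^-ddCt computation", {
  folds <- matrix(c(4, 1, 0.25, 8), 2, 2,
                  dimnames = list(c("g1", "g2"), c("heat", "salt")))
  ct <- generate_ct_table(c("g1", "g2"), c("heat", "salt"), folds,
                          noise_sd = 0, seed = 115)
  for (g in rownames(folds)) for (trt in colnames(folds)) {
    res <- compute_relative_expression(ct, g, "REF", "control", trt)
    expect_equal(res$fold_change, folds[g, trt], tolerance = 1e-12)
  }
  # fold change 1 means ddCt 0 in the table itself
  res1 <- compute_relative_expression(ct, "g2", "REF", "control", "heat")
  expect_equal(res1$ddct, 0)
  expect_error(generate_ct_table("g", "t", -2), "fold changes")
})

test_that("noisy Ct tables recover folds within a tolerant band", {
  ok <- 0; runs <- 60
  for (r in seq_len(runs)) {
    ct <- generate_ct_table("g1", "heat",
                            matrix(4, 1, 1, dimnames = list("g1", "heat")),
                            n_replicates = 3, noise_sd = 0.1,
                            seed = 7000 + r)
    f <- compute_relative_expression(ct, "g1", "REF", "control",
                                     "heat")$fold_change
    ok <- ok + (abs(f - 4) / 4 <= 0.3)
  }
  expect_gte(ok / runs, 0.9)
})

test_that("written synthetic genomes are readable by the package readers", {
  sg <- small_genome(116)
  d <- withr::local_tempdir()
  write_synthetic_genome(sg, d)
  prot <- read_fasta(file.path(d, "proteins.fa"))
  expect_identical(prot[names(sg$proteins)], sg$proteins)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_setequal(unlist(truth$family_gene_ids), sg$truth$family_gene_ids)
  gm <- read_gff3(file.path(d, "genes.gff3"),
                  genome = read_fasta(file.path(d, "genome.fa")))
  expect_setequal(names(gm), names(sg$genes))
})
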