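blosum <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

test_that("pairwise global alignment is optimal and symmetric", {
  S <- blosum()
  id <- align_pair("ACD", "ACD")
  expect_equal(id$score, S["A", "A"] + S["C", "C"] + S["D", "D"])
  expect_identical(id$alignment, c("ACD", "ACD"))

  gap <- align_pair("ACD", "AD")
  expect_equal(gap$score, oracle_global_score("ACD", "AD"))

  set.seed(21)
  for (k in 1:20) {
    a <- rand_prot(sample(2:5, 1)); b <- rand_prot(sample(2:5, 1))
    al <- align_pair(a, b)
    expect_equal(al$score, oracle_global_score(a, b),
                 info = paste(a, b))
    expect_equal(al$score, align_pair(b, a)$score)
  }
})

test_that("progressive alignment handles identity and length bounds", {
  seqs <- c(a = "MKVLANNE", b = "MKVLANNE", c = "MKVLANNE",
            d = "MKVLANNE")
  m <- build_msa(seqs)
  expect_identical(unname(m$rows), unname(seqs))  # gap-free
  expect_equal(m$n_columns, 8)

  set.seed(22)
  seqs2 <- setNames(vapply(1:6, function(i)
    rand_prot(sample(20:40, 1)), ""), paste0("s", 1:6))
  m2 <- build_msa(seqs2)
  expect_gte(m2$n_columns, max(nchar(seqs2)))
  # ungapping every row reproduces its input exactly
  expect_identical(gsub("-", "", m2$rows), seqs2)
})

test_that("a planted shared domain ends up in shared columns", {
  cons <- default_domain_consensus()
  set.seed(23)
  n <- 8
  flank_n <- sample(5:20, n); flank_c <- sample(5:15, n)
  seqs <- setNames(vapply(1:n, function(i)
    paste0(rand_prot(flank_n[i]), diverge(cons, 0.08),
           rand_prot(flank_c[i])), ""), paste0("s", 1:n))
  m <- build_msa(seqs)
  mat <- do.call(rbind, strsplit(m$rows, ""))
  # map each row's domain residues to alignment columns
  col_of <- function(row, positions) {
    idx <- cumsum(mat[row, ] != "-")
    vapply(positions, function(p) which(idx == p & mat[row, ] != "-")[1],
           1L)
  }
  dom_cols <- lapply(1:n, function(i)
    col_of(i, (flank_n[i] + 1):(flank_n[i] + nchar(cons))))
  # fraction of domain positions placed in the majority column
  agree <- mean(vapply(seq_len(nchar(cons)), function(k) {
    cols <- vapply(dom_cols, `[`, 1L, k)
    max(table(cols)) / n
  }, 1))
  expect_gte(agree, 0.8)
})

test_that("Poisson distances follow the mismatch proportion", {
  msa <- list(ids = c("x", "y"),
              rows = c(x = strrep("A", 100),
                       y = paste0(strrep("C", 10), strrep("A", 90))))
  D <- protein_distance(msa)
  expect_equal(D["x", "y"], -log(0.9), tolerance = 1e-9)
  expect_equal(D["x", "x"], 0)
  expect_equal(D, t(D))

  # gapped columns are excluded pairwise
  msa2 <- list(ids = c("x", "y"),
               rows = c(x = "AC-DE", y = "ACQD-"))
  expect_equal(protein_distance(msa2)["x", "y"], 0)

  # saturation capped with a warning
  msa3 <- list(ids = c("x", "y"),
               rows = c(x = strrep("A", 50), y = strrep("C", 50)))
  expect_warning(D3 <- protein_distance(msa3), "capped")
  expect_equal(D3["x", "y"], 3.0)

  msa4 <- list(ids = c("x", "y"), rows = c(x = "A-", y = "-A"))
  expect_error(protein_distance(msa4), "no comparable sites")
})

test_that("neighbor joining reconstructs additive distances exactly", {
  # classic 4-taxon additive matrix with known branch lengths
  D <- matrix(c(0, 5, 9, 10,
                5, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-12)

  # property: random additive trees up to 12 leaves are recovered with
  # exact topology and path lengths
  set.seed(24)
  for (k in 1:40) {
    n <- sample(4:12, 1)
    true_tree <- ape::rtree(n, rooted = FALSE,
                            br = function(x) runif(x, 0.05, 1))
    Dk <- ape::cophenetic.phylo(true_tree)
    rec <- nj_tree(Dk)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), rec), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(Dk), colnames(Dk)]
                      - Dk)), 1e-9)
  }
})

test_that("our NJ agrees with the reference implementation in ape", {
  set.seed(25)
  for (k in 1:10) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n, 0.1, 2), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(ape::dist.topo(nj_tree(D), ape::nj(as.dist(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equidistant taxa give a tree reproducing the flat metric", {
  D <- matrix(2, 5, 5); diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:5), paste0("t", 1:5))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), paste0("t", 1:5))
  C <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(C, D, tolerance = 1e-9)
  expect_true(all(tr$edge.length >= 0))
})

test_that("two well-separated clades get full bootstrap support", {
  # two clades with many diagnostic columns and none conflicting
  blockA <- strrep("A", 30); blockC <- strrep("C", 30)
  set.seed(26)
  shared <- rand_prot(30)
  mk <- function(block) paste0(block, diverge(shared, 0.05))
  seqs <- c(a1 = mk(blockA), a2 = mk(blockA), a3 = mk(blockA),
            b1 = mk(blockC), b2 = mk(blockC), b3 = mk(blockC))
  msa <- build_msa(seqs)
  tr <- bootstrap_support(msa, replicates = 100, seed = 5)
  sup <- attr(tr, "support")
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))  # the clade split itself
  # determinism
  tr2 <- bootstrap_support(msa, replicates = 100, seed = 5)
  expect_identical(attr(tr2, "support"), attr(tr, "support"))
})

test_that("the collapse rule removes support 49 but keeps 50", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "CCCCCCCCCA",
            d = "CCCCCCCCCC", e = "ACACACACAC")
  msa <- build_msa(seqs)
  tr <- bootstrap_support(msa, replicates = 50, seed = 1, collapse = NULL)
  n <- length(tr$tip.label)
  sup <- attr(tr, "support")
  # plant the boundary supports directly and collapse
  sup_test <- sup
  sup_test[!is.na(sup_test)] <- c(49, 50)[
    seq_along(sup_test[!is.na(sup_test)]) %% 2 + 1]
  attr(tr, "support") <- sup_test
  before_internal <- sum(tr$edge[, 2] > n)
  n49 <- sum(sup_test == 49, na.rm = TRUE)
  collapsed <- collapse_low_support(tr, 50)
  after_internal <- sum(collapsed$edge[, 2] > n)
  expect_equal(after_internal, before_internal - n49)
  expect_true(all(attr(collapsed, "support") >= 50, na.rm = TRUE))
})

test_that("subfamily labels come from the smallest supported clade", {
  tr <- ape::read.tree(text = paste0(
    "((q1:0.1,(r1:0.1,r2:0.1)90:0.1)95:0.2,",
    "((r3:0.1,r4:0.1)99:0.1,q2:0.6)80:0.2,q3:2.0);"))
  tr$node.label[tr$node.label == ""] <- NA
  attr(tr, "support") <- suppressWarnings(as.numeric(tr$node.label))
  refs <- c(r1 = "CI", r2 = "CI", r3 = "CII", r4 = "CII")
  asg <- assign_subfamilies(tr, refs)
  expect_identical(asg[["q1"]], "CI")
  expect_identical(asg[["q2"]], "CII")

  # a query on a long isolated branch hanging off a collapsed
  # multifurcation between three labeled subfamilies is an orphan: every
  # clade containing it mixes labels
  tr2 <- ape::read.tree(text = paste0(
    "((r1:0.1,r2:0.1)99:0.1,(r3:0.1,r4:0.1)99:0.1,",
    "(r5:0.1,r6:0.1)99:0.1,q:3.0);"))
  attr(tr2, "support") <- suppressWarnings(as.numeric(tr2$node.label))
  refs2 <- c(r1 = "CI", r2 = "CI", r3 = "MII", r4 = "MII",
             r5 = "ER", r6 = "ER")
  expect_identical(unname(assign_subfamilies(tr2, refs2)["q"]), "orphan")

  expect_error(assign_subfamilies(tr2, c(zz = "CI")), "no reference")
})

test_that("subfamily assignment recovers generator truth and ignores leaf order", {
  sg <- suppressMessages(generate_family_genome(
    n_chromosomes = 2, n_family_genes = 16, n_decoys = 4,
    n_subfamilies = 4, tandem_spec = list(),
    collinear_spec = list(n_blocks = 1, anchors_each = 2, intervening = 1),
    seed = 31))
  fam <- sg$truth$family_gene_ids
  sf <- sg$truth$subfamily
  msa <- build_msa(sg$proteins[fam])
  tr <- bootstrap_support(msa, replicates = 100, seed = 7)
  refs_idx <- unlist(lapply(split(names(sf), sf), head, 2))
  refs <- setNames(paste0("C", sf[refs_idx]), refs_idx)
  asg <- assign_subfamilies(tr, refs)
  expect_identical(unname(asg), unname(paste0("C", sf[names(asg)])))

  # invariance to input order of the leaves
  msa_r <- build_msa(sg$proteins[rev(fam)])
  tr_r <- bootstrap_support(msa_r, replicates = 100, seed = 7)
  asg_r <- assign_subfamilies(tr_r, refs)
  expect_identical(asg_r[names(asg)], asg)
})

test_that("logo data sums residue heights to the column information", {
  msa <- list(ids = c("x", "y"), rows = c(x = "AAC", y = "ACC"))
  ld <- logo_data(msa)
  h1 <- sum(ld$height[ld$position == 1])
  expect_equal(h1, log2(20))                    # conserved column
  h2 <- sum(ld$height[ld$position == 2])
  expect_equal(h2, log2(20) - 1)                # 50/50 column
  expect_true(all(ld$height >= 0))
})

test_that("column information content spans [0, log2 20]", {
  expect_equal(column_information(rep("W", 12)), log2(20))
  expect_equal(column_information(AA20), 0)
  expect_equal(column_information(c(rep("A", 5), rep("C", 5))),
               log2(20) - 1)
  expect_warning(ic <- column_information(c("-", "-")), "all-gap")
  expect_true(is.na(ic))
  set.seed(27)
  for (k in 1:50) {
    col <- sample(c(AA20, "-"), 30, replace = TRUE)
    if (all(col == "-")) next
    ic <- column_information(col)
    expect_true(ic >= 0 && ic <= log2(20) + 1e-12)
  }
})
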