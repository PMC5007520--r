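# Fixed 103-residue domain consensus used by the synthetic genomes; an
# alpha-crystallin-like compact domain stand-in (invented sequence, not a
# database entry).
DOMAIN_CONSENSUS <- paste0(
  "SLFDPFSLDLWDPFEGFPFSSSLANVPSSARETAAFANARIDWKETPEAHVFKADLPGLK",
  "KEEVKVEVEDDRVLQISGERSVEKEDKNDKWHRVERSSGKFMR")

#' The built-in domain consensus sequence
#'
#' @return A 103-residue amino-acid string (synthetic consensus).
#' @export
default_domain_consensus <- function() DOMAIN_CONSENSUS

#' Randomly substitute residues of a protein sequence
#'
#' Each residue is independently replaced (never by itself) with
#' probability `p`; no indels.  Used to derive diverged domain copies and
#' seed alignments for profile building.
#'
#' @param seq amino-acid string over the 20-letter alphabet.
#' @param p per-site substitution probability.
#' @return The mutated sequence.
#' @export
mutate_protein <- function(seq, p) {
  res <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(res)) < p)
  if (length(hit)) {
    cur <- match(res[hit], AA_ALPHABET)
    r <- sample.int(19L, length(hit), replace = TRUE)
    res[hit] <- AA_ALPHABET[r + (r >= cur)]   # any residue but the current
  }
  paste(res, collapse = "")
}

random_protein <- function(length, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = freqs),
        collapse = "")
}

# reverse-translate a protein with uniformly random synonymous codons
reverse_translate <- function(protein) {
  if (is.null(.genefam_env$by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .genefam_env$by_aa <- split(names(gc), unname(gc))
  }
  by_aa <- .genefam_env$by_aa
  choices <- by_aa[strsplit(protein, "")[[1]]]
  lens <- lengths(choices)
  pick <- ceiling(runif(length(choices)) * lens)
  flat <- unlist(choices, use.names = FALSE)
  off <- cumsum(lens) - lens
  paste(flat[off + pick], collapse = "")
}

#' Evolve a codon pair to a target synonymous divergence
#'
#' Two descendants are evolved independently from the ancestor by a
#' continuous-time codon substitution process with equal codon
#' frequencies and no transition/transversion bias: each synonymous
#' single-nucleotide change occurs at rate 1/3 and each nonsynonymous
#' change at `omega/3`; changes creating stop codons are forbidden.
#' Each branch runs for time `target_Ks / 2`, so the expected synonymous
#' divergence between the descendants is `target_Ks` (the same
#' simplified rate structure the Nei-Gojobori estimator assumes).
#'
#' @param ancestor_cds in-frame coding sequence, no stop codons.
#' @param target_Ks target synonymous substitutions per synonymous site
#'   between the two descendants (>= 0).
#' @param omega dN/dS ratio (> 0).
#' @param seed RNG seed.
#' @return List with `descendant_a`, `descendant_b`, and `counts`
#'   (realized synonymous / nonsynonymous substitution events per
#'   branch).
#' @export
evolve_codon_pair <- function(ancestor_cds, target_Ks, omega, seed = 1L) {
  ancestor_cds <- toupper(ancestor_cds)
  if (nchar(ancestor_cds) %% 3L != 0L)
    stop("ancestor length must be a multiple of 3")
  if (target_Ks < 0) stop("target_Ks must be >= 0")
  if (omega < 0) stop("omega must be >= 0")   # 0 = synonymous-only
  tabs <- codon_tables()
  cod <- split_codons(ancestor_cds)
  idx <- tabs$cidx[cod]
  if (any(is.na(idx))) stop("ancestor contains invalid codons")
  if (any(tabs$is_stop[idx])) stop("ancestor contains stop codon(s)")
  set.seed(seed)
  # per-codon neighbor partitions (precomputed once per call)
  syn_nb <- lapply(seq_along(tabs$codons), function(i) {
    nb <- tabs$neighbors[[i]]
    if (is.null(nb)) return(character(0))
    nb[tabs$aa[tabs$cidx[nb]] == tabs$aa[i]]
  })
  non_nb <- lapply(seq_along(tabs$codons), function(i) {
    nb <- tabs$neighbors[[i]]
    if (is.null(nb)) return(character(0))
    nb[tabs$aa[tabs$cidx[nb]] != tabs$aa[i]]
  })
  # per-codon fluxes matched to the estimator's site definitions: the
  # synonymous substitution rate of codon c equals its synonymous site
  # count S_c (so one time unit = one expected synonymous substitution
  # per synonymous site), and the nonsynonymous rate is omega * (3 - S_c)
  syn_rate <- tabs$syn_sites
  non_rate <- omega * (3 - tabs$syn_sites)
  syn_rate[lengths(syn_nb) == 0L] <- 0
  non_rate[lengths(non_nb) == 0L] <- 0
  t_branch <- target_Ks / 2
  evolve_branch <- function(idx0) {
    cur <- idx0
    nsyn <- 0L; nnon <- 0L
    if (t_branch == 0) return(list(idx = cur, syn = 0L, non = 0L))
    rem <- rep(t_branch, length(cur))
    act <- seq_along(cur)
    while (length(act)) {
      rate <- syn_rate[cur[act]] + non_rate[cur[act]]
      dt <- ifelse(rate > 0, rexp(length(act), pmax(rate, 1e-12)), Inf)
      rem[act] <- rem[act] - dt
      jump <- act[rem[act] > 0]
      for (i in jump) {
        c0 <- cur[i]
        p_syn <- syn_rate[c0] / (syn_rate[c0] + non_rate[c0])
        if (runif(1) < p_syn) {
          sn <- syn_nb[[c0]]
          pick <- sn[sample.int(length(sn), 1L)]
          nsyn <- nsyn + 1L
        } else {
          nn <- non_nb[[c0]]
          pick <- nn[sample.int(length(nn), 1L)]
          nnon <- nnon + 1L
        }
        cur[i] <- tabs$cidx[[pick]]
      }
      act <- jump
    }
    list(idx = cur, syn = nsyn, non = nnon)
  }
  a <- evolve_branch(idx)
  b <- evolve_branch(idx)
  list(descendant_a = paste(tabs$codons[a$idx], collapse = ""),
       descendant_b = paste(tabs$codons[b$idx], collapse = ""),
       counts = data.frame(branch = c("a", "b"),
                           synonymous = c(a$syn, b$syn),
                           nonsynonymous = c(a$non, b$non)))
}

#' Generate a synthetic multi-chromosome genome with a planted family
#'
#' Builds a genome carrying a multigene family defined by a diverged copy
#' of a domain consensus, organized into subfamilies, with planted tandem
#' clusters and collinear (segmental) duplicated blocks whose anchor
#' pairs are evolved at known Ks and omega, plus decoy genes free of the
#' domain (verified by rejection against the consensus profile).
#' Intergenic and intronic sequence is uninformative filler (synthetic
#' genomes here test positional logic, not sequence composition).
#'
#' @param n_chromosomes number of chromosomes (default 5).
#' @param n_family_genes total family genes (default 24; must cover the
#'   planted tandem and collinear members).
#' @param n_decoys domain-free background genes (default 60).
#' @param domain_consensus consensus amino-acid string.
#' @param substitution_prob per-site substitution probability applied to
#'   the domain (and subfamily backbones); default 0.1.
#' @param n_subfamilies subfamily count (default 4).
#' @param tandem_spec list of planted clusters, each
#'   `list(size =, spacing =)` with spacing < `tandem_window`.
#' @param collinear_spec `list(n_blocks =, anchors_each =, intervening =)`
#'   (intervening decoys between consecutive anchors, <= the gap rule).
#' @param anchor_ks_range,anchor_omega_range ranges from which each
#'   anchor pair's true Ks and omega are drawn.
#' @param tandem_window the positional rule the layout must respect
#'   (default 200000).
#' @param max_chromosome_length feasibility bound in bp (default 2e7).
#' @param seed RNG seed; identical seed and parameters give
#'   byte-identical output.
#' @return List of class `"synthetic_genome"`: `genome` (named character
#'   vector), `genes` (named list of [gene_model()]), `proteins`, `cds`
#'   (named character vectors), and `truth` (planted ground truth: family
#'   and decoy ids, domain intervals, subfamily labels, tandem clusters,
#'   collinear blocks, per-pair Ks/omega).
#' @export
generate_family_genome <- function(
    n_chromosomes = 5L, n_family_genes = 24L, n_decoys = 60L,
    domain_consensus = default_domain_consensus(),
    substitution_prob = 0.1, n_subfamilies = 4L,
    tandem_spec = list(list(size = 2L, spacing = 120000),
                       list(size = 3L, spacing = 90000)),
    collinear_spec = list(n_blocks = 2L, anchors_each = 4L,
                          intervening = 2L),
    anchor_ks_range = c(0.1, 0.6), anchor_omega_range = c(0.15, 0.5),
    tandem_window = 200000, max_chromosome_length = 2e7, seed = 1L) {

  for (ts in tandem_spec)
    if (ts$spacing >= tandem_window)
      stop("tandem cluster spacing must be below the tandem window")
  n_tandem <- sum(vapply(tandem_spec, function(ts) as.numeric(ts$size),
                         0))
  n_anchor <- 2L * collinear_spec$n_blocks * collinear_spec$anchors_each
  if (n_family_genes < n_tandem + n_anchor)
    stop("n_family_genes too small for the planted clusters and blocks")
  n_block_decoys <- 2L * collinear_spec$n_blocks *
    (collinear_spec$anchors_each - 1L) * collinear_spec$intervening
  if (n_decoys < n_block_decoys)
    stop("n_decoys too small for the planted block gaps")
  if (collinear_spec$n_blocks > 0 && n_chromosomes < 2L)
    stop("collinear blocks need >= 2 chromosomes")

  set.seed(seed)
  W <- nchar(domain_consensus)

  # subfamily backbones: fixed flank lengths per subfamily, diverged
  # domain copy; members are light mutations of the backbone
  sub_backbone <- vector("list", max(n_subfamilies, 1L))
  for (s in seq_len(max(n_subfamilies, 1L))) {
    nlen <- sample(45:70, 1L); clen <- sample(30:50, 1L)
    sub_backbone[[s]] <- list(
      nterm = random_protein(nlen),
      domain = mutate_protein(domain_consensus, substitution_prob),
      cterm = random_protein(clen),
      domain_start = nlen + 1L)
  }
  make_member <- function(s) {
    bb <- sub_backbone[[s]]
    prot <- paste0(mutate_protein(bb$nterm, 0.05),
                   mutate_protein(bb$domain, 0.05),
                   mutate_protein(bb$cterm, 0.05))
    list(protein = prot, cds = reverse_translate(prot),
         domain_start = bb$domain_start,
         domain_end = bb$domain_start + W - 1L, subfamily = s)
  }

  fam <- list()       # per family gene: protein, cds, domain interval
  fam_sub <- integer(0)
  new_fam_id <- function() sprintf("FAM%03d", length(fam) + 1L)

  add_family_gene <- function(member) {
    id <- new_fam_id()
    fam[[id]] <<- member
    fam_sub[id] <<- member$subfamily
    id
  }

  # --- tandem clusters: members of one subfamily each
  tandem_truth <- list()
  tandem_units <- list()
  for (tc in tandem_spec) {
    s <- sample.int(n_subfamilies, 1L)
    ids <- vapply(seq_len(tc$size), function(i)
      add_family_gene(make_member(s)), "")
    tandem_units[[length(tandem_units) + 1L]] <-
      list(type = "tandem", ids = ids, spacing = tc$spacing)
    tandem_truth[[length(tandem_truth) + 1L]] <- list(gene_ids = ids)
  }

  # --- collinear blocks: anchor pairs evolved at known Ks / omega
  pair_params <- NULL
  block_truth <- list()
  seg_units <- list()
  decoy_counter <- 0L
  new_decoy_id <- function() {
    decoy_counter <<- decoy_counter + 1L
    sprintf("BGD%03d", decoy_counter)
  }
  decoys <- list()
  fam_comp <- NULL    # family residue composition, filled later

  block_gene_spacing <- max(60000,
    ceiling((tandem_window + 20000) / (collinear_spec$intervening + 1L)))

  for (b in seq_len(collinear_spec$n_blocks)) {
    idsA <- character(0); idsB <- character(0)
    for (a in seq_len(collinear_spec$anchors_each)) {
      s <- sample.int(n_subfamilies, 1L)
      anc <- make_member(s)
      ks <- runif(1, anchor_ks_range[1], anchor_ks_range[2])
      om <- runif(1, anchor_omega_range[1], anchor_omega_range[2])
      ev <- evolve_codon_pair(anc$cds, ks, om,
                              seed = sample.int(1e6, 1L))
      memA <- list(protein = translate_cds(ev$descendant_a),
                   cds = ev$descendant_a,
                   domain_start = anc$domain_start,
                   domain_end = anc$domain_end, subfamily = s)
      memB <- list(protein = translate_cds(ev$descendant_b),
                   cds = ev$descendant_b,
                   domain_start = anc$domain_start,
                   domain_end = anc$domain_end, subfamily = s)
      ia <- add_family_gene(memA); ib <- add_family_gene(memB)
      idsA <- c(idsA, ia); idsB <- c(idsB, ib)
      pair_params <- rbind(pair_params, data.frame(
        gene_a = ia, gene_b = ib, true_ks = ks, true_omega = om))
    }
    block_truth[[length(block_truth) + 1L]] <-
      list(anchors_a = idsA, anchors_b = idsB)
    seg_units[[length(seg_units) + 1L]] <- list(
      type = "block_segment", block = b, side = "A", ids = idsA,
      spacing = block_gene_spacing,
      intervening = collinear_spec$intervening)
    seg_units[[length(seg_units) + 1L]] <- list(
      type = "block_segment", block = b, side = "B", ids = idsB,
      spacing = block_gene_spacing,
      intervening = collinear_spec$intervening)
  }

  # --- remaining family genes, scattered singly
  single_units <- list()
  while (length(fam) < n_family_genes) {
    s <- sample.int(n_subfamilies, 1L)
    id <- add_family_gene(make_member(s))
    single_units[[length(single_units) + 1L]] <-
      list(type = "single", ids = id)
  }

  # --- decoys from family residue composition, profile-rejected
  if (length(fam)) {
    fam_res <- unlist(strsplit(vapply(fam, `[[`, "", "protein"), ""))
    fam_comp <- tabulate(match(fam_res, AA_ALPHABET), 20)
    fam_comp <- fam_comp / sum(fam_comp)
  } else {
    fam_comp <- rep(1 / 20, 20)
  }
  cons_profile <- build_profile(
    rep(c(domain_consensus), 3L))        # consensus-only log-odds
  self_score <- sum(apply(cons_profile$log_odds, 1L, max))
  make_decoy <- function() {
    repeat {
      p <- random_protein(sample(150:250, 1L), fam_comp)
      sc <- score_windows(cons_profile, p)
      if (max(sc) < 0.5 * self_score) return(p)
    }
  }
  for (k in seq_len(n_decoys)) {
    id <- new_decoy_id()
    p <- make_decoy()
    decoys[[id]] <- list(protein = p, cds = reverse_translate(p))
  }
  decoy_ids <- names(decoys)
  block_decoy_pool <- decoy_ids[seq_len(n_block_decoys)]
  single_decoy_ids <- setdiff(decoy_ids, block_decoy_pool)
  for (id in single_decoy_ids)
    single_units[[length(single_units) + 1L]] <-
      list(type = "single", ids = id)

  # expand block segments with intervening decoys
  pool_i <- 0L
  take_decoy <- function() {
    pool_i <<- pool_i + 1L
    block_decoy_pool[pool_i]
  }
  for (u in seq_along(seg_units)) {
    ids <- seg_units[[u]]$ids
    layout <- ids[1L]
    if (length(ids) > 1L) for (a in 2L:length(ids)) {
      if (seg_units[[u]]$intervening > 0L)
        layout <- c(layout, vapply(seq_len(seg_units[[u]]$intervening),
                                   function(i) take_decoy(), ""))
      layout <- c(layout, ids[a])
    }
    seg_units[[u]]$layout <- layout
  }
  for (u in seq_along(tandem_units)) tandem_units[[u]]$layout <-
    tandem_units[[u]]$ids
  for (u in seq_along(single_units)) single_units[[u]]$layout <-
    single_units[[u]]$ids

  # --- distribute units over chromosomes (block sides kept apart)
  units <- c(seg_units, tandem_units, single_units)
  chrom_of_unit <- integer(length(units))
  nextc <- 0L
  for (u in seq_along(units)) {
    if (identical(units[[u]]$type, "block_segment")) {
      off <- if (units[[u]]$side == "A") 0L else 1L
      chrom_of_unit[u] <- ((units[[u]]$block - 1L + off) %% n_chromosomes) + 1L
    } else {
      chrom_of_unit[u] <- (nextc %% n_chromosomes) + 1L
      nextc <- nextc + 1L
    }
  }

  # --- place genes, build gene models and chromosome sequences
  all_seq <- c(lapply(fam, `[[`, "cds"), lapply(decoys, `[[`, "cds"))
  all_prot <- c(lapply(fam, `[[`, "protein"),
                lapply(decoys, `[[`, "protein"))
  genes <- list()
  gene_order <- list()
  chrom_parts <- vector("list", n_chromosomes)
  chrom_pos <- rep(1L, n_chromosomes)   # next free bp
  inter_unit_gap <- 400000
  chrom_names <- sprintf("chr%02d", seq_len(n_chromosomes))

  place_gene <- function(id, ch, at) {
    cds <- all_seq[[id]]
    n_int <- sample(0:2, 1L, prob = c(0.5, 0.4, 0.1))
    L <- nchar(cds)
    if (n_int > 0L && L >= 3L * (n_int + 1L)) {
      sites <- seq(3L, L - 3L, by = 3L)
      cuts <- sort(sites[sample.int(length(sites), n_int)])
    } else { n_int <- 0L; cuts <- integer(0) }
    bounds <- c(0L, cuts, L)
    chunks <- substring(cds, bounds[-length(bounds)] + 1L,
                        bounds[-1L])
    intron_len <- if (n_int > 0L) sample(200:800, n_int,
                                         replace = TRUE) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      genomic_chunks <- rev(vapply(chunks, revcomp, ""))
      intron_len <- rev(intron_len)
    } else genomic_chunks <- chunks
    exon_start <- integer(length(chunks)); exon_end <- integer(length(chunks))
    pos <- at
    pieces <- character(0)
    for (e in seq_along(genomic_chunks)) {
      exon_start[e] <- pos
      exon_end[e] <- pos + nchar(genomic_chunks[e]) - 1L
      pieces <- c(pieces, genomic_chunks[e])
      pos <- exon_end[e] + 1L
      if (e < length(genomic_chunks)) {
        pieces <- c(pieces, strrep("T", intron_len[e]))
        pos <- pos + intron_len[e]
      }
    }
    gm <- gene_model(id, chrom_names[ch], at, pos - 1L, strand,
                     cbind(exon_start, exon_end), cds)
    list(gm = gm, seq = paste(pieces, collapse = ""), end = pos - 1L)
  }

  for (u in order(chrom_of_unit)) {
    ch <- chrom_of_unit[u]
    layout <- units[[u]]$layout
    spacing <- if (!is.null(units[[u]]$spacing)) units[[u]]$spacing else 0
    at <- chrom_pos[ch] + if (chrom_pos[ch] == 1L) 100000 else inter_unit_gap
    for (g in seq_along(layout)) {
      id <- layout[g]
      if (g > 1L) at <- at + spacing
      placed <- place_gene(id, ch, at)
      # filler up to gene start, then the gene body
      gap <- at - chrom_pos[ch]
      chrom_parts[[ch]] <- c(chrom_parts[[ch]],
                             strrep("A", gap), placed$seq)
      genes[[id]] <- placed$gm
      gene_order[[chrom_names[ch]]] <-
        c(gene_order[[chrom_names[ch]]], id)
      chrom_pos[ch] <- placed$end + 1L
      at <- placed$gm$start
    }
    if (chrom_pos[ch] > max_chromosome_length)
      stop("infeasible layout: chromosome ", chrom_names[ch],
           " exceeds max_chromosome_length")
  }
  genome <- vapply(seq_len(n_chromosomes), function(ch) {
    paste(c(chrom_parts[[ch]], strrep("A", 1000L)), collapse = "")
  }, "")
  names(genome) <- chrom_names

  truth <- list(
    family_gene_ids = names(fam),
    decoy_gene_ids = decoy_ids,
    domain_intervals = do.call(rbind, lapply(names(fam), function(id)
      data.frame(gene_id = id, start = fam[[id]]$domain_start,
                 end = fam[[id]]$domain_end))),
    subfamily = setNames(fam_sub, names(fam)),
    tandem_clusters = lapply(tandem_truth, function(tc)
      list(gene_ids = tc$gene_ids,
           chromosome = genes[[tc$gene_ids[1]]]$chromosome)),
    collinear_blocks = block_truth,
    pair_params = pair_params)

  structure(list(
    genome = genome,
    genes = genes,
    gene_order = gene_order,
    proteins = setNames(unlist(all_prot), names(all_prot)),
    cds = setNames(unlist(all_seq), names(all_seq)),
    truth = truth,
    domain_consensus = domain_consensus,
    seed = seed), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d chromosome(s), %d family + %d decoy genes\n",
    length(x$genome), length(x$truth$family_gene_ids),
    length(x$truth$decoy_gene_ids)))
  cat(sprintf("  planted: %d tandem cluster(s), %d collinear block(s)\n",
              length(x$truth$tandem_clusters),
              length(x$truth$collinear_blocks)))
  invisible(x)
}

#' Write a synthetic genome to disk
#'
#' Emits the genome, protein and CDS FASTA files, the GFF3 gene models,
#' and the planted truth as JSON.
#'
#' @param sg a [generate_family_genome()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(sg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sg$genome, file.path(dir, "genome.fa"))
  write_fasta(sg$proteins, file.path(dir, "proteins.fa"))
  write_fasta(sg$cds, file.path(dir, "cds.fa"))
  write_gff3(sg$genes, file.path(dir, "genes.gff3"))
  truth <- sg$truth
  truth$subfamily <- as.list(truth$subfamily)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate an FPKM matrix with planted expression classes
#'
#' Columns are tissues plus a control/treatment pair per stress.  Tissue
#' patterns set which tissues a gene is "on" in (high FPKM) versus off
#' (below the expressed threshold).  Stress classes draw
#' treatment/control ratios outside a safety margin of the twofold /
#' one-half calling rules, so calls are unambiguous at the stated noise;
#' incompatible margin and noise raise an error.
#'
#' @param gene_ids character vector of gene ids.
#' @param tissues tissue condition names.
#' @param tissue_pattern named list: gene -> character vector of "on"
#'   tissues (possibly empty).
#' @param stresses stress names; each yields `<stress>_control` and
#'   `<stress>_treatment` columns.
#' @param stress_class gene x stress character matrix (or data.frame) of
#'   `"up"`, `"down"`, `"unchanged"`.
#' @param noise_sd log-normal noise (sdlog) applied multiplicatively;
#'   default 0.
#' @param margin safety factor between the planted ratios and the calling
#'   bounds (default 1.5).
#' @param seed RNG seed.
#' @return List with `matrix` (gene x condition FPKM) and `truth`
#'   (`tissue_pattern`, `stress_class`).
#' @export
generate_expression_matrix <- function(gene_ids,
                                       tissues = c("root", "stem", "leaf"),
                                       tissue_pattern = NULL,
                                       stresses = c("heat", "salt"),
                                       stress_class = NULL,
                                       noise_sd = 0, margin = 1.5,
                                       seed = 1L) {
  n <- length(gene_ids)
  set.seed(seed)
  if (margin <= 1) stop("margin must be > 1")
  # ratio noise is log-normal with sdlog noise_sd * sqrt(2); require the
  # 99.9% band inside the margin
  if (noise_sd > 0 && exp(qnorm(0.999) * noise_sd * sqrt(2)) >= margin)
    stop("margin incompatible with noise level")
  if (is.null(tissue_pattern)) {
    tissue_pattern <- lapply(seq_len(n), function(i)
      tissues[seq_len(1 + (i %% length(tissues)))])
    names(tissue_pattern) <- gene_ids
  }
  if (is.null(stress_class)) {
    stress_class <- matrix(sample(c("up", "down", "unchanged"),
                                  n * length(stresses), replace = TRUE),
                           n, length(stresses),
                           dimnames = list(gene_ids, stresses))
  }
  stress_class <- as.matrix(stress_class)
  cols <- c(tissues,
            as.vector(rbind(paste0(stresses, "_control"),
                            paste0(stresses, "_treatment"))))
  mat <- matrix(0, n, length(cols), dimnames = list(gene_ids, cols))
  hi <- 50; lo <- 0.05
  for (i in seq_len(n)) {
    on <- tissue_pattern[[gene_ids[i]]]
    for (tis in tissues)
      mat[i, tis] <- if (tis %in% on) hi * runif(1, 0.5, 2) else
        lo * runif(1, 0.2, 1)
    for (s in seq_along(stresses)) {
      ctrl <- 5 * runif(1, 0.8, 1.25)
      ratio <- switch(stress_class[i, s],
        up = 2 * margin * runif(1, 1, 2),
        down = 0.5 / (margin * runif(1, 1, 2)),
        unchanged = exp(runif(1, log(0.5 * margin), log(2 / margin))))
      mat[i, paste0(stresses[s], "_control")] <- ctrl
      mat[i, paste0(stresses[s], "_treatment")] <- ctrl * ratio
    }
  }
  if (noise_sd > 0)
    mat <- mat * matrix(rlnorm(length(mat), 0, noise_sd), nrow(mat))
  list(matrix = mat,
       truth = list(tissue_pattern = tissue_pattern,
                    stress_class = stress_class))
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Constructs cycle-threshold values so that the 2^-ddCt method recovers
#' the planted fold changes exactly at zero noise: the reference gene
#' sits at a constant Ct, the target's control Ct at a constant base,
#' and each treatment Ct at `base - log2(fold)`.
#'
#' @param genes target gene ids.
#' @param treatments treatment condition names (the calibrator is
#'   `"control"`).
#' @param true_fold_changes gene x treatment numeric matrix (or a named
#'   vector for a single gene), all > 0.
#' @param reference_gene internal-control gene id.
#' @param n_replicates replicates per condition (default 3).
#' @param noise_sd per-measurement normal noise on Ct (default 0).
#' @param seed RNG seed.
#' @return Long-format data.frame: `gene`, `condition`, `replicate`,
#'   `ct`, ready for [compute_relative_expression()].
#' @export
generate_ct_table <- function(genes, treatments, true_fold_changes,
                              reference_gene = "REF", n_replicates = 3L,
                              noise_sd = 0, seed = 1L) {
  if (is.vector(true_fold_changes) && is.null(dim(true_fold_changes)))
    true_fold_changes <- matrix(true_fold_changes, nrow = length(genes),
                                ncol = length(treatments),
                                dimnames = list(genes, treatments))
  if (any(true_fold_changes <= 0))
    stop("fold changes must be > 0")
  set.seed(seed)
  conds <- c("control", treatments)
  rows <- list()
  add <- function(g, cond, ct_base) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = g, condition = cond, replicate = r,
        ct = ct_base + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0)
    }
  }
  for (cond in conds) add(reference_gene, cond, 15)
  for (g in genes) {
    add(g, "control", 24)
    for (trt in treatments)
      add(g, trt, 24 - log2(true_fold_changes[g, trt]))
  }
  do.call(rbind, rows)
}
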