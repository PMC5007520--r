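#' All-vs-all protein similarity with paralog-link filters
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) for every
#' protein pair, with e-values calibrated against shuffled decoy pairs
#' (Gumbel fit).  A link is retained when (i) its e-value passes the gate
#' (default 1e-20), (ii) it does not exceed `best_hit_ratio` times the
#' best non-self e-value of either member (restricting links to closest
#' family members), and (iii) the alignment covers at least
#' `min_coverage` of the longer protein.  The three filter tallies are
#' logged separately.
#'
#' @param proteins named character vector (>= 2).
#' @param config a [pipeline_config()].
#' @param n_decoys shuffled decoy pairs for calibration (default 500).
#' @param seed calibration seed.
#' @return data.frame of retained hits: `query_id`, `subject_id`,
#'   `score`, `evalue`, `log10_evalue`, `coverage`, plus alignment spans;
#'   all scored pairs (pre-filter) in `attr(, "all_pairs")`.
#' @export
all_vs_all_similarity <- function(proteins, config = pipeline_config(),
                                  n_decoys = 500L, seed = 1L) {
  n <- length(proteins)
  if (n < 2L) stop("need >= 2 proteins")
  ids <- names(proteins)
  S <- blosum62()
  aln1 <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = S,
      gapOpening = 10, gapExtension = 0.5)
    list(score = Biostrings::score(pa),
         qs = Biostrings::start(Biostrings::pattern(pa)),
         qe = Biostrings::end(Biostrings::pattern(pa)),
         ss = Biostrings::start(Biostrings::subject(pa)),
         se = Biostrings::end(Biostrings::subject(pa)))
  }
  # decoy calibration
  set.seed(seed)
  dsc <- numeric(n_decoys)
  for (k in seq_len(n_decoys)) {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    da <- paste(sample(strsplit(proteins[[i]], "")[[1]]), collapse = "")
    db <- paste(sample(strsplit(proteins[[j]], "")[[1]]), collapse = "")
    dsc[k] <- aln1(da, db)$score
  }
  beta <- sd(dsc) * sqrt(6) / pi
  mu <- mean(dsc) - 0.5772156649 * beta

  n_pairs <- n * (n - 1L) / 2L
  rows <- vector("list", n_pairs)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    al <- aln1(proteins[[i]], proteins[[j]])
    longer <- max(nchar(proteins[[i]]), nchar(proteins[[j]]))
    cov_q <- (al$qe - al$qs + 1L) / nchar(proteins[[i]])
    cov_s <- (al$se - al$ss + 1L) / nchar(proteins[[j]])
    coverage <- if (nchar(proteins[[i]]) >= nchar(proteins[[j]]))
      cov_q else cov_s
    l10 <- gumbel_upper_log10(al$score, mu, beta, n_pairs)
    rows[[k]] <- data.frame(
      query_id = ids[i], subject_id = ids[j], score = al$score,
      evalue = 10 ^ l10, log10_evalue = l10, coverage = coverage,
      query_start = al$qs, query_end = al$qe,
      subject_start = al$ss, subject_end = al$se)
  }
  all_pairs <- do.call(rbind, rows)

  pass_e <- all_pairs$log10_evalue < log10(config$similarity_evalue)
  message(sprintf("similarity gate (E < %g): %d of %d pairs pass",
                  config$similarity_evalue, sum(pass_e), n_pairs))
  # best non-self hit per protein (log10 scale)
  best <- setNames(rep(Inf, n), ids)
  for (r in seq_len(n_pairs)) {
    q <- all_pairs$query_id[r]; s <- all_pairs$subject_id[r]
    e <- all_pairs$log10_evalue[r]
    best[q] <- min(best[q], e); best[s] <- min(best[s], e)
  }
  # a retained link must lie within a factor 1/best_hit_ratio (1e20 by
  # default) of the best non-self hit of either member, restricting the
  # link set to each gene's closest relatives
  lr <- -log10(config$best_hit_ratio)
  pass_ratio <- all_pairs$log10_evalue <=
    pmin(best[all_pairs$query_id], best[all_pairs$subject_id]) + lr
  message(sprintf("best-hit ratio (within %g x best): %d of %d pass",
                  1 / config$best_hit_ratio, sum(pass_e & pass_ratio),
                  sum(pass_e)))
  pass_cov <- all_pairs$coverage >= config$min_coverage
  keep <- pass_e & pass_ratio & pass_cov
  message(sprintf("coverage >= %g of longer: %d of %d retained",
                  config$min_coverage, sum(keep),
                  sum(pass_e & pass_ratio)))
  hits <- all_pairs[keep, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "all_pairs") <- all_pairs
  attr(hits, "calibration") <- list(mu = mu, beta = beta,
                                    n_decoys = n_decoys)
  hits
}

#' Detect tandem duplication clusters
#'
#' Per chromosome, family genes are sorted by start position; consecutive
#' genes whose starts lie within `window` (200 kb by default) are linked,
#' and maximal linked runs of two or more genes are emitted as tandem
#' clusters (transitive closure of the pairwise window rule).
#'
#' @param genes list of [gene_model()]s (the family members).
#' @param window maximum start-to-start distance in bp (default 200000).
#' @return List of clusters, each a list with `chromosome`, `gene_ids`
#'   (in positional order) and `span` (bp between first and last start).
#' @export
detect_tandem_clusters <- function(genes, window = 200000) {
  if (!length(genes)) return(list())
  chrom <- vapply(genes, `[[`, "", "chromosome")
  start <- vapply(genes, `[[`, 0, "start")
  id <- vapply(genes, `[[`, "", "gene_id")
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(start[sel])]
    if (length(sel) < 2L) next
    s <- start[sel]
    brk <- c(0L, which(diff(s) > window), length(sel))
    for (b in seq_len(length(brk) - 1L)) {
      run <- sel[(brk[b] + 1L):brk[b + 1L]]
      if (length(run) >= 2L)
        out[[length(out) + 1L]] <- list(
          chromosome = ch, gene_ids = id[run],
          span = max(start[run]) - min(start[run]))
    }
  }
  message(sprintf("tandem detection: %d cluster(s) covering %d gene(s)",
                  length(out), sum(lengths(lapply(out, `[[`, "gene_ids")))))
  out
}

#' Chain similarity hits into collinear (segmental) blocks
#'
#' Retained similarity hits are projected onto per-chromosome gene ranks
#' and chained by dynamic programming: consecutive anchors of a chain
#' must advance in rank on both chromosomes (both orientations are
#' tried) with at most `gap` intervening non-anchor genes on each side.
#' Chains are extracted best-first; each anchor joins at most one block,
#' and chains with at least `min_anchors` anchors are emitted.
#'
#' @param hits data.frame with `query_id`/`subject_id` columns (e.g. from
#'   [all_vs_all_similarity()]).
#' @param gene_order named list: chromosome -> character vector of ALL
#'   gene ids (family and background) in positional order.
#' @param gap maximum intervening non-anchor genes (default 6).
#' @param min_anchors minimum anchors per block (default 2).
#' @return List of blocks, each a list with `chromosomes` (length 2),
#'   `anchors` (data.frame `gene_a`, `gene_b`, `rank_a`, `rank_b`) and
#'   `orientation` (`"forward"` or `"reverse"`).
#' @export
chain_collinear_blocks <- function(hits, gene_order, gap = 6L,
                                   min_anchors = 2L) {
  if (!nrow(hits)) return(list())
  rank_of <- list()
  for (ch in names(gene_order)) {
    rk <- seq_along(gene_order[[ch]])
    names(rk) <- gene_order[[ch]]
    rank_of[[ch]] <- rk
  }
  chrom_of <- unlist(lapply(names(gene_order), function(ch)
    setNames(rep(ch, length(gene_order[[ch]])), gene_order[[ch]])))
  miss <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                  names(chrom_of))
  if (length(miss))
    stop("gene(s) in hits missing from gene_order: ",
         paste(miss, collapse = ", "))

  # group anchors by (unordered) chromosome pair
  ca <- chrom_of[hits$query_id]; cb <- chrom_of[hits$subject_id]
  ga <- hits$query_id; gb <- hits$subject_id
  swap <- ca > cb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
  keys <- paste(ca, cb, sep = "\r")
  blocks <- list()
  for (key in unique(keys)) {
    sel <- which(keys == key)
    anch <- data.frame(
      gene_a = ga[sel], gene_b = gb[sel],
      rank_a = as.integer(rank_of[[ca[sel][1]]][ga[sel]]),
      rank_b = as.integer(rank_of[[cb[sel][1]]][gb[sel]]))
    repeat {
      res <- best_chain(anch, gap)
      if (is.null(res) || length(res$chain) < min_anchors) break
      blocks[[length(blocks) + 1L]] <- list(
        chromosomes = c(ca[sel][1], cb[sel][1]),
        anchors = anch[res$chain, , drop = FALSE],
        orientation = res$orientation)
      anch <- anch[-res$chain, , drop = FALSE]
      if (!nrow(anch)) break
    }
  }
  message(sprintf("collinearity: %d block(s), %d anchor pair(s) assigned",
                  length(blocks),
                  sum(vapply(blocks, function(b) nrow(b$anchors), 0))))
  blocks
}

# longest single chain over anchors (both orientations); returns row
# indices in chain order, or NULL
best_chain <- function(anch, gap) {
  n <- nrow(anch)
  if (n == 0L) return(NULL)
  best <- NULL
  for (orient in c("forward", "reverse")) {
    rb <- if (orient == "forward") anch$rank_b else -anch$rank_b
    ord <- order(anch$rank_a, rb)
    ra_o <- anch$rank_a[ord]; rb_o <- rb[ord]
    L <- rep(1L, n); prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (ra_o[j] < ra_o[i] && rb_o[j] < rb_o[i] &&
            ra_o[i] - ra_o[j] - 1L <= gap &&
            rb_o[i] - rb_o[j] - 1L <= gap &&
            L[j] + 1L > L[i]) {
          L[i] <- L[j] + 1L; prev[i] <- j
        }
      }
    }
    top <- which.max(L)
    chain <- integer(0); cur <- top
    while (cur != 0L) { chain <- c(cur, chain); cur <- prev[cur] }
    if (is.null(best) || L[top] > length(best$chain)) {
      best <- list(chain = ord[chain], orientation = orient)
    }
  }
  best
}
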