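#' Run the full family characterization on a gene set
#'
#' Chains the pipeline stages on in-memory inputs: domain identification
#' ([family_scan()]), multiple alignment and bootstrapped NJ phylogeny,
#' intron categorization, tandem and collinear duplication detection, and
#' Ka/Ks with dating for the duplicated pairs.  Intended for synthetic
#' genomes ([generate_family_genome()]) and small real gene sets alike.
#'
#' @param proteins named character vector of candidate proteins.
#' @param cds named character vector of matching coding sequences.
#' @param genes named list of [gene_model()]s.
#' @param gene_order named list: chromosome -> gene ids in positional
#'   order (all genes, background included).
#' @param profile a [build_profile()] domain profile.
#' @param config a [pipeline_config()].
#' @param bootstrap_replicates overrides the config value (handy for
#'   quick runs).
#' @param seed RNG seed for calibration and bootstrap.
#' @return List of class `"family_analysis"` with elements `scan`,
#'   `msa`, `tree`, `introns`, `similarity`, `tandem`, `blocks`, `kaks`.
#' @export
run_family_analysis <- function(proteins, cds, genes, gene_order,
                                profile, config = pipeline_config(),
                                bootstrap_replicates = NULL,
                                seed = 1L) {
  reps <- if (is.null(bootstrap_replicates))
    config$bootstrap_replicates else bootstrap_replicates
  scan <- family_scan(proteins, profile,
                      evalue_threshold = config$domain_evalue,
                      seed = seed)
  acc <- scan$accepted
  fam_prot <- proteins[acc]
  msa <- build_msa(fam_prot)
  tree <- bootstrap_support(msa, replicates = reps, seed = seed,
                            collapse = config$collapse_support)
  introns <- classify_intron_counts(genes[acc])
  sim <- all_vs_all_similarity(fam_prot, config, seed = seed)
  tandem <- detect_tandem_clusters(genes[acc],
                                   window = config$tandem_window)
  blocks <- chain_collinear_blocks(sim, gene_order,
                                   gap = config$collinearity_gap,
                                   min_anchors = config$min_anchors)
  anchor_pairs <- do.call(rbind, lapply(blocks, function(b)
    b$anchors[, c("gene_a", "gene_b")]))
  kaks <- if (!is.null(anchor_pairs) && nrow(anchor_pairs))
    analyze_paralog_pairs(anchor_pairs, proteins, cds,
                          r = config$neutral_rate_r) else NULL
  structure(list(scan = scan, msa = msa, tree = tree, introns = introns,
                 similarity = sim, tandem = tandem, blocks = blocks,
                 kaks = kaks, config = config),
            class = "family_analysis")
}

#' @export
print.family_analysis <- function(x, ...) {
  cat("<family_analysis>\n")
  cat(sprintf("  accepted family members : %d of %d candidates\n",
              length(x$scan$accepted), nrow(x$scan$members)))
  tal <- attr(x$introns, "tally")
  cat(sprintf("  intron categories       : %d / %d / %d (none/one/multi)\n",
              tal[1], tal[2], tal[3]))
  cat(sprintf("  tandem clusters         : %d\n", length(x$tandem)))
  cat(sprintf("  collinear blocks        : %d\n", length(x$blocks)))
  if (!is.null(x$kaks)) {
    ok <- !is.na(x$kaks$ratio)
    cat(sprintf("  duplicated pairs dated  : %d (Ka/Ks < 1: %s%%)\n",
                nrow(x$kaks),
                format(summarize_counts(sum(x$kaks$ratio[ok] < 1),
                                        max(sum(ok), 1)))))
  }
  invisible(x)
}
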