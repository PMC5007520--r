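#' Pipeline configuration
#'
#' Collects every tunable threshold of the family-characterization pipeline
#' in one validated list.  Defaults are the values used throughout the
#' package: a domain-scan gate of 1e-10, a similarity gate of 1e-20 with a
#' best-hit ratio of 1e-20 and >= 50% coverage of the longer protein, a
#' 200-kb tandem window, a collinearity gap of 6 intervening genes with at
#' least 2 anchors per block, 1000 bootstrap replicates collapsed below 50%
#' support, a neutral substitution rate of 2.6e-9 per site per year for
#' duplication dating, FPKM > 1 for "expressed", twofold / one-half
#' differential rules, a 0.5-correlation cut for expression pattern
#' clusters, and up to 8 motifs of width 8-100 residues.
#'
#' @param ... named overrides of any default listed above.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(tandem_window = 150000)
#' cfg$tandem_window
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    domain_evalue      = 1e-10,
    similarity_evalue  = 1e-20,
    best_hit_ratio     = 1e-20,
    min_coverage       = 0.5,
    tandem_window      = 200000,
    collinearity_gap   = 6L,
    min_anchors        = 2L,
    bootstrap_replicates = 1000L,
    collapse_support   = 50,
    neutral_rate_r     = 2.6e-9,
    fpkm_expressed     = 1.0,
    fold_up            = 2.0,
    fold_down          = 0.5,
    cluster_threshold  = 0.5,
    max_motifs         = 8L,
    motif_width_range  = c(8L, 100L),
    rng_seed           = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  num <- c("domain_evalue", "similarity_evalue", "best_hit_ratio",
           "min_coverage", "tandem_window", "collinearity_gap",
           "min_anchors", "bootstrap_replicates", "collapse_support",
           "neutral_rate_r", "fpkm_expressed", "fold_up", "fold_down",
           "cluster_threshold", "max_motifs")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("configuration field '", f, "' must be a single positive number")
  }
  if (!(cfg$fold_down < 1 && 1 < cfg$fold_up))
    stop("need fold_down < 1 < fold_up")
  wr <- cfg$motif_width_range
  if (length(wr) != 2L || wr[1] < 2 || wr[2] < wr[1])
    stop("motif_width_range must be an increasing pair of widths >= 2")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s %s\n", f, paste(format(x[[f]]), collapse = "-")))
  }
  invisible(x)
}
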