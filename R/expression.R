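#' Call expressed genes from an FPKM matrix
#'
#' A gene is expressed in a condition when its abundance strictly exceeds
#' the threshold (FPKM > 1 by default), and expressed overall when it is
#' expressed in at least one condition.  Boundary values (FPKM exactly at
#' the threshold) are logged so the non-strict convention remains
#' recoverable.
#'
#' @param matrix numeric gene x condition matrix (FPKM, non-negative).
#' @param threshold expression threshold (default 1.0, strict).
#' @return List with `flags` (logical gene x condition matrix),
#'   `expressed_any` (named logical), `n_expressed`.
#' @export
call_expressed <- function(matrix, threshold = 1.0) {
  if (any(matrix < 0)) stop("FPKM values must be non-negative")
  flags <- matrix > threshold
  boundary <- sum(matrix == threshold)
  if (boundary > 0)
    message(sprintf("%d value(s) exactly at threshold %g called not expressed (strict rule)",
                    boundary, threshold))
  expressed_any <- apply(flags, 1L, any)
  list(flags = flags, expressed_any = expressed_any,
       n_expressed = sum(expressed_any))
}

#' Differential call for one treatment/control pair
#'
#' `ratio = (treatment + pseudocount) / (control + pseudocount)`; strictly
#' more than `fold_up` (twofold) is `"up"`, strictly less than
#' `fold_down` (one half) is `"down"`, anything else `"unchanged"`.
#'
#' @param treatment_fpkm,control_fpkm non-negative values (vectorized).
#' @param fold_up,fold_down fold-change bounds (2 and 0.5).
#' @param pseudocount added to both values (default 0.01).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
call_differential <- function(treatment_fpkm, control_fpkm,
                              fold_up = 2.0, fold_down = 0.5,
                              pseudocount = 0.01) {
  if (any(treatment_fpkm < 0) || any(control_fpkm < 0))
    stop("FPKM values must be non-negative")
  ratio <- (treatment_fpkm + pseudocount) / (control_fpkm + pseudocount)
  ifelse(ratio > fold_up, "up",
         ifelse(ratio < fold_down, "down", "unchanged"))
}

#' Cluster expression patterns by correlation
#'
#' Average-linkage hierarchical clustering on `1 - Pearson correlation`
#' of `log2(FPKM + pseudocount)` rows, cut where merge similarity drops
#' below the correlation threshold (0.5 by default, so genes in one
#' cluster correlate at >= 0.5 on average).  Constant rows have undefined
#' correlation and are assigned singleton clusters with a warning.
#'
#' @param matrix numeric gene x condition FPKM matrix (>= 2 genes).
#' @param threshold correlation cut (default 0.5).
#' @param pseudocount added before the log2 transform (default 1).
#' @return List with `clusters` (named integer vector gene -> cluster
#'   id), `n_clusters`, `merge_similarity` (per-merge correlation), and
#'   the `hclust` object.
#' @export
cluster_expression_patterns <- function(matrix, threshold = 0.5,
                                        pseudocount = 1) {
  if (nrow(matrix) < 2L) stop("need >= 2 genes")
  lg <- log2(matrix + pseudocount)
  sds <- apply(lg, 1L, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " constant row(s) assigned singleton clusters")
  act <- rownames(matrix)[!flat]
  clusters <- setNames(integer(nrow(matrix)), rownames(matrix))
  hc <- NULL; msim <- numeric(0)
  if (length(act) >= 2L) {
    cm <- suppressWarnings(cor(t(lg[act, , drop = FALSE])))
    d <- as.dist(1 - cm)
    hc <- hclust(d, method = "average")
    msim <- 1 - hc$height
    cl <- cutree(hc, h = 1 - threshold)
    clusters[act] <- cl
  } else if (length(act) == 1L) {
    clusters[act] <- 1L
  }
  nxt <- max(clusters, 0L)
  for (g in rownames(matrix)[flat]) {
    nxt <- nxt + 1L
    clusters[g] <- nxt
  }
  list(clusters = clusters, n_clusters = length(unique(clusters)),
       merge_similarity = msim, hclust = hc)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each replicate, `dCt = Ct(target) - Ct(reference)`; `ddCt` is the
#' mean treatment dCt minus the mean calibrator dCt, and the fold change
#' is `2^-ddCt`.  Replicate standard deviations are propagated
#' (`sqrt(sd_t^2/n_t + sd_c^2/n_c)` on the ddCt scale).
#'
#' @param ct_table long-format data.frame with columns `gene`,
#'   `condition`, `replicate`, `ct`.
#' @param target_gene,reference_gene gene ids present in the table.
#' @param calibrator_condition the control/calibrator condition id.
#' @param treatment_condition the treatment condition id; default all
#'   non-calibrator conditions in the table.
#' @return data.frame with one row per treatment: `gene`, `treatment`,
#'   `ddct`, `fold_change`, `ddct_sd`, and a two-sided t-test p-value on
#'   the replicate dCt values where both sides have >= 2 replicates.
#' @export
compute_relative_expression <- function(ct_table, target_gene,
                                        reference_gene,
                                        calibrator_condition,
                                        treatment_condition = NULL) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(need, collapse = ", "))
  dct_for <- function(cond) {
    tg <- ct_table[ct_table$gene == target_gene &
                     ct_table$condition == cond, ]
    rf <- ct_table[ct_table$gene == reference_gene &
                     ct_table$condition == cond, ]
    if (!nrow(rf))
      stop("missing reference Ct for condition '", cond, "'")
    if (!nrow(tg))
      stop("missing target Ct for condition '", cond, "'")
    m <- merge(tg[, c("replicate", "ct")], rf[, c("replicate", "ct")],
               by = "replicate", suffixes = c("_t", "_r"))
    if (!nrow(m))
      stop("no matched replicates for condition '", cond, "'")
    m$ct_t - m$ct_r
  }
  if (is.null(treatment_condition))
    treatment_condition <- setdiff(unique(ct_table$condition),
                                   calibrator_condition)
  dct_cal <- dct_for(calibrator_condition)
  out <- vector("list", length(treatment_condition))
  for (k in seq_along(treatment_condition)) {
    trt <- treatment_condition[k]
    dct_trt <- dct_for(trt)
    ddct <- mean(dct_trt) - mean(dct_cal)
    sd_prop <- sqrt(sd(dct_trt)^2 / length(dct_trt) +
                    sd(dct_cal)^2 / length(dct_cal))
    pval <- if (length(dct_trt) >= 2L && length(dct_cal) >= 2L &&
                (sd(dct_trt) > 0 || sd(dct_cal) > 0))
      t.test(dct_trt, dct_cal)$p.value else NA_real_
    out[[k]] <- data.frame(
      gene = target_gene, treatment = trt, ddct = ddct,
      fold_change = 2 ^ (-ddct), ddct_sd = sd_prop, p_value = pval)
  }
  do.call(rbind, out)
}
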