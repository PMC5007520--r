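# 20-letter amino-acid alphabet, fixed column order for all profiles
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Build a position-specific log-odds profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped; retained columns get
#' per-residue log-odds scores `log2((count + pseudocount) / (n + 20 *
#' pseudocount) / background)` in bits.  This gapless position profile is
#' the package's stand-in for a profile HMM: the family domain it targets
#' is compact and well conserved, so insert/delete states add little (see
#' the methods vignette).
#'
#' @param seed_alignment character vector of >= 2 equal-length gapped
#'   amino-acid sequences (gap = `-`).
#' @param background 20 background frequencies (named by residue), summing
#'   to 1; default uniform.
#' @param pseudocount per-residue pseudocount (Jeffreys 0.5 default).
#' @return An object of class `"domain_profile"` with fields `width`,
#'   `log_odds` (width x 20, bits), `background`, and `consensus`.
#' @export
build_profile <- function(seed_alignment, background = NULL,
                          pseudocount = 0.5) {
  if (length(seed_alignment) < 2L)
    stop("seed alignment needs >= 2 sequences")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  background <- background[AA_ALPHABET]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must assign positive frequency to all 20 residues")
  background <- background / sum(background)

  mat <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0L) stop("no alignment columns with <= 50% gaps")

  lo <- matrix(0, length(keep), 20, dimnames = list(NULL, AA_ALPHABET))
  consensus <- character(length(keep))
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    col <- col[col %in% AA_ALPHABET]
    counts <- table(factor(col, levels = AA_ALPHABET))
    freq <- (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
    lo[k, ] <- log2(freq / background)
    consensus[k] <- AA_ALPHABET[which.max(lo[k, ])]
  }
  structure(list(width = length(keep), log_odds = lo,
                 background = background,
                 consensus = paste(consensus, collapse = ""),
                 calibration = NULL),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> width %d, %s\n", x$width,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel calibration mu=%.2f beta=%.2f (n=%d)",
                           x$calibration$mu, x$calibration$beta,
                           x$calibration$n_decoys)))
  invisible(x)
}

# score every length-`width` window of `sequence` against the profile;
# X (or any non-standard residue) scores 0 at every position
score_windows <- function(profile, sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  L <- length(res); W <- profile$width
  if (L < W) return(numeric(0))
  idx <- match(res, AA_ALPHABET)          # NA for X etc. -> scores 0
  n_win <- L - W + 1L
  acc <- numeric(n_win)
  lo <- profile$log_odds
  for (k in seq_len(W)) {
    s <- lo[k, idx[k:(k + n_win - 1L)]]
    s[is.na(s)] <- 0
    acc <- acc + s
  }
  acc
}

#' Calibrate a profile's e-values against shuffled decoys
#'
#' Scores `n_decoys` decoy proteins (residues shuffled from the supplied
#' proteins, or drawn i.i.d. from the profile background when none are
#' given), records each decoy's best window score, and fits a Gumbel
#' distribution to those maxima by the method of moments.  E-values
#' reported by [scan_protein()] are `n_db * P(max window score >= s)`
#' under this fit.
#'
#' @param profile a [build_profile()] result.
#' @param proteins optional character vector of real protein sequences to
#'   shuffle into decoys.
#' @param n_decoys number of decoys (default 10000).
#' @param decoy_length decoy length when sampling from background
#'   (default `2 * width`).
#' @param seed RNG seed for decoy generation.
#' @return The profile with a `calibration` field
#'   (`mu`, `beta`, `n_decoys`, `decoy_scores`).
#' @export
calibrate_profile <- function(profile, proteins = NULL, n_decoys = 10000L,
                              decoy_length = NULL, seed = 1L) {
  W <- profile$width
  if (is.null(decoy_length)) decoy_length <- 2L * W
  set.seed(seed)
  if (is.null(proteins)) {
    pool <- NULL
  } else {
    pool <- strsplit(toupper(proteins[nchar(proteins) >= W]), "")
    if (length(pool) == 0L) pool <- NULL
  }
  # build all decoys as an index matrix (rows = decoys) and score all
  # windows of all decoys simultaneously, one profile row at a time
  if (is.null(pool)) {
    L <- decoy_length
    idx <- matrix(sample.int(20, n_decoys * L, replace = TRUE,
                             prob = profile$background),
                  nrow = n_decoys)
  } else {
    lens <- vapply(pool, length, integer(1))
    L <- max(lens)
    pick <- sample.int(length(pool), n_decoys, replace = TRUE)
    idx <- matrix(NA_integer_, n_decoys, L)
    for (i in seq_len(n_decoys)) {
      p <- match(sample(pool[[pick[i]]]), AA_ALPHABET)
      # pad cyclically to common length so the matrix trick applies
      idx[i, ] <- p[((seq_len(L) - 1L) %% length(p)) + 1L]
    }
  }
  n_win <- L - W + 1L
  best <- rep(-Inf, n_decoys)
  lo <- profile$log_odds
  acc <- matrix(0, n_decoys, n_win)
  for (k in seq_len(W)) {
    block <- idx[, k:(k + n_win - 1L), drop = FALSE]
    sc <- lo[k, ][block]
    sc[is.na(sc)] <- 0
    acc <- acc + matrix(sc, n_decoys, n_win)
  }
  best <- apply(acc, 1L, max)
  beta <- sd(best) * sqrt(6) / pi
  mu <- mean(best) - 0.5772156649 * beta
  profile$calibration <- list(mu = mu, beta = beta,
                              n_decoys = as.integer(n_decoys),
                              decoy_scores = best)
  profile
}

# upper-tail Gumbel probability and the score achieving a given e-value
gumbel_upper_log10 <- function(score, mu, beta, n_db) {
  z <- (score - mu) / beta
  if (z > 30) {
    log10(n_db) - z / log(10)        # 1 - exp(-exp(-z)) ~ exp(-z)
  } else {
    log10(n_db) + log10(1 - exp(-exp(-z)))
  }
}

gumbel_score_at <- function(evalue, mu, beta, n_db) {
  p <- min(evalue / n_db, 0.999999)
  mu + beta * (-log(-log1p(-p)))
}

#' Scan a protein for domain hits
#'
#' Scores every window against the profile and reports non-overlapping
#' local maxima whose empirically calibrated e-value passes the gate
#' (default 1e-10, the pipeline's identification threshold).  Overlapping
#' candidate windows are resolved best-score-first, ties to the leftmost.
#'
#' @param profile a calibrated [build_profile()] result
#'   (see [calibrate_profile()]).
#' @param protein protein sequence (string) or a named length-1 vector;
#'   the name is used as `protein_id`.
#' @param evalue_threshold e-value gate (default 1e-10).
#' @param n_db number of sequences in the scanned database (e-values
#'   scale with it); default 1.
#' @return data.frame with columns `protein_id`, `start`, `end`, `score`
#'   (bits), `evalue`, `log10_evalue`.  Proteins shorter than the profile
#'   width yield an empty frame with a warning.
#' @export
scan_protein <- function(profile, protein, evalue_threshold = 1e-10,
                         n_db = 1L) {
  if (is.null(profile$calibration))
    stop("profile is uncalibrated; run calibrate_profile() first")
  pid <- if (!is.null(names(protein))) names(protein)[1] else "protein"
  seqstr <- as.character(protein[[1]])
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      evalue = numeric(0), log10_evalue = numeric(0))
  if (nchar(seqstr) < profile$width) {
    warning("protein ", pid, " shorter than profile width; no scan")
    return(empty)
  }
  sc <- score_windows(profile, seqstr)
  cal <- profile$calibration
  s_min <- gumbel_score_at(evalue_threshold, cal$mu, cal$beta, n_db)
  cand <- which(sc >= s_min)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(-sc[cand], cand)]   # best first, leftmost on ties
  W <- profile$width
  taken <- integer(0)
  keep <- integer(0)
  for (p in cand) {
    if (!length(taken) || all(abs(taken - p) >= W)) {
      keep <- c(keep, p)
      taken <- c(taken, p)
    }
  }
  keep <- sort(keep)
  l10 <- vapply(sc[keep], gumbel_upper_log10, numeric(1),
                mu = cal$mu, beta = cal$beta, n_db = n_db)
  data.frame(protein_id = pid, start = keep,
             end = keep + W - 1L, score = sc[keep],
             evalue = 10 ^ l10, log10_evalue = l10,
             row.names = NULL)
}

#' Classify scanned candidates into family members and rejects
#'
#' Applies the family-membership rule: exactly one passing, non-overlapping
#' domain hit means acceptance; none means `rejected_no_domain`; two or
#' more mean `rejected_multi_domain` (multi-domain proteins are excluded
#' from the family).  The three class counts are logged.
#'
#' @param hits data.frame of domain hits as returned by [scan_protein()]
#'   (rows from several proteins may be concatenated).
#' @param candidate_ids character vector of all scanned protein ids
#'   (including those with no hits).
#' @return data.frame with `protein_id`, `n_hits`, `status`.
#' @export
select_family_members <- function(hits, candidate_ids) {
  n_hits <- vapply(candidate_ids, function(id)
    sum(hits$protein_id == id), integer(1))
  status <- ifelse(n_hits == 0L, "rejected_no_domain",
            ifelse(n_hits == 1L, "accepted", "rejected_multi_domain"))
  out <- data.frame(protein_id = candidate_ids, n_hits = n_hits,
                    status = status, row.names = NULL)
  message(sprintf(
    "domain selection: %d candidates -> %d accepted, %d no-domain, %d multi-domain",
    length(candidate_ids), sum(status == "accepted"),
    sum(status == "rejected_no_domain"),
    sum(status == "rejected_multi_domain")))
  out
}

#' Identify family members in a protein set
#'
#' Convenience wrapper: calibrates the profile against the candidate set
#' (shuffled decoys), scans every protein, and classifies candidates with
#' [select_family_members()].
#'
#' @param proteins named character vector of candidate protein sequences.
#' @param profile a [build_profile()] result (calibrated or not).
#' @param evalue_threshold identification gate (default 1e-10).
#' @param n_decoys decoys for calibration when needed.
#' @param seed calibration seed.
#' @return List of class `"family_scan"`: `hits` (all passing hits),
#'   `members` (classification frame), `accepted` (ids).
#' @export
family_scan <- function(proteins, profile, evalue_threshold = 1e-10,
                        n_decoys = 10000L, seed = 1L) {
  if (is.null(profile$calibration))
    profile <- calibrate_profile(profile, proteins, n_decoys = n_decoys,
                                 seed = seed)
  n_db <- length(proteins)
  hit_list <- lapply(names(proteins), function(id) {
    suppressWarnings(
      scan_protein(profile, setNames(proteins[id], id),
                   evalue_threshold = evalue_threshold, n_db = n_db))
  })
  hits <- do.call(rbind, hit_list)
  members <- select_family_members(hits, names(proteins))
  structure(list(hits = hits, members = members,
                 accepted = members$protein_id[members$status == "accepted"],
                 profile = profile),
            class = "family_scan")
}

#' @export
print.family_scan <- function(x, ...) {
  tab <- table(x$members$status)
  cat(sprintf("<family_scan> %d candidates: %d accepted (%s%%)\n",
              nrow(x$members), length(x$accepted),
              format(summarize_counts(length(x$accepted), nrow(x$members)))))
  for (s in names(tab)) cat(sprintf("  %-22s %d\n", s, tab[[s]]))
  invisible(x)
}
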