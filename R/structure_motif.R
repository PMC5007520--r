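#' Classify genes by intron count
#'
#' Intron count = exon count - 1; genes fall into the three classic
#' categories: intronless, single intron, multiple (>= 2) introns.  The
#' category tally is logged and attached as an attribute.
#'
#' @param genes list of [gene_model()]s.
#' @return data.frame with `gene_id`, `intron_count`, `category`; the
#'   three-category tally is in `attr(, "tally")`.
#' @export
classify_intron_counts <- function(genes) {
  if (!length(genes)) stop("no genes supplied")
  nint <- vapply(genes, function(g) {
    if (nrow(g$exons) == 0L) stop("gene ", g$gene_id, " has zero exons")
    nrow(g$exons) - 1L
  }, integer(1))
  cat3 <- ifelse(nint == 0L, "intronless",
          ifelse(nint == 1L, "single_intron", "multiple_introns"))
  out <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    intron_count = nint, category = cat3, row.names = NULL)
  tally <- c(intronless = sum(cat3 == "intronless"),
             single_intron = sum(cat3 == "single_intron"),
             multiple_introns = sum(cat3 == "multiple_introns"))
  message(sprintf("intron categories: %d intronless, %d single, %d multiple (of %d genes)",
                  tally[1], tally[2], tally[3], length(genes)))
  attr(out, "tally") <- tally
  out
}

# width grid used for motif search (coarse, roughly geometric)
MOTIF_WIDTH_GRID <- c(8L, 12L, 16L, 21L, 29L, 41L, 58L, 81L, 100L)

# small-sample bias of a 20-letter entropy/IC estimate, in bits
ic_bias <- function(n_eff) 19 / (2 * log(2) * max(n_eff, 1e-9))

# one EM run (ZOOPS) at fixed width from a seeded start window.
# x: list of integer vectors (NA = non-standard or masked residue)
zoops_em <- function(x, w, bg, seed_seq, seed_pos, max_iter = 60L,
                     tol = 1e-4) {
  n <- length(x)
  logb <- log(bg)
  # init PWM from the seed window
  f <- matrix((1 - 0.6) / 19, w, 20)
  seedres <- x[[seed_seq]][seed_pos:(seed_pos + w - 1L)]
  for (k in seq_len(w)) {
    if (!is.na(seedres[k])) f[k, seedres[k]] <- 0.6
    else f[k, ] <- bg
  }
  gamma <- 0.5
  ll_old <- -Inf
  ll_trace <- numeric(0)
  z <- vector("list", n)
  prior_c <- 10 * bg      # Dirichlet pseudocount mass per column
  for (iter in seq_len(max_iter)) {
    logf <- log(f)
    # penalized objective (log posterior): data log-likelihood plus the
    # Dirichlet prior on each PWM column and a Beta(2,2) prior on gamma;
    # MAP-EM makes THIS quantity non-decreasing
    log_prior <- sum(logf %*% prior_c) + log(gamma) + log(1 - gamma)
    ll <- log_prior
    cnt <- matrix(0, w, 20)
    zsum <- 0
    for (i in seq_len(n)) {
      xi <- x[[i]]
      m <- length(xi) - w + 1L
      if (m < 1L) { z[[i]] <- numeric(0); next }
      llr <- numeric(m)
      ok <- rep(TRUE, m)
      for (k in seq_len(w)) {
        r <- xi[k:(k + m - 1L)]
        bad <- is.na(r)
        contrib <- numeric(m)
        contrib[!bad] <- logf[k, r[!bad]] - logb[r[!bad]]
        ok <- ok & !bad
        llr <- llr + contrib
      }
      llr[!ok] <- -Inf   # windows touching masked/unknown residues
      mx <- max(llr, 0)  # log-sum-exp guard
      num <- gamma / m * exp(llr - mx)
      denom <- (1 - gamma) * exp(-mx) + sum(num)
      zi <- num / denom
      z[[i]] <- zi
      ll <- ll + log(denom) + mx
      zsum <- zsum + sum(zi)
      use <- zi > 1e-8
      if (any(use)) {
        for (k in seq_len(w)) {
          r <- xi[k:(k + m - 1L)][use]
          agg <- tapply(zi[use], r, sum)
          cnt[k, as.integer(names(agg))] <-
            cnt[k, as.integer(names(agg))] + agg
        }
      }
    }
    ll_trace <- c(ll_trace, ll)
    # Jeffreys-style background-proportional pseudocount (total mass 10
    # per column): deliberately strong regularization so that weakly
    # supported motifs stay near background and the information-content
    # stop rule can reject them
    f <- (cnt + 10 * matrix(bg, w, 20, byrow = TRUE)) / (zsum + 10)
    gamma <- (zsum + 1) / (n + 2)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(f = f, gamma = gamma, z = z, loglik = ll, ll_trace = ll_trace,
       n_eff = zsum, width = w)
}

# corrected information content per column of a fitted motif
motif_ic <- function(fit) {
  f <- fit$f
  ic <- apply(f, 1L, function(col) {
    col <- col[col > 0]
    log2(20) + sum(col * log2(col))
  })
  pmax(ic - ic_bias(fit$n_eff), 0)
}

#' De-novo motif discovery by ZOOPS expectation-maximization
#'
#' Iteratively fits a zero-or-one-occurrence-per-sequence motif model:
#' for each candidate width on a coarse grid the EM is restarted from
#' several seeded windows and the best likelihood kept; across widths the
#' motif with the highest total (small-sample-corrected) information
#' content wins.  Its occurrences are then masked and the next motif
#' sought, until `max_motifs` motifs are found or the best candidate's
#' mean corrected information content per column falls below `min_ic`
#' (0.5 bits).
#'
#' @param proteins named character vector of >= 5 protein sequences.
#' @param max_motifs maximum number of motifs (default 8).
#' @param width_range allowed motif widths, default `c(8, 100)`.
#' @param seed RNG seed.
#' @param n_restarts EM restarts per width (default 10).
#' @param min_ic stop threshold, bits/column (default 0.5).
#' @return List of `"motif_model"` objects with fields `motif_id`,
#'   `width`, `pfm` (width x 20 frequency grid), `occurrences`
#'   (data.frame: protein_id, start, score), `ic_per_column`, `loglik`.
#' @export
discover_motifs <- function(proteins, max_motifs = 8L,
                            width_range = c(8L, 100L), seed = 1L,
                            n_restarts = 10L, min_ic = 0.5) {
  if (length(proteins) < 5L) stop("need >= 5 sequences")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  x0 <- lapply(proteins, function(s) match(strsplit(toupper(s), "")[[1]],
                                           AA_ALPHABET))
  widths <- MOTIF_WIDTH_GRID[MOTIF_WIDTH_GRID >= width_range[1] &
                             MOTIF_WIDTH_GRID <= width_range[2]]
  widths <- widths[widths <= max(lengths(x0))]
  if (!length(widths))
    stop("all sequences shorter than the minimum motif width")
  set.seed(seed)
  x <- x0   # working copy; found occurrences masked with NA
  motifs <- list()
  for (mid in seq_len(max_motifs)) {
    res_all <- unlist(lapply(x, function(v) v[!is.na(v)]))
    if (length(res_all) < 20L) break
    bg <- (tabulate(res_all, nbins = 20) + 1) / (length(res_all) + 20)
    best <- NULL; best_ic_total <- -Inf
    for (w in widths) {
      hosts <- which(lengths(x) >= w)
      if (length(hosts) < 2L) next
      for (r in seq_len(n_restarts)) {
        si <- sample(hosts, 1L)
        maxp <- length(x[[si]]) - w + 1L
        sp <- sample.int(maxp, 1L)
        fit <- zoops_em(x, w, bg, si, sp)
        ic <- motif_ic(fit)
        tot <- sum(ic)
        if (tot > best_ic_total) {
          best <- fit; best_ic_total <- tot
          best$ic <- ic
        }
      }
    }
    if (is.null(best) || mean(best$ic) < min_ic) break
    occ <- motif_occurrences(best, names(proteins))
    if (nrow(occ) == 0L) break
    motifs[[mid]] <- structure(
      list(motif_id = mid, width = best$width, pfm = best$f,
           occurrences = occ, ic_per_column = best$ic,
           loglik = best$loglik, ll_trace = best$ll_trace,
           background = bg),
      class = "motif_model")
    # mask discovered occurrences
    for (i in seq_len(nrow(occ))) {
      si <- match(occ$protein_id[i], names(proteins))
      x[[si]][occ$start[i]:(occ$start[i] + best$width - 1L)] <- NA
    }
  }
  motifs
}

# extract per-sequence best occurrence (posterior occurrence prob > 0.5)
motif_occurrences <- function(fit, ids) {
  out <- list()
  for (i in seq_along(fit$z)) {
    zi <- fit$z[[i]]
    if (!length(zi) || sum(zi) <= 0.5) next
    p <- which.max(zi)
    out[[length(out) + 1L]] <- data.frame(
      protein_id = ids[i], start = p,
      score = log(zi[p] / max(1 - sum(zi), 1e-12)))
  }
  if (!length(out))
    return(data.frame(protein_id = character(0), start = integer(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> #%d width %d, %d occurrence(s), %.2f bits/col\n",
              x$motif_id, x$width, nrow(x$occurrences),
              mean(x$ic_per_column)))
  invisible(x)
}

#' Map discovered motifs back onto proteins
#'
#' Scans each protein with each motif's log-odds form; occurrences above
#' the per-motif decoy-calibrated score threshold are reported with
#' positions (the in-package analogue of scanning a database with found
#' motifs).
#'
#' @param motifs list of `"motif_model"` objects from [discover_motifs()].
#' @param proteins named character vector of protein sequences.
#' @param evalue_threshold per-motif e-value gate (default 1e-3).
#' @param n_decoys decoys per motif for calibration.
#' @param seed calibration seed.
#' @return data.frame with `motif_id`, `protein_id`, `start`, `end`,
#'   `score`, `evalue`.
#' @export
map_motifs <- function(motifs, proteins, evalue_threshold = 1e-3,
                       n_decoys = 1000L, seed = 1L) {
  empty <- data.frame(motif_id = integer(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), evalue = numeric(0))
  if (!length(motifs)) return(empty)
  out <- list()
  for (m in motifs) {
    prof <- structure(
      list(width = m$width,
           log_odds = log2(sweep(pmax(m$pfm, 1e-6), 2, m$background, "/")),
           background = setNames(m$background, AA_ALPHABET),
           calibration = NULL),
      class = "domain_profile")
    prof <- calibrate_profile(prof, proteins, n_decoys = n_decoys,
                              seed = seed + m$motif_id)
    for (id in names(proteins)) {
      h <- suppressWarnings(
        scan_protein(prof, setNames(proteins[id], id),
                     evalue_threshold = evalue_threshold,
                     n_db = length(proteins)))
      if (nrow(h))
        out[[length(out) + 1L]] <- data.frame(
          motif_id = m$motif_id, protein_id = h$protein_id,
          start = h$start, end = h$end, score = h$score,
          evalue = h$evalue)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
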