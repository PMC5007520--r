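NUCS <- c("A", "C", "G", "T")

# codon machinery: sense codons, per-codon synonymous site counts, and a
# 64x64 lookup of pathway-averaged (Sd, Nd) per codon pair.  Built once
# and cached.
codon_tables <- function() {
  if (!is.null(.genefam_env$codon_tables)) return(.genefam_env$codon_tables)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  is_stop <- aa == "*"
  ncod <- length(codons)
  cidx <- setNames(seq_len(ncod), codons)

  # synonymous site count per sense codon: per position, the fraction of
  # non-stop single-nucleotide changes that preserve the amino acid
  syn_sites <- rep(NA_real_, ncod)
  neighbors <- vector("list", ncod)
  for (c1 in seq_len(ncod)) {
    if (is_stop[c1]) next
    s <- 0
    nb <- character(0)
    for (pos in 1:3) {
      base <- substr(codons[c1], pos, pos)
      alts <- setdiff(NUCS, base)
      alt_codons <- vapply(alts, function(b) {
        x <- codons[c1]; substr(x, pos, pos) <- b; x
      }, "")
      ok <- !is_stop[cidx[alt_codons]]
      nb <- c(nb, alt_codons[ok])
      if (any(ok))
        s <- s + sum(aa[cidx[alt_codons[ok]]] == aa[c1]) / sum(ok)
    }
    syn_sites[c1] <- s
    neighbors[[c1]] <- nb
  }

  # pathway-averaged observed differences for every sense-codon pair
  Sd <- matrix(NA_real_, ncod, ncod, dimnames = list(codons, codons))
  Nd <- Sd
  for (c1 in seq_len(ncod)) {
    if (is_stop[c1]) next
    for (c2 in seq_len(ncod)) {
      if (is_stop[c2]) next
      diffpos <- which(strsplit(codons[c1], "")[[1]] !=
                       strsplit(codons[c2], "")[[1]])
      d <- length(diffpos)
      if (d == 0L) { Sd[c1, c2] <- 0; Nd[c1, c2] <- 0; next }
      perms <- permutations_of(diffpos)
      stot <- 0; ntot <- 0; nvalid <- 0L
      for (p in seq_len(nrow(perms))) {
        cur <- codons[c1]
        svals <- 0; nvals <- 0
        valid <- TRUE
        for (step in perms[p, ]) {
          nxt <- cur
          substr(nxt, step, step) <- substr(codons[c2], step, step)
          if (is_stop[cidx[nxt]]) { valid <- FALSE; break }
          if (aa[cidx[nxt]] == aa[cidx[cur]]) svals <- svals + 1
          else nvals <- nvals + 1
          cur <- nxt
        }
        if (valid) {
          stot <- stot + svals; ntot <- ntot + nvals
          nvalid <- nvalid + 1L
        }
      }
      if (nvalid > 0L) {
        Sd[c1, c2] <- stot / nvalid
        Nd[c1, c2] <- ntot / nvalid
      }   # else NA: every pathway passes through a stop
    }
  }
  .genefam_env$codon_tables <- list(
    codons = codons, aa = aa, is_stop = is_stop, cidx = cidx,
    syn_sites = syn_sites, neighbors = neighbors, Sd = Sd, Nd = Nd)
  .genefam_env$codon_tables
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Each protein alignment column becomes the corresponding codon triplet
#' (or a `---` gap).  Each CDS must be exactly 3x its ungapped protein
#' length and translate to it.
#'
#' @param protein_alignment character vector of two equal-length gapped
#'   protein sequences.
#' @param cds_a,cds_b in-frame coding sequences (no stop codon).
#' @return List with codon-aligned strings `a` and `b` (class
#'   `"codon_alignment"`).
#' @export
align_codons <- function(protein_alignment, cds_a, cds_b) {
  stopifnot(length(protein_alignment) == 2L)
  pa <- protein_alignment[1]; pb <- protein_alignment[2]
  if (nchar(pa) != nchar(pb)) stop("alignment rows differ in length")
  back_one <- function(prot_aln, cds, label) {
    ungapped <- gsub("-", "", prot_aln)
    if (nchar(cds) != 3L * nchar(ungapped))
      stop("CDS length of ", label, " is not 3x its aligned protein")
    if (translate_cds(cds) != toupper(ungapped))
      stop("CDS of ", label, " does not translate to its protein row")
    codons <- split_codons(toupper(cds))
    cols <- strsplit(prot_aln, "")[[1]]
    out <- character(length(cols))
    ci <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { ci <- ci + 1L; out[i] <- codons[ci] }
    }
    paste(out, collapse = "")
  }
  structure(list(a = back_one(pa, cds_a, "sequence a"),
                 b = back_one(pb, cds_b, "sequence b")),
            class = "codon_alignment")
}

#' Nei-Gojobori Ka and Ks
#'
#' The classical codon-based estimator: synonymous (S) and nonsynonymous
#' (N) site counts per codon come from single-nucleotide-neighbor
#' enumeration under the standard code (changes to stop codons are
#' excluded from the denominators, so S + N = 3 per compared codon);
#' observed differences are averaged over all minimal substitution
#' pathways, discarding pathways through stop codons; and the Jukes-
#' Cantor correction maps the proportions to distances,
#' `Ks = -3/4 ln(1 - 4 pS / 3)` (likewise Ka).
#'
#' @param codon_alignment an [align_codons()] result, or a list with
#'   in-frame aligned codon strings `a` and `b` (gaps as `---`).
#' @return List with `Ka`, `Ks`, `ratio` (`NA` when `Ks` is 0 or
#'   undefined), and `sites` (`S`, `N`, `Sd`, `Nd`, `codons_used`).
#'   `Ka`/`Ks` are `NA` with a flag when a proportion reaches the
#'   Jukes-Cantor singularity (p >= 3/4).
#' @export
nei_gojobori <- function(codon_alignment) {
  tabs <- codon_tables()
  ca <- split_codons(toupper(codon_alignment$a))
  cb <- split_codons(toupper(codon_alignment$b))
  if (length(ca) != length(cb)) stop("codon rows differ in length")
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ix <- unname(tabs$cidx[ca]); iy <- unname(tabs$cidx[cb])
  stops <- clean & (tabs$is_stop[ix] | tabs$is_stop[iy])
  if (any(stops))
    warning("stop codon(s) in alignment column(s) ",
            paste(head(which(stops), 5L), collapse = ", "),
            "; column(s) skipped")
  ok <- clean & !stops
  sd <- rep(NA_real_, length(ca))
  sd[ok] <- tabs$Sd[cbind(ix[ok], iy[ok])]
  blocked <- ok & is.na(sd)
  if (any(blocked))
    warning(sum(blocked),
            " codon pair(s) with no stop-free substitution pathway skipped")
  use <- ok & !blocked
  if (!any(use)) stop("no comparable codons in alignment")
  half_syn <- (tabs$syn_sites[ix[use]] + tabs$syn_sites[iy[use]]) / 2
  S <- sum(half_syn)
  N <- sum(3 - half_syn)
  Sd <- sum(sd[use])
  Nd <- sum(tabs$Nd[cbind(ix[use], iy[use])])
  used <- sum(use)
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  flagged <- is.na(Ks) || is.na(Ka)
  ratio <- if (flagged || Ks == 0) NA_real_ else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio, flagged = flagged,
       sites = c(S = S, N = N, Sd = Sd, Nd = Nd, codons_used = used))
}

#' Selection class from Ka and Ks
#'
#' `Ka/Ks > 1` positive, `= 1` (within 1e-9) neutral, `< 1` purifying;
#' `Ks = 0` leaves the ratio undefined.
#'
#' @param Ka,Ks non-negative substitution rates.
#' @return One of `"positive"`, `"neutral"`, `"purifying"`,
#'   `"undefined"`.
#' @export
classify_selection <- function(Ka, Ks) {
  if (is.na(Ka) || is.na(Ks)) return("undefined")
  if (Ka < 0 || Ks < 0) stop("Ka and Ks must be non-negative")
  if (Ks == 0) return("undefined")
  ratio <- Ka / Ks
  if (abs(ratio - 1) < 1e-9) "neutral"
  else if (ratio > 1) "positive"
  else "purifying"
}

#' Date a duplication event from Ks
#'
#' `T = Ks / (2 r)`, reported in million years; the default neutral rate
#' is `r = 2.6e-9` substitutions per site per year.
#'
#' @param Ks synonymous distance (substitutions/site, >= 0).
#' @param r neutral substitution rate per site per year (> 0).
#' @return Estimated duplication date in Mya.
#' @examples
#' date_duplication(0.0052)  # 1 Mya
#' @export
date_duplication <- function(Ks, r = 2.6e-9) {
  if (any(r <= 0)) stop("neutral rate r must be > 0")
  if (any(Ks < 0, na.rm = TRUE)) stop("Ks must be >= 0")
  Ks / (2 * r) / 1e6
}

#' Ka/Ks, selection class and date for paralogous gene pairs
#'
#' For each gene pair: global protein alignment ([align_pair()]),
#' protein-guided codon back-translation ([align_codons()]),
#' Nei-Gojobori estimation, selection classification and dating.  Pairs
#' whose Jukes-Cantor correction is undefined are flagged and excluded
#' from dating.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (or
#'   `query_id`/`subject_id`).
#' @param proteins,cds named character vectors covering all genes in
#'   `pairs`.
#' @param r neutral substitution rate for dating.
#' @return data.frame with `gene_a`, `gene_b`, `Ka`, `Ks`, `ratio`,
#'   `selection_class`, `T_mya`.
#' @export
analyze_paralog_pairs <- function(pairs, proteins, cds, r = 2.6e-9) {
  if (!is.null(pairs$query_id) && is.null(pairs$gene_a)) {
    pairs$gene_a <- pairs$query_id
    pairs$gene_b <- pairs$subject_id
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    al <- align_pair(proteins[[a]], proteins[[b]])
    cal <- align_codons(al$alignment, cds[[a]], cds[[b]])
    ng <- suppressWarnings(nei_gojobori(cal))
    cls <- classify_selection(ng$Ka, ng$Ks)
    out[[i]] <- data.frame(
      gene_a = a, gene_b = b, Ka = ng$Ka, Ks = ng$Ks, ratio = ng$ratio,
      selection_class = cls,
      T_mya = if (ng$flagged || is.na(ng$Ks)) NA_real_
              else date_duplication(ng$Ks, r))
  }
  do.call(rbind, out)
}
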