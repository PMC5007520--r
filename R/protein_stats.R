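# Average residue masses (Da) for the 20 standard amino acids, as used by
# the common proteomics calculators; a protein's MW is the sum of residue
# masses plus one water (18.015).
RESIDUE_MASS <- c(
  A = 71.079,  R = 156.188, N = 114.104, D = 115.089, C = 103.145,
  E = 129.116, Q = 128.131, G = 57.052,  H = 137.141, I = 113.160,
  L = 113.160, K = 128.175, M = 131.199, F = 147.177, P = 97.117,
  S = 87.078,  T = 101.105, W = 186.213, Y = 163.176, V = 99.133)
WATER_MASS <- 18.015

# Ionizable-group pKa values (EMBOSS set); positive groups carry +1 below
# their pKa, negative groups -1 above theirs.
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Protein length, molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' `X` contributes the mean of the 20 standard residue masses and is
#' excluded from the charge model.  The isoelectric point is the pH at
#' which the Henderson-Hasselbalch net charge (EMBOSS pKa set, including
#' the two termini) vanishes, solved by bisection to |charge| < 1e-4.
#'
#' @param sequence amino-acid string over the 20-letter alphabet plus X.
#' @return List with `length`, `molecular_weight` (Da) and
#'   `isoelectric_point` (pH units).
#' @examples
#' compute_protein_stats("GGG")$molecular_weight  # 189.171
#' @export
compute_protein_stats <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, c(names(RESIDUE_MASS), "X"))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  mw <- sum(ifelse(res == "X", mean(RESIDUE_MASS), RESIDUE_MASS[res])) +
    WATER_MASS
  counts <- table(factor(res, levels = names(RESIDUE_MASS)))
  list(length = length(res),
       molecular_weight = mw,
       isoelectric_point = solve_pi(counts))
}

#' Net protein charge at a given pH
#'
#' @param counts named counts of the 20 standard residues (termini are
#'   always included once each).
#' @param ph pH at which to evaluate the charge.
#' @return Net charge in elementary units.
#' @export
protein_charge <- function(counts, ph) {
  npos <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
            H = unname(counts["H"]))
  nneg <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
            C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos <- sum(npos / (1 + 10 ^ (ph - PKA_POS[names(npos)])))
  neg <- sum(nneg / (1 + 10 ^ (PKA_NEG[names(nneg)] - ph)))
  pos - neg
}

solve_pi <- function(counts, tol = 1e-4) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- protein_charge(counts, mid)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}
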