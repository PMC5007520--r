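# BLOSUM62 over the 20 standard residues, cached from Biostrings
blosum62 <- function() {
  if (is.null(.genefam_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .genefam_env$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .genefam_env$blosum62
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gap penalties via
#' [Biostrings::pairwiseAlignment()] (BLOSUM62; a gap of length L costs
#' `gap_open + gap_extend * L`).  This is the pairwise primitive whose
#' scoring scheme the progressive aligner [build_msa()] shares.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param substitution_matrix numeric substitution matrix; default
#'   BLOSUM62.
#' @return List with `alignment` (two gapped strings) and `score`.
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 0.5,
                       substitution_matrix = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(alignment = c(as.character(Biostrings::pattern(pa)),
                     as.character(Biostrings::subject(pa))),
       score = Biostrings::score(pa))
}

# residue-frequency profile (20 x L) of a character matrix of gapped rows;
# gaps and non-standard residues contribute zero frequency
profile_freq <- function(mat) {
  L <- ncol(mat)
  f <- matrix(0, 20, L, dimnames = list(AA_ALPHABET, NULL))
  n <- nrow(mat)
  for (j in seq_len(L)) {
    tab <- tabulate(match(mat[, j], AA_ALPHABET), nbins = 20)
    f[, j] <- tab / n
  }
  f
}

# affine-gap global profile-profile alignment; returns for each output
# column which input columns (or gaps) it consumes.  Vectorized by row:
# the within-row gap state uses the cummax identity
#   Iy[i,j] = -open - ext*j + max_{k<j} (M[i,k] + ext*k).
profile_align <- function(fa, fb, gap_open = 10, gap_extend = 0.5) {
  S <- blosum62()
  La <- ncol(fa); Lb <- ncol(fb)
  CS <- t(fa) %*% S %*% fb                     # column-score matrix
  NEG <- -1e18
  M  <- matrix(NEG, La + 1L, Lb + 1L)
  Ix <- matrix(NEG, La + 1L, Lb + 1L)          # gap in B (consume A row)
  Iy <- matrix(NEG, La + 1L, Lb + 1L)          # gap in A (consume B col)
  M[1, 1] <- 0
  j <- seq_len(Lb)
  Iy[1, j + 1L] <- -gap_open - gap_extend * j
  i <- seq_len(La)
  Ix[i + 1L, 1] <- -gap_open - gap_extend * i
  ext_j <- gap_extend * (0:Lb)
  for (ii in seq_len(La)) {
    pM <- M[ii, ]; pX <- Ix[ii, ]; pY <- Iy[ii, ]
    diag_best <- pmax(pM[j], pX[j], pY[j])
    M[ii + 1L, j + 1L] <- CS[ii, ] + diag_best
    Ix[ii + 1L, j + 1L] <- pmax(pM[j + 1L] - gap_open - gap_extend,
                                pX[j + 1L] - gap_extend)
    run <- cummax(M[ii + 1L, ] + ext_j)
    Iy[ii + 1L, j + 1L] <- -gap_open - ext_j[j + 1L] + run[j]
  }
  # traceback by recomputation
  tol <- 1e-9
  ii <- La + 1L; jj <- Lb + 1L
  fin <- c(M[ii, jj], Ix[ii, jj], Iy[ii, jj])
  state <- which.max(fin)
  opsA <- integer(0); opsB <- integer(0)       # input column or 0 for gap
  while (ii > 1L || jj > 1L) {
    if (state == 1L) {
      opsA <- c(ii - 1L, opsA); opsB <- c(jj - 1L, opsB)
      prev <- c(M[ii - 1L, jj - 1L], Ix[ii - 1L, jj - 1L],
                Iy[ii - 1L, jj - 1L])
      target <- M[ii, jj] - CS[ii - 1L, jj - 1L]
      state <- which(abs(prev - target) < tol)[1L]
      ii <- ii - 1L; jj <- jj - 1L
    } else if (state == 2L) {
      opsA <- c(ii - 1L, opsA); opsB <- c(0L, opsB)
      from_m <- M[ii - 1L, jj] - gap_open - gap_extend
      state <- if (abs(Ix[ii, jj] - from_m) < tol) 1L else 2L
      ii <- ii - 1L
    } else {
      opsA <- c(0L, opsA); opsB <- c(jj - 1L, opsB)
      from_m <- M[ii, jj - 1L] - gap_open - gap_extend
      state <- if (abs(Iy[ii, jj] - from_m) < tol) 1L else 3L
      jj <- jj - 1L
    }
  }
  list(opsA = opsA, opsB = opsB,
       score = max(fin))
}

# expand a gapped row matrix according to alignment ops (0 = new gap)
expand_rows <- function(mat, ops) {
  out <- matrix("-", nrow(mat), length(ops),
                dimnames = list(rownames(mat), NULL))
  nz <- ops != 0L
  out[, nz] <- mat[, ops[nz], drop = FALSE]
  out
}

# 3-mer composition distance between ungapped sequences, for guide trees
kmer_distance <- function(sequences, k = 3L) {
  n <- length(sequences)
  km <- lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- table(km[[i]]); tj <- table(km[[j]])
    shared <- sum(pmin(ti[names(tj)], tj), na.rm = TRUE)
    denom <- min(length(km[[i]]), length(km[[j]]))
    d <- if (denom == 0L) 1 else 1 - shared / denom
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively along a neighbor-joining guide
#' tree of 3-mer composition distances: sequences are merged into profiles
#' by affine-gap profile-profile alignment (BLOSUM62, gap open 10 /
#' extend 0.5, the classic defaults).  No iterative refinement is
#' performed.
#'
#' @param sequences named character vector of >= 2 protein sequences.
#' @param gap_open,gap_extend affine gap penalties.
#' @return Object of class `"multiple_alignment"`: list with `ids`,
#'   `rows` (named character vector of equal-length gapped sequences) and
#'   `n_columns`.
#' @export
build_msa <- function(sequences, gap_open = 10, gap_extend = 0.5) {
  n <- length(sequences)
  if (n < 2L) stop("need >= 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("sequences must be non-empty")

  profiles <- lapply(names(sequences), function(id)
    matrix(strsplit(sequences[[id]], "")[[1]], nrow = 1,
           dimnames = list(id, NULL)))
  if (n == 2L) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]],
                             gap_open, gap_extend)
  } else {
    D <- kmer_distance(sequences)
    guide <- nj_tree(D)
    merged <- merge_along_tree(guide, profiles, names(sequences),
                               gap_open, gap_extend)
  }
  rows <- apply(merged, 1L, paste, collapse = "")
  rows <- rows[names(sequences)]               # input order
  structure(list(ids = names(sequences), rows = rows,
                 n_columns = ncol(merged)),
            class = "multiple_alignment")
}

merge_profiles <- function(A, B, gap_open, gap_extend) {
  al <- profile_align(profile_freq(A), profile_freq(B),
                      gap_open, gap_extend)
  rbind(expand_rows(A, al$opsA), expand_rows(B, al$opsB))
}

# post-order traversal of the (possibly trifurcating) guide tree,
# merging child profiles pairwise
merge_along_tree <- function(tree, profiles, ids, gap_open, gap_extend) {
  ntip <- length(tree$tip.label)
  prof_of <- function(node) {
    if (node <= ntip) {
      profiles[[match(tree$tip.label[node], ids)]]
    } else {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      acc <- prof_of(kids[1])
      for (k in kids[-1])
        acc <- merge_profiles(acc, prof_of(k), gap_open, gap_extend)
      acc
    }
  }
  root <- ntip + 1L
  prof_of(root)
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

as_alignment_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Poisson-corrected evolutionary distances from an alignment
#'
#' For each sequence pair, columns gapped in either row are ignored;
#' p = mismatches / compared sites and d = -ln(1 - p) (Poisson
#' correction).  Pairs with p >= 0.95 are capped at d = 3.0 with a
#' warning; a pair with no comparable sites is an error.
#'
#' @param msa a [build_msa()] result (or any list with `rows`).
#' @return Symmetric numeric distance matrix (substitutions/site).
#' @export
protein_distance <- function(msa) {
  mat <- as_alignment_matrix(msa)
  ids <- msa$ids
  n <- nrow(mat)
  isgap <- mat == "-" | mat == "."
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !isgap[i, ] & !isgap[j, ]
    m <- sum(ok)
    if (m == 0L)
      stop("no comparable sites between ", ids[i], " and ", ids[j])
    p <- sum(mat[i, ok] != mat[j, ok]) / m
    if (p >= 0.95) {
      warning("pair ", ids[i], "/", ids[j],
              " beyond Poisson correction range; distance capped at 3")
      d <- 3.0
    } else {
      d <- -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Information content of an alignment column
#'
#' `log2(20)` minus the Shannon entropy of the residue frequencies in the
#' column (gaps excluded, no small-sample correction) -- the stack height
#' of a sequence logo.
#'
#' @param column character vector of residues/gaps (one alignment column).
#' @return Information content in bits, in `[0, log2(20)]`; an all-gap
#'   column returns `NA` with a warning.
#' @export
column_information <- function(column) {
  res <- column[column %in% AA_ALPHABET]
  if (length(res) == 0L) {
    warning("all-gap column: information content undefined")
    return(NA_real_)
  }
  f <- tabulate(match(res, AA_ALPHABET), nbins = 20) / length(res)
  f <- f[f > 0]
  log2(20) + sum(f * log2(f))
}

#' Per-column logo data for an alignment
#'
#' @param msa a [build_msa()] result.
#' @return data.frame with `position`, `residue`, `height` (bits), the
#'   usual sequence-logo table: height = column IC * residue frequency.
#' @export
logo_data <- function(msa) {
  mat <- as_alignment_matrix(msa)
  out <- list()
  for (j in seq_len(ncol(mat))) {
    res <- mat[, j][mat[, j] %in% AA_ALPHABET]
    if (!length(res)) next
    ic <- column_information(mat[, j])
    f <- table(res) / length(res)
    out[[length(out) + 1L]] <- data.frame(
      position = j, residue = names(f),
      height = as.numeric(f) * ic)
  }
  do.call(rbind, out)
}
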