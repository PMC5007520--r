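# Independent oracles used by the test suite.  These deliberately share no
# code with the package implementations they check.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# --- genetic-code oracle (independent of the package's cached tables)
.gc <- Biostrings::GENETIC_CODE
.sense <- names(.gc)[.gc != "*"]

# brute-force synonymous site count of one codon: per position, fraction
# of the non-stop single-nucleotide changes that are synonymous
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A","C","G","T"), substr(codon, pos, pos))
    alt_cod <- sapply(alts, function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    })
    nonstop <- alt_cod[.gc[alt_cod] != "*"]
    if (length(nonstop))
      s <- s + mean(.gc[nonstop] == .gc[codon])
  }
  s
}

# brute-force pathway-averaged (Sd, Nd) between two sense codons:
# enumerate all orderings of the differing positions, drop orderings that
# pass through a stop codon, average syn/nonsyn step counts
oracle_pair_diffs <- function(c1, c2) {
  dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dp)) return(c(Sd = 0, Nd = 0))
  perm_list <- if (length(dp) == 1) list(dp) else {
    if (length(dp) == 2) list(dp, rev(dp)) else {
      out <- list()
      for (a in dp) for (b in setdiff(dp, a))
        out[[length(out) + 1]] <- c(a, b, setdiff(dp, c(a, b)))
      out
    }
  }
  tot_s <- 0; tot_n <- 0; nv <- 0
  for (perm in perm_list) {
    cur <- c1; s <- 0; n <- 0; good <- TRUE
    for (pos in perm) {
      nxt <- cur; substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (.gc[nxt] == "*") { good <- FALSE; break }
      if (.gc[nxt] == .gc[cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (good) { tot_s <- tot_s + s; tot_n <- tot_n + n; nv <- nv + 1 }
  }
  if (nv == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = tot_s / nv, Nd = tot_n / nv)
}

# --- tandem-cluster oracle: explicit pair graph + connected components
oracle_tandem_clusters <- function(chrom, start, ids, window) {
  n <- length(ids)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        abs(start[i] - start[j]) <= window) {
      ri <- findp(i); rj <- findp(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), findp, 1L)
  out <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) >= 2)
      out[[length(out) + 1]] <-
        sort(ids[members])
  }
  out[order(vapply(out, `[`, "", 1))]
}

# --- exhaustive chain oracle: longest valid anchor chain (either
# orientation) by depth-first enumeration; anchors as (rank_a, rank_b)
oracle_longest_chain <- function(ra, rb, gap) {
  n <- length(ra)
  best <- 0
  for (orient in c(1, -1)) {
    rbo <- orient * rb
    extend <- function(last, used, len) {
      best <<- max(best, len)
      for (k in seq_len(n)) {
        if (used[k]) next
        if (last == 0 ||
            (ra[k] > ra[last] && rbo[k] > rbo[last] &&
             ra[k] - ra[last] - 1 <= gap &&
             rbo[k] - rbo[last] - 1 <= gap)) {
          used[k] <- TRUE
          extend(k, used, len + 1)
          used[k] <- FALSE
        }
      }
    }
    extend(0, rep(FALSE, n), 0)
  }
  best
}

# --- brute-force global alignment score with affine gaps: enumerate
# every alignment as an op string (M = pair, D = gap in b, I = gap in a)
# and score it from scratch; a gap run of length L costs open + ext * L.
# Exponential -- only for short sequences.
oracle_global_score <- function(a, b, open = 10, ext = 0.5, S = NULL) {
  if (is.null(S)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    S <- e$BLOSUM62
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  score_ops <- function(ops) {
    i <- 0; j <- 0; sc <- 0
    run <- ""     # current gap-run type
    for (op in ops) {
      if (op == "M") {
        i <- i + 1; j <- j + 1
        sc <- sc + S[av[i], bv[j]]
        run <- ""
      } else {
        if (op != run) sc <- sc - open
        sc <- sc - ext
        run <- op
        if (op == "D") i <- i + 1 else j <- j + 1
      }
    }
    sc
  }
  best <- -Inf
  enum <- function(i, j, ops) {
    if (i == length(av) && j == length(bv)) {
      best <<- max(best, score_ops(ops))
      return(invisible())
    }
    if (i < length(av) && j < length(bv)) enum(i + 1, j + 1, c(ops, "M"))
    if (i < length(av)) enum(i + 1, j, c(ops, "D"))
    if (j < length(bv)) enum(i, j + 1, c(ops, "I"))
  }
  enum(0, 0, character(0))
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# random protein helper
rand_prot <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

# diverged copies of a consensus (independent of the package generator)
diverge <- function(seq, p) {
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < p
  v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1), "")
  paste(v, collapse = "")
}

# small shared fixture: a calibrated consensus profile (built once per
# test run; calibration is the expensive step)
shared_profile <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) {
      set.seed(4242)
      aln <- replicate(10, diverge(default_domain_consensus(), 0.1))
      p <- build_profile(aln)
      prof <<- calibrate_profile(p, n_decoys = 4000, seed = 4242)
    }
    prof
  }
})
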