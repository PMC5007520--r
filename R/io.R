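#' Gene model
#'
#' A light container for one gene: chromosome placement, strand, exon
#' coordinates and (optionally) the coding sequence.  All coordinates are
#' 1-based and inclusive, the GFF3 convention; the CDS is always stored
#' 5'->3' on the coding strand so that codon-level analyses can use it
#' directly.
#'
#' @param gene_id character scalar, unique gene identifier.
#' @param chromosome character scalar.
#' @param start,end 1-based inclusive gene span, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon coordinates.
#' @param cds_sequence coding sequence over ACGTN, or `NA` when unknown.
#'
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chromosome, start, end, strand,
                       exons, cds_sequence = NA_character_) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  gm <- structure(
    list(gene_id = as.character(gene_id),
         chromosome = as.character(chromosome),
         start = as.numeric(start), end = as.numeric(end),
         strand = as.character(strand),
         exons = exons,
         cds_sequence = toupper(as.character(cds_sequence))),
    class = "gene_model")
  validate_gene_model(gm)
  gm
}

#' Validate a gene model
#'
#' Checks the structural invariants: strand in `{+,-}`, exons sorted by
#' start, pairwise non-overlapping and inside the gene span, and -- when a
#' CDS is present -- length a multiple of three with no internal stop codon
#' in frame 1.
#'
#' @param gm a [gene_model()].
#' @return `gm`, invisibly; errors describe the first violated invariant.
#' @export
validate_gene_model <- function(gm) {
  if (!gm$strand %in% c("+", "-"))
    stop("gene ", gm$gene_id, ": unknown strand symbol '", gm$strand, "'")
  if (gm$end < gm$start)
    stop("gene ", gm$gene_id, ": end < start")
  ex <- gm$exons
  if (nrow(ex) == 0L) stop("gene ", gm$gene_id, ": no exons")
  if (is.unsorted(ex[, 1], strictly = FALSE))
    stop("gene ", gm$gene_id, ": exons not sorted by start")
  if (any(ex[, 2] < ex[, 1]))
    stop("gene ", gm$gene_id, ": exon with end < start")
  if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
    stop("gene ", gm$gene_id, ": overlapping exons")
  if (any(ex[, 1] < gm$start | ex[, 2] > gm$end))
    stop("gene ", gm$gene_id, ": exon outside gene span")
  cds <- gm$cds_sequence
  if (!is.na(cds) && nzchar(cds)) {
    if (grepl("[^ACGTN]", cds))
      stop("gene ", gm$gene_id, ": CDS contains non-ACGTN characters")
    if (nchar(cds) %% 3L != 0L)
      stop("gene ", gm$gene_id, ": CDS length not a multiple of 3")
    aa <- translate_cds(cds)
    if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
      stop("gene ", gm$gene_id, ": internal stop codon in CDS")
  }
  invisible(gm)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)%s\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons),
              if (is.na(x$cds_sequence)) "" else
                sprintf(", CDS %d nt", nchar(x$cds_sequence))))
  invisible(x)
}

# translate a CDS in frame 1 (standard code); N-containing codons -> X
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] with the pipeline's contract:
#' sequences are uppercased, identifiers are the first whitespace-delimited
#' header token and must be unique, record order is preserved, and an empty
#' file yields an empty result with a warning.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return Named character vector of sequences, names = record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) into a list of
#' [gene_model()]s.  Exons are taken from the first mRNA of each gene (in
#' file order) and sorted by start; when a genome is supplied the CDS
#' features are stitched in transcription order and reverse-complemented on
#' the minus strand, so `cds_sequence` is always the 5'->3' coding strand.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features, 1-based
#'   inclusive coordinates.
#' @param genome optional named character vector (or
#'   [Biostrings::DNAStringSet]) of chromosome sequences used to extract
#'   CDS sequences.
#' @return Named list of `gene_model` objects, in file order of the genes.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(genome) && !is.character(genome))
    genome <- setNames(as.character(genome), names(genome))
  type   <- as.character(gr$type)
  id     <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  chrom  <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr)
  ends   <- GenomicRanges::end(gr)

  gi <- which(type == "gene")
  out <- vector("list", length(gi))
  names(out) <- id[gi]
  for (k in seq_along(gi)) {
    g <- gi[k]
    if (!strand[g] %in% c("+", "-"))
      stop("gene ", id[g], ": unknown strand symbol '", strand[g], "'")
    mr <- which(type == "mRNA" & parent == id[g])
    if (length(mr) == 0L)
      stop("gene ", id[g], ": no mRNA feature")
    tr <- id[mr[1L]]  # first mRNA in file order
    exi <- which(type == "exon" & parent == tr)
    if (length(exi) == 0L)
      stop("gene ", id[g], ": mRNA ", tr, " has no exons")
    exi <- exi[order(starts[exi])]
    exons <- cbind(start = starts[exi], end = ends[exi])
    cds_seq <- NA_character_
    cdi <- which(type == "CDS" & parent == tr)
    if (length(cdi) && !is.null(genome)) {
      chrseq <- genome[[chrom[g]]]
      if (is.null(chrseq)) stop("chromosome ", chrom[g], " not in genome")
      cdi <- cdi[order(starts[cdi])]
      pieces <- substring(chrseq, starts[cdi], ends[cdi])
      cds_seq <- paste(pieces, collapse = "")
      if (strand[g] == "-") cds_seq <- revcomp(cds_seq)
    }
    out[[k]] <- gene_model(id[g], chrom[g], starts[g], ends[g], strand[g],
                           exons, cds_seq)
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS lines (one mRNA per gene; CDS features mirror
#' the exons, the convention of the synthetic genomes this package builds).
#'
#' @param genes list of [gene_model()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in genes) {
    tr <- paste0(gm$gene_id, ".t1")
    lines <- c(
      gff_line(gm$chromosome, "gene", gm$start, gm$end, gm$strand,
               paste0("ID=", gm$gene_id)),
      gff_line(gm$chromosome, "mRNA", gm$start, gm$end, gm$strand,
               paste0("ID=", tr, ";Parent=", gm$gene_id)))
    for (i in seq_len(nrow(gm$exons))) {
      lines <- c(lines,
        gff_line(gm$chromosome, "exon", gm$exons[i, 1], gm$exons[i, 2],
                 gm$strand, paste0("Parent=", tr)),
        gff_line(gm$chromosome, "CDS", gm$exons[i, 1], gm$exons[i, 2],
                 gm$strand, paste0("Parent=", tr)))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "genefam", type, format(start, scientific = FALSE),
        format(end, scientific = FALSE), ".", strand,
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a gene-by-condition expression table
#'
#' TSV with gene ids in the first column and condition ids in the header.
#' Values must be numeric and non-negative; gene and condition ids must be
#' unique.
#'
#' @param path TSV file path.
#' @return Numeric matrix, rownames = gene ids, colnames = condition ids.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs >= 1 condition column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  conds <- colnames(df)[-1L]
  if (anyDuplicated(conds)) stop("duplicated condition id(s)")
  vals <- matrix(NA_real_, nrow(df), length(conds),
                 dimnames = list(ids, conds))
  for (j in seq_along(conds)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(col))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1L], conds[j]))
    if (any(num < 0))
      stop(sprintf("negative value at row %d, column '%s'",
                   which(num < 0)[1L], conds[j]))
    vals[, j] <- num
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param id_column header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Takes 1-based inclusive coordinates (the convention used throughout
#' this package) and writes standard 0-based half-open BED records; the
#' conversion is handled here so callers never shift coordinates
#' themselves.
#'
#' @param intervals data.frame with `chromosome`, `start`, `end`
#'   (1-based inclusive) and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) intervals$name else
    rep(".", nrow(intervals))
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chromosome,
                   as.integer(intervals$start) - 1L,
                   as.integer(intervals$end), nm)
  writeLines(lines, path)
  invisible(path)
}

#' BED-style interval tables for tandem clusters and collinear blocks
#'
#' @param clusters [detect_tandem_clusters()] output.
#' @param blocks [chain_collinear_blocks()] output.
#' @param genes named list of [gene_model()]s covering all member genes.
#' @return data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive) and `name`, ready for [write_bed()].
#' @export
tandem_intervals <- function(clusters, genes) {
  if (!length(clusters))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    sp <- vapply(cl$gene_ids, function(id)
      c(genes[[id]]$start, genes[[id]]$end), c(1, 1))
    data.frame(chromosome = cl$chromosome, start = min(sp), end = max(sp),
               name = sprintf("tandem_%d", i))
  }))
}

#' @rdname tandem_intervals
#' @export
block_intervals <- function(blocks, genes) {
  if (!length(blocks))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    span <- function(ids, chrom) {
      sp <- vapply(ids, function(id)
        c(genes[[id]]$start, genes[[id]]$end), c(1, 1))
      data.frame(chromosome = chrom, start = min(sp), end = max(sp),
                 name = sprintf("block_%d", i))
    }
    rbind(span(b$anchors$gene_a, b$chromosomes[1]),
          span(b$anchors$gene_b, b$chromosomes[2]))
  }))
}

#' Write a tree in Newick format
#'
#' Thin wrapper over [ape::write.tree()]; bootstrap supports stored as
#' node labels travel with the tree.
#'
#' @param tree a `"phylo"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Percentage summary in the "x of y" style
#'
#' `100 * part / whole`, rounded half-up to one decimal -- the convention
#' used by the pipeline's logged summaries (e.g. 50 of 73 -> 68.5).
#'
#' @param part,whole non-negative integer counts, `part <= whole`,
#'   `whole > 0`.
#' @return Percentage rounded half-up to one decimal.
#' @examples
#' summarize_counts(74, 82)  # 90.2
#' @export
summarize_counts <- function(part, whole) {
  if (!is.numeric(part) || !is.numeric(whole))
    stop("part and whole must be numeric counts")
  if (whole <= 0) stop("whole must be > 0")
  if (part < 0 || part > whole) stop("need 0 <= part <= whole")
  x <- 100 * part / whole
  # round half-up to one decimal (base round() is round-half-even)
  floor(x * 10 + 0.5 + 1e-9) / 10
}
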