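#' Collapse an alignment into a haplotype table
#'
#' Groups identical sequences (after upper-casing) into haplotypes and
#' partitions their counts by deme. Input must be phased and unambiguous:
#' IUPAC ambiguity codes raise an error. Alignment columns containing
#' non-ACGT symbols (gaps, missing data) are excluded from downstream
#' distance and site statistics and recorded in the table.
#'
#' @param alignment named character vector of equal-length sequences (or a
#'   character matrix with rownames).
#' @param demeMap data.frame with columns \code{sample_id}, \code{deme}.
#' @return a \linkS4class{HaplotypeTable}; haplotypes are named H1, H2, ...
#'   in order of decreasing total count (ties by first occurrence).
#' @examples
#' aln <- c(a = "ACGT", b = "ACGT", c = "ACGA")
#' dm <- data.frame(sample_id = c("a", "b", "c"), deme = "F")
#' collapseHaplotypes(aln, dm)
#' @export
collapseHaplotypes <- function(alignment, demeMap) {
  aln <- asAlignmentMatrix(alignment)
  aln[] <- toupper(aln)
  amb <- setdiff(unique(as.vector(aln)), c("A", "C", "G", "T", "-", "N"))
  if (length(amb))
    stop("IUPAC ambiguity code(s) ", paste(amb, collapse = ", "),
         " present: input must be phased/resolved before analysis")
  missing <- setdiff(rownames(aln), demeMap$sample_id)
  if (length(missing))
    stop("sequence id(s) missing from deme map: ",
         paste(missing, collapse = ", "))
  demes <- unique(demeMap$deme)
  dm <- stats::setNames(demeMap$deme, demeMap$sample_id)
  seqs <- apply(aln, 1, paste, collapse = "")
  keep <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  excluded <- which(!keep)
  uniq <- unique(seqs)
  counts <- matrix(0L, length(uniq), length(demes),
                   dimnames = list(NULL, demes))
  hidx <- match(seqs, uniq)
  didx <- match(dm[rownames(aln)], demes)
  for (i in seq_along(seqs))
    counts[hidx[i], didx[i]] <- counts[hidx[i], didx[i]] + 1L
  ord <- order(-rowSums(counts), seq_along(uniq))
  counts <- counts[ord, , drop = FALSE]
  uniq <- uniq[ord]
  names(uniq) <- rownames(counts) <- paste0("H", seq_along(uniq))
  new("HaplotypeTable", sequences = uniq, counts = counts,
      locusLength = ncol(aln), excludedColumns = as.integer(excluded))
}

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes, %d sequences, %d demes (%s), L = %d\n",
              nrow(object@counts), sum(object@counts), ncol(object@counts),
              paste(colnames(object@counts), collapse = "/"),
              object@locusLength))
  if (length(object@excludedColumns))
    cat(sprintf("  %d column(s) with non-ACGT symbols excluded from statistics\n",
                length(object@excludedColumns)))
})

#' Per-deme haplotype counts
#' @param table a \linkS4class{HaplotypeTable}.
#' @return integer matrix haplotype x deme.
#' @export
haplotypeCounts <- function(table) table@counts

#' Haplotype sequences
#' @param table a \linkS4class{HaplotypeTable}.
#' @return named character vector.
#' @export
haplotypeSequences <- function(table) table@sequences

#' Nei's unbiased haplotype diversity
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} for haplotype
#' frequencies \eqn{p_i}: the small-sample-corrected probability that two
#' randomly drawn sequences carry different haplotypes.
#'
#' @param counts vector of haplotype counts (one deme or pooled).
#' @return h in [0, 1].
#' @examples
#' haplotypeDiversity(c(3, 1)) # 0.5
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity is undefined for n < 2")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

## Pairwise Hamming distances between haplotype sequences over the retained
## (all-ACGT) columns.
haplotypeDistances <- function(table) {
  seqs <- table@sequences
  m <- do.call(rbind, strsplit(seqs, ""))
  if (length(table@excludedColumns))
    m <- m[, -table@excludedColumns, drop = FALSE]
  nh <- length(seqs)
  d <- matrix(0L, nh, nh, dimnames = list(names(seqs), names(seqs)))
  if (nh > 1)
    for (i in seq_len(nh - 1)) for (j in (i + 1):nh)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' Nucleotide diversity per site
#'
#' Mean pairwise Hamming distance among all sequence pairs (with haplotype
#' multiplicities) divided by the locus length; computed over the retained
#' all-ACGT columns.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param deme optional deme label to restrict to; default pooled.
#' @return numeric per-site diversity.
#' @export
nucleotideDiversity <- function(table, deme = NULL) {
  counts <- if (is.null(deme)) rowSums(table@counts)
            else table@counts[, deme]
  n <- sum(counts)
  if (n < 2) stop("nucleotide diversity is undefined for n < 2")
  d <- haplotypeDistances(table)
  L <- table@locusLength - length(table@excludedColumns)
  tot <- 0
  for (i in seq_along(counts)) for (j in seq_along(counts)) {
    if (j > i) tot <- tot + counts[i] * counts[j] * d[i, j]
  }
  unname(tot / (n * (n - 1) / 2) / L)
}

#' Classify segregating sites
#'
#' A variable alignment column is parsimony-informative when at least two
#' distinct bases each occur in at least two sequences; otherwise every
#' variant base occurring in exactly one sequence counts as a singleton
#' mutation. Columns with non-ACGT symbols are excluded.
#'
#' @param alignment named character vector of equal-length sequences or a
#'   character matrix.
#' @return named integer vector \code{c(singleton =, parsimony_informative =)}.
#' @examples
#' classifySegregatingSites(c(a = "AAT", b = "AAT", c = "AAC", d = "GAC"))
#' @export
classifySegregatingSites <- function(alignment) {
  aln <- asAlignmentMatrix(alignment)
  if (nrow(aln) < 2) stop("at least 2 sequences are required")
  aln[] <- toupper(aln)
  singleton <- pi <- 0L
  for (s in seq_len(ncol(aln))) {
    col <- aln[, s]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    tab <- table(col)
    if (length(tab) < 2) next
    if (sum(tab >= 2) >= 2) pi <- pi + 1L
    else singleton <- singleton + sum(tab[-which.max(tab)] == 1L)
  }
  c(singleton = singleton, parsimony_informative = pi)
}
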