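#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j for which the probability of a
#' parsimonious connection between two sequences of length L is at least the
#' given confidence. The probability model is non-homoplasy under uniform
#' placement: j mutations land on j distinct sites of the L-site sequence
#' with probability \eqn{\prod_{i=0}^{j-1}(1 - i/L)}; any repeated hit
#' (including parallel or back mutation) shortens the observable path and
#' breaks parsimony. The limit is capped at L.
#'
#' @param L sequence length in sites.
#' @param confidence required probability of parsimony (default 0.95).
#' @return integer, the maximum number of parsimony steps.
#' @examples
#' connectionLimit(604) # the 95% limit for a 604 bp locus
#' @export
connectionLimit <- function(L, confidence = 0.95) {
  stopifnot(L >= 1, confidence > 0, confidence < 1)
  j <- 1L
  while (j < L && parsimonyProbability(j + 1L, L) >= confidence)
    j <- j + 1L
  j
}

#' Probability that j mutational steps are parsimonious
#'
#' @param j number of mutational steps.
#' @param L sequence length.
#' @return probability that all j mutations hit distinct sites.
#' @export
parsimonyProbability <- function(j, L) {
  if (j <= 1) return(1)
  prod(1 - (seq_len(j - 1)) / L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes in order of increasing Hamming distance. Distance-1
#' pairs are joined directly; a pair at distance d (d <= limit) whose members
#' are still in different components at the start of level d is joined
#' through d-1 inferred intermediate haplotypes of frequency 0. All
#' alternative connections of equal length between components are retained,
#' so the network may contain loops. Pairs beyond the connection limit stay
#' unconnected. Candidate edges at each level are processed in a
#' deterministic order: summed haplotype frequency decreasing, then
#' lexicographic id.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param limit connection limit in steps; default the 95% limit for the
#'   table's retained length.
#' @return a \linkS4class{HaplotypeNetwork}.
#' @examples
#' aln <- c(a = "AAAA", b = "AAAT", c = "AATT", d = "AAAT")
#' dm <- data.frame(sample_id = letters[1:4], deme = c("F", "F", "S", "S"))
#' buildNetwork(collapseHaplotypes(aln, dm))
#' @export
buildNetwork <- function(table, limit = NULL) {
  nh <- length(table@sequences)
  Luse <- table@locusLength - length(table@excludedColumns)
  if (is.null(limit)) limit <- connectionLimit(max(Luse, 1L))
  limit <- as.integer(limit)
  freq <- rowSums(table@counts)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nh, name = names(table@sequences),
                            frequency = as.numeric(freq), inferred = FALSE)
  for (d in colnames(table@counts))
    g <- igraph::set_vertex_attr(g, paste0("n_", d),
                                 value = as.numeric(table@counts[, d]))
  if (nh > 1) {
    dist <- haplotypeDistances(table)
    nInter <- 0L
    for (d in seq_len(limit)) {
      pairs <- which(dist == d & upper.tri(dist), arr.ind = TRUE)
      if (!nrow(pairs)) next
      ord <- order(-(freq[pairs[, 1]] + freq[pairs[, 2]]),
                   rownames(dist)[pairs[, 1]], rownames(dist)[pairs[, 2]])
      pairs <- pairs[ord, , drop = FALSE]
      comp <- igraph::components(g)$membership
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (comp[i] == comp[j]) next # already connected at a shorter level
        if (d == 1L) {
          g <- igraph::add_edges(g, c(names(table@sequences)[i],
                                      names(table@sequences)[j]))
        } else {
          inter <- paste0("i", nInter + seq_len(d - 1L))
          nInter <- nInter + d - 1L
          g <- igraph::add_vertices(g, d - 1L, name = inter,
                                    frequency = 0, inferred = TRUE)
          for (a in colnames(table@counts))
            g <- igraph::set_vertex_attr(g, paste0("n_", a), inter, 0)
          chain <- c(names(table@sequences)[i], inter,
                     names(table@sequences)[j])
          g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)],
                                                    chain[-1])))
        }
      }
    }
  }
  new("HaplotypeNetwork", graph = g, limit = limit,
      demeLabels = colnames(table@counts))
}

setMethod("show", "HaplotypeNetwork", function(object) {
  g <- object@graph
  inf <- sum(igraph::V(g)$inferred)
  cat(sprintf("HaplotypeNetwork: %d sampled + %d inferred haplotypes, %d single-step edges, %d component(s), limit %d steps\n",
              igraph::vcount(g) - inf, inf, igraph::ecount(g),
              igraph::components(g)$no, object@limit))
})

#' Component membership of the sampled haplotypes
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @return named integer vector over sampled haplotypes.
#' @export
networkComponents <- function(network) {
  g <- network@graph
  memb <- igraph::components(g)$membership
  memb[!igraph::V(g)$inferred]
}
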