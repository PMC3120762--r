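#' Read an aligned FASTA file
#'
#' Reads a (possibly line-wrapped, mixed-case) FASTA file of aligned
#' sequences, validates equal lengths and unique ids, and returns a named
#' character vector of upper-case sequences.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaAlignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  if (length(unique(Biostrings::width(ss))) > 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write an aligned FASTA file
#'
#' @param alignment named character vector of sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(alignment, path) {
  ss <- Biostrings::DNAStringSet(alignment)
  names(ss) <- names(alignment)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a sample-to-deme map
#'
#' Reads a tab-separated table with header columns \code{sample_id} and
#' \code{deme}. When an alignment is supplied, ids missing from the map
#' raise an error naming them; map rows absent from the alignment are
#' dropped with a warning.
#'
#' @param path TSV path.
#' @param alignment optional named character vector to validate against.
#' @return data.frame with columns \code{sample_id}, \code{deme}.
#' @export
readDemeMap <- function(path, alignment = NULL) {
  dm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "deme") %in% names(dm)))
    stop("deme map must have columns 'sample_id' and 'deme'")
  dm$sample_id <- as.character(dm$sample_id)
  dm$deme <- as.character(dm$deme)
  if (anyDuplicated(dm$sample_id))
    stop("duplicate sample_id in deme map: ",
         paste(unique(dm$sample_id[duplicated(dm$sample_id)]), collapse = ", "))
  if (!is.null(alignment)) {
    missing <- setdiff(names(alignment), dm$sample_id)
    if (length(missing))
      stop("sequence id(s) missing from deme map: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(dm$sample_id, names(alignment))
    if (length(extra)) {
      warning("deme map sample(s) absent from alignment, ignored: ",
              paste(extra, collapse = ", "))
      dm <- dm[dm$sample_id %in% names(alignment), , drop = FALSE]
    }
  }
  dm
}

## Provenance block stamped into all JSON outputs.
provenance <- function(seed, config = NULL) {
  list(package = "demeflow",
       version = as.character(utils::packageVersion("demeflow")),
       seed = seed,
       config_hash = if (is.null(config)) NULL else
         sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9)
}

#' Write a haplotype network as GraphML
#'
#' Node attributes: \code{name}, \code{frequency}, \code{inferred} and one
#' per-deme count column; edge attribute \code{steps} (always 1: every edge
#' is a single mutational step).
#'
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- network@graph
  if (igraph::ecount(g) > 0)
    igraph::E(g)$steps <- 1L
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
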