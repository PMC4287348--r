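#' Contig lengths from a FASTA file
#'
#' Reads an assembled transcriptome FASTA and returns per-contig lengths in
#' base pairs, keyed by the first whitespace-delimited token of each header.
#'
#' @param path Path to the FASTA file.
#' @return Named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate contig ID: ",
                               ids[duplicated(ids)][1L])
  setNames(Biostrings::width(seqs), ids)
}

.check_lengths <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("contig lengths must be positive integers")
  lengths
}

#' N50 of a set of contig lengths
#'
#' The largest contig length L such that contigs of length >= L together
#' contain at least half the total bases of the assembly.
#'
#' @param lengths Numeric vector of contig lengths (>= 1 bp each).
#' @return The N50 length in bp.
#' @export
n50 <- function(lengths) {
  lengths <- .check_lengths(lengths)
  ls <- sort(unname(as.numeric(lengths)), decreasing = TRUE)
  cum <- cumsum(ls)
  ls[which(cum >= sum(ls) / 2)[1L]]
}

#' Summary statistics of an assembly's contig lengths
#'
#' @param lengths Numeric vector of contig lengths.
#' @return List with elements `count`, `total_bp`, `n50`, `mean`, `median`.
#'   The median uses the midpoint convention for even counts.
#' @export
length_summary <- function(lengths) {
  lengths <- .check_lengths(lengths)
  list(count = length(lengths),
       total_bp = sum(lengths),
       n50 = n50(lengths),
       mean = mean(lengths),
       median = median(lengths))
}

#' Assembly statistics straight from a FASTA file
#'
#' @param path Path to the FASTA file.
#' @return As [length_summary()].
#' @export
assembly_summary <- function(path) {
  length_summary(read_contig_lengths(path))
}
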