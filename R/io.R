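#' Read a BLAST tabular file and reduce it to best hits
#'
#' Expects the 12-column outfmt-6 dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), tab-separated,
#' with `#`-prefixed comment lines ignored.  Hits above the e-value ceiling
#' are dropped; the remainder is reduced to at most one row per query using
#' a deterministic tie-break chain: highest bit score, then lowest e-value,
#' then highest percent identity, then lexicographically smallest subject.
#'
#' @param path Path to the BLAST tabular file.
#' @param evalue_max E-value ceiling; hits with larger e-values are dropped.
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `e_value`, `bit_score`; at most one row per query.
#' @export
read_best_hits <- function(path, evalue_max = 1e-5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(keep)[which(nf != 12L)[1L]]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 bad, nf[which(nf != 12L)[1L]]))
  }
  if (length(fields) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), e_value = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     percent_identity = as.numeric(m[, 3L]),
                     e_value = as.numeric(m[, 11L]),
                     bit_score = as.numeric(m[, 12L]),
                     stringsAsFactors = FALSE)
  best_hits(hits, evalue_max = evalue_max)
}

#' Best-hit reduction of a hit table
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `e_value`, `bit_score` (possibly several rows per
#'   query).
#' @param evalue_max E-value ceiling applied before reduction.
#' @return One row per surviving query, ordered by query ID.
#' @export
best_hits <- function(hits, evalue_max = 1e-5) {
  hits <- hits[hits$e_value <= evalue_max, , drop = FALSE]
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
               -hits$percent_identity, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a best-hit table as 12-column BLAST tabular
#'
#' Columns not represented in the table (alignment coordinates, mismatches,
#' gap opens) are written as zeros/placeholders so the file round-trips
#' through [read_best_hits()].
#'
#' @param hits Best-hit data frame (see [best_hits()]).
#' @param path Output path.
#' @return `hits`, invisibly.
#' @export
write_best_hits <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    hits$percent_identity, 0L, 0L, 0L, 1L, 1L, 1L, 1L,
                    format(hits$e_value, digits = 10),
                    hits$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(hits)
}

#' Read a transcript-to-GO annotation table
#'
#' Two-column TSV (`transcript_id`, GO ID), one pair per line, aggregated
#' per transcript.  GO IDs must match `GO:` followed by seven digits.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `transcript_id` and `go_id`, one row per
#'   unique pair, of class `atlas_go`.
#' @export
read_go_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L)
    return(go_annotation(data.frame(transcript_id = character(),
                                    go_id = character())))
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(keep)[which(nf < 2L)[1L]]
    stop(sprintf("line %d: expected 2 tab-separated columns", bad))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:2))
  badgo <- !grepl("^GO:\\d{7}$", m[, 2L])
  if (any(badgo)) {
    bad <- which(keep)[which(badgo)[1L]]
    stop(sprintf("line %d: malformed GO ID '%s'", bad, m[which(badgo)[1L], 2L]))
  }
  go_annotation(data.frame(transcript_id = m[, 1L], go_id = m[, 2L],
                           stringsAsFactors = FALSE))
}

#' Construct a validated GO annotation
#'
#' @param df Data frame with columns `transcript_id` and `go_id`.
#' @return The de-duplicated data frame with class `atlas_go`.
#' @export
go_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "go_id") %in% names(df)))
    stop("GO annotation needs columns 'transcript_id' and 'go_id'")
  bad <- !grepl("^GO:\\d{7}$", df$go_id)
  if (any(bad)) stop("malformed GO ID: ", df$go_id[which(bad)[1L]])
  df <- unique(df[, c("transcript_id", "go_id")])
  rownames(df) <- NULL
  class(df) <- c("atlas_go", "data.frame")
  df
}

#' GO terms of one transcript
#' @param annotation An `atlas_go` annotation.
#' @param transcript_id Transcript ID.
#' @return Character vector of GO IDs (possibly empty).
#' @export
go_terms <- function(annotation, transcript_id) {
  annotation$go_id[annotation$transcript_id == transcript_id]
}

#' Write a GO annotation table to TSV
#' @param annotation An `atlas_go` annotation.
#' @param path Output path.
#' @return `annotation`, invisibly.
#' @export
write_go_annotation <- function(annotation, path) {
  write.table(as.data.frame(annotation), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(annotation)
}
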