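#' Default pseudo-organ labels
#'
#' The six morphological regions sampled along the apical-basal axis of a
#' siphonous alga, ordered apical to basal.
#'
#' @export
atlas_organs <- c("apex", "pinnule", "rachis", "frond_base", "stolon",
                  "holdfast")

#' Construct a validated count matrix
#'
#' Bundles an integer transcript-by-sample count matrix with a sample sheet
#' mapping each sample to a pseudo-organ label.
#'
#' @param counts Integer matrix, transcripts in rows (rownames = transcript
#'   IDs), samples in columns (colnames = sample IDs).  All cells must be
#'   finite, non-negative integers.
#' @param sample_sheet Data frame with columns `sample_id` and `organ`,
#'   one row per sample.
#' @param organ_levels Character vector of admissible organ labels, or
#'   `NULL` to accept any label.  Defaults to [atlas_organs].
#' @return An object of class `atlas_counts`: a list with elements
#'   `counts` (integer matrix) and `sample_sheet` (data frame).
#' @export
count_matrix <- function(counts, sample_sheet, organ_levels = atlas_organs) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate transcript ID: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ID: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"  # integer-valued; double avoids overflow
  sample_sheet <- as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "organ") %in% names(sample_sheet)))
    stop("sample sheet needs columns 'sample_id' and 'organ'")
  missing <- setdiff(colnames(counts), sample_sheet$sample_id)
  if (length(missing) > 0L)
    stop("sample missing from sample sheet: ",
         paste(missing, collapse = ", "))
  sample_sheet <- sample_sheet[match(colnames(counts),
                                     sample_sheet$sample_id), , drop = FALSE]
  rownames(sample_sheet) <- NULL
  if (!is.null(organ_levels)) {
    bad_org <- setdiff(sample_sheet$organ, organ_levels)
    if (length(bad_org) > 0L)
      stop("unknown pseudo-organ label: ", paste(bad_org, collapse = ", "))
  }
  structure(list(counts = counts, sample_sheet = sample_sheet),
            class = "atlas_counts")
}

#' @export
print.atlas_counts <- function(x, ...) {
  cat(sprintf("atlas_counts: %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$sample_sheet$organ)),
                            table(x$sample_sheet$organ)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.atlas_counts <- function(x) dim(x$counts)

#' Organ label of each sample, in column order
#' @param cm An `atlas_counts` object.
#' @return Named character vector, one element per sample column.
#' @export
sample_organs <- function(cm) {
  setNames(cm$sample_sheet$organ, cm$sample_sheet$sample_id)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read a transcript count matrix and its sample sheet
#'
#' The count file is a tab-separated table whose header row names the
#' samples and whose first column holds transcript IDs.  The sample sheet
#' is a two-column TSV (`sample_id`, `organ`).  Lines starting with `#`
#' are ignored in both files.  Fractional counts (as produced by
#' expectation-maximization abundance estimators) are rounded half-to-even
#' when `round_counts = TRUE`, otherwise they are an error.
#'
#' @param path Path to the count TSV.
#' @param sheet_path Path to the sample sheet TSV.
#' @param organ_levels Admissible organ labels (`NULL` to accept any).
#' @param round_counts Round fractional counts before validation.
#' @return An `atlas_counts` object; row and column order follow the file.
#' @export
read_count_matrix <- function(path, sheet_path, organ_levels = atlas_organs,
                              round_counts = TRUE) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2L) stop("count matrix needs >= 1 sample column")
  ids <- as.character(tab[[1L]])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric count cells in ", path)
  rownames(counts) <- ids
  if (round_counts) counts <- round(counts)
  sheet <- .read_tsv(sheet_path)
  names(sheet)[1:2] <- c("sample_id", "organ")
  count_matrix(counts, sheet, organ_levels = organ_levels)
}

#' Write a count matrix and sample sheet to TSV
#'
#' @param cm An `atlas_counts` object.
#' @param path Output path for the count TSV.
#' @param sheet_path Output path for the sample sheet TSV (omitted if `NULL`).
#' @return `cm`, invisibly.
#' @export
write_count_matrix <- function(cm, path, sheet_path = NULL) {
  tab <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path))
    write.table(cm$sample_sheet, sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(cm)
}
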