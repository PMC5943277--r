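# Inoculum tracking: define the inoculum-type OTU set from an
# inoculum-only sequencing sample and sum its reads per field sample.
# Reads of these OTUs cannot be split into inoculum-origin and
# indigenous-origin fractions; the combined signal is reported.

#' Define the inoculum-type OTU set
#'
#' All OTUs whose share of the inoculum sample's AM reads exceeds
#' `min_share` are combined into the tracking marker set (with the
#' default `min_share = 0`, every OTU detected in the inoculum sample).
#'
#' @param table an `amf_otu_table` containing the inoculum sample.
#' @param inoculum_sample sample id of the inoculum-only sequencing run.
#' @param min_share detection threshold as a fraction of the inoculum
#'   sample's AM reads.
#' @return an object of class `amf_inoculum_set`: list with `otu_ids`,
#'   `source_sample`, `min_share`.
#' @export
define_inoculum_set <- function(table, inoculum_sample, min_share = 0) {
  stopifnot(inherits(table, "amf_otu_table"))
  if (!inoculum_sample %in% rownames(table$counts))
    stop("inoculum sample '", inoculum_sample, "' not in table",
         call. = FALSE)
  row <- table$counts[inoculum_sample, ]
  total <- sum(row)
  if (total == 0)
    stop("inoculum sample '", inoculum_sample, "' has no AM reads",
         call. = FALSE)
  ids <- colnames(table$counts)[row / total > min_share]
  if (!length(ids))
    stop("no OTU exceeds min_share = ", min_share,
         " in the inoculum sample", call. = FALSE)
  structure(list(otu_ids = ids, source_sample = inoculum_sample,
                 min_share = min_share),
            class = "amf_inoculum_set")
}

#' @export
print.amf_inoculum_set <- function(x, ...) {
  cat("Inoculum OTU set:", length(x$otu_ids), "OTUs from sample",
      x$source_sample, "\n")
  invisible(x)
}

#' Track the inoculum-type read abundance per sample
#'
#' Sums the reads of the inoculum-set OTUs in every sample of a
#' rarefied table and reports the share relative to the rarefaction
#' depth.
#'
#' @param table a rarefied `amf_otu_table`.
#' @param set an `amf_inoculum_set` (or a character vector of OTU ids).
#' @param exclude_inoculum_sample drop the inoculum-only sample from the
#'   output (default TRUE when it is present).
#' @return data.frame with one row per sample: `sample`,
#'   `tracked_reads`, `total_reads`, `share`.
#' @export
track <- function(table, set, exclude_inoculum_sample = TRUE) {
  stopifnot(inherits(table, "amf_otu_table"))
  if (!isTRUE(table$rarefied))
    stop("track() expects a rarefied table; call rarefy() first",
         call. = FALSE)
  ids <- if (inherits(set, "amf_inoculum_set")) set$otu_ids else set
  missing <- setdiff(ids, colnames(table$counts))
  if (length(missing))
    stop("inoculum-set OTUs absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  counts <- table$counts
  if (exclude_inoculum_sample && inherits(set, "amf_inoculum_set"))
    counts <- counts[setdiff(rownames(counts), set$source_sample), ,
                     drop = FALSE]
  tracked <- rowSums(counts[, ids, drop = FALSE])
  total <- rowSums(counts)
  data.frame(sample = rownames(counts),
             tracked_reads = as.integer(tracked),
             total_reads = as.integer(total),
             share = ifelse(total > 0, tracked / total, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}
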