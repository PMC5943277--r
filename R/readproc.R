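# Read processing: 3' quality trimming, length filtering, and ungapped
# overlap merging of paired amplicon reads. The criteria are implemented
# natively so behaviour is fixed by this package, not by external tool
# versions.

#' Quality-trim a read
#'
#' Removes 3'-terminal bases until the terminal base has a quality value
#' at or above `qv_threshold` (a simple terminal scan, not a sliding
#' window), strips a 5' prefix exactly matching `adapter` if given, and
#' rejects reads shorter than `min_length` after trimming.
#'
#' @param seq nucleotide string.
#' @param qual Phred+33 quality string, same length as `seq`.
#' @param qv_threshold minimum acceptable 3'-terminal quality (default 30).
#' @param adapter optional 5' adapter-index sequence to strip.
#' @param min_length minimum retained length (default 200 nt).
#' @return a list with `seq`, `qual`, and logical `rejected`.
#' @export
#' @examples
#' r <- quality_trim("ACGTACGT", "IIIII###")  # three terminal Q2 bases
#' r$seq
quality_trim <- function(seq, qual, qv_threshold = 30, adapter = NULL,
                         min_length = 200) {
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality lengths differ", call. = FALSE)
  if (!is.null(adapter) && nzchar(adapter) &&
      startsWith(seq, adapter)) {
    seq <- substr(seq, nchar(adapter) + 1L, nchar(seq))
    qual <- substr(qual, nchar(adapter) + 1L, nchar(qual))
  }
  q <- char_to_phred(qual)
  keep <- which(q >= qv_threshold)
  end <- if (length(keep)) max(keep) else 0L
  seq <- substr(seq, 1L, end)
  qual <- substr(qual, 1L, end)
  list(seq = seq, qual = qual, rejected = nchar(seq) < min_length)
}

# Mismatch counts of every candidate ungapped 3' overlap between s1 and
# the (already reverse-complemented) mate rc2, scanning from the longest
# candidate down so that a zero-mismatch overlap short-circuits (ties on
# mismatch count resolve to the longest overlap).
best_overlap <- function(s1, rc2, min_overlap, max_overlap) {
  n1 <- nchar(s1); n2 <- nchar(rc2)
  lmax <- min(max_overlap, n1, n2)
  if (lmax < min_overlap) return(NULL)
  r1 <- charToRaw(s1); r2 <- charToRaw(rc2)
  best_len <- 0L; best_mm <- .Machine$integer.max
  for (L in seq.int(lmax, min_overlap)) {
    mm <- sum(r1[(n1 - L + 1L):n1] != r2[seq_len(L)])
    if (mm < best_mm) {
      best_mm <- mm; best_len <- L
      if (mm == 0L) break
    }
  }
  list(overlap = best_len, mismatches = best_mm)
}

#' Merge a read pair by its best ungapped 3' overlap
#'
#' Mate 2 is reverse-complemented, then the ungapped overlap between the
#' 3' end of mate 1 and the 5' end of the flipped mate 2 is scanned over
#' `[min_overlap, max_overlap]` nt; the overlap with the fewest
#' mismatches wins, ties going to the longest. At disagreeing overlap
#' positions the consensus takes the base of the mate with the higher
#' quality value (mate 1 on equal quality). The pair is rejected when no
#' candidate overlap exists or the best overlap's mismatch rate exceeds
#' `max_mismatch_rate`.
#'
#' @param seq1,qual1 mate 1 sequence and Phred+33 qualities.
#' @param seq2,qual2 mate 2 sequence and qualities (as sequenced).
#' @param min_overlap,max_overlap allowed overlap range in nt.
#' @param max_mismatch_rate maximum tolerated mismatch fraction in the
#'   overlap.
#' @return a list with `seq`, `qual`, `length`, `overlap_len`,
#'   `mismatches`, and logical `rejected`.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2,
                       min_overlap = 10, max_overlap = 300,
                       max_mismatch_rate = 0.1) {
  rc2 <- revcomp(seq2)
  q2 <- rev(char_to_phred(qual2))
  ov <- best_overlap(seq1, rc2, min_overlap, max_overlap)
  if (is.null(ov) || ov$mismatches / ov$overlap > max_mismatch_rate)
    return(list(seq = NA_character_, qual = NA_character_, length = 0L,
                overlap_len = 0L, mismatches = NA_integer_, rejected = TRUE))
  L <- ov$overlap
  n1 <- nchar(seq1); n2 <- nchar(rc2)
  c1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(rc2, "", fixed = TRUE)[[1]]
  q1 <- char_to_phred(qual1)
  i1 <- (n1 - L + 1L):n1
  i2 <- seq_len(L)
  cons <- c1[i1]
  consq <- pmax(q1[i1], q2[i2])
  take2 <- c1[i1] != c2[i2] & q2[i2] > q1[i1]
  cons[take2] <- c2[i2][take2]
  merged <- c(c1[seq_len(n1 - L)], cons,
              if (L < n2) c2[(L + 1L):n2] else character(0))
  mq <- c(q1[seq_len(n1 - L)], consq,
          if (L < n2) q2[(L + 1L):n2] else integer(0))
  list(seq = paste(merged, collapse = ""),
       qual = phred_to_char(mq),
       length = length(merged), overlap_len = L,
       mismatches = ov$mismatches, rejected = FALSE)
}

#' Read a FASTQ file into id/seq/qual vectors
#'
#' @param path FASTQ path (Phred+33).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record '", hdr[bad[1]], "' in ", path,
         call. = FALSE)
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = seqs,
             qual = qual, stringsAsFactors = FALSE)
}

#' Process a paired-end sample: trim, filter, merge
#'
#' Runs [quality_trim()] on both mates of every pair and [merge_pair()]
#' on the survivors. Counts are conserved: `input = merged + rejected`.
#'
#' @param r1,r2 FASTQ paths, or data.frames as returned by
#'   [read_fastq()].
#' @param qv_threshold,adapter,min_length see [quality_trim()].
#' @param min_overlap,max_overlap,max_mismatch_rate see [merge_pair()].
#' @return list with `merged` (data.frame `id`, `seq`, `length`,
#'   `overlap_len`) and `counts` (named: input, trim_rejected,
#'   merge_rejected, merged, rejected).
#' @export
process_sample <- function(r1, r2, qv_threshold = 30, adapter = NULL,
                           min_length = 200, min_overlap = 10,
                           max_overlap = 300, max_mismatch_rate = 0.1) {
  f1 <- if (is.character(r1)) read_fastq(r1) else r1
  f2 <- if (is.character(r2)) read_fastq(r2) else r2
  if (nrow(f1) != nrow(f2))
    stop("mate files differ in record count (", nrow(f1), " vs ",
         nrow(f2), ")", call. = FALSE)
  n <- nrow(f1)
  out_id <- character(n); out_seq <- character(n)
  out_len <- integer(n); out_ov <- integer(n)
  kept <- logical(n)
  n_trim_rej <- 0L; n_merge_rej <- 0L
  for (i in seq_len(n)) {
    t1 <- quality_trim(f1$seq[i], f1$qual[i], qv_threshold, adapter,
                       min_length)
    t2 <- quality_trim(f2$seq[i], f2$qual[i], qv_threshold, adapter,
                       min_length)
    if (t1$rejected || t2$rejected) {
      n_trim_rej <- n_trim_rej + 1L
      next
    }
    m <- merge_pair(t1$seq, t1$qual, t2$seq, t2$qual, min_overlap,
                    max_overlap, max_mismatch_rate)
    if (m$rejected) {
      n_merge_rej <- n_merge_rej + 1L
      next
    }
    kept[i] <- TRUE
    out_id[i] <- f1$id[i]; out_seq[i] <- m$seq
    out_len[i] <- m$length; out_ov[i] <- m$overlap_len
  }
  merged <- data.frame(id = out_id[kept], seq = out_seq[kept],
                       length = out_len[kept], overlap_len = out_ov[kept],
                       stringsAsFactors = FALSE)
  counts <- c(input = n, trim_rejected = n_trim_rej,
              merge_rejected = n_merge_rej, merged = nrow(merged),
              rejected = n_trim_rej + n_merge_rej)
  list(merged = merged, counts = counts)
}

#' Write merged reads as FASTA
#'
#' @param merged data.frame with `id` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merged_fasta <- function(merged, path) {
  x <- Biostrings::DNAStringSet(merged$seq)
  names(x) <- merged$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
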