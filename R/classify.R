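# Best-hit OTU classification of merged amplicon reads against a
# two-group (AM / outgroup) reference set, with BLAST-like acceptance
# criteria: E-value <= 1e-100, identity >= 95%, and a group-specific
# minimum alignment length (330 nt for AM OTUs, 220 nt for outgroup
# sequences). Local affine-gap alignment is delegated to
# Biostrings::pairwiseAlignment; scoring, E-values, the k-mer prescreen
# and the acceptance logic live here.

#' Alignment scoring parameters
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap opening 5 and gap
#' extension 2 (a gap of length L costs `gap_open + gap_extend * L`),
#' with Karlin-Altschul constants K and lambda for converting a local
#' alignment score S into an expectation
#' `E = K * m * n * exp(-lambda * S)`, where `m` is the query length and
#' `n` the total length of the searched reference group.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend positive gap costs.
#' @param K,lambda Karlin-Altschul constants (`lambda > 0`, `K > 0`).
#' @return an object of class `amf_alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2, K = 0.41, lambda = 0.625) {
  stopifnot(lambda > 0, K > 0, match > 0, mismatch < 0,
            gap_open >= 0, gap_extend >= 0)
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- mismatch
  mat[, "N"] <- mismatch
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda,
                 submat = mat),
            class = "amf_alignment_params")
}

# Fraction of identical columns in a global (Needleman-Wunsch) alignment
# of `a` against each sequence in `b`; the divergence yardstick for
# full-length reference sequences.
global_identity <- function(a, b, params = alignment_params()) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = rep(Biostrings::DNAStringSet(a), length(b)),
    subject = Biostrings::DNAStringSet(b), type = "global",
    substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains characters outside ACGTN (first offender: ",
         which(bad)[1], ")", call. = FALSE)
  invisible(x)
}

#' Locally align one read against reference sequences
#'
#' Smith-Waterman-style local alignment with affine gaps on both
#' strands (unless disabled); per reference the better strand is kept.
#' Identity is matches divided by alignment columns including gaps, as
#' in BLAST identity reporting.
#'
#' @param read a single nucleotide string (ACGTN).
#' @param ref_seqs character vector of reference sequences; names are
#'   used as `otu_id` when present.
#' @param params an [alignment_params()] object.
#' @param search_space_n total reference length `n` for the E-value;
#'   defaults to `sum(nchar(ref_seqs))`.
#' @param both_strands also align the reverse complement of the read.
#' @return data.frame with one row per reference: `otu_id`, `score`,
#'   `identity`, `aln_length`, `strand`, `evalue`.
#' @export
align_read <- function(read, ref_seqs, params = alignment_params(),
                       search_space_n = sum(nchar(ref_seqs)),
                       both_strands = TRUE) {
  stopifnot(length(read) == 1L, nchar(read) > 0L, all(nchar(ref_seqs) > 0L))
  check_dna(read, "read")
  check_dna(ref_seqs, "reference")
  ids <- names(ref_seqs) %||% sprintf("ref%d", seq_along(ref_seqs))
  subj <- Biostrings::DNAStringSet(ref_seqs)
  one_strand <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = rep(Biostrings::DNAStringSet(q), length(ref_seqs)),
      subject = subj, type = "local",
      substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    data.frame(score = Biostrings::score(aln),
               nmatch = Biostrings::nmatch(aln),
               aln_length = Biostrings::nchar(aln))
  }
  fwd <- one_strand(read)
  if (both_strands) {
    rev <- one_strand(revcomp(read))
    use_rev <- rev$score > fwd$score
    strand <- ifelse(use_rev, "-", "+")
    res <- fwd
    res[use_rev, ] <- rev[use_rev, ]
  } else {
    res <- fwd
    strand <- rep("+", nrow(res))
  }
  m <- nchar(read)
  data.frame(
    otu_id = ids,
    score = res$score,
    identity = ifelse(res$aln_length > 0, res$nmatch / res$aln_length, 0),
    aln_length = res$aln_length,
    strand = strand,
    evalue = params$K * m * search_space_n *
      exp(-params$lambda * res$score),
    stringsAsFactors = FALSE)
}

#' Assignment acceptance thresholds
#'
#' @param evalue_max maximum E-value (the "E-value <= -100" criterion,
#'   read as `1e-100`).
#' @param identity_min minimum fractional identity.
#' @param am_length_min minimum alignment length against an AM OTU (nt).
#' @param out_length_min minimum alignment length against an outgroup
#'   sequence (nt).
#' @return a named list of class `amf_assign_criteria`.
#' @export
assign_criteria <- function(evalue_max = 1e-100, identity_min = 0.95,
                            am_length_min = 330, out_length_min = 220) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 1,
            am_length_min > 0, out_length_min > 0)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 am_length_min = am_length_min,
                 out_length_min = out_length_min),
            class = "amf_assign_criteria")
}

# k-mer prescreen: shared 12-mer counts between a read (both strands)
# and every reference, used to shortlist alignment candidates. Returns
# a function(read) -> data.frame(ref_idx, strand, count) of the top
# `n_candidates` references.
make_prescreen <- function(ref_seqs, k = 12L, n_candidates = 3L) {
  n_ref <- length(ref_seqs)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  }
  ref_kmers <- lapply(ref_seqs, kmers_of)
  # hash map kmer -> integer vector of reference indices, built once
  index <- new.env(hash = TRUE, size = 4L * sum(lengths(ref_kmers)))
  for (i in seq_len(n_ref)) {
    for (km in ref_kmers[[i]])
      assign(km, c(index[[km]], i), envir = index)
  }
  function(read) {
    score_strand <- function(s) {
      hits <- unlist(mget(kmers_of(s), envir = index,
                          ifnotfound = list(NULL)),
                     use.names = FALSE)
      if (!length(hits)) return(integer(n_ref))
      tabulate(hits, nbins = n_ref)
    }
    cf <- score_strand(read)
    cr <- score_strand(revcomp(read))
    best <- pmax(cf, cr)
    ord <- order(-best, seq_len(n_ref))[seq_len(min(n_candidates, n_ref))]
    data.frame(ref_idx = ord,
               strand = ifelse(cr[ord] > cf[ord], "-", "+"),
               count = best[ord])
  }
}

#' Assign one merged read to an OTU, the outgroup, or nothing
#'
#' The best hit (highest score; ties broken by lower E-value, then
#' lexicographic `otu_id`) over all reference records and both strands
#' decides the candidate; it is accepted only if it meets the E-value,
#' identity, and group-specific alignment-length criteria. A read whose
#' best hit is an outgroup record failing the outgroup criteria is
#' `no_hit`, not an AM failure.
#'
#' @param read a nucleotide string.
#' @param reference an `amf_reference` data.frame (columns `otu_id`,
#'   `group`, `seq`).
#' @param params [alignment_params()].
#' @param criteria [assign_criteria()].
#' @return one-row data.frame: `assignment` (one of `otu_id`,
#'   `"unassigned_AM_fail"`, `"outgroup"`, `"no_hit"`), `otu_id`,
#'   `group`, `score`, `identity`, `aln_length`, `evalue`, `strand`.
#' @export
assign_read <- function(read, reference, params = alignment_params(),
                        criteria = assign_criteria()) {
  classify_reads(stats::setNames(read, "q"), reference, params, criteria,
                 prescreen = FALSE)[, -1]
}

#' Classify a batch of merged reads
#'
#' Batch driver for [assign_read()] semantics. With `prescreen = TRUE`
#' (the default) a shared-12-mer screen shortlists `n_candidates`
#' reference records per read and only those are aligned, which is the
#' standard seed-and-extend economy; `prescreen = FALSE` aligns every
#' read against every reference record.
#'
#' @param reads named character vector (names = read ids) or data.frame
#'   with `id` and `seq` columns.
#' @param reference an `amf_reference` data.frame.
#' @param params [alignment_params()].
#' @param criteria [assign_criteria()].
#' @param prescreen use the k-mer shortlist.
#' @param n_candidates references shortlisted per read.
#' @return data.frame with one row per read: `read_id`, `assignment`,
#'   `otu_id`, `group`, `score`, `identity`, `aln_length`, `evalue`,
#'   `strand`.
#' @export
classify_reads <- function(reads, reference, params = alignment_params(),
                           criteria = assign_criteria(), prescreen = TRUE,
                           n_candidates = 3L) {
  if (is.data.frame(reads)) reads <- stats::setNames(reads$seq, reads$id)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%d", seq_along(reads))
  if (!nrow(reference) || !any(reference$group == "AM"))
    stop("reference set must contain at least one AM record", call. = FALSE)
  check_dna(reads, "read")
  n_am <- sum(nchar(reference$seq[reference$group == "AM"]))
  n_out <- sum(nchar(reference$seq[reference$group == "OUT"]))
  group_n <- c(AM = n_am, OUT = max(n_out, 1))

  if (prescreen) {
    # seed-and-extend economy: rank the shortlisted candidates by
    # score-only alignment on the k-mer-preferred strand, then run the
    # full alignment only for each read's winning candidate
    screen <- make_prescreen(reference$seq, n_candidates = n_candidates)
    cand <- lapply(reads, screen)
    jobs <- data.frame(
      read_idx = rep(seq_along(reads), vapply(cand, nrow, integer(1))),
      ref_idx = unlist(lapply(cand, `[[`, "ref_idx"), use.names = FALSE),
      strand = unlist(lapply(cand, `[[`, "strand"), use.names = FALSE),
      stringsAsFactors = FALSE)
    jobs$score <- NA_real_
    key <- paste(jobs$ref_idx, jobs$strand)
    for (kk in unique(key)) {
      sel <- which(key == kk)
      q <- unname(reads[jobs$read_idx[sel]])
      if (jobs$strand[sel[1]] == "-") q <- revcomp(q)
      jobs$score[sel] <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(q),
        subject = Biostrings::DNAString(reference$seq[jobs$ref_idx[sel[1]]]),
        type = "local", substitutionMatrix = params$submat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend,
        scoreOnly = TRUE)
    }
    jobs$group <- reference$group[jobs$ref_idx]
    jobs$otu_id <- reference$otu_id[jobs$ref_idx]
    jobs$evalue <- params$K * nchar(reads)[jobs$read_idx] *
      group_n[jobs$group] * exp(-params$lambda * jobs$score)
    jobs <- jobs[order(jobs$read_idx, -jobs$score, jobs$evalue,
                       jobs$otu_id), ]
    win <- jobs[!duplicated(jobs$read_idx), ]
    # full alignment of each read against its winning reference only
    win$identity <- NA_real_
    win$aln_length <- NA_integer_
    wkey <- paste(win$ref_idx, win$strand)
    for (kk in unique(wkey)) {
      sel <- which(wkey == kk)
      q <- unname(reads[win$read_idx[sel]])
      if (win$strand[sel[1]] == "-") q <- revcomp(q)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(q),
        subject = Biostrings::DNAString(reference$seq[win$ref_idx[sel[1]]]),
        type = "local", substitutionMatrix = params$submat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      win$score[sel] <- Biostrings::score(aln)
      cols <- Biostrings::nchar(aln)
      win$aln_length[sel] <- cols
      win$identity[sel] <- ifelse(cols > 0,
                                  Biostrings::nmatch(aln) / cols, 0)
    }
    win$evalue <- params$K * nchar(reads)[win$read_idx] *
      group_n[win$group] * exp(-params$lambda * win$score)
    best <- win[order(win$read_idx), ]
  } else {
    # exhaustive mode: full alignment of every read against every
    # reference record on both strands
    hits <- vector("list", nrow(reference))
    for (ri in seq_len(nrow(reference))) {
      h <- align_batch(reads, reference$seq[ri], params)
      h$read_idx <- seq_along(reads)
      h$ref_idx <- ri
      hits[[ri]] <- h
    }
    hits <- do.call(rbind, hits)
    hits$group <- reference$group[hits$ref_idx]
    hits$otu_id <- reference$otu_id[hits$ref_idx]
    m <- nchar(reads)[hits$read_idx]
    hits$evalue <- params$K * m * group_n[hits$group] *
      exp(-params$lambda * hits$score)
    # best hit per read: highest score, ties by lower evalue then
    # lexicographic otu_id
    hits <- hits[order(hits$read_idx, -hits$score, hits$evalue,
                       hits$otu_id), ]
    best <- hits[!duplicated(hits$read_idx), ]
  }
  stopifnot(nrow(best) == length(reads))
  ok <- best$evalue <= criteria$evalue_max &
    best$identity >= criteria$identity_min
  assignment <- ifelse(
    best$group == "AM",
    ifelse(ok & best$aln_length >= criteria$am_length_min,
           best$otu_id, "unassigned_AM_fail"),
    ifelse(ok & best$aln_length >= criteria$out_length_min,
           "outgroup", "no_hit"))
  res <- data.frame(read_id = names(reads)[best$read_idx],
                    assignment = assignment, otu_id = best$otu_id,
                    group = best$group, score = best$score,
                    identity = best$identity,
                    aln_length = best$aln_length, evalue = best$evalue,
                    strand = best$strand, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Vectorized alignment of many reads against one reference, both
# strands; returns the better strand per read.
align_batch <- function(reads, ref_seq, params) {
  subj <- Biostrings::DNAString(ref_seq)
  one <- function(qs) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(qs), subject = subj,
      type = "local", substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    data.frame(score = Biostrings::score(aln),
               nmatch = Biostrings::nmatch(aln),
               aln_length = Biostrings::nchar(aln))
  }
  fwd <- one(unname(reads))
  rev <- one(revcomp(unname(reads)))
  use_rev <- rev$score > fwd$score
  res <- fwd
  res[use_rev, ] <- rev[use_rev, ]
  res$strand <- ifelse(use_rev, "-", "+")
  res$identity <- ifelse(res$aln_length > 0, res$nmatch / res$aln_length, 0)
  res
}

#' Build an OTU read-count table from per-sample assignments
#'
#' AM-assigned reads are counted per (sample, OTU); unassigned,
#' outgroup, and no-hit reads are tallied in a QC report and excluded
#' from the community counts.
#'
#' @param assignments named list of per-sample data.frames from
#'   [classify_reads()].
#' @param reference `amf_reference`; fixes the OTU universe so absent
#'   OTUs appear as zero columns.
#' @return an `amf_otu_table`: list with `counts` (samples x OTUs
#'   integer matrix), `rarefied = FALSE`, and `qc` (per-sample
#'   data.frame of input/assigned/unassigned_AM_fail/outgroup/no_hit).
#' @export
build_otu_table <- function(assignments, reference) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  am_ids <- reference$otu_id[reference$group == "AM"]
  counts <- matrix(0L, length(assignments), length(am_ids),
                   dimnames = list(names(assignments), am_ids))
  qc <- data.frame(sample = names(assignments), input = 0L, assigned = 0L,
                   unassigned_AM_fail = 0L, outgroup = 0L, no_hit = 0L,
                   stringsAsFactors = FALSE)
  for (i in seq_along(assignments)) {
    a <- assignments[[i]]
    if (anyDuplicated(a$read_id))
      stop("duplicate read ids in sample '", names(assignments)[i], "'",
           call. = FALSE)
    qc$input[i] <- nrow(a)
    assigned <- a$assignment[!a$assignment %in%
                               c("unassigned_AM_fail", "outgroup", "no_hit")]
    tab <- table(factor(assigned, levels = am_ids))
    counts[i, ] <- as.integer(tab)
    qc$assigned[i] <- length(assigned)
    qc$unassigned_AM_fail[i] <- sum(a$assignment == "unassigned_AM_fail")
    qc$outgroup[i] <- sum(a$assignment == "outgroup")
    qc$no_hit[i] <- sum(a$assignment == "no_hit")
  }
  new_otu_table(counts, rarefied = FALSE, qc = qc)
}

new_otu_table <- function(counts, rarefied, qc = NULL, depth = NA_integer_) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  structure(list(counts = counts, rarefied = rarefied, qc = qc,
                 depth = depth),
            class = "amf_otu_table")
}

#' @export
print.amf_otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs",
      if (x$rarefied) sprintf("(rarefied to %d reads)", x$depth)
      else "(raw counts)", "\n")
  invisible(x)
}

#' Normalize an OTU table to a common depth
#'
#' With `method = "subsample"` (rarefaction, the default) exactly
#' `depth` reads are drawn per sample without replacement; with
#' `method = "scale"` each sample's counts are proportionally rescaled
#' to sum to `depth` and rounded (largest-remainder rounding so totals
#' are exact). Samples whose total is below `depth` are dropped with a
#' warning under subsampling.
#'
#' @param table an `amf_otu_table`.
#' @param depth target reads per sample (default 10,000).
#' @param seed integer; the subsampling draw is deterministic under it.
#' @param method `"subsample"` or `"scale"`.
#' @return a normalized `amf_otu_table` (flagged rarefied).
#' @export
rarefy <- function(table, depth = 10000, seed = 1,
                   method = c("subsample", "scale")) {
  stopifnot(inherits(table, "amf_otu_table"))
  method <- match.arg(method)
  if (depth <= 0) stop("rarefaction depth must be positive", call. = FALSE)
  totals <- rowSums(table$counts)
  if (method == "scale") {
    keep <- table$counts[totals > 0, , drop = FALSE]
    out <- t(apply(keep, 1, function(row) {
      x <- row / sum(row) * depth
      f <- floor(x)
      short <- as.integer(round(depth - sum(f)))
      if (short > 0) {
        extra <- order(x - f, decreasing = TRUE)[seq_len(short)]
        f[extra] <- f[extra] + 1
      }
      as.integer(f)
    }))
    dimnames(out) <- dimnames(keep)
    return(new_otu_table(out, rarefied = TRUE, qc = table$qc,
                         depth = as.integer(depth)))
  }
  drop <- totals < depth
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table$counts)[drop], collapse = ", "),
            call. = FALSE)
  keep <- table$counts[!drop, , drop = FALSE]
  if (!nrow(keep))
    return(new_otu_table(keep, rarefied = TRUE, qc = table$qc,
                         depth = as.integer(depth)))
  out <- with_seed(seed, {
    t(apply(keep, 1, function(row) {
      if (sum(row) == depth) return(as.integer(row))
      pool <- rep.int(seq_along(row), row)
      got <- pool[sample.int(length(pool), depth)]
      tabulate(got, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(keep)
  new_otu_table(out, rarefied = TRUE, qc = table$qc, depth = as.integer(depth))
}

#' Write an OTU table as TSV (rows = OTUs, columns = samples)
#'
#' @param table an `amf_otu_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table written by [write_otu_table()]
#'
#' @param path TSV path (rows = OTUs, columns = samples).
#' @param rarefied logical flag to set on the result.
#' @return an `amf_otu_table`.
#' @export
read_otu_table <- function(path, rarefied = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  depth <- unique(colSums(m))
  new_otu_table(t(m), rarefied = rarefied,
                depth = if (rarefied && length(depth) == 1L)
                  depth else NA_integer_)
}
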