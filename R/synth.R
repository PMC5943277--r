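#' Synthetic-data configuration
#'
#' Bundles every knob of the synthetic amplicon study generator. The
#' defaults emulate the field-trial design the package is built around:
#' three trials in a randomized complete block design (n = 4 blocks),
#' two phosphorus fertilizer levels, paired control/inoculated plots,
#' indigenous AM fungal propagule densities of about 0.02 propagules per
#' mL soil in two bare-fallow trials and an order of magnitude more in a
#' previously cropped trial, and MiSeq-like paired 300-cycle amplicon
#' reads of an LSU rDNA D2-like locus (~360 nt).
#'
#' The inoculum's community share in an inoculated plot follows a
#' logistic-decreasing function of the trial propagule density,
#' `share = plogis(inoc_link_a - inoc_link_b * log(density))`, so that
#' plots with few indigenous propagules are dominated by the inoculum
#' (>70% of AM reads) while high-propagule plots are barely colonized.
#' Grain yield is `baseline_yield + inoculum_effect * share` plus
#' Gaussian noise.
#'
#' @param n_trials number of field trials (habitats).
#' @param n_blocks replicated blocks per trial.
#' @param p_levels phosphorus application levels (kg P2O5/ha).
#' @param n_indigenous_otus number of indigenous AM fungal OTUs.
#' @param n_inoculum_otus number of OTUs the inoculum fungus resolves into.
#' @param n_outgroup_seqs number of non-AM outgroup reference sequences.
#' @param ref_length reference amplicon length (nt), >= 330.
#' @param read_error_rate mean per-base substitution error of a read.
#' @param propagule_density_per_trial indigenous propagule density
#'   (propagules/mL soil), recycled to `n_trials`.
#' @param reads_per_sample read pairs generated per sample.
#' @param inoculum_effect slope of yield (kg/ha) on inoculum read share.
#' @param baseline_yield control-level yield (kg/ha).
#' @param yield_noise_sd s.d. of plot-level yield noise (kg/ha).
#' @param background_share inoculum-type OTU share in uninoculated plots
#'   (indigenous look-alikes; the mechanism is deliberately left open).
#' @param share_logit_sd plot-level s.d. of the inoculum share on the
#'   logit scale.
#' @param inoc_link_a,inoc_link_b intercept and slope of the logistic
#'   link from log propagule density to inoculum share.
#' @param outgroup_frac,junk_frac fractions of reads drawn from outgroup
#'   references and from random (junk) templates.
#' @param mate_length length of each sequenced mate (nt).
#' @param assay_volume_ml soil volume per dilution-assay pot (mL).
#' @param n_plants_per_level replicate plants per dilution level.
#' @param dilutions dilution factors of the bioassay series.
#' @param seed integer; fully determines every generated artifact.
#' @return an object of class `amf_synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(reads_per_sample = 200, seed = 42)
#' ref <- make_reference(cfg)
#' table(ref$group)
synth_config <- function(n_trials = 3,
                         n_blocks = 4,
                         p_levels = c(0, 100),
                         n_indigenous_otus = 22,
                         n_inoculum_otus = 3,
                         n_outgroup_seqs = 10,
                         ref_length = 360,
                         read_error_rate = 0.01,
                         propagule_density_per_trial = c(0.02, 0.02, 0.2),
                         reads_per_sample = 5000,
                         inoculum_effect = 600,
                         baseline_yield = 3000,
                         yield_noise_sd = 100,
                         background_share = 0.10,
                         share_logit_sd = 0.4,
                         inoc_link_a = -2.21,
                         inoc_link_b = 0.845,
                         outgroup_frac = 0.02,
                         junk_frac = 0.02,
                         mate_length = 230,
                         assay_volume_ml = 20,
                         n_plants_per_level = 8,
                         dilutions = 2^c(-1, -3, -5, -7),
                         seed = 1) {
  cfg <- list(
    n_trials = as.integer(n_trials), n_blocks = as.integer(n_blocks),
    p_levels = as.numeric(p_levels),
    n_indigenous_otus = as.integer(n_indigenous_otus),
    n_inoculum_otus = as.integer(n_inoculum_otus),
    n_outgroup_seqs = as.integer(n_outgroup_seqs),
    ref_length = as.integer(ref_length),
    read_error_rate = as.numeric(read_error_rate),
    propagule_density_per_trial =
      rep_len(as.numeric(propagule_density_per_trial), n_trials),
    reads_per_sample = as.integer(reads_per_sample),
    inoculum_effect = as.numeric(inoculum_effect),
    baseline_yield = as.numeric(baseline_yield),
    yield_noise_sd = as.numeric(yield_noise_sd),
    background_share = as.numeric(background_share),
    share_logit_sd = as.numeric(share_logit_sd),
    inoc_link_a = as.numeric(inoc_link_a),
    inoc_link_b = as.numeric(inoc_link_b),
    outgroup_frac = as.numeric(outgroup_frac),
    junk_frac = as.numeric(junk_frac),
    mate_length = as.integer(mate_length),
    assay_volume_ml = as.numeric(assay_volume_ml),
    n_plants_per_level = as.integer(n_plants_per_level),
    dilutions = as.numeric(dilutions),
    seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "amf_synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_trials", "n_blocks", "n_indigenous_otus", "n_inoculum_otus",
              "n_outgroup_seqs", "reads_per_sample", "mate_length",
              "n_plants_per_level")
  for (f in counts)
    if (cfg[[f]] < 1L) stop("'", f, "' must be >= 1", call. = FALSE)
  probs <- c("read_error_rate", "background_share", "outgroup_frac",
             "junk_frac")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a probability in [0, 1]", call. = FALSE)
  if (cfg$ref_length < 330L)
    stop("'ref_length' must be >= 330 nt", call. = FALSE)
  if (any(cfg$propagule_density_per_trial < 0))
    stop("propagule densities must be non-negative", call. = FALSE)
  if (cfg$outgroup_frac + cfg$junk_frac >= 1)
    stop("outgroup_frac + junk_frac must be < 1", call. = FALSE)
  invisible(cfg)
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

otu_ids <- function(cfg) {
  list(
    indigenous = sprintf("OTU_%03d", seq_len(cfg$n_indigenous_otus)),
    inoculum = sprintf("RHZ_%02d", seq_len(cfg$n_inoculum_otus)),
    outgroup = sprintf("OUT_%02d", seq_len(cfg$n_outgroup_seqs)))
}

#' Generate a synthetic reference sequence set
#'
#' Builds AM-fungal OTU reference sequences plus non-AM outgroup
#' sequences. AM sequences descend from a common random ancestor with
#' enough per-OTU divergence that all pairs are below 95% identity, so
#' best-hit assignment against them is unambiguous; inoculum OTUs form a
#' tighter subclade (a multi-OTU strain). Outgroup sequences are
#' independent random DNA, far below 80% identity to any AM sequence.
#' The constraints are verified with the package's own aligner and the
#' draw is retried a bounded number of times if violated.
#'
#' @param config an [synth_config()] object.
#' @param validate verify the pairwise-identity constraints by alignment.
#' @param max_attempts attempts before giving up.
#' @return a `data.frame` with columns `otu_id`, `group` ("AM"/"OUT"),
#'   `seq`, and a logical `inoculum` flag; class `amf_reference`.
#' @export
make_reference <- function(config, validate = TRUE, max_attempts = 5L) {
  ids <- otu_ids(config)
  for (attempt in seq_len(max_attempts)) {
    ref <- with_seed(derive_seed(config$seed, 11L + 1000L * (attempt - 1L)), {
      L <- config$ref_length
      ancestor <- random_dna(1, L)
      indig <- vapply(seq_len(config$n_indigenous_otus),
                      function(i) mutate_seq(ancestor, 0.15), character(1))
      sub_anc <- mutate_seq(ancestor, 0.15)
      inoc <- vapply(seq_len(config$n_inoculum_otus),
                     function(i) mutate_seq(sub_anc, 0.05), character(1))
      out_len <- sample(seq(L - 20L, L + 60L), config$n_outgroup_seqs,
                        replace = TRUE)
      outg <- random_dna(config$n_outgroup_seqs, out_len)
      data.frame(
        otu_id = c(ids$indigenous, ids$inoculum, ids$outgroup),
        group = rep(c("AM", "OUT"),
                    c(length(indig) + length(inoc), length(outg))),
        seq = c(indig, inoc, outg),
        inoculum = rep(c(FALSE, TRUE, FALSE),
                       c(length(indig), length(inoc), length(outg))),
        stringsAsFactors = FALSE)
    })
    if (!validate || reference_margins_ok(ref)) {
      class(ref) <- c("amf_reference", "data.frame")
      return(ref)
    }
  }
  stop("could not satisfy reference pairwise-divergence constraints in ",
       max_attempts, " attempts", call. = FALSE)
}

# All AM pairs < 95% identity; every outgroup sequence < 80% identity to
# every AM sequence. Identity between full-length reference sequences is
# judged on a global alignment with the package's scoring (a local
# alignment of unrelated sequences always contains short perfect
# segments, which say nothing about sequence divergence).
reference_margins_ok <- function(ref) {
  am <- ref[ref$group == "AM", ]
  out <- ref[ref$group == "OUT", ]
  pars <- alignment_params()
  for (i in seq_len(nrow(am) - 1L)) {
    idt <- global_identity(am$seq[i], am$seq[(i + 1L):nrow(am)], pars)
    if (any(idt >= 0.95)) return(FALSE)
  }
  for (i in seq_len(nrow(out))) {
    if (any(global_identity(out$seq[i], am$seq, pars) >= 0.80))
      return(FALSE)
  }
  TRUE
}

#' Write a reference set as FASTA
#'
#' Headers carry the group tag as `otu_id|AM` or `otu_id|OUT`.
#'
#' @param ref an `amf_reference` data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- paste(ref$otu_id, ref$group, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a group-tagged reference FASTA
#'
#' @param path FASTA whose headers end in `|AM` or `|OUT`.
#' @return an `amf_reference` data.frame.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L | !vapply(parts, function(p)
    p[2] %in% c("AM", "OUT"), logical(1))
  if (any(bad))
    stop("reference headers must be '<otu_id>|AM' or '<otu_id>|OUT'; bad: ",
         paste(utils::head(names(x)[bad], 3), collapse = ", "), call. = FALSE)
  ref <- data.frame(
    otu_id = vapply(parts, `[`, character(1), 1),
    group = vapply(parts, `[`, character(1), 2),
    seq = as.character(x),
    stringsAsFactors = FALSE)
  ref$inoculum <- grepl("^RHZ_", ref$otu_id) & ref$group == "AM"
  class(ref) <- c("amf_reference", "data.frame")
  ref
}

#' Generate the field-trial design with ground-truth plot states
#'
#' One row per plot of the crossed trial x block x P-level x
#' {control, inoculated} design. Each plot carries its true propagule
#' density (the MPN covariate), its true inoculum read share (logistic
#' in log propagule density for inoculated plots, the background share
#' for controls, with plot-level logit noise), and a yield drawn as
#' `baseline_yield + inoculum_effect * share + N(0, yield_noise_sd)`.
#'
#' @param config an [synth_config()] object.
#' @return a `data.frame` (class `amf_design`) with columns `sample_id`,
#'   `trial`, `block`, `p_level`, `inoculated`, `mpn_true`,
#'   `true_inoc_share`, `yield`, plus soil covariates `phos_abs_coef`,
#'   `nitrate_n`, `exch_k`, `avail_p`.
#' @export
make_design <- function(config) {
  with_seed(derive_seed(config$seed, 12L), {
    g <- expand.grid(
      inoculated = c(FALSE, TRUE),
      p_level = config$p_levels,
      block = seq_len(config$n_blocks),
      trial = seq_len(config$n_trials),
      KEEP.OUT.ATTRS = FALSE)
    g <- g[, c("trial", "block", "p_level", "inoculated")]
    g$trial <- sprintf("T%d", g$trial)
    g$sample_id <- sprintf("%s_B%d_P%g_%s", g$trial, g$block, g$p_level,
                           ifelse(g$inoculated, "R10", "CTL"))
    dens <- config$propagule_density_per_trial
    names(dens) <- sprintf("T%d", seq_along(dens))
    g$mpn_true <- dens[g$trial]
    eps <- stats::rnorm(nrow(g), 0, config$share_logit_sd)
    mu_inoc <- config$inoc_link_a - config$inoc_link_b * log(g$mpn_true)
    share <- ifelse(g$inoculated,
                    stats::plogis(mu_inoc + eps),
                    if (config$background_share > 0)
                      stats::plogis(stats::qlogis(config$background_share) + eps)
                    else 0)
    g$true_inoc_share <- share
    g$yield <- config$baseline_yield +
      config$inoculum_effect * g$true_inoc_share +
      stats::rnorm(nrow(g), 0, config$yield_noise_sd)
    g$yield <- pmax(g$yield, 0)
    # abiotic soil covariates: trial-level means + block noise, units as
    # in standard soil assays
    n_t <- config$n_trials
    t_idx <- as.integer(sub("^T", "", g$trial))
    g$phos_abs_coef <- (1500 + 100 * t_idx) + stats::rnorm(nrow(g), 0, 30)
    g$nitrate_n <- (5 + 0.5 * t_idx) + stats::rnorm(nrow(g), 0, 0.4)
    g$exch_k <- (30 + 2 * t_idx) + stats::rnorm(nrow(g), 0, 2)
    g$avail_p <- (8 + 2 * t_idx) + stats::rnorm(nrow(g), 0, 0.8)
    rownames(g) <- NULL
    class(g) <- c("amf_design", "data.frame")
    g
  })
}

# Per-sample true community proportions over all AM OTUs (indigenous +
# inoculum), honouring each plot's true inoculum share exactly.
sample_communities <- function(config, design) {
  ids <- otu_ids(config)
  with_seed(derive_seed(config$seed, 13L), {
    trial_base <- lapply(seq_len(config$n_trials), function(i)
      rdirichlet1(rep(0.8, config$n_indigenous_otus)))
    names(trial_base) <- sprintf("T%d", seq_len(config$n_trials))
    inoc_profile <- rdirichlet1(rep(2, config$n_inoculum_otus))
    all_ids <- c(ids$indigenous, ids$inoculum)
    P <- matrix(0, nrow(design), length(all_ids),
                dimnames = list(design$sample_id, all_ids))
    for (r in seq_len(nrow(design))) {
      base <- trial_base[[design$trial[r]]]
      indig <- rdirichlet1(200 * base + 1e-6)
      s <- design$true_inoc_share[r]
      P[r, ] <- c((1 - s) * indig, s * inoc_profile)
    }
    list(proportions = P, inoc_profile = inoc_profile,
         trial_base = do.call(rbind, trial_base))
  })
}

# Heterogeneous per-base quality model with mean error `rate`: a mixture
# of high-quality (Q40) and low-quality (Q12) bases weighted so the
# expected per-base error equals `rate`. Returns for a flat vector of n
# bases: integer qualities and a logical error indicator, both drawn
# i.i.d.; errors substitute to a uniformly chosen different base.
draw_read_errors <- function(n, rate) {
  if (rate <= 0)
    return(list(qual = rep(40L, n), err = rep(FALSE, n)))
  q_low <- 12L
  p_low <- 10^(-q_low / 10)
  p_high <- 1e-4
  w <- min(1, max(0, (rate - p_high) / (p_low - p_high)))
  low <- stats::runif(n) < w
  qual <- ifelse(low, q_low, 40L)
  perr <- ifelse(low, p_low, p_high)
  err <- stats::runif(n) < perr
  list(qual = as.integer(qual), err = err)
}

.bases <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A")
.phred_chars <- strsplit(intToUtf8(33:74), "")[[1]]

# Build `n_reads` mates of length `ml` from a character matrix of
# templates (rows = reads) in one vectorized pass. Returns seq and qual
# string vectors.
build_mates <- function(tpl, rate) {
  n_reads <- nrow(tpl)
  ml <- ncol(tpl)
  flat <- as.vector(t(tpl))  # read-major
  de <- draw_read_errors(length(flat), rate)
  hit <- which(de$err)
  if (length(hit)) {
    # substitute to one of the three other bases, uniformly
    cur <- match(flat[hit], .bases)
    flat[hit] <- .bases[((cur - 1L +
                            sample.int(3L, length(hit), replace = TRUE))
                         %% 4L) + 1L]
  }
  sm <- as.data.frame(matrix(flat, nrow = n_reads, byrow = TRUE),
                      stringsAsFactors = FALSE)
  qm <- as.data.frame(matrix(.phred_chars[de$qual + 1L], nrow = n_reads,
                             byrow = TRUE), stringsAsFactors = FALSE)
  list(seq = do.call(paste0, sm), qual = do.call(paste0, qm))
}

#' Generate paired amplicon reads for every sample
#'
#' Draws, for each plot in the design plus one inoculum-only sequencing
#' sample (`"INOCULUM"`), `reads_per_sample` read pairs from a
#' Dirichlet-multinomial community mixture in which the inoculum OTUs
#' jointly hold the plot's true inoculum share. Each read pair covers a
#' reference template with i.i.d. substitution errors at the configured
#' mean rate; mate 2 is the reverse complement of the template's 3' end,
#' so mates overlap by `2 * mate_length - ref_length` nt. Quality
#' strings encode the true per-base error probabilities (Phred+33). A
#' configurable fraction of outgroup-derived and random junk read pairs
#' is interleaved.
#'
#' @param config an [synth_config()] object.
#' @param reference from [make_reference()].
#' @param design from [make_design()].
#' @param dir if non-NULL, write `<sample>_R1.fastq` / `<sample>_R2.fastq`
#'   files there.
#' @return a list of class `amf_reads` with `$samples` (per-sample
#'   data.frames of id/seq1/qual1/seq2/qual2/source), `$truth` (the
#'   ground-truth per-sample proportions, inoculum shares, and source
#'   labels) and `$files` (paths, when written).
#' @export
make_reads <- function(config, reference, design, dir = NULL) {
  if (config$reads_per_sample < 1L)
    stop("reads_per_sample must be >= 1", call. = FALSE)
  comm <- sample_communities(config, design)
  am_ref <- reference[reference$group == "AM", ]
  out_ref <- reference[reference$group == "OUT", ]
  stopifnot(all(colnames(comm$proportions) %in% am_ref$otu_id))
  samples <- c(design$sample_id, "INOCULUM")
  n_inoc_ids <- otu_ids(config)$inoculum
  ml <- config$mate_length
  if (2L * ml - config$ref_length < 10L)
    stop("mate_length too short: mates must overlap by >= 10 nt",
         call. = FALSE)
  if (any(nchar(reference$seq) < ml))
    stop("reference sequences shorter than mate_length", call. = FALSE)
  # per-reference mate templates: first ml bases, and the reverse
  # complement of the last ml bases (mate 2 as sequenced)
  ref_chars <- strsplit(reference$seq, "", fixed = TRUE)
  heads_mat <- t(vapply(ref_chars, function(ch) ch[seq_len(ml)],
                        character(ml)))
  rctails_mat <- t(vapply(ref_chars, function(ch)
    unname(.comp[rev(ch)[seq_len(ml)]]), character(ml)))
  rownames(heads_mat) <- rownames(rctails_mat) <- reference$otu_id
  res <- with_seed(derive_seed(config$seed, 14L), {
    lapply(samples, function(sid) {
      if (sid == "INOCULUM") {
        props <- stats::setNames(numeric(ncol(comm$proportions)),
                                 colnames(comm$proportions))
        props[n_inoc_ids] <- comm$inoc_profile
      } else {
        props <- comm$proportions[sid, ]
      }
      n <- config$reads_per_sample
      kind <- sample(c("am", "out", "junk"), n, replace = TRUE,
                     prob = c(1 - config$outgroup_frac - config$junk_frac,
                              config$outgroup_frac, config$junk_frac))
      src <- character(n)
      src[kind == "am"] <- sample(names(props), sum(kind == "am"),
                                  replace = TRUE, prob = props)
      if (nrow(out_ref) && any(kind == "out"))
        src[kind == "out"] <- sample(out_ref$otu_id, sum(kind == "out"),
                                     replace = TRUE)
      else kind[kind == "out"] <- "junk"
      src[kind == "junk"] <- "JUNK"
      tpl1 <- matrix("", n, ml)
      tpl2 <- matrix("", n, ml)
      real <- kind != "junk"
      if (any(real)) {
        tpl1[real, ] <- heads_mat[src[real], ]
        tpl2[real, ] <- rctails_mat[src[real], ]
      }
      n_junk <- sum(!real)
      if (n_junk) {
        J <- matrix(sample(.bases, n_junk * config$ref_length,
                           replace = TRUE), n_junk)
        tpl1[!real, ] <- J[, seq_len(ml), drop = FALSE]
        tail_rev <- J[, config$ref_length:(config$ref_length - ml + 1L),
                      drop = FALSE]
        tpl2[!real, ] <- matrix(unname(.comp[tail_rev]), n_junk)
      }
      m1 <- build_mates(tpl1, config$read_error_rate)
      m2 <- build_mates(tpl2, config$read_error_rate)
      data.frame(
        id = sprintf("%s_read%05d", sid, seq_len(n)),
        seq1 = m1$seq, qual1 = m1$qual,
        seq2 = m2$seq, qual2 = m2$qual,
        source = src, stringsAsFactors = FALSE)
    })
  })
  names(res) <- samples
  truth <- list(proportions = comm$proportions,
                inoc_profile = comm$inoc_profile,
                inoc_share = stats::setNames(design$true_inoc_share,
                                             design$sample_id),
                inoculum_otus = n_inoc_ids)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- lapply(samples, function(sid) {
      f1 <- file.path(dir, paste0(sid, "_R1.fastq"))
      f2 <- file.path(dir, paste0(sid, "_R2.fastq"))
      write_fastq(res[[sid]]$id, res[[sid]]$seq1, res[[sid]]$qual1, f1)
      write_fastq(res[[sid]]$id, res[[sid]]$seq2, res[[sid]]$qual2, f2)
      c(r1 = f1, r2 = f2)
    })
    names(files) <- samples
  }
  structure(list(samples = res, truth = truth, files = files),
            class = "amf_reads")
}

write_fastq <- function(ids, seqs, quals, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Generate dilution-series bioassay outcomes
#'
#' For each trial x block, simulates a most-probable-number bioassay: at
#' each dilution `d` of the series, each of `n_plants_per_level`
#' replicate plants becomes colonized (positive) independently with
#' probability `1 - exp(-lambda * d * v)`, where `lambda` is the trial's
#' true propagule density and `v` the assay soil volume.
#'
#' @param config an [synth_config()] object.
#' @return a `data.frame` with columns `trial`, `block`, `dilution`,
#'   `volume_ml`, `n_tested`, `n_positive`; attribute `"lambda_true"`
#'   holds the per-trial densities.
#' @export
make_dilution_series <- function(config) {
  dens <- config$propagule_density_per_trial
  with_seed(derive_seed(config$seed, 15L), {
    g <- expand.grid(
      dilution = config$dilutions,
      block = seq_len(config$n_blocks),
      trial = seq_len(config$n_trials),
      KEEP.OUT.ATTRS = FALSE)[, c("trial", "block", "dilution")]
    g$trial <- sprintf("T%d", g$trial)
    lam <- dens[as.integer(sub("^T", "", g$trial))]
    g$volume_ml <- config$assay_volume_ml
    g$n_tested <- config$n_plants_per_level
    p_pos <- 1 - exp(-lam * g$dilution * g$volume_ml)
    g$n_positive <- stats::rbinom(nrow(g), g$n_tested, p_pos)
    attr(g, "lambda_true") <- stats::setNames(dens,
                                              sprintf("T%d", seq_along(dens)))
    g
  })
}
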