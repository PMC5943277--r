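# Pipeline orchestration: a validated configuration object, a
# one-command synthetic demo, and the staged run
# readproc -> classify -> tracking -> ecostats with logged read
# accounting and fully seeded, re-runnable outputs.

#' Pipeline configuration
#'
#' Collects paths and every stage threshold. The defaults are the
#' pipeline's canonical operating point: 3'-terminal quality 30, 200-nt
#' minimum read length, overlap merging within [10, 300] nt, E-value
#' 1e-100 with 95% identity and 330 nt (AM) / 220 nt (outgroup) minimum
#' alignment lengths, and rarefaction to 10,000 reads per sample.
#'
#' @param ref_fasta reference FASTA (`|AM` / `|OUT` header tags).
#' @param reads_dir directory of `<sample>_R1.fastq` / `_R2.fastq` pairs.
#' @param metadata_tsv sample metadata table.
#' @param out_dir output directory.
#' @param inoculum_sample sample id of the inoculum-only sequencing run.
#' @param qv_threshold,min_length,min_overlap,max_overlap,max_mismatch_rate
#'   read-processing thresholds.
#' @param identity_min,am_length_min,out_length_min,evalue_max
#'   classification acceptance criteria.
#' @param depth rarefaction depth.
#' @param n_perm PERMANOVA permutations.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a validated list of class `amf_pipeline_config`.
#' @export
pipeline_config <- function(ref_fasta, reads_dir, metadata_tsv, out_dir,
                            inoculum_sample = "INOCULUM",
                            qv_threshold = 30, min_length = 200,
                            min_overlap = 10, max_overlap = 300,
                            max_mismatch_rate = 0.1,
                            identity_min = 0.95, am_length_min = 330,
                            out_length_min = 220, evalue_max = 1e-100,
                            depth = 10000, n_perm = 9999, seed = 1) {
  cfg <- list(ref_fasta = ref_fasta, reads_dir = reads_dir,
              metadata_tsv = metadata_tsv, out_dir = out_dir,
              inoculum_sample = inoculum_sample,
              qv_threshold = as.numeric(qv_threshold),
              min_length = as.integer(min_length),
              min_overlap = as.integer(min_overlap),
              max_overlap = as.integer(max_overlap),
              max_mismatch_rate = as.numeric(max_mismatch_rate),
              identity_min = as.numeric(identity_min),
              am_length_min = as.integer(am_length_min),
              out_length_min = as.integer(out_length_min),
              evalue_max = as.numeric(evalue_max),
              depth = as.integer(depth), n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  if (cfg$identity_min < 0 || cfg$identity_min > 1)
    stop("identity_min must be in [0, 1]", call. = FALSE)
  if (cfg$min_overlap < 1 || cfg$max_overlap < cfg$min_overlap)
    stop("overlap range invalid", call. = FALSE)
  if (cfg$max_mismatch_rate < 0 || cfg$max_mismatch_rate > 1)
    stop("max_mismatch_rate must be in [0, 1]", call. = FALSE)
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  if (cfg$evalue_max <= 0) stop("evalue_max must be positive", call. = FALSE)
  if (cfg$qv_threshold < 0 || cfg$min_length < 1 || cfg$n_perm < 1)
    stop("thresholds out of range", call. = FALSE)
  structure(cfg, class = "amf_pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly.
#'
#' @param config an `amf_pipeline_config`.
#' @param path YAML path.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v)
}

#' Run the full analysis pipeline
#'
#' Stages run in order readproc (trim + merge every sample's read
#' pairs) -> classify (best-hit assignment, OTU table, rarefaction) ->
#' tracking (inoculum-set definition and per-sample tracked share) ->
#' ecostats (yield response, commonness, robustness, Bray-Curtis +
#' PERMANOVA, stepwise OLS of yield response, binomial GLMM of tracked
#' reads). Every artifact is written as TSV under `out_dir` together
#' with the configuration and a per-stage count log; re-running with
#' the same configuration is bit-identical.
#'
#' @param config an `amf_pipeline_config`.
#' @param quiet suppress console log lines.
#' @return (invisibly) a result bundle: list with `otu_table`,
#'   `rarefied`, `inoculum_set`, `tracking`, `yield_response`,
#'   `commonness`, `robustness`, `permanova`, `lm_fit`, `glmm_fit`,
#'   `qc`, `log`, `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "amf_pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    invisible(NULL)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- tryCatch(read_reference_fasta(config$ref_fasta),
                  error = function(e) fail("reference", e))
  meta <- tryCatch(
    utils::read.table(config$metadata_tsv, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) fail("metadata", e))
  r1 <- sort(list.files(config$reads_dir, pattern = "_R1\\.fastq$",
                        full.names = TRUE))
  samples <- sub("_R1\\.fastq$", "", basename(r1))
  if (!length(samples)) stop("no *_R1.fastq files in ", config$reads_dir,
                             call. = FALSE)

  # -- readproc ------------------------------------------------------
  assignments <- list()
  params <- alignment_params()
  criteria <- assign_criteria(evalue_max = config$evalue_max,
                              identity_min = config$identity_min,
                              am_length_min = config$am_length_min,
                              out_length_min = config$out_length_min)
  merged_all <- list()
  for (s in samples) {
    pr <- tryCatch(
      process_sample(file.path(config$reads_dir, paste0(s, "_R1.fastq")),
                     file.path(config$reads_dir, paste0(s, "_R2.fastq")),
                     qv_threshold = config$qv_threshold,
                     min_length = config$min_length,
                     min_overlap = config$min_overlap,
                     max_overlap = config$max_overlap,
                     max_mismatch_rate = config$max_mismatch_rate),
      error = function(e) fail(paste0("readproc:", s), e))
    merged_all[[s]] <- pr
    say("readproc %s: input=%d merged=%d rejected=%d", s,
        pr$counts[["input"]], pr$counts[["merged"]],
        pr$counts[["rejected"]])
  }

  # -- classify ------------------------------------------------------
  for (s in samples) {
    m <- merged_all[[s]]$merged
    assignments[[s]] <- tryCatch(
      classify_reads(stats::setNames(m$seq, m$id), ref, params, criteria),
      error = function(e) fail(paste0("classify:", s), e))
    say("classify %s: reads=%d assigned=%d", s, nrow(assignments[[s]]),
        sum(!assignments[[s]]$assignment %in%
              c("unassigned_AM_fail", "outgroup", "no_hit")))
  }
  otu <- build_otu_table(assignments, ref)
  rar <- tryCatch(
    rarefy(otu, depth = config$depth,
           seed = derive_seed(config$seed, 21L)),
    error = function(e) fail("rarefy", e))
  say("rarefy: %d/%d samples at depth %d", nrow(rar$counts),
      nrow(otu$counts), config$depth)

  # -- tracking ------------------------------------------------------
  inoc_set <- tryCatch(
    define_inoculum_set(rar, config$inoculum_sample),
    error = function(e) fail("tracking", e))
  trk <- track(rar, inoc_set)
  say("tracking: %d inoculum-type OTUs; mean share %.3f",
      length(inoc_set$otu_ids), mean(trk$share))

  # -- ecostats ------------------------------------------------------
  meta_f <- meta[match(trk$sample, meta$sample_id), ]
  yr <- tryCatch(yield_response(meta), error = function(e)
    fail("yield_response", e))
  field <- new_otu_table(
    rar$counts[intersect(rownames(rar$counts), meta$sample_id), ,
               drop = FALSE],
    rarefied = TRUE, depth = rar$depth)
  ctl_ids <- meta$sample_id[!meta$inoculated]
  ctl_tab <- field$counts[intersect(rownames(field$counts), ctl_ids), ,
                          drop = FALSE]
  cm <- tryCatch(
    commonness(ctl_tab, meta$trial[match(rownames(ctl_tab),
                                         meta$sample_id)],
               inoculum_set = inoc_set),
    error = function(e) fail("commonness", e))
  rb <- tryCatch(robustness(field, meta, inoculum_set = inoc_set),
                 error = function(e) fail("robustness", e))
  D <- bray_curtis_dist(field)
  meta_d <- meta[match(rownames(field$counts), meta$sample_id), ]
  pmv <- tryCatch(
    permanova(D, meta_d, ~ trial * inoculated,
              permutations = config$n_perm,
              seed = derive_seed(config$seed, 22L)),
    error = function(e) fail("permanova", e))
  say("permanova: trial F=%.2f p=%.4g", pmv$F[1], pmv$p[1])

  # regressions: tracked share (percent of AM reads) against yield
  # response; tracked reads against environmental covariates
  trk_f <- trk[match(meta$sample_id, trk$sample), ]
  meta$r10_share_pct <- 100 * trk_f$share
  meta$tracked_reads <- trk_f$tracked_reads
  yr$r10_share_pct <- meta$r10_share_pct[match(yr$sample_id,
                                               meta$sample_id)]
  env_cands <- intersect(c("p_level", "phos_abs_coef", "nitrate_n",
                           "exch_k", "avail_p"), names(meta))
  lm_data <- merge(yr[, c("sample_id", "response", "r10_share_pct")],
                   meta[, c("sample_id", env_cands)], by = "sample_id")
  lm_fit <- tryCatch(
    stepwise_lm(lm_data, "response", c("r10_share_pct", env_cands)),
    error = function(e) fail("stepwise_lm", e))
  meta_i <- meta[meta$inoculated & !is.na(meta$tracked_reads), ]
  meta_i$depth <- rar$depth
  glmm_cands <- intersect(c("p_level", "phos_abs_coef", "mpn_true",
                            "nitrate_n", "exch_k"), names(meta_i))
  glmm_fit <- tryCatch(
    logistic_glmm(meta_i, "tracked_reads", "depth", glmm_cands, "block",
                  standardize = TRUE),
    error = function(e) fail("logistic_glmm", e))
  say("regressions: OLS terms {%s}; GLMM AIC %.1f",
      paste(lm_fit$selected, collapse = ","), glmm_fit$aic)

  # -- outputs -------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  wtsv <- function(d, f) {
    utils::write.table(d, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out(f)
  }
  files <- c(
    otu_table = write_otu_table(otu, out("otu_table.tsv")),
    rarefied = write_otu_table(rar, out("otu_table_rarefied.tsv")),
    qc = wtsv(otu$qc, "qc_report.tsv"),
    tracking = wtsv(trk, "tracking.tsv"),
    yield_response = wtsv(yr, "yield_response.tsv"),
    commonness = wtsv(data.frame(otu_id = names(cm$commonness),
                                 commonness = cm$commonness),
                      "commonness.tsv"),
    robustness = wtsv(rb, "robustness.tsv"),
    permanova = wtsv(as.data.frame(pmv), "permanova.tsv"),
    lm_fit = wtsv(lm_fit$coefficients, "stepwise_lm.tsv"),
    glmm_fit = wtsv(glmm_fit$coefficients, "logistic_glmm.tsv"),
    config = write_pipeline_config(config, out("config.yaml")))
  writeLines(log_lines, out("log.txt"))
  files <- c(files, log = out("log.txt"))
  invisible(list(otu_table = otu, rarefied = rar, inoculum_set = inoc_set,
                 tracking = trk, yield_response = yr, commonness = cm,
                 robustness = rb, permanova = pmv, lm_fit = lm_fit,
                 glmm_fit = glmm_fit, qc = otu$qc, log = log_lines,
                 files = files))
}

#' Generate a self-contained synthetic demo fixture set
#'
#' Calls the synthetic-data generator with a compact default
#' configuration (3 trials x 4 blocks, 25 AM OTUs, 5,000 read pairs per
#' sample), writes reference FASTA, per-sample FASTQ pairs, metadata,
#' ground truth, and dilution series under `dir`, and returns a ready
#' [pipeline_config()] pointing at them plus the ground-truth manifest.
#'
#' @param seed master seed.
#' @param dir fixture directory (created).
#' @param reads_per_sample read pairs per sample.
#' @param depth rarefaction depth for the demo run (below the per-sample
#'   read count so no sample is dropped).
#' @param n_perm PERMANOVA permutations for the demo run.
#' @param ... further overrides passed to [synth_config()].
#' @return list: `config` (pipeline configuration), `synth_config`,
#'   `truth` (ground-truth proportions/shares), `dilution` (bioassay
#'   table), `files`.
#' @export
make_demo <- function(seed = 1, dir = tempfile("amf_demo"),
                      reads_per_sample = 5000,
                      depth = floor(reads_per_sample * 0.6),
                      n_perm = 999, ...) {
  scfg <- synth_config(seed = seed, reads_per_sample = reads_per_sample,
                       ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(scfg)
  design <- make_design(scfg)
  reads <- make_reads(scfg, ref, design, dir = file.path(dir, "reads"))
  dil <- make_dilution_series(scfg)
  ref_path <- file.path(dir, "reference.fasta")
  write_reference_fasta(ref, ref_path)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(design, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dil_path <- file.path(dir, "dilution_series.tsv")
  utils::write.table(dil, dil_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth_shares.tsv")
  utils::write.table(
    data.frame(sample_id = names(reads$truth$inoc_share),
               true_inoc_share = reads$truth$inoc_share),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- pipeline_config(
    ref_fasta = ref_path, reads_dir = file.path(dir, "reads"),
    metadata_tsv = meta_path, out_dir = file.path(dir, "out"),
    depth = depth, n_perm = n_perm, seed = seed)
  list(config = cfg, synth_config = scfg, truth = reads$truth,
       dilution = dil,
       files = c(reference = ref_path, metadata = meta_path,
                 dilution = dil_path, truth = truth_path))
}
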