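# Synthetic-data generator: determinism, ground-truth bookkeeping, and
# agreement of the stochastic models with their closed forms.

test_that("configuration validation rejects out-of-range values", {
  expect_error(synth_config(n_blocks = 0), "n_blocks")
  expect_error(synth_config(read_error_rate = 1.5), "probability")
  expect_error(synth_config(ref_length = 300), "330")
  expect_error(synth_config(outgroup_frac = 0.6, junk_frac = 0.6), "< 1")
})

test_that("reference generation honours counts, tags, and divergence", {
  cfg <- small_cfg(n_indigenous_otus = 20, n_inoculum_otus = 3)
  ref <- make_reference(cfg)
  expect_equal(sum(ref$group == "AM"), 23)
  expect_equal(sum(ref$group == "OUT"), cfg$n_outgroup_seqs)
  expect_equal(sum(ref$inoculum), 3)
  # all-vs-all divergence, checked through the aligner: AM pairs below
  # 95% identity, outgroup far from every AM sequence
  am <- ref$seq[ref$group == "AM"]
  for (i in seq_len(length(am) - 1)) {
    idt <- amfniche:::global_identity(am[i], am[(i + 1):length(am)])
    expect_true(all(idt < 0.95))
  }
  out <- ref$seq[ref$group == "OUT"]
  expect_true(all(amfniche:::global_identity(out[1], am) < 0.80))
})

test_that("identical config and seed reproduce every artifact exactly", {
  cfg <- small_cfg(reads_per_sample = 30)
  w1 <- list(make_reference(cfg, validate = FALSE), make_design(cfg),
             make_dilution_series(cfg))
  w2 <- list(make_reference(cfg, validate = FALSE), make_design(cfg),
             make_dilution_series(cfg))
  expect_identical(w1, w2)
  r1 <- make_reads(cfg, w1[[1]], w1[[2]])
  r2 <- make_reads(cfg, w1[[1]], w1[[2]])
  expect_identical(r1$samples, r2$samples)
  # FASTA serialization is byte-identical too
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference_fasta(w1[[1]], f1); write_reference_fasta(w2[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("design is the full crossed layout with the generating yield model", {
  cfg <- synth_config(n_trials = 3, n_blocks = 4, p_levels = c(0, 100),
                      seed = 5)
  d <- make_design(cfg)
  expect_equal(nrow(d), 3 * 4 * 2 * 2)
  expect_equal(anyDuplicated(d[, c("trial", "block", "p_level",
                                   "inoculated")]), 0)
  expect_true(all(d$mpn_true ==
                    cfg$propagule_density_per_trial[
                      as.integer(sub("T", "", d$trial))]))
  # noiseless yields are exactly baseline + effect * share
  cfg0 <- synth_config(yield_noise_sd = 0, inoculum_effect = 500, seed = 5)
  d0 <- make_design(cfg0)
  expect_equal(d0$yield, 3000 + 500 * d0$true_inoc_share, tolerance = 1e-12)
  # with zero effect and zero noise, yield responses vanish
  cfg00 <- synth_config(yield_noise_sd = 0, inoculum_effect = 0, seed = 5)
  yr <- yield_response(make_design(cfg00))
  expect_equal(yr$response, rep(0, nrow(yr)), tolerance = 1e-12)
})

test_that("ground-truth proportions sum to one and share falls with propagule density", {
  w <- small_world()
  P <- w$reads$truth$proportions
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  # inoculum share in the mixture equals the design's true share
  inoc_cols <- w$reads$truth$inoculum_otus
  expect_equal(unname(rowSums(P[, inoc_cols])),
               unname(w$reads$truth$inoc_share[rownames(P)]),
               tolerance = 1e-12)
  # hypothesis structure: mean inoculated share non-increasing in
  # propagule density (plots pooled per distinct density)
  d <- w$design[w$design$inoculated, ]
  m <- tapply(d$true_inoc_share, d$mpn_true, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) <= 0))
})

test_that("error-free reads copy their source references exactly", {
  cfg <- small_cfg(read_error_rate = 0, junk_frac = 0, outgroup_frac = 0,
                   reads_per_sample = 40)
  ref <- make_reference(cfg, validate = FALSE)
  d <- make_design(cfg)
  reads <- make_reads(cfg, ref, d)
  s <- reads$samples[[1]]
  refseq <- setNames(ref$seq, ref$otu_id)
  ml <- cfg$mate_length
  for (i in seq_len(nrow(s))) {
    tpl <- refseq[[s$source[i]]]
    expect_identical(s$seq1[i], substr(tpl, 1, ml))
    expect_identical(s$seq2[i],
                     amfniche:::revcomp(substr(tpl, nchar(tpl) - ml + 1,
                                               nchar(tpl))))
  }
  expect_true(all(strsplit(s$qual1[1], "")[[1]] == intToUtf8(40 + 33)))
})

test_that("controls with zero background share contain no inoculum reads", {
  cfg <- small_cfg(background_share = 0, read_error_rate = 0,
                   junk_frac = 0, outgroup_frac = 0, reads_per_sample = 50)
  ref <- make_reference(cfg, validate = FALSE)
  d <- make_design(cfg)
  reads <- make_reads(cfg, ref, d)
  ctl <- d$sample_id[!d$inoculated]
  inoc_ids <- amfniche:::otu_ids(cfg)$inoculum
  for (sid in ctl)
    expect_false(any(reads$samples[[sid]]$source %in% inoc_ids))
})

test_that("observed per-base error rate matches the configured rate", {
  cfg <- small_cfg(read_error_rate = 0.01, junk_frac = 0,
                   outgroup_frac = 0, reads_per_sample = 150)
  ref <- make_reference(cfg, validate = FALSE)
  d <- make_design(cfg)
  reads <- make_reads(cfg, ref, d)
  refseq <- setNames(ref$seq, ref$otu_id)
  ml <- cfg$mate_length
  mism <- 0; total <- 0
  for (s in reads$samples[1:4]) {
    tpl <- substr(refseq[s$source], 1, ml)
    a <- strsplit(s$seq1, ""); b <- strsplit(tpl, "")
    mism <- mism + sum(mapply(function(x, y) sum(x != y), a, b))
    total <- total + length(s$seq1) * ml
  }
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(mism / total - 0.01), 3 * se)
})

test_that("dilution-series positives follow the Poisson exposure model", {
  # closed form: lambda*d*v = 1 -> P(positive) = 1 - exp(-1)
  cfg <- synth_config(n_trials = 1, n_blocks = 1,
                      propagule_density_per_trial = 1,
                      assay_volume_ml = 1, dilutions = 1,
                      n_plants_per_level = 10000, seed = 31)
  ds <- make_dilution_series(cfg)
  p_hat <- ds$n_positive / ds$n_tested
  se <- sqrt(0.632 * 0.368 / 10000)
  expect_lt(abs(p_hat - (1 - exp(-1))), 3 * se)
  # degenerate cases
  cfg0 <- synth_config(n_trials = 1, n_blocks = 2,
                       propagule_density_per_trial = 0,
                       dilutions = 2^c(-1, -3), seed = 31)
  expect_true(all(make_dilution_series(cfg0)$n_positive == 0))
  cfg_inf <- synth_config(n_trials = 1, n_blocks = 2,
                          propagule_density_per_trial = 1e9,
                          dilutions = 2^c(-1, -3), seed = 31)
  ds_inf <- make_dilution_series(cfg_inf)
  expect_true(all(ds_inf$n_positive == ds_inf$n_tested))
})
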