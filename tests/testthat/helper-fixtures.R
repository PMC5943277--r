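# Shared small fixtures, built once per test run. Sizes are kept small:
# the synthetic generator is exercised at full scale only in the
# acceptance suite.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 2, reads_per_sample = 120, seed = 101), list(...))
  do.call(synth_config, args)
}

# One cached small reference + design (validation alignment is the
# expensive part).
.fx <- new.env()
small_world <- function() {
  if (is.null(.fx$world)) {
    cfg <- small_cfg()
    ref <- make_reference(cfg)
    design <- make_design(cfg)
    .fx$world <- list(cfg = cfg, ref = ref, design = design,
                      reads = make_reads(cfg, ref, design))
  }
  .fx$world
}

# Phred+33 helper for constructing reads by hand.
qstr <- function(q, n = 1) paste(rep(intToUtf8(q + 33), n), collapse = "")
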