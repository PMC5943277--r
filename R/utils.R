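# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so seeded operations inside the
#' package never disturb the caller's random number stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a single master seed. Fixed affine map modulo a
# Mersenne prime keeps every derived seed a valid 32-bit integer and makes
# one master seed fan out reproducibly across pipeline stages.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) + 1000003 * as.double(stage)) %% 2147483647)
}

# Random DNA of given length(s).
random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Substitute bases i.i.d. at rate `rate`; substitutions are always to a
# different base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

# Reverse complement of ACGTN strings (vectorized, base R).
revcomp <- function(seq) {
  vapply(seq, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))),
    character(1), USE.NAMES = FALSE)
}

# Phred+33 encoding helpers.
phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(as.integer(round(q)), 0L), 41L) + 33L, multiple = FALSE)
}

char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
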