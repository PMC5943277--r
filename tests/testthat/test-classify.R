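# Alignment, best-hit assignment criteria, OTU tables, rarefaction.

test_that("alignment scores match the brute-force dynamic-programming oracle", {
  # exhaustive small-pair sweep: random pairs up to 50 nt, including
  # identical, disjoint, and indel-containing cases
  pars <- alignment_params()
  cases <- list()
  set.seed(9)
  for (i in 1:30) {
    la <- sample(5:50, 1); lb <- sample(5:50, 1)
    cases[[length(cases) + 1]] <- c(toy_dna(1, la, seed = i),
                                    toy_dna(1, lb, seed = 1000 + i))
  }
  # related pair with an internal deletion
  base <- toy_dna(1, 50, seed = 77)
  cases[[length(cases) + 1]] <- c(base, paste0(substr(base, 1, 20),
                                               substr(base, 26, 50)))
  cases[[length(cases) + 1]] <- c(base, base)
  for (cs in cases) {
    got <- align_read(cs[1], cs[2], pars, both_strands = FALSE)$score
    expect_equal(got, sw_score_oracle(cs[1], cs[2]))
  }
})

test_that("both strands are searched with identical scores", {
  ref <- toy_dna(1, 120, seed = 3)
  pars <- alignment_params()
  fwd <- align_read(ref, c(r = ref), pars)
  rev <- align_read(amfniche:::revcomp(ref), c(r = ref), pars)
  expect_equal(fwd$score, rev$score)
  expect_equal(rev$strand, "-")
  expect_equal(fwd$identity, 1.0)
  expect_equal(fwd$aln_length, 120)
})

test_that("non-nucleotide characters are an input error", {
  expect_error(align_read("ACGU", "ACGT"), "ACGTN")
})

test_that("dual acceptance criteria drive the assignment labels", {
  w <- small_world()
  ref <- w$ref
  am1 <- ref$otu_id[ref$group == "AM"][1]
  refseq <- setNames(ref$seq, ref$otu_id)
  # perfect copy of an AM OTU
  a <- assign_read(refseq[[am1]], ref)
  expect_identical(a$assignment, am1)
  # ~90% identity to its best AM OTU fails the identity rule
  set.seed(11)
  noisy <- amfniche:::mutate_seq(refseq[[am1]], 0.10)
  a <- assign_read(noisy, ref)
  expect_identical(a$assignment, "unassigned_AM_fail")
  expect_lt(a$identity, 0.95)
  # a 250-nt piece of an outgroup record: passes the 220-nt outgroup
  # rule (and could never pass the 330-nt AM rule)
  out1 <- ref$otu_id[ref$group == "OUT"][1]
  frag <- substr(refseq[[out1]], 1, 250)
  a <- assign_read(frag, ref)
  expect_identical(a$assignment, "outgroup")
  expect_gte(a$aln_length, 220)
  # a 250-nt piece of an AM record fails the 330-nt AM length rule
  frag_am <- substr(refseq[[am1]], 1, 250)
  a <- assign_read(frag_am, ref)
  expect_identical(a$assignment, "unassigned_AM_fail")
  # random junk hits nothing
  a <- assign_read(toy_dna(1, 360, seed = 12), ref)
  expect_true(a$assignment %in% c("no_hit", "unassigned_AM_fail"))
  expect_error(classify_reads("ACGT", ref[ref$group == "OUT", ]),
               "AM record")
})

test_that("prescreened batch classification agrees with exhaustive search", {
  w <- small_world()
  s <- w$reads$samples[[2]]
  pr <- process_sample(data.frame(id = s$id, seq = s$seq1, qual = s$qual1),
                       data.frame(id = s$id, seq = s$seq2, qual = s$qual2))
  reads <- setNames(pr$merged$seq, pr$merged$id)[1:40]
  fast <- classify_reads(reads, w$ref, prescreen = TRUE)
  slow <- classify_reads(reads, w$ref, prescreen = FALSE)
  expect_identical(fast$assignment, slow$assignment)
})

test_that("lowering the identity threshold never loses assignments", {
  w <- small_world()
  s <- w$reads$samples[[2]]
  pr <- process_sample(data.frame(id = s$id, seq = s$seq1, qual = s$qual1),
                       data.frame(id = s$id, seq = s$seq2, qual = s$qual2))
  reads <- setNames(pr$merged$seq, pr$merged$id)[1:60]
  n_assigned <- function(idmin) {
    cl <- classify_reads(reads, w$ref,
                         criteria = assign_criteria(identity_min = idmin))
    sum(!cl$assignment %in% c("unassigned_AM_fail", "outgroup", "no_hit"))
  }
  counts <- vapply(c(0.99, 0.95, 0.90, 0.80), n_assigned, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("OTU tables count AM assignments and conserve reads", {
  assign_df <- function(ids, labels)
    data.frame(read_id = ids, assignment = labels,
               stringsAsFactors = FALSE)
  ref <- data.frame(otu_id = c("OTU_001", "OTU_002", "OUT_01"),
                    group = c("AM", "AM", "OUT"),
                    seq = strrep("A", 360), stringsAsFactors = FALSE)
  a <- list(
    s1 = assign_df(paste0("r", 1:5),
                   c("OTU_001", "OTU_001", "OTU_002", "outgroup",
                     "no_hit")),
    s2 = assign_df(paste0("q", 1:3),
                   c("unassigned_AM_fail", "OTU_002", "OTU_002")))
  tab <- build_otu_table(a, ref)
  expect_equal(unname(tab$counts["s1", ]), c(2L, 1L))
  expect_equal(unname(tab$counts["s2", ]), c(0L, 2L))
  expect_equal(tab$qc$input,
               tab$qc$assigned + tab$qc$unassigned_AM_fail +
                 tab$qc$outgroup + tab$qc$no_hit)
  # all-zero table when nothing is assigned
  tab0 <- build_otu_table(list(s = assign_df("r1", "no_hit")), ref)
  expect_true(all(tab0$counts == 0))
  # duplicate read ids are an error
  expect_error(build_otu_table(
    list(s = assign_df(c("r1", "r1"), c("OTU_001", "OTU_002"))), ref),
    "duplicate")
})

test_that("rarefaction draws exactly depth reads without replacement", {
  set.seed(20)
  counts <- matrix(rpois(12, 800), 3, 4,
                   dimnames = list(paste0("s", 1:3), paste0("o", 1:4)))
  tab <- amfniche:::new_otu_table(counts, rarefied = FALSE)
  r <- rarefy(tab, depth = 1000, seed = 4)
  expect_true(all(rowSums(r$counts) == 1000))
  expect_true(all(r$counts <= counts))
  expect_identical(rarefy(tab, depth = 1000, seed = 4)$counts, r$counts)
  # sample exactly at depth is unchanged
  exact <- matrix(c(600L, 400L), 1, 2,
                  dimnames = list("s", c("a", "b")))
  te <- amfniche:::new_otu_table(exact, rarefied = FALSE)
  expect_equal(rarefy(te, depth = 1000, seed = 1)$counts, exact)
  # short samples are dropped with a warning
  expect_warning(r2 <- rarefy(tab, depth = 3500, seed = 1), "dropping")
  expect_lt(nrow(r2$counts), 3)
  expect_error(rarefy(tab, depth = 0), "positive")
})

test_that("rarefied counts are hypergeometric in expectation", {
  counts <- matrix(c(3000L, 1000L), 1, 2,
                   dimnames = list("s", c("a", "b")))
  tab <- amfniche:::new_otu_table(counts, rarefied = FALSE)
  draws <- vapply(1:400, function(sd)
    rarefy(tab, depth = 400, seed = sd)$counts[1, "a"], numeric(1))
  # E[count] = depth * share = 400 * 0.75; hypergeometric s.e.
  se <- sqrt(400 * 0.75 * 0.25 * (4000 - 400) / (4000 - 1)) / sqrt(400)
  expect_lt(abs(mean(draws) - 300), 3 * se)
})

test_that("proportional scaling normalizes totals exactly", {
  counts <- matrix(c(1500L, 500L, 7L, 300L, 600L, 0L), 2, 3,
                   byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:3)))
  tab <- amfniche:::new_otu_table(counts, rarefied = FALSE)
  r <- rarefy(tab, depth = 1000, method = "scale")
  expect_true(all(rowSums(r$counts) == 1000))
  # shares preserved up to rounding
  expect_equal(r$counts["s1", "o1"] / 1000, 1500 / 2007, tolerance = 1e-3)
})

test_that("OTU tables round-trip through TSV", {
  w <- small_world()
  counts <- matrix(1:6, 2, 3,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:3)))
  tab <- amfniche:::new_otu_table(counts, rarefied = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_otu_table(tab, f)
  back <- read_otu_table(f)
  expect_equal(back$counts, counts)
})
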