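test_that("pair matrix is symmetric, non-negative and background-normalized", {
  m <- shared_matrix
  expect_true(all(m$scores >= 0))
  expect_equal(m$scores, t(m$scores))
  f <- residue_frequencies()
  expect_equal(sum(outer(f, f) * m$scores[names(f), names(f)]), 1,
               tolerance = 1e-9)
  # direct formula vs table lookup
  n <- normalized_values(hydro_scale(kyte_doolittle()))
  expect_equal(m$scores["I", "L"], m$constant * n[["I"]] * n[["L"]],
               tolerance = 1e-12)
  # ambiguity letters score at the background-mean hydrophobicity
  expect_equal(m$scores["X", "L"], m$constant * m$nbar * n[["L"]],
               tolerance = 1e-12)
  expect_true(all(c("X", "B", "Z", "U", "O") %in% rownames(m$scores)))
})

test_that("two-letter toy matrix solves the normalization by hand", {
  # n = (0, 1), uniform background: the only nonzero cell is (hyd, hyd)
  # and mean 1 forces c * 1/4 = 1, so M(hyd, hyd) = 4.
  m <- pair_score_matrix(hydro_scale(c(p = 0, y = 1), "toy2"),
                         c(p = 0.5, y = 0.5), ambiguity = character())
  expect_equal(m$scores["y", "y"], 4)
  expect_equal(m$scores["p", "y"], 0)
  expect_equal(m$scores["p", "p"], 0)
})

test_that("degenerate scales and bad backgrounds are configuration errors", {
  expect_error(hydro_scale(c(A = 1, B = 1)), "degenerate")
  expect_error(pair_score_matrix(background = c(A = 1)),
               "missing for residue")
  bad <- residue_frequencies()
  bad["L"] <- bad["L"] + 0.1
  expect_error(pair_score_matrix(background = bad), "sum to 1")
})

test_that("matrix serialization round-trips scoring exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_pair_matrix(shared_matrix, f)
  back <- read_pair_matrix(f)
  ln <- rownames(shared_matrix$scores)
  expect_equal(back$scores[ln, ln], shared_matrix$scores)
  expect_setequal(back$ambiguity, shared_matrix$ambiguity)
})

test_that("alignment surface matches the brute-force windowed mean", {
  m <- shared_matrix
  # homopolymer, window 1: constant surface at M(A, A)
  s <- alignment_surface("AAAA", "AAAA", m, window = 1)
  expect_equal(s$S, matrix(m$scores["A", "A"], 4, 4))

  set.seed(500)
  for (i in 1:5) {
    aa <- rownames(m$scores)[1:20]
    q <- paste(sample(aa, 5, replace = TRUE), collapse = "")
    r <- paste(sample(aa, 5, replace = TRUE), collapse = "")
    got <- alignment_surface(q, r, m, window = 3)
    expect_equal(got$S, oracle_surface(q, r, m$scores, 3), tolerance = 1e-12)
    # transpose symmetry from the symmetry of M
    expect_equal(alignment_surface(r, q, m, window = 3)$S, t(got$S),
                 tolerance = 1e-12)
  }
  expect_error(alignment_surface("AAA", "AAA", m, window = 4), "odd")
  expect_error(alignment_surface("AAA", "AAA", m, window = 0), "odd")
})

test_that("cumulative and cross-weighted profiles match their definitions", {
  # constant surface -> constant profiles
  s <- alignment_surface("LLLL", "LLLL", shared_matrix, window = 1)
  v <- shared_matrix$scores["L", "L"]
  expect_equal(as.numeric(cumulative_profile(s)), rep(v, 4))
  expect_equal(as.numeric(cross_weighted_profile(s)), rep(v, 4))

  set.seed(501)
  fake <- function(S) structure(list(S = S, window = 1,
                                     query_id = NA, reference_id = NA),
                                class = "alignment_surface")
  S <- matrix(runif(24), 4, 6)
  expect_equal(as.numeric(cumulative_profile(fake(S))), rowMeans(S),
               tolerance = 1e-12)
  expect_equal(as.numeric(cumulative_profile(fake(S), "reference")),
               colMeans(S), tolerance = 1e-12)

  S2 <- matrix(runif(48), 6, 8)
  cw <- cross_weighted_profile(fake(S2))
  cr <- colMeans(S2)
  manual <- sapply(1:6, function(i) sum(S2[i, ] * cr) / sum(cr))
  expect_equal(as.numeric(cw), manual, tolerance = 1e-12)

  # single nonzero column concentrates all weight there
  S3 <- matrix(0, 5, 4); S3[, 3] <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(cross_weighted_profile(fake(S3))), c(1, 2, 3, 4, 5))
  # all-zero surface: degenerate weights rule gives a zero profile
  expect_equal(as.numeric(cross_weighted_profile(fake(matrix(0, 3, 3)))),
               rep(0, 3))
})

test_that("das_profile composes, averages and excludes self", {
  m <- shared_matrix
  lib <- shared_library$records
  q <- synth_tm_protein(n_segments = 2, seed = 77)

  # library of one member: profile equals that member's cross-weighted one
  one <- lib[3, , drop = FALSE]
  expect_equal(as.numeric(das_profile(q, one, m)),
               as.numeric(cross_weighted_profile(
                 alignment_surface(q$seq, one$seq, m, 15))))

  # four identical copies: identical to the single-member result, exactly
  copies <- one[rep(1, 4), ]
  copies$id <- paste0("copy", 1:4)
  expect_identical(as.numeric(das_profile(q, copies, m)),
                   as.numeric(das_profile(q, copies[1, ], m)))

  # compositional oracle: mean of the 8 individual profiles
  manual <- rowMeans(sapply(seq_len(nrow(lib)), function(i)
    as.numeric(cross_weighted_profile(
      alignment_surface(q$seq, lib$seq[i], m, 15)))))
  expect_equal(as.numeric(das_profile(q, lib, m)), manual, tolerance = 1e-12)

  # self-exclusion by id
  self <- lib[1, , drop = FALSE]
  others <- lib[-1, , drop = FALSE]
  expect_equal(as.numeric(das_profile(self, lib, m)),
               as.numeric(das_profile(self, others, m)), tolerance = 1e-15)
  expect_error(das_profile(self, self, m), "empty after self-exclusion")
})

test_that("das pipeline is linear in the matrix and monotone in hydrophobicity", {
  m <- shared_matrix
  lib <- shared_library
  q <- synth_tm_protein(n_segments = 2, seed = 31)
  d1 <- as.numeric(das_profile(q, lib, m))
  m3 <- m
  m3$scores <- 3 * m$scores
  expect_equal(as.numeric(das_profile(q, lib, m3)), 3 * d1,
               tolerance = 1e-12)

  # homopolymer queries ordered by normalized hydrophobicity
  n <- normalized_values(hydro_scale(kyte_doolittle()))
  for (pair in list(c("S", "A"), c("A", "L"), c("T", "V"), c("R", "I"))) {
    lo <- strrep(pair[1], 30); hi <- strrep(pair[2], 30)
    expect_true(n[[pair[2]]] > n[[pair[1]]])
    expect_true(all(as.numeric(das_profile(hi, lib, m)) >=
                      as.numeric(das_profile(lo, lib, m))))
  }

  # poly-Leu clearly beats poly-Ser in the interior
  dL <- as.numeric(das_profile(strrep("L", 30), lib, m))
  dS <- as.numeric(das_profile(strrep("S", 30), lib, m))
  expect_true(all(dL[8:23] > dS[8:23]))
})

test_that("profile TSV export writes one row per residue", {
  q <- "MKTLLILV"
  p <- das_profile(q, shared_library, shared_matrix)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, q, f)
  d <- read.delim(f)
  expect_equal(nrow(d), nchar(q))
  expect_equal(d$residue, strsplit(q, "")[[1]])
  expect_equal(d$score, as.numeric(p), tolerance = 1e-6)
})
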