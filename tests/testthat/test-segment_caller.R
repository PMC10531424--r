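test_that("call_segments extracts maximal runs at or above the cutoff", {
  p <- caller_params()
  expect_equal(nrow(call_segments(c(1, 2, 2.4, 1), p)), 0L)

  segs <- call_segments(c(1, 3, 3, 1, 1, 3, 1), p)
  expect_equal(segs$start, c(2L, 6L))
  expect_equal(segs$end, c(3L, 6L))
  expect_equal(segs$peak, c(3, 3))
  expect_equal(segs$mean_excess, c(0.5, 0.5))

  # the boundary is inclusive: exactly 2.5 is called
  segs <- call_segments(c(1, 2.5, 1), p)
  expect_equal(segs[, c("start", "end")], data.frame(start = 2L, end = 2L))

  # runs touching the profile ends
  segs <- call_segments(c(3, 3, 1, 3), p)
  expect_equal(segs$start, c(1L, 4L))
  expect_equal(segs$end, c(2L, 4L))
})

test_that("called segments are maximal and monotone in the cutoff", {
  set.seed(600)
  for (i in 1:25) {
    prof <- runif(60, 0, 5)
    segs <- call_segments(prof, caller_params())
    for (s in seq_len(nrow(segs))) {
      expect_true(all(prof[segs$start[s]:segs$end[s]] >= 2.5))
      if (segs$start[s] > 1) expect_lt(prof[segs$start[s] - 1], 2.5)
      if (segs$end[s] < 60) expect_lt(prof[segs$end[s] + 1], 2.5)
    }
    called <- function(cutoff)
      sum(call_segments(prof, caller_params(cutoff = cutoff))$end -
            call_segments(prof, caller_params(cutoff = cutoff))$start + 1)
    n_called <- vapply(c(1, 2, 2.5, 3, 4), called, 0)
    expect_true(all(diff(n_called) <= 0))
  }
})

test_that("warnings flag N-terminal and twin-peak segments without altering them", {
  p <- caller_params()
  seg <- function(s, e) data.frame(start = s, end = e, peak = 3,
                                   mean_excess = 0.5, peak_pos = s,
                                   possible_signal_peptide = FALSE,
                                   twin_peak = FALSE)
  one <- annotate_warnings(seg(3, 20), p)
  expect_true(one$possible_signal_peptide)
  expect_false(one$twin_peak)

  pair <- annotate_warnings(rbind(seg(30, 50), seg(52, 70)), p)
  expect_equal(pair$twin_peak, c(TRUE, TRUE))      # gap of 1 <= 4
  expect_equal(pair$possible_signal_peptide, c(FALSE, FALSE))

  far <- annotate_warnings(rbind(seg(30, 50), seg(56, 70)), p)
  expect_equal(far$twin_peak, c(FALSE, FALSE))     # gap of 5 > 4

  none <- annotate_warnings(seg(40, 60), p)
  expect_false(any(none$possible_signal_peptide, none$twin_peak))

  # boundary: start exactly at the signal window; gap exactly at twin_gap
  expect_true(annotate_warnings(seg(25, 40), p)$possible_signal_peptide)
  expect_false(annotate_warnings(seg(26, 41), p)$possible_signal_peptide)
  exact <- annotate_warnings(rbind(seg(30, 50), seg(55, 70)), p)
  expect_equal(exact$twin_peak, c(TRUE, TRUE))     # gap of 4 <= 4

  expect_error(annotate_warnings(rbind(seg(30, 50), seg(40, 60)), p),
               "non-overlapping")
})

test_that("quality value is the maximum segment peak", {
  p <- caller_params()
  seg <- data.frame(start = c(10L, 40L), end = c(20L, 55L),
                    peak = c(2.8, 3.9), mean_excess = 0, peak_pos = c(12L, 44L),
                    possible_signal_peptide = FALSE, twin_peak = FALSE)
  expect_equal(quality_value(runif(60), seg, p), 3.9)
  expect_equal(quality_value(runif(60), seg[1, ], p), 2.8)
  expect_error(quality_value(runif(60), seg[0, ], p), "undefined")
})

test_that("classification follows the segment-count and quality rules", {
  p <- caller_params()
  seg <- function(n) data.frame(start = seq(1, by = 30, length.out = n),
                                end = seq(20, by = 30, length.out = n))
  expect_equal(classify_protein(seg(3), NA, p), "TM")
  expect_equal(classify_protein(seg(2), NA, p), "TM")
  expect_equal(classify_protein(seg(0), NA, p), "non-TM")
  expect_equal(classify_protein(seg(1), quality = 2.6, p), "non-TM")
  expect_equal(classify_protein(seg(1), quality = 3.0, p), "TM")
  expect_equal(classify_protein(seg(1), quality = 4.1, p), "TM")
  expect_error(classify_protein(seg(1), NA, p), "quality")
  # monotone in quality for the single-segment case
  calls <- vapply(c(1, 2.9, 3, 3.5, 5),
                  function(q) classify_protein(seg(1), q, p), "")
  expect_equal(calls, c("non-TM", "non-TM", "TM", "TM", "TM"))
})

test_that("das_predict runs the full pipeline deterministically", {
  q2 <- synth_tm_protein(n_segments = 2, seed = 42)
  pred <- das_predict(q2, shared_library, shared_matrix)
  expect_s3_class(pred, "das_prediction")
  expect_equal(nrow(pred$segments), 2L)
  expect_equal(pred$classification, "TM")
  # trusted mode with >1 segment: no quality computed
  expect_true(is.na(pred$quality))

  glob <- synth_globular(length = 250, seed = 8)
  predg <- das_predict(glob, shared_library, shared_matrix)
  expect_equal(nrow(predg$segments), 0L)
  expect_equal(predg$classification, "non-TM")

  # unconditional mode always computes quality when segments exist
  predu <- das_predict(q2, shared_library, shared_matrix,
                       params = caller_params(mode = "unconditional"))
  expect_equal(predu$quality, max(predu$segments$peak))
  expect_equal(predu$segments[, c("start", "end")],
               pred$segments[, c("start", "end")])

  # determinism: identical inputs give identical results
  expect_identical(das_predict(q2, shared_library, shared_matrix), pred)

  # quality equals max(D) over the called segment, recomputed independently
  q1 <- synth_tm_protein(n_segments = 1, seed = 5)
  p1 <- das_predict(q1, shared_library, shared_matrix)
  expect_equal(nrow(p1$segments), 1L)
  d <- as.numeric(das_profile(q1, shared_library, shared_matrix))
  expect_equal(p1$quality, max(d[p1$segments$start:p1$segments$end]))
})

test_that("prediction TSV output is stable and complete", {
  q2 <- synth_tm_protein(n_segments = 2, seed = 42)
  pred <- das_predict(q2, shared_library, shared_matrix)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_tsv(pred, f)
  d <- read.delim(f)
  expect_equal(nrow(d), 2L)
  expect_equal(d$start, pred$segments$start)
  expect_equal(unique(d$classification), "TM")

  glob <- das_predict(synth_globular(length = 150, seed = 8),
                      shared_library, shared_matrix)
  lines <- write_prediction_tsv(glob, NULL, header = FALSE)
  expect_match(lines, "non-TM\t-\t-\t-\t-\t-\t-")
})

test_that("profile rendering honours fixed and free scaling", {
  prof <- c(runif(40, 0, 2), rep(8, 10), runif(40, 0, 2))
  segs <- call_segments(prof, caller_params())
  f1 <- withr::local_tempfile(fileext = ".svg")
  r1 <- render_profile(prof, segs, caller_params(), "fixed", file = f1)
  expect_equal(r1$ylim, c(0, 5))
  expect_gt(file.size(f1), 0)
  f2 <- withr::local_tempfile(fileext = ".png")
  r2 <- render_profile(prof, segs, caller_params(), "free", file = f2)
  expect_gte(r2$ylim[2], 8)
  expect_gt(file.size(f2), 0)
})
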