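# Variant-effect aggregation schemes and conservation annotation.

tensor_from <- function(arr, center) prediction_tensor(arr, center)

rand_tensor_pair <- function(n_win = 7, n_trk = 3) {
  dims <- c(2, n_win, n_trk)
  list(ref = array(runif(prod(dims), 0, 4), dims),
       alt = array(runif(prod(dims), 0, 4), dims))
}

test_that("transcription effect follows the window/track recipe", {
  # one track, strands equal, ref window-sum 1, alt window-sum 3
  ref <- array(0, c(2, 5, 1)); ref[, , 1] <- 0.2   # sums to 1 over 5 windows
  alt <- array(0, c(2, 5, 1)); alt[, , 1] <- 0.6   # sums to 3
  es <- transcription_effect(tensor_from(ref, 3), tensor_from(alt, 3),
                             cage_tracks = 1)
  expect_equal(es$raw, log2(4) - log2(2))  # exactly 1
  expect_equal(es$abs, 1)

  # identical tensors score zero
  same <- transcription_effect(tensor_from(ref, 3), tensor_from(ref, 3), 1)
  expect_equal(same$raw, 0)

  # two tracks contributing raw 1 and 0 average to 0.5
  ref2 <- array(0, c(2, 5, 2)); ref2[, , 1] <- 0.2; ref2[, , 2] <- 0.2
  alt2 <- array(0, c(2, 5, 2)); alt2[, , 1] <- 0.6; alt2[, , 2] <- 0.2
  es2 <- transcription_effect(tensor_from(ref2, 3), tensor_from(alt2, 3),
                              cage_tracks = 1:2)
  expect_equal(es2$raw, 0.5)
})

test_that("transcription effect matches the nested-loop oracle", {
  set.seed(31)
  for (i in 1:50) {
    pair <- rand_tensor_pair()
    tracks <- sort(sample(1:3, sample(1:3, 1)))
    es <- transcription_effect(tensor_from(pair$ref, 4),
                               tensor_from(pair$alt, 4), tracks)
    expect_equal(es$raw,
                 oracle_transcription(pair$ref, pair$alt, 4, tracks),
                 tolerance = 1e-12)
  }
})

test_that("transcription effect ignores tracks and windows not selected", {
  set.seed(5)
  pair <- rand_tensor_pair(n_win = 9)
  base <- transcription_effect(tensor_from(pair$ref, 5),
                               tensor_from(pair$alt, 5), c(1, 3))
  # permute the unselected track, perturb windows outside centre +/- 2
  ref2 <- pair$ref; alt2 <- pair$alt
  ref2[, c(1, 2, 8, 9), ] <- 99; alt2[, c(1, 2, 8, 9), ] <- -7
  ref2[, , 2] <- rev(ref2[, , 2]) * 0  # unselected track
  es2 <- transcription_effect(tensor_from(ref2, 5), tensor_from(alt2, 5),
                              c(1, 3))
  expect_equal(es2$raw, base$raw, tolerance = 1e-12)
  # track order permutation of the selection does not matter
  es3 <- transcription_effect(tensor_from(pair$ref, 5),
                              tensor_from(pair$alt, 5), c(3, 1))
  expect_equal(es3$raw, base$raw, tolerance = 1e-12)
})

test_that("transcription effect validates its inputs", {
  pair <- rand_tensor_pair(n_win = 5)
  expect_error(transcription_effect(tensor_from(pair$ref, 1),
                                    tensor_from(pair$alt, 1), 1),
               class = "utr_input_error")  # too few windows left of centre
  expect_error(transcription_effect(tensor_from(pair$ref, 3),
                                    tensor_from(pair$alt, 3), integer(0)),
               class = "utr_input_error")
  expect_error(transcription_effect(tensor_from(pair$ref, 3),
                                    tensor_from(pair$alt, 3), 1,
                                    n_windows = 4),
               class = "utr_input_error")
})

test_that("stability effect is the difference of ensemble means", {
  expect_equal(stability_effect(c(0, 0), c(1, 3))$raw, 2)
  expect_equal(stability_effect(c(1.5, 2.5), c(1.5, 2.5))$raw, 0)
  expect_equal(stability_effect(2, 5)$raw, 3)  # K = 1 degenerate
  expect_error(stability_effect(c(1, 2), c(1, 2, 3)),
               class = "utr_input_error")
})

test_that("ORF effect is an MRL fold change on either scale", {
  expect_equal(orf_effect(2, 2)$raw, 0)
  expect_equal(orf_effect(2, 1)$raw, -1)
  expect_equal(orf_effect(2, 1, scale = "ratio")$raw, 0.5)
  expect_error(orf_effect(0, 1), class = "utr_input_error")
})

test_that("effect operations are antisymmetric under ref/alt swap", {
  set.seed(99)
  for (i in 1:50) {
    pair <- rand_tensor_pair()
    fwd <- transcription_effect(tensor_from(pair$ref, 4),
                                tensor_from(pair$alt, 4), 1:3)
    rev <- transcription_effect(tensor_from(pair$alt, 4),
                                tensor_from(pair$ref, 4), 1:3)
    expect_equal(fwd$raw, -rev$raw, tolerance = 1e-12)
    expect_equal(fwd$abs, rev$abs, tolerance = 1e-12)

    a <- runif(5); b <- runif(5)
    expect_identical(stability_effect(a, b)$raw + stability_effect(b, a)$raw,
                     0)
    m1 <- runif(1, 0.1, 5); m2 <- runif(1, 0.1, 5)
    expect_equal(orf_effect(m1, m2)$raw, -orf_effect(m2, m1)$raw,
                 tolerance = 1e-12)
    # ratio scale inverts instead of negating
    expect_equal(orf_effect(m1, m2, "ratio")$raw,
                 1 / orf_effect(m2, m1, "ratio")$raw, tolerance = 1e-12)
  }
})

test_that("six-channel track encodes one-hot, frame and splice channels", {
  m <- build_six_channel_track("ACGT")
  expect_equal(unname(m[, 1:4]), diag(4L), ignore_attr = TRUE)
  expect_true(all(m[, c("frame", "splice")] == 0L))

  m2 <- build_six_channel_track("AAAAAA", coding_interval = c(1, 6))
  expect_equal(unname(which(m2[, "frame"] == 1L)), c(1L, 4L))

  m3 <- build_six_channel_track("ACGTA", splice_positions = 3)
  expect_equal(unname(which(m3[, "splice"] == 1L)), 3L)

  # N is an all-zero one-hot; U maps to T
  m4 <- build_six_channel_track("ANU")
  expect_equal(unname(rowSums(m4[, 1:4])), c(1, 0, 1))
  expect_equal(unname(m4[3, "T"]), 1L)
  expect_error(build_six_channel_track("ACGX"), class = "utr_input_error")
  expect_error(build_six_channel_track("ACG", coding_interval = c(2, 9)),
               class = "utr_input_error")
})

test_that("PhyloP annotation takes the max over multi-base spans", {
  trk <- conservation_track(data.frame(
    chrom = "chr1", start = c(100, 101, 102), end = c(100, 101, 102),
    score = c(0.2, 1.6, -0.4)))
  snv <- variant_record("chr1", 101, "A", "G")
  expect_equal(phylop_annotate(snv, trk)$phylop, 1.6)
  del <- variant_record("chr1", 100, "AAA", "A")
  expect_equal(phylop_annotate(del, trk)$phylop, 1.6)
  # uncovered positions inside the span are ignored
  del2 <- variant_record("chr1", 102, "AAAA", "A")
  expect_equal(phylop_annotate(del2, trk)$phylop, -0.4)
  # fully uncovered span reports absence, not an error
  far <- variant_record("chr1", 5000, "AA", "A")
  expect_true(is.na(phylop_annotate(far, trk)$phylop))
})

test_that("PhyloP annotation matches a position-scanning oracle", {
  set.seed(13)
  for (i in 1:50) {
    n_iv <- sample(3:8, 1)
    starts <- sort(sample(seq(1, 200, by = 4), n_iv))
    ivs <- data.frame(chrom = "chr1", start = starts,
                      end = starts + sample(0:3, n_iv, replace = TRUE),
                      score = rnorm(n_iv))
    trk <- conservation_track(ivs)
    pos <- sample(1:200, 1); len <- sample(1:6, 1)
    v <- variant_record("chr1", pos, paste(rep("A", len), collapse = ""),
                        "A")
    got <- phylop_annotate(v, trk)$phylop
    want <- oracle_phylop_max(ivs, "chr1", pos, len)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})
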