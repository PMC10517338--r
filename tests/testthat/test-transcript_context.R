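# Region calls, the transcript-context confidence score and the
# APPRIS/MANE inclusion rules.

test_that("locate_variant classifies every region of the toy transcript", {
  tx <- toy_transcript()
  expect_equal(locate_variant(snv_at(1050), tx), "utr3_exonic")
  expect_equal(locate_variant(snv_at(150), tx), "utr5_exonic")
  expect_equal(locate_variant(snv_at(600), tx), "cds_exonic")
  expect_equal(locate_variant(snv_at(260), tx), "cds_exonic")
  # intron 301-499: 306 is 6 bp from the upstream exon boundary
  expect_equal(locate_variant(snv_at(306), tx), "splice_proximal_intronic")
  expect_equal(locate_variant(snv_at(495), tx), "splice_proximal_intronic")
  expect_equal(locate_variant(snv_at(400), tx), "intronic")
  expect_equal(locate_variant(snv_at(50), tx), "intergenic")
  expect_equal(locate_variant(snv_at(600, chrom = "chr2"), tx), "intergenic")
})

test_that("the splice-proximal window is exactly 8 bases and configurable", {
  tx <- toy_transcript()
  # intron starts at 301; distance of position p is p - 300
  expect_equal(locate_variant(snv_at(308), tx), "splice_proximal_intronic")
  expect_equal(locate_variant(snv_at(309), tx), "intronic")
  expect_equal(locate_variant(snv_at(309), tx, splice_window = 9L),
               "splice_proximal_intronic")
  # exonic positions near the boundary are NOT splice-proximal
  expect_equal(locate_variant(snv_at(300), tx), "cds_exonic")
})

test_that("spans crossing a region boundary are spanning", {
  tx <- toy_transcript()
  # deletion starting in 3' UTR 1001.. and reaching back into CDS
  del <- variant_record("chr1", 995, paste(rep("A", 10), collapse = ""), "A")
  expect_equal(locate_variant(del, tx), "spanning")
  # exon/intron boundary
  del2 <- variant_record("chr1", 298, "AAAAAA", "A")
  expect_equal(locate_variant(del2, tx), "spanning")
  # off the end of the transcript
  del3 <- variant_record("chr1", 1095, paste(rep("A", 10), collapse = ""), "A")
  expect_equal(locate_variant(del3, tx), "spanning")
})

test_that("insertions are located by their flanking interval", {
  tx <- toy_transcript()
  ins <- variant_record("chr1", 1050, "", "TTT")
  expect_equal(locate_variant(ins, tx), "utr3_exonic")
  # flanks 1000|1001 straddle the CDS/3'UTR boundary
  ins2 <- variant_record("chr1", 1001, "", "TTT")
  expect_equal(locate_variant(ins2, tx), "spanning")
})

test_that("confidence score reproduces the criteria truth table", {
  tx <- toy_transcript()
  v <- snv_at(1050)  # utr3_exonic on the preferred transcript
  # other transcripts engineered so v gets each call
  mk <- function(id, exons, cds) transcript_model(id, "OTHER", "chr1", "+",
                                                  exons, cds = cds)
  other_cds <- mk("O_CDS.1", cbind(1000, 1200), c(1010, 1190))
  other_splice <- mk("O_SPL.1", rbind(c(900, 1045), c(1055, 1200)),
                     c(950, 1150))       # v intronic, 5 bp from boundary
  other_intronic <- mk("O_INT.1", rbind(c(100, 200), c(2000, 2100)),
                       c(150, 2050))     # v deep intronic
  other_utr5 <- mk("O_U5.1", cbind(1000, 1300), c(1150, 1250))
  other_utr3 <- mk("O_U3.1", cbind(800, 1200), c(850, 1000))
  far_away <- mk("O_FAR.1", cbind(5000, 6000), c(5200, 5800))

  cases <- list(
    list(others = list(), want = 2L),
    list(others = list(far_away), want = 2L),
    list(others = list(other_utr3), want = 2L),
    list(others = list(other_cds), want = 0L),
    list(others = list(other_splice), want = 0L),
    list(others = list(other_intronic), want = 1L),
    list(others = list(other_utr5), want = 1L),
    list(others = list(other_intronic, other_utr5), want = 1L),
    list(others = list(other_intronic, other_cds), want = 0L),
    list(others = list(other_utr3, other_utr5, other_splice), want = 0L),
    list(others = list(far_away, other_utr3, other_intronic), want = 1L)
  )
  for (cs in cases) {
    expect_identical(confidence_score(v, tx, cs$others, "utr3")$value,
                     cs$want)
  }
})

test_that("confidence score is order-invariant and monotone", {
  tx <- toy_transcript()
  v <- snv_at(1050)
  mk <- function(id, exons, cds) transcript_model(id, "O", "chr1", "+",
                                                  exons, cds = cds)
  pool <- list(
    mk("P1.1", cbind(1000, 1200), c(1010, 1190)),
    mk("P2.1", rbind(c(100, 200), c(2000, 2100)), c(150, 2050)),
    mk("P3.1", cbind(1000, 1300), c(1150, 1250)),
    mk("P4.1", cbind(800, 1200), c(850, 1000)),
    mk("P5.1", cbind(5000, 6000), c(5200, 5800))
  )
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(0:5, 1)
    subset <- sample(pool, k)
    base_val <- confidence_score(v, tx, subset, "utr3")$value
    expect_identical(confidence_score(v, tx, rev(subset), "utr3")$value,
                     base_val)
    # adding one more transcript can never increase the score
    extra <- sample(pool, 1)
    expect_lte(confidence_score(v, tx, c(subset, extra), "utr3")$value,
               base_val)
  }
})

test_that("non-eligible preferred-transcript calls are an error", {
  tx <- toy_transcript()
  expect_error(confidence_score(snv_at(600), tx, list(), "utr3"),
               class = "utr_not_eligible_error")
  expect_error(confidence_score(snv_at(1050), tx, list(), "utr5"),
               class = "utr_not_eligible_error")
})

test_that("inclusion rules reproduce the documented exclusion patterns", {
  flags <- list(PRIN.1 = "appris_principal",
                MANE.1 = "mane_select",
                PLUS.1 = "mane_plus_clinical",
                ALT.1 = "appris_alternative")
  v <- snv_at(1050, clinvar_class = "P", origin = "germline")

  # missense on MANE Select while 3' UTR on the principal -> exclude
  res <- resolve_inclusion(v, c(PRIN.1 = "utr3_exonic",
                                MANE.1 = "cds_exonic"), flags)
  expect_equal(res, list(decision = "exclude", reason = "mane_conflict"))

  # UTR on Select + principal, non-UTR on Plus Clinical, thin evidence
  res <- resolve_inclusion(v, c(PRIN.1 = "utr5_exonic",
                                MANE.1 = "utr5_exonic",
                                PLUS.1 = "cds_exonic"),
                           flags, evidence_context = "insufficient")
  expect_equal(res$decision, "exclude")
  expect_equal(res$reason, "mane_conflict")

  # clean germline SNV, no conflicts -> include
  res <- resolve_inclusion(v, c(PRIN.1 = "utr3_exonic",
                                MANE.1 = "utr3_exonic"), flags)
  expect_equal(res$decision, "include")

  # non-UTR on an APPRIS alternative only excludes without UTR evidence
  calls <- c(PRIN.1 = "utr3_exonic", ALT.1 = "cds_exonic")
  expect_equal(resolve_inclusion(v, calls, flags,
                                 "insufficient")$reason,
               "alternative_conflict")
  expect_equal(resolve_inclusion(v, calls, flags,
                                 "non_utr_supported")$reason,
               "alternative_conflict")
  expect_equal(resolve_inclusion(v, calls, flags,
                                 "utr_mechanism_supported")$decision,
               "include")

  # not UTR-exonic on the principal dominates
  expect_equal(resolve_inclusion(v, c(PRIN.1 = "cds_exonic"),
                                 flags)$reason, "not_utr_on_principal")
  # somatic origin and excluded variant types
  vsom <- snv_at(1050, origin = "somatic")
  expect_equal(resolve_inclusion(vsom, c(PRIN.1 = "utr3_exonic"),
                                 flags)$reason, "somatic")
  expect_equal(resolve_inclusion(v, c(PRIN.1 = "utr3_exonic"), flags,
                                 variant_type = "repeat_expansion")$reason,
               "excluded_variant_type")
  # missing principal call is an input error
  expect_error(resolve_inclusion(v, c(MANE.1 = "utr3_exonic"), flags),
               class = "utr_input_error")
})
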