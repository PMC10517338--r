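# Transcript models, per-transcript region calls, the 0/1/2 confidence
# score and the APPRIS/MANE inclusion-exclusion rules.

.TX_FLAGS <- c("clinvar_preferred", "appris_principal", "appris_alternative",
               "mane_select", "mane_plus_clinical")

#' Construct a transcript model
#'
#' A strand-aware exon/CDS/UTR model for one transcript. UTR intervals are
#' derived as exonic territory minus the CDS span, split by side of the CDS
#' respecting strand: on `+` the upstream side is the 5' UTR, on `-` it is
#' the 3' UTR. UTR interval lists are ordered in transcript direction
#' (5' to 3').
#'
#' @param transcript_id Versioned accession.
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data.frame (`start`, `end`) of genomic
#'   exon intervals, 1-based inclusive; must be non-overlapping.
#' @param cds Genomic CDS span `c(start, end)`, or `NULL` for a non-coding
#'   transcript (flagged `coding = FALSE`, no UTR intervals).
#' @param flags Character subset of
#'   `clinvar_preferred, appris_principal, appris_alternative, mane_select,
#'   mane_plus_clinical`.
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- transcript_model("NM_TEST.1", "GENE", "chr1", "+",
#'                        exons = cbind(100, 500), cds = c(200, 400))
#' tx$utr5  # IRanges 100..199
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exons, cds = NULL, flags = character(0)) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) utr_input_error("exons must have two columns")
  ex <- IRanges::IRanges(start = as.integer(exons[, 1]),
                         end = as.integer(exons[, 2]))
  ex <- ex[order(IRanges::start(ex), IRanges::end(ex))]
  if (length(IRanges::reduce(ex, min.gapwidth = 0L)) != length(ex))
    utr_input_error(paste0("overlapping exons in ", transcript_id))
  bad <- setdiff(flags, .TX_FLAGS)
  if (length(bad))
    utr_input_error(paste0("unknown transcript flag(s): ",
                           paste(bad, collapse = ", ")))

  utr5 <- utr3 <- IRanges::IRanges()
  coding <- !is.null(cds)
  if (coding) {
    cds <- as.integer(cds)
    span_lo <- min(IRanges::start(ex)); span_hi <- max(IRanges::end(ex))
    if (cds[1] < span_lo || cds[2] > span_hi)
      utr_input_error(paste0("CDS outside exonic span in ", transcript_id))
    left <- IRanges::intersect(ex, IRanges::IRanges(span_lo, cds[1] - 1L))
    right <- IRanges::intersect(ex, IRanges::IRanges(cds[2] + 1L, span_hi))
    if (strand == "+") {
      utr5 <- left; utr3 <- right
    } else {
      utr5 <- rev(right); utr3 <- rev(left)
    }
  }

  structure(list(
    transcript_id = transcript_id, gene = gene, chrom = chrom,
    strand = strand, exons = ex,
    cds = if (coding) cds else NULL,
    utr5 = utr5, utr3 = utr3, coding = coding, flags = flags
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s%s %d exon(s)%s%s>\n",
              x$transcript_id, x$gene, x$chrom, x$strand, length(x$exons),
              if (x$coding) sprintf(" CDS %d-%d", x$cds[1], x$cds[2])
              else " non-coding",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# Genomic reference span of a variant record row. A zero-length ref (pure
# insertion) is located by its two flanking bases, so "entirely within"
# requires both flanks inside the same interval.
.variant_span <- function(variant) {
  pos <- as.integer(variant$pos)
  n <- nchar(variant$ref %||% "")
  if (is.na(n)) n <- 0L
  if (n == 0L) c(pos - 1L, pos) else c(pos, pos + n - 1L)
}

.span_within <- function(span, ir) {
  any(IRanges::start(ir) <= span[1] & span[2] <= IRanges::end(ir))
}

#' Classify a variant's region on one transcript
#'
#' The call is `utr5_exonic`/`utr3_exonic`/`cds_exonic` only when the
#' variant's full reference span lies inside a single interval of that
#' region; spans crossing a UTR/CDS or exon/intron boundary are `spanning`.
#' Intronic calls within 8 bases of an intron/exon boundary (configurable)
#' are `splice_proximal_intronic`. A variant on another chromosome, or not
#' overlapping the transcript's genomic span, is `intergenic`. Pure
#' insertions are located by their two flanking bases.
#'
#' @param variant One variant record (one-row `variant_table` or a list
#'   with `chrom`, `pos`, `ref`).
#' @param transcript A coding [transcript_model()].
#' @param splice_window Splice-proximal window in bases (default 8).
#' @return A single region string, one of `utr5_exonic`, `utr3_exonic`,
#'   `cds_exonic`, `splice_proximal_intronic`, `intronic`, `intergenic`,
#'   `spanning`.
#' @export
locate_variant <- function(variant, transcript, splice_window = 8L) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (!transcript$coding)
    utr_input_error(paste0("transcript ", transcript$transcript_id,
                           " is non-coding; UTR region calls are undefined"))
  if (!identical(as.character(variant$chrom), transcript$chrom))
    return("intergenic")
  span <- .variant_span(variant)
  ex <- transcript$exons
  tx_lo <- min(IRanges::start(ex)); tx_hi <- max(IRanges::end(ex))
  if (span[2] < tx_lo || span[1] > tx_hi) return("intergenic")
  if (span[1] < tx_lo || span[2] > tx_hi) return("spanning")

  if (.span_within(span, transcript$utr5)) return("utr5_exonic")
  if (.span_within(span, transcript$utr3)) return("utr3_exonic")
  cds_ex <- IRanges::intersect(ex, IRanges::IRanges(transcript$cds[1],
                                                    transcript$cds[2]))
  if (.span_within(span, cds_ex)) return("cds_exonic")

  introns <- IRanges::gaps(IRanges::reduce(ex),
                           start = tx_lo, end = tx_hi)
  idx <- which(IRanges::start(introns) <= span[1] &
                 span[2] <= IRanges::end(introns))
  if (length(idx)) {
    intr <- introns[idx[1]]
    dist <- min(span[1] - IRanges::start(intr) + 1L,
                IRanges::end(intr) - span[2] + 1L)
    return(if (dist <= splice_window) "splice_proximal_intronic"
           else "intronic")
  }
  "spanning"
}

#' Assign the transcript-context confidence score (0, 1 or 2)
#'
#' The variant must be UTR-exonic for `target_region` on the preferred
#' transcript. The score then depends only on its region calls on the
#' other transcripts:
#' \itemize{
#'   \item 0 if any other transcript yields `cds_exonic`,
#'     `splice_proximal_intronic` (intronic within 8 bp of an intron/exon
#'     boundary) or `spanning` (a span crossing region boundaries touches
#'     non-UTR sequence and is treated as a coding/splicing conflict);
#'   \item otherwise 1 if any other transcript yields `intronic` or the
#'     opposite-side UTR-exonic call;
#'   \item otherwise 2 (same-side UTR-exonic calls and non-overlapping
#'     transcripts are compatible with full confidence).
#' }
#' Non-coding models in `others` are skipped (UTR logic is undefined for
#' them). Higher scores mean higher confidence that the effect is mediated
#' by the UTR of the preferred transcript.
#'
#' @param variant One variant record.
#' @param preferred The preferred (e.g. ClinVar-named) coding
#'   [transcript_model()].
#' @param others List of other overlapping transcript models (any gene).
#' @param target_region `"utr5"` or `"utr3"`.
#' @param splice_window Splice-proximal window in bases (default 8).
#' @return Object of class `confidence_score`: list with integer `value`
#'   and `rationale`, a data.frame of the other-transcript calls that
#'   triggered the deduction.
#' @export
confidence_score <- function(variant, preferred, others = list(),
                             target_region = c("utr3", "utr5"),
                             splice_window = 8L) {
  target_region <- match.arg(target_region)
  want <- paste0(target_region, "_exonic")
  pref_call <- locate_variant(variant, preferred, splice_window)
  if (!identical(pref_call, want))
    utr_error(sprintf(
      "variant is %s (not %s) on preferred transcript %s; not eligible",
      pref_call, want, preferred$transcript_id), "utr_not_eligible_error")

  others <- Filter(function(tx) tx$coding, others)
  calls <- vapply(others, function(tx) locate_variant(variant, tx,
                                                      splice_window),
                  character(1))
  ids <- vapply(others, function(tx) tx$transcript_id, character(1))

  opposite <- paste0(setdiff(c("utr3", "utr5"), target_region), "_exonic")
  zero_trig <- calls %in% c("cds_exonic", "splice_proximal_intronic",
                            "spanning")
  one_trig <- calls %in% c("intronic", opposite)

  value <- if (any(zero_trig)) 0L else if (any(one_trig)) 1L else 2L
  trig <- if (value == 0L) zero_trig else if (value == 1L) one_trig
          else rep(FALSE, length(calls))
  structure(list(
    value = value,
    rationale = data.frame(transcript_id = ids[trig], region = calls[trig],
                           stringsAsFactors = FALSE),
    calls = setNames(calls, ids)
  ), class = "confidence_score")
}

#' @export
print.confidence_score <- function(x, ...) {
  cat(sprintf("<confidence score %d", x$value))
  if (nrow(x$rationale))
    cat(": ", paste(x$rationale$transcript_id, x$rationale$region,
                    sep = "=", collapse = ", "), sep = "")
  cat(">\n")
  invisible(x)
}

.UTR_CALLS <- c("utr5_exonic", "utr3_exonic")
# "Non-UTR impact": any overlap with the transcript that is not UTR-exonic.
# A variant that does not overlap the transcript at all (intergenic) has no
# impact on it.
.NON_UTR_IMPACT <- c("cds_exonic", "splice_proximal_intronic", "intronic",
                     "spanning")

#' Decide inclusion of a variant under the APPRIS/MANE curation rules
#'
#' A variant is kept only when its pathogenicity can be attributed to a
#' UTR effect on the designated APPRIS principal transcript. Exclusion
#' reasons, in order of precedence:
#' \describe{
#'   \item{`not_utr_on_principal`}{not UTR-exonic on the APPRIS principal.}
#'   \item{`somatic`}{somatic origin.}
#'   \item{`excluded_variant_type`}{repeat expansions and multi-region
#'     structural variants.}
#'   \item{`mane_conflict`}{non-UTR impact on a MANE Select or MANE Plus
#'     Clinical transcript of the gene. By default this excludes the
#'     variant regardless of mechanistic evidence (the conservative
#'     stance); set `mane_override = TRUE` to let
#'     `evidence_context = "utr_mechanism_supported"` rescue it.}
#'   \item{`alternative_conflict`}{non-UTR impact on an APPRIS alternative
#'     transcript while the mechanistic evidence is absent or supports the
#'     non-UTR effect (`evidence_context` of `"non_utr_supported"` or
#'     `"insufficient"`).}
#' }
#'
#' @param variant One variant record (its `origin` is consulted).
#' @param calls Named character vector or list, transcript_id -> region
#'   call from [locate_variant()]; must include the principal transcript.
#' @param flags Named list, transcript_id -> character vector of flags.
#' @param evidence_context `"utr_mechanism_supported"`,
#'   `"non_utr_supported"` or `"insufficient"`.
#' @param variant_type Optional [classify_variant_type()] label; used for
#'   the type-based exclusions (`"repeat_expansion"`, `"multi_region_SV"`).
#' @param mane_override Logical; see `mane_conflict` above.
#' @return List with `decision` (`"include"`/`"exclude"`) and `reason`.
#' @export
resolve_inclusion <- function(variant, calls, flags,
                              evidence_context = c("insufficient",
                                                   "utr_mechanism_supported",
                                                   "non_utr_supported"),
                              variant_type = NULL,
                              mane_override = FALSE) {
  evidence_context <- match.arg(evidence_context)
  calls <- unlist(calls)
  has_flag <- function(tid, f) f %in% (flags[[tid]] %||% character(0))
  principal <- names(calls)[vapply(names(calls), has_flag, logical(1),
                                   f = "appris_principal")]
  if (length(principal) == 0L)
    utr_input_error("no region call for an appris_principal transcript")
  principal <- principal[1]

  if (!calls[[principal]] %in% .UTR_CALLS)
    return(list(decision = "exclude", reason = "not_utr_on_principal"))
  if (identical(variant$origin, "somatic"))
    return(list(decision = "exclude", reason = "somatic"))
  if (!is.null(variant_type) &&
      variant_type %in% c("repeat_expansion", "multi_region_SV"))
    return(list(decision = "exclude", reason = "excluded_variant_type"))

  for (tid in setdiff(names(calls), principal)) {
    if ((has_flag(tid, "mane_select") || has_flag(tid, "mane_plus_clinical")) &&
        calls[[tid]] %in% .NON_UTR_IMPACT) {
      if (!(mane_override && evidence_context == "utr_mechanism_supported"))
        return(list(decision = "exclude", reason = "mane_conflict"))
    }
  }
  for (tid in setdiff(names(calls), principal)) {
    if (has_flag(tid, "appris_alternative") &&
        calls[[tid]] %in% .NON_UTR_IMPACT &&
        evidence_context %in% c("non_utr_supported", "insufficient"))
      return(list(decision = "exclude", reason = "alternative_conflict"))
  }
  list(decision = "include", reason = "utr_effect_on_principal")
}
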