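# The three variant-effect aggregation schemes (transcription windows,
# mRNA-stability ensemble, ribosome-load fold change), the six-channel
# stability input track, and PhyloP conservation annotation.

#' Construct a strand x window x track prediction tensor
#'
#' Holds the raw output of a sequence-to-activity predictor for one input
#' sequence: real values indexed by strand (`fwd`, `rev`), genomic window
#' and output track, plus the index of the window centred on the variant.
#'
#' @param values Numeric array `dim = c(2, n_windows, n_tracks)` (strand
#'   first) or a `n_windows x n_tracks` matrix used for both strands.
#' @param center Integer index of the centre window.
#' @param track_labels Optional track names.
#' @return Object of class `prediction_tensor`.
#' @export
prediction_tensor <- function(values, center, track_labels = NULL) {
  if (is.matrix(values)) {
    values <- array(rep(values, each = 2L),
                    dim = c(2L, nrow(values), ncol(values)))
  }
  if (length(dim(values)) != 3L || dim(values)[1] != 2L)
    utr_input_error("tensor must be strand x window x track with 2 strands")
  center <- as.integer(center)
  if (center < 1L || center > dim(values)[2])
    utr_input_error("center window index out of range")
  dimnames(values)[[1]] <- c("fwd", "rev")
  if (!is.null(track_labels)) dimnames(values)[[3]] <- track_labels
  structure(list(values = values, center = center), class = "prediction_tensor")
}

.effect_score <- function(raw, model, variant_key = NA_character_) {
  structure(list(variant_key = variant_key, model = model,
                 raw = as.numeric(raw), abs = abs(as.numeric(raw))),
            class = "effect_score")
}

#' @export
print.effect_score <- function(x, ...) {
  cat(sprintf("<effect_score %s raw=%.6g abs=%.6g>\n", x$model, x$raw,
              x$abs))
  invisible(x)
}

#' Transcription-level variant effect from window/track predictions
#'
#' For each of the reference and alternative tensors: average the forward
#' and reverse strand predictions elementwise, subset to the centre window
#' plus `(n_windows - 1) / 2` windows on either side and to the supplied
#' track subset, then per track compute `log2(1 + sum over windows)` and
#' average over tracks. The effect is the alternative score minus the
#' reference score.
#'
#' @param ref,alt [prediction_tensor()]s of identical shape and centre.
#' @param cage_tracks Integer (or name) indices of the tracks to use;
#'   must be non-empty. Which track subset is appropriate depends on the
#'   predictor, so it is always explicit.
#' @param n_windows Odd number of windows to aggregate (default 5).
#' @param variant_key Optional key stored on the score.
#' @return An `effect_score` with `raw = score(alt) - score(ref)`.
#' @examples
#' m_ref <- matrix(0.5, nrow = 5, ncol = 1)   # window sum 2.5
#' m_alt <- matrix(1.0, nrow = 5, ncol = 1)   # window sum 5
#' transcription_effect(prediction_tensor(m_ref, 3),
#'                      prediction_tensor(m_alt, 3), cage_tracks = 1)
#' @export
transcription_effect <- function(ref, alt, cage_tracks, n_windows = 5L,
                                 variant_key = NA_character_) {
  stopifnot(inherits(ref, "prediction_tensor"),
            inherits(alt, "prediction_tensor"))
  if (!identical(dim(ref$values), dim(alt$values)))
    utr_input_error("ref and alt tensors differ in shape")
  if (ref$center != alt$center)
    utr_input_error("ref and alt tensors differ in centre window")
  if (length(cage_tracks) == 0L)
    utr_input_error("cage_tracks must be non-empty")
  if (n_windows %% 2L != 1L)
    utr_input_error("n_windows must be odd")
  half <- (n_windows - 1L) %/% 2L
  win <- (ref$center - half):(ref$center + half)
  if (min(win) < 1L || max(win) > dim(ref$values)[2])
    utr_input_error("fewer than n_windows windows around the centre")

  seq_score <- function(tensor) {
    avg <- (tensor$values["fwd", , , drop = FALSE] +
              tensor$values["rev", , , drop = FALSE]) / 2
    avg <- array(avg, dim = dim(tensor$values)[2:3],
                 dimnames = dimnames(tensor$values)[2:3])
    sub <- avg[win, cage_tracks, drop = FALSE]
    mean(log2(1 + colSums(sub)))
  }
  .effect_score(seq_score(alt) - seq_score(ref), "transcription",
                variant_key)
}

#' mRNA-stability variant effect from a cross-validation ensemble
#'
#' Each of the reference and alternative sequence is scored by averaging
#' the predictions of the `K` ensemble members; the effect is the
#' alternative average minus the reference average.
#'
#' @param ref_preds,alt_preds Numeric vectors of equal length `K >= 1`
#'   (one prediction per ensemble member).
#' @param variant_key Optional key stored on the score.
#' @return An `effect_score`.
#' @export
stability_effect <- function(ref_preds, alt_preds,
                             variant_key = NA_character_) {
  if (length(ref_preds) != length(alt_preds) || length(ref_preds) < 1L)
    utr_input_error("ref and alt prediction lists must share length K >= 1")
  .effect_score(mean(alt_preds) - mean(ref_preds), "stability", variant_key)
}

#' Ribosome-load variant effect as a fold change
#'
#' The effect of a 5' UTR variant on predicted mean ribosome load (MRL),
#' expressed as `mrl_alt / mrl_ref` or its log2 (the default: symmetric
#' around zero, so the absolute value is meaningful).
#'
#' @param mrl_ref,mrl_alt Positive predicted MRL values.
#' @param scale `"log2_ratio"` (default) or `"ratio"`.
#' @param variant_key Optional key stored on the score.
#' @return An `effect_score`.
#' @export
orf_effect <- function(mrl_ref, mrl_alt, scale = c("log2_ratio", "ratio"),
                       variant_key = NA_character_) {
  scale <- match.arg(scale)
  if (!(mrl_ref > 0 && mrl_alt > 0))
    utr_input_error("MRL values must be positive")
  fc <- mrl_alt / mrl_ref
  .effect_score(if (scale == "log2_ratio") log2(fc) else fc, "orf",
                variant_key)
}

#' Build the six-channel input track for a stability predictor
#'
#' Per-nucleotide channels: one-hot A/C/G/T (U is treated as T; N is
#' all-zero), a coding-frame indicator marking the first base of each
#' codon inside the coding interval, and a splice-site indicator.
#'
#' @param sequence Nucleotide string over `ACGTUN` (case-insensitive).
#' @param coding_interval `c(start, end)` in 1-based transcript
#'   coordinates, or `NULL` for none.
#' @param splice_positions Integer positions (1-based) of splice sites.
#' @return Integer matrix `nchar(sequence) x 6` with columns
#'   `A, C, G, T, frame, splice`.
#' @export
build_six_channel_track <- function(sequence, coding_interval = NULL,
                                    splice_positions = integer(0)) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "U"] <- "T"
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    utr_input_error("sequence contains a non-ACGTUN character")
  n <- length(chars)
  if (length(splice_positions) &&
      (min(splice_positions) < 1L || max(splice_positions) > n))
    utr_input_error("splice position outside sequence bounds")
  m <- matrix(0L, nrow = n, ncol = 6L,
              dimnames = list(NULL, c("A", "C", "G", "T", "frame",
                                      "splice")))
  for (b in c("A", "C", "G", "T")) m[chars == b, b] <- 1L
  if (!is.null(coding_interval)) {
    ci <- as.integer(coding_interval)
    if (ci[1] < 1L || ci[2] > n || ci[1] > ci[2])
      utr_input_error("coding interval outside sequence bounds")
    firsts <- seq.int(ci[1], ci[2], by = 3L)
    m[firsts, "frame"] <- 1L
  }
  m[splice_positions, "splice"] <- 1L
  m
}

#' Annotate a variant with a conservation score
#'
#' Single-base reference: the track value at the position. Multi-base
#' reference: the maximum over `[pos, pos + nchar(ref) - 1]`; uncovered
#' positions within the span are ignored, and a fully uncovered span
#' yields `NA` (absence is a value, not an error).
#'
#' @param variant One variant record (`chrom`, `pos`, `ref`).
#' @param track A [conservation_track()].
#' @return List with `variant_key` and `phylop` (numeric, possibly `NA`).
#' @export
phylop_annotate <- function(variant, track) {
  n <- nchar(variant$ref %||% "")
  if (is.na(n) || n == 0L) n <- 1L
  pos <- seq.int(variant$pos, variant$pos + n - 1L)
  vals <- track_score(track, as.character(variant$chrom), pos)
  vals <- vals[!is.na(vals)]
  list(variant_key = .variant_key(variant),
       phylop = if (length(vals)) max(vals) else NA_real_)
}

#' Tabulate effect scores
#'
#' @param scores List of `effect_score` objects.
#' @return data.frame (`variant_key`, `model`, `raw`, `abs`).
#' @export
effect_score_table <- function(scores) {
  data.frame(
    variant_key = vapply(scores, `[[`, character(1), "variant_key"),
    model = vapply(scores, `[[`, character(1), "model"),
    raw = vapply(scores, `[[`, numeric(1), "raw"),
    abs = vapply(scores, `[[`, numeric(1), "abs"),
    stringsAsFactors = FALSE
  )
}
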