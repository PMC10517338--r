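# Population-frequency, significance and variant-type filters, plus the
# tandem-repeat band classifier.

#' Default DMPK-style repeat bands
#'
#' Normal alleles span 5–34 CTG repeats, premutation alleles 35–49, and
#' fully penetrant alleles more than 50. Note the source band definitions
#' leave a count of exactly 50 undefined; it is deliberately returned as
#' `"unclassified"` by the defaults rather than silently assigned, and the
#' band table is configurable.
#'
#' @return data.frame with columns `label`, `min_repeats`, `max_repeats`.
#' @export
default_repeat_bands <- function() {
  data.frame(label = c("normal", "premutation", "fully_penetrant"),
             min_repeats = c(5, 35, 51),
             max_repeats = c(34, 49, Inf),
             stringsAsFactors = FALSE)
}

#' Build a filter configuration
#'
#' @param af_discard_threshold Discard a variant when any subpopulation
#'   allele frequency strictly exceeds this fraction (default 0.05; strong
#'   evidence for a benign classification).
#' @param benign_min_af Putative-benign variants must have total AF
#'   strictly above this fraction (default 0.01) — deliberately looser
#'   than the discard threshold so most UTRs gain a matched benign
#'   variant.
#' @param sv_min_len Minimum net length in bases for a pure
#'   insertion/deletion to count as a structural variant (default 51,
#'   i.e. indels are <= 50 nucleotides).
#' @param repeat_bands Repeat band table, see [default_repeat_bands()].
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(af_discard_threshold = 0.05,
                          benign_min_af = 0.01,
                          sv_min_len = 51L,
                          repeat_bands = default_repeat_bands()) {
  if (!(benign_min_af > 0 && benign_min_af < af_discard_threshold &&
        af_discard_threshold <= 1))
    utr_input_error("need 0 < benign_min_af < af_discard_threshold <= 1")
  stopifnot(sv_min_len >= 2L)
  rb <- repeat_bands[order(repeat_bands$min_repeats), , drop = FALSE]
  if (nrow(rb) > 1L &&
      any(rb$min_repeats[-1] <= rb$max_repeats[-nrow(rb)]))
    utr_input_error("repeat bands must be non-overlapping and ordered")
  structure(list(af_discard_threshold = af_discard_threshold,
                 benign_min_af = benign_min_af,
                 sv_min_len = as.integer(sv_min_len),
                 repeat_bands = rb),
            class = "filter_config")
}

#' Keep P, LP and conflicting-P/LP records
#'
#' @param records A `variant_table`.
#' @return The subset with `clinvar_class` in
#'   `{P, LP, P_and_LP_conflicting}`, order preserved. Idempotent.
#' @export
filter_significance <- function(records) {
  keep <- records$clinvar_class %in% c("P", "LP", "P_and_LP_conflicting")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard records common in any subpopulation
#'
#' A record is discarded iff its maximum allele frequency over the
#' subpopulation AF map (and the total AF, when present) strictly exceeds
#' the discard threshold. Records with no AF data are kept: absence of an
#' observation is treated as rarity.
#'
#' @param records A `variant_table`.
#' @param config A [filter_config()].
#' @return The retained subset, order preserved. Idempotent.
#' @export
filter_allele_frequency <- function(records, config = filter_config()) {
  validate_variant_table(records)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    vals <- c(unlist(records$af[[i]], use.names = FALSE),
              records$af_total[i])
    vals <- vals[!is.na(vals)]
    !length(vals) || max(vals) <= config$af_discard_threshold
  }, logical(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Trim the shared suffix, then the shared prefix, keeping at least one base
# on the longer allele (left normalization, VCF anchor-base style).
.left_normalize <- function(ref, alt) {
  rs <- strsplit(ref, "")[[1]]; as <- strsplit(alt, "")[[1]]
  while (length(rs) > 1L && length(as) > 1L &&
         rs[length(rs)] == as[length(as)]) {
    rs <- rs[-length(rs)]; as <- as[-length(as)]
  }
  while (length(rs) > 1L && length(as) > 1L && rs[1] == as[1]) {
    rs <- rs[-1]; as <- as[-1]
  }
  list(ref = paste(rs, collapse = ""), alt = paste(as, collapse = ""))
}

#' Classify a variant's type from its alleles
#'
#' Deterministic partition of (ref, alt) pairs:
#' \itemize{
#'   \item `SNV` — both alleles a single, differing base;
#'   \item `indel` — pure insertion/deletion of net length <= 50 bases;
#'   \item `SV` — pure insertion/deletion of net length > 50 bases;
#'   \item `delins` — after left normalization both alleles longer than
#'     one base and neither a prefix of the other;
#'   \item `CNV` / `repeat_expansion` — taken from `symbolic`.
#' }
#' Net length is `max(nchar(ref), nchar(alt)) - 1` on the left-normalized
#' (anchor-base) representation.
#'
#' @param ref,alt Allele strings.
#' @param symbolic Optional symbolic descriptor (`"CNV"`,
#'   `"repeat_expansion"`, or a VCF-style `"<CNV>"` allele).
#' @param config A [filter_config()] (supplies `sv_min_len`).
#' @return One of `"SNV"`, `"indel"`, `"delins"`, `"SV"`, `"CNV"`,
#'   `"repeat_expansion"`.
#' @export
classify_variant_type <- function(ref, alt, symbolic = NULL,
                                  config = filter_config()) {
  if (!is.null(symbolic)) {
    s <- gsub("[<>]", "", symbolic)
    if (s %in% c("CNV", "CN0", "CN2", "DUP:TANDEM"))
      return("CNV")
    if (s %in% c("repeat_expansion", "STR"))
      return("repeat_expansion")
    utr_input_error(paste0("unknown symbolic descriptor: ", symbolic))
  }
  if (identical(ref, alt)) utr_data_error("ref and alt alleles are equal")
  n <- .left_normalize(ref, alt)
  if (nchar(n$ref) == 1L && nchar(n$alt) == 1L) return("SNV")
  pure <- (nchar(n$ref) == 1L && startsWith(n$alt, n$ref)) ||
          (nchar(n$alt) == 1L && startsWith(n$ref, n$alt)) ||
          nchar(n$ref) == 0L || nchar(n$alt) == 0L
  if (!pure) return("delins")
  net <- max(nchar(n$ref), nchar(n$alt)) - 1L
  if (net >= config$sv_min_len) "SV" else "indel"
}

#' Classify a tandem-repeat allele into a penetrance band
#'
#' @param repeat_count Non-negative repeat count.
#' @param bands Band table (`label`, `min_repeats`, `max_repeats`);
#'   default [default_repeat_bands()].
#' @return The label of the unique band containing the count, or
#'   `"unclassified"` when no band covers it (e.g. exactly 50 repeats
#'   under the defaults).
#' @export
classify_repeat_allele <- function(repeat_count,
                                   bands = default_repeat_bands()) {
  stopifnot(repeat_count >= 0)
  hit <- bands$min_repeats <= repeat_count & repeat_count <= bands$max_repeats
  if (!any(hit)) "unclassified" else bands$label[which(hit)[1]]
}
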