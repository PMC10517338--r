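# Assembly of the model-evaluation datasets: putative-benign variants
# drawn from UTR exons of census transcripts, and mechanism-based
# matched/mismatched/benign group assignment.

#' Default model-to-mechanism map
#'
#' Which curated mechanisms each predictor archetype is designed to model:
#' \describe{
#'   \item{`orf`}{5' UTR ribosome-load predictors (FramePool-style):
#'     impact on an existing regulatory uORF or introduction of a novel
#'     upstream start codon.}
#'   \item{`stability`}{3' UTR mRNA-stability predictors (Saluki-style):
#'     polyadenylation-signal and mRNA-stability mechanisms.}
#'   \item{`transcription`}{5' UTR transcription-level predictors
#'     (Enformer-style): promoter activity, promoter methylation and 5'
#'     UTR splicing. Whether splicing belongs in this matched set is an
#'     interpretation — "operating at the level of transcription" — so the
#'     map is data and can be edited.}
#' }
#'
#' @return Named list of class `model_mechanism_map`; each element has
#'   `model`, `side` (`"utr5"`/`"utr3"`) and `mechanisms`.
#' @export
default_model_map <- function() {
  structure(list(
    orf = list(model = "orf", side = "utr5",
               mechanisms = c("uorf_existing", "novel_upstream_start")),
    stability = list(model = "stability", side = "utr3",
                     mechanisms = c("polyadenylation_signal",
                                    "mrna_stability")),
    transcription = list(model = "transcription", side = "utr5",
                         mechanisms = c("promoter_activity",
                                        "promoter_methylation",
                                        "splicing_5utr"))
  ), class = "model_mechanism_map")
}

#' Select putative-benign variants from an allele-frequency table
#'
#' Returns the variants whose full reference span lies inside a UTR exon
#' interval (for `side`) of a transcript that carries a P/LP census
#' variant, and whose total allele frequency strictly exceeds
#' `config$benign_min_af`. Variants in UTR introns are excluded. The
#' benign threshold (1%) is deliberately looser than the P/LP discard
#' threshold (5%); the two are distinct configuration keys. Duplicates
#' shared across overlapping transcripts are deduplicated by
#' (chrom, pos, ref, alt); output order follows the input.
#'
#' @param af_table data.frame from [read_af_table()] (columns `chrom`,
#'   `pos`, `ref`, `alt`, `af_total`, list column `af`).
#' @param transcripts_with_plp List of coding [transcript_model()]s that
#'   harbour a P/LP census variant in the relevant UTR.
#' @param side `"utr3"` or `"utr5"`.
#' @param config A [filter_config()].
#' @return A `variant_table` of putative-benign variants (possibly empty,
#'   with a warning when no transcript qualifies).
#' @export
assemble_benign <- function(af_table, transcripts_with_plp,
                            side = c("utr3", "utr5"),
                            config = filter_config()) {
  side <- match.arg(side)
  txs <- Filter(function(tx) tx$coding && length(tx[[side]]) > 0L,
                transcripts_with_plp)
  if (length(txs) == 0L) {
    warning("no qualifying transcripts; empty benign set")
    return(empty_variant_table())
  }
  keep <- logical(nrow(af_table))
  for (i in seq_len(nrow(af_table))) {
    af <- af_table$af_total[i]
    if (is.na(af) || af <= config$benign_min_af) next
    row <- af_table[i, ]
    span <- .variant_span(row)
    keep[i] <- any(vapply(txs, function(tx) {
      identical(as.character(row$chrom), tx$chrom) &&
        .span_within(span, tx[[side]])
    }, logical(1)))
  }
  sel <- af_table[keep, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty_variant_table())
  sel <- sel[!duplicated(paste(sel$chrom, sel$pos, sel$ref, sel$alt)), ,
             drop = FALSE]
  out <- do.call(bind_variant_tables, lapply(seq_len(nrow(sel)), function(i)
    variant_record(sel$chrom[i], sel$pos[i], sel$ref[i], sel$alt[i],
                   af = sel$af[[i]], af_total = sel$af_total[i])))
  out
}

#' Assign benchmark groups for one model
#'
#' Every P/LP census entry appears exactly once: `plp_matched` when its
#' curated mechanism belongs to the model's matched set, otherwise
#' `plp_mismatched` (an undetermined mechanism is mismatched). Benign
#' variants form the `benign` group and carry no mechanism.
#'
#' @param census_entries Census table rows for the model's UTR side.
#' @param benign_variants A `variant_table` of putative-benign variants
#'   (keys taken from `hgvs` when present, else `chrom:pos:ref:alt`).
#' @param model One entry of [default_model_map()].
#' @return Object of class `benchmark_dataset`: a data.frame (`key`,
#'   `group`, `mechanism`) with attribute `utr_side`.
#' @export
assign_groups <- function(census_entries, benign_variants, model) {
  if (any(census_entries$utr_side != model$side))
    utr_input_error(sprintf(
      "census entries are not all %s; side mismatch with model '%s'",
      model$side, model$model))
  plp <- data.frame(
    key = census_entries$hgvs,
    group = ifelse(census_entries$mechanism %in% model$mechanisms,
                   "plp_matched", "plp_mismatched"),
    mechanism = census_entries$mechanism,
    stringsAsFactors = FALSE
  )
  ben <- if (nrow(benign_variants) > 0L) {
    keys <- benign_variants$hgvs
    if (is.null(keys)) keys <- rep(NA_character_, nrow(benign_variants))
    keys[is.na(keys)] <- .variant_key(benign_variants)[is.na(keys)]
    data.frame(key = keys, group = "benign", mechanism = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(0), group = character(0),
               mechanism = character(0), stringsAsFactors = FALSE)
  }
  out <- rbind(plp, ben)
  rownames(out) <- NULL
  structure(out, utr_side = model$side, model = model$model,
            class = c("benchmark_dataset", "data.frame"))
}

#' Write a benchmark dataset as TSV
#' @param dataset A `benchmark_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$model <- attr(dataset, "model")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
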