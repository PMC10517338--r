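# The curated census of P/LP UTR variants (shipped as versioned TSV
# fixtures) and its mechanism/classification summaries.

# Checksums of the shipped fixture files; load_census() refuses to read a
# silently modified census.
.CENSUS_MD5 <- c(
  census_utr3_plp.tsv = "cfb998231c95c6105daad102d6c1e653",
  census_utr5_plp.tsv = "0c7963cf8fb9ad06fe96a84485f56ba2"
)

# Prose mechanism headers, as printed in the census tables, normalised to
# the internal enum.
.MECHANISM_PROSE <- c(
  "Altered miRNA binding" = "mirna_binding",
  "Impact on polyadenylation signal" = "polyadenylation_signal",
  "Impact on mRNA stability" = "mrna_stability",
  "Altered splicing" = "splicing_3utr",
  "Impact on secondary structure" = "secondary_structure",
  "Translation: Impact on existing regulatory uORF" = "uorf_existing",
  "Translation: introduction of novel upstream start codon" =
    "novel_upstream_start",
  "Translation: altered mRNA-protein interaction" =
    "mrna_protein_interaction",
  "Transcription: altered promoter activity" = "promoter_activity",
  "Transcription: altered promoter methylation" = "promoter_methylation",
  "Transcription: splicing" = "splicing_5utr",
  "Undetermined mechanism" = "undetermined"
)

#' Normalise a prose mechanism label to the internal enum
#'
#' @param label Prose label (a census table section header) or an enum
#'   value, which passes through unchanged.
#' @return Enum mechanism string.
#' @export
normalize_mechanism <- function(label) {
  if (label %in% .MECHANISMS) return(label)
  out <- .MECHANISM_PROSE[[label]]
  if (is.null(out))
    utr_input_error(paste0("unknown mechanism label: ", label))
  out
}

#' Load the curated P/LP UTR variant census
#'
#' Reads the packaged census fixtures: 26 3' UTR and 68 5' UTR variants
#' classified pathogenic or likely pathogenic, each with transcript HGVS,
#' gene, ClinVar class, study class and curated molecular mechanism. The
#' `functional_evidence` column is nullable: per-variant flags are not
#' printed in the source tables.
#'
#' @param side `"utr3"`, `"utr5"` or `"both"`.
#' @param path Optional directory holding the fixture TSVs (defaults to
#'   the installed package data).
#' @param check_integrity Verify the fixture checksums (default `TRUE`);
#'   a mismatch raises a `utr_integrity_error`. Skipped for a custom
#'   `path`.
#' @return data.frame of class `census_table` with columns `hgvs`, `gene`,
#'   `utr_side`, `clinvar_class`, `study_class`, `mechanism`,
#'   `functional_evidence`.
#' @examples
#' nrow(load_census("utr3"))  # 26
#' nrow(load_census("both"))  # 94
#' @export
load_census <- function(side = c("both", "utr3", "utr5"), path = NULL,
                        check_integrity = is.null(path)) {
  side <- match.arg(side)
  dir <- path %||% system.file("extdata", package = "utrcensus")
  files <- c(utr3 = "census_utr3_plp.tsv", utr5 = "census_utr5_plp.tsv")
  want <- if (side == "both") names(files) else side

  parts <- lapply(want, function(s) {
    f <- file.path(dir, files[[s]])
    if (!file.exists(f))
      utr_input_error(paste0("census fixture not found: ", f))
    if (check_integrity &&
        !identical(unname(tools::md5sum(f)), unname(.CENSUS_MD5[[files[[s]]]])))
      utr_error(paste0("census fixture checksum mismatch: ", files[[s]]),
                "utr_integrity_error")
    df <- read.delim(f, sep = "\t", header = TRUE,
                     colClasses = "character", quote = "", na.strings = "NA")
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  validate_census(out)
}

#' Validate a census table
#'
#' Checks column presence, enum membership, HGVS parseability (every
#' entry must parse with [parse_hgvs_utr()] and agree with the recorded
#' UTR side) and mechanism/side consistency.
#'
#' @param entries Census data.frame.
#' @return The validated table, classed `census_table`.
#' @export
validate_census <- function(entries) {
  need <- c("hgvs", "gene", "utr_side", "clinvar_class", "study_class",
            "mechanism")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    utr_format_error(paste0("census lacks column(s): ",
                            paste(miss, collapse = ", ")))
  if (any(!entries$utr_side %in% c("utr3", "utr5")))
    utr_data_error("utr_side must be utr3 or utr5")
  if (any(!entries$clinvar_class %in%
            c("P", "LP", "P_and_LP_conflicting")))
    utr_data_error("census clinvar_class outside {P, LP, P_and_LP_conflicting}")
  if (any(!entries$study_class %in% .STUDY_CLASSES))
    utr_data_error("census study_class outside {P, LP, VUS}")
  entries$mechanism <- vapply(entries$mechanism, normalize_mechanism,
                              character(1), USE.NAMES = FALSE)
  side_ok <- ifelse(entries$utr_side == "utr3",
                    entries$mechanism %in% .MECHANISMS_UTR3,
                    entries$mechanism %in% .MECHANISMS_UTR5)
  if (any(!side_ok))
    utr_data_error(paste0("mechanism inconsistent with UTR side for: ",
                          paste(entries$hgvs[!side_ok], collapse = ", ")))
  for (h in entries$hgvs) {
    loc <- parse_hgvs_utr(h)
    side <- if (loc$region == "three_prime_utr") "utr3" else "utr5"
    if (!identical(side, entries$utr_side[entries$hgvs == h][1]))
      utr_data_error(paste0("HGVS region disagrees with utr_side: ", h))
  }
  if (!inherits(entries, "census_table"))
    class(entries) <- c("census_table", "data.frame")
  entries
}

#' Count census entries per mechanism
#'
#' @param entries A census table (or subset).
#' @return Named integer vector, mechanism -> count; only mechanisms
#'   present in the input appear, and the counts partition it.
#' @examples
#' stratify_mechanism(load_census("utr3"))["polyadenylation_signal"]  # 10
#' @export
stratify_mechanism <- function(entries) {
  if (nrow(entries) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(entries$mechanism)
  setNames(as.integer(tab), names(tab))
}

#' Cross-tabulate study classification against ClinVar classification
#'
#' @param entries A census table.
#' @return Matrix of class `census_crosstab` with study classes as rows
#'   (`P`, `LP`, `VUS`) and ClinVar classes as columns (`P`, `LP`,
#'   `P_and_LP_conflicting`, `other`); cell counts sum to `nrow(entries)`.
#' @examples
#' ct <- cross_tabulate(load_census("utr3"))
#' ct["LP", "P"]  # 12
#' @export
cross_tabulate <- function(entries) {
  tab <- table(factor(entries$study_class, levels = .STUDY_CLASSES),
               factor(entries$clinvar_class, levels = .CLINVAR_CLASSES))
  m <- unclass(as.matrix(tab))
  dimnames(m) <- list(study_class = .STUDY_CLASSES,
                      clinvar_class = .CLINVAR_CLASSES)
  class(m) <- c("census_crosstab", class(m))
  m
}

#' Unique gene symbols in a census table
#'
#' @param entries A census table.
#' @return Sorted character vector of deduplicated gene symbols.
#' @examples
#' length(unique_genes(load_census("both")))  # 49
#' @export
unique_genes <- function(entries) {
  sort(unique(entries$gene))
}

#' Compare a per-gene metric between two gene groups
#'
#' Thin wrapper over [rank_sum_test()] for gene-level metrics such as
#' ClinVar P/LP counts or LOEUF scores.
#'
#' @param groupA,groupB Named (gene -> value) or plain numeric vectors;
#'   both non-empty.
#' @return A `comparison_result`, see [rank_sum_test()].
#' @export
compare_gene_metric <- function(groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    utr_input_error("both gene groups must be non-empty")
  rank_sum_test(as.numeric(groupA), as.numeric(groupB))
}
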