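# Readers/writers for the external formats the pipeline touches, plus
# HGVS UTR-coordinate parsing. Internal coordinates are 1-based inclusive
# (GFF convention); BED/bedGraph inputs are converted at the parser
# boundary.

# ---- variant records ----------------------------------------------------

#' Construct a variant record table
#'
#' A variant record holds a genomic variant (chrom, 1-based pos, ref, alt)
#' together with transcript HGVS, gene symbol, ClinVar significance class,
#' origin and an allele-frequency map. Records are stored as rows of a
#' data.frame; the per-subpopulation AF map is a list column of named
#' numeric vectors.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position of the first reference base.
#' @param ref,alt Allele strings. An empty `ref` denotes a pure insertion
#'   located between `pos - 1` and `pos`.
#' @param hgvs Transcript-level HGVS string (may be `NA`).
#' @param gene Gene symbol (may be `NA`).
#' @param clinvar_class One of `"P"`, `"LP"`, `"P_and_LP_conflicting"`,
#'   `"other"`.
#' @param origin One of `"germline"`, `"somatic"`, `"unknown"`.
#' @param af Named numeric vector of per-subpopulation allele frequencies
#'   in \[0, 1\].
#' @param af_total Total allele frequency in \[0, 1\] (may be `NA`).
#' @return A one-row data.frame of class `variant_table`.
#' @examples
#' variant_record("chr1", 100, "A", "G", clinvar_class = "P")
#' @export
variant_record <- function(chrom, pos, ref, alt, hgvs = NA_character_,
                           gene = NA_character_, clinvar_class = "other",
                           origin = "unknown", af = numeric(0),
                           af_total = NA_real_) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    hgvs = as.character(hgvs), gene = as.character(gene),
    clinvar_class = as.character(clinvar_class),
    origin = as.character(origin), af_total = as.numeric(af_total),
    stringsAsFactors = FALSE
  )
  df$af <- list(af)
  class(df) <- c("variant_table", "data.frame")
  validate_variant_table(df)
}

#' Validate a variant record table
#'
#' Checks the record invariants: positions at least 1, non-empty alleles
#' unless the record carries a symbolic allele, all allele frequencies in
#' \[0, 1\], and enum fields within their allowed sets.
#'
#' @param records A `variant_table` data.frame.
#' @return The validated table, invisibly classed as `variant_table`.
#' @export
validate_variant_table <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("chrom", "pos", "ref", "alt", "clinvar_class", "origin")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    utr_format_error(paste0("variant table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  if (any(records$pos < 1L, na.rm = TRUE))
    utr_data_error("variant position must be >= 1")
  symbolic <- grepl("^<.+>$", records$alt)
  if (any(!symbolic & !nzchar(records$alt)))
    utr_data_error("empty alt allele in a non-symbolic record")
  bad_class <- !records$clinvar_class %in% .CLINVAR_CLASSES
  if (any(bad_class))
    utr_data_error(paste0("unknown clinvar_class: ",
                          paste(unique(records$clinvar_class[bad_class]),
                                collapse = ", ")))
  if (any(!records$origin %in% .ORIGINS))
    utr_data_error("unknown origin value")
  afs <- c(unlist(records$af, use.names = FALSE), records$af_total)
  afs <- afs[!is.na(afs)]
  if (length(afs) && (any(afs < 0) || any(afs > 1)))
    utr_data_error("allele frequencies must lie in [0, 1]")
  if (!inherits(records, "variant_table"))
    class(records) <- c("variant_table", "data.frame")
  invisible(records)
}

.variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

#' Variant keys for a record table
#'
#' @param records A `variant_table`.
#' @return Character vector `chrom:pos:ref:alt`, one per record.
#' @export
variant_key <- function(records) .variant_key(records)

# ---- ClinVar summary ----------------------------------------------------

#' Default ClinVar summary column mapping
#'
#' Column names follow the ClinVar tab-delimited `variant_summary` layout;
#' the mapping is exposed so other releases (or synthetic files) can rename
#' columns without touching the reader.
#'
#' @return Named list mapping logical fields to file column names.
#' @export
clinvar_summary_columns <- function() {
  list(hgvs = "Name", gene = "GeneSymbol",
       significance = "ClinicalSignificance", chrom = "Chromosome",
       pos = "PositionVCF", ref = "ReferenceAlleleVCF",
       alt = "AlternateAlleleVCF", origin = "OriginSimple")
}

#' Default significance-string mapping
#'
#' ClinVar free text varies by release, so the mapping from significance
#' strings to the internal classes is data, not code. Unmapped strings
#' become `"other"`.
#'
#' @return Named character vector, names are ClinVar strings, values are
#'   internal classes.
#' @export
clinvar_significance_map <- function() {
  c("Pathogenic" = "P",
    "Likely pathogenic" = "LP",
    "Pathogenic/Likely pathogenic" = "P_and_LP_conflicting")
}

#' Read a ClinVar-style tab-delimited variant summary
#'
#' One variant record per data row. Significance strings are mapped through
#' `significance_map`; anything unmapped becomes class `"other"`. Rows with
#' malformed genomic coordinates (non-numeric or < 1) are skipped with a
#' message.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param significance_map Named character vector, see
#'   [clinvar_significance_map()].
#' @param columns Column mapping, see [clinvar_summary_columns()].
#' @return A `variant_table` data.frame (zero rows for a header-only file).
#' @export
read_clinvar_summary <- function(path,
                                 significance_map = clinvar_significance_map(),
                                 columns = clinvar_summary_columns()) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- unlist(columns, use.names = FALSE)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    utr_format_error(paste0("missing required column(s): ",
                            paste(miss, collapse = ", ")))
  if (nrow(raw) == 0L) return(empty_variant_table())

  pos <- suppressWarnings(as.integer(raw[[columns$pos]]))
  ok <- !is.na(pos) & pos >= 1L
  if (any(!ok))
    message(sum(!ok), " row(s) skipped for malformed coordinates")
  raw <- raw[ok, , drop = FALSE]
  pos <- pos[ok]
  if (nrow(raw) == 0L) return(empty_variant_table())

  sig <- raw[[columns$significance]]
  cls <- unname(significance_map[sig])
  cls[is.na(cls)] <- "other"
  origin <- tolower(raw[[columns$origin]])
  origin[!origin %in% .ORIGINS] <- "unknown"

  df <- data.frame(
    chrom = raw[[columns$chrom]], pos = pos, ref = raw[[columns$ref]],
    alt = raw[[columns$alt]], hgvs = raw[[columns$hgvs]],
    gene = raw[[columns$gene]], clinvar_class = cls, origin = origin,
    af_total = NA_real_, stringsAsFactors = FALSE
  )
  df$af <- rep(list(numeric(0)), nrow(df))
  class(df) <- c("variant_table", "data.frame")
  validate_variant_table(df)
  df
}

#' An empty variant table
#' @return A zero-row `variant_table`.
#' @export
empty_variant_table <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   hgvs = character(0), gene = character(0),
                   clinvar_class = character(0), origin = character(0),
                   af_total = numeric(0), stringsAsFactors = FALSE)
  df$af <- list()
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Bind variant tables by row
#' @param ... `variant_table` objects.
#' @return A combined `variant_table`.
#' @export
bind_variant_tables <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

# ---- variant table round-trip ------------------------------------------

#' Write / read a variant table as TSV
#'
#' The AF map is serialised as `pop=value` pairs joined by `;` with full
#' double precision, so a write/read round trip reproduces every field
#' exactly.
#'
#' @param records A `variant_table`.
#' @param path Output/input TSV path.
#' @return `write_variant_table` returns `path` invisibly;
#'   `read_variant_table` returns a `variant_table`.
#' @export
write_variant_table <- function(records, path) {
  validate_variant_table(records)
  flat <- records
  class(flat) <- "data.frame"
  flat$af <- vapply(records$af, function(m) {
    if (!length(m)) return("")
    paste(names(m), sprintf("%.17g", m), sep = "=", collapse = ";")
  }, character(1))
  flat$af_total <- ifelse(is.na(flat$af_total), "",
                          sprintf("%.17g", flat$af_total))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  flat <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", quote = "", na.strings = "NA")
  if (nrow(flat) == 0L) return(empty_variant_table())
  af <- lapply(flat$af, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
             vapply(kv, `[`, character(1), 1))
  })
  df <- data.frame(
    chrom = flat$chrom, pos = as.integer(flat$pos), ref = flat$ref,
    alt = flat$alt, hgvs = flat$hgvs, gene = flat$gene,
    clinvar_class = flat$clinvar_class, origin = flat$origin,
    af_total = suppressWarnings(as.numeric(flat$af_total)),
    stringsAsFactors = FALSE
  )
  df$ref[is.na(df$ref)] <- ""
  df$af <- af
  class(df) <- c("variant_table", "data.frame")
  validate_variant_table(df)
  df
}

# ---- HGVS UTR parsing ---------------------------------------------------

.HGVS_POS <- "([*-])(\\d+)"

#' Parse a transcript-level HGVS string restricted to UTR coordinates
#'
#' Accepts `c.-N` (5' UTR, counted upstream from the CDS start) and `c.*N`
#' (3' UTR, counted downstream from the CDS end) positions with the edit
#' forms substitution (`A>C`), deletion (`del`), duplication (`dup`),
#' insertion (`ins`) and deletion-insertion (`delins`). Offsets of a range
#' are normalised so `start_offset <= end_offset`.
#'
#' Coding-region HGVS (no `-`/`*` prefix) raises a `utr_not_utr_error`;
#' intronic offsets (e.g. `c.-15+3`) are rejected the same way because the
#' pipeline is restricted to UTR-exonic variants. Anything else unparseable
#' raises `utr_parse_error`.
#'
#' @param hgvs A string like `"NM_000518.4:c.*32A>C"`.
#' @return An object of class `hgvs_utr_location`: a list with
#'   `transcript_id`, `region` (`"five_prime_utr"` / `"three_prime_utr"`),
#'   `start_offset`, `end_offset`, `edit` and (where applicable)
#'   `ref_allele` / `alt_allele`.
#' @examples
#' parse_hgvs_utr("NM_000518.4:c.*32A>C")
#' parse_hgvs_utr("NM_000518.4:c.*110_*114del")
#' @export
parse_hgvs_utr <- function(hgvs) {
  stopifnot(is.character(hgvs), length(hgvs) == 1L)
  m <- regmatches(hgvs, regexec("^([A-Za-z_]+[0-9]+(?:\\.[0-9]+)?):c\\.(.+)$",
                                hgvs))[[1]]
  if (length(m) == 0L)
    utr_parse_error(paste0("not a transcript c. HGVS string: ", hgvs))
  tid <- m[2]
  body <- m[3]

  if (grepl("^[0-9]", body))
    utr_error(paste0("coding-region HGVS, not a UTR variant: ", hgvs),
              "utr_not_utr_error")
  if (grepl(sprintf("^%s[+-][0-9]", .HGVS_POS), body) ||
      grepl(sprintf("_%s[+-][0-9]", .HGVS_POS), body))
    utr_error(paste0("intronic offset, not UTR-exonic: ", hgvs),
              "utr_not_utr_error")

  pos1 <- sprintf("^%s", .HGVS_POS)
  range_pat <- sprintf("^%s(?:_%s)?", .HGVS_POS, .HGVS_POS)

  take <- function(pattern, text)
    regmatches(text, regexec(pattern, text, perl = TRUE))[[1]]

  # substitution: <pos><ref>><alt>
  sub <- take(sprintf("%s([ACGTN])>([ACGTN])$", pos1), body)
  if (length(sub)) {
    return(.hgvs_loc(tid, sub[2], as.integer(sub[3]), as.integer(sub[3]),
                     "substitution", ref = sub[4], alt = sub[5],
                     hgvs = hgvs))
  }

  for (spec in list(
    list(suffix = "del(?:[ACGTN]+)?", edit = "deletion"),
    list(suffix = "dup(?:[ACGTN]+)?", edit = "duplication"),
    list(suffix = "delins([ACGTN]+)", edit = "delins"),
    list(suffix = "ins([ACGTN]+)", edit = "insertion")
  )) {
    mt <- take(sprintf("%s%s$", range_pat, spec$suffix), body)
    if (!length(mt)) next
    sign1 <- mt[2]; off1 <- as.integer(mt[3])
    sign2 <- if (nzchar(mt[4])) mt[4] else sign1
    off2 <- if (nzchar(mt[5])) as.integer(mt[5]) else off1
    if (sign1 != sign2)
      utr_parse_error(paste0("range spans UTR boundary: ", hgvs))
    if (spec$edit == "insertion" && !nzchar(mt[4]))
      utr_parse_error(paste0("insertion requires a flanking range: ", hgvs))
    alt <- if (spec$edit %in% c("delins", "insertion") && length(mt) >= 6)
      mt[6] else NA_character_
    return(.hgvs_loc(tid, sign1, min(off1, off2), max(off1, off2),
                     spec$edit, alt = alt, hgvs = hgvs))
  }

  utr_parse_error(paste0("unrecognised HGVS edit: ", hgvs))
}

.hgvs_loc <- function(tid, sign, start, end, edit, ref = NA_character_,
                      alt = NA_character_, hgvs = NA_character_) {
  if (start > end) utr_parse_error("start offset exceeds end offset")
  structure(list(
    transcript_id = tid,
    region = if (sign == "*") "three_prime_utr" else "five_prime_utr",
    start_offset = as.integer(start), end_offset = as.integer(end),
    edit = edit, ref_allele = ref, alt_allele = alt, hgvs = hgvs
  ), class = "hgvs_utr_location")
}

#' @export
print.hgvs_utr_location <- function(x, ...) {
  side <- if (x$region == "three_prime_utr") "3' UTR" else "5' UTR"
  cat(sprintf("<%s %s %s offsets %d..%d>\n", x$transcript_id, side, x$edit,
              x$start_offset, x$end_offset))
  invisible(x)
}

# ---- transcript annotation ---------------------------------------------

#' Read transcript models from a GTF/GFF file
#'
#' Builds one [transcript_model()] per transcript from its exon and CDS
#' features. Transcripts with exons but no CDS are flagged non-coding
#' (`coding = FALSE`) and carry no UTR intervals; the curation pipeline
#' requires coding transcripts.
#'
#' @param path GTF or GFF3 file with `exon` and `CDS` features carrying a
#'   `transcript_id` attribute.
#' @param flags Optional data.frame (`transcript_id`, `flag`) assigning
#'   APPRIS/MANE flags; see [read_transcript_flags()].
#' @return Named list of `transcript_model` objects.
#' @export
read_transcripts <- function(path, flags = NULL) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  tid <- meta$transcript_id
  if (is.null(tid))
    utr_format_error("annotation lacks a transcript_id attribute")
  gene <- meta$gene_id %||% meta$gene_name %||% rep(NA_character_, length(gr))
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]; tid <- tid[keep]; gene <- gene[keep]
  type <- meta$type[keep]

  out <- lapply(split(seq_along(gr), tid), function(idx) {
    sub <- gr[idx]
    st <- as.character(GenomicRanges::strand(sub))[1]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    is_exon <- type[idx] == "exon"
    exons <- cbind(start = GenomicRanges::start(sub)[is_exon],
                   end = GenomicRanges::end(sub)[is_exon])
    cds <- NULL
    if (any(!is_exon)) {
      cs <- GenomicRanges::start(sub)[!is_exon]
      ce <- GenomicRanges::end(sub)[!is_exon]
      cds <- c(min(cs), max(ce))
    }
    transcript_model(tid[idx][1], gene = gene[idx][1], chrom = chrom,
                     strand = if (st %in% c("+", "-")) st else "+",
                     exons = exons, cds = cds)
  })
  if (!is.null(flags)) out <- apply_transcript_flags(out, flags)
  out
}

#' Read a transcript flag sidecar (TSV: transcript_id, flag)
#'
#' @param path TSV path with columns `transcript_id` and `flag`.
#' @return data.frame with those two columns.
#' @export
read_transcript_flags <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "")
  miss <- setdiff(c("transcript_id", "flag"), names(df))
  if (length(miss))
    utr_format_error(paste0("flag table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  df
}

#' Attach flags to a list of transcript models
#' @param transcripts Named list of `transcript_model`.
#' @param flags data.frame (`transcript_id`, `flag`).
#' @return The list with `flags` fields filled in.
#' @export
apply_transcript_flags <- function(transcripts, flags) {
  for (i in seq_len(nrow(flags))) {
    tid <- flags$transcript_id[i]
    if (!is.null(transcripts[[tid]]))
      transcripts[[tid]]$flags <- union(transcripts[[tid]]$flags,
                                        flags$flag[i])
  }
  transcripts
}

#' Write transcript models as GTF
#'
#' Emits `exon` and `CDS` lines; the inverse of [read_transcripts()] for
#' synthetic annotation.
#'
#' @param transcripts List of `transcript_model`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene, tx$transcript_id)
    ex <- tx$exons
    lines <- c(lines, sprintf("%s\tutrcensus\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom, IRanges::start(ex), IRanges::end(ex),
                              tx$strand, attrs))
    if (!is.null(tx$cds)) {
      # emit CDS clipped to exons
      cds_parts <- IRanges::intersect(
        ex, IRanges::IRanges(tx$cds[1], tx$cds[2]))
      lines <- c(lines,
                 sprintf("%s\tutrcensus\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                         tx$chrom, IRanges::start(cds_parts),
                         IRanges::end(cds_parts), tx$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- conservation tracks ------------------------------------------------

#' Build a position-indexed conservation score lookup
#'
#' `read_conservation_track` parses a bedGraph file (0-based half-open,
#' converted to 1-based inclusive on input); `conservation_track` builds
#' the same object from a data.frame with 1-based inclusive `start`/`end`.
#' Overlapping intervals on a chromosome are a format error; adjacent
#' intervals are fine and every covered position resolves to exactly one
#' interval.
#'
#' @param path bedGraph file (chrom, start, end, score).
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and `score`.
#' @return An object of class `conservation_track`.
#' @export
read_conservation_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  conservation_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    score = S4Vectors::mcols(gr)$score, stringsAsFactors = FALSE
  ))
}

#' @rdname read_conservation_track
#' @export
conservation_track <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(intervals)))
  if (any(intervals$end < intervals$start))
    utr_format_error("interval end precedes start")
  by_chrom <- split(intervals, intervals$chrom)
  for (sub in by_chrom) {
    ir <- IRanges::IRanges(sub$start, sub$end)
    hits <- IRanges::findOverlaps(ir, ir)
    if (length(hits) > length(ir))
      utr_format_error("overlapping intervals in conservation track")
  }
  by_chrom <- lapply(by_chrom, function(sub) sub[order(sub$start), ])
  structure(list(by_chrom = by_chrom), class = "conservation_track")
}

#' Look up conservation scores at 1-based positions
#'
#' @param track A `conservation_track`.
#' @param chrom Chromosome name (length 1).
#' @param pos Integer vector of 1-based positions.
#' @return Numeric vector of scores, `NA` where the track has no coverage.
#' @export
track_score <- function(track, chrom, pos) {
  stopifnot(inherits(track, "conservation_track"))
  sub <- track$by_chrom[[chrom]]
  if (is.null(sub)) return(rep(NA_real_, length(pos)))
  idx <- findInterval(pos, sub$start)
  out <- rep(NA_real_, length(pos))
  ok <- idx >= 1L
  ok[ok] <- pos[ok] <= sub$end[idx[ok]]
  out[ok] <- sub$score[idx[ok]]
  out
}

#' Write a conservation track as bedGraph
#' @param track A `conservation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_bedgraph <- function(track, path) {
  rows <- do.call(rbind, track$by_chrom)
  lines <- sprintf("%s\t%d\t%d\t%s", rows$chrom, rows$start - 1L, rows$end,
                   sprintf("%.17g", rows$score))
  writeLines(lines, path)
  invisible(path)
}

# ---- allele-frequency tables -------------------------------------------

#' Read an allele-frequency table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `af_total` and any number
#' of per-subpopulation columns prefixed `af_` (e.g. `af_afr`), emulating a
#' gnomAD extract.
#'
#' @param path TSV path.
#' @return data.frame with an additional `af` list column (named numeric
#'   per-subpopulation map).
#' @export
read_af_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "af_total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    utr_format_error(paste0("AF table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  subpop_cols <- setdiff(grep("^af_", names(df), value = TRUE), "af_total")
  vals <- c(df$af_total, unlist(df[subpop_cols], use.names = FALSE))
  vals <- vals[!is.na(vals)]
  if (length(vals) && (any(vals < 0) || any(vals > 1)))
    utr_data_error("allele frequencies must lie in [0, 1]")
  df$af <- lapply(seq_len(nrow(df)), function(i) {
    m <- unlist(df[i, subpop_cols, drop = FALSE])
    m <- m[!is.na(m)]
    setNames(as.numeric(m), sub("^af_", "", names(m)))
  })
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df
}

#' Write an allele-frequency table
#' @param df data.frame as returned by [read_af_table()] (the `af` list
#'   column is expanded back into `af_<pop>` columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_af_table <- function(df, path) {
  pops <- unique(unlist(lapply(df$af, names)))
  flat <- df[setdiff(names(df), "af")]
  for (p in pops)
    flat[[paste0("af_", p)]] <- vapply(df$af, function(m) {
      if (p %in% names(m)) m[[p]] else NA_real_
    }, numeric(1))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
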