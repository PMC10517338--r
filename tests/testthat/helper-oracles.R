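# Independent oracles used to check the statistical and scoring layers.
# These deliberately use naive nested-loop / enumeration strategies and
# never call the implementation they verify.

# U statistic of group A by explicit pair counting with half credit for
# ties.
pair_count_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Vectorised pair counting (same statistic as pair_count_u).
pair_count_u_fast <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled values to group A (twice the smaller tail, capped at 1).
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_null <- apply(idx, 2, function(i)
    pair_count_u_fast(pooled[i], pooled[-i]))
  u_obs <- pair_count_u_fast(a, b)
  eps <- 1e-9
  min(1, 2 * min(mean(u_null <= u_obs + eps),
                 mean(u_null >= u_obs - eps)))
}

# AUC by brute-force pair counting.
pair_auc <- function(pos, neg) {
  pair_count_u(pos, neg) / (length(pos) * length(neg))
}

# Nested-loop evaluation of the transcription aggregation recipe:
# strand average, centre +/- 2 windows, per-track log2(1 + window sum),
# mean over tracks, alt minus ref.
oracle_transcription <- function(ref_arr, alt_arr, center, tracks,
                                 n_windows = 5L) {
  half <- (n_windows - 1L) %/% 2L
  score <- function(arr) {
    s_tracks <- numeric(0)
    for (t in tracks) {
      acc <- 0
      for (w in (center - half):(center + half)) {
        acc <- acc + (arr[1, w, t] + arr[2, w, t]) / 2
      }
      s_tracks <- c(s_tracks, log2(1 + acc))
    }
    mean(s_tracks)
  }
  score(alt_arr) - score(ref_arr)
}

# Maximum conservation score over a reference span, scanning position by
# position and skipping uncovered ones.
oracle_phylop_max <- function(intervals, chrom, pos, ref_len) {
  best <- NA_real_
  for (p in pos:(pos + ref_len - 1L)) {
    hit <- intervals[intervals$chrom == chrom & intervals$start <= p &
                       p <= intervals$end, ]
    if (nrow(hit) == 1L && (is.na(best) || hit$score > best))
      best <- hit$score
  }
  best
}

# A compact coding transcript for region-call tests:
#   plus strand, exons 100-300 / 500-700 / 900-1100, CDS 250-1000.
#   5' UTR: 100-249; 3' UTR: 1001-1100; introns 301-499 and 701-899.
toy_transcript <- function(id = "NM_TOY.1", gene = "TOY", strand = "+",
                           flags = character(0)) {
  transcript_model(id, gene, "chr1", strand,
                   rbind(c(100, 300), c(500, 700), c(900, 1100)),
                   cds = c(250, 1000), flags = flags)
}

snv_at <- function(pos, chrom = "chr1", ref = "A", alt = "G", ...) {
  variant_record(chrom, pos, ref, alt, ...)
}
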