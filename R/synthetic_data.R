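# Synthetic generators for every pipeline input: multi-transcript gene
# structures, variant and AF tables, effect-score distributions with
# controllable group structure, and conservation tracks. Generators are
# pure functions of (config, seed) and write in exactly the formats the
# readers consume.

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: effect
#' magnitudes for model-matched variants three times the benign noise
#' scale, with Rademacher (+/-1) signs because pathogenic regulatory
#' effects act in both directions (expression increase and decrease);
#' mismatched variants carry a smaller magnitude; putative-benign effects
#' are zero-centred noise. The allele-frequency spectrum is a long-tailed
#' Beta with mass straddling the 1% benign and 5% discard thresholds so
#' both frequency filters are exercised.
#'
#' @param seed Integer seed; generators restore the caller's RNG state.
#' @param n_genes Number of synthetic genes.
#' @param transcripts_per_gene Transcripts per gene (>= 1; the first is
#'   the flagged APPRIS principal).
#' @param utr_exon_count_range Inclusive range for the number of exons in
#'   each UTR.
#' @param n_plp Number of P/LP variants in the benchmark (split evenly
#'   between model-matched and model-mismatched mechanisms).
#' @param n_benign Number of putative-benign variants.
#' @param matched_effect_size Location of `|raw|` for matched variants.
#' @param mismatched_effect_size Location of `|raw|` for mismatched
#'   variants (must not exceed `matched_effect_size`).
#' @param benign_effect_sd Standard deviation of the zero-centred benign
#'   scores and of the noise added to P/LP scores.
#' @param conservation_shift Elevation of conservation scores at P/LP
#'   positions (benign positions are standard normal around zero).
#' @param af_shape1,af_shape2 Beta parameters of the AF spectrum.
#' @param alt_overlap One of `"none"`, `"cds"`, `"splice_proximal"`,
#'   `"intronic"`, `"opposite_utr"`: what the non-principal transcripts
#'   are engineered to place at the principal's variant positions, used
#'   to exercise each confidence-score outcome.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 6L,
                              transcripts_per_gene = 1L,
                              utr_exon_count_range = c(1L, 2L),
                              n_plp = 60L, n_benign = 30L,
                              matched_effect_size = 3,
                              mismatched_effect_size = 1.5,
                              benign_effect_sd = 1,
                              conservation_shift = 2,
                              af_shape1 = 0.3, af_shape2 = 8,
                              alt_overlap = c("none", "cds",
                                              "splice_proximal", "intronic",
                                              "opposite_utr")) {
  alt_overlap <- match.arg(alt_overlap)
  if (!(matched_effect_size >= mismatched_effect_size &&
        mismatched_effect_size >= 0))
    utr_input_error("need matched_effect_size >= mismatched_effect_size >= 0")
  stopifnot(n_genes >= 1L, transcripts_per_gene >= 1L, n_plp >= 0L,
            n_benign >= 0L, benign_effect_sd > 0)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    utr_exon_count_range = as.integer(utr_exon_count_range),
    n_plp = as.integer(n_plp), n_benign = as.integer(n_benign),
    matched_effect_size = matched_effect_size,
    mismatched_effect_size = mismatched_effect_size,
    benign_effect_sd = benign_effect_sd,
    conservation_shift = conservation_shift,
    af_shape1 = af_shape1, af_shape2 = af_shape2,
    alt_overlap = alt_overlap
  ), class = "simulation_config")
}

# One synthetic gene: a plus-strand principal transcript with UTR exons
# of width 200 separated by 300-bp introns around a single 600-bp CDS
# exon, plus alternatives engineered around the gene's variant position.
# Genes are laid out every 100 kb on chr1.
.simulate_gene <- function(gene_idx, config) {
  base <- 100000L * gene_idx
  rng <- seq(config$utr_exon_count_range[1], config$utr_exon_count_range[2])
  pick <- function() if (length(rng) == 1L) rng else sample(rng, 1L)
  n5 <- pick(); n3 <- pick()
  exons <- NULL
  cur <- base
  for (i in seq_len(n5)) {
    exons <- rbind(exons, c(cur, cur + 199L)); cur <- cur + 500L
  }
  cds <- c(cur, cur + 599L)
  exons <- rbind(exons, cds)
  cur <- cur + 900L
  for (i in seq_len(n3)) {
    exons <- rbind(exons, c(cur, cur + 199L)); cur <- cur + 500L
  }
  gene <- sprintf("GENE%03d", gene_idx)
  principal <- transcript_model(sprintf("NMSYN%04d.1", gene_idx * 10L),
                                gene, "chr1", "+", exons, cds = cds,
                                flags = c("appris_principal",
                                          "clinvar_preferred"))
  # the gene's variant sits 100 bases into the first 3' UTR exon
  pos <- IRanges::start(principal$utr3)[1] + 99L
  txs <- list(principal)
  if (config$transcripts_per_gene > 1L && config$alt_overlap != "none") {
    for (k in seq_len(config$transcripts_per_gene - 1L)) {
      alt_tid <- sprintf("NMSYN%04d.1", gene_idx * 10L + k)
      alt <- switch(config$alt_overlap,
        # exon around pos with CDS covering it -> cds_exonic
        cds = transcript_model(alt_tid, gene, "chr1", "+",
                               cbind(pos - 500L, pos + 500L),
                               cds = c(pos - 400L, pos + 400L),
                               flags = "appris_alternative"),
        # pos falls 4 bases before an exon start -> splice-proximal
        splice_proximal = transcript_model(
          alt_tid, gene, "chr1", "+",
          rbind(c(pos - 300L, pos - 101L), c(pos + 4L, pos + 203L)),
          cds = c(pos - 250L, pos + 150L), flags = "appris_alternative"),
        # pos deep inside a long intron -> intronic
        intronic = transcript_model(
          alt_tid, gene, "chr1", "+",
          rbind(c(pos - 2000L, pos - 1801L), c(pos + 1801L, pos + 2000L)),
          cds = c(pos - 1900L, pos + 1900L), flags = "appris_alternative"),
        # pos falls in the alternative's 5' UTR -> opposite-side call
        opposite_utr = transcript_model(
          alt_tid, gene, "chr1", "+", cbind(pos - 99L, pos + 500L),
          cds = c(pos + 101L, pos + 400L), flags = "appris_alternative")
      )
      txs <- c(txs, list(alt))
    }
  }
  list(transcripts = txs, principal = principal, variant_pos = pos)
}

#' Simulate a transcript annotation with engineered overlaps
#'
#' Generates `n_genes` plus-strand genes on chr1, each with a flagged
#' APPRIS-principal transcript and, depending on
#' `config$transcripts_per_gene` and `config$alt_overlap`, alternative
#' transcripts engineered so a variant in the principal's 3' UTR receives
#' a known confidence score (e.g. `alt_overlap = "cds"` forces score 0;
#' single-transcript genes force score 2). One 3' UTR SNV per gene is
#' generated in the principal transcript.
#'
#' @param config A [simulation_config()].
#' @return List with `transcripts` (named list of [transcript_model()]),
#'   `flags` (data.frame `transcript_id`, `flag`), and `variants`
#'   (a `variant_table`, one UTR SNV per gene with an AF map drawn from
#'   the configured spectrum).
#' @export
simulate_annotation <- function(config = simulation_config()) {
  with_seed(config$seed, {
    txs <- list()
    vars <- list()
    for (g in seq_len(config$n_genes)) {
      sim <- .simulate_gene(g, config)
      for (tx in sim$transcripts) txs[[tx$transcript_id]] <- tx
      pos <- sim$variant_pos
      af <- c(nfe = rbeta(1, config$af_shape1, config$af_shape2),
              afr = rbeta(1, config$af_shape1, config$af_shape2))
      vars[[g]] <- variant_record(
        "chr1", pos, "A", "G",
        hgvs = sprintf("%s:c.*%d%s", sim$principal$transcript_id,
                       pos - sim$principal$cds[2], "A>G"),
        gene = sim$principal$gene, clinvar_class = "P",
        af = af, af_total = mean(af))
    }
    flags <- do.call(rbind, lapply(txs, function(tx) {
      if (length(tx$flags) == 0L) return(NULL)
      data.frame(transcript_id = tx$transcript_id, flag = tx$flags,
                 stringsAsFactors = FALSE)
    }))
    rownames(flags) <- NULL
    list(transcripts = txs, flags = flags,
         variants = do.call(bind_variant_tables, vars))
  })
}

#' Simulate a benchmark dataset with known group structure
#'
#' Generates `n_plp` P/LP entries (mechanisms drawn so that half are
#' matched to `model` and half mismatched) and `n_benign` putative-benign
#' variants, together with per-variant effect scores and a conservation
#' track:
#' \itemize{
#'   \item matched raw scores: `s * matched_effect_size + noise`, with
#'     `s` a Rademacher sign and noise `N(0, benign_effect_sd)`;
#'   \item mismatched raw scores: the same with `mismatched_effect_size`;
#'   \item benign raw scores: `N(0, benign_effect_sd)`;
#'   \item conservation: `N(conservation_shift, 1)` at P/LP positions,
#'     `N(0, 1)` at benign positions.
#' }
#' Benign total AFs are drawn from the configured Beta spectrum,
#' re-drawn until they clear the 1% benign threshold.
#'
#' @param config A [simulation_config()].
#' @param model Entry of [default_model_map()] (default: the `orf` model).
#' @return List with `dataset` (a `benchmark_dataset`), `scores`
#'   (data.frame from [effect_score_table()]), `track`
#'   (a `conservation_track`), `census` (the synthetic census table) and
#'   `benign` (a `variant_table`).
#' @export
simulate_benchmark <- function(config = simulation_config(),
                               model = default_model_map()$orf) {
  with_seed(config$seed, {
    side <- model$side
    all_mech <- if (side == "utr5") .MECHANISMS_UTR5 else .MECHANISMS_UTR3
    matched_pool <- intersect(model$mechanisms, all_mech)
    mismatched_pool <- setdiff(all_mech, matched_pool)
    n_matched <- config$n_plp %/% 2L + config$n_plp %% 2L
    n_mismatched <- config$n_plp %/% 2L
    mech <- c(sample(matched_pool, n_matched, replace = TRUE),
              sample(mismatched_pool, n_mismatched, replace = TRUE))

    star <- if (side == "utr3") "*" else "-"
    plp_pos <- 1000L + 10L * seq_len(config$n_plp)
    census <- data.frame(
      hgvs = sprintf("NMSYN%04d.1:c.%s%dA>G", seq_len(config$n_plp), star,
                     seq_len(config$n_plp) + 10L),
      gene = sprintf("GENE%03d", seq_len(config$n_plp)),
      utr_side = side,
      clinvar_class = "P", study_class = "P", mechanism = mech,
      functional_evidence = NA_character_, stringsAsFactors = FALSE)
    census <- validate_census(census)

    benign <- if (config$n_benign > 0L) {
      af <- vapply(seq_len(config$n_benign), function(i) {
        repeat {
          x <- rbeta(1, config$af_shape1, config$af_shape2)
          if (x > 0.01) return(x)
        }
      }, numeric(1))
      ben_pos <- 100000L + 10L * seq_len(config$n_benign)
      do.call(bind_variant_tables,
              lapply(seq_len(config$n_benign), function(i)
                variant_record("chr1", ben_pos[i], "A", "C",
                               af_total = af[i])))
    } else empty_variant_table()

    dataset <- assign_groups(census, benign, model)

    eff_loc <- ifelse(dataset$group == "plp_matched",
                      config$matched_effect_size,
                      ifelse(dataset$group == "plp_mismatched",
                             config$mismatched_effect_size, 0))
    sign <- sample(c(-1, 1), nrow(dataset), replace = TRUE)
    raw <- sign * eff_loc + rnorm(nrow(dataset), 0, config$benign_effect_sd)
    scores <- data.frame(variant_key = dataset$key, model = model$model,
                         raw = raw, abs = abs(raw),
                         stringsAsFactors = FALSE)

    pos_all <- c(plp_pos, if (config$n_benign > 0L)
      100000L + 10L * seq_len(config$n_benign))
    cons <- c(rnorm(config$n_plp, config$conservation_shift, 1),
              rnorm(config$n_benign, 0, 1))
    track <- conservation_track(data.frame(
      chrom = "chr1", start = pos_all, end = pos_all, score = cons,
      stringsAsFactors = FALSE))

    list(dataset = dataset, scores = scores, track = track,
         census = census, benign = benign, plp_positions = plp_pos,
         benign_positions = if (config$n_benign > 0L)
           100000L + 10L * seq_len(config$n_benign) else integer(0),
         config = config)
  })
}
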