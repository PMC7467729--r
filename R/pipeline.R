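# End-to-end orchestration: simulate isolates -> map -> depth -> junctions ->
# segments -> classification -> spectrum and rate statistics.

#' Run the full caller on one sample
#'
#' Maps a read set against the reference, computes depth profiles, detects
#' and assembles discordant junction clusters and telomere-addition
#' junctions, validates them against span depth, segments copy number, and
#' classifies the GCR (with resolution class for foldback inversions).
#'
#' @param reference the reference `toy_genome`.
#' @param reads a `read_set` (typically simulated from a rearranged genome).
#' @param insert_mean,insert_sd fragment-size model (defaults from the
#'   reference's config).
#' @param min_support,alpha junction validation parameters (see
#'   [filter_junctions()]).
#' @param min_segment segmentation resolution (bp).
#' @return a list: `alignments`, `depths`, `genome_median`, `clusters`,
#'   `junctions`, `segments`, `classification` (with `$resolution` when
#'   applicable).
#' @export
call_gcr_sample <- function(reference, reads,
                            insert_mean = NULL, insert_sd = NULL,
                            min_support = 3L, alpha = 0.2,
                            min_segment = 200L) {
  cfg <- reference$config
  if (is.null(insert_mean)) insert_mean <- cfg$insert_mean
  if (is.null(insert_sd)) insert_sd <- cfg$insert_sd

  aln <- map_reads(reference, reads)
  depths <- compute_depths(aln, reference, insert_mean, insert_sd)
  all_rd <- unlist(lapply(depths, function(x) x$read_depth))
  genome_median <- stats::median(all_rd)

  clusters <- detect_discordant_clusters(aln, insert_mean, insert_sd)
  calls <- empty_telomere_calls()
  if (nrow(clusters) > 0L) {
    calls <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
      assemble_junction(clusters[i, ], aln, reads, reference, insert_mean)
    }))
  }
  tel_calls <- detect_telomere_junctions(aln, reads, reference, insert_mean,
                                         min_support = min_support)
  calls <- rbind(calls, tel_calls)
  calls <- filter_junctions(calls, depths, min_support = min_support,
                            alpha = alpha)

  segments <- lapply(depths, function(x) {
    segment_copy_number(x$read_depth, genome_median,
                        min_segment = min_segment)
  })
  classification <- classify_gcr(calls, segments, reference$features,
                                 reference, min_segment = min_segment)
  if (classification$event_type == "foldback_inversion") {
    classification$resolution <- classify_resolution(
      classification, calls, segments, reference$features,
      pad = insert_mean
    )
  }
  list(
    alignments = aln, depths = depths, genome_median = genome_median,
    clusters = clusters, junctions = calls, segments = segments,
    classification = classification
  )
}

#' Simulate one GCR isolate
#'
#' Applies the requested event to a fresh copy of the reference genome and
#' simulates reads from the rearranged genome.
#'
#' @param reference the reference `toy_genome`.
#' @param event_type `"foldback_inversion"`, `"telomere_addition"`,
#'   `"mh_translocation"`, `"interstitial_deletion"` or `"none"`.
#' @param seed read-simulation seed for this isolate.
#' @param site_index which planted hairpin site to use (foldbacks).
#' @param secondary secondary resolution for foldbacks.
#' @param mh_len planted microhomology for translocations/deletions.
#' @return list with `reads`, `truth` (NULL for "none") and the rearranged
#'   `genome`.
#' @export
simulate_isolate <- function(reference, event_type, seed,
                             site_index = 1L,
                             secondary = "ssa_capture",
                             mh_len = 5L) {
  cfg <- reference$config
  if (event_type == "none") {
    reads <- simulate_reads(reference, seed = seed)
    return(list(reads = reads, truth = NULL, genome = reference))
  }
  if (event_type == "foldback_inversion") {
    hp <- reference$features[reference$features$kind == "hairpin_site", ]
    site <- hp[((site_index - 1L) %% nrow(hp)) + 1L, ]
    ev <- apply_foldback_inversion(
      reference, site,
      resection_start = site$end + 500L,
      secondary = secondary
    )
  } else if (event_type == "telomere_addition") {
    bp <- cfg$breakpoint_region[1] +
      (cfg$breakpoint_region[2] - cfg$breakpoint_region[1]) %/% 2L
    ev <- apply_simple_gcr(reference, "telomere_addition", breakpoint = bp)
  } else if (event_type == "mh_translocation") {
    bp <- cfg$breakpoint_region[1] + 2000L
    ev <- apply_simple_gcr(reference, "mh_translocation", breakpoint = bp,
                           mh_len = mh_len)
  } else if (event_type == "interstitial_deletion") {
    bp <- cfg$breakpoint_region[1] + 1000L
    ev <- apply_simple_gcr(reference, "interstitial_deletion",
                           breakpoint = bp, mh_len = mh_len)
  } else {
    stop("unknown event type: ", event_type)
  }
  reads <- simulate_reads(ev$genome, seed = seed)
  list(reads = reads, truth = ev$truth, genome = ev$genome)
}

#' Run the full pipeline over a batch of simulated isolates
#'
#' Simulates a batch of GCR isolates (a mixture of event types at configured
#' proportions), runs the caller on each, and aggregates: the classified
#' spectrum, a truth-versus-called confusion matrix, loop-size summaries for
#' called foldbacks, and (if fluctuation parameters are given) a subtype
#' rate with propagated confidence intervals.
#'
#' @param config a [sim_config()]; `config$master_seed` drives everything.
#' @param n_isolates number of isolates in the batch.
#' @param event_mix named numeric vector of event-type proportions (must sum
#'   to 1); the default mirrors a hairpin-surveillance-deficient spectrum,
#'   19 foldbacks in 20 GCRs.
#' @param fluctuation optional list with `m` (expected mutations per
#'   culture), `n_cultures`, `n_cells` for the rate arm of the report.
#' @param out_dir optional run directory: per-stage TSV/JSON outputs and a
#'   manifest with file digests are written there.
#' @return a list of class `foldback_run`: `spectrum`, `confusion`,
#'   `isolates` (per-isolate truth/called records), `loop_summary`,
#'   `rates` (or NULL), `manifest`.
#' @export
run_end_to_end <- function(config, n_isolates = 20L,
                           event_mix = c(foldback_inversion = 0.95,
                                         telomere_addition = 0.05),
                           fluctuation = list(m = 2, n_cultures = 50,
                                              n_cells = 1e9),
                           out_dir = NULL) {
  stopifnot(abs(sum(event_mix) - 1) < 1e-8)
  reference <- build_toy_genome(config)
  set.seed(substream_seed(config$master_seed, "events"))
  types <- sample(names(event_mix), n_isolates, replace = TRUE,
                  prob = event_mix)
  secondaries <- c("ssa_capture", "homology_translocation",
                   "telomere_addition")

  records <- vector("list", n_isolates)
  classifications <- vector("list", n_isolates)
  for (i in seq_len(n_isolates)) {
    iso_seed <- (substream_seed(config$master_seed, "reads") + i * 131L) %%
      2147483629
    iso <- simulate_isolate(
      reference, types[i], seed = iso_seed, site_index = i,
      secondary = secondaries[((i - 1L) %% 3L) + 1L]
    )
    res <- call_gcr_sample(reference, iso$reads)
    cls <- res$classification
    classifications[[i]] <- cls
    records[[i]] <- data.frame(
      isolate = i,
      truth_type = if (is.null(iso$truth)) "none" else iso$truth$event_type,
      called_type = cls$event_type,
      truth_secondary = if (is.null(iso$truth)) NA_character_
                        else iso$truth$secondary_resolution,
      called_resolution = if (!is.null(cls$resolution)) cls$resolution
                          else NA_character_,
      called_loop = if (!is.null(cls$hairpin)) cls$hairpin$loop_len
                    else NA_integer_,
      called_stem = if (!is.null(cls$hairpin)) cls$hairpin$stem_len
                    else NA_integer_,
      n_junctions = sum(res$junctions$validated)
    )
  }
  records <- do.call(rbind, records)
  spectrum <- spectrum_table(classifications)
  confusion <- table(truth = records$truth_type, called = records$called_type)

  loop_summary <- NULL
  fb <- records[records$called_type == "foldback_inversion" &
                  !is.na(records$called_loop), , drop = FALSE]
  if (nrow(fb) > 0L) {
    infs <- data.frame(chrom = "chr1", pos_a = fb$isolate, pos_b = fb$isolate,
                       loop_len = fb$called_loop)
    loop_summary <- loop_size_summary(infs, mode = "per_event")
  }

  rates <- NULL
  if (!is.null(fluctuation)) {
    counts <- simulate_fluctuation_experiment(
      fluctuation$m, fluctuation$n_cultures,
      seed = substream_seed(config$master_seed, "fluctuation")
    )
    rate <- estimate_rate(counts, n_cells = fluctuation$n_cells)
    k <- sum(records$called_type == "foldback_inversion")
    prop <- bootstrap_proportion_ci(
      k, n_isolates, seed = substream_seed(config$master_seed, "bootstrap")
    )
    subtype <- propagate_subtype_rate(rate, prop)
    rates <- list(rate = rate, proportion = prop, subtype = subtype)
  }

  manifest <- list(
    tool = "foldbackr",
    version = as.character(utils::packageVersion("foldbackr")),
    master_seed = config$master_seed,
    n_isolates = n_isolates,
    event_mix = as.list(event_mix),
    digests = NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(reference, file.path(out_dir, "reference.fa"),
                 file.path(out_dir, "features.bed"))
    utils::write.table(records, file.path(out_dir, "isolates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(confusion),
                       file.path(out_dir, "confusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(
      spectrum = as.list(spectrum$foldback_vs_other),
      event_counts = as.list(spectrum$event_counts),
      rates = if (!is.null(rates)) list(
        r = rates$rate$r, r_lo = rates$rate$r_lo, r_hi = rates$rate$r_hi,
        p = rates$proportion$p, p_lo = rates$proportion$p_lo,
        p_hi = rates$proportion$p_hi,
        q = rates$subtype$q, q_lo = rates$subtype$q_lo,
        q_hi = rates$subtype$q_hi
      ) else NULL
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$digests <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out <- list(
    spectrum = spectrum, confusion = confusion, isolates = records,
    loop_summary = loop_summary, rates = rates, manifest = manifest
  )
  class(out) <- "foldback_run"
  out
}
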