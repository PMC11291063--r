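## End-to-end pipeline: simulate -> score -> fit -> classify -> summarize.

#' Generate a synthetic reference protein and CDS
#'
#' Random amino-acid sequence with one random codon per residue, sized
#' like the study system by default: a 593-residue full-length construct
#' containing a contiguous 289-residue catalytic-domain window.
#'
#' @param length Protein length (residues).
#' @param ptp_start First residue of the PTP window, or `NULL` for no PTP
#'   window. The window length is `ptp_length`.
#' @param ptp_length PTP window length (default 289).
#' @param name Reference name.
#' @param seed Integer seed.
#' @return A [protein_reference()].
#' @export
synthetic_reference <- function(length = 593L, ptp_start = 247L,
                                ptp_length = 289L, name = "toy_shp2",
                                seed = 1L) {
  set.seed(seed)
  aa <- sample(aa_alphabet(), length, replace = TRUE)
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(aa, function(a) {
    hits <- names(gc)[gc == a]
    hits[sample.int(length(hits), 1L)]
  }, character(1), USE.NAMES = FALSE)
  ptp_range <- NULL
  if (!is.null(ptp_start)) {
    ptp_range <- c(ptp_start, ptp_start + ptp_length - 1L)
  }
  protein_reference(name, paste(codons, collapse = ""), ptp_range = ptp_range)
}

#' Default pipeline configuration
#'
#' Nested list of all stage parameters. Values mirror the study
#' conditions: a 593-residue full-length construct with a 289-residue
#' catalytic-domain window, 42-codon tiles (15 + 7), the full-length
#' selection paired with the weak kinase (`cSrc_KD`) and the isolated
#' domain with the strong kinase (`vSrc_FL`), 3 replicates at 1e5 reads
#' per tile and timepoint, and a 24-hour outgrowth.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @return Nested configuration list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    reference = list(length = 593L, ptp_start = 247L, ptp_length = 289L,
                     name = "toy_shp2"),
    landscape = list(class_fractions = as.list(default_class_fractions()),
                     phi_wt = 0.05, include_stop = FALSE),
    tiles = list(max_tile_codons = 42L),
    selection = list(
      FL = list(kinase = "cSrc_KD", depth = 1e5, n_replicates = 3L),
      PTP = list(kinase = "vSrc_FL", depth = 1e5, n_replicates = 3L)
    ),
    scoring = list(pseudocount = 0.5, min_reads = 10, min_pearson_r = 0.6),
    fits = list(fl_components = 1L, ptp_components = 2L, z = 2),
    annotations = list(enabled = TRUE)
  ), class = "run_config")
}

## Reject unknown keys (recursively) against the default config shape.
validate_config <- function(config, template = pipeline_config()) {
  check <- function(cfg, tpl, path = "config") {
    extra <- setdiff(names(cfg), names(tpl))
    if (length(extra) > 0L) {
      stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]]))) {
        check(cfg[[nm]], tpl[[nm]], paste0(path, "$", nm))
      }
    }
  }
  check(config, template)
  merged <- utils::modifyList(unclass(template), unclass(config))
  class(merged) <- "run_config"
  merged
}

#' Load / save a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected at load time.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_run_config`: a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic-scan pipeline
#'
#' Executes, in order: simulate (both constructs), score, fit, classify,
#' summarize; writes every stage artifact plus a manifest (seeds, stage
#' row counts, file MD5 hashes) under `outdir`. Re-running with the same
#' configuration and seed reproduces byte-identical score tables.
#'
#' @param config A [pipeline_config()] list (possibly partial - missing
#'   entries take defaults), or a YAML path.
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results
#'   (`ref`, `gt`, `scores_fl`, `scores_ptp`, `fit_fl`, `fit_ptp`,
#'   `regions`, `funnel`, `groups`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  seed <- config$seed

  ## stage 1: simulate --------------------------------------------------
  rc <- config$reference
  ref <- synthetic_reference(rc$length, rc$ptp_start, rc$ptp_length,
                             rc$name, seed = seed)
  lc <- config$landscape
  gt <- plant_landscape(ref,
                        class_fractions = unlist(lc$class_fractions),
                        phi_wt = lc$phi_wt,
                        include_stop = lc$include_stop,
                        seed = seed + 1L)
  sims <- list()
  for (construct in c("FL", "PTP")) {
    sc <- config$selection[[construct]]
    cfg <- selection_config(kinase = sc$kinase, depth_pre = sc$depth,
                            depth_post = sc$depth,
                            n_replicates = sc$n_replicates,
                            seed = seed + 2L)
    rng <- construct_range(ref, construct)
    tiles <- tile_sequence(rng[2] - rng[1] + 1L,
                           config$tiles$max_tile_codons)
    sims[[construct]] <- simulate_selection(gt, ref, construct, cfg,
                                            tiles = tiles)
    write_count_table(sims[[construct]]$counts,
                      file.path(outdir, paste0("counts_", construct, ".tsv")))
    write_tile_table(tiles,
                     file.path(outdir, paste0("tiles_", construct, ".tsv")))
  }
  utils::write.table(sims$FL$truth, file.path(outdir, "truth_sidecar.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$simulate <- list(
    n_variants = nrow(gt),
    n_count_rows = vapply(sims, function(s) nrow(s$counts), numeric(1))
  )

  ## stage 2: score -----------------------------------------------------
  sco <- config$scoring
  scores <- list()
  for (construct in c("FL", "PTP")) {
    rep_scores <- enrichment_scores(sims[[construct]]$counts,
                                    pseudocount = sco$pseudocount,
                                    min_reads = sco$min_reads)
    qc <- replicate_qc(rep_scores, min_pearson_r = sco$min_pearson_r)
    scores[[construct]] <- average_scores(rep_scores, retained = qc$retained)
    write_score_table(scores[[construct]],
                      file.path(outdir, paste0("scores_", construct, ".tsv")))
  }
  manifest$stages$score <- list(
    n_scored = vapply(scores, nrow, numeric(1))
  )

  ## stage 3: fit -------------------------------------------------------
  fit_fl <- fit_score_distribution(scores$FL$score,
                                   n_components = config$fits$fl_components,
                                   z = config$fits$z, seed = seed + 3L)
  fit_ptp <- fit_score_distribution(scores$PTP$score,
                                    n_components = config$fits$ptp_components,
                                    z = config$fits$z, seed = seed + 4L)
  fits_out <- lapply(list(FL = fit_fl, PTP = fit_ptp), function(f) {
    f$loglik_trace <- NULL
    unclass(f)
  })
  jsonlite::write_json(fits_out, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$fit <- list(
    fl_sd_wt = fit_fl$sd[fit_fl$wt_component],
    ptp_sd_wt = fit_ptp$sd[fit_ptp$wt_component]
  )

  ## stage 4: classify --------------------------------------------------
  fl_called <- significance_calls(scores$FL, fit_fl)
  ptp_called <- significance_calls(scores$PTP, fit_ptp)
  shared <- intersect(fl_called$variant_id, ptp_called$variant_id)
  regions <- classify_regions(
    fl_called$call[match(shared, fl_called$variant_id)],
    ptp_called$call[match(shared, ptp_called$variant_id)],
    variant_id = shared
  )
  utils::write.table(regions, file.path(outdir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- NULL
  if (isTRUE(config$annotations$enabled)) {
    ann <- emit_annotations(gt, seed = seed + 5L)
    utils::write.csv(ann, file.path(outdir, "annotations.csv"),
                     row.names = FALSE)
  }
  funnel <- funnel_table(scores$FL, scores$PTP, regions, ann)
  utils::write.csv(funnel, file.path(outdir, "funnel.csv"), row.names = FALSE)
  manifest$stages$classify <- list(
    n_shared = nrow(funnel),
    region_counts = as.list(table(regions$region))
  )

  ## stage 5: summarize -------------------------------------------------
  groups <- NULL
  if (!is.null(ann)) {
    groups <- group_summaries(scores$FL, ann)
    utils::write.table(groups, file.path(outdir, "group_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sites <- site_summary(scores$FL)
  utils::write.table(sites, file.path(outdir, "site_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$summarize <- list(
    n_sites = nrow(sites),
    n_groups = if (is.null(groups)) 0L else nrow(groups)
  )

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$hashes <- as.list(tools::md5sum(files))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(ref = ref, gt = gt, sims = sims,
                 scores_fl = scores$FL, scores_ptp = scores$PTP,
                 fit_fl = fit_fl, fit_ptp = fit_ptp,
                 regions = regions, funnel = funnel, groups = groups,
                 manifest = manifest))
}
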