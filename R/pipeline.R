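stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the screen analysis pipeline end to end
#'
#' Stage order: simulate (optional) -> aggregate/QC -> normalise ->
#' call-hits -> fingerprint. Every stage writes its table under
#' `config$paths$out_dir` as delimited text; when `resume = TRUE` a stage
#' whose output file already exists is reloaded instead of recomputed, so
#' deleting intermediates and re-running reproduces identical final
#' tables for a fixed seed. The run manifest records the config hash,
#' per-output checksums, package version, timestamps and every threshold
#' applied.
#'
#' @param config a [runConfig()]
#' @param resume reload existing stage outputs instead of recomputing
#' @return list: `manifest`, `wfs` (normalised [WellFeatureSet-class]),
#'   `hits`, `exclusions`, `fingerprint` ([FingerprintMatrix-class]),
#'   `clustering`
#' @export
runPipeline <- function(config = runConfig(), resume = FALSE) {
  dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$paths$out_dir, f)
  cfg_path <- out("config.yaml")
  writeRunConfig(config, cfg_path)
  seed <- config$master_seed
  scheme <- compartmentScheme(config$scheme$perinuclear_max,
                              config$scheme$intermediate_max)
  log <- c(sprintf("cargoHCS %s", as.character(packageVersion("cargoHCS"))),
           sprintf("start %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  # --- simulate / ingest -----------------------------------------------
  raw_path <- out("wells_raw.csv")
  wfs <- stage_run("simulate", {
    if (resume && file.exists(raw_path)) readWellTable(raw_path)
    else if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      genes <- sprintf("gene_%04d", seq_len(sim$n_genes))
      lay <- generatePlateLayout(sim$n_plates, genes,
                                 controls = unlist(sim$controls), seed = seed)
      w <- simulateScreen(lay, seed = seed, n_cells_mean = sim$n_cells_mean,
                          scheme = scheme,
                          min_cells = config$normalise$min_cells)
      writeWellTable(w, raw_path)
      w
    } else {
      if (is.null(config$paths$well_table))
        stop("simulate disabled and no well_table path given")
      readWellTable(config$paths$well_table)
    }
  })
  log <- c(log, sprintf("wells: %d (%d qc-pass, min_cells=%d)",
                        ncol(wfs), sum(qcPass(wfs), na.rm = TRUE),
                        config$normalise$min_cells))

  # --- normalise --------------------------------------------------------
  wfs <- stage_run("normalise", {
    w <- normaliseWells(wfs, method = "rZ",
                        min_ntc = config$normalise$min_ntc)
    writeWellTable(w, out("wells_rz.csv"), assay_name = "rZ")
    qcrep <- plateQuality(w)
    write.csv(qcrep, out("plate_quality.csv"), row.names = FALSE)
    w
  })

  # --- call hits --------------------------------------------------------
  policy <- hitPolicy(metric_set = config$hit$metrics,
                      k_sd = config$hit$k_sd, mode = config$hit$mode)
  hits_res <- stage_run("call-hits", {
    pe <- poolEffects(wfs, assay_name = "rZ")
    pf <- prefilterGenes(pe$effects, wfs, policy)
    ch <- callHits(pe$effects[pf$retained, , drop = FALSE], wfs, policy)
    write.csv(ch$table, out("hits_by_metric.csv"), row.names = FALSE)
    write.csv(ch$hits, out("hits.csv"), row.names = FALSE)
    write.csv(pf$ledger, out("exclusions.csv"), row.names = FALSE)
    list(hits = ch, prefilter = pf, effects = pe)
  })
  log <- c(log, sprintf("hit thresholds: k_sd=%.2f (%s mode) on %s",
                        policy$k_sd, policy$mode,
                        paste(policy$metric_set, collapse = ",")),
           sprintf("prefilter: %d of %d genes excluded",
                   sum(hits_res$prefilter$ledger$excluded),
                   nrow(hits_res$prefilter$ledger)))

  # --- fingerprint ------------------------------------------------------
  fpc <- config$fingerprint
  fng <- stage_run("fingerprint", {
    fp <- aggregatePoolProfiles(wfs)
    ctrl <- t(assay(wfs, "rZ")[, wellRoles(wfs) == "positive_control" &
                                 !is.na(qcPass(wfs)) & qcPass(wfs),
                               drop = FALSE])
    fp <- filterVariableFeatures(fp, ctrl, sd_threshold = fpc$sd_threshold)
    fp <- filterRedundantFeatures(fp, r2_threshold = fpc$r2_threshold)
    fp <- scale01(fp)
    cl <- hierarchicalCluster(fp, k = fpc$k_cut, linkage = fpc$linkage)
    write.csv(data.frame(pool = rownames(poolProfiles(fp)),
                         poolProfiles(fp), check.names = FALSE),
              out("fingerprints.csv"), row.names = FALSE)
    write.csv(featureLedger(fp), out("feature_ledger.csv"), row.names = FALSE)
    write.csv(cl$merges, out("linkage.csv"), row.names = FALSE)
    writeLines(hclustToNewick(cl$hclust), out("dendrogram.nwk"))
    list(fp = fp, clustering = cl)
  })
  log <- c(log, sprintf(
    "fingerprint filters: sd>=%.1f variable, R2>=%.2f redundant; %d features kept",
    fpc$sd_threshold, fpc$r2_threshold, ncol(poolProfiles(fng$fp))))

  # --- manifest ---------------------------------------------------------
  outputs <- list.files(config$paths$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, out("manifest.yaml"))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    version = as.character(packageVersion("cargoHCS")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    checksums = as.list(tools::md5sum(sort(outputs))),
    log = log)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  writeLines(log, out("run.log"))
  list(manifest = manifest, wfs = wfs, hits = hits_res$hits$hits,
       hit_table = hits_res$hits$table, thresholds = hits_res$hits$thresholds,
       exclusions = hits_res$prefilter$ledger, fingerprint = fng$fp,
       clustering = fng$clustering)
}
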