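#' Read a well-level feature table
#'
#' Delimited text, one row per well: mandatory columns `plate_id`, `well`,
#' `pool_id`, `role`, optional `n_cells`, `n_viable`, `qc_pass`, and any
#' number of numeric feature columns. The delimiter is auto-detected
#' (comma or tab); unknown roles are rejected.
#'
#' @param path file path
#' @return a [WellFeatureSet-class]
#' @export
readWellTable <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c("plate_id", "well", "pool_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("well table schema error; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$role), WELL_ROLES)
  if (length(bad))
    stop("unknown well roles: ", paste(bad, collapse = ", "), call. = FALSE)
  meta_cols <- intersect(c(need, "n_cells", "n_viable", "qc_pass"), names(df))
  feat_cols <- setdiff(names(df), meta_cols)
  feat_cols <- feat_cols[vapply(df[feat_cols], is.numeric, logical(1))]
  vals <- t(as.matrix(df[, feat_cols, drop = FALSE]))
  WellFeatureSet(vals, df[, meta_cols, drop = FALSE])
}

#' Write a well-level feature table
#'
#' Inverse of [readWellTable()]: one row per well, metadata columns then
#' features. Numeric values are written with 17 significant digits so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param wfs a [WellFeatureSet-class]
#' @param path output file
#' @param assay_name assay to write
#' @param sep field delimiter (`","` or `"\t"`)
#' @return `path`, invisibly
#' @export
writeWellTable <- function(wfs, path, assay_name = "values", sep = ",") {
  cd <- as.data.frame(colData(wfs))
  meta_cols <- intersect(c("plate_id", "well", "pool_id", "role",
                           "n_cells", "n_viable", "qc_pass"), names(cd))
  vals <- t(assay(wfs, assay_name))
  out <- cbind(cd[, meta_cols, drop = FALSE], as.data.frame(vals))
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, formatC(v, digits = 17, format = "g")))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' Default run configuration
#'
#' One schema with one source of truth for every tunable the pipeline
#' uses; fully serialisable to YAML with [writeRunConfig()]. Any subset
#' can be overridden via `...` (named sub-lists are merged).
#'
#' @param ... overrides, e.g. `hit = list(k_sd = 2.5)`
#' @return nested `RunConfig` list
#' @export
runConfig <- function(...) {
  cfg <- list(
    master_seed = 1L,
    simulate = list(enabled = TRUE, n_plates = 1L, n_genes = 300L,
                    controls = list(NTC = 38L, positive = 13L, editing = 2L),
                    n_cells_mean = 260),
    geometry = list(pixel_size = 0.6, width = 1080L, height = 1080L),
    scheme = list(perinuclear_max = 7, intermediate_max = 14,
                  two_ring = TRUE),
    normalise = list(min_cells = 100L, min_ntc = 8L, anchor = -100,
                     min_window = 0.1),
    hit = list(k_sd = 2, mode = "primary",
               metrics = c("loc_ratio_PEX", "loc_ratio_EEA1",
                           "loc_ratio_TGN")),
    fingerprint = list(sd_threshold = 3, r2_threshold = 0.8,
                       linkage = "complete", distance = "correlation",
                       umap_neighbors = 15, umap_min_dist = 0.1, k_cut = 6L),
    paths = list(out_dir = "cargoHCS_run", well_table = NULL))
  mods <- list(...)
  for (nm in names(mods)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(mods[[nm]]))
      modifyList(cfg[[nm]], mods[[nm]]) else mods[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' Serialise / restore a run configuration
#'
#' @param config a [runConfig()]
#' @param path YAML file path
#' @return `readRunConfig`: the restored `RunConfig`;
#'   `writeRunConfig`: `path`, invisibly
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}
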