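#' Valid well roles
#'
#' Roles a well can carry on a screening plate: library (one crRNA pool per
#' gene), NTC (non-targeting control, the neutral reference), positive
#' control (strong dispersion phenotype, e.g. a crLIS1-like pool), editing
#' control (viability readout, e.g. a crPLK1-like pool) and empty.
#'
#' @export
WELL_ROLES <- c("library", "NTC", "positive_control", "editing_control", "empty")

#' WellFeatureSet: wells-by-features container for screen data
#'
#' A \linkS4class{SummarizedExperiment} subclass holding well-level screen
#' data: assays are features (rows) by wells (columns); `colData` carries the
#' plate map (`plate_id`, `well`, `pool_id`, `role`) plus per-well QC counts
#' (`n_cells`, `n_viable`, `qc_pass`). The raw per-well feature means live in
#' assay `"values"`; normalisation adds assays such as `"rZ"` and
#' `"two_point"`.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @seealso [WellFeatureSet()], [normaliseWells()], [aggregateWells()]
#' @name WellFeatureSet-class
#' @exportClass WellFeatureSet
setClass("WellFeatureSet", contains = "SummarizedExperiment")

setValidity("WellFeatureSet", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("plate_id", "well", "pool_id", "role")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  if ("role" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$role)), WELL_ROLES)
    if (length(bad))
      msg <- c(msg, paste0("unknown well roles: ", paste(bad, collapse = ", ")))
  }
  if (!"values" %in% assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a WellFeatureSet
#'
#' @param values numeric matrix, features in rows, wells in columns. Row
#'   names are feature names; column names are unique well keys.
#' @param wellData data.frame or DataFrame with one row per well (column of
#'   `values`) carrying at least `plate_id`, `well`, `pool_id`, `role`.
#'   `n_cells`, `n_viable` and `qc_pass` are added (as `NA`) if absent.
#' @param metadata optional list stored as object metadata.
#' @return a [WellFeatureSet-class]
#' @examples
#' v <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
#' wd <- data.frame(plate_id = "P1", well = c("A01", "A02", "A03"),
#'                  pool_id = c("NTC", "g1", "g2"),
#'                  role = c("NTC", "library", "library"))
#' WellFeatureSet(v, wd)
#' @export
WellFeatureSet <- function(values, wellData, metadata = list()) {
  values <- as.matrix(values)
  wellData <- as(wellData, "DataFrame")
  for (col in c("n_cells", "n_viable")) {
    if (!col %in% colnames(wellData)) wellData[[col]] <- NA_integer_
  }
  if (!"qc_pass" %in% colnames(wellData)) wellData$qc_pass <- NA
  if (is.null(colnames(values)))
    colnames(values) <- paste(wellData$plate_id, wellData$well, sep = ":")
  rownames(wellData) <- colnames(values)
  new("WellFeatureSet",
      SummarizedExperiment(assays = list(values = values), colData = wellData,
                           metadata = metadata))
}

#' @describeIn WellFeatureSet well roles as a character vector
#' @param x a WellFeatureSet
#' @export
wellRoles <- function(x) as.character(colData(x)$role)

#' @describeIn WellFeatureSet crRNA pool (gene) ids per well
#' @export
poolIds <- function(x) as.character(colData(x)$pool_id)

#' @describeIn WellFeatureSet plate ids per well
#' @export
plateIds <- function(x) as.character(colData(x)$plate_id)

#' @describeIn WellFeatureSet logical QC flag per well (`NA` if not set)
#' @export
qcPass <- function(x) as.logical(colData(x)$qc_pass)

#' @describeIn WellFeatureSet feature matrix for one assay (default the raw
#'   `"values"`)
#' @param assay_name assay to extract
#' @export
featureValues <- function(x, assay_name = "values") assay(x, assay_name)

setMethod("show", "WellFeatureSet", function(object) {
  cat("WellFeatureSet:", nrow(object), "features x", ncol(object), "wells\n")
  cat("  plates:", paste(unique(plateIds(object)), collapse = ", "), "\n")
  tab <- table(wellRoles(object))
  cat("  roles: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  qc <- qcPass(object)
  if (!all(is.na(qc)))
    cat("  qc_pass:", sum(qc, na.rm = TRUE), "of", length(qc), "wells\n")
})

#' FingerprintMatrix: reduced phenotypic profiles per crRNA pool
#'
#' Holds the pool-by-feature matrix used for phenotypic fingerprinting along
#' with its provenance: the per-feature keep/drop ledger written by the
#' variability and redundancy filters, the per-feature min/max used for 0-1
#' scaling, and optional ground-truth group labels (from the simulator).
#'
#' @slot profiles numeric matrix, pools in rows, retained features in columns
#' @slot ledger data.frame, one row per *input* feature: `feature`,
#'   `status` (kept/variable/redundant), `detail`
#' @slot scaling data.frame with per-retained-feature `min`, `max`,
#'   `constant` (logical); zero rows until [scale01()] has run
#' @slot scaled logical, whether `profiles` is on the 0-1 scale
#' @slot truth optional character vector of ground-truth group labels per
#'   pool (`NA` for null pools), zero-length when unknown
#' @seealso [aggregatePoolProfiles()], [filterVariableFeatures()],
#'   [filterRedundantFeatures()], [scale01()], [hierarchicalCluster()]
#' @name FingerprintMatrix-class
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
         representation(profiles = "matrix", ledger = "data.frame",
                        scaling = "data.frame", scaled = "logical",
                        truth = "character"))

setValidity("FingerprintMatrix", function(object) {
  msg <- character()
  p <- object@profiles
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "profiles must have pool row names and feature column names")
  if (anyNA(p)) msg <- c(msg, "profiles must not contain missing values")
  if (nrow(object@ledger) &&
      !all(colnames(p) %in% object@ledger$feature))
    msg <- c(msg, "every retained feature must appear in the ledger")
  if (isTRUE(object@scaled) &&
      (min(p) < -1e-9 || max(p) > 1 + 1e-9))
    msg <- c(msg, "scaled profiles must lie in [0, 1]")
  if (length(object@truth) && length(object@truth) != nrow(p))
    msg <- c(msg, "truth labels must align with pools")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param profiles pools-by-features numeric matrix (dimnames required)
#' @param ledger per-feature keep/drop ledger (defaults to all-kept)
#' @param truth optional ground-truth group labels per pool (NA = null pool)
#' @return a [FingerprintMatrix-class]
#' @export
FingerprintMatrix <- function(profiles, ledger = NULL, truth = character()) {
  profiles <- as.matrix(profiles)
  if (is.null(ledger))
    ledger <- data.frame(feature = colnames(profiles), status = "kept",
                         detail = "", stringsAsFactors = FALSE)
  new("FingerprintMatrix", profiles = profiles, ledger = ledger,
      scaling = data.frame(), scaled = FALSE,
      truth = as.character(truth))
}

#' @describeIn FingerprintMatrix the pool-by-feature profile matrix
#' @param x a FingerprintMatrix
#' @export
poolProfiles <- function(x) x@profiles

#' @describeIn FingerprintMatrix the per-feature keep/drop ledger
#' @export
featureLedger <- function(x) x@ledger

#' @describeIn FingerprintMatrix min/max scaling metadata (per retained
#'   feature) recorded by [scale01()]
#' @export
scalingInfo <- function(x) x@scaling

#' @describeIn FingerprintMatrix ground-truth group labels (zero-length when
#'   unknown)
#' @export
truthLabels <- function(x) x@truth

setMethod("show", "FingerprintMatrix", function(object) {
  p <- object@profiles
  cat("FingerprintMatrix:", nrow(p), "pools x", ncol(p), "features",
      if (object@scaled) "(0-1 scaled)" else "(unscaled)", "\n")
  if (nrow(object@ledger)) {
    tab <- table(object@ledger$status)
    cat("  feature ledger: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (length(object@truth))
    cat("  ground truth:", sum(!is.na(object@truth)), "grouped pools,",
        sum(is.na(object@truth)), "nulls\n")
})
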