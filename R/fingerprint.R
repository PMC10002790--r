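#' Aggregate well rZ profiles into per-pool fingerprints
#'
#' Median across each crRNA pool's qc-passing wells, for every feature, on
#' data already rZ-transformed per plate. Pools with no passing well are
#' dropped with a logged reason.
#'
#' @param wfs a [WellFeatureSet-class] carrying an `"rZ"` assay
#' @param roles roles to aggregate (default library pools)
#' @param assay_name assay to aggregate
#' @return a [FingerprintMatrix-class]; dropped pools in
#'   `metadata`-free attribute `attr(, "dropped")`
#' @export
aggregatePoolProfiles <- function(wfs, roles = "library", assay_name = "rZ") {
  vals <- assay(wfs, assay_name)
  sel <- wellRoles(wfs) %in% roles
  qc <- qcPass(wfs); qc[is.na(qc)] <- TRUE
  pools <- poolIds(wfs)
  ids <- unique(pools[sel])
  prof <- matrix(NA_real_, length(ids), nrow(vals),
                 dimnames = list(ids, rownames(vals)))
  dropped <- character()
  for (g in ids) {
    cols <- sel & pools == g & qc
    if (!any(cols)) { dropped <- c(dropped, g); next }
    prof[g, ] <- apply(vals[, cols, drop = FALSE], 1, median, na.rm = TRUE)
  }
  prof <- prof[!rownames(prof) %in% dropped, , drop = FALSE]
  truth <- if ("true_group" %in% colnames(colData(wfs))) {
    tg <- colData(wfs)$true_group
    as.character(tg[match(rownames(prof), pools)])
  } else character()
  fp <- FingerprintMatrix(prof, truth = truth)
  attr(fp, "dropped") <- dropped
  fp
}

ledger_update <- function(ledger, dropped, status) {
  hit <- ledger$feature %in% dropped & ledger$status == "kept"
  ledger$status[hit] <- status
  ledger
}

#' Drop features that are highly variable across scattered positive controls
#'
#' A feature is removed when the standard deviation of its rZ values
#' across the plate-scattered positive-control wells is at or above
#' `sd_threshold` (default 3): such features fluctuate for technical
#' reasons rather than biology. Idempotent.
#'
#' @param fp a [FingerprintMatrix-class]
#' @param control_profiles positive-control wells x features rZ matrix
#'   (>= `min_wells` rows), e.g. from the scattered crLIS1-like wells
#' @param sd_threshold drop threshold on the control-well S.D.
#' @param min_wells minimum scattered control wells
#' @return the filtered [FingerprintMatrix-class] (ledger updated with
#'   reason `"variable"`)
#' @export
filterVariableFeatures <- function(fp, control_profiles, sd_threshold = 3,
                                   min_wells = 8) {
  if (is.null(control_profiles) || nrow(control_profiles) < min_wells)
    stop(sprintf("need >= %d scattered control wells", min_wells),
         call. = FALSE)
  feats <- colnames(poolProfiles(fp))
  miss <- setdiff(feats, colnames(control_profiles))
  if (length(miss))
    stop("control profiles missing features: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  sds <- apply(control_profiles[, feats, drop = FALSE], 2, sd)
  drop <- feats[sds >= sd_threshold]
  fp@profiles <- fp@profiles[, setdiff(feats, drop), drop = FALSE]
  fp@ledger <- ledger_update(fp@ledger, drop, "variable")
  validObject(fp)
  fp
}

#' Drop redundant features by pairwise regression R-squared
#'
#' Redundancy is judged by simple linear regression between feature
#' columns (R^2, equal to the squared Pearson correlation). Features are
#' visited greedily in a deterministic order — descending dynamic range
#' (max - min of the profile values), ties broken by feature name — and a
#' visited feature is dropped when its R^2 against any already-kept
#' feature reaches `r2_threshold`, so exactly one representative survives
#' per fully collinear block. Idempotent, order-stable.
#'
#' @param fp a [FingerprintMatrix-class] (variability filter first)
#' @param r2_threshold drop threshold (default 0.8)
#' @return the filtered [FingerprintMatrix-class] (ledger reason
#'   `"redundant"`)
#' @export
filterRedundantFeatures <- function(fp, r2_threshold = 0.8) {
  X <- poolProfiles(fp)
  feats <- colnames(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  ord <- feats[order(-rng, feats)]
  kept <- character()
  dropped <- character()
  for (f in ord) {
    if (length(kept)) {
      r2 <- suppressWarnings(cor(X[, f], X[, kept, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      if (any(r2 >= r2_threshold)) { dropped <- c(dropped, f); next }
    }
    kept <- c(kept, f)
  }
  fp@profiles <- X[, feats[feats %in% kept], drop = FALSE]
  fp@ledger <- ledger_update(fp@ledger, dropped, "redundant")
  validObject(fp)
  fp
}

#' Min-max scale fingerprint features to [0, 1]
#'
#' Per-feature scaling `(x - min) / (max - min)`; constant features map to
#' 0.5 and are flagged in the scaling metadata. The recorded min/max allow
#' exact inversion of non-constant features.
#'
#' @param fp a [FingerprintMatrix-class]
#' @return the scaled [FingerprintMatrix-class] (`scalingInfo()` filled,
#'   `@scaled = TRUE`)
#' @export
scale01 <- function(fp) {
  X <- poolProfiles(fp)
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  const <- maxs == mins
  S <- X
  for (j in seq_len(ncol(X)))
    S[, j] <- if (const[j]) 0.5 else (X[, j] - mins[j]) / (maxs[j] - mins[j])
  fp@profiles <- S
  fp@scaling <- data.frame(feature = colnames(X), min = mins, max = maxs,
                           constant = const, row.names = NULL)
  fp@scaled <- TRUE
  validObject(fp)
  fp
}

#' Correlation distance between pool profiles
#'
#' `d(i, j) = 1 - Pearson(profile_i, profile_j)`; pools with zero profile
#' variance have undefined correlations and must be excluded first.
#'
#' @param X pools x features matrix
#' @return a `dist` object
#' @export
correlationDistance <- function(X) {
  as.dist(1 - cor(t(X)))
}

#' Hierarchically cluster pool fingerprints
#'
#' Agglomerative clustering of pools with complete linkage on the
#' correlation distance (1 - Pearson between profiles). Pools whose
#' profile has zero variance are flagged and excluded (their correlation
#' is undefined). Flat labels are produced at a requested cluster count
#' and/or cut height.
#'
#' @param fp a [FingerprintMatrix-class] (typically after [scale01()])
#' @param k requested number of flat clusters (optional)
#' @param h cut height (optional alternative)
#' @param linkage linkage criterion for [stats::hclust()]
#' @return list: `hclust` (the merge tree), `labels` (flat labels when
#'   `k`/`h` given), `merges` (data.frame left/right/height/size),
#'   `excluded` (zero-variance pools), `truth` (pass-through ground-truth
#'   labels for retained pools)
#' @export
hierarchicalCluster <- function(fp, k = NULL, h = NULL, linkage = "complete") {
  X <- poolProfiles(fp)
  v <- apply(X, 1, var)
  excluded <- rownames(X)[v == 0 | is.na(v)]
  keep <- setdiff(rownames(X), excluded)
  if (length(keep) < 2) stop("need >= 2 pools with variance", call. = FALSE)
  Xk <- X[keep, , drop = FALSE]
  hc <- hclust(correlationDistance(Xk), method = linkage)
  labels <- NULL
  if (!is.null(k) || !is.null(h))
    labels <- cutree(hc, k = k, h = h)
  m <- hc$merge
  sizes <- integer(nrow(m))
  csize <- function(i) if (i < 0) 1L else sizes[i]
  for (r in seq_len(nrow(m)))
    sizes[r] <- csize(m[r, 1]) + csize(m[r, 2])
  truth <- truthLabels(fp)
  if (length(truth)) truth <- setNames(truth, rownames(X))[keep]
  list(hclust = hc, labels = labels,
       merges = data.frame(left = m[, 1], right = m[, 2],
                           height = hc$height, size = sizes),
       excluded = excluded, truth = truth)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object
#' @return single Newick string with branch lengths from merge heights
#' @export
hclustToNewick <- function(hc) {
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  rec <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_h))
    h <- hc$height[i]
    sprintf("(%s,%s):%g", rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
            parent_h - h)
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  sprintf("(%s,%s);", rec(hc$merge[n, 1], h), rec(hc$merge[n, 2], h))
}

#' UMAP embedding of pool fingerprints
#'
#' Two-dimensional Uniform Manifold Approximation and Projection of the
#' scaled profiles, for visualisation only — never for hit calling.
#' Deterministic given `seed` (single SGD thread).
#'
#' @param fp a [FingerprintMatrix-class] or plain pools x features matrix
#' @param n_neighbors,min_dist UMAP hyper-parameters
#' @param seed integer seed
#' @return pools x 2 coordinate matrix
#' @export
umapEmbed <- function(fp, n_neighbors = 15, min_dist = 0.1, seed = 1) {
  X <- if (is(fp, "FingerprintMatrix")) poolProfiles(fp) else as.matrix(fp)
  if (nrow(X) < n_neighbors + 1)
    stop(sprintf("need >= n_neighbors + 1 = %d pools", n_neighbors + 1),
         call. = FALSE)
  set.seed(seed)
  co <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                   n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  rownames(co) <- rownames(X)
  colnames(co) <- c("UMAP1", "UMAP2")
  co
}

#' Cluster-recovery diagnostics against ground-truth groups
#'
#' Adjusted Rand index (pair counting) between predicted flat labels and
#' ground-truth group labels, plus per-group purity (largest fraction of a
#' true group captured by a single predicted cluster). Pools with `NA`
#' truth (null pools without a planted group) are excluded from both
#' statistics.
#'
#' @param flat_labels predicted cluster labels (named or aligned)
#' @param truth_labels ground-truth group labels, `NA` for null pools
#' @return list: `ari`, `purity` (named per true group), `n_evaluated`
#' @export
evaluateRecovery <- function(flat_labels, truth_labels) {
  if (length(flat_labels) != length(truth_labels))
    stop("label vectors must align on pools", call. = FALSE)
  ok <- !is.na(truth_labels)
  fl <- flat_labels[ok]; tr <- truth_labels[ok]
  purity <- vapply(split(fl, tr),
                   function(v) max(table(v)) / length(v), numeric(1))
  list(ari = adjustedRandIndex(fl, tr), purity = purity,
       n_evaluated = sum(ok))
}
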