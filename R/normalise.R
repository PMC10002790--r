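#' Robust Z-score against NTC wells
#'
#' `rZ(x) = (x - median(NTC)) / (1.4826 * MAD(NTC))`, the one-point plate
#' normalisation with the non-targeting control as central reference. The
#' MAD is the median absolute deviation from the NTC median; the 1.4826
#' factor makes it consistent with the Gaussian S.D. If the MAD is zero
#' the NTC sample S.D. is used instead; if that is also zero the endpoint
#' is degenerate and all scores are `NA` (with attribute
#' `degenerate = TRUE`).
#'
#' @param values numeric vector of per-well values to normalise
#' @param ntc_values numeric vector of NTC well values (non-empty)
#' @param mad_constant scale factor for the MAD (default Gaussian 1.4826)
#' @return rZ scores, same length as `values`
#' @examples
#' robustZ(c(3, 4), c(1, 2, 3, 4, 5))   # 0 and ~0.674
#' @export
robustZ <- function(values, ntc_values, mad_constant = 1.4826) {
  ntc_values <- ntc_values[!is.na(ntc_values)]
  if (!length(ntc_values))
    stop("no NTC values supplied for robust-Z normalisation", call. = FALSE)
  ctr <- median(ntc_values)
  scl <- mad_constant * median(abs(ntc_values - ctr))
  if (scl == 0) scl <- sd(ntc_values)
  if (is.na(scl) || scl == 0) {
    out <- rep(NA_real_, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - ctr) / scl
}

#' Two-point control-anchored normalisation
#'
#' Affine map sending the NTC median to 0 and the positive-control median
#' to `positive_anchor` (default -100, the inhibition anchor), so library
#' wells are expressed as a percentage of the control window.
#'
#' @param values per-well values
#' @param ntc_values NTC well values (non-empty)
#' @param positive_values positive-control well values (non-empty)
#' @param positive_anchor score of the positive-control median
#' @return normalised scores
#' @examples
#' twoPointNormalise(7.5, ntc_values = c(10, 10), positive_values = c(5, 5))
#' @export
twoPointNormalise <- function(values, ntc_values, positive_values,
                              positive_anchor = -100) {
  ntc_values <- ntc_values[!is.na(ntc_values)]
  positive_values <- positive_values[!is.na(positive_values)]
  if (!length(ntc_values) || !length(positive_values))
    stop("both control sets must be non-empty", call. = FALSE)
  m0 <- median(ntc_values); m1 <- median(positive_values)
  if (m0 == m1)
    stop("degenerate control window: equal control medians", call. = FALSE)
  (values - m0) / (m1 - m0) * positive_anchor
}

#' Robust Z-prime assay window
#'
#' `rZ' = 1 - 3 * (1.4826*MAD(pos) + 1.4826*MAD(ntc)) / |median(pos) -
#' median(ntc)|` — the classical Z-prime with robust plug-ins. Values near
#' 1 indicate a wide assay window; <= 0 an unusable one. Equal control
#' medians give no window: `NA` with attribute `undefined = TRUE`.
#'
#' @param ntc_values neutral-control well values (>= `min_wells`)
#' @param positive_values positive-control well values (>= `min_wells`)
#' @param min_wells minimum replicates per control group
#' @param mad_constant MAD scale factor
#' @return rZ' (<= 1) or `NA` (undefined window)
#' @examples
#' robustZPrime(rnorm(10), rnorm(10, 10))
#' @export
robustZPrime <- function(ntc_values, positive_values, min_wells = 4,
                         mad_constant = 1.4826) {
  ntc_values <- ntc_values[!is.na(ntc_values)]
  positive_values <- positive_values[!is.na(positive_values)]
  if (length(ntc_values) < min_wells || length(positive_values) < min_wells)
    stop(sprintf("insufficient control replicates (need >= %d per group)",
                 min_wells), call. = FALSE)
  m0 <- median(ntc_values); m1 <- median(positive_values)
  if (m0 == m1) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  s0 <- mad_constant * median(abs(ntc_values - m0))
  s1 <- mad_constant * median(abs(positive_values - m1))
  1 - 3 * (s1 + s0) / abs(m1 - m0)
}

#' Aggregate per-cell measurements into well summaries
#'
#' Per-well mean of every per-cell metric over viable, non-boundary cells,
#' with the minimum-cell QC rule: wells with fewer analysed cells than
#' `min_cells` are flagged `qc_pass = FALSE` and their metrics withheld as
#' `NA` (missing, not zero).
#'
#' @param cell_table data.frame with `plate_id`, `well`, optional `viable`
#'   and `boundary_cell` flags, and numeric metric columns
#' @param layout plate map ([generatePlateLayout()]) providing `pool_id`
#'   and `role` per well
#' @param min_cells QC threshold on analysed cells per well
#' @param metrics metric columns (default: all numeric columns except ids)
#' @return a [WellFeatureSet-class]
#' @export
aggregateWells <- function(cell_table, layout, min_cells = 100,
                           metrics = NULL) {
  ct <- as.data.frame(cell_table)
  if (!all(c("plate_id", "well") %in% names(ct)))
    stop("cell_table needs plate_id and well columns", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- names(ct)[vapply(ct, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("cell_id", "x_px", "y_px"))
  }
  viable <- if ("viable" %in% names(ct)) ct$viable else TRUE
  boundary <- if ("boundary_cell" %in% names(ct)) ct$boundary_cell else FALSE
  key <- paste(ct$plate_id, ct$well, sep = ":")
  use <- viable & !boundary
  wells <- unique(key)
  vals <- matrix(NA_real_, length(metrics), length(wells),
                 dimnames = list(metrics, wells))
  n_cells <- as.integer(table(factor(key, levels = wells)))
  n_viable <- as.integer(table(factor(key[use], levels = wells)))
  for (m in metrics)
    vals[m, ] <- vapply(wells, function(w) {
      v <- ct[[m]][use & key == w]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
  qc <- n_viable >= min_cells
  vals[, !qc] <- NA_real_
  lk <- paste(layout$plate_id, layout$well, sep = ":")
  idx <- match(wells, lk)
  wd <- data.frame(plate_id = sub(":.*", "", wells),
                   well = sub(".*:", "", wells),
                   pool_id = layout$pool_id[idx], role = layout$role[idx],
                   n_cells = n_cells, n_viable = n_viable, qc_pass = qc,
                   stringsAsFactors = FALSE)
  WellFeatureSet(vals, wd, metadata = list(min_cells = min_cells))
}

#' Normalise well-level features against plate controls
#'
#' Adds a normalised assay to a [WellFeatureSet-class]: per plate (controls
#' are on every plate precisely because plate effects exist) and per
#' feature, either the one-point robust Z against that plate's QC-passing
#' NTC wells or the two-point control-anchored score. Cross-plate pooling
#' of controls is available behind `per_plate = FALSE`.
#'
#' @param wfs a [WellFeatureSet-class]
#' @param method `"rZ"` (one-point) or `"two_point"`
#' @param min_ntc minimum QC-passing NTC wells per plate
#' @param positive_anchor anchor for two-point mode
#' @param per_plate use only same-plate controls (default) or pool plates
#' @return `wfs` with the new assay (named as `method`)
#' @export
normaliseWells <- function(wfs, method = c("rZ", "two_point"), min_ntc = 8,
                           positive_anchor = -100, per_plate = TRUE) {
  method <- match.arg(method)
  vals <- assay(wfs, "values")
  roles <- wellRoles(wfs)
  qc <- qcPass(wfs); qc[is.na(qc)] <- TRUE
  plates <- if (per_plate) plateIds(wfs) else rep("all", ncol(wfs))
  out <- vals * NA_real_
  for (p in unique(plates)) {
    sel <- plates == p
    ntc <- sel & roles == "NTC" & qc
    pos <- sel & roles == "positive_control" & qc
    if (sum(ntc) < min_ntc)
      stop(sprintf("plate %s has %d QC-passing NTC wells (need >= %d)",
                   p, sum(ntc), min_ntc), call. = FALSE)
    for (f in rownames(vals)) {
      out[f, sel] <- if (method == "rZ")
        robustZ(vals[f, sel], vals[f, ntc])
      else
        twoPointNormalise(vals[f, sel], vals[f, ntc], vals[f, pos],
                          positive_anchor = positive_anchor)
    }
  }
  assays(wfs)[[method]] <- out
  wfs
}

#' @importFrom SummarizedExperiment `assays<-`
NULL

#' Per-plate robust Z-prime QC report
#'
#' Computes the rZ' assay window between NTC and positive-control wells
#' for every feature on every plate.
#'
#' @param wfs a [WellFeatureSet-class]
#' @param assay_name assay to evaluate (raw `"values"` by default)
#' @param min_wells minimum control replicates per group
#' @return data.frame `plate_id`, `feature`, `rz_prime`, `n_ntc`, `n_pos`
#' @export
plateQuality <- function(wfs, assay_name = "values", min_wells = 4) {
  vals <- assay(wfs, assay_name)
  roles <- wellRoles(wfs)
  qc <- qcPass(wfs); qc[is.na(qc)] <- TRUE
  plates <- plateIds(wfs)
  res <- list()
  for (p in unique(plates)) {
    ntc <- vals[, plates == p & roles == "NTC" & qc, drop = FALSE]
    pos <- vals[, plates == p & roles == "positive_control" & qc, drop = FALSE]
    for (f in rownames(vals)) {
      rz <- tryCatch(robustZPrime(ntc[f, ], pos[f, ], min_wells = min_wells),
                     error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(
        plate_id = p, feature = f, rz_prime = as.numeric(rz),
        n_ntc = sum(!is.na(ntc[f, ])), n_pos = sum(!is.na(pos[f, ])))
    }
  }
  do.call(rbind, res)
}

# Ledoit-Wolf / Schafer-Strimmer style shrinkage of a covariance matrix
# toward its diagonal, intensity estimated from the variance of the
# empirical covariances
shrink_cov <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  if (p == 1 || n < 4) return(S)
  varS <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    w <- Xc[, i] * Xc[, j]
    varS[i, j] <- n / ((n - 1)^3) * sum((w - mean(w))^2)
  }
  off <- !diag(p)
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(varS[off]) / denom)) else 1
  Sh <- S
  Sh[off] <- (1 - lambda) * S[off]
  attr(Sh, "lambda") <- lambda
  Sh
}

#' LDA composite endpoint from multiple features
#'
#' Combines individual features into a single linear-discriminant
#' endpoint separating NTC from positive-control wells, as done when no
#' single feature suffices. Features are first filtered by their own
#' control-separation window (rZ' >= `min_window`), standardised on the
#' control wells, and a Fisher discriminant with shrinkage-regularised
#' within-class covariance is fitted on the controls; all wells are then
#' projected, with the sign oriented so the NTC median exceeds the
#' positive-control median. The composite is itself a metric, suitable
#' for [robustZ()].
#'
#' @param feature_matrix wells x features numeric matrix
#' @param labels per-well labels: `"NTC"`, `"positive"`, anything else is
#'   projected but not fitted
#' @param min_window per-feature rZ' threshold for inclusion
#' @param filter `"window"` (rZ' between controls, default) or
#'   `"mean_rz"` (mean |rZ| of the positive controls on the NTC scale)
#' @return list: `scores` (per well), `weights` (per passing feature),
#'   `passing` (feature names), `windows` (per-feature filter statistic),
#'   `shrinkage` (estimated intensity)
#' @export
ldaComposite <- function(feature_matrix, labels, min_window = 0.1,
                         filter = c("window", "mean_rz")) {
  filter <- match.arg(filter)
  X <- as.matrix(feature_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  ntc <- labels == "NTC"; pos <- labels == "positive"
  if (sum(ntc) < 4 || sum(pos) < 4)
    stop("need >= 4 control wells per group", call. = FALSE)
  win <- vapply(seq_len(ncol(X)), function(j) {
    if (filter == "window")
      as.numeric(tryCatch(robustZPrime(X[ntc, j], X[pos, j]),
                          error = function(e) NA_real_))
    else mean(abs(robustZ(X[pos, j], X[ntc, j])))
  }, numeric(1))
  names(win) <- colnames(X)
  passing <- colnames(X)[!is.na(win) & win >= min_window]
  if (length(passing) < 2)
    stop(paste0("fewer than 2 features pass the control-window filter; ",
                "windows: ",
                paste(sprintf("%s=%.3f", names(win), win), collapse = ", ")),
         call. = FALSE)
  ctrl <- ntc | pos
  mu <- colMeans(X[ctrl, passing, drop = FALSE])
  sg <- apply(X[ctrl, passing, drop = FALSE], 2, sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X[, passing, drop = FALSE], 2, mu), 2, sg, "/")
  Zc <- rbind(scale(Z[ntc, , drop = FALSE], scale = FALSE),
              scale(Z[pos, , drop = FALSE], scale = FALSE))
  Sw <- shrink_cov(Zc)
  dmu <- colMeans(Z[ntc, , drop = FALSE]) - colMeans(Z[pos, , drop = FALSE])
  w <- solve(Sw, dmu)
  scores <- drop(Z %*% w)
  if (median(scores[ntc]) < median(scores[pos])) { w <- -w; scores <- -scores }
  list(scores = scores, weights = w, passing = passing, windows = win,
       shrinkage = attr(Sw, "lambda"))
}
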