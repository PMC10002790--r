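#' Ring compartment scheme around the nucleus
#'
#' Cargo puncta are classified by their distance to the nuclear envelope:
#' perinuclear (distance <= `perinuclear_max`, boundary inclusive),
#' intermediate (up to `intermediate_max`) and outer. Two-ring mode merges
#' intermediate and outer into a single peripheral region. The 7 um and
#' 14 um defaults follow the ring cutoffs used for cargo localisation
#' endpoints; distances are measured from the envelope, not the centroid,
#' and spots inside the nucleus carry distance <= 0 (perinuclear).
#'
#' @param perinuclear_max um, outer limit of the perinuclear ring
#' @param intermediate_max um, outer limit of the intermediate ring
#' @return a `CompartmentScheme` list
#' @export
compartmentScheme <- function(perinuclear_max = 7, intermediate_max = 14) {
  if (!(perinuclear_max > 0 && perinuclear_max < intermediate_max))
    stop("need 0 < perinuclear_max < intermediate_max", call. = FALSE)
  structure(list(perinuclear_max = perinuclear_max,
                 intermediate_max = intermediate_max),
            class = "CompartmentScheme")
}

norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian smoothing, Otsu threshold on the normalised image, hole
#' filling, connected-component labelling, and a minimum-area filter.
#' Per-nucleus area, perimeter and roundness (`4*pi*A/P^2`) are reported
#' in microns using the pixel size; nuclei touching the image border are
#' flagged `boundary_cell` and should be excluded downstream.
#'
#' @param img single-channel 2D numeric matrix
#' @param pixel_size um per pixel
#' @param min_area_um2 smallest object kept as a primary nucleus
#' @param smooth_sigma_um Gaussian pre-smoothing sigma
#' @param threshold optional absolute intensity threshold; default Otsu
#' @return list: `labels` (integer label matrix) and `cells` (data.frame:
#'   `cell_id`, `x_px`, `y_px`, `nucleus_area`, `perimeter_um`,
#'   `nucleus_roundness`, `dna_mean`, `dna_intensity` (integrated),
#'   `boundary_cell`). A blank image yields zero nuclei.
#' @export
segmentNuclei <- function(img, pixel_size = 0.6, min_area_um2 = 30,
                          smooth_sigma_um = 1, threshold = NULL) {
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                cells = data.frame(cell_id = integer(), x_px = numeric(),
                                   y_px = numeric(), nucleus_area = numeric(),
                                   perimeter_um = numeric(),
                                   nucleus_roundness = numeric(),
                                   dna_mean = numeric(), dna_intensity = numeric(),
                                   boundary_cell = logical()))
  if (diff(range(img)) == 0) return(empty)
  sm <- EBImage::gblur(img, sigma = max(smooth_sigma_um / pixel_size, 0.5))
  if (is.null(threshold)) {
    nm <- norm01(sm)
    thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
    mask <- nm > thr
  } else mask <- sm > threshold
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(shp) || nrow(shp) == 0) return(empty)
  keep <- which(shp[, "s.area"] * pixel_size^2 >= min_area_um2)
  if (!length(keep)) return(empty)
  lab <- EBImage::rmObjects(lab, setdiff(seq_len(nrow(shp)), keep),
                            reenumerate = TRUE)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab, ref = norm01(img))
  n <- nrow(shp)
  border <- vapply(seq_len(n), function(i) {
    any(lab[1, ] == i) || any(lab[nrow(lab), ] == i) ||
      any(lab[, 1] == i) || any(lab[, ncol(lab)] == i)
  }, logical(1))
  sums <- rowsum(as.numeric(img[lab > 0]), lab[lab > 0])
  area_px <- shp[, "s.area"]
  cells <- data.frame(
    cell_id = seq_len(n),
    x_px = mom[, "m.cx"], y_px = mom[, "m.cy"],
    nucleus_area = area_px * pixel_size^2,
    perimeter_um = shp[, "s.perimeter"] * pixel_size,
    nucleus_roundness = pmin(1, 4 * pi * area_px / pmax(shp[, "s.perimeter"], 1)^2),
    dna_mean = sums[, 1] / area_px,
    dna_intensity = sums[, 1],
    boundary_cell = border)
  rownames(cells) <- NULL
  list(labels = lab, cells = cells)
}

# Euclidean distance (px) of every pixel to the region where sel is TRUE
dist_to_region <- function(sel) {
  d <- EBImage::distmap(EBImage::Image(1 - sel))
  matrix(as.numeric(EBImage::imageData(d)), nrow(sel), ncol(sel))
}

#' Segment cytoplasm by nearest-nucleus assignment over the foreground
#'
#' Above-background pixels (Otsu on the diffuse channel, or an explicit
#' threshold) are assigned to the nearest retained nucleus by exact
#' Euclidean distance transforms, producing one cytoplasm region per
#' nucleus; regions partition the foreground (no pixel belongs to two
#' cells). When the foreground is blank the fallback is the nucleus
#' dilated by a minimum rim.
#'
#' @param img cytoplasm reference channel (diffuse DNA or tubulin)
#' @param nuclei result of [segmentNuclei()]
#' @param pixel_size um per pixel
#' @param threshold optional absolute threshold; default Otsu on the
#'   smoothed image
#' @param min_rim_um fallback rim width when no foreground is found
#' @return list: `labels` (cell label matrix, same ids as nuclei) and
#'   `zero_cyto` (ids of cells whose cytoplasm does not extend beyond the
#'   nucleus)
#' @export
segmentCytoplasm <- function(img, nuclei, pixel_size = 0.6, threshold = NULL,
                             min_rim_um = 2) {
  lab <- nuclei$labels
  ids <- nuclei$cells$cell_id
  if (!length(ids))
    return(list(labels = matrix(0L, nrow(lab), ncol(lab)),
                zero_cyto = integer()))
  sm <- EBImage::gblur(img, sigma = max(1 / pixel_size, 0.5))
  if (is.null(threshold)) {
    nm <- norm01(sm)
    thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
    fg <- nm > thr
  } else fg <- sm > threshold
  fg <- fg | lab > 0
  if (sum(fg) <= sum(lab > 0)) {
    # blank foreground: nucleus dilated by the minimum rim
    rim <- min_rim_um / pixel_size
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (i in ids) {
      d <- dist_to_region(lab == i)
      out[d <= rim & out == 0L] <- i
    }
    out[lab > 0] <- lab[lab > 0]
    return(list(labels = out, zero_cyto = ids))
  }
  best_d <- matrix(Inf, nrow(lab), ncol(lab))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in ids) {
    d <- dist_to_region(lab == i)
    upd <- fg & (d < best_d)
    out[upd] <- i
    best_d[upd] <- d[upd]
  }
  cyto_area <- table(factor(out[out > 0 & lab == 0], levels = ids))
  list(labels = out, zero_cyto = ids[cyto_area == 0])
}

# strict-ish local maxima: >= all 8 neighbours (ties on plateaus collapse
# to the first index by the subsequent > threshold test on response)
local_maxima <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  res <- matrix(TRUE, nx, ny)
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    res <- res & m >= pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  }
  res
}

#' Detect fluorescent puncta with a difference-of-Gaussians filter
#'
#' Band-pass response `gblur(sigma) - gblur(2*sigma)`; candidate spots are
#' local maxima of the response above a robust per-cell background
#' threshold (median + `k_mad` * 1.4826 * MAD of the response inside the
#' cell; global when no masks are given). Centroids are refined to
#' sub-pixel precision by intensity-weighted averaging of the 3x3 response
#' patch, and each spot is assigned to the cell whose mask contains it.
#'
#' Partially overlapping puncta (closer than about twice the filter sigma)
#' merge into a single response maximum; a greedy deflation pass
#' (`deflation_rounds > 0`) subtracts a Gaussian of the detected amplitude
#' at each accepted peak and re-runs detection on the residual, recovering
#' the fainter partner of close pairs.
#'
#' @param img single-channel matrix
#' @param cell_masks optional cell label matrix (e.g. from
#'   [segmentCytoplasm()]); `NULL` for global detection
#' @param spot_sigma_um expected punctum sigma in um (> 0)
#' @param pixel_size um per pixel
#' @param k_mad robust threshold multiplier
#' @param deflation_rounds extra detection passes on the
#'   Gaussian-subtracted residual (0 disables)
#' @return data.frame: `x`, `y` (sub-pixel, pixel units), `cell_id` (0 =
#'   outside any cell), `intensity` (image value at the peak), `response`
#'   (DoG value at the peak)
#' @export
detectSpots <- function(img, cell_masks = NULL, spot_sigma_um = 0.8,
                        pixel_size = 0.6, k_mad = 5, deflation_rounds = 1) {
  if (spot_sigma_um <= 0) stop("spot_sigma_um must be > 0", call. = FALSE)
  s <- spot_sigma_um / pixel_size
  out <- detect_spots_once(img, cell_masks, s, k_mad)
  if (deflation_rounds > 0 && nrow(out)) {
    bg <- median(img)
    res <- img
    r <- ceiling(3 * s)
    for (round in seq_len(deflation_rounds)) {
      for (i in seq_len(nrow(out))) {   # in-place Gaussian subtraction
        xs <- max(1, floor(out$x[i]) - r):min(nrow(res), floor(out$x[i]) + r + 1)
        ys <- max(1, floor(out$y[i]) - r):min(ncol(res), floor(out$y[i]) + r + 1)
        res[xs, ys] <- res[xs, ys] - (out$intensity[i] - bg) *
          outer(exp(-(xs - out$x[i])^2 / (2 * s^2)),
                exp(-(ys - out$y[i])^2 / (2 * s^2)))
      }
      extra <- detect_spots_once(res, cell_masks, s, k_mad)
      if (!nrow(extra)) break
      # keep only residual peaks not explained by an accepted spot and
      # comparable in strength to real first-pass detections (subtraction
      # residuals are a small fraction of the parent response)
      dmin <- vapply(seq_len(nrow(extra)), function(i)
        min((extra$x[i] - out$x)^2 + (extra$y[i] - out$y)^2), numeric(1))
      extra <- extra[dmin > (1.5)^2 &
                       extra$response >= 0.3 * min(out$response), ,
                     drop = FALSE]
      if (!nrow(extra)) break
      extra$intensity <- img[cbind(pmin(pmax(round(extra$x), 1), nrow(img)),
                                   pmin(pmax(round(extra$y), 1), ncol(img)))]
      out <- rbind(out, extra)
    }
  }
  rownames(out) <- NULL
  out
}

detect_spots_once <- function(img, cell_masks, s, k_mad) {
  dog <- EBImage::gblur(img, sigma = s) - EBImage::gblur(img, sigma = 2 * s)
  dog <- matrix(as.numeric(dog), nrow(img), ncol(img))
  mx <- local_maxima(dog)
  cand <- which(mx, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(x = numeric(), y = numeric(), cell_id = integer(),
                      intensity = numeric(), response = numeric()))
  resp <- dog[cand]
  if (is.null(cell_masks)) {
    thr <- median(dog) + k_mad * mad(dog)
    ok <- resp > thr & resp > 0
    cid <- rep(0L, nrow(cand))
  } else {
    cid <- cell_masks[cand]
    thr_by <- vapply(split(as.numeric(dog), as.integer(cell_masks)),
                     function(v) median(v) + k_mad * mad(v), numeric(1))
    thr <- thr_by[as.character(cid)]
    thr[is.na(thr)] <- Inf
    ok <- resp > thr & resp > 0 & cid > 0
  }
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(x = numeric(), y = numeric(), cell_id = integer(),
                      intensity = numeric(), response = numeric()))
  cid <- cid[ok]; resp <- resp[ok]
  # sub-pixel refinement on the 3x3 response patch (clipped at zero)
  xr <- yr <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    x0 <- cand[i, 1]; y0 <- cand[i, 2]
    xs <- max(1, x0 - 1):min(nrow(img), x0 + 1)
    ys <- max(1, y0 - 1):min(ncol(img), y0 + 1)
    w <- pmax(dog[xs, ys, drop = FALSE], 0)
    if (sum(w) == 0) { xr[i] <- x0; yr[i] <- y0; next }
    xr[i] <- sum(outer(xs, rep(1, length(ys))) * w) / sum(w)
    yr[i] <- sum(outer(rep(1, length(xs)), ys) * w) / sum(w)
  }
  out <- data.frame(x = xr, y = yr, cell_id = as.integer(cid),
                    intensity = img[cand], response = resp)
  # response plateaus (peaks centred between pixels) produce coincident
  # maxima: keep the strongest of any candidates closer than 1.2 px
  if (nrow(out) > 1) {
    ord <- order(-out$response)
    keep <- logical(nrow(out))
    for (i in ord) {
      if (any(keep & (out$x - out$x[i])^2 + (out$y - out$y[i])^2 < 1.2^2))
        next
      keep[i] <- TRUE
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Assign spots to ring compartments by envelope distance
#'
#' The distance of each spot to the nuclear envelope of its own cell is
#' computed from exact Euclidean distance transforms: positive outside the
#' nucleus, negative inside (distance to the nearest background pixel,
#' negated). Compartments follow [compartmentScheme()] with the inner
#' boundary inclusive: `d <= perinuclear_max` is perinuclear. Spots whose
#' position falls outside their cell mask are flagged `excluded`.
#'
#' @param spots data.frame from [detectSpots()] (needs `x`, `y`,
#'   `cell_id`); cell ids must match nucleus labels
#' @param nuclei result of [segmentNuclei()] (label matrix used)
#' @param cell_masks optional cell label matrix for the exclusion flag
#' @param pixel_size um per pixel
#' @param scheme a [compartmentScheme()]
#' @param two_ring merge intermediate and outer into `"peripheral"`
#' @return `spots` with `envelope_distance` (um), `compartment`, `excluded`
#' @export
assignCompartments <- function(spots, nuclei, cell_masks = NULL,
                               pixel_size = 0.6, scheme = compartmentScheme(),
                               two_ring = FALSE) {
  lab <- nuclei$labels
  n <- nrow(spots)
  d_um <- rep(NA_real_, n)
  excluded <- rep(FALSE, n)
  if (n) {
    xi <- pmin(pmax(round(spots$x), 1), nrow(lab))
    yi <- pmin(pmax(round(spots$y), 1), ncol(lab))
    din <- dist_to_region(lab == 0)   # distance to background, >0 inside nuclei
    for (L in unique(spots$cell_id)) {
      sel <- which(spots$cell_id == L)
      if (L <= 0) { excluded[sel] <- TRUE; next }
      dout <- dist_to_region(lab == L)
      for (s in sel) {
        at <- lab[xi[s], yi[s]]
        # inside: boundary pixels (background-adjacent) sit at 0
        d_um[s] <- if (at == L) -(din[xi[s], yi[s]] - 1) * pixel_size
                   else dout[xi[s], yi[s]] * pixel_size
      }
      if (!is.null(cell_masks))
        excluded[sel] <- excluded[sel] |
          (cell_masks[cbind(xi[sel], yi[sel])] != L & lab[cbind(xi[sel], yi[sel])] != L)
    }
  }
  comp <- rep(NA_character_, n)
  ok <- !is.na(d_um)
  comp[ok & d_um <= scheme$perinuclear_max] <- "perinuclear"
  mid <- ok & d_um > scheme$perinuclear_max & d_um <= scheme$intermediate_max
  comp[mid] <- if (two_ring) "peripheral" else "intermediate"
  far <- ok & d_um > scheme$intermediate_max
  comp[far] <- if (two_ring) "peripheral" else "outer"
  spots$envelope_distance <- d_um
  spots$compartment <- comp
  spots$excluded <- excluded
  spots
}

#' Perinuclear-to-peripheral localisation ratio
#'
#' `ratio = n_perinuclear / (n_peripheral + pseudocount)`; the pseudocount
#' (default 1) sits in the denominator only, so a cell with no spots at
#' all scores 0 and division by zero cannot occur. Lower values indicate
#' increased cargo dispersion.
#'
#' @param perinuclear,peripheral non-negative spot counts (vectorised)
#' @param pseudocount added to the denominator
#' @return numeric ratio(s)
#' @examples
#' localisationRatio(6, 2)   # 2
#' localisationRatio(0, 0)   # 0
#' @export
localisationRatio <- function(perinuclear, peripheral, pseudocount = 1) {
  perinuclear / (peripheral + pseudocount)
}

#' Per-cell, per-channel localisation ratios from compartment-labelled spots
#'
#' @param spots data.frame with `cell_id`, `channel`, `compartment` and
#'   optionally `excluded` (excluded spots are dropped)
#' @param cell_ids cells to report (default: those present in `spots`)
#' @param pseudocount see [localisationRatio()]
#' @return data.frame `cell_id`, `channel`, `n_perinuclear`,
#'   `n_peripheral`, `loc_ratio`
#' @export
cellLocalisationRatios <- function(spots, cell_ids = NULL, pseudocount = 1) {
  if ("excluded" %in% names(spots)) spots <- spots[!spots$excluded, , drop = FALSE]
  if (is.null(cell_ids)) cell_ids <- sort(unique(spots$cell_id))
  chans <- unique(as.character(spots$channel))
  if (!length(chans)) chans <- NA_character_
  grid <- expand.grid(cell_id = cell_ids, channel = chans,
                      stringsAsFactors = FALSE)
  peri <- with(spots, table(factor(cell_id[compartment == "perinuclear"],
                                   levels = cell_ids),
                            factor(channel[compartment == "perinuclear"],
                                   levels = chans)))
  tot <- with(spots, table(factor(cell_id, levels = cell_ids),
                           factor(channel, levels = chans)))
  np <- as.vector(peri[cbind(match(grid$cell_id, cell_ids),
                             match(grid$channel, chans))])
  nt <- as.vector(tot[cbind(match(grid$cell_id, cell_ids),
                            match(grid$channel, chans))])
  grid$n_perinuclear <- np
  grid$n_peripheral <- nt - np
  grid$loc_ratio <- localisationRatio(np, nt - np, pseudocount)
  grid
}

#' Gate viable cells against NTC-derived nuclear morphology bounds
#'
#' Cells are flagged non-viable when nuclear area, roundness or integrated
#' DNA intensity fall outside percentile bounds estimated from a reference
#' (NTC) cell population — the label-free apoptotic/mitotic exclusion.
#' Gating with fixed reference bounds is idempotent.
#'
#' @param cells data.frame with the gate metrics as columns
#' @param reference data.frame of NTC cells with the same columns (or a
#'   precomputed bounds matrix from a previous call, `attr "bounds"`)
#' @param probs lower/upper percentile bounds
#' @param metrics columns to gate on
#' @return `cells` with a logical `viable` column; attributes
#'   `viability_fraction` and `bounds`
#' @export
gateViable <- function(cells, reference,
                       probs = c(0.01, 0.99),
                       metrics = c("nucleus_area", "nucleus_roundness",
                                   "dna_intensity")) {
  if (is.matrix(reference)) bounds <- reference
  else {
    if (is.null(reference) || nrow(reference) == 0)
      stop("empty viability reference", call. = FALSE)
    bounds <- vapply(metrics,
                     function(m) quantile(reference[[m]], probs, na.rm = TRUE),
                     numeric(2))
    dimnames(bounds) <- list(c("lo", "hi"), metrics)
  }
  ok <- rep(TRUE, nrow(cells))
  for (m in metrics)
    ok <- ok & cells[[m]] >= bounds["lo", m] & cells[[m]] <= bounds["hi", m]
  cells$viable <- ok
  attr(cells, "viability_fraction") <- mean(ok)
  attr(cells, "bounds") <- bounds
  cells
}

#' Count MTOC-scale foci per cell
#'
#' Runs the punctum detector at the MTOC sigma on the gamma-tubulin
#' channel and reports per-cell focus counts plus the per-well category
#' fractions of cells with 0, exactly 1 and more than 1 focus.
#'
#' @param img gamma-tubulin channel
#' @param cell_masks cell label matrix
#' @param cell_ids cells to report (default: labels present in the mask)
#' @param mtoc_sigma_um focus scale (um)
#' @param pixel_size um per pixel
#' @param k_mad robust threshold multiplier passed to [detectSpots()]
#' @return list: `counts` (data.frame `cell_id`, `mtoc_count`) and
#'   `fractions` (named numeric: `none`, `one`, `multiple`)
#' @export
countMTOC <- function(img, cell_masks, cell_ids = NULL, mtoc_sigma_um = 1.2,
                      pixel_size = 0.6, k_mad = 5) {
  if (is.null(cell_ids))
    cell_ids <- sort(setdiff(unique(as.integer(cell_masks)), 0L))
  sp <- detectSpots(img, cell_masks, spot_sigma_um = mtoc_sigma_um,
                    pixel_size = pixel_size, k_mad = k_mad)
  cnt <- table(factor(sp$cell_id, levels = cell_ids))
  counts <- data.frame(cell_id = cell_ids, mtoc_count = as.integer(cnt))
  k <- counts$mtoc_count
  fr <- c(none = mean(k == 0), one = mean(k == 1), multiple = mean(k > 1))
  list(counts = counts, fractions = fr)
}

#' Detect micronuclei
#'
#' Micronuclei are DNA-positive objects inside a cell's cytoplasm that are
#' smaller than the primary-nucleus lower bound, larger than a noise
#' floor, and do not touch the primary nucleus.
#'
#' @param img DNA channel
#' @param nuclei result of [segmentNuclei()] (primary nuclei)
#' @param cell_masks cell label matrix from [segmentCytoplasm()]
#' @param pixel_size um per pixel
#' @param size_bounds_um2 `c(noise_floor, upper)` area window; the upper
#'   default is the primary-nucleus `min_area_um2` used at segmentation
#' @param min_area_um2 primary-nucleus lower bound (upper micronucleus cap)
#' @param threshold optional absolute DNA threshold (default Otsu)
#' @return data.frame `cell_id`, `micronucleus_count` (one row per cell in
#'   the mask)
#' @export
detectMicronuclei <- function(img, nuclei, cell_masks, pixel_size = 0.6,
                              min_area_um2 = 30,
                              size_bounds_um2 = c(1, min_area_um2),
                              threshold = NULL) {
  lab <- nuclei$labels
  cell_ids <- nuclei$cells$cell_id
  sm <- EBImage::gblur(img, sigma = max(0.5 / pixel_size, 0.5))
  if (is.null(threshold)) {
    nm <- norm01(sm)
    thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
    mask <- nm > thr
  } else mask <- sm > threshold
  objs <- EBImage::bwlabel(mask & lab == 0)
  shp <- EBImage::computeFeatures.shape(objs)
  counts <- setNames(rep(0L, length(cell_ids)), cell_ids)
  if (!is.null(shp) && nrow(shp)) {
    area <- shp[, "s.area"] * pixel_size^2
    ok <- which(area >= size_bounds_um2[1] & area < size_bounds_um2[2])
    if (length(ok)) {
      objm <- matrix(as.integer(EBImage::imageData(objs)), nrow(img), ncol(img))
      near <- dist_to_region(lab > 0)   # px distance to any primary nucleus
      mom <- EBImage::computeFeatures.moment(objs)
      for (o in ok) {
        pxls <- objm == o
        if (min(near[pxls]) <= 1.5) next   # touching a primary nucleus
        cx <- pmin(pmax(round(mom[o, "m.cx"]), 1), nrow(img))
        cy <- pmin(pmax(round(mom[o, "m.cy"]), 1), ncol(img))
        host <- cell_masks[cx, cy]
        if (host > 0 && as.character(host) %in% names(counts))
          counts[as.character(host)] <- counts[as.character(host)] + 1L
      }
    }
  }
  data.frame(cell_id = cell_ids, micronucleus_count = as.integer(counts))
}

cell_feature_names <- function(channels) {
  nuc <- c("nucleus_area", "nucleus_perimeter", "nucleus_roundness")
  per_ch <- function(ch) paste0(ch, "_",
    c("int_mean", "int_sd", "int_q10", "int_q50", "int_q90", "int_cv",
      "ring1_mean", "ring2_mean", "ring3_mean",
      "n_spots", "n_perinuclear", "n_intermediate", "n_outer",
      "loc_ratio", "spot_int_mean", "spot_dist_mean"))
  c(nuc, unlist(lapply(channels, per_ch)))
}

#' Extract the per-cell feature vector
#'
#' A reduced, deterministic morphological-profiling schema: nuclear
#' morphology; per-channel intensity summaries and a three-ring radial
#' intensity profile (rings at the compartment cutoffs, measured over the
#' cell's own region); and per-channel spot statistics including the
#' localisation ratio. Feature names are stable across runs; channels
#' absent from `images` yield `NA` features (never zero).
#'
#' @param images named list of channel matrices
#' @param nuclei result of [segmentNuclei()]
#' @param cell_masks cell label matrix
#' @param spots compartment-labelled spot table from
#'   [assignCompartments()] (may be empty)
#' @param channels channel order defining the schema (default: names of
#'   `images`)
#' @param pixel_size um per pixel
#' @param scheme a [compartmentScheme()] (ring radii)
#' @param pseudocount see [localisationRatio()]
#' @return data.frame, one row per cell, columns `cell_id` +
#'   `cellFeatureNames(channels)`
#' @export
extractCellFeatures <- function(images, nuclei, cell_masks, spots,
                                channels = names(images), pixel_size = 0.6,
                                scheme = compartmentScheme(), pseudocount = 1) {
  cells <- nuclei$cells
  ids <- cells$cell_id
  feat <- cell_feature_names(channels)
  out <- matrix(NA_real_, length(ids), length(feat),
                dimnames = list(NULL, feat))
  out[, "nucleus_area"] <- cells$nucleus_area
  out[, "nucleus_perimeter"] <- cells$perimeter_um
  out[, "nucleus_roundness"] <- cells$nucleus_roundness
  lab <- nuclei$labels
  din <- dist_to_region(lab == 0)
  region <- as.integer(cell_masks)
  region[lab > 0] <- lab[lab > 0]
  if (is.null(spots) || !nrow(spots))
    spots <- data.frame(cell_id = integer(), channel = character(),
                        compartment = character(), intensity = numeric(),
                        envelope_distance = numeric())
  if ("excluded" %in% names(spots))
    spots <- spots[!spots$excluded, , drop = FALSE]
  has_spots <- nrow(spots) > 0
  for (L in ids) {
    i <- match(L, ids)
    sel <- region == L
    douts <- dist_to_region(lab == L)
    d_um <- ifelse(lab == L, -(din - 1), douts) * pixel_size
    r1 <- sel & d_um <= scheme$perinuclear_max
    r2 <- sel & d_um > scheme$perinuclear_max & d_um <= scheme$intermediate_max
    r3 <- sel & d_um > scheme$intermediate_max
    for (ch in channels) {
      if (!ch %in% names(images)) next
      v <- images[[ch]][sel]
      qs <- quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
      mu <- mean(v)
      out[i, paste0(ch, "_int_mean")] <- mu
      out[i, paste0(ch, "_int_sd")] <- sd(v)
      out[i, paste0(ch, "_int_q10")] <- qs[1]
      out[i, paste0(ch, "_int_q50")] <- qs[2]
      out[i, paste0(ch, "_int_q90")] <- qs[3]
      out[i, paste0(ch, "_int_cv")] <- if (mu != 0) sd(v) / mu else NA_real_
      out[i, paste0(ch, "_ring1_mean")] <-
        if (any(r1)) mean(images[[ch]][r1]) else NA_real_
      out[i, paste0(ch, "_ring2_mean")] <-
        if (any(r2)) mean(images[[ch]][r2]) else NA_real_
      out[i, paste0(ch, "_ring3_mean")] <-
        if (any(r3)) mean(images[[ch]][r3]) else NA_real_
      sp <- if (has_spots)
        spots[spots$cell_id == L & spots$channel == ch, , drop = FALSE]
      else spots[integer(0), ]
      np <- sum(sp$compartment == "perinuclear")
      ni <- sum(sp$compartment == "intermediate")
      no <- sum(sp$compartment %in% c("outer", "peripheral"))
      out[i, paste0(ch, "_n_spots")] <- nrow(sp)
      out[i, paste0(ch, "_n_perinuclear")] <- np
      out[i, paste0(ch, "_n_intermediate")] <- ni
      out[i, paste0(ch, "_n_outer")] <- no
      out[i, paste0(ch, "_loc_ratio")] <-
        localisationRatio(np, nrow(sp) - np, pseudocount)
      out[i, paste0(ch, "_spot_int_mean")] <-
        if (nrow(sp)) mean(sp$intensity) else NA_real_
      out[i, paste0(ch, "_spot_dist_mean")] <-
        if (nrow(sp)) mean(sp$envelope_distance) else NA_real_
    }
  }
  data.frame(cell_id = ids, out, check.names = FALSE)
}

#' @rdname extractCellFeatures
#' @export
cellFeatureNames <- cell_feature_names
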