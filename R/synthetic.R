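#' Planted per-gene effect for the synthetic screen
#'
#' Describes what disrupting one gene does in the simulator: a signed
#' dispersion effect per cargo channel (negative = cargo dispersion, the
#' crLIS1-like phenotype; positive = hyper-clustering), a multiplicative
#' survival fraction, additive shifts to mean nuclear area and roundness,
#' a micronucleus induction rate, and an optional latent co-functional
#' group label used by fingerprint recovery diagnostics.
#'
#' `dispersion_delta` is expressed in units of the planted-effect slope on
#' the clustered mixture fraction (see [radialSpotModel()]); its realised
#' size in NTC well-level standard deviations depends on cell counts and
#' well noise and is measured downstream, not assumed.
#'
#' @param gene_id character label
#' @param dispersion_delta named numeric, one entry per cargo channel
#' @param viability_factor survival fraction in `[0, 1]`
#' @param nuclear_shift numeric `c(area = , roundness = )`, additive offsets
#'   to the mean nuclear area (um^2) and roundness
#' @param micronucleus_rate per-cell probability of carrying a micronucleus
#' @param group_id latent group label or `NA`
#' @return a `GeneEffect` list
#' @examples
#' geneEffect("LIS1like", dispersion_delta = c(PEX = -3, EEA1 = -2, TGN = -2),
#'            viability_factor = 0.85)
#' @export
geneEffect <- function(gene_id,
                       dispersion_delta = c(PEX = 0, EEA1 = 0, TGN = 0),
                       viability_factor = 1,
                       nuclear_shift = c(area = 0, roundness = 0),
                       micronucleus_rate = 0.05,
                       group_id = NA_character_) {
  stopifnot_finite(dispersion_delta, "dispersion_delta")
  stopifnot_finite(viability_factor, "viability_factor")
  stopifnot_finite(nuclear_shift, "nuclear_shift")
  if (viability_factor < 0 || viability_factor > 1)
    stop("viability_factor must lie in [0, 1]", call. = FALSE)
  structure(list(gene_id = gene_id,
                 dispersion_delta = dispersion_delta,
                 viability_factor = viability_factor,
                 nuclear_shift = c(area = unname(nuclear_shift["area"]),
                                   roundness = unname(nuclear_shift["roundness"])),
                 micronucleus_rate = micronucleus_rate,
                 group_id = group_id),
            class = "GeneEffect")
}

#' Radial spot distribution model
#'
#' Distances of cargo puncta from the nuclear envelope follow a
#' two-component exponential mixture: a clustered (perinuclear) component
#' with a short characteristic scale and a dispersed component with a long
#' one. A planted dispersion effect moves probability mass between the
#' components: clustered fraction
#' `p = clamp01(baseline_mix + delta_to_mix_slope * dispersion_delta)`,
#' so negative deltas disperse cargo and positive deltas hyper-cluster it.
#'
#' @param clustered_scale um, mean envelope distance of the clustered
#'   component (exponential scale)
#' @param dispersed_scale um, scale of the dispersed component
#' @param baseline_mix clustered fraction under NTC
#' @param delta_to_mix_slope change in clustered fraction per unit effect
#' @param spots_per_cell_mean Poisson mean puncta per cell per channel
#' @param intensity_meanlog,intensity_sdlog lognormal spot amplitude
#'   parameters (arbitrary units)
#' @param mix_well_sd well-to-well technical S.D. of the clustered fraction
#' @return a `RadialSpotModel` list
#' @export
radialSpotModel <- function(clustered_scale = 2, dispersed_scale = 12,
                            baseline_mix = 0.6, delta_to_mix_slope = 0.1,
                            spots_per_cell_mean = 12,
                            intensity_meanlog = 0, intensity_sdlog = 0.3,
                            mix_well_sd = 0.02) {
  if (clustered_scale <= 0 || dispersed_scale <= 0)
    stop("mixture scales must be positive", call. = FALSE)
  structure(list(clustered_scale = clustered_scale,
                 dispersed_scale = dispersed_scale,
                 baseline_mix = baseline_mix,
                 delta_to_mix_slope = delta_to_mix_slope,
                 spots_per_cell_mean = spots_per_cell_mean,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 mix_well_sd = mix_well_sd),
            class = "RadialSpotModel")
}

#' Nuclear morphology model
#'
#' Area is lognormal (median `area_median` um^2), roundness a scaled Beta
#' on (0, 1], integrated DNA intensity lognormal. These are desk-scale
#' stand-ins supporting the area/roundness/intensity endpoints, not claims
#' about U-2 OS morphology.
#'
#' @param area_median um^2; `area_sdlog` lognormal sdlog
#' @param roundness_shape1,roundness_shape2 Beta parameters (mean ~0.85)
#' @param dna_meanlog,dna_sdlog integrated DNA intensity (a.u.)
#' @param area_sdlog lognormal sdlog of nuclear area
#' @param base_viability fraction of cells surviving the apoptotic/mitotic
#'   gate under NTC conditions; a gene's `viability_factor` multiplies it
#' @return a `CellModel` list
#' @export
cellModel <- function(area_median = 170, area_sdlog = 0.25,
                      roundness_shape1 = 14, roundness_shape2 = 2.5,
                      dna_meanlog = log(1000), dna_sdlog = 0.2,
                      base_viability = 0.93) {
  structure(list(area_median = area_median, area_sdlog = area_sdlog,
                 roundness_shape1 = roundness_shape1,
                 roundness_shape2 = roundness_shape2,
                 dna_meanlog = dna_meanlog, dna_sdlog = dna_sdlog,
                 base_viability = base_viability),
            class = "CellModel")
}

#' Clustered fraction and analytic mean of the radial mixture
#'
#' @param model a [radialSpotModel()]
#' @param delta signed dispersion effect
#' @return `mixtureClusteredFraction`: clustered fraction after the effect
#'   (clamped to `[0, 1]`); `mixtureMeanDistance`: analytic mean envelope
#'   distance `p * clustered_scale + (1 - p) * dispersed_scale`.
#' @export
mixtureClusteredFraction <- function(model, delta = 0) {
  clamp01(model$baseline_mix + model$delta_to_mix_slope * delta)
}

#' @rdname mixtureClusteredFraction
#' @export
mixtureMeanDistance <- function(model, delta = 0) {
  p <- mixtureClusteredFraction(model, delta)
  p * model$clustered_scale + (1 - p) * model$dispersed_scale
}

# probability a mixture-drawn envelope distance is <= cutoff (um)
mixtureCdf <- function(model, delta, cutoff, p = NULL) {
  if (is.null(p)) p <- mixtureClusteredFraction(model, delta)
  p * (1 - exp(-cutoff / model$clustered_scale)) +
    (1 - p) * (1 - exp(-cutoff / model$dispersed_scale))
}

well_addresses <- function(n_rows = 16, n_cols = 24) {
  paste0(rep(LETTERS[seq_len(n_rows)], each = n_cols),
         sprintf("%02d", rep(seq_len(n_cols), n_rows)))
}

#' Generate arrayed screening plate layouts
#'
#' Builds 384-well (16 x 24) plate maps mirroring a genome-wide arrayed
#' screen: each plate carries a configured number of scattered NTC,
#' positive-control and editing-control wells; library genes fill the
#' remaining wells, each gene placed exactly once. Assignment (control
#' positions and the gene order) is a deterministic function of `seed`.
#'
#' @param n_plates number of plates
#' @param genes character vector of library gene / pool ids
#' @param controls named counts per plate:
#'   `c(NTC = 38, positive = 13, editing = 2)`
#' @param seed integer seed
#' @param n_rows,n_cols plate geometry (default 16 x 24 = 384)
#' @return data.frame with columns `plate_id`, `well`, `pool_id`, `role`;
#'   one row per well (unassigned wells carry role `"empty"`)
#' @examples
#' lay <- generatePlateLayout(1, character(), seed = 1)
#' table(lay$role)
#' @export
generatePlateLayout <- function(n_plates, genes,
                                controls = c(NTC = 38, positive = 13, editing = 2),
                                seed = 1, n_rows = 16, n_cols = 24) {
  controls <- controls[c("NTC", "positive", "editing")]
  controls[is.na(controls)] <- 0
  names(controls) <- c("NTC", "positive", "editing")
  if (any(controls < 0)) stop("control counts must be >= 0", call. = FALSE)
  n_wells <- n_rows * n_cols
  n_ctrl <- sum(controls)
  if (n_ctrl > n_wells)
    stop("controls exceed plate capacity", call. = FALSE)
  capacity <- n_plates * (n_wells - n_ctrl)
  if (length(genes) > capacity)
    stop(sprintf("plate capacity exceeded on plate %d: %d library genes for %d free wells",
                 n_plates, length(genes), capacity), call. = FALSE)
  set.seed(childSeed(seed, 0))
  genes <- sample(genes)
  addr <- well_addresses(n_rows, n_cols)
  out <- vector("list", n_plates)
  g0 <- 0
  for (p in seq_len(n_plates)) {
    set.seed(childSeed(seed, p))
    ctrl_pos <- sample(n_wells, n_ctrl)
    role <- rep("empty", n_wells)
    pool <- rep(NA_character_, n_wells)
    idx <- 0
    for (r in c("NTC", "positive", "editing")) {
      k <- controls[[r]]
      if (k > 0) {
        pos <- ctrl_pos[idx + seq_len(k)]
        role[pos] <- switch(r, NTC = "NTC", positive = "positive_control",
                            editing = "editing_control")
        pool[pos] <- switch(r, NTC = "NTC", positive = "crPOS", editing = "crEDIT")
        idx <- idx + k
      }
    }
    free <- which(role == "empty")
    n_take <- min(length(free), length(genes) - g0)
    if (n_take > 0) {
      pos <- free[seq_len(n_take)]
      role[pos] <- "library"
      pool[pos] <- genes[g0 + seq_len(n_take)]
      g0 <- g0 + n_take
    }
    out[[p]] <- data.frame(plate_id = sprintf("P%02d", p), well = addr,
                           pool_id = pool, role = role,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default control-well effects
#'
#' NTC pools are null; the positive control is a crLIS1-like pan-cargo
#' dispersion pool with mildly reduced viability; the editing control is a
#' crPLK1-like pool with strongly reduced viability, condensed nuclei and
#' elevated micronuclei.
#'
#' @return named list of [geneEffect()] objects for pools
#'   `NTC`, `crPOS`, `crEDIT`
#' @export
controlEffects <- function() {
  list(NTC = geneEffect("NTC"),
       crPOS = geneEffect("crPOS",
                          dispersion_delta = c(PEX = -3, EEA1 = -2.5, TGN = -2.5),
                          viability_factor = 0.85),
       crEDIT = geneEffect("crEDIT",
                           dispersion_delta = c(PEX = 0, EEA1 = 0, TGN = 0),
                           viability_factor = 0.25,
                           nuclear_shift = c(area = -60, roundness = 0.04),
                           micronucleus_rate = 0.2))
}

# vectorised per-well cell population; shared by simulateWell/simulateScreen
sim_cells <- function(effect, n_cells, cmod) {
  n_surv <- rbinom(1, n_cells, cmod$base_viability * effect$viability_factor)
  if (n_surv == 0)
    return(data.frame(cell_id = integer(), nucleus_area = numeric(),
                      nucleus_roundness = numeric(), dna_intensity = numeric(),
                      micronucleus_count = integer()))
  area_med <- max(cmod$area_median + effect$nuclear_shift[["area"]], 10)
  area <- rlnorm(n_surv, log(area_med), cmod$area_sdlog)
  rnd <- rbeta(n_surv, cmod$roundness_shape1, cmod$roundness_shape2) +
    effect$nuclear_shift[["roundness"]]
  rnd <- pmin(1, pmax(0.05, rnd))
  dna <- rlnorm(n_surv, cmod$dna_meanlog, cmod$dna_sdlog)
  mn <- rbinom(n_surv, 1, clamp01(effect$micronucleus_rate))
  data.frame(cell_id = seq_len(n_surv), nucleus_area = area,
             nucleus_roundness = rnd, dna_intensity = dna,
             micronucleus_count = mn)
}

#' Simulate one well's cell population with per-spot detail
#'
#' Survivors are Binomial(`n_cells`, `viability_factor`); each surviving
#' cell gets nuclear morphology from [cellModel()] shifted by the effect's
#' `nuclear_shift`, and per-channel puncta whose envelope distances are
#' drawn from the radial two-component mixture with the planted clustered
#' fraction.
#'
#' @param effect a [geneEffect()]
#' @param model a [radialSpotModel()]
#' @param n_cells seeded cell count (>= 1)
#' @param seed integer seed
#' @param cell_model a [cellModel()]
#' @param channels cargo channel names (default from the effect's deltas)
#' @param well_noise logical; apply the model's well-level jitter of the
#'   clustered fraction (disable to study per-cell sampling alone)
#' @return list with `cells` (one row per surviving cell) and `spots`
#'   (columns `cell_id`, `channel`, `envelope_distance`, `intensity`),
#'   plus `clustered_fraction`, the per-channel generating fractions used
#' @examples
#' w <- simulateWell(geneEffect("g"), radialSpotModel(), n_cells = 50, seed = 7)
#' head(w$spots)
#' @export
simulateWell <- function(effect, model, n_cells, seed = 1,
                         cell_model = cellModel(),
                         channels = names(effect$dispersion_delta),
                         well_noise = TRUE) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  stopifnot_finite(unlist(effect$dispersion_delta), "dispersion_delta")
  set.seed(seed)
  cells <- sim_cells(effect, n_cells, cell_model)
  n <- nrow(cells)
  pmix <- numeric(0)
  spots <- list()
  for (ch in channels) {
    delta <- effect$dispersion_delta[[ch]]
    p <- clamp01(mixtureClusteredFraction(model, delta) +
                   if (well_noise) rnorm(1, 0, model$mix_well_sd) else 0)
    pmix[ch] <- p
    if (n == 0) next
    k <- rpois(n, model$spots_per_cell_mean)
    tot <- sum(k)
    if (tot == 0) next
    clustered <- runif(tot) < p
    d <- ifelse(clustered, rexp(tot, 1 / model$clustered_scale),
                rexp(tot, 1 / model$dispersed_scale))
    spots[[ch]] <- data.frame(cell_id = rep(cells$cell_id, k), channel = ch,
                              envelope_distance = d,
                              intensity = rlnorm(tot, model$intensity_meanlog,
                                                 model$intensity_sdlog))
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(cell_id = integer(), channel = character(),
               envelope_distance = numeric(), intensity = numeric())
  rownames(spots) <- NULL
  list(cells = cells, spots = spots, clustered_fraction = pmix)
}

#' Simulate a whole arrayed screen at the well level
#'
#' Runs the per-well generative model over one or more plate layouts and
#' returns well-aggregated endpoints in a [WellFeatureSet-class]. Each well
#' gets an independent child seed derived from `seed` and its plate/well
#' index, so any single well can be re-simulated in isolation. Perinuclear
#' spot fractions are drawn by binomial thinning of the radial mixture at
#' the 7 um ring cutoff, which is distributionally identical to sampling
#' individual envelope distances and thresholding them.
#'
#' Emitted features (means over surviving cells): `loc_ratio_<ch>` and
#' `n_spots_<ch>` per cargo channel, `nucleus_area`, `nucleus_roundness`,
#' `dna_intensity`, `micronuclei_rate`, `viable_fraction`.
#'
#' @param layout plate map from [generatePlateLayout()]
#' @param effects named list of [geneEffect()] per pool id; pools absent
#'   from the list are null, control pools default to [controlEffects()]
#' @param model a [radialSpotModel()]
#' @param seed master integer seed
#' @param cell_model a [cellModel()]
#' @param n_cells_mean Poisson mean of seeded cells per well
#' @param channels cargo channel names
#' @param scheme a [compartmentScheme()]; its perinuclear cutoff defines
#'   the localisation ratio
#' @param min_cells QC threshold for `qc_pass` (analysed cells per well)
#' @return a [WellFeatureSet-class] with ground-truth columns
#'   `true_delta_<ch>`, `true_viability`, `true_group` in `colData`
#' @export
simulateScreen <- function(layout, effects = list(), model = radialSpotModel(),
                           seed = 1, cell_model = cellModel(),
                           n_cells_mean = 260,
                           channels = c("PEX", "EEA1", "TGN"),
                           scheme = compartmentScheme(), min_cells = 100) {
  effects <- modifyList(controlEffects(), effects)
  lay <- layout[layout$role != "empty", , drop = FALSE]
  plates <- unique(lay$plate_id)
  feat <- c(paste0("loc_ratio_", channels), paste0("n_spots_", channels),
            "nucleus_area", "nucleus_roundness", "dna_intensity",
            "micronuclei_rate", "viable_fraction")
  vals <- matrix(NA_real_, length(feat), nrow(lay),
                 dimnames = list(feat, NULL))
  n_cells <- n_viable <- integer(nrow(lay))
  truth <- matrix(0, nrow(lay), length(channels),
                  dimnames = list(NULL, paste0("true_delta_", channels)))
  true_via <- rep(1, nrow(lay)); true_grp <- rep(NA_character_, nrow(lay))
  cut7 <- scheme$perinuclear_max
  for (i in seq_len(nrow(lay))) {
    pid <- match(lay$plate_id[i], plates)
    widx <- match(lay$well[i], well_addresses())
    set.seed(childSeed(seed, pid, widx))
    eff <- effects[[lay$pool_id[i]]]
    if (is.null(eff)) eff <- geneEffect(lay$pool_id[i])
    n_seed <- max(1L, rpois(1, n_cells_mean))
    cells <- sim_cells(eff, n_seed, cell_model)
    n <- nrow(cells)
    n_cells[i] <- n_seed; n_viable[i] <- n
    truth[i, ] <- unlist(eff$dispersion_delta[channels])
    true_via[i] <- eff$viability_factor; true_grp[i] <- eff$group_id
    if (n == 0) next
    for (ch in channels) {
      p <- clamp01(mixtureClusteredFraction(model, eff$dispersion_delta[[ch]]) +
                     rnorm(1, 0, model$mix_well_sd))
      q7 <- mixtureCdf(model, 0, cut7, p = p)
      k <- rpois(n, model$spots_per_cell_mean)
      kin <- rbinom(n, k, q7)
      vals[paste0("loc_ratio_", ch), i] <- mean(kin / (k - kin + 1))
      vals[paste0("n_spots_", ch), i] <- mean(k)
    }
    vals["nucleus_area", i] <- mean(cells$nucleus_area)
    vals["nucleus_roundness", i] <- mean(cells$nucleus_roundness)
    vals["dna_intensity", i] <- mean(cells$dna_intensity)
    vals["micronuclei_rate", i] <- mean(cells$micronucleus_count > 0)
    vals["viable_fraction", i] <- n / n_seed
  }
  qc <- n_viable >= min_cells
  vals[, !qc] <- NA_real_  # metrics withheld for QC-failed wells
  wd <- cbind(lay, n_cells = n_cells, n_viable = n_viable, qc_pass = qc,
              as.data.frame(truth), true_viability = true_via,
              true_group = true_grp)
  WellFeatureSet(vals, wd,
                 metadata = list(seed = seed, model = model,
                                 channels = channels, min_cells = min_cells))
}

#' Simulate a pool-by-feature fingerprint table with planted group structure
#'
#' Emulates a post-normalisation profile matrix: pools in the same latent
#' group share a mean profile (strength `effect_scale`); features are
#' organised into correlated blocks (shared latent factor, pairwise
#' correlation `block_correlation`) so redundancy filtering has known true
#' positives; scattered positive-control wells are emitted alongside, with
#' a configurable subset of features made highly variable across them so
#' the variability filter has known targets too.
#'
#' @param n_pools number of crRNA pools (rows)
#' @param n_features number of features (columns)
#' @param groups named list mapping group label to member pool indices
#'   (disjoint); unlisted pools are null
#' @param effect_scale strength of the shared group profile (rZ-like units)
#' @param block_correlation within-block feature correlation in `[0, 1)`
#' @param seed integer seed
#' @param n_blocks number of feature blocks (default ~4 features per block)
#' @param n_control_wells scattered positive-control wells to emit
#' @param variable_features indices of features given S.D. >= 3 across the
#'   control wells (default ~5% of features)
#' @param control_sd S.D. of the planted "variable" features across control
#'   wells (the rest have S.D. ~0.8)
#' @return list: `profiles` (pools x features), `truth` (group label per
#'   pool, `NA` for nulls), `control_profiles` (control wells x features),
#'   `blocks` (feature -> block index)
#' @export
simulateFingerprintTable <- function(n_pools, n_features, groups = list(),
                                     effect_scale = 3, block_correlation = 0.6,
                                     seed = 1,
                                     n_blocks = max(1L, n_features %/% 4L),
                                     n_control_wells = 16,
                                     variable_features = NULL,
                                     control_sd = 5) {
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must lie in [0, 1)", call. = FALSE)
  if (n_features < n_blocks)
    stop("n_features must be >= number of blocks", call. = FALSE)
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop("groups must be disjoint", call. = FALSE)
  set.seed(childSeed(seed, 1))
  blocks <- sort(rep_len(seq_len(n_blocks), n_features))
  rho <- block_correlation
  z <- matrix(rnorm(n_pools * n_blocks), n_pools, n_blocks)
  eps <- matrix(rnorm(n_pools * n_features), n_pools, n_features)
  x <- sqrt(rho) * z[, blocks, drop = FALSE] + sqrt(1 - rho) * eps
  truth <- rep(NA_character_, n_pools)
  for (g in names(groups)) {
    sig <- rnorm(n_features)   # per-feature group signature
    for (p in groups[[g]]) x[p, ] <- x[p, ] + effect_scale * sig
    truth[groups[[g]]] <- g
  }
  dimnames(x) <- list(sprintf("pool_%03d", seq_len(n_pools)),
                      sprintf("f%04d", seq_len(n_features)))
  if (is.null(variable_features))
    variable_features <- seq_len(max(0L, round(0.05 * n_features)))
  ctrl_sd <- rep(0.8, n_features)
  ctrl_sd[variable_features] <- control_sd
  ctrl <- matrix(rnorm(n_control_wells * n_features, sd = rep(ctrl_sd, each = n_control_wells)),
                 n_control_wells, n_features,
                 dimnames = list(sprintf("ctrl_%02d", seq_len(n_control_wells)),
                                 colnames(x)))
  list(profiles = x, truth = truth, control_profiles = ctrl,
       blocks = setNames(blocks, colnames(x)))
}
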