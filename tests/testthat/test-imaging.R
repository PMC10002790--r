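test_that("blank image yields zero nuclei, not an error", {
  res <- segmentNuclei(matrix(100, 120, 120), pixel_size = 0.6)
  expect_equal(nrow(res$cells), 0)
  expect_true(all(res$labels == 0))
})

test_that("a noiseless rendered ellipse is recovered with its analytic area", {
  cells <- data.frame(cell_id = 1L, nucleus_area = 180,
                      nucleus_roundness = 0.9, dna_intensity = 1000,
                      micronucleus_count = 0L)
  opt <- opticsConfig(width = 200, height = 200)
  rf <- renderField(cells, optics = opt, seed = 3, noise = FALSE)
  res <- segmentNuclei(rf$image[, , "DNA"], pixel_size = 0.6)
  expect_equal(nrow(res$cells), 1)
  expect_lt(abs(res$cells$nucleus_area - 180) / 180, 0.05)
  expect_false(res$cells$boundary_cell)
  expect_lte(res$cells$nucleus_roundness, 1)
})

test_that("a 50-cell noisy field is segmented and matched to ground truth", {
  w <- simulateWell(geneEffect("ntc"), radialSpotModel(spots_per_cell_mean = 0),
                    n_cells = 54, seed = 31)
  opt <- opticsConfig(width = 720, height = 720)
  rf <- renderField(w$cells, optics = opt, seed = 32)
  tr <- rf$truth$cells
  skip_if(nrow(tr) < 50, "placement failed to fit 50 cells")
  res <- segmentNuclei(rf$image[, , "DNA"], pixel_size = 0.6)
  matched <- sum(vapply(seq_len(nrow(tr)), function(i) {
    d <- sqrt((res$cells$x_px - tr$x_px[i])^2 + (res$cells$y_px - tr$y_px[i])^2)
    any(d < 5)
  }, logical(1)))
  expect_gte(matched, floor(nrow(tr) * 48 / 50))
})

test_that("cytoplasm contains the nucleus and splits contacts by nearest nucleus", {
  lab <- disc_mask(80, 60, rbind(c(25, 30), c(55, 30)), c(8, 8))
  nuclei <- list(labels = lab,
                 cells = data.frame(cell_id = 1:2, x_px = c(25, 55),
                                    y_px = c(30, 30)))
  img <- matrix(50, 80, 60)          # uniform foreground via threshold = 0
  cyto <- segmentCytoplasm(img, nuclei, pixel_size = 0.6, threshold = 0)
  expect_true(all(cyto$labels[lab == 1] == 1))
  expect_true(all(cyto$labels[lab == 2] == 2))
  expect_true(all(cyto$labels > 0))  # partition of the foreground
  # brute-force per-pixel nearest-nucleus oracle
  n1 <- which(lab == 1, arr.ind = TRUE); n2 <- which(lab == 2, arr.ind = TRUE)
  px <- which(lab == 0, arr.ind = TRUE)
  set.seed(1)
  px <- px[sample(nrow(px), 400), ]
  for (i in seq_len(nrow(px))) {
    d1 <- min(sqrt((n1[, 1] - px[i, 1])^2 + (n1[, 2] - px[i, 2])^2))
    d2 <- min(sqrt((n2[, 1] - px[i, 1])^2 + (n2[, 2] - px[i, 2])^2))
    if (abs(d1 - d2) < 1e-9) next    # exact tie: either label is valid
    expect_equal(unname(cyto$labels[px[i, 1], px[i, 2]]),
                 if (d1 < d2) 1L else 2L)
  }
})

test_that("blank foreground falls back to a nucleus rim", {
  lab <- disc_mask(60, 60, rbind(c(30, 30)), 7)
  nuclei <- list(labels = lab, cells = data.frame(cell_id = 1L))
  img <- matrix(0, 60, 60)
  cyto <- segmentCytoplasm(img, nuclei, pixel_size = 0.6, threshold = 10,
                           min_rim_um = 2)
  expect_true(all(cyto$labels[lab == 1] == 1))
  rim <- cyto$labels == 1 & lab == 0
  expect_true(any(rim))
  d <- which(rim, arr.ind = TRUE)
  expect_true(all(sqrt((d[, 1] - 30)^2 + (d[, 2] - 30)^2) <= 7 + 2 / 0.6 + 1.5))
  expect_equal(cyto$zero_cyto, 1L)
})

test_that("noiseless puncta are detected exactly with sub-pixel centroids", {
  img <- matrix(100, 160, 160)
  pos <- cbind(x = c(30.3, 70.0, 110.6, 40.2, 120.0),
               y = c(40.0, 80.5, 30.0, 120.7, 120.3))
  s <- 0.8 / 0.6
  for (i in 1:5)
    img <- img + 80 * outer(exp(-(seq_len(160) - pos[i, 1])^2 / (2 * s^2)),
                            exp(-(seq_len(160) - pos[i, 2])^2 / (2 * s^2)))
  sp <- detectSpots(img, NULL, spot_sigma_um = 0.8, pixel_size = 0.6)
  expect_equal(nrow(sp), 5)
  ord <- order(sp$x)
  for (i in seq_len(5)) {
    d <- min(sqrt((sp$x - pos[i, 1])^2 + (sp$y - pos[i, 2])^2))
    expect_lt(d, 0.5)
  }
})

test_that("a blank image yields zero spots and bad sigma errors", {
  expect_equal(nrow(detectSpots(matrix(100, 50, 50), NULL)), 0)
  expect_error(detectSpots(matrix(100, 50, 50), NULL, spot_sigma_um = 0),
               "spot_sigma_um")
})

test_that("compartment boundaries are inclusive on the inner side", {
  # single-pixel nucleus at (20, 20), pixel size 1 um: exact distances
  lab <- matrix(0L, 60, 60); lab[20, 20] <- 1L
  nuclei <- list(labels = lab, cells = data.frame(cell_id = 1L))
  sp <- data.frame(x = c(20, 27, 27.9, 34, 35), y = rep(20, 5), cell_id = 1L)
  out <- assignCompartments(sp, nuclei, pixel_size = 1,
                            scheme = compartmentScheme(7, 14))
  expect_equal(out$envelope_distance, c(0, 7, 8, 14, 15), tolerance = 1e-9)
  expect_equal(out$compartment,
               c("perinuclear", "perinuclear", "intermediate", "intermediate",
                 "outer"))
  two <- assignCompartments(sp, nuclei, pixel_size = 1, two_ring = TRUE)
  expect_equal(two$compartment[3:5], rep("peripheral", 3))
})

test_that("envelope distances agree with the brute-force boundary oracle", {
  set.seed(77)
  lab <- disc_mask(140, 140, rbind(c(35, 35), c(100, 40), c(60, 100)),
                   c(9, 12, 7))
  nuclei <- list(labels = lab, cells = data.frame(cell_id = 1:3))
  sp <- data.frame(x = runif(60, 2, 138), y = runif(60, 2, 138),
                   cell_id = sample(1:3, 60, replace = TRUE))
  out <- assignCompartments(sp, nuclei, pixel_size = 0.6)
  for (i in seq_len(nrow(sp))) {
    d_oracle <- brute_envelope_distance(sp$x[i], sp$y[i], lab, sp$cell_id[i], 0.6)
    expect_lt(abs(out$envelope_distance[i] - d_oracle),
              0.6 * sqrt(2) / 2 + 1e-9)
  }
})

test_that("every in-cell spot gets exactly one compartment and counts sum", {
  set.seed(5)
  lab <- disc_mask(100, 100, rbind(c(30, 30), c(70, 70)), c(8, 10))
  nuclei <- list(labels = lab, cells = data.frame(cell_id = 1:2))
  sp <- data.frame(x = runif(80, 2, 98), y = runif(80, 2, 98),
                   cell_id = sample(1:2, 80, replace = TRUE),
                   channel = "PEX")
  out <- assignCompartments(sp, nuclei, pixel_size = 0.6)
  expect_true(all(!is.na(out$compartment)))
  r <- cellLocalisationRatios(out, cell_ids = 1:2)
  expect_equal(sum(r$n_perinuclear + r$n_peripheral), nrow(sp))
})

test_that("localisation ratio arithmetic matches its definition", {
  expect_equal(localisationRatio(6, 2), 2)
  expect_equal(localisationRatio(0, 0), 0)
  expect_equal(localisationRatio(c(3, 0), c(0, 5)), c(3, 0))
})

test_that("per-cell measures are invariant to whole-pixel translation", {
  cells <- data.frame(cell_id = 1L, nucleus_area = 150,
                      nucleus_roundness = 0.88, dna_intensity = 900,
                      micronucleus_count = 0L)
  opt <- opticsConfig(width = 140, height = 140)
  rf <- renderField(cells, optics = opt, seed = 9, noise = FALSE)
  img <- rf$image[, , "DNA"]
  shift <- function(m, dx, dy) {
    out <- matrix(100, nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  r1 <- segmentNuclei(img, pixel_size = 0.6)
  r2 <- segmentNuclei(shift(img, 6, 9), pixel_size = 0.6)
  expect_equal(r2$cells$nucleus_area, r1$cells$nucleus_area, tolerance = 1e-9)
  expect_equal(r2$cells$nucleus_roundness, r1$cells$nucleus_roundness,
               tolerance = 1e-9)
  expect_equal(r2$cells$x_px - r1$cells$x_px, 6, tolerance = 1e-6)
})

test_that("viability gating flags outliers, is idempotent, and needs a reference", {
  set.seed(21)
  ref <- data.frame(nucleus_area = rlnorm(2000, log(170), 0.25),
                    nucleus_roundness = rbeta(2000, 14, 2.5),
                    dna_intensity = rlnorm(2000, log(1000), 0.2))
  g <- gateViable(ref, ref)
  # three joint 1st-99th percentile gates trim ~6% of a clean population
  expect_gte(attr(g, "viability_fraction"), 0.93)
  small <- ref[1:5, ]; small$nucleus_area <- 0.1 * mean(ref$nucleus_area)
  g2 <- gateViable(small, ref)
  expect_true(all(!g2$viable))
  bounds <- attr(g, "bounds")
  once <- gateViable(ref, bounds)
  twice <- gateViable(once[once$viable, names(ref)], bounds)
  expect_true(all(twice$viable))
  expect_error(gateViable(ref, ref[0, ]), "empty")
})

test_that("crPLK1-like wells lose viable cells relative to NTC", {
  ntc_eff <- geneEffect("NTC")
  plk_eff <- geneEffect("crPLK1", viability_factor = 0.2,
                        nuclear_shift = c(area = -60, roundness = 0.04))
  m <- radialSpotModel(spots_per_cell_mean = 0)
  worse <- vapply(1:30, function(i) {
    ntc <- simulateWell(ntc_eff, m, 260, seed = childSeed(1, i, 1))$cells
    plk <- simulateWell(plk_eff, m, 260, seed = childSeed(1, i, 2))$cells
    nrow(plk) < nrow(ntc)
  }, logical(1))
  expect_true(all(worse))
})

test_that("MTOC counting recovers planted focus-count categories", {
  set.seed(61)
  n <- 30
  cells <- data.frame(cell_id = seq_len(n),
                      nucleus_area = rlnorm(n, log(170), 0.2),
                      nucleus_roundness = rbeta(n, 14, 2.5),
                      dna_intensity = 1000, micronucleus_count = 0L,
                      mtoc_count = rep(c(0L, 1L, 2L), each = n / 3))
  opt <- opticsConfig(width = 620, height = 620)
  rf <- renderField(cells, optics = opt, seed = 62)
  nuc <- segmentNuclei(rf$image[, , "DNA"], pixel_size = 0.6)
  cyto <- segmentCytoplasm(rf$image[, , "DNA"], nuc, pixel_size = 0.6,
                           threshold = 0)
  res <- countMTOC(rf$image[, , "gTub"], cyto$labels,
                   cell_ids = nuc$cells$cell_id, pixel_size = 0.6)
  planted <- rf$truth$cells$mtoc_count
  frac_true <- c(none = mean(planted == 0), one = mean(planted == 1),
                 multiple = mean(planted > 1))
  expect_true(all(abs(res$fractions - frac_true) <= 0.1 + 1e-9))
})

test_that("micronuclei are counted only for satellite DNA bodies", {
  cells <- data.frame(cell_id = 1:2, nucleus_area = c(170, 170),
                      nucleus_roundness = 0.9, dna_intensity = 1000,
                      micronucleus_count = c(1L, 0L))
  opt <- opticsConfig(width = 240, height = 240)
  rf <- renderField(cells, optics = opt, seed = 71, noise = FALSE)
  nuc <- segmentNuclei(rf$image[, , "DNA"], pixel_size = 0.6)
  skip_if(nrow(nuc$cells) != 2)
  cyto <- segmentCytoplasm(rf$image[, , "DNA"], nuc, pixel_size = 0.6,
                           threshold = 0)
  mn <- detectMicronuclei(rf$image[, , "DNA"], nuc, cyto$labels,
                          pixel_size = 0.6)
  # match rendered cells to segmented ids via position
  tr <- rf$truth$cells
  seg_id <- vapply(seq_len(nrow(tr)), function(i)
    nuc$cells$cell_id[which.min((nuc$cells$x_px - tr$x_px[i])^2 +
                                  (nuc$cells$y_px - tr$y_px[i])^2)],
    integer(1))
  got <- mn$micronucleus_count[match(seg_id, mn$cell_id)]
  expect_equal(got, tr$micronucleus_count)
})

test_that("cell feature vectors are deterministic with a stable schema", {
  lab <- disc_mask(90, 90, rbind(c(30, 30), c(65, 60)), c(8, 8))
  nuclei <- list(labels = lab,
                 cells = data.frame(cell_id = 1:2, x_px = c(30, 65),
                                    y_px = c(30, 60), nucleus_area = 70,
                                    perimeter_um = 30, nucleus_roundness = 0.9))
  cyto <- matrix(0L, 90, 90)
  cyto[1:45, ] <- 1L; cyto[46:90, ] <- 2L
  set.seed(3)
  imgs <- list(DNA = matrix(runif(8100, 90, 110), 90, 90),
               PEX = matrix(runif(8100, 90, 110), 90, 90))
  sp <- data.frame(x = c(31, 40, 70), y = c(31, 55, 60), cell_id = c(1, 1, 2),
                   channel = "PEX", intensity = 1)
  sp <- assignCompartments(sp, nuclei, pixel_size = 0.6)
  f1 <- extractCellFeatures(imgs, nuclei, cyto, sp, pixel_size = 0.6)
  f2 <- extractCellFeatures(imgs, nuclei, cyto, sp, pixel_size = 0.6)
  expect_identical(f1, f2)
  expect_equal(colnames(f1), c("cell_id", cellFeatureNames(names(imgs))))
  # missing channel gives NA features, not zeros
  f3 <- extractCellFeatures(imgs["DNA"], nuclei, cyto, sp,
                            channels = c("DNA", "PEX"), pixel_size = 0.6)
  expect_true(all(is.na(f3$PEX_int_mean)))
})

test_that("radial ring intensity features match a per-pixel oracle", {
  lab <- disc_mask(70, 70, rbind(c(35, 35)), 8)
  nuclei <- list(labels = lab,
                 cells = data.frame(cell_id = 1L, x_px = 35, y_px = 35,
                                    nucleus_area = 72, perimeter_um = 30,
                                    nucleus_roundness = 0.9))
  cyto <- matrix(1L, 70, 70)
  set.seed(8)
  imgs <- list(DNA = matrix(runif(4900, 50, 150), 70, 70))
  f <- extractCellFeatures(imgs, nuclei, cyto, NULL, pixel_size = 0.6)
  # oracle: per-pixel distance to nucleus via explicit min over pixels
  nucpx <- which(lab == 1, arr.ind = TRUE)
  bgpx <- which(lab == 0, arr.ind = TRUE)
  d <- matrix(NA_real_, 70, 70)
  for (x in 1:70) for (y in 1:70) {
    d[x, y] <- if (lab[x, y] == 1)
      -(min(sqrt((bgpx[, 1] - x)^2 + (bgpx[, 2] - y)^2)) - 1) * 0.6
    else min(sqrt((nucpx[, 1] - x)^2 + (nucpx[, 2] - y)^2)) * 0.6
  }
  r1 <- mean(imgs$DNA[d <= 7])
  r2 <- mean(imgs$DNA[d > 7 & d <= 14])
  r3 <- mean(imgs$DNA[d > 14])
  expect_equal(f$DNA_ring1_mean, r1, tolerance = 1e-9)
  expect_equal(f$DNA_ring2_mean, r2, tolerance = 1e-9)
  expect_equal(f$DNA_ring3_mean, r3, tolerance = 1e-9)
})
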