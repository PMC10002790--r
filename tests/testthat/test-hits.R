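# Builds a WellFeatureSet whose library "genes" have planted shifts on the
# rZ-like scale, plus NTC / positive-control wells, for hit-calling tests.
make_hit_wfs <- function(gene_shift, metrics = c("loc_ratio_PEX"),
                         prefilter_metrics = TRUE, n_ntc = 30, n_pos = 8,
                         seed = 1) {
  set.seed(seed)
  genes <- names(gene_shift)
  feat <- metrics
  if (prefilter_metrics)
    feat <- c(feat, "nucleus_area", "nucleus_roundness", "micronuclei_rate",
              "viable_fraction")
  n <- n_ntc + n_pos + length(genes)
  role <- c(rep("NTC", n_ntc), rep("positive_control", n_pos),
            rep("library", length(genes)))
  pool <- c(rep("NTC", n_ntc), rep("crPOS", n_pos), genes)
  vals <- matrix(rnorm(length(feat) * n), length(feat), n,
                 dimnames = list(feat, NULL))
  for (m in metrics)
    vals[m, role == "library"] <- vals[m, role == "library"] + gene_shift
  if (prefilter_metrics)
    vals["viable_fraction", role == "positive_control"] <-
      vals["viable_fraction", role == "positive_control"] - 4
  wd <- data.frame(plate_id = "P01", well = well_key(seq_len(n)),
                   pool_id = pool, role = role, n_cells = 250L,
                   n_viable = 230L, qc_pass = TRUE)
  WellFeatureSet(vals, wd)
}

test_that("hit policies validate their configuration", {
  expect_error(hitPolicy("m1", k_sd = 0), "k_sd")
  expect_error(hitPolicy(c("m1", "m2"), direction = c(m1 = "two-sided")),
               "direction")
  expect_error(hitPolicy("m1", direction = c(m1 = "sideways")), "direction")
  expect_equal(hitPolicy("m1", mode = "primary")$k_sd, 2)
  expect_equal(hitPolicy("m1", mode = "validation")$k_sd, 2.5)
})

test_that("prefilter retains NTC-like genes and excludes with reasons", {
  shifts <- setNames(rep(0, 20), sprintf("g%02d", 1:20))
  wfs <- make_hit_wfs(shifts, seed = 2)
  pe <- poolEffects(wfs, assay_name = "values")
  # plant gross morphology / viability offenders
  eff <- pe$effects
  eff["g01", "nucleus_area"] <- eff["g01", "nucleus_area"] + 10
  eff["g02", "nucleus_roundness"] <- -8
  eff["g03", "viable_fraction"] <- -10
  pol <- hitPolicy("loc_ratio_PEX")
  pf <- prefilterGenes(eff, wfs, pol, assay_name = "values")
  expect_true(all(sprintf("g%02d", 4:20) %in% pf$retained))
  led <- pf$ledger
  expect_equal(led$reason[led$gene == "g01"], "nucleus_area")
  expect_equal(led$reason[led$gene == "g02"], "nucleus_roundness")
  expect_equal(led$reason[led$gene == "g03"], "viable_fraction")
  expect_error(prefilterGenes(eff[, 1, drop = FALSE], wfs, pol),
               "missing prefilter")
})

test_that("exclusion ledger matches a rule-by-rule brute-force replay", {
  set.seed(6)
  shifts <- setNames(rnorm(40, sd = 3), sprintf("g%02d", 1:40))
  wfs <- make_hit_wfs(shifts, seed = 6)
  pe <- poolEffects(wfs, assay_name = "values")
  eff <- pe$effects
  eff[, "nucleus_area"] <- rnorm(40, sd = 3)
  eff[, "viable_fraction"] <- rnorm(40, sd = 3)
  pol <- hitPolicy("loc_ratio_PEX")
  pf <- prefilterGenes(eff, wfs, pol, assay_name = "values")
  vals <- featureValues(wfs)
  ntc <- wellRoles(wfs) == "NTC"
  for (g in rownames(eff)) {
    excl <- FALSE
    for (m in c("nucleus_area", "nucleus_roundness", "micronuclei_rate")) {
      z <- (eff[g, m] - mean(vals[m, ntc])) / sd(vals[m, ntc])
      b <- pol$prefilters[[m]]
      if (z < b$lower || z > b$upper) excl <- TRUE
    }
    pos_min <- min(vals["viable_fraction", wellRoles(wfs) == "positive_control"])
    if (eff[g, "viable_fraction"] < pos_min) excl <- TRUE
    expect_equal(pf$ledger$excluded[pf$ledger$gene == g], excl, label = g)
  }
})

test_that("hits require crossing the NTC mean +/- k S.D. in an allowed direction", {
  wfs <- make_hit_wfs(setNames(c(0, -5, 5, -1), paste0("g", 1:4)),
                      prefilter_metrics = FALSE, seed = 3)
  vals <- featureValues(wfs)
  ntc_mean <- mean(vals["loc_ratio_PEX", wellRoles(wfs) == "NTC"])
  eff <- poolEffects(wfs, assay_name = "values")$effects
  eff["g1", "loc_ratio_PEX"] <- ntc_mean        # exactly at the NTC mean
  pol <- hitPolicy("loc_ratio_PEX", k_sd = 2)
  ch <- callHits(eff, wfs, pol, assay_name = "values")
  hits <- setNames(ch$hits$hit, ch$hits$gene)
  expect_false(hits[["g1"]])
  expect_true(hits[["g2"]]); expect_true(hits[["g3"]])
  expect_false(hits[["g4"]])
  dec <- hitPolicy("loc_ratio_PEX", k_sd = 2,
                   direction = c(loc_ratio_PEX = "decrease-only"))
  hd <- callHits(eff, wfs, dec, assay_name = "values")
  hd <- setNames(hd$hits$hit, hd$hits$gene)
  expect_true(hd[["g2"]]); expect_false(hd[["g3"]])
})

test_that("a planted effect on one metric hits that metric only", {
  set.seed(8)
  metrics <- c("loc_ratio_PEX", "loc_ratio_EEA1")
  wfs <- make_hit_wfs(setNames(0, "g1"), metrics = metrics,
                      prefilter_metrics = FALSE, seed = 8)
  eff <- poolEffects(wfs, assay_name = "values")$effects
  eff["g1", "loc_ratio_PEX"] <- -5
  eff["g1", "loc_ratio_EEA1"] <- 0
  ch <- callHits(eff, wfs, hitPolicy(metrics, k_sd = 2),
                 assay_name = "values")
  tab <- ch$table
  expect_true(tab$hit[tab$metric == "loc_ratio_PEX"])
  expect_false(tab$hit[tab$metric == "loc_ratio_EEA1"])
})

test_that("the stricter threshold's hit set nests inside the looser one", {
  set.seed(12)
  shifts <- setNames(rnorm(300, sd = 2.2), sprintf("g%03d", 1:300))
  wfs <- make_hit_wfs(shifts, prefilter_metrics = FALSE, seed = 12)
  eff <- poolEffects(wfs, assay_name = "values")$effects
  h20 <- callHits(eff, wfs, hitPolicy("loc_ratio_PEX", k_sd = 2),
                  assay_name = "values")$hits
  h25 <- callHits(eff, wfs, hitPolicy("loc_ratio_PEX", k_sd = 2.5),
                  assay_name = "values")$hits
  set25 <- h25$gene[h25$hit]; set20 <- h20$gene[h20$hit]
  expect_true(all(set25 %in% set20))
  expect_gt(length(set20), length(set25))
})

test_that("null hit rate matches the two-sided Gaussian tail", {
  shifts <- setNames(rep(0, 800), sprintf("g%03d", 1:800))
  wfs <- make_hit_wfs(shifts, prefilter_metrics = FALSE, n_ntc = 120, seed = 19)
  eff <- poolEffects(wfs, assay_name = "values")$effects
  ch <- callHits(eff, wfs, hitPolicy("loc_ratio_PEX", k_sd = 2),
                 assay_name = "values")
  p <- 2 * pnorm(-2)
  rate <- mean(ch$hits$hit)
  half <- 1.96 * sqrt(p * (1 - p) / 800) + 0.01   # + NTC estimation slack
  expect_lt(abs(rate - p), half + 0.015)
})

test_that("insufficient NTC wells raise an error", {
  wfs <- make_hit_wfs(setNames(0, "g1"), prefilter_metrics = FALSE,
                      n_ntc = 1, seed = 4)
  eff <- poolEffects(wfs, assay_name = "values")$effects
  expect_error(callHits(eff, wfs, hitPolicy("loc_ratio_PEX"),
                        assay_name = "values"), "NTC")
})

test_that("cargo categories encode the per-cargo sign pattern", {
  mk <- function(genes, hit, dirn) {
    data.frame(gene = genes, metric = "m", hit = hit,
               effect_direction = dirn)
  }
  genes <- c("null", "fhf", "pan", "mixed")
  tabs <- list(
    PEX = mk(genes, c(FALSE, FALSE, TRUE, TRUE),
             c("none", "none", "decrease", "decrease")),
    EEA1 = mk(genes, c(FALSE, TRUE, TRUE, TRUE),
              c("none", "decrease", "decrease", "increase")),
    TGN = mk(genes, c(FALSE, FALSE, TRUE, FALSE),
             c("none", "none", "decrease", "none")))
  cat <- categoriseCargoEffects(tabs)
  got <- setNames(cat$cargo_category, cat$gene)
  expect_equal(got[["null"]], "unchanged")
  expect_equal(got[["fhf"]], "EEA1- only")
  expect_equal(got[["pan"]], "PEX-/EEA1-/TGN-")
  expect_equal(got[["mixed"]], "PEX-/EEA1+")
})

test_that("cargo categories equal an exhaustive truth-table evaluation", {
  states <- c("unchanged", "dispersed", "clustered")
  grid <- expand.grid(PEX = states, EEA1 = states, stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  tabs <- lapply(c("PEX", "EEA1"), function(ca) {
    st <- grid[[ca]]
    data.frame(gene = genes, metric = "m", hit = st != "unchanged",
               effect_direction = c(unchanged = "none", dispersed = "decrease",
                                    clustered = "increase")[st])
  })
  names(tabs) <- c("PEX", "EEA1")
  cat <- categoriseCargoEffects(tabs)
  for (i in seq_along(genes)) {
    marks <- character()
    for (ca in c("PEX", "EEA1")) {
      if (grid[[ca]][i] == "dispersed") marks <- c(marks, paste0(ca, "-"))
      if (grid[[ca]][i] == "clustered") marks <- c(marks, paste0(ca, "+"))
    }
    want <- if (!length(marks)) "unchanged"
            else if (length(marks) == 1) paste(marks, "only")
            else paste(marks, collapse = "/")
    expect_equal(cat$cargo_category[i], want)
  }
  expect_equal(cat$PEX, grid$PEX)
})

test_that("k-means grouping handles the degenerate and separable cases", {
  set.seed(23)
  X <- matrix(rnorm(12), 6, 2)
  rownames(X) <- paste0("g", 1:6)
  km <- kmeansGroup(X, k = 6, seed = 1)
  expect_equal(km$objective, 0, tolerance = 1e-12)
  expect_equal(length(unique(km$labels)), 6)
  blob <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  rownames(blob) <- paste0("g", 1:20)
  km2 <- kmeansGroup(blob, k = 2, seed = 2)
  expect_equal(adjustedRandIndex(km2$labels, rep(1:2, each = 10)), 1)
  expect_error(kmeansGroup(X, k = 10), "exceeds")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(kmeansGroup(Xna, k = 2), "NA")
})

test_that("k-means with restarts attains the exhaustive-enumeration optimum", {
  set.seed(29)
  X <- matrix(rnorm(18), 9, 2)
  rownames(X) <- paste0("g", 1:9)
  km <- kmeansGroup(X, k = 3, n_init = 40, seed = 5)
  # brute force over all 3^9 label assignments
  best <- Inf
  lab <- integer(9)
  for (code in 0:(3^9 - 1)) {
    c0 <- code
    for (j in 1:9) { lab[j] <- c0 %% 3; c0 <- c0 %/% 3 }
    if (length(unique(lab)) < 3) next
    ss <- 0
    for (g in 0:2) {
      sub <- X[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (ss < best) best <- ss
  }
  expect_equal(km$objective, best, tolerance = 1e-9)
})

test_that("more restarts never worsen the kept objective", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  rownames(X) <- paste0("g", 1:20)
  o1 <- kmeansGroup(X, k = 4, n_init = 1, seed = 9)$objective
  o10 <- kmeansGroup(X, k = 4, n_init = 10, seed = 9)$objective
  expect_lte(o10, o1 + 1e-12)
})
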