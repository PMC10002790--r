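#' Hit-calling policy
#'
#' The gating-then-threshold rule set: prefilter bounds that exclude genes
#' with strong viability / nuclear-morphology / micronuclei effects before
#' any cargo endpoint is considered, then per-metric thresholds at
#' `mean(NTC) +/- k_sd * S.D.(NTC)` with a direction per metric; a gene is
#' a hit if it passes on at least one metric of `metric_set`.
#'
#' Default prefilter bounds mirror the screening convention: |effect| <= 4
#' NTC S.D. on nuclear area, effect >= -3.5 S.D. on roundness, micronuclei
#' below +4 S.D., and viability above the positive-control range (the
#' crLIS1-like bound; genes killing cells faster than the positive control
#' are excluded as indirect).
#'
#' @param metric_set endpoints considered for hit calling
#' @param k_sd threshold multiple of the NTC S.D. (2.0 primary-screen
#'   mode; 2.5 validation mode)
#' @param direction named per-metric direction:
#'   `"two-sided"`, `"decrease-only"` or `"increase-only"`; unnamed single
#'   value recycles
#' @param mode convenience: `"primary"` sets `k_sd = 2`, `"validation"`
#'   sets `k_sd = 2.5` (explicit `k_sd` wins)
#' @param prefilters named list of prefilter rules, each
#'   `list(metric=, lower=, upper=)` in NTC-S.D. units (or
#'   `viability = "positive_control"` for the control-range rule)
#' @return a `HitPolicy` list
#' @export
hitPolicy <- function(metric_set, k_sd = NULL,
                      direction = "two-sided",
                      mode = c("primary", "validation"),
                      prefilters = list(
                        nucleus_area = list(lower = -4, upper = 4),
                        nucleus_roundness = list(lower = -3.5, upper = Inf),
                        micronuclei_rate = list(lower = -Inf, upper = 4),
                        viable_fraction = "positive_control")) {
  mode <- match.arg(mode)
  if (is.null(k_sd)) k_sd <- if (mode == "primary") 2.0 else 2.5
  if (k_sd <= 0) stop("k_sd must be > 0", call. = FALSE)
  if (length(direction) == 1 && is.null(names(direction)))
    direction <- setNames(rep(direction, length(metric_set)), metric_set)
  if (!all(metric_set %in% names(direction)))
    stop("every metric in metric_set needs a direction", call. = FALSE)
  ok <- direction %in% c("two-sided", "decrease-only", "increase-only")
  if (!all(ok)) stop("unknown direction value", call. = FALSE)
  structure(list(metric_set = metric_set, k_sd = k_sd,
                 direction = direction, mode = mode, prefilters = prefilters),
            class = "HitPolicy")
}

# NTC mean/SD per metric from a WellFeatureSet assay
ntc_stats <- function(wfs, assay_name, metrics) {
  vals <- assay(wfs, assay_name)
  ntc <- wellRoles(wfs) == "NTC"
  qc <- qcPass(wfs); qc[is.na(qc)] <- TRUE
  t(vapply(metrics, function(m) {
    v <- vals[m, ntc & qc]
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = sd(v), n = length(v))
  }, numeric(3)))
}

#' Per-gene effect estimates from well-level data
#'
#' A gene's effect on a metric is the mean of its qc-passing wells'
#' values; genes whose wells all fail QC are dropped with a logged reason.
#'
#' @param wfs a [WellFeatureSet-class]
#' @param assay_name assay to summarise (typically `"rZ"` or `"values"`)
#' @param roles well roles treated as genes (default `"library"`)
#' @return list: `effects` (genes x metrics matrix), `n_wells` (passing
#'   wells per gene), `dropped` (gene ids with no passing well)
#' @export
poolEffects <- function(wfs, assay_name = "rZ", roles = "library") {
  vals <- assay(wfs, assay_name)
  sel <- wellRoles(wfs) %in% roles
  qc <- qcPass(wfs); qc[is.na(qc)] <- TRUE
  pools <- poolIds(wfs)
  genes <- unique(pools[sel])
  eff <- matrix(NA_real_, length(genes), nrow(vals),
                dimnames = list(genes, rownames(vals)))
  nw <- setNames(integer(length(genes)), genes)
  for (g in genes) {
    cols <- sel & pools == g & qc
    nw[g] <- sum(cols)
    if (nw[g] > 0)
      eff[g, ] <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
  }
  dropped <- genes[nw == 0]
  list(effects = eff[nw > 0, , drop = FALSE], n_wells = nw[nw > 0],
       dropped = dropped)
}

#' Prefilter genes on viability, nuclear morphology and micronuclei
#'
#' Applies the policy's prefilter rules to per-gene effects expressed in
#' NTC-S.D. units. Rules with numeric bounds exclude genes outside
#' `[lower, upper]`; the `"positive_control"` viability rule excludes
#' genes whose viability endpoint falls below the minimum observed across
#' positive-control wells (same scale).
#'
#' @param effects genes x metrics matrix (endpoint scale)
#' @param wfs the [WellFeatureSet-class] the effects came from (source of
#'   NTC / positive-control statistics)
#' @param policy a [hitPolicy()]
#' @param assay_name assay the effects were computed on
#' @return list: `retained` (gene ids), `ledger` (data.frame `gene`,
#'   `excluded`, `reason`)
#' @export
prefilterGenes <- function(effects, wfs, policy, assay_name = "rZ") {
  rules <- policy$prefilters
  need <- names(rules)
  miss <- setdiff(need, colnames(effects))
  if (length(miss))
    stop("missing prefilter metrics: ", paste(miss, collapse = ", "),
         call. = FALSE)
  st <- ntc_stats(wfs, assay_name, need)
  genes <- rownames(effects)
  reason <- setNames(rep(NA_character_, length(genes)), genes)
  for (m in need) {
    z <- (effects[, m] - st[m, "mean"]) / st[m, "sd"]
    rule <- rules[[m]]
    if (identical(rule, "positive_control")) {
      vals <- assay(wfs, assay_name)
      pos <- vals[m, wellRoles(wfs) == "positive_control"]
      bound <- min(pos, na.rm = TRUE)
      bad <- !is.na(effects[, m]) & effects[, m] < bound
    } else {
      bad <- !is.na(z) & (z < rule$lower | z > rule$upper)
    }
    reason[bad & is.na(reason)] <- m
  }
  ledger <- data.frame(gene = genes, excluded = !is.na(reason),
                       reason = reason, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(retained = genes[is.na(reason)], ledger = ledger)
}

#' Call hits against NTC mean +/- k S.D. thresholds
#'
#' A gene is a hit on metric `m` iff its effect lies beyond
#' `mean(NTC) +/- k_sd * S.D.(NTC)` in an allowed direction; the overall
#' hit flag is the union over the policy's `metric_set`. Thresholds are
#' applied on the endpoint scale and recorded in the output together with
#' the equivalent NTC-S.D. z value.
#'
#' @param effects genes x metrics matrix (endpoint scale, prefiltered)
#' @param wfs source [WellFeatureSet-class] (NTC statistics)
#' @param policy a [hitPolicy()]
#' @param assay_name assay the effects were computed on
#' @return list: `table` (one row per gene x metric: `gene`, `metric`,
#'   `effect`, `z`, `lower`, `upper`, `direction`, `hit`,
#'   `effect_direction`), `hits` (per-gene summary: `gene`, `hit`,
#'   `n_metrics_hit`), `thresholds`
#' @export
callHits <- function(effects, wfs, policy, assay_name = "rZ") {
  metrics <- policy$metric_set
  miss <- setdiff(metrics, colnames(effects))
  if (length(miss))
    stop("metrics absent from effects: ", paste(miss, collapse = ", "),
         call. = FALSE)
  st <- ntc_stats(wfs, assay_name, metrics)
  if (any(st[, "n"] < 2))
    stop("fewer than 2 NTC wells with data", call. = FALSE)
  rows <- list()
  genes <- rownames(effects)
  hit_any <- setNames(rep(FALSE, length(genes)), genes)
  n_hit <- setNames(rep(0L, length(genes)), genes)
  thr <- data.frame(metric = metrics,
                    lower = st[metrics, "mean"] - policy$k_sd * st[metrics, "sd"],
                    upper = st[metrics, "mean"] + policy$k_sd * st[metrics, "sd"],
                    direction = policy$direction[metrics], row.names = NULL)
  for (m in metrics) {
    lo <- thr$lower[thr$metric == m]; hi <- thr$upper[thr$metric == m]
    dirn <- policy$direction[[m]]
    e <- effects[, m]
    dn <- !is.na(e) & e < lo
    up <- !is.na(e) & e > hi
    hit <- switch(dirn, `two-sided` = dn | up, `decrease-only` = dn,
                  `increase-only` = up)
    rows[[m]] <- data.frame(gene = genes, metric = m, effect = e,
                            z = (e - st[m, "mean"]) / st[m, "sd"],
                            lower = lo, upper = hi, direction = dirn,
                            hit = hit,
                            effect_direction = ifelse(dn, "decrease",
                                                      ifelse(up, "increase",
                                                             "none")),
                            row.names = NULL)
    hit_any <- hit_any | hit
    n_hit <- n_hit + hit
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  list(table = tab,
       hits = data.frame(gene = genes, hit = unname(hit_any),
                         n_metrics_hit = unname(n_hit), row.names = NULL),
       thresholds = thr)
}

#' Categorise multi-cargo effect signatures
#'
#' Automates the per-cargo annotation: for each cargo the gene is
#' `dispersed` (hit with decreased localisation ratio), `clustered` (hit
#' with increase) or `unchanged`; the category string concatenates the
#' affected cargoes as e.g. `"PEX-/EEA1-"` (pan-dispersion components) or
#' `"EEA1+ only"`; genes with no hits are `"unchanged"`.
#'
#' @param hit_tables named list (per cargo) of `table` data.frames from
#'   [callHits()], each restricted to that cargo's metric — same gene
#'   universe across cargoes
#' @return data.frame `gene`, one `<cargo>` column each with
#'   `dispersed`/`clustered`/`unchanged`, and `cargo_category`
#' @export
categoriseCargoEffects <- function(hit_tables) {
  cargoes <- names(hit_tables)
  genes <- unique(hit_tables[[1]]$gene)
  for (ht in hit_tables)
    if (!setequal(unique(ht$gene), genes))
      stop("hit tables must share one gene universe", call. = FALSE)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  marks <- matrix("", length(genes), length(cargoes),
                  dimnames = list(genes, cargoes))
  for (ca in cargoes) {
    ht <- hit_tables[[ca]]
    idx <- match(genes, ht$gene)
    state <- ifelse(!ht$hit[idx], "unchanged",
                    ifelse(ht$effect_direction[idx] == "decrease",
                           "dispersed", "clustered"))
    out[[ca]] <- state
    marks[, ca] <- ifelse(state == "dispersed", paste0(ca, "-"),
                          ifelse(state == "clustered", paste0(ca, "+"), ""))
  }
  cat_str <- apply(marks, 1, function(r) {
    r <- r[r != ""]
    if (!length(r)) return("unchanged")
    s <- paste(r, collapse = "/")
    if (length(r) == 1) paste(s, "only") else s
  })
  out$cargo_category <- unname(cat_str)
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centres
kmeanspp_centres <- function(X, k) {
  n <- nrow(X)
  centres <- numeric(k)
  centres[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centres[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centres[j] <- sample.int(n, 1, prob = pr)
    nd <- rowSums((X - matrix(X[centres[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centres, , drop = FALSE]
}

#' Group genes by K-means on cargo effect profiles
#'
#' Euclidean K-means (Lloyd iterations) with k-means++ initialisation and
#' `n_init` restarts, keeping the solution with the lowest within-cluster
#' sum of squares. Genes with missing effects must be excluded first.
#' Deterministic given `seed`.
#'
#' @param effect_matrix genes x cargo-effect numeric matrix, no `NA`
#' @param k number of clusters (the cargo grouping convention is 14;
#'   always log the value used)
#' @param n_init number of restarts
#' @param seed integer seed
#' @param max_iter Lloyd iteration cap per restart
#' @return list: `labels` (named cluster per gene), `centroids`,
#'   `objective` (total within-cluster SS), `k`
#' @export
kmeansGroup <- function(effect_matrix, k, n_init = 10, seed = 1,
                        max_iter = 100) {
  X <- as.matrix(effect_matrix)
  if (anyNA(X)) stop("effect_matrix must not contain NA", call. = FALSE)
  if (k > nrow(X)) stop("k exceeds the number of genes", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    ctr <- kmeanspp_centres(X, k)
    km <- suppressWarnings(
      kmeans(X, centers = ctr, iter.max = max_iter, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(labels = setNames(best$cluster, rownames(X)),
       centroids = best$centers, objective = best$tot.withinss, k = k)
}
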