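# Shared fixtures, built in code at test time.

# Small well-level feature set with known NTC / positive / library values.
make_wfs <- function(n_ntc = 12, n_pos = 6, n_lib = 20, n_feat = 3,
                     seed = 1, lib_shift = 0, pos_shift = -5) {
  set.seed(seed)
  n <- n_ntc + n_pos + n_lib
  role <- c(rep("NTC", n_ntc), rep("positive_control", n_pos),
            rep("library", n_lib))
  pool <- c(rep("NTC", n_ntc), rep("crPOS", n_pos),
            sprintf("g%03d", seq_len(n_lib)))
  vals <- matrix(rnorm(n_feat * n), n_feat, n,
                 dimnames = list(paste0("m", seq_len(n_feat)), NULL))
  vals[, role == "positive_control"] <-
    vals[, role == "positive_control"] + pos_shift
  vals[, role == "library"] <- vals[, role == "library"] + lib_shift
  wd <- data.frame(plate_id = "P01",
                   well = well_key(seq_len(n)),
                   pool_id = pool, role = role,
                   n_cells = 250L, n_viable = 230L, qc_pass = TRUE)
  WellFeatureSet(vals, wd)
}

well_key <- function(i) paste0(LETTERS[(i - 1) %/% 24 + 1],
                               sprintf("%02d", (i - 1) %% 24 + 1))

# Label matrix with disc-shaped nuclei at given centres/radii (pixels).
disc_mask <- function(nx, ny, centres, radii) {
  lab <- matrix(0L, nx, ny)
  for (i in seq_len(nrow(centres))) {
    xs <- seq_len(nx); ys <- seq_len(ny)
    d2 <- outer((xs - centres[i, 1])^2, (ys - centres[i, 2])^2, "+")
    lab[d2 <= radii[i]^2] <- i
  }
  lab
}

# Brute-force signed envelope distance: positive outside = min distance to
# any pixel of the own nucleus; negative inside = -min distance to any
# background pixel. Independent O(spots x pixels) oracle.
brute_envelope_distance <- function(x, y, lab, own, pixel_size) {
  xi <- round(x); yi <- round(y)
  if (lab[xi, yi] == own) {
    bg <- which(lab == 0, arr.ind = TRUE)
    -(min(sqrt((bg[, 1] - xi)^2 + (bg[, 2] - yi)^2)) - 1) * pixel_size
  } else {
    nuc <- which(lab == own, arr.ind = TRUE)
    min(sqrt((nuc[, 1] - xi)^2 + (nuc[, 2] - yi)^2)) * pixel_size
  }
}

# proximity precision/recall for spot detection (2 px default)
match_stats <- function(det, truth, tol = 2) {
  if (!nrow(det) || !nrow(truth))
    return(c(precision = as.numeric(!nrow(det)), recall = as.numeric(!nrow(truth))))
  d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2
  c(precision = mean(apply(d2, 1, min) <= tol^2),
    recall = mean(apply(d2, 2, min) <= tol^2))
}

# naive agglomerative clustering oracle: recompute all pairwise complete-
# linkage distances from scratch at every merge
naive_complete <- function(X) {
  d <- as.matrix(correlationDistance(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    lab <- integer(nrow(X))
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- lab
  }
  list(heights = heights, partitions = partitions)
}
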