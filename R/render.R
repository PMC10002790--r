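#' Optical / geometry configuration for field rendering
#'
#' Defaults emulate a 20x acquisition with 2x2 binning: 0.6 um per pixel on
#' a 1080 x 1080 field. Noise is Poisson shot noise on the photon image plus
#' Gaussian read noise; the approximate single-pixel SNR of a punctum is
#' `spot_amplitude / sqrt(background + read_noise_sd^2)`.
#'
#' @param pixel_size um per pixel (> 0)
#' @param width,height field size in pixels
#' @param background mean background photon count
#' @param nucleus_amplitude added DNA-channel signal inside nuclei
#' @param spot_amplitude peak photon count of a punctum
#' @param spot_sigma_um Gaussian punctum sigma (um)
#' @param mtoc_sigma_um sigma used for MTOC-scale foci (um)
#' @param read_noise_sd Gaussian read noise S.D.
#' @return an `OpticsConfig` list
#' @export
opticsConfig <- function(pixel_size = 0.6, width = 1080, height = 1080,
                         background = 100, nucleus_amplitude = 600,
                         spot_amplitude = 150, spot_sigma_um = 0.8,
                         mtoc_sigma_um = 1.2, read_noise_sd = 5) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(pixel_size = pixel_size, width = width, height = height,
                 background = background, nucleus_amplitude = nucleus_amplitude,
                 spot_amplitude = spot_amplitude, spot_sigma_um = spot_sigma_um,
                 mtoc_sigma_um = mtoc_sigma_um, read_noise_sd = read_noise_sd),
            class = "OpticsConfig")
}

# ellipse roundness 4*pi*A/P^2 with Ramanujan perimeter; q = b/a aspect
ellipse_roundness <- function(q) {
  a <- 1; b <- q
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * (pi * a * b) / p^2
}

aspect_from_roundness <- function(r) {
  r <- min(r, ellipse_roundness(1) - 1e-9)
  if (r >= 0.995) return(1)
  tryCatch(stats::uniroot(function(q) ellipse_roundness(q) - r,
                          c(0.05, 1))$root,
           error = function(e) 1)
}

# radius of ellipse boundary from centre along direction phi (frame angle th)
ellipse_radius <- function(phi, a, b, th) {
  psi <- phi - th
  1 / sqrt((cos(psi) / a)^2 + (sin(psi) / b)^2)
}

stamp_gaussian <- function(img, x0, y0, amp, sigma) {
  r <- ceiling(3 * sigma)
  xs <- max(1, floor(x0) - r):min(nrow(img), floor(x0) + r + 1)
  ys <- max(1, floor(y0) - r):min(ncol(img), floor(y0) + r + 1)
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  img[xs, ys] <- img[xs, ys] + amp * outer(gx, gy)
  img
}

#' Render a multi-channel fluorescence field from simulated cells
#'
#' Places cells in the field by rejection sampling (nuclei never overlap;
#' cytoplasm may), rasterises nuclei as filled ellipses in the DNA channel
#' (ellipse axes derived from each cell's area and roundness), converts
#' each spot's envelope distance into an image position along a random
#' direction from its nucleus boundary, renders spots as Gaussian puncta,
#' and applies Poisson shot noise plus Gaussian read noise. Micronuclei
#' (cells with `micronucleus_count > 0`) are rendered as small DNA bodies
#' near the nucleus; if the cell table carries an `mtoc_count` column, a
#' `"gTub"` channel with MTOC-scale foci is added.
#'
#' @param cells cell table from [simulateWell()] (or compatible)
#' @param spots spot table from [simulateWell()] (`cell_id`, `channel`,
#'   `envelope_distance`, `intensity`); may be empty
#' @param optics an [opticsConfig()]
#' @param seed integer seed (placement, noise)
#' @param noise logical; `FALSE` renders the clean photon image
#' @param channels channel names to render (default: `"DNA"` plus all spot
#'   channels, plus `"gTub"` when `mtoc_count` is present)
#' @return list: `image` (array width x height x channel, named), `truth`
#'   with `cells` (placed cells incl. pixel centres and axes),
#'   `spots` (pixel coordinates per rendered spot), `micronuclei`,
#'   `nucleus_mask` (label matrix), `optics`
#' @export
renderField <- function(cells, spots = NULL, optics = opticsConfig(),
                        seed = 1, noise = TRUE, channels = NULL) {
  set.seed(seed)
  px <- optics$pixel_size
  W <- optics$width; H <- optics$height
  if (is.null(spots))
    spots <- data.frame(cell_id = integer(), channel = character(),
                        envelope_distance = numeric(), intensity = numeric())
  spot_ch <- unique(as.character(spots$channel))
  has_mtoc <- "mtoc_count" %in% names(cells)
  if (is.null(channels))
    channels <- c("DNA", spot_ch, if (has_mtoc) "gTub")
  # --- place cells (rejection sampling on nucleus bounding circles)
  n <- nrow(cells)
  placed <- logical(n)
  cx <- cy <- aa <- bb <- th <- numeric(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      r_area <- sqrt(cells$nucleus_area[i] / pi) / px       # px, circle-equiv
      q <- aspect_from_roundness(cells$nucleus_roundness[i])
      a <- r_area / sqrt(q); b <- r_area * sqrt(q)          # semi-axes, px
      margin <- a + 2
      ok <- FALSE
      for (try in seq_len(200)) {
        x <- runif(1, margin, W - margin); y <- runif(1, margin, H - margin)
        prev <- which(placed[seq_len(i - 1L)])
        if (!length(prev) ||
            all(sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2) >
                  a + aa[prev] + 2)) { ok <- TRUE; break }
      }
      if (!ok) next
      placed[i] <- TRUE
      cx[i] <- x; cy[i] <- y; aa[i] <- a; bb[i] <- b
      th[i] <- runif(1, 0, pi)
    }
  }
  keep <- which(placed)
  # --- nucleus label mask
  mask <- matrix(0L, W, H)
  for (i in keep) {
    r <- ceiling(aa[i]) + 1
    xs <- max(1, floor(cx[i]) - r):min(W, ceiling(cx[i]) + r)
    ys <- max(1, floor(cy[i]) - r):min(H, ceiling(cy[i]) + r)
    dx <- xs - cx[i]; dy <- ys - cy[i]
    u <- outer(dx, dy, function(p, q) (p * cos(th[i]) + q * sin(th[i])) / aa[i])
    v <- outer(dx, dy, function(p, q) (-p * sin(th[i]) + q * cos(th[i])) / bb[i])
    inside <- u^2 + v^2 <= 1
    sub <- mask[xs, ys]
    sub[inside] <- cells$cell_id[i]
    mask[xs, ys] <- sub
  }
  # --- channel images
  img <- array(optics$background, dim = c(W, H, length(channels)),
               dimnames = list(NULL, NULL, channels))
  dna <- img[, , "DNA"]
  dna[mask > 0] <- dna[mask > 0] + optics$nucleus_amplitude
  # micronuclei: small DNA bodies, ~5% nuclear area, a few um off the nucleus
  mn_truth <- list()
  if ("micronucleus_count" %in% names(cells)) {
    for (i in keep) {
      k <- cells$micronucleus_count[i]
      if (is.na(k) || k < 1) next
      for (j in seq_len(k)) {
        phi <- runif(1, 0, 2 * pi)
        rb <- ellipse_radius(phi, aa[i], bb[i], th[i])
        d <- runif(1, 2, 5) / px
        x0 <- cx[i] + (rb + d) * cos(phi); y0 <- cy[i] + (rb + d) * sin(phi)
        r_mn <- sqrt(0.05 * cells$nucleus_area[i] / pi) / px
        xs <- max(1, floor(x0 - r_mn)):min(W, ceiling(x0 + r_mn))
        ys <- max(1, floor(y0 - r_mn)):min(H, ceiling(y0 + r_mn))
        disc <- outer(xs - x0, ys - y0, function(p, q) p^2 + q^2) <= r_mn^2
        sub <- dna[xs, ys]; sub[disc] <- sub[disc] + optics$nucleus_amplitude
        dna[xs, ys] <- sub
        mn_truth[[length(mn_truth) + 1L]] <-
          data.frame(cell_id = cells$cell_id[i], x = x0, y = y0, radius_px = r_mn)
      }
    }
  }
  img[, , "DNA"] <- dna
  # --- spots
  spot_truth <- list()
  sig <- optics$spot_sigma_um / px
  for (ch in spot_ch) {
    if (!ch %in% channels) next
    sp <- spots[spots$channel == ch & spots$cell_id %in% cells$cell_id[keep], ,
                drop = FALSE]
    if (!nrow(sp)) next
    layer <- img[, , ch]
    ii <- match(sp$cell_id, cells$cell_id)
    phi <- runif(nrow(sp), 0, 2 * pi)
    rb <- mapply(ellipse_radius, phi, aa[ii], bb[ii], th[ii])
    x0 <- cx[ii] + (rb + sp$envelope_distance / px) * cos(phi)
    y0 <- cy[ii] + (rb + sp$envelope_distance / px) * sin(phi)
    inb <- x0 >= 2 & x0 <= W - 1 & y0 >= 2 & y0 <= H - 1
    r <- ceiling(3 * sig)
    for (s in which(inb)) {   # inlined stamp: avoids copying the layer
      xs <- max(1, floor(x0[s]) - r):min(W, floor(x0[s]) + r + 1)
      ys <- max(1, floor(y0[s]) - r):min(H, floor(y0[s]) + r + 1)
      layer[xs, ys] <- layer[xs, ys] +
        (optics$spot_amplitude * sp$intensity[s]) *
        outer(exp(-(xs - x0[s])^2 / (2 * sig^2)),
              exp(-(ys - y0[s])^2 / (2 * sig^2)))
    }
    img[, , ch] <- layer
    spot_truth[[ch]] <- data.frame(cell_id = sp$cell_id[inb], channel = ch,
                                   x = x0[inb], y = y0[inb],
                                   envelope_distance = sp$envelope_distance[inb])
  }
  # --- MTOC foci
  if (has_mtoc && "gTub" %in% channels) {
    layer <- img[, , "gTub"]
    mt <- list()
    for (i in keep) {
      k <- cells$mtoc_count[i]
      if (is.na(k) || k < 1) next
      for (j in seq_len(k)) {
        phi <- runif(1, 0, 2 * pi)
        rb <- ellipse_radius(phi, aa[i], bb[i], th[i])
        d <- runif(1, 0.5, 2.5) / px
        x0 <- cx[i] + (rb + d) * cos(phi); y0 <- cy[i] + (rb + d) * sin(phi)
        layer <- stamp_gaussian(layer, x0, y0, optics$spot_amplitude * 3,
                                optics$mtoc_sigma_um / px)
        mt[[length(mt) + 1L]] <- data.frame(cell_id = cells$cell_id[i],
                                            x = x0, y = y0)
      }
    }
    img[, , "gTub"] <- layer
    spot_truth[["gTub"]] <- if (length(mt)) do.call(rbind, mt) else NULL
  }
  if (noise) {
    nvals <- rpois(length(img), lambda = img) +
      rnorm(length(img), 0, optics$read_noise_sd)
    img <- array(nvals, dim = dim(img), dimnames = dimnames(img))
  }
  placed_cells <- cells[keep, , drop = FALSE]
  placed_cells$x_px <- cx[keep]; placed_cells$y_px <- cy[keep]
  placed_cells$a_px <- aa[keep]; placed_cells$b_px <- bb[keep]
  placed_cells$theta <- th[keep]
  sp_all <- spot_truth[spot_ch[spot_ch %in% names(spot_truth)]]
  sp_all <- if (length(sp_all)) do.call(rbind, sp_all) else
    data.frame(cell_id = integer(), channel = character(), x = numeric(),
               y = numeric(), envelope_distance = numeric())
  rownames(sp_all) <- NULL
  list(image = img,
       truth = list(cells = placed_cells, spots = sp_all,
                    micronuclei = if (length(mn_truth)) do.call(rbind, mn_truth)
                                  else NULL,
                    nucleus_mask = mask, mtoc = spot_truth[["gTub"]]),
       optics = optics)
}
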