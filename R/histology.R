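# Quantification of collagen histology: birefringence colour classes and
# maturity ratio (polarized picrosirius red), fiber-orientation histograms
# with median-peak normalization and the 0 +/- 5 degree alignment fraction,
# and trichrome interstitial-fibrosis fraction.

#' Colour-space decision boundaries for pixel classification
#'
#' Birefringence classes are separated in CIE Lab space: pixels darker
#' than `l_background` are background; the remaining pixels split into
#' orange-red (a* >= `a_split`, mature collagen) and green-yellow
#' (a* < `a_split`, immature collagen). Trichrome classes are separated
#' in RGB: near-white pixels (`min(R,G,B) > rgb_background`) are
#' background; blue pixels satisfy B - R > `blue_margin`; the rest are
#' (red) tissue. The defaults separate the synthetic generator's palettes
#' exactly; calibration against real slides is the user's responsibility.
#'
#' @param l_background L* threshold below which a pixel is background.
#' @param a_split a* boundary between green-yellow and orange-red.
#' @param rgb_background min-channel threshold above which a pixel is
#'   (white) background in trichrome images.
#' @param blue_margin minimum B - R excess for a blue (fibrotic) pixel.
#' @return an object of class `color_thresholds`.
#' @export
color_thresholds <- function(l_background = 18, a_split = 0,
                             rgb_background = 0.88, blue_margin = 0.05) {
  structure(list(l_background = l_background, a_split = a_split,
                 rgb_background = rgb_background, blue_margin = blue_margin),
            class = "color_thresholds")
}

.as_rgb_matrix <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  d <- dim(image)
  matrix(image[, , 1:3], nrow = d[1] * d[2], ncol = 3)
}

#' Classify pixels of a polarized birefringence image
#'
#' Every pixel is assigned exactly one of `background`, `green_yellow`,
#' `orange_red` using Lab-space thresholds.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param thresholds a [color_thresholds].
#' @return character matrix (H x W) of class labels, of class
#'   `birefringence_classmap`.
#' @export
classify_birefringence <- function(image, thresholds = color_thresholds()) {
  d <- dim(image)
  rgb <- .as_rgb_matrix(image)
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  cls <- matrix("background", d[1], d[2])
  fg <- lab[, 1] > thresholds$l_background
  cls[fg & lab[, 2] >= thresholds$a_split] <- "orange_red"
  cls[fg & lab[, 2] < thresholds$a_split] <- "green_yellow"
  structure(cls, class = c("birefringence_classmap", class(cls)))
}

#' Collagen maturity ratio
#'
#' Ratio of orange-red (mature, predominantly type I collagen) to
#' green-yellow (immature, predominantly type III) pixel areas.
#'
#' @param classmap output of [classify_birefringence()].
#' @return dimensionless ratio.
#' @export
maturity_ratio <- function(classmap) {
  n_or <- sum(classmap == "orange_red")
  n_gy <- sum(classmap == "green_yellow")
  if (n_gy == 0) stop("no green-yellow pixels: maturity ratio undefined")
  n_or / n_gy
}

# Zhang-Suen binary thinning (vectorized over the image)
.thin_mask <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1); p6 <- shift(pad, 1, 0); p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      ctr <- pad[2:(h + 1), 2:(w + 1)]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9), as.vector(p2))
      a <- matrix(rowSums(seqs[, 1:8, drop = FALSE] == 0 &
                          seqs[, 2:9, drop = FALSE] == 1), h, w)
      if (pass == 1) {
        cond <- ctr & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- ctr & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        ctr[cond] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- ctr
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# 8-connected component labelling by iterative label propagation (the
# skeleton is one pixel wide, so diagonal connectivity is essential)
.label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  pad <- matrix(0L, h + 2, w + 2)
  repeat {
    pad[2:(h + 1), 2:(w + 1)] <- lab
    mn <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
      upd <- mask & sh > 0L & sh < mn
      mn[upd] <- sh[upd]
    }
    if (identical(mn, lab)) break
    lab <- mn
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Extract per-fiber-segment orientations from a classified image
#'
#' The union of fiber-pixel classes is skeletonized (Zhang-Suen
#' thinning); skeleton junction pixels are removed; the remaining
#' branches are labelled as segments and the orientation of each segment
#' of sufficient length is taken from the principal axis of its pixel
#' coordinates. Angles are measured from the image x-axis,
#' counter-clockwise, in (-90, 90] degrees.
#'
#' @param classmap a `birefringence_classmap`, or a logical fiber mask.
#' @param min_length minimum segment pixel count.
#' @param min_segments minimum number of segments expected for downstream
#'   statistics; a warning is issued below this count.
#' @return numeric vector of segment angles (degrees), with attribute
#'   `n_segments`.
#' @export
fiber_orientations <- function(classmap, min_length = 6, min_segments = 100) {
  mask <- if (is.logical(classmap)) classmap
          else classmap %in% c("orange_red", "green_yellow")
  mask <- matrix(mask, nrow = nrow(classmap), ncol = ncol(classmap))
  skel <- .thin_mask(mask)
  # remove junctions: skeleton pixels with 3+ skeleton neighbours
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- skel
  nb <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  branches <- skel & nb <= 2
  lab <- .label8(branches)
  if (max(lab) == 0) return(structure(numeric(0), n_segments = 0L))
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  angles <- vapply(split(seq_along(idx), lab[idx]), function(ii) {
    if (length(ii) < min_length) return(NA_real_)
    x <- cols[ii]; y <- -rows[ii] # y up
    cx <- x - mean(x); cy <- y - mean(y)
    cv <- matrix(c(sum(cx * cx), sum(cx * cy), sum(cx * cy), sum(cy * cy)), 2)
    v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    a <- atan2(v[2], v[1]) * 180 / pi
    a <- ((a + 90) %% 180) - 90
    if (a <= -90) a + 180 else a
  }, numeric(1))
  angles <- angles[!is.na(angles)]
  if (length(angles) < min_segments)
    warning(sprintf("only %d fiber segments detected (expected >= %d)",
                    length(angles), min_segments))
  structure(unname(angles), n_segments = length(angles))
}

#' Bin fiber angles into a 5-degree orientation histogram
#'
#' 36 bins over (-90, 90] degrees; the total count equals the number of
#' angles.
#'
#' @param angles numeric vector of angles (degrees), any representative
#'   of the 180-degree periodic orientation.
#' @param bin_width bin width in degrees (must divide 180).
#' @return an object of class `orientation_histogram`: list with
#'   `counts`, `breaks`, `mid`, `normalized`, `shift_deg`.
#' @export
orientation_histogram <- function(angles, bin_width = 5) {
  stopifnot(180 %% bin_width == 0)
  a <- ((angles + 90) %% 180) - 90
  a[a <= -90] <- a[a <= -90] + 180
  breaks <- seq(-90, 90, by = bin_width)
  # bins are half-open (lo, hi]
  bin <- ceiling((a + 90) / bin_width)
  bin[bin < 1] <- 1
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  structure(list(counts = counts, breaks = breaks,
                 mid = breaks[-1] - bin_width / 2,
                 normalized = FALSE, shift_deg = 0),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("Orientation histogram: %d angles in %d bins of %g deg%s\n",
              sum(x$counts), length(x$counts), diff(x$breaks[1:2]),
              if (x$normalized)
                sprintf(" (peak-normalized, shift %g deg)", x$shift_deg)
              else ""))
  invisible(x)
}

#' @export
plot.orientation_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$mid, xlab = "orientation (deg)",
                    ylab = "count", ...)
  invisible(x)
}

# circular median direction of binned axial data (doubled-angle circle)
.circular_median_bin <- function(hist) {
  th <- 2 * hist$mid * pi / 180
  s <- sum(hist$counts * sin(th)); cc <- sum(hist$counts * cos(th))
  med <- atan2(s, cc) / 2 * 180 / pi
  which.min(pmin(abs(hist$mid - med), 180 - abs(hist$mid - med)))
}

#' Shift an orientation histogram so its median peak sits at 0 degrees
#'
#' The peak bin of the histogram is found; ties between equal-count bins
#' are broken first by the larger circularly 3-bin-smoothed count, then
#' by nearness to the circular median of the data (the readings coincide
#' on unimodal data). All bins are then shifted circularly by the same
#' amount so the peak bin becomes the bin just right of 0 degrees.
#' Counts are preserved and the operation is idempotent.
#'
#' @param hist an `orientation_histogram`.
#' @return the shifted histogram (`normalized = TRUE`).
#' @export
normalize_peak <- function(hist) {
  stopifnot(inherits(hist, "orientation_histogram"))
  n <- length(hist$counts)
  peak_bins <- which(hist$counts == max(hist$counts))
  if (length(peak_bins) > 1L) {
    sm <- (hist$counts + hist$counts[c(n, 1:(n - 1))] +
           hist$counts[c(2:n, 1)]) / 3
    peak_bins <- peak_bins[sm[peak_bins] == max(sm[peak_bins])]
  }
  peak <- if (length(peak_bins) == 1L) peak_bins else {
    med_bin <- .circular_median_bin(hist)
    d <- pmin(abs(peak_bins - med_bin), n - abs(peak_bins - med_bin))
    peak_bins[which.min(d)]
  }
  target <- n / 2 + 1L # bin (0, bin_width]
  k <- (target - peak) %% n
  idx <- ((seq_len(n) - 1L - k) %% n) + 1L
  out <- hist
  out$counts <- hist$counts[idx]
  out$normalized <- TRUE
  out$shift_deg <- hist$shift_deg + k * diff(hist$breaks[1:2])
  out
}

#' Alignment fraction within 0 +/- 5 degrees
#'
#' Percentage of fibers whose (peak-normalized) orientation falls within
#' `window_deg` of 0 degrees; with 5-degree bins and the default window
#' this is the mass of the two central bins, (-5, 0] and (0, 5].
#'
#' @param hist a peak-normalized `orientation_histogram`.
#' @param window_deg half-width of the window (degrees); the fraction
#'   counts the bins lying fully inside (-window_deg, window_deg).
#' @return percent.
#' @export
alignment_fraction <- function(hist, window_deg = 5) {
  stopifnot(inherits(hist, "orientation_histogram"))
  if (!hist$normalized)
    warning("histogram is not peak-normalized; fraction is about raw 0 deg")
  tot <- sum(hist$counts)
  if (tot == 0) stop("empty histogram")
  sel <- hist$mid > -window_deg & hist$mid < window_deg
  100 * sum(hist$counts[sel]) / tot
}

#' Interstitial fibrosis fraction of a trichrome image
#'
#' Percentage of blue (fibrotic) pixels among tissue pixels; near-white
#' background pixels are excluded.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param thresholds a [color_thresholds].
#' @return percent.
#' @export
fibrosis_fraction <- function(image, thresholds = color_thresholds()) {
  rgb <- .as_rgb_matrix(image)
  bg <- pmin(rgb[, 1], rgb[, 2], rgb[, 3]) > thresholds$rgb_background
  blue <- !bg & (rgb[, 3] - rgb[, 1] > thresholds$blue_margin)
  tissue <- !bg
  if (!any(tissue)) stop("no tissue pixels detected")
  100 * sum(blue) / sum(tissue)
}

#' Full fiber-image analysis
#'
#' Classifies the image, computes the maturity ratio, extracts fiber
#' orientations, and returns the peak-normalized histogram and alignment
#' fraction.
#'
#' @param image H x W x 3 RGB array.
#' @param thresholds a [color_thresholds].
#' @param min_segments passed to [fiber_orientations()].
#' @return list: `classmap`, `maturity_ratio`, `angles`, `histogram`
#'   (normalized), `alignment_percent`.
#' @export
analyze_fiber_image <- function(image, thresholds = color_thresholds(),
                                min_segments = 100) {
  cm <- classify_birefringence(image, thresholds)
  ratio <- maturity_ratio(cm)
  ang <- fiber_orientations(cm, min_segments = min_segments)
  hist <- normalize_peak(orientation_histogram(ang))
  list(classmap = cm, maturity_ratio = ratio, angles = ang,
       histogram = hist, alignment_percent = alignment_fraction(hist))
}

#' Per-animal averaging of image statistics
#'
#' Averages per-image statistics (maturity ratio, alignment percent or
#' fibrosis percent) across the images of one animal, mirroring the
#' several-images-per-animal design of histological quantification.
#'
#' @param values numeric vector of per-image statistics.
#' @return their mean.
#' @export
batch_mean <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  mean(values)
}
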