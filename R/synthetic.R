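# Ground-truthed synthetic histology image generation: polarized
# picrosirius-red-like fiber images (two birefringence colour classes,
# von Mises orientation field) and Masson's-trichrome-like fibrosis fields.

# evaluate expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric `seed` is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution on
# the full circle; kappa = 0 falls back to the uniform distribution.
.rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ce <- kappa * (r - f)
    if (ce * (2 - ce) - u2 > 0 || log(ce / u2) + 1 - ce >= 0) {
      got <- got + 1L
      out[got] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
    }
  }
  out
}

#' Sample axial fiber angles from a von Mises orientation distribution
#'
#' Fiber orientations are axial (defined modulo 180 degrees): the von
#' Mises distribution is applied on the doubled-angle circle and the
#' result halved, giving angles in (-90, 90] degrees. `kappa = 0` gives
#' the uniform orientation distribution.
#'
#' @param n number of angles.
#' @param mu mean orientation (degrees).
#' @param kappa concentration (>= 0) on the doubled circle.
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @return numeric vector of angles in (-90, 90] degrees.
#' @export
#' @examples
#' a <- gen_angle_sample(200, mu = 30, kappa = 8, seed = 1)
gen_angle_sample <- function(n, mu = 0, kappa = 2, seed) {
  stopifnot(n >= 0, kappa >= 0)
  .with_seed(seed, {
    phi <- .rvonmises(n, 2 * mu * pi / 180, kappa)
    ang <- (phi / 2) * 180 / pi
    ang <- ((ang + 90) %% 180) - 90
    ang[ang <= -90] <- ang[ang <= -90] + 180
    ang
  })
}

#' Specification of a synthetic polarized fiber image
#'
#' @param size image size in pixels, c(height, width).
#' @param pixel_size physical pixel size (um/px), bookkeeping only.
#' @param n_fibers number of fiber strokes.
#' @param mu,kappa axial von Mises orientation parameters (degrees, -).
#' @param length_mean,length_sd fiber length distribution (px).
#' @param width fiber stroke width (px).
#' @param class_mix fraction of fibers in the orange-red (mature collagen)
#'   class; the remainder are green-yellow (immature).
#' @param noise additive Gaussian pixel noise sd.
#' @param seed RNG seed (required).
#' @return an object of class `fiber_image_spec`.
#' @export
fiber_image_spec <- function(size = c(384, 384), pixel_size = 1,
                             n_fibers = 400, mu = 0, kappa = 2,
                             length_mean = 60, length_sd = 12, width = 3,
                             class_mix = 0.5, noise = 0.01, seed) {
  stopifnot(length(size) == 2, all(size > 16), n_fibers >= 0, kappa >= 0,
            class_mix >= 0, class_mix <= 1, width > 0, noise >= 0)
  if (missing(seed)) stop("`seed` is required")
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_fibers = as.integer(n_fibers), mu = mu, kappa = kappa,
                 length_mean = length_mean, length_sd = length_sd,
                 width = width, class_mix = class_mix, noise = noise,
                 seed = seed),
            class = "fiber_image_spec")
}

# palette shared by the generator and the default classifier thresholds
.palette_birefringence <- function() {
  # the two classes are luminance-matched (L* ~ 55) so that intensity
  # thresholds trim the anti-aliased stroke fringes of both classes alike
  list(orange_red = c(0.90, 0.32, 0.06),
       green_yellow = c(0.29, 0.59, 0.07),
       background = c(0.02, 0.02, 0.03))
}

.palette_trichrome <- function() {
  list(blue = c(0.25, 0.32, 0.75),
       tissue = c(0.82, 0.32, 0.36),
       background = c(0.96, 0.96, 0.97))
}

#' Generate a synthetic polarized picrosirius-red-like image
#'
#' Fibers are drawn as anti-aliased elongated strokes on a dark
#' background; each fiber carries a ground-truth angle (axial von Mises)
#' and a colour class (orange-red vs green-yellow birefringence).
#' Deterministic given the spec's seed.
#'
#' @param spec a [fiber_image_spec].
#' @return list with `image` (H x W x 3 array in [0, 1]), `truth`
#'   (data.frame: id, x, y, angle_deg, length, class) and `class_pixels`
#'   (H x W integer ground-truth map: 0 background, 1 orange-red,
#'   2 green-yellow, by dominant stroke coverage).
#' @export
gen_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_image_spec"))
  pal <- .palette_birefringence()
  h <- spec$size[1]; w <- spec$size[2]
  .with_seed(spec$seed, {
    img <- array(rep(pal$background, each = h * w), c(h, w, 3))
    winner <- matrix(0L, h, w)
    ang <- gen_angle_sample(spec$n_fibers, spec$mu, spec$kappa,
                            seed = sample.int(.Machine$integer.max, 1))
    n <- spec$n_fibers
    cx <- runif(n, 1, w); cy <- runif(n, 1, h)
    len <- pmax(8, rnorm(n, spec$length_mean, spec$length_sd))
    cls <- ifelse(runif(n) < spec$class_mix, "orange_red", "green_yellow")
    bright <- runif(n, 0.85, 1)
    half_w <- spec$width / 2
    for (i in seq_len(n)) {
      th <- ang[i] * pi / 180
      dx <- cos(th); dy <- -sin(th) # image rows grow downward
      x1 <- cx[i] - dx * len[i] / 2; y1 <- cy[i] - dy * len[i] / 2
      x2 <- cx[i] + dx * len[i] / 2; y2 <- cy[i] + dy * len[i] / 2
      r0 <- max(1L, floor(min(y1, y2) - half_w - 1))
      r1 <- min(h, ceiling(max(y1, y2) + half_w + 1))
      c0 <- max(1L, floor(min(x1, x2) - half_w - 1))
      c1 <- min(w, ceiling(max(x1, x2) + half_w + 1))
      if (r0 > r1 || c0 > c1) next
      xs <- c0:c1; ys <- r0:r1
      px <- matrix(rep(xs, each = length(ys)), length(ys))
      py <- matrix(rep(ys, length(xs)), length(ys))
      # distance from pixel to segment
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx^2 + vy^2
      t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
      d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
      cov <- pmin(1, pmax(0, half_w + 0.5 - d))
      if (all(cov == 0)) next
      col <- pal[[cls[i]]] * bright[i]
      for (ch in 1:3) { # alpha-over compositing, later strokes on top
        sub <- img[ys, xs, ch]
        img[ys, xs, ch] <- sub * (1 - cov) + cov * col[ch]
      }
      upd <- cov > 0.5
      if (any(upd)) {
        sub_w <- winner[ys, xs]
        sub_w[upd] <- if (cls[i] == "orange_red") 1L else 2L
        winner[ys, xs] <- sub_w
      }
    }
    if (spec$noise > 0) {
      img <- img + array(rnorm(h * w * 3, 0, spec$noise), c(h, w, 3))
      img[] <- pmin(1, pmax(0, img))
    }
    list(image = img,
         truth = data.frame(id = seq_len(n), x = cx, y = cy,
                            angle_deg = ang, length = len, class = cls),
         class_pixels = winner)
  })
}

#' Specification of a synthetic trichrome-like fibrosis image
#'
#' @param size image size (px).
#' @param fibrosis_fraction target blue-area fraction of the tissue.
#' @param blob_scale correlation length of the fibrotic regions (px).
#' @param noise additive Gaussian pixel noise sd.
#' @param seed RNG seed (required).
#' @return an object of class `trichrome_image_spec`.
#' @export
trichrome_image_spec <- function(size = c(256, 256), fibrosis_fraction = 0.25,
                                 blob_scale = 12, noise = 0.015, seed) {
  stopifnot(length(size) == 2, fibrosis_fraction >= 0, fibrosis_fraction <= 1,
            blob_scale > 0, noise >= 0)
  if (missing(seed)) stop("`seed` is required")
  structure(list(size = as.integer(size),
                 fibrosis_fraction = fibrosis_fraction,
                 blob_scale = blob_scale, noise = noise, seed = seed),
            class = "trichrome_image_spec")
}

#' Generate a synthetic Masson's-trichrome-like image
#'
#' A smooth Gaussian random field is thresholded at the quantile matching
#' the target fibrosis fraction inside an elliptical tissue region (blue
#' fibrotic pixels vs red muscle); outside the ellipse the image is
#' near-white background. The realized blue fraction matches the target
#' exactly at the pixel level (before noise).
#'
#' @param spec a [trichrome_image_spec].
#' @return list with `image` (H x W x 3 array), `truth_fraction` (the
#'   realized blue/tissue pixel fraction) and `tissue_mask`.
#' @export
gen_trichrome_image <- function(spec) {
  stopifnot(inherits(spec, "trichrome_image_spec"))
  pal <- .palette_trichrome()
  h <- spec$size[1]; w <- spec$size[2]
  .with_seed(spec$seed, {
    ys <- matrix(rep(seq_len(h), w), h)
    xs <- matrix(rep(seq_len(w), each = h), h)
    tissue <- ((xs - w / 2) / (0.48 * w))^2 + ((ys - h / 2) / (0.48 * h))^2 <= 1
    field <- matrix(rnorm(h * w), h, w)
    field <- as.matrix(EBImage::gblur(EBImage::Image(field),
                                      sigma = spec$blob_scale))
    nblue <- round(spec$fibrosis_fraction * sum(tissue))
    blue <- matrix(FALSE, h, w)
    if (nblue > 0) {
      thr <- sort(field[tissue], decreasing = TRUE)[nblue]
      blue <- tissue & field >= thr
    }
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(pal$background[ch], h, w)
      plane[tissue] <- pal$tissue[ch]
      plane[blue] <- pal$blue[ch]
      img[, , ch] <- plane
    }
    if (spec$noise > 0) {
      img <- img + array(rnorm(h * w * 3, 0, spec$noise), c(h, w, 3))
      img[] <- pmin(1, pmax(0, img))
    }
    list(image = img, truth_fraction = sum(blue) / sum(tissue),
         tissue_mask = tissue)
  })
}

#' Write an RGB array to a PNG file
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read an RGB image from a PNG file
#'
#' @param path input path.
#' @return H x W x 3 array in [0, 1].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
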