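#' Geometry parameters of the truncated-ellipsoid left ventricle
#'
#' The reference geometry is a truncated prolate spheroid: endocardial
#' semi-axes (`endo_short_radius` equatorial, `endo_long_radius` apex-base),
#' a uniform wall thickness added outward, truncated by a flat basal plane.
#' `truncation_fraction` is the fraction of the full long axis (2c, measured
#' from the apex) retained below the base, so the basal plane sits at
#' z = c (2 f - 1) with the apex at z = -c. The wall is divided into
#' `n_layers` transmural layers carrying per-layer helical fiber angles in
#' the local circumferential-longitudinal plane (0 deg = circumferential),
#' listed endocardium to epicardium.
#'
#' Default dimensions are a human-scale ventricle frozen after a one-time
#' calibration of the healthy two-phase protocol (see the methods vignette).
#'
#' @param endo_short_radius endocardial equatorial radius a (mm).
#' @param endo_long_radius endocardial long semi-axis c (mm).
#' @param wall_thickness wall thickness (mm).
#' @param truncation_fraction fraction of the long axis retained (0, 1].
#' @param n_circ,n_long circumferential / longitudinal element counts.
#' @param n_layers transmural layers.
#' @param fiber_angles per-layer helix angles (deg), endo to epi.
#' @return an object of class `lv_geometry`.
#' @export
lv_geometry <- function(endo_short_radius = 20, endo_long_radius = 48,
                        wall_thickness = 19, truncation_fraction = 0.75,
                        n_circ = 20, n_long = 12, n_layers = 3,
                        fiber_angles = c(60, 0, -60)) {
  stopifnot(endo_short_radius > 0, endo_long_radius > 0, wall_thickness > 0,
            truncation_fraction > 0, truncation_fraction <= 1,
            n_circ >= 4, n_long >= 2, n_layers >= 1,
            length(fiber_angles) == n_layers)
  structure(list(endo_short_radius = endo_short_radius,
                 endo_long_radius = endo_long_radius,
                 wall_thickness = wall_thickness,
                 truncation_fraction = truncation_fraction,
                 n_circ = as.integer(n_circ), n_long = as.integer(n_long),
                 n_layers = as.integer(n_layers),
                 fiber_angles = fiber_angles),
            class = "lv_geometry")
}

#' Region specification: infarct zone, border zone, patch
#'
#' The infarct zone (IZ) is a contiguous anterior sector covering
#' `infarct_fraction` of the reference wall area, thinned to
#' `thinning_ratio` of the original thickness (epicardial surface moved
#' inward, endocardial cavity preserved). The patch window covers
#' `patch_coverage` of the wall; patch-covered non-IZ wall is labelled BZ,
#' the remainder RZ. When `patch` is TRUE one element layer of patch
#' elements is extruded from the epicardium over the patch window, sharing
#' nodes (perfect bonding).
#'
#' @param infarct_fraction wall-area fraction of the IZ.
#' @param thinning_ratio IZ thickness ratio in (0, 1].
#' @param patch_coverage wall-area fraction under the patch window.
#' @param patch_thickness patch layer thickness (mm).
#' @param patch logical: extrude patch elements.
#' @param infarct_center angular position of the IZ centre (rad) on the
#'   anterior free wall.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(infarct_fraction = 0.134, thinning_ratio = 1 / 3,
                        patch_coverage = 0.228, patch_thickness = 1,
                        patch = FALSE, infarct_center = 0) {
  stopifnot(infarct_fraction >= 0, patch_coverage <= 1,
            thinning_ratio > 0, thinning_ratio <= 1, patch_thickness > 0)
  if (infarct_fraction > patch_coverage)
    stop("infarct_fraction must not exceed patch_coverage")
  structure(list(infarct_fraction = infarct_fraction,
                 thinning_ratio = thinning_ratio,
                 patch_coverage = patch_coverage,
                 patch_thickness = patch_thickness,
                 patch = patch, infarct_center = infarct_center),
            class = "region_spec")
}

# analytic volume of the truncated spheroid cavity (mm^3):
# V = int_{-c}^{zb} pi a^2 (1 - z^2/c^2) dz
truncated_spheroid_volume <- function(a, c, truncation_fraction) {
  zb <- c * (2 * truncation_fraction - 1)
  pi * a^2 * ((zb + c) - (zb^3 + c^3) / (3 * c^2))
}

#' Build the left-ventricular hexahedral mesh
#'
#' Nodes lie on nested spheroids (endocardium to epicardium); the apex strip
#' uses collapsed hexahedra sharing the apical node of each transmural
#' level. Per-element fiber frames are computed at element centroids:
#' axis 1 = fiber (helix angle of the element's layer), axis 2 = in-plane
#' cross-fiber, axis 3 = outward transmural.
#'
#' @param geom an [lv_geometry] object.
#' @return an object of class `lv_mesh` with node coordinates (mm), element
#'   connectivity, per-element layer/region/fiber data and facet sets.
#' @export
build_lv_mesh <- function(geom) {
  stopifnot(inherits(geom, "lv_geometry"))
  a0 <- geom$endo_short_radius; c0 <- geom$endo_long_radius
  h <- geom$wall_thickness; f <- geom$truncation_fraction
  nc <- geom$n_circ; nl <- geom$n_long; K <- geom$n_layers
  zb <- c0 * (2 * f - 1)
  if (zb >= c0) stop("degenerate truncation")

  tk <- (0:K) / K
  ak <- a0 + tk * h
  ck <- c0 + tk * h
  phi <- 2 * pi * (0:(nc - 1)) / nc
  # place ring nodes at a slightly enlarged equatorial radius so that the
  # inscribed n-gon has the area of the circle it discretizes (makes the
  # discrete cavity volume consistent with the smooth spheroid)
  comp <- sqrt((2 * pi / nc) / sin(2 * pi / nc))

  # node ids: apex nodes 1..K+1 (k = 0..K); ring nodes follow
  apex_id <- function(k) k + 1L
  ring_id <- function(i, j, k) { # i in 0..nc-1 (wraps), j in 1..nl, k in 0..K
    i <- i %% nc
    (K + 1L) + ((j - 1L) * (K + 1L) + k) * nc + i + 1L
  }
  n_nodes <- (K + 1L) + nl * (K + 1L) * nc
  nodes <- matrix(0, n_nodes, 3)
  for (k in 0:K) {
    nodes[apex_id(k), ] <- c(0, 0, -ck[k + 1])
    th_base <- acos(min(1, max(-1, zb / ck[k + 1]))) # polar angle at base
    for (j in 1:nl) {
      th <- pi - (j / nl) * (pi - th_base) # uniform polar-angle spacing
      ct <- cos(th); st <- sin(th)
      for (i in 0:(nc - 1)) {
        nodes[ring_id(i, j, k), ] <- c(comp * ak[k + 1] * st * cos(phi[i + 1]),
                                       comp * ak[k + 1] * st * sin(phi[i + 1]),
                                       ck[k + 1] * ct)
      }
    }
  }

  # elements: column (i, j) x layer l; j = 1 is the collapsed apex strip
  n_elem <- nc * nl * K
  elems <- matrix(0L, n_elem, 8)
  el_layer <- integer(n_elem)
  el_col <- matrix(0L, n_elem, 2) # (i, j) wall column
  e <- 0L
  for (l in 1:K) {
    for (j in 1:nl) {
      for (i in 0:(nc - 1)) {
        e <- e + 1L
        if (j == 1L) {
          lo <- c(apex_id(l - 1L), apex_id(l - 1L),
                  ring_id(i + 1L, 1L, l - 1L), ring_id(i, 1L, l - 1L))
          hi <- c(apex_id(l), apex_id(l),
                  ring_id(i + 1L, 1L, l), ring_id(i, 1L, l))
        } else {
          lo <- c(ring_id(i, j - 1L, l - 1L), ring_id(i + 1L, j - 1L, l - 1L),
                  ring_id(i + 1L, j, l - 1L), ring_id(i, j, l - 1L))
          hi <- c(ring_id(i, j - 1L, l), ring_id(i + 1L, j - 1L, l),
                  ring_id(i + 1L, j, l), ring_id(i, j, l))
        }
        elems[e, ] <- c(lo, hi)
        el_layer[e] <- l
        el_col[e, ] <- c(i, j)
      }
    }
  }

  mesh <- structure(list(
    nodes = nodes, elems = elems, layer = el_layer, column = el_col,
    region = rep("RZ", n_elem),
    fiber = NULL, rot = NULL,
    geom = geom, spec = NULL,
    n_wall_elem = n_elem,
    apex_ids = vapply(0:K, apex_id, integer(1))
  ), class = "lv_mesh")

  mesh <- .mesh_facets(mesh)
  mesh <- .mesh_fibers(mesh)
  ord <- .cpp_min_jacobian(mesh$nodes, mesh$elems)
  if (any(ord <= 0)) stop("mesh contains non-positive element Jacobians")
  mesh
}

# endocardial facets, basal node sets, basal endo ring (ordered)
.mesh_facets <- function(mesh) {
  geom <- mesh$geom
  nc <- geom$n_circ; nl <- geom$n_long; K <- geom$n_layers
  inner <- which(mesh$layer == 1L & seq_len(nrow(mesh$elems)) <= mesh$n_wall_elem)
  # zeta = -1 face of the trilinear hex, ordered so the outward (into-wall)
  # normal of cross(t_xi, t_eta) points from the cavity into the tissue
  ef <- mesh$elems[inner, c(1, 2, 3, 4), drop = FALSE]
  # basal nodes: ring j = nl, all k; basal endo ring: k = 0
  K1 <- K + 1L
  ring0 <- integer(nc)
  base_nodes <- integer(0)
  for (k in 0:K) {
    ids <- (K1) + ((nl - 1L) * K1 + k) * nc + (0:(nc - 1)) + 1L
    base_nodes <- c(base_nodes, ids)
    if (k == 0) ring0 <- ids
    if (k == K) base_epi_ring <- ids
  }
  mesh$endo_facets <- ef
  mesh$base_nodes <- base_nodes
  mesh$basal_endo_ring <- ring0
  mesh$basal_epi_ring <- base_epi_ring
  mesh
}

# per-element fiber frame from centroid position
.mesh_fibers <- function(mesh) {
  geom <- mesh$geom
  n_elem <- nrow(mesh$elems)
  fiber <- matrix(0, n_elem, 3)
  rot <- matrix(0, n_elem, 9)
  angs <- geom$fiber_angles * pi / 180
  for (e in seq_len(n_elem)) {
    xc <- colMeans(mesh$nodes[mesh$elems[e, ], ])
    phi <- atan2(xc[2], xc[1])
    ec <- c(-sin(phi), cos(phi), 0)
    # longitudinal direction: tangent to the spheroid meridian, toward base
    rad <- sqrt(xc[1]^2 + xc[2]^2)
    er <- c(cos(phi), sin(phi), 0)
    a <- geom$endo_short_radius; cc <- geom$endo_long_radius
    # meridian tangent of x = a sin(th) er + c cos(th) ez, d/d(-th):
    th <- atan2(rad / a, xc[3] / cc)
    el <- -(a * cos(th) * er - cc * sin(th) * c(0, 0, 1))
    el <- el / sqrt(sum(el^2))
    if (el[3] < 0) el <- -el # toward base (+z)
    n_out <- c(ec[2] * el[3] - ec[3] * el[2],
               ec[3] * el[1] - ec[1] * el[3],
               ec[1] * el[2] - ec[2] * el[1])
    if (sum(n_out * c(er[1], er[2], 0.2)) < 0) n_out <- -n_out
    n_out <- n_out / sqrt(sum(n_out^2))
    lay <- mesh$layer[e]
    alpha <- if (lay <= length(angs)) angs[lay] else 0 # patch layer: 0
    a1 <- cos(alpha) * ec + sin(alpha) * el
    a1 <- a1 - sum(a1 * n_out) * n_out
    a1 <- a1 / sqrt(sum(a1^2))
    a2 <- c(n_out[2] * a1[3] - n_out[3] * a1[2],
            n_out[3] * a1[1] - n_out[1] * a1[3],
            n_out[1] * a1[2] - n_out[2] * a1[1])
    fiber[e, ] <- a1
    rot[e, ] <- c(a1, a2, n_out) # column-major [a1 a2 a3]
  }
  mesh$fiber <- fiber
  mesh$rot <- rot
  mesh
}

# reference mid-wall area of each wall column (i, j), as a matrix [nc x nl]
.column_areas <- function(mesh) {
  geom <- mesh$geom
  nc <- geom$n_circ; nl <- geom$n_long
  area <- matrix(0, nc, nl)
  first_layer <- which(mesh$layer == 1L)
  for (e in first_layer) {
    quad_lo <- mesh$nodes[mesh$elems[e, 1:4], ] # endo face
    # mid-wall approximated by the endo face of layer 1 scaled to mid radius;
    # endo-face area is adequate for relative fractions
    p <- quad_lo
    v1 <- p[3, ] - p[1, ]; v2 <- p[4, ] - p[2, ]
    a2 <- 0.5 * sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                           v1[3] * v2[1] - v1[1] * v2[3],
                           v1[1] * v2[2] - v1[2] * v2[1])^2))
    ij <- mesh$column[e, ]
    area[ij[1] + 1L, ij[2]] <- a2
  }
  area
}

# pick a contiguous centred (i, j) window whose area fraction is closest to
# `target`; returns list(cols = logical [nc x nl] mask, frac)
.pick_window <- function(area, target, i_center, j_center,
                         min_ni = 1L, min_nj = 1L) {
  nc <- nrow(area); nl <- ncol(area)
  tot <- sum(area)
  best <- NULL
  for (ni in max(1L, min_ni):nc) {
    for (nj in max(1L, min_nj):nl) {
      is <- (i_center - (ni - 1L) %/% 2L + 0:(ni - 1L)) %% nc + 1L
      j0 <- j_center - (nj - 1L) %/% 2L
      j0 <- max(1L, min(j0, nl - nj + 1L))
      js <- j0:(j0 + nj - 1L)
      fr <- sum(area[is, js]) / tot
      score <- abs(fr - target) + 1e-4 * abs(ni - 2 * nj)
      if (is.null(best) || score < best$score)
        best <- list(is = is, js = js, frac = fr, score = score,
                     ni = ni, nj = nj)
    }
  }
  mask <- matrix(FALSE, nc, nl)
  mask[best$is, best$js] <- TRUE
  list(mask = mask, frac = best$frac, is = best$is, js = best$js)
}

#' Assign infarct / border / remote regions and apply infarct thinning
#'
#' Labels a contiguous anterior sector of wall-area fraction
#' `infarct_fraction` as IZ and moves its epicardial-side nodes inward so
#' the local thickness becomes `thinning_ratio` of the original (scaling
#' each transmural node line about its endocardial node, so the cavity is
#' preserved). Patch-covered non-IZ wall is labelled BZ, the remainder RZ.
#' With `patch = TRUE`, one layer of patch elements is extruded outward
#' from the (possibly thinned) epicardium over the patch window.
#'
#' @param mesh an [lv_mesh] from [build_lv_mesh()].
#' @param spec a [region_spec].
#' @return the mesh with `region` labels, thinned nodes, and (optionally)
#'   patch elements appended.
#' @export
assign_regions <- function(mesh, spec) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(spec, "region_spec"))
  if (!is.null(mesh$spec)) stop("regions already assigned to this mesh")
  geom <- mesh$geom
  nc <- geom$n_circ; nl <- geom$n_long; K <- geom$n_layers
  mesh$spec <- spec
  if (spec$infarct_fraction == 0 && !spec$patch && spec$patch_coverage == 0)
    return(mesh)

  area <- .column_areas(mesh)
  i_center <- (round(spec$infarct_center / (2 * pi) * nc)) %% nc + 0L
  j_center <- as.integer(round(0.55 * nl))

  win_iz <- if (spec$infarct_fraction > 0) {
    .pick_window(area, spec$infarct_fraction, i_center, j_center)
  } else NULL
  win_patch <- .pick_window(area, spec$patch_coverage, i_center, j_center,
                            min_ni = if (is.null(win_iz)) 1L else length(win_iz$is),
                            min_nj = if (is.null(win_iz)) 1L else length(win_iz$js))
  if (!is.null(win_iz)) # guarantee containment
    win_patch$mask <- win_patch$mask | win_iz$mask

  col_region <- matrix("RZ", nc, nl)
  if (spec$patch_coverage > 0) col_region[win_patch$mask] <- "BZ"
  if (!is.null(win_iz)) col_region[win_iz$mask] <- "IZ"

  for (e in seq_len(mesh$n_wall_elem)) {
    ij <- mesh$column[e, ]
    mesh$region[e] <- col_region[ij[1] + 1L, ij[2]]
  }

  # --- thinning: nodes adjacent to any IZ column are scaled about their
  #     endocardial node so thickness -> ratio * original
  if (!is.null(win_iz) && spec$thinning_ratio < 1) {
    iz_cols <- which(col_region == "IZ", arr.ind = TRUE)
    thin_vert <- matrix(FALSE, nc, nl + 1L) # ring vertices (i, j), j in 0..nl
    for (r in seq_len(nrow(iz_cols))) {
      i <- iz_cols[r, 1] - 1L; j <- iz_cols[r, 2]
      for (di in 0:1) for (dj in 0:1)
        thin_vert[(i + di) %% nc + 1L, j - 1L + dj + 1L] <- TRUE
    }
    K1 <- K + 1L
    ring_id <- function(i, j, k) (K1) + ((j - 1L) * K1 + k) * nc + (i %% nc) + 1L
    for (i in 0:(nc - 1)) for (j in 1:nl) {
      if (!thin_vert[i + 1L, j + 1L]) next
      p0 <- mesh$nodes[ring_id(i, j, 0L), ]
      for (k in 1:K) {
        id <- ring_id(i, j, k)
        mesh$nodes[id, ] <- p0 + spec$thinning_ratio * (mesh$nodes[id, ] - p0)
      }
    }
    ord <- .cpp_min_jacobian(mesh$nodes, mesh$elems)
    if (any(ord <= 0)) stop("infarct thinning produced inverted elements")
    mesh <- .mesh_fibers(mesh) # centroids moved
  }

  # --- patch extrusion over the patch window (IZ + BZ columns)
  if (spec$patch && spec$patch_coverage > 0) {
    K1 <- K + 1L
    ring_id <- function(i, j, k) (K1) + ((j - 1L) * K1 + k) * nc + (i %% nc) + 1L
    patch_cols <- which(matrix(col_region %in% c("IZ", "BZ"),
                               nc, nl), arr.ind = TRUE)
    pv <- matrix(FALSE, nc, nl + 1L)
    for (r in seq_len(nrow(patch_cols))) {
      i <- patch_cols[r, 1] - 1L; j <- patch_cols[r, 2]
      for (di in 0:1) for (dj in 0:1)
        pv[(i + di) %% nc + 1L, j - 1L + dj + 1L] <- TRUE
    }
    apex_in_patch <- any(pv[, 1])
    new_id <- matrix(0L, nc, nl + 1L)
    nn <- nrow(mesh$nodes)
    add <- list()
    epi_of <- function(i, j) if (j == 0L) mesh$apex_ids[K1] else ring_id(i, j, K)
    endo_of <- function(i, j) if (j == 0L) mesh$apex_ids[1L] else ring_id(i, j, 0L)
    apex_new <- 0L
    for (i in 0:(nc - 1)) for (j in 0:nl) {
      if (!pv[i + 1L, j + 1L]) next
      if (j == 0L && apex_new > 0L) { new_id[i + 1L, 1L] <- apex_new; next }
      pe <- mesh$nodes[epi_of(i, j), ]
      p0 <- mesh$nodes[endo_of(i, j), ]
      nrm <- pe - p0; nrm <- nrm / sqrt(sum(nrm^2))
      nn <- nn + 1L
      add[[length(add) + 1L]] <- pe + spec$patch_thickness * nrm
      new_id[i + 1L, j + 1L] <- nn
      if (j == 0L) apex_new <- nn
    }
    mesh$nodes <- rbind(mesh$nodes, do.call(rbind, add))
    pe_list <- list(); pc_list <- list()
    for (r in seq_len(nrow(patch_cols))) {
      i <- patch_cols[r, 1] - 1L; j <- patch_cols[r, 2]
      if (j == 1L) {
        lo <- c(epi_of(0L, 0L), epi_of(0L, 0L), epi_of(i + 1L, 1L), epi_of(i, 1L))
        hi <- c(new_id[1L, 1L], new_id[1L, 1L],
                new_id[(i + 1L) %% nc + 1L, 2L], new_id[i + 1L, 2L])
      } else {
        lo <- c(epi_of(i, j - 1L), epi_of(i + 1L, j - 1L),
                epi_of(i + 1L, j), epi_of(i, j))
        hi <- c(new_id[i + 1L, j], new_id[(i + 1L) %% nc + 1L, j],
                new_id[(i + 1L) %% nc + 1L, j + 1L], new_id[i + 1L, j + 1L])
      }
      pe_list[[length(pe_list) + 1L]] <- c(lo, hi)
      pc_list[[length(pc_list) + 1L]] <- c(i, j)
    }
    pe_mat <- do.call(rbind, pe_list)
    mesh$elems <- rbind(mesh$elems, pe_mat)
    mesh$layer <- c(mesh$layer, rep(K + 1L, nrow(pe_mat)))
    mesh$region <- c(mesh$region, rep("patch", nrow(pe_mat)))
    mesh$column <- rbind(mesh$column, do.call(rbind, pc_list))
    mesh <- .mesh_fibers(mesh) # recompute, includes patch elements
    ord <- .cpp_min_jacobian(mesh$nodes, mesh$elems)
    if (any(ord <= 0)) stop("patch extrusion produced inverted elements")
  }
  mesh
}

#' Deformed endocardial cavity volume
#'
#' Divergence-theorem volume of the endocardial surface closed by the basal
#' plane: V = (1/3) sum over closed-surface triangles of x1 . (x2 x x3)/2,
#' evaluated on deformed coordinates. Zero displacement returns the
#' reference cavity volume.
#'
#' @param mesh an [lv_mesh].
#' @param displacement N x 3 matrix of nodal displacements (mm) or NULL.
#' @return cavity volume (ml).
#' @export
cavity_volume <- function(mesh, displacement = NULL) {
  x <- mesh$nodes
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    stopifnot(nrow(displacement) >= max(mesh$endo_facets))
    x <- x + displacement[seq_len(nrow(x)), , drop = FALSE]
  }
  tris <- rbind(mesh$endo_facets[, c(1, 2, 3)], mesh$endo_facets[, c(1, 3, 4)])
  # basal cap: fan from the ring centroid
  ring <- mesh$basal_endo_ring
  ctr <- colMeans(x[ring, , drop = FALSE])
  v <- 0
  p1 <- x[tris[, 1], , drop = FALSE]
  p2 <- x[tris[, 2], , drop = FALSE]
  p3 <- x[tris[, 3], , drop = FALSE]
  v <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
           p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
           p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  nring <- length(ring)
  for (i in seq_len(nring)) {
    q1 <- x[ring[i], ]; q2 <- x[ring[i %% nring + 1L], ]
    v <- v + sum(ctr * c(q1[2] * q2[3] - q1[3] * q2[2],
                         q1[3] * q2[1] - q1[1] * q2[3],
                         q1[1] * q2[2] - q1[2] * q2[1])) / 6
  }
  abs(v) / 1000 # mm^3 -> ml
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV mesh: %d nodes, %d elements (%d wall + %d patch), %d layers\n",
              nrow(x$nodes), nrow(x$elems), x$n_wall_elem,
              nrow(x$elems) - x$n_wall_elem, x$geom$n_layers))
  if (!is.null(x$spec)) {
    tb <- table(x$region)
    cat("  regions:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  reference cavity volume: %.1f ml\n", cavity_volume(x)))
  invisible(x)
}

#' Measured wall-area fraction of a region
#'
#' @param mesh an [lv_mesh] with regions assigned.
#' @param region region label.
#' @return fraction of reference wall area (layer-1 endocardial facet areas).
#' @export
region_area_fraction <- function(mesh, region) {
  area <- .column_areas(mesh)
  geom <- mesh$geom
  sel <- matrix(FALSE, geom$n_circ, geom$n_long)
  first_layer <- which(mesh$layer == 1L)
  for (e in first_layer) {
    if (mesh$region[e] == region || (region == "patchwin" &&
                                     mesh$region[e] %in% c("IZ", "BZ"))) {
      ij <- mesh$column[e, ]
      sel[ij[1] + 1L, ij[2]] <- TRUE
    }
  }
  sum(area[sel]) / sum(area)
}

#' Mean wall thickness over a set of columns
#'
#' Thickness measured as the distance from endocardial to outermost
#' myocardial node along each transmural node line of the selected region's
#' columns.
#'
#' @param mesh an [lv_mesh] with regions assigned.
#' @param region region label ("IZ", "BZ", "RZ").
#' @return mean thickness (mm).
#' @export
region_mean_thickness <- function(mesh, region) {
  geom <- mesh$geom
  nc <- geom$n_circ; K <- geom$n_layers; K1 <- K + 1L
  ring_id <- function(i, j, k) (K1) + ((j - 1L) * K1 + k) * nc + (i %% nc) + 1L
  sel <- mesh$region[seq_len(mesh$n_wall_elem)] == region
  cols <- unique(mesh$column[seq_len(mesh$n_wall_elem), , drop = FALSE][sel, ,
                                                                        drop = FALSE])
  th <- numeric(0)
  for (r in seq_len(nrow(cols))) {
    i <- cols[r, 1]; j <- cols[r, 2]
    if (j < 1) next
    d <- sqrt(sum((mesh$nodes[ring_id(i, j, K), ] -
                   mesh$nodes[ring_id(i, j, 0L), ])^2))
    th <- c(th, d)
  }
  mean(th)
}

#' Export a mesh and optional fields to an ascii VTU file
#'
#' Minimal VTK unstructured-grid writer (hexahedral cells) with cell data
#' (region, layer, fiber vectors, any per-element numeric fields) and point
#' data (displacement).
#'
#' @param mesh an [lv_mesh].
#' @param path output file path (.vtu).
#' @param displacement optional N x 3 nodal displacement (mm).
#' @param cell_fields optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, displacement = NULL, cell_fields = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  cat(apply(mesh$nodes, 1, paste, collapse = " "), sep = "\n", file = con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  cat(apply(mesh$elems - 1L, 1, paste, collapse = " "), sep = "\n", file = con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  cat(seq_len(m) * 8L, sep = "\n", file = con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  cat(rep(12L, m), sep = "\n", file = con)
  w('</DataArray></Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  cat(as.integer(factor(mesh$region,
                        levels = c("RZ", "BZ", "IZ", "patch"))) - 1L,
      sep = "\n", file = con)
  w('</DataArray>')
  w('<DataArray type="Int32" Name="layer" format="ascii">')
  cat(mesh$layer, sep = "\n", file = con)
  w('</DataArray>')
  w('<DataArray type="Float64" NumberOfComponents="3" Name="fiber" format="ascii">')
  cat(apply(mesh$fiber, 1, paste, collapse = " "), sep = "\n", file = con)
  w('</DataArray>')
  for (nm in names(cell_fields)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    cat(cell_fields[[nm]], sep = "\n", file = con)
    w('</DataArray>')
  }
  w('</CellData>')
  if (!is.null(displacement)) {
    w('<PointData>')
    w('<DataArray type="Float64" NumberOfComponents="3" Name="displacement" format="ascii">')
    cat(apply(displacement, 1, paste, collapse = " "), sep = "\n", file = con)
    w('</DataArray></PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
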