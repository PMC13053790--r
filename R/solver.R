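#' Solver configuration
#'
#' Quasi-static total-Lagrangian Newton solver settings. Incompressibility
#' is enforced by a volumetric penalty (default 1e7 Pa, giving |J - 1| of
#' order p/kappa at converged states); load is applied in equal increments
#' with automatic halving on divergence. The solver is fully deterministic.
#'
#' @param penalty_bulk_modulus volumetric penalty kappa (Pa).
#' @param newton_rel_tol relative residual tolerance (vs the first
#'   iterate of each load step).
#' @param newton_abs_tol absolute residual tolerance (N).
#' @param newton_max_iter maximum Newton iterations per load step.
#' @param n_load_steps number of equal load increments.
#' @param line_search logical, backtracking line search.
#' @param min_step_fraction smallest allowed load increment before the
#'   solve is abandoned.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(penalty_bulk_modulus = 1e7,
                          newton_rel_tol = 1e-9,
                          newton_abs_tol = 1e-7,
                          newton_max_iter = 40,
                          n_load_steps = 10,
                          line_search = TRUE,
                          min_step_fraction = 1 / 320) {
  stopifnot(penalty_bulk_modulus >= 0, newton_rel_tol > 0, newton_abs_tol > 0,
            newton_max_iter >= 1, n_load_steps >= 1)
  structure(list(penalty_bulk_modulus = penalty_bulk_modulus,
                 newton_rel_tol = newton_rel_tol,
                 newton_abs_tol = newton_abs_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 n_load_steps = as.integer(n_load_steps),
                 line_search = line_search,
                 min_step_fraction = min_step_fraction),
            class = "solver_config")
}

# reverse Cuthill-McKee node ordering from element connectivity, to keep the
# stiffness bandwidth small for the banded LU
.rcm_order <- function(n_nodes, elems) {
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(elems))) {
    ids <- unique(elems[e, ])
    for (a in ids) adj[[a]] <- c(adj[[a]], ids)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  deg <- lengths(adj)
  visited <- logical(n_nodes)
  ord <- integer(0)
  while (length(ord) < n_nodes) {
    start <- which(!visited)[which.min(deg[!visited])]
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ord <- c(ord, v)
      nb <- adj[[v]][!visited[adj[[v]]]]
      if (length(nb)) {
        nb <- nb[order(deg[nb])]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  rev(ord)
}

# per-element material parameter matrix and active flags from a region ->
# material_params mapping
.element_materials <- function(mesh, materials, active_regions) {
  regions <- mesh$region
  miss <- setdiff(unique(regions), names(materials))
  if (length(miss))
    stop("no material supplied for region(s): ", paste(miss, collapse = ", "))
  matpar <- matrix(0, length(regions), 4)
  for (nm in unique(regions)) {
    m <- materials[[nm]]
    stopifnot(inherits(m, "material_params"))
    sel <- regions == nm
    matpar[sel, ] <- matrix(rep(c(m$c_scale, m$b1, m$b2, m$b3),
                                each = sum(sel)), ncol = 4)
  }
  list(matpar = matpar,
       active_flag = as.numeric(regions %in% active_regions))
}

#' Internal nodal force vector
#'
#' Assembles the internal forces of the total stress (passive + active,
#' rotated from the fiber frame) for a given displacement field. Zero
#' displacement with zero activation gives zero internal force.
#'
#' @param mesh an [lv_mesh] (or compatible mesh list).
#' @param displacement N x 3 nodal displacements (mm).
#' @param materials named list mapping region labels to [material_params].
#' @param ct activation scaling in [0, 1].
#' @param active an [active_params] object.
#' @param active_regions region labels that generate active tension.
#' @param config a [solver_config] (for the penalty modulus).
#' @return 3N vector of internal nodal forces (N), dof order (node, xyz).
#' @export
assemble_internal_forces <- function(mesh, displacement, materials,
                                     ct = 0, active = active_params(),
                                     active_regions = c("BZ", "RZ"),
                                     config = solver_config()) {
  em <- .element_materials(mesh, materials, active_regions)
  u <- as.vector(t(as.matrix(displacement))) * 1e-3
  out <- .cpp_assemble(mesh$nodes * 1e-3, mesh$elems, u, mesh$rot,
                       em$matpar, em$active_flag,
                       config$penalty_bulk_modulus,
                       unclass(active), ct, FALSE)
  out$f
}

#' Follower endocardial pressure load
#'
#' Nodal force vector of a uniform pressure acting on the (deformed)
#' endocardial facets -- a follower load, integrated with 2x2 Gauss points
#' per bilinear facet. The load vector is linear in the pressure at fixed
#' configuration.
#'
#' @param mesh an [lv_mesh].
#' @param pressure cavity pressure (Pa).
#' @param displacement N x 3 nodal displacements (mm), or NULL.
#' @return 3N vector of external nodal forces (N).
#' @export
apply_endocardial_pressure <- function(mesh, pressure, displacement = NULL) {
  n <- nrow(mesh$nodes)
  f <- numeric(3 * n)
  if (pressure == 0 || is.null(mesh$endo_facets)) return(f)
  x <- mesh$nodes * 1e-3
  if (!is.null(displacement)) x <- x + as.matrix(displacement) * 1e-3
  gp <- 1 / sqrt(3)
  gxi <- c(-gp, gp, gp, -gp); geta <- c(-gp, -gp, gp, gp)
  for (fi in seq_len(nrow(mesh$endo_facets))) {
    ids <- mesh$endo_facets[fi, ]
    p <- x[ids, , drop = FALSE]
    for (g in 1:4) {
      xi <- gxi[g]; eta <- geta[g]
      N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
      dNxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
      dNeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
      t1 <- colSums(dNxi * p)
      t2 <- colSums(dNeta * p)
      nv <- c(t1[2] * t2[3] - t1[3] * t2[2],
              t1[3] * t2[1] - t1[1] * t2[3],
              t1[1] * t2[2] - t1[2] * t2[1])
      for (a in 1:4) {
        d <- 3 * (ids[a] - 1)
        f[d + 1:3] <- f[d + 1:3] + pressure * N[a] * nv
      }
    }
  }
  f
}

#' Default basal boundary conditions for the LV protocols
#'
#' Basal-plane nodes are fixed in the long-axis (z) direction; rigid-body
#' modes are removed by pinning the in-plane motion of the basal
#' epicardial ring.
#'
#' @param mesh an [lv_mesh].
#' @return a data.frame with columns `node`, `dof` (1 = x, 2 = y, 3 = z)
#'   and `value` (mm).
#' @export
lv_base_constraints <- function(mesh) {
  z <- data.frame(node = mesh$base_nodes, dof = 3L, value = 0)
  xy <- rbind(data.frame(node = mesh$basal_epi_ring, dof = 1L, value = 0),
              data.frame(node = mesh$basal_epi_ring, dof = 2L, value = 0))
  rbind(z, xy)
}

#' Solve a static equilibrium
#'
#' Newton iteration with incremental loading: the pressure, the activation
#' and any prescribed displacement values are ramped together from 0 to
#' their targets over `n_load_steps` equal increments (with automatic
#' halving on divergence). Deterministic: identical inputs give identical
#' states.
#'
#' @param mesh an [lv_mesh] (regions assigned).
#' @param materials named list region -> [material_params].
#' @param pressure endocardial pressure (Pa).
#' @param ct activation scaling in [0, 1] at full load.
#' @param config a [solver_config].
#' @param constraints data.frame (node, dof, value(mm)); defaults to
#'   [lv_base_constraints()].
#' @param active an [active_params] object.
#' @param active_regions region labels that develop active tension.
#' @return an object of class `sim_state`: displacement field (mm),
#'   per-element strains, cavity volume (ml), convergence report.
#' @export
solve_static <- function(mesh, materials, pressure, ct = 0,
                         config = solver_config(),
                         constraints = NULL,
                         active = active_params(),
                         active_regions = c("BZ", "RZ")) {
  if (is.null(constraints)) constraints <- lv_base_constraints(mesh)
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  em <- .element_materials(mesh, materials, active_regions)
  nodes_m <- mesh$nodes * 1e-3
  fixed <- 3L * (constraints$node - 1L) + constraints$dof
  if (anyDuplicated(fixed)) {
    keep <- !duplicated(fixed)
    constraints <- constraints[keep, ]
    fixed <- fixed[keep]
  }
  fixval <- constraints$value * 1e-3
  free <- setdiff(seq_len(ndof), fixed)

  # free-dof numbering in RCM order for the banded factorization
  node_ord <- .rcm_order(n, mesh$elems)
  rank_of <- integer(n); rank_of[node_ord] <- seq_len(n)
  dof_rank <- 3L * (rank_of[rep(seq_len(n), each = 3L)] - 1L) +
    rep.int(1:3, n)
  dmap <- integer(ndof)
  dmap[free] <- rank(dof_rank[free], ties.method = "first")
  nf <- length(free)
  inv_free <- integer(nf); inv_free[dmap[free]] <- free

  u <- numeric(ndof)
  total_iters <- 0L
  have_facets <- pressure != 0 && !is.null(mesh$endo_facets)
  assemble <- function(u, s, want_K) {
    .cpp_assemble(nodes_m, mesh$elems, u, mesh$rot, em$matpar, em$active_flag,
                  config$penalty_bulk_modulus, unclass(active), s * ct, want_K)
  }
  press <- function(u, s, want_K) {
    if (!have_facets) return(list(f = numeric(ndof)))
    .cpp_pressure(nodes_m, mesh$endo_facets, u, s * pressure, want_K)
  }
  residual <- function(u, s) {
    r <- assemble(u, s, FALSE)$f - press(u, s, FALSE)$f
    r[fixed] <- 0
    r
  }

  s <- 0; ds <- 1 / config$n_load_steps
  u_last <- u
  while (s < 1 - 1e-12) {
    s_try <- min(1, s + ds)
    u <- u_last
    u[fixed] <- s_try * fixval
    ok <- FALSE
    rn0 <- NA_real_
    r <- residual(u, s_try)
    rn <- sqrt(sum(r^2))
    for (it in seq_len(config$newton_max_iter)) {
      if (!is.finite(rn)) break
      if (it == 1L) rn0 <- max(rn, config$newton_abs_tol)
      if (rn <= max(config$newton_rel_tol * rn0, config$newton_abs_tol)) {
        ok <- TRUE
        break
      }
      total_iters <- total_iters + 1L
      asm <- assemble(u, s_try, TRUE)
      if (isTRUE(asm$bad)) break
      ki <- asm$ki; kj <- asm$kj; kx <- asm$kx
      if (have_facets) {
        pr <- press(u, s_try, TRUE)
        ki <- c(ki, pr$ki); kj <- c(kj, pr$kj); kx <- c(kx, -pr$kx)
      }
      ii <- dmap[ki]; jj <- dmap[kj]
      keep <- ii > 0L & jj > 0L
      ii <- ii[keep]; jj <- jj[keep]; xx <- kx[keep]
      bw <- max(abs(ii - jj))
      rhs <- numeric(nf)
      rhs[dmap[free]] <- -r[free]
      sol <- .cpp_band_solve(ii, jj, xx, rhs, bw, bw)
      if (anyNA(sol)) break
      du <- numeric(ndof)
      du[inv_free] <- sol
      # full Newton step, with backtracking only on blow-up: transient
      # residual growth is normal for Newton, so the full step is accepted
      # unless the residual grows beyond a safety cap
      r_new <- residual(u + du, s_try)
      rn_new <- sqrt(sum(r_new^2))
      if (is.finite(rn_new) &&
          (!config$line_search || rn_new <= 50 * max(rn, rn0))) {
        u <- u + du
        r <- r_new; rn <- rn_new
      } else {
        advanced <- FALSE
        alpha <- 0.5
        for (ls in 1:5) {
          r_new <- residual(u + alpha * du, s_try)
          rn_new <- sqrt(sum(r_new^2))
          if (is.finite(rn_new) && rn_new < rn) {
            u <- u + alpha * du
            r <- r_new; rn <- rn_new
            advanced <- TRUE
            break
          }
          alpha <- alpha / 2
        }
        if (!advanced) break # give up this step; load increment is halved
      }
    }
    if (ok) {
      s <- s_try
      u_last <- u
    } else {
      ds <- ds / 2
      if (ds < config$min_step_fraction)
        stop(sprintf(
          "solver failed to converge: last converged load factor %.4f", s))
    }
  }

  disp_mm <- matrix(u, ncol = 3, byrow = TRUE) * 1e3
  strains <- .cpp_element_strains(nodes_m, mesh$elems, u, mesh$rot)
  colnames(strains) <- c("Ef11", "Ef22", "Ef33", "Ef23", "Ef13", "Ef12",
                         "E11", "E22", "E33", "E23", "E13", "E12",
                         "J", "vol_ref")
  vol <- if (!is.null(mesh$endo_facets) && !is.null(mesh$basal_endo_ring))
    cavity_volume(mesh, disp_mm) else NA_real_
  structure(list(mesh = mesh, displacement = disp_mm, pressure = pressure,
                 ct = ct, converged = TRUE, iterations = total_iters,
                 cavity_volume = vol, strains = strains,
                 residual_norm = sqrt(sum(residual(u, 1)^2))),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "Static LV state: p = %g Pa, ct = %g, cavity volume = %.2f ml (%d Newton iterations)\n",
    x$pressure, x$ct, x$cavity_volume, x$iterations))
  invisible(x)
}

#' First-principal Green strain per element
#'
#' Largest eigenvalue of the global-frame Green strain tensor at the
#' element centre.
#'
#' @param state a [sim_state].
#' @return numeric vector, one value per element.
#' @export
principal_strain <- function(state) {
  s <- state$strains
  vapply(seq_len(nrow(s)), function(e) {
    E <- matrix(c(s[e, "E11"], s[e, "E12"], s[e, "E13"],
                  s[e, "E12"], s[e, "E22"], s[e, "E23"],
                  s[e, "E13"], s[e, "E23"], s[e, "E33"]), 3, 3)
    max(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
}

#' Export a simulation state to VTU
#'
#' Writes displacement, fiber strain, first-principal strain and region to
#' an ascii VTU file.
#'
#' @param state a [sim_state].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_vtu <- function(state, path) {
  write_vtu(state$mesh, path, displacement = state$displacement,
            cell_fields = list(fiber_strain = state$strains[, "Ef11"],
                               principal_strain = principal_strain(state),
                               jacobian = state$strains[, "J"]))
}
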