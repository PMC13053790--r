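# shared fixtures: tiny meshes and independent oracles built in code

# single-hexahedron mesh with edge length L (mm), fiber along +x
make_cube_mesh <- function(L = 10) {
  nodes <- as.matrix(expand.grid(x = c(0, L), y = c(0, L), z = c(0, L)))
  colnames(nodes) <- NULL
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7) # (-,-,-) (+,-,-) (+,+,-) (-,+,-) then +z
  structure(list(nodes = nodes[ord, ], elems = matrix(1:8, 1, 8),
                 layer = 1L, region = "RZ",
                 fiber = matrix(c(1, 0, 0), 1, 3),
                 rot = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 1, 9),
                 endo_facets = NULL, n_wall_elem = 1L),
            class = "lv_mesh")
}

# small LV mesh for fast protocol tests
small_geom <- function(n_circ = 10, n_long = 6, ...) {
  lv_geometry(endo_short_radius = 20, endo_long_radius = 48,
              wall_thickness = 10, n_circ = n_circ, n_long = n_long, ...)
}

# independent uniaxial oracle: incompressible fiber-direction stretch with
# the transverse condition eliminated numerically from finite differences
# of the strain-energy density (no reuse of the analytic stress path)
oracle_uniaxial <- function(mat, lam) {
  en <- function(E) strain_energy(E, mat)
  lt <- 1 / sqrt(lam)
  Efun <- function(l1, lt) diag(c((l1^2 - 1) / 2, (lt^2 - 1) / 2, (lt^2 - 1) / 2))
  h <- 1e-6
  E <- Efun(lam, lt)
  dW <- function(i) {
    Ep <- E; Em <- E
    Ep[i, i] <- Ep[i, i] + h
    Em[i, i] <- Em[i, i] - h
    (en(Ep) - en(Em)) / (2 * h)
  }
  s11 <- dW(1); s22 <- dW(2)
  p <- lt^2 * s22
  lam^2 * s11 - p
}

# 1D incompressible thick-walled-sphere inflation oracle: given internal
# pressure P, solve for the deformed inner radius by quadrature of the
# radial equilibrium equation (isotropic exponential material)
oracle_sphere_inner_radius <- function(Ri, Ro, mat, P, n_grid = 400) {
  stopifnot(mat$b1 == mat$b2, mat$b2 == mat$b3)
  b <- mat$b1; C <- mat$c_scale
  sig_diff <- function(R, ri) {
    r <- (R^3 + ri^3 - Ri^3)^(1 / 3)
    lt <- r / R         # hoop stretch
    lr <- (R / r)^2     # radial stretch (incompressible)
    Et <- (lt^2 - 1) / 2; Er <- (lr^2 - 1) / 2
    Q <- b * (Er^2 + 2 * Et^2)
    St <- C * exp(Q) * b * Et
    Sr <- C * exp(Q) * b * Er
    lt^2 * St - lr^2 * Sr
  }
  p_of_ri <- function(ri) {
    R <- seq(Ri, Ro, length.out = n_grid)
    r <- (R^3 + ri^3 - Ri^3)^(1 / 3)
    f <- 2 * sig_diff(R, ri) / r * (R / r)^2 # d sigma_rr / dR
    sum((f[-1] + f[-n_grid]) / 2 * diff(R))
  }
  uniroot(function(ri) p_of_ri(ri) - P, c(Ri, 3 * Ri), tol = 1e-10)$root
}

# build a sim_state-like object from a displacement field (mm) without
# solving, for testing the strain reporting path
fake_state <- function(mesh, disp_mm) {
  u <- as.vector(t(disp_mm)) * 1e-3
  strains <- lvmech:::.cpp_element_strains(mesh$nodes * 1e-3, mesh$elems,
                                           u, mesh$rot)
  colnames(strains) <- c("Ef11", "Ef22", "Ef33", "Ef23", "Ef13", "Ef12",
                         "E11", "E22", "E33", "E23", "E13", "E12",
                         "J", "vol_ref")
  structure(list(mesh = mesh, displacement = disp_mm, pressure = NA,
                 ct = NA, converged = TRUE, iterations = 0L,
                 cavity_volume = if (!is.null(mesh$endo_facets))
                   cavity_volume(mesh, disp_mm) else NA_real_,
                 strains = strains, residual_norm = NA_real_),
            class = "sim_state")
}

# circular mean of axial angles (degrees)
axial_mean <- function(a) {
  th <- 2 * a * pi / 180
  atan2(mean(sin(th)), mean(cos(th))) / 2 * 180 / pi
}
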