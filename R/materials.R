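#' Constitutive parameters for a tissue class
#'
#' Transversely isotropic exponential strain-energy parameters
#' \eqn{W = (C/2)(e^Q - 1)} with
#' \eqn{Q = b_1 E_{11}^2 + b_2 (E_{22}^2 + E_{33}^2 + E_{23}^2 + E_{32}^2)
#'        + b_3 (E_{12}^2 + E_{21}^2 + E_{13}^2 + E_{31}^2)},
#' axis 1 being the fiber direction. The four canonical parameter sets
#' (healthy myocardium, infarct scar, patch-implanted scar, and the patch
#' itself) share the stress scale C = 359 Pa and density 1.37e3 kg/m3 and
#' differ in the exponent coefficients.
#'
#' @param label tissue class, one of `"healthy"`, `"infarcted"`,
#'   `"implanted"`, `"patch"`, or `"custom"`.
#' @param c_scale stress scale C (Pa).
#' @param b numeric length-3 vector (b1, b2, b3), dimensionless.
#' @param density mass density (kg/m3); inertial terms are not used by the
#'   static solver but the value is carried for completeness.
#' @return an object of class `material_params`.
#' @export
#' @examples
#' material_params("healthy")
#' material_params("custom", b = c(30, 12, 10))
material_params <- function(label = c("healthy", "infarcted", "implanted",
                                      "patch", "custom"),
                            c_scale = 359, b = NULL, density = 1.37e3) {
  label <- match.arg(label)
  canon <- list(
    healthy   = c(67.07, 24.16, 21.60),
    infarcted = c(46.80, 22.00, 18.00),
    implanted = c(53.40, 22.00, 18.00),
    patch     = c(50.00, 50.00, 21.60)
  )
  if (label == "custom") {
    if (is.null(b)) stop("custom material requires `b`")
  } else if (is.null(b)) {
    b <- canon[[label]]
  }
  b <- as.numeric(b)
  if (length(b) != 3L || any(!is.finite(b)) || any(b <= 0))
    stop("`b` must be three positive finite numbers")
  if (!is.finite(c_scale) || c_scale <= 0) stop("`c_scale` must be positive")
  if (!is.finite(density) || density <= 0) stop("`density` must be positive")
  structure(list(c_scale = c_scale, b1 = b[1], b2 = b[2], b3 = b[3],
                 density = density, label = label),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("Passive material [%s]: C = %g Pa, b = (%g, %g, %g), rho = %g kg/m3\n",
              x$label, x$c_scale, x$b1, x$b2, x$b3, x$density))
  invisible(x)
}

#' Parameters of the length-dependent active tension model
#'
#' Sarcomere-length-dependent active fiber tension
#' \eqn{T_0 = T_{max} \, Ca_0^2 / (Ca_0^2 + ECa_{50}^2) \cdot C_t} with
#' \eqn{ECa_{50} = (Ca_0)_{max} / \sqrt{e^{B(l - l_0)} - 1}} and sarcomere
#' length \eqn{l = l_R \sqrt{2 E_{11} + 1}} recovered from the fiber Green
#' strain. Defaults are the canonical myocardial values.
#'
#' @param t_max maximum isometric tension (Pa).
#' @param l0 sarcomere length at which no active tension develops (um).
#' @param lR stress-free sarcomere length (um).
#' @param big_b length-sensitivity constant B (1/um).
#' @param m_slope,b_intercept relaxation-duration constants (s/um, s); stored
#'   for completeness, unused by the two static protocols.
#' @param ca0 peak intracellular calcium (umol/l).
#' @param ca0_max maximum peak intracellular calcium (umol/l).
#' @return an object of class `active_params`.
#' @export
active_params <- function(t_max = 1.357e5, l0 = 1.58, lR = 1.91,
                          big_b = 4.75, m_slope = 1.049, b_intercept = -1.429,
                          ca0 = 4.35, ca0_max = 4.35) {
  stopifnot(t_max > 0, big_b > 0, l0 > 0, lR > l0, ca0 > 0, ca0_max > 0)
  structure(list(t_max = t_max, l0 = l0, lR = lR, big_b = big_b,
                 m_slope = m_slope, b_intercept = b_intercept,
                 ca0 = ca0, ca0_max = ca0_max),
            class = "active_params")
}

#' @export
print.active_params <- function(x, ...) {
  cat(sprintf("Active tension: Tmax = %g Pa, l0 = %g um, lR = %g um, B = %g /um\n",
              x$t_max, x$l0, x$lR, x$big_b))
  invisible(x)
}

#' Activation state for a static protocol
#'
#' The activation scaling \eqn{C_t = (1 - \cos w)/2} lies in [0, 1]; the two
#' static protocols use only its limits (0 at end-diastole, 1 at end-systole).
#' The phase angle `w` and relaxation duration `tr` are stored but unused.
#'
#' @param ct activation scaling in [0, 1].
#' @param w phase angle (rad), optional bookkeeping.
#' @param tr relaxation duration (s), optional bookkeeping.
#' @return an object of class `activation_state`.
#' @export
activation_state <- function(ct, w = NA_real_, tr = NA_real_) {
  stopifnot(is.numeric(ct), length(ct) == 1L, ct >= 0, ct <= 1)
  structure(list(ct = ct, w = w, tr = tr), class = "activation_state")
}

#' Finite-deformation kinematic state
#'
#' Packages a deformation gradient F with the derived Green-Lagrange strain
#' E = (F'F - I)/2, right Cauchy-Green tensor C = F'F, Jacobian J = det(F)
#' and a static pressure p.
#'
#' @param f 3x3 deformation gradient (dimensionless), det(f) > 0.
#' @param p_hydro static pressure p (Pa).
#' @return an object of class `deformation_state` with elements
#'   `f`, `e`, `c_right`, `jac`, `p_hydro`.
#' @export
deformation_state <- function(f, p_hydro = 0) {
  f <- as.matrix(f)
  stopifnot(all(dim(f) == c(3L, 3L)), all(is.finite(f)))
  jac <- det(f)
  if (jac <= 0) stop("deformation gradient must have positive determinant")
  cr <- crossprod(f)              # F'F
  e <- (cr - diag(3)) / 2
  structure(list(f = f, e = e, c_right = cr, jac = jac, p_hydro = p_hydro),
            class = "deformation_state")
}

# component weights of Q as a 3x3 matrix in the fiber frame
.q_weights <- function(mat) {
  matrix(c(mat$b1, mat$b3, mat$b3,
           mat$b3, mat$b2, mat$b2,
           mat$b3, mat$b2, mat$b2), 3, 3, byrow = TRUE)
}

#' Passive strain-energy density
#'
#' Evaluates \eqn{W = (C/2)(e^Q - 1)} for a Green-Lagrange strain tensor given
#' in fiber-aligned coordinates (axis 1 = fiber, axis 2 = cross-fiber in
#' sheet plane, axis 3 = transmural).
#'
#' @param e symmetric 3x3 Green-Lagrange strain tensor (fiber frame).
#' @param mat a [material_params] object.
#' @return scalar energy density (Pa).
#' @export
#' @examples
#' e <- matrix(0, 3, 3); e[1, 1] <- 0.1
#' strain_energy(e, material_params("healthy"))  # ~171.5 Pa
strain_energy <- function(e, mat) {
  e <- as.matrix(e)
  stopifnot(all(dim(e) == c(3L, 3L)))
  if (max(abs(e - t(e))) > 1e-10 * max(1, max(abs(e))))
    stop("strain tensor must be symmetric")
  w <- .q_weights(mat)
  q <- sum(w * e^2)
  mat$c_scale / 2 * (expm1(q))
}

#' Passive second Piola-Kirchhoff stress
#'
#' \eqn{S = \partial W / \partial E - p J C^{-1}} in fiber-aligned
#' coordinates. The deviatoric part is the analytic derivative of the
#' exponential strain energy, \eqn{S_{ij} = C e^Q w_{ij} E_{ij}} (no sum).
#'
#' @param state a [deformation_state] (fiber frame).
#' @param mat a [material_params] object.
#' @return symmetric 3x3 second Piola-Kirchhoff stress (Pa).
#' @export
passive_second_pk <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"))
  e <- state$e
  w <- .q_weights(mat)
  q <- sum(w * e^2)
  s_dev <- mat$c_scale * exp(q) * w * e
  cinv <- tryCatch(solve(state$c_right),
                   error = function(err) stop("singular right Cauchy-Green tensor"))
  s_dev - state$p_hydro * state$jac * cinv
}

#' Cauchy stress from a second Piola-Kirchhoff stress
#'
#' \eqn{\sigma = (1/J) F S F'}.
#'
#' @param state a [deformation_state].
#' @param s symmetric 3x3 second Piola-Kirchhoff stress (Pa).
#' @return symmetric 3x3 Cauchy stress (Pa).
#' @export
cauchy_stress <- function(state, s) {
  stopifnot(inherits(state, "deformation_state"))
  s <- as.matrix(s)
  sig <- state$f %*% s %*% t(state$f) / state$jac
  (sig + t(sig)) / 2
}

#' Length-dependent active fiber tension
#'
#' Computes \eqn{T_0} from the fiber Green strain via the sarcomere length
#' \eqn{l = l_R\sqrt{2E_{11}+1}}. For \eqn{l \le l_0} (where
#' \eqn{ECa_{50}} is undefined) the tension is clamped to zero, consistent
#' with \eqn{l_0} being the no-tension length; the algebraic form used,
#' \eqn{T_0 = T_{max}\,Ca_0^2 g /(Ca_0^2 g + (Ca_0)_{max}^2)\,C_t} with
#' \eqn{g = e^{B(l-l_0)} - 1}, is continuous at the clamp.
#'
#' @param e11 fiber-direction Green strain (must satisfy 2*e11 + 1 > 0).
#' @param act an [active_params] object.
#' @param activation an [activation_state] or a bare number in [0, 1].
#' @return scalar active fiber tension (Pa).
#' @export
#' @examples
#' active_tension_t0(0, active_params(), 1)    # ~1.074e5 Pa
#' active_tension_t0(-0.1579, active_params(), 1)  # ~0 (l = l0)
active_tension_t0 <- function(e11, act, activation) {
  ct <- if (inherits(activation, "activation_state")) activation$ct else activation
  stopifnot(ct >= 0, ct <= 1, 2 * e11 + 1 > 0)
  l <- act$lR * sqrt(2 * e11 + 1)
  if (l <= act$l0) return(0)
  g <- expm1(act$big_b * (l - act$l0))
  act$t_max * act$ca0^2 * g / (act$ca0^2 * g + act$ca0_max^2) * ct
}

#' Active stress tensor in fiber coordinates
#'
#' diag(T0, 0.4 T0, 0.4 T0): full tension along the fiber, 40% in the two
#' transverse directions, no shear.
#'
#' @param t0 fiber tension (Pa).
#' @return 3x3 active stress tensor (fiber frame).
#' @export
active_stress_tensor <- function(t0) {
  diag(c(t0, 0.4 * t0, 0.4 * t0))
}

#' Incompressible uniaxial fiber-direction Cauchy stress
#'
#' Uniaxial extension along the fiber axis of an incompressible bar with
#' traction-free transverse faces: transverse stretches
#' \eqn{\lambda_t = \lambda^{-1/2}}, and the static pressure is eliminated by
#' the condition \eqn{\sigma_{22} = \sigma_{33} = 0}, which for this law has
#' the explicit solution \eqn{p = \lambda_t^2 S_{22}^{dev}}, giving
#' \eqn{\sigma_{11} = \lambda^2 S_{11}^{dev} - \lambda_t^2 S_{22}^{dev}}.
#'
#' @param mat a [material_params] object.
#' @param stretch fiber-direction stretch lambda (> 0); may be a vector.
#' @return fiber-direction Cauchy stress (Pa), vectorized over `stretch`.
#' @export
#' @examples
#' uniaxial_stress(material_params("healthy"), 1.2)
uniaxial_stress <- function(mat, stretch) {
  stopifnot(all(stretch > 0))
  vapply(stretch, function(lam) {
    lt2 <- 1 / lam
    e11 <- (lam^2 - 1) / 2
    et <- (lt2 - 1) / 2
    q <- mat$b1 * e11^2 + 2 * mat$b2 * et^2
    s11 <- mat$c_scale * exp(q) * mat$b1 * e11
    s22 <- mat$c_scale * exp(q) * mat$b2 * et
    lam^2 * s11 - lt2 * s22
  }, numeric(1))
}

#' Convert a fiber strain value to a stretch
#'
#' `"green"` reads the strain as Green-Lagrange fiber strain,
#' \eqn{\lambda = \sqrt{2\epsilon + 1}}; `"engineering"` as engineering
#' strain, \eqn{\lambda = 1 + \epsilon}.
#'
#' @param strain strain value(s).
#' @param strain_measure `"green"` (default) or `"engineering"`.
#' @return stretch value(s).
#' @export
strain_to_stretch <- function(strain, strain_measure = c("green", "engineering")) {
  strain_measure <- match.arg(strain_measure)
  switch(strain_measure,
         green = sqrt(2 * strain + 1),
         engineering = 1 + strain)
}

#' Uniaxial force-development ratio of two materials
#'
#' 100 x the ratio of incompressible uniaxial fiber-direction stresses of a
#' test material against a reference material at a given fiber strain point.
#' This is the quantity the infarct and implant parameter sets were fitted
#' against (35% and 49% of healthy force at the 0.2-strain point).
#'
#' @param mat_test,mat_ref [material_params] objects.
#' @param strain_point fiber strain at which to compare (default 0.2).
#' @param strain_measure strain reading, see [strain_to_stretch()]. Green
#'   strain is the default: with the canonical printed parameter sets it
#'   reproduces the stated fitting targets markedly better than the
#'   engineering reading.
#' @return percent (scalar).
#' @export
#' @examples
#' force_reduction_ratio(material_params("infarcted"), material_params("healthy"))
force_reduction_ratio <- function(mat_test, mat_ref, strain_point = 0.2,
                                  strain_measure = c("green", "engineering")) {
  lam <- strain_to_stretch(strain_point, match.arg(strain_measure))
  100 * uniaxial_stress(mat_test, lam) / uniaxial_stress(mat_ref, lam)
}

#' Fit a degraded parameter set to a target force-reduction ratio
#'
#' Returns a parameter set whose uniaxial force development at the given
#' strain point is `target_ratio` percent of the reference material's. The
#' fit uses a single global scale s on (b1, b2, b3) -- the simplest
#' well-posed one-parameter objective for a one-number target (the canonical
#' printed sets are not a uniform scaling of the healthy set and are taken
#' verbatim; this utility is for constructing sweep variants).
#'
#' @param mat_ref reference [material_params].
#' @param target_ratio target percent in (0, 100].
#' @param strain_point fiber strain point (default 0.2).
#' @param strain_measure see [strain_to_stretch()].
#' @param tol solver tolerance on the ratio (percentage points).
#' @return a [material_params] object with scaled b-vector, label `"custom"`.
#' @export
fit_reduced_params <- function(mat_ref, target_ratio, strain_point = 0.2,
                               strain_measure = c("green", "engineering"),
                               tol = 1e-8) {
  strain_measure <- match.arg(strain_measure)
  if (!is.finite(target_ratio) || target_ratio <= 0 || target_ratio > 100)
    stop("`target_ratio` must lie in (0, 100]")
  if (target_ratio == 100) return(mat_ref)
  b_ref <- c(mat_ref$b1, mat_ref$b2, mat_ref$b3)
  objective <- function(s) {
    m <- material_params("custom", c_scale = mat_ref$c_scale, b = s * b_ref,
                         density = mat_ref$density)
    force_reduction_ratio(m, mat_ref, strain_point, strain_measure) - target_ratio
  }
  # ratio is monotone increasing in s and -> 0 as s -> 0
  root <- stats::uniroot(objective, lower = 1e-6, upper = 1, tol = tol)
  material_params("custom", c_scale = mat_ref$c_scale,
                  b = root$root * b_ref, density = mat_ref$density)
}

#' Scale the stiffness of a material
#'
#' Used by the stiffness-sensitivity sweep ("material properties reduced
#' to 1/2 or 1/5"). `what = "c_scale"` (default) multiplies the stress
#' scale C by `factor`, scaling the whole stress-strain curve uniformly;
#' `what = "b"` multiplies the exponent coefficients instead, which
#' softens the large-strain response far more aggressively.
#'
#' @param mat a [material_params] object.
#' @param factor positive scale factor.
#' @param what which parameter group to scale.
#' @return a [material_params] object, label `"custom"`.
#' @export
scale_material <- function(mat, factor, what = c("c_scale", "b")) {
  stopifnot(factor > 0)
  what <- match.arg(what)
  if (what == "c_scale") {
    material_params("custom", c_scale = factor * mat$c_scale,
                    b = c(mat$b1, mat$b2, mat$b3), density = mat$density)
  } else {
    material_params("custom", c_scale = mat$c_scale,
                    b = factor * c(mat$b1, mat$b2, mat$b3),
                    density = mat$density)
  }
}

#' Read or write material parameter sets as YAML
#'
#' The bundled file `system.file("extdata", "material_params.yaml",
#' package = "lvmech")` reproduces the canonical parameter tables exactly.
#'
#' @param path file path.
#' @return `read_material_yaml` returns a named list of [material_params]
#'   plus an [active_params] entry under `$active`.
#' @export
read_material_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y$passive), function(nm) {
    p <- y$passive[[nm]]
    material_params("custom", c_scale = p$c_scale, b = unlist(p$b),
                    density = p$density)
  })
  names(out) <- names(y$passive)
  for (nm in names(out)) {
    if (nm %in% c("healthy", "infarcted", "implanted", "patch"))
      out[[nm]]$label <- nm
  }
  a <- y$active
  out$active <- active_params(t_max = a$t_max, l0 = a$l0, lR = a$lR,
                              big_b = a$big_b, m_slope = a$m_slope,
                              b_intercept = a$b_intercept,
                              ca0 = a$ca0, ca0_max = a$ca0_max)
  out
}

#' @rdname read_material_yaml
#' @param materials named list of [material_params] objects.
#' @param active an [active_params] object.
#' @export
write_material_yaml <- function(materials, active, path) {
  passive <- lapply(materials, function(m)
    list(c_scale = m$c_scale, b = c(m$b1, m$b2, m$b3), density = m$density))
  yaml::write_yaml(list(passive = passive, active = unclass(active)), path)
  invisible(path)
}
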