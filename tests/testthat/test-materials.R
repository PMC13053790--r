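test_that("canonical parameter sets match the constitutive tables", {
  h <- material_params("healthy")
  expect_equal(c(h$b1, h$b2, h$b3), c(67.07, 24.16, 21.60))
  expect_equal(h$c_scale, 359)
  expect_equal(h$density, 1370)
  i <- material_params("infarcted")
  expect_equal(c(i$b1, i$b2, i$b3), c(46.80, 22.00, 18.00))
  im <- material_params("implanted")
  expect_equal(c(im$b1, im$b2, im$b3), c(53.40, 22.00, 18.00))
  p <- material_params("patch")
  expect_equal(c(p$b1, p$b2, p$b3), c(50.00, 50.00, 21.60))
  a <- active_params()
  expect_equal(a$t_max, 1.357e5)
  expect_equal(c(a$l0, a$lR, a$big_b), c(1.58, 1.91, 4.75))
  expect_equal(c(a$ca0, a$ca0_max), c(4.35, 4.35))
})

test_that("bundled YAML reproduces the parameter tables exactly", {
  path <- system.file("extdata", "material_params.yaml", package = "lvmech")
  y <- read_material_yaml(path)
  for (nm in c("healthy", "infarcted", "implanted", "patch")) {
    ref <- material_params(nm)
    expect_identical(c(y[[nm]]$c_scale, y[[nm]]$b1, y[[nm]]$b2, y[[nm]]$b3,
                       y[[nm]]$density),
                     c(ref$c_scale, ref$b1, ref$b2, ref$b3, ref$density))
  }
  expect_identical(unclass(y$active), unclass(active_params()))
})

test_that("strain energy matches hand evaluation and its invariances", {
  h <- material_params("healthy")
  expect_identical(strain_energy(matrix(0, 3, 3), h), 0)
  e <- matrix(0, 3, 3); e[1, 1] <- 0.1
  # frozen hand evaluation: Q = 67.07 * 0.01, W = 179.5 (e^Q - 1)
  expect_equal(strain_energy(e, h), 171.5312, tolerance = 1e-6)
  h2 <- material_params("custom", b = c(2 * 67.07, 24.16, 21.60))
  expect_gt(strain_energy(e, h2), strain_energy(e, h))
  # shear-pair symmetry of Q: (1,2) vs (1,3) shears are interchangeable
  e12 <- matrix(0, 3, 3); e12[1, 2] <- e12[2, 1] <- 0.05
  e13 <- matrix(0, 3, 3); e13[1, 3] <- e13[3, 1] <- 0.05
  expect_equal(strain_energy(e12, h), strain_energy(e13, h))
  expect_error(strain_energy(matrix(c(0, 0.1, rep(0, 7)), 3, 3), h),
               "symmetric")
  # W = 0 iff E = 0 over random nonzero strains
  set.seed(11)
  for (k in 1:20) {
    s <- matrix(rnorm(9, sd = 0.05), 3, 3)
    s <- (s + t(s)) / 2
    expect_gt(strain_energy(s, h), 0)
  }
})

test_that("second Piola-Kirchhoff stress matches finite differences of W", {
  h <- material_params("healthy")
  st0 <- deformation_state(diag(3))
  expect_equal(passive_second_pk(st0, h), matrix(0, 3, 3))
  stP <- deformation_state(diag(3), p_hydro = 1000)
  expect_equal(passive_second_pk(stP, h), -1000 * diag(3))
  # uniaxial fiber strain: S11 = C b1 E11 e^Q ~ 4.709 kPa
  f <- diag(c(sqrt(1.2), 1, 1)) # E11 = 0.1
  s <- passive_second_pk(deformation_state(f), h)
  expect_equal(s[1, 1], 4708.73, tolerance = 1e-4)
  expect_equal(s[2, 2], 0); expect_equal(s[1, 2], 0)
  # property: deviatoric part agrees with central differences of W
  set.seed(7)
  hh <- 1e-6
  for (k in 1:100) {
    a <- matrix(rnorm(9, sd = 0.03), 3, 3)
    f <- diag(3) + a
    if (det(f) <= 0.1) next
    st <- deformation_state(f)
    s_dev <- passive_second_pk(st, h)
    for (idx in list(c(1, 1), c(2, 2), c(1, 2), c(2, 3))) {
      ep <- st$e; em <- st$e
      ep[idx[1], idx[2]] <- ep[idx[1], idx[2]] + hh
      ep[idx[2], idx[1]] <- ep[idx[1], idx[2]]
      em[idx[1], idx[2]] <- em[idx[1], idx[2]] - hh
      em[idx[2], idx[1]] <- em[idx[1], idx[2]]
      fd <- (strain_energy(ep, h) - strain_energy(em, h)) / (2 * hh)
      # off-diagonal FD perturbs both symmetric entries -> 2 S_ij
      fac <- if (idx[1] == idx[2]) 1 else 2
      expect_equal(s_dev[idx[1], idx[2]] * fac, fd,
                   tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("Cauchy stress push-forward is correct", {
  h <- material_params("healthy")
  s <- matrix(c(5, 1, 0, 1, 3, 0, 0, 0, 2), 3, 3) * 1e3
  st_id <- deformation_state(diag(3))
  expect_equal(cauchy_stress(st_id, s), s)
  th <- 0.3
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(cauchy_stress(deformation_state(rot), matrix(0, 3, 3)),
               matrix(0, 3, 3))
  lam <- 1.2; lt <- 1 / sqrt(lam)
  f <- diag(c(lam, lt, lt)) # J = 1
  st <- deformation_state(f)
  expect_equal(cauchy_stress(st, s), f %*% s %*% t(f) / det(f))
  expect_equal(cauchy_stress(st, s)[1, 1], lam^2 * s[1, 1])
})

test_that("active tension follows the sarcomere length-dependence", {
  a <- active_params()
  # l = l0 at E11 = ((l0/lR)^2 - 1)/2: no tension develops
  e_l0 <- ((a$l0 / a$lR)^2 - 1) / 2
  expect_equal(active_tension_t0(e_l0, a, 1), 0)
  expect_equal(active_tension_t0(e_l0 - 0.05, a, 1), 0)
  # frozen hand evaluations of the T0 chain
  expect_equal(active_tension_t0(0, a, 1), 107397.6, tolerance = 1e-6)
  expect_equal(active_tension_t0(0.1, a, 1), 123794.3, tolerance = 1e-6)
  expect_gt(active_tension_t0(0.1, a, 1), active_tension_t0(0, a, 1))
  # monotone non-decreasing and bounded by Tmax over physiological strains
  ee <- seq(-0.2, 0.35, by = 0.01)
  t0 <- vapply(ee, active_tension_t0, numeric(1), act = a, activation = 1)
  expect_true(all(diff(t0) >= -1e-9))
  expect_true(all(t0 <= a$t_max))
  # continuity at the clamp (tension vanishes as l -> l0 from above)
  expect_lt(active_tension_t0(e_l0 + 1e-6, a, 1), 5)
  # activation scaling
  expect_equal(active_tension_t0(0, a, activation_state(0.5)),
               0.5 * active_tension_t0(0, a, 1))
  expect_equal(active_tension_t0(0, a, 0), 0)
})

test_that("active stress tensor carries 40% transverse tension", {
  expect_equal(active_stress_tensor(0), matrix(0, 3, 3))
  t <- active_stress_tensor(1e5)
  expect_equal(diag(t), c(1e5, 4e4, 4e4))
  expect_equal(t[upper.tri(t)], rep(0, 3))
  expect_equal(sum(diag(active_stress_tensor(123))), 1.8 * 123)
})

test_that("uniaxial stress matches the finite-difference oracle", {
  h <- material_params("healthy")
  expect_equal(uniaxial_stress(h, 1), 0)
  lams <- c(1.05, 1.1, 1.2, 1.25)
  s <- uniaxial_stress(h, lams)
  expect_true(all(diff(s) > 0))
  for (lam in lams) {
    expect_equal(uniaxial_stress(h, lam), oracle_uniaxial(h, lam),
                 tolerance = 1e-5)
  }
  # isotropic parameter set: the response must be axis-independent, i.e.
  # invariant under any permutation of (b1, b2, b3)
  iso <- material_params("custom", b = c(20, 20, 20))
  perm <- material_params("custom", b = c(20, 20, 20)[c(2, 3, 1)])
  expect_equal(uniaxial_stress(iso, 1.15), uniaxial_stress(perm, 1.15))
  expect_equal(uniaxial_stress(iso, 1.15), oracle_uniaxial(iso, 1.15),
               tolerance = 1e-5)
})

test_that("patch and infarct uniaxial responses agree within bounds", {
  # the printed patch set tracks the infarct set only loosely under this
  # uniaxial protocol (within a factor ~2.6 over the working range, the
  # fitting protocol behind the printed sets being unstated); assert the
  # documented bounded agreement and shared monotonicity
  pa <- material_params("patch")
  inf <- material_params("infarcted")
  lams <- seq(1.02, 1.25, by = 0.01)
  rp <- uniaxial_stress(pa, lams) / uniaxial_stress(inf, lams)
  expect_true(all(rp > 1 & rp < 3))
  expect_true(all(diff(uniaxial_stress(pa, lams)) > 0))
})

test_that("force reduction ratios and the reduced-parameter fit", {
  h <- material_params("healthy")
  inf <- material_params("infarcted")
  expect_equal(force_reduction_ratio(h, h), 100)
  # frozen values of the printed sets at the 0.2 Green-strain point
  expect_equal(force_reduction_ratio(inf, h), 30.9393, tolerance = 1e-4)
  expect_equal(force_reduction_ratio(material_params("implanted"), h),
               45.4060, tolerance = 1e-4)
  # engineering-strain reading is switchable
  expect_equal(force_reduction_ratio(inf, h, strain_measure = "engineering"),
               25.9539, tolerance = 1e-4)
  # fit: round trip hits the target by construction
  expect_identical(fit_reduced_params(h, 100), h)
  for (target in c(35, 49)) {
    fit <- fit_reduced_params(h, target)
    expect_equal(force_reduction_ratio(fit, h), target, tolerance = 0.1)
    expect_equal(fit$b2 / fit$b1, h$b2 / h$b1) # single global scale
  }
  expect_error(fit_reduced_params(h, 0))
  expect_error(fit_reduced_params(h, 120))
})

test_that("deformation state derives consistent kinematics", {
  f <- matrix(c(1.1, 0.05, 0, 0.02, 0.95, 0.01, 0, 0.03, 1.04), 3, 3)
  st <- deformation_state(f, p_hydro = 10)
  expect_equal(st$jac, det(f))
  expect_equal(st$c_right, t(f) %*% f)
  expect_equal(st$c_right, 2 * st$e + diag(3))
  expect_equal(st$e, t(st$e))
  expect_error(deformation_state(diag(c(1, 1, -1))))
})
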