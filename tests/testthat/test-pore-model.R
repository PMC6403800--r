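test_that("parametric pore geometry matches its stated dimensions", {
  g <- parametric_alpha_hl()
  # constriction area chosen so the 6 A region holds 924 A^3
  expect_equal(sqrt(min(g$area_A2) / pi), sqrt(924 / (6 * pi)), tolerance = 1e-8)
  expect_equal(sqrt(min(g$area_A2) / pi), 7.00, tolerance = 0.01)
  # barrel area from the 20 A diameter
  expect_equal(g$area_A2[g$z_A == 20], pi * 100, tolerance = 1e-8)
  # 1/A peaks in the constriction, exceeds the barrel, minimal in vestibule
  inv <- 1 / g$area_A2
  reg <- attr(g, "regions")
  in_c <- g$z_A >= reg$constriction[1] & g$z_A <= reg$constriction[2]
  in_b <- g$z_A >= 5 & g$z_A <= 40
  in_v <- g$z_A >= 55 & g$z_A <= 100
  expect_equal(max(inv), max(inv[in_c]))
  expect_gt(max(inv[in_c]), max(inv[in_b]))
  expect_lt(max(inv[in_v]), min(inv[in_b]))
})

test_that("series resistance matches the closed form and adds in series", {
  # uniform cylinder r = 10 A, L = 100 A, sigma = 20 S/m
  z <- seq(0, 100, 0.5)
  g <- pore_geometry(z, rep(pi * 100, length(z)), conductivity = 20)
  expect_equal(pore_resistance(g), 100e-10 / (20 * pi * (10e-10)^2),
               tolerance = 1e-12)
  # two half-cylinders in series equal the whole
  r1 <- pore_resistance(g, z_range = c(0, 50))
  r2 <- pore_resistance(g, z_range = c(50, 100))
  expect_equal(r1 + r2, pore_resistance(g), tolerance = 1e-12)
  # the constriction contributes the largest per-Angstrom share in alpha-HL
  ahl <- parametric_alpha_hl()
  reg <- attr(ahl, "regions")
  per_A <- vapply(reg, function(rg) {
    pore_resistance(ahl, z_range = rg) / diff(rg)
  }, numeric(1))
  expect_identical(names(which.max(per_A)), "constriction")
  # zero area signals infinite resistance
  suppressWarnings({
    g0 <- pore_geometry(z, c(rep(100, 100), 0, rep(100, 100)), 20)
    expect_warning(r <- pore_resistance(g0), "infinite|Zero")
  })
  expect_identical(r, Inf)
})

test_that("resistance is monotone under pointwise area increase", {
  z <- seq(0, 100, 1)
  set.seed(31)
  a <- runif(length(z), 100, 400)
  g_small <- pore_geometry(z, a, 20)
  g_big <- pore_geometry(z, a * runif(length(z), 1, 2), 20)
  expect_lt(pore_resistance(g_big), pore_resistance(g_small))
})

test_that("open-pore current is Ohmic in voltage and conductivity", {
  g <- parametric_alpha_hl(conductivity = 20)
  i100 <- open_pore_current(g, 100)
  expect_gt(i100, 0)
  expect_true(is.finite(i100))
  expect_equal(open_pore_current(g, 200), 2 * i100, tolerance = 1e-12)
  g2 <- parametric_alpha_hl(conductivity = 40)
  expect_equal(open_pore_current(g2, 100), 2 * i100, tolerance = 1e-12)
  # reproducible bit-exactly
  expect_identical(open_pore_current(parametric_alpha_hl(), 100),
                   open_pore_current(parametric_alpha_hl(), 100))
})

test_that("area profile recovers analytic cylinder and annulus sections", {
  probe <- 1.4
  atoms <- nanoblock:::.pseudo_cylinder_atoms(inner_radius = 10, length = 20,
                                              r_eff = 1.7 + probe)
  atoms$radius <- 1.7
  for (gs in c(1, 0.5)) {
    g <- area_profile_from_coords(atoms, z_step = 2, grid_step = gs,
                                  probe = probe)
    ring <- 2 * pi * 10 * gs  # one grid-cell ring of the lumen boundary
    expect_true(all(abs(g$area_A2 - pi * 100) <= ring))
  }
  # finer grid reduces the error
  e1 <- max(abs(area_profile_from_coords(atoms, z_step = 2, grid_step = 1,
                                         probe = probe)$area_A2 - pi * 100))
  e2 <- max(abs(area_profile_from_coords(atoms, z_step = 2, grid_step = 0.25,
                                         probe = probe)$area_A2 - pi * 100))
  expect_lt(e2, e1)
  # coaxial rod leaves the analytic annulus
  rod <- nanoblock:::.pseudo_rod_atoms(radius = 5, length = 20,
                                       r_eff = 1.7 + probe)
  rod$radius <- 1.7
  both <- rbind(atoms, rod)
  ga <- area_profile_from_coords(both, z_step = 2, grid_step = 0.5,
                                 probe = probe, axis_xy = c(7.5, 0))
  ring_a <- 2 * pi * (10 + 5) * 0.5
  expect_true(all(abs(ga$area_A2 - pi * (100 - 25)) <= ring_a))
})

test_that("an empty atom list over a bounded box gives the box area", {
  g <- area_profile_from_coords(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   radius = numeric()),
    z_step = 1, grid_step = 0.5,
    xy_limits = c(-5, 5, -5, 5), z_range = c(0, 5)
  )
  expect_true(all(g$area_A2 == 100))
})

test_that("a blocked slab reports zero area with a warning", {
  wall <- expand.grid(x = seq(-6, 6, 0.5), y = seq(-6, 6, 0.5))
  atoms <- tibble::tibble(x = wall$x, y = wall$y, z = 2.5, radius = 1.7)
  w <- testthat::capture_warnings(
    g <- area_profile_from_coords(atoms, z_step = 5, grid_step = 1,
                                  xy_limits = c(-5, 5, -5, 5),
                                  z_range = c(0, 5))
  )
  expect_true(any(grepl("axis blocked", w)))
  expect_true(any(g$area_A2 == 0))
})

test_that("excluded-volume blockade is monotone and ranks Ile above Ser", {
  g <- parametric_alpha_hl()
  # strictly increasing in excluded volume over 0-500 A^3
  vols <- seq(10, 500, by = 35)
  fracs <- vapply(vols, function(v) {
    pep <- peptide_model("custom", middle_residue = "XXX", residue_volume = v)
    predict_blockade(g, pep, n_residues = 1)$frac_block
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  # zero excluded volume: no blockade
  tiny <- peptide_model("custom", middle_residue = "XXX", residue_volume = 1e-9)
  expect_equal(predict_blockade(g, tiny, n_residues = 1)$frac_block, 0,
               tolerance = 1e-6)
  # isoleucine triplet blocks more than serine triplet
  b_ile <- predict_blockade(g, peptide_model("Pe4"))
  b_ser <- predict_blockade(g, peptide_model("Pe6"))
  expect_gt(b_ile$frac_block, b_ser$frac_block)
  expect_equal(b_ile$excluded_volume_A3, 3 * 175.4)
  expect_equal(b_ser$excluded_volume_A3, 3 * 100.7)
  # centered placement blocks more than offset at identical volume
  b_off <- predict_blockade(g, peptide_model("Pe4"), placement = "offset")
  expect_gt(b_ile$frac_block, b_off$frac_block)
  # full occlusion is rejected
  huge <- peptide_model("custom", middle_residue = "XXX", residue_volume = 400)
  expect_error(predict_blockade(g, huge, n_residues = 3), "occluded")
})

test_that("Debye length follows the closed form and its scaling law", {
  expect_equal(debye_length(0.1, 1, 298, 78.5), 9.6, tolerance = 0.02)
  # quadrupling the concentration halves the screening length
  expect_equal(debye_length(0.5, 1, 300, 70) / debye_length(2, 1, 300, 70), 2,
               tolerance = 1e-10)
  expect_error(debye_length(-1), "positive")
})
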