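test_that("Coulomb term matches the closed form and its symmetries", {
  ## two unit charges at k/100 Angstrom apart -> exactly +100 kcal/mol
  d <- tcr_constants$coulomb_k / 100
  x <- micro_structure(rbind(c(0, 0, 0), c(d, 0, 0)), charge = 1,
                       chain = c("R", "L"), receptor = "R", ligand = "L")
  expect_equal(pair_elec(x), 100, tolerance = 1e-10)
  ## antisymmetry under charge flip
  y <- x; y$atoms$charge[2] <- -1
  expect_equal(pair_elec(y), -pair_elec(x))
  ## empty group sums to zero
  expect_equal(pair_elec(x, "R:1:", character(0)), 0)
  ## interior dielectric scales it down
  expect_equal(pair_elec(x, eps_in = 4), 25, tolerance = 1e-10)
  ## coincident atoms are an error
  z <- x; z$xyz[2, , 1] <- z$xyz[1, , 1]
  expect_error(pair_elec(z), "overlapping")
})

test_that("Lennard-Jones term has its minimum, decay, and brute-force value", {
  mk <- function(d) micro_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                    rmin2 = 2, eps = 0.2,
                                    chain = c("R", "L"),
                                    receptor = "R", ligand = "L")
  expect_equal(pair_vdw(mk(4)), -0.2, tolerance = 1e-12)     # r = rmin -> -eps
  expect_lt(abs(pair_vdw(mk(60))), 1e-6)                     # decay
  ## three-atom toy against explicit pair enumeration
  xyz <- rbind(c(0, 0, 0), c(3.7, 0.4, 0), c(4.2, -1, 0.7))
  x <- micro_structure(xyz, rmin2 = c(1.9, 2.1, 1.7), eps = c(0.1, 0.15, 0.08),
                       chain = c("R", "L", "L"), receptor = "R", ligand = "L")
  brute <- 0
  for (j in 2:3) {
    r <- sqrt(sum((xyz[1, ] - xyz[j, ])^2))
    rm <- x$atoms$rmin2[1] + x$atoms$rmin2[j]
    ep <- sqrt(x$atoms$eps[1] * x$atoms$eps[j])
    brute <- brute + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(pair_vdw(x), brute, tolerance = 1e-12)
})

test_that("GB reduces to the Born formula and closed two-ion form", {
  diel <- dielectric_model(1, 78.5)
  one <- micro_structure(c(0, 0, 0), charge = 1, born = 3 + 0.09)
  ## supplied effective radius 3.0 -> Born ion solvation
  born <- -0.5 * tcr_constants$coulomb_k * (1 - 1 / 78.5) / 3
  expect_equal(gb_energy(one, dielectric = diel, radii = 3), born,
               tolerance = 1e-9)
  expect_equal(born, -54.640, tolerance = 1e-4)
  ## HCT radius of an isolated atom is its intrinsic radius
  expect_equal(born_radii(one), 3, tolerance = 1e-12)
  ## all charges zero -> no solvation
  expect_equal(gb_energy(micro_structure(rbind(c(0, 0, 0), c(4, 0, 0)),
                                         charge = 0)), 0)
  ## two distant ions: self terms plus screened cross term, by hand
  two <- micro_structure(rbind(c(0, 0, 0), c(50, 0, 0)), charge = c(1, -1))
  a <- c(2.5, 3.0)
  f12 <- sqrt(50^2 + a[1] * a[2] * exp(-50^2 / (4 * a[1] * a[2])))
  k <- tcr_constants$coulomb_k * (1 - 1 / 78.5)
  hand <- -0.5 * k * (1 / a[1] + 1 / a[2]) + k / f12
  expect_equal(gb_energy(two, dielectric = diel, radii = a), hand,
               tolerance = 1e-6)
  ## eps_out -> eps_in kills the solvation term
  expect_equal(gb_energy(two, dielectric = dielectric_model(1, 1 + 1e-12),
                         radii = a), 0, tolerance = 1e-6)
  ## missing Born radius is an error
  bad <- two; bad$atoms$born[1] <- NA
  expect_error(gb_energy(bad, dielectric = diel), "Born radius")
})

test_that("SASA matches sphere closed forms and buries caged atoms", {
  one <- micro_structure(c(0, 0, 0), rmin2 = 1.9)
  s <- sasa(one, probe_radius = 1.4)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.005)
  ## per-atom areas are non-negative and sum to the total
  tcx <- toy(7)
  sc <- sasa(tcx$structure)
  expect_true(all(sc$per_atom >= 0))
  expect_equal(sum(sc$per_atom), sc$total)
  ## atom enclosed by a dense cage has zero accessible area
  pts <- tcrforge:::.sphere_points(80) * 2.6
  cage <- micro_structure(rbind(c(0, 0, 0), pts), rmin2 = 1.9)
  expect_equal(unname(sasa(cage, probe_radius = 1.4)$per_atom["1"]), 0)
  ## two-atom overlap against a high-resolution evaluation
  two <- micro_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)), rmin2 = 1.9)
  coarse <- sasa(two, n_points = 512)$total
  fine <- sasa(two, n_points = 20000)$total
  expect_equal(coarse, fine, tolerance = 0.01)
})

test_that("effective energy obeys its bookkeeping identity and limits", {
  x <- toy(7)$structure
  ee <- effective_energy(x)
  expect_equal(ee$total, ee$elec + ee$vdw + ee$gb + ee$np + ee$intra,
               tolerance = 1e-9)
  ## neutral partners far apart: interaction terms vanish
  far <- micro_structure(rbind(c(0, 0, 0), c(1.2, 0, 0),
                               c(500, 0, 0), c(501.2, 0, 0)),
                         charge = c(0.3, -0.3, 0.25, -0.25),
                         chain = c("R", "R", "L", "L"),
                         resno = c(1, 1, 2, 2), name = c("X1", "X2", "X1", "X2"),
                         receptor = "R", ligand = "L")
  expect_lt(abs(pair_elec(far)), 1e-3)
  expect_lt(abs(pair_vdw(far)), 1e-3)
})

test_that("all energy terms are invariant under a global rigid transform", {
  x <- toy(7)$structure
  y <- apply_rigid(x, seed = 11)
  bx <- binding_energy(x); by <- binding_energy(y)
  for (t in c("elec", "vdw", "gb", "np", "total"))
    expect_equal(by[[t]], bx[[t]], tolerance = 1e-6)
})

test_that("binding energy honours the single-trajectory identities", {
  tc <- toy(7)
  x <- tc$structure
  be <- binding_energy(x)
  ## delta-elec / delta-vdw equal the inter-partner pair sums exactly
  expect_identical(be$elec, pair_elec(x))
  expect_identical(be$vdw, pair_vdw(x))
  expect_identical(be$intra, 0)
  ## engineered salt bridges: attractive inter-partner electrostatics
  expect_lt(be$elec, 0)
  ## external entropy hook shifts only the total
  be2 <- binding_energy(x, entropy = 3)
  expect_equal(be2$total - be$total, 3)
  ## no-interaction limit: receptor displaced far away
  far <- x
  rec <- which(far$atoms$partner == "receptor")
  far$xyz[rec, 3, 1] <- far$xyz[rec, 3, 1] + 150
  bf <- binding_energy(far)
  expect_lt(abs(bf$total), 0.05)
})
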