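test_that("BFED conserves the binding energy and localises contributions", {
  tc <- toy(7)
  b <- bfed(tc$structure)
  expect_equal(sum(b$total), attr(b, "binding")$total, tolerance = 1e-6)
  for (t in c("elec", "vdw", "gb", "np"))
    expect_equal(sum(b[[t]]), attr(b, "binding")[[t]], tolerance = 1e-6)
  ## the engineered ring is net electrostatically attractive
  hot <- b[b$reskey %in% tc$truth$hotspots, ]
  expect_lt(sum(hot$elec), 0)
  ## each engineered salt bridge is pairwise attractive from either side
  for (k in seq_len(8)) {
    lig_site <- paste0("C:", k, ":")
    expect_lt(pair_elec(tc$structure, lig_site, tc$truth$hotspots[k]), 0)
  }
  ## conservation also holds for a multi-frame ensemble
  b5 <- bfed(toy(3, n_frames = 5)$structure)
  expect_equal(sum(b5$total), attr(b5, "binding")$total, tolerance = 1e-6)
})

test_that("pairwise decomposition matches brute-force enumeration on a toy", {
  ## 2 residues per partner, one atom each: every pair term is explicit
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 0, 5), c(4, 0.5, 5))
  x <- micro_structure(xyz, charge = c(0.5, -0.5, -0.4, 0.4),
                       rmin2 = 2, eps = 0.1, born = 2,
                       chain = c("R", "R", "L", "L"), resno = c(1, 2, 1, 2),
                       receptor = "R", ligand = "L")
  b <- bfed(x)
  k <- tcr_constants$coulomb_k
  q <- x$atoms$charge
  d13 <- 5; d14 <- sqrt(16 + 0.25 + 25); d23 <- sqrt(16 + 25); d24 <- sqrt(0.25 + 25)
  e13 <- k * q[1] * q[3] / d13; e14 <- k * q[1] * q[4] / d14
  e23 <- k * q[2] * q[3] / d23; e24 <- k * q[2] * q[4] / d24
  expect_equal(b$elec[b$reskey == "R:1:"], (e13 + e14) / 2, tolerance = 1e-10)
  expect_equal(b$elec[b$reskey == "R:2:"], (e23 + e24) / 2, tolerance = 1e-10)
  expect_equal(b$elec[b$reskey == "L:1:"], (e13 + e23) / 2, tolerance = 1e-10)
  expect_equal(b$elec[b$reskey == "L:2:"], (e14 + e24) / 2, tolerance = 1e-10)
  expect_equal(sum(b$total), binding_energy(x)$total, tolerance = 1e-10)
})

test_that("residues far from the interface contribute almost nothing", {
  tc <- toy(7)
  x <- tc$structure
  ## park a neutral probe residue 40 A away from everything
  far <- x
  i <- which(far$atoms$reskey == "C:10:")   # a neutral groove ALA
  far$xyz[i, 1, 1] <- far$xyz[i, 1, 1] + 40
  b <- bfed(far)
  expect_lt(abs(b$total[b$reskey == "C:10:"]), 0.01)
})

test_that("alanine scanning flags hotspots and skips unmutable residues", {
  tc <- toy(7)
  x <- tc$structure
  expect_warning(cas <- alanine_scan(x, c(tc$truth$np_hotspot, "C:9:")),
                 "skipped")
  expect_setequal(attr(cas, "skipped"), "C:9:")  # a groove alanine
  ## the engineered nonpolar patch is a > +1 kcal/mol hotspot
  expect_gt(cas$ddg[cas$reskey == tc$truth$np_hotspot], 1)
  ## a residue moved far from the interface scores ~0
  far <- x
  i <- which(far$atoms$reskey == "A:2:")
  far$xyz[i, 3, 1] <- far$xyz[i, 3, 1] - 60
  cf <- alanine_scan(far, "A:2:")
  expect_lt(abs(cf$ddg), 0.1)
})

test_that("CAS/BFED comparison computes Pearson r with sign handling", {
  a <- data.frame(reskey = c("R:1:", "R:2:", "R:3:"), ddg = c(1, 2, 3))
  b <- data.frame(reskey = c("R:1:", "R:2:", "R:3:"), total = c(1, 2, 3))
  expect_equal(compare_cas_bfed(a, b, bfed_sign = 1)$r, 1)
  expect_equal(compare_cas_bfed(a, b, bfed_sign = -1)$r, -1)
  b2 <- b; b2$total <- -b$total
  expect_equal(compare_cas_bfed(a, b2)$r, 1)
  expect_error(compare_cas_bfed(a[1:2, ], b), "at least 3")
})

test_that("ddg_mutation applies the local summation rule", {
  tc <- toy(7)
  x <- tc$structure
  expect_error(ddg_mutation(x, x), "no differing residue")
  ## ALA -> GLU on the ligand groove near a receptor LYS ring residue
  lys_keys <- x$atoms$reskey[x$atoms$resid == "LYS" & x$atoms$partner == "receptor"]
  site <- "C:11:"
  mut <- build_point_mutant(x, site, "GLU")
  ms <- ddg_mutation(x, mut, contact_cutoff = 4.5)
  expect_s3_class(ms, "mutation_score")
  expect_true(ms$site == site)
  ## cutoff -> Inf equals the full sum over all residues
  ms_inf <- ddg_mutation(x, mut, contact_cutoff = Inf)
  bw <- bfed(x); bm <- bfed(mut)
  full <- sum(bm$total) - sum(bw$total)
  expect_equal(ms_inf$ddg, full, tolerance = 1e-9)
  ## numbering mismatch rejected
  y <- mut
  y$atoms$resno[y$atoms$reskey == "A:1:"] <- 99
  y$atoms$reskey[y$atoms$resno == 99] <- "A:99:"
  expect_error(ddg_mutation(x, y), "numbering mismatch")
})

test_that("a designed buried charge complement comes out ddG < 0", {
  ## micro complex: a +1 receptor site shielded by a neutral shell faces a
  ## ligand site 3.3 A below, likewise shielded; introducing a -1 charge at
  ## the ligand site is a designed ionic complement whose gain survives the
  ## solvent screening (the pair is partially buried)
  shell <- function(center, r, n = 14)
    sweep(tcrforge:::.sphere_points(n) * r, 2, center, "+")
  rec <- rbind(c(0, 0, 3.3), shell(c(0, 0, 6.0), 2.5))
  lig <- rbind(c(0, 0, 0), shell(c(0, 0, -2.7), 2.5))
  mkx <- function(qlig, resid_lig = "XXX") {
    n_r <- nrow(rec); n_l <- nrow(lig)
    x <- micro_structure(rbind(rec, lig),
                         charge = c(1, rep(0, n_r - 1), qlig, rep(0, n_l - 1)),
                         chain = c(rep("R", n_r), rep("L", n_l)),
                         resno = c(1, rep(2, n_r - 1), 1, rep(2, n_l - 1)),
                         name = c(paste0("X", 1:n_r), paste0("X", 1:n_l)),
                         receptor = "R", ligand = "L")
    x$atoms$resid[x$atoms$chain == "L" & x$atoms$resno == 1] <- resid_lig
    x
  }
  ms <- ddg_mutation(mkx(0), mkx(-1, "YYY"), contact_cutoff = 6)
  expect_lt(ms$ddg, 0)
  expect_gt(ms$n_contacts, 0)
  ## on the toy complex, a groove ALA -> GLU design gains electrostatics
  ## against the facing receptor lysine
  tc <- toy(12)
  x <- tc$structure
  rec_lys <- x$atoms$reskey[x$atoms$resid == "LYS" &
                              x$atoms$partner == "receptor"][1]
  nz <- x$xyz[x$atoms$reskey == rec_lys & x$atoms$name == "NZ", , 1]
  ala_keys <- unique(x$atoms$reskey[x$atoms$resid == "ALA" &
                                      x$atoms$partner == "ligand"])
  cb <- vapply(ala_keys, function(rk)
    sqrt(sum((x$xyz[x$atoms$reskey == rk & x$atoms$name == "CB", , 1] - nz)^2)),
    numeric(1))
  site <- ala_keys[which.min(cb)]
  mut <- build_point_mutant(x, site, "GLU")
  expect_lt(pair_elec(mut, site, rec_lys), pair_elec(x, site, rec_lys))
})

test_that("rank_designs orders by ddG with stable label ties", {
  mk <- function(lbl, ddg) structure(list(label = lbl, ddg = ddg,
                                          n_contacts = 1L),
                                     class = "mutation_score")
  r <- rank_designs(list(mk("b", 0.5), mk("a", -1.2), mk("c", -0.3)))
  expect_equal(r$ddg, c(-1.2, -0.3, 0.5))
  r2 <- rank_designs(list(mk("b", 1), mk("a", 1)))
  expect_equal(r2$label, c("a", "b"))
  expect_equal(nrow(rank_designs(list(mk("x", 0)))), 1)
})

test_that("K_D fold change reproduces the published affinity gain", {
  tab <- read_affinity_table(system.file("extdata", "bc1_affinity.tsv",
                                         package = "tcrforge"))
  wt <- tab$kd_um[tab$variant == "Wild-type"]
  best <- tab$kd_um[tab$variant == "a-S53W+b-G50A+A51E+A97L"]
  fc <- kd_fold_change(wt, best, temperature = 298)
  expect_gte(fc$fold, 150)
  expect_equal(fc$fold, 21.4 / 0.14, tolerance = 1e-12)
  expect_equal(fc$ddg_exp, 0.0019872 * 298 * log(21.4 / 0.14), tolerance = 1e-12)
  expect_equal(fc$ddg_exp, 2.98, tolerance = 0.005)
  ident <- kd_fold_change(21.4, 21.4)
  expect_equal(ident$fold, 1)
  expect_equal(ident$ddg_exp, 0)
  expect_error(kd_fold_change(-1, 2), "positive")
})
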