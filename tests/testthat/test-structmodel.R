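test_that("PDB round trip preserves topology and coordinates", {
  tc <- make_toy_complex(seed = 7, n_frames = 2)
  f1 <- tempfile(fileext = ".pdb")
  write_structure(tc$structure, f1)
  x <- read_structure(f1, frame_policy = "all")
  expect_equal(nrow(x$atoms), nrow(tc$structure$atoms))
  expect_equal(n_frames(x), 2)
  expect_equal(x$atoms$name, tc$structure$atoms$name)
  expect_equal(x$atoms$chain, tc$structure$atoms$chain)
  expect_lt(max(abs(x$xyz - tc$structure$xyz)), 1e-3 + 1e-9)
  ## second round trip is stable
  f2 <- tempfile(fileext = ".pdb")
  write_structure(x, f2)
  y <- read_structure(f2, frame_policy = "all")
  expect_equal(y$xyz, x$xyz)
})

test_that("frame policy controls multi-MODEL reading", {
  tc <- make_toy_complex(seed = 3, n_frames = 5)
  f <- tempfile(fileext = ".pdb")
  write_structure(tc$structure, f)
  expect_equal(n_frames(read_structure(f, "all")), 5)
  expect_equal(n_frames(read_structure(f, "first")), 1)
})

test_that("inconsistent MODEL blocks and empty files are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL", "END"), f)
  expect_error(read_structure(f, "all"), "inconsistent models")
  writeLines(c("REMARK nothing", "END"), f)
  expect_error(read_structure(f), "no atoms")
})

test_that("alternate locations resolve to the highest occupancy, tie to A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  x <- read_structure(f)
  expect_equal(nrow(x$atoms), 2)
  expect_equal(x$xyz[x$atoms$name == "CA", 1, 1], 9)  # higher occupancy wins
  expect_equal(x$xyz[x$atoms$name == "CB", 1, 1], 1)  # tie -> altloc A
})

test_that("parameter assignment satisfies formal-charge sums and is idempotent", {
  tc <- make_toy_complex(seed = 7)
  x1 <- assign_parameters(tc$structure)
  q <- residue_charges(x1)
  expect_true(all(abs(q - round(q)) < 1e-4))
  resid <- x1$atoms$resid[match(names(q), x1$atoms$reskey)]
  expect_true(all(round(q[resid == "LYS"]) == 1))
  expect_true(all(round(q[resid == "ASP"]) == -1))
  x2 <- assign_parameters(x1)
  expect_equal(nrow(x2$atoms), nrow(x1$atoms))
  expect_equal(x2$atoms$charge, x1$atoms$charge)
  expect_equal(x2$xyz, x1$xyz)
})

test_that("every standard template carries its formal charge in the table", {
  tab <- default_parameter_table()
  for (t in unique(tab$template)) {
    rows <- tab[tab$template == t, ]
    expect_lt(abs(sum(rows$charge) - rows$formal[1]), 1e-4)
  }
})

test_that("unknown residues follow the requested policy", {
  tc <- make_toy_complex(seed = 7)
  x <- tc$structure
  x$atoms$resid[x$atoms$reskey == "A:1:"] <- "LIG"  # pretend HETATM ligand
  x$atoms$het[x$atoms$reskey == "A:1:"] <- TRUE
  expect_error(assign_parameters(x, unknown_policy = "error"), "unknown residue")
  expect_warning(y <- assign_parameters(x, unknown_policy = "skip-residue"),
                 "skipped")
  expect_false("A:1:" %in% y$atoms$reskey)
})

test_that("polar hydrogens are built for structures read without them", {
  tc <- make_toy_complex(seed = 7)
  x <- tc$structure
  keep <- x$atoms$element != "H"
  x$atoms <- x$atoms[keep, , drop = FALSE]
  x$xyz <- x$xyz[keep, , , drop = FALSE]
  y <- assign_parameters(x)
  ser_key <- unique(y$atoms$reskey[y$atoms$resid == "SER"])[1]
  ser <- y$atoms$name[y$atoms$reskey == ser_key]
  expect_true("HG" %in% ser)
  ## built hydrogen sits at its ideal bond length
  i_og <- which(y$atoms$reskey == ser_key & y$atoms$name == "OG")
  i_hg <- which(y$atoms$reskey == ser_key & y$atoms$name == "HG")
  expect_equal(sqrt(sum((y$xyz[i_og, , 1] - y$xyz[i_hg, , 1])^2)), 0.96,
               tolerance = 1e-6)
})

test_that("partner split validates chains", {
  tc <- make_toy_complex(seed = 7)
  x <- tc$structure
  s <- split_partners(x, c("D", "E"), c("A", "C"))
  expect_setequal(unique(s$atoms$partner[s$atoms$chain == "D"]), "receptor")
  expect_error(split_partners(x, "A", "A"), "overlap")
  expect_error(split_partners(x, c("D", "E"), "Z"), "missing chain")
})

test_that("region tagging honours ranges and defaults", {
  tc <- make_toy_complex(seed = 7)
  x <- split_partners(tc$structure, c("D", "E"), c("A", "C"))
  y <- tag_regions(x, tc$region_map)
  expect_true(all(y$atoms$region[y$atoms$chain == "A"] == "peptide"))
  expect_true("CDR3a" %in% y$atoms$region)
  ## untagged receptor residues default to framework
  y2 <- tag_regions(x, data.frame(chain = "A", start = 1, end = 3,
                                  region = "peptide"))
  expect_true(all(y2$atoms$region[y2$atoms$partner == "receptor"] == "framework"))
  expect_error(tag_regions(x, data.frame(chain = "D", start = 900, end = 999,
                                         region = "CDR1a")), "outside chain")
  expect_error(tag_regions(x, rbind(
    data.frame(chain = "D", start = 1, end = 3, region = "CDR1a"),
    data.frame(chain = "D", start = 2, end = 4, region = "CDR2a"))),
    "overlapping")
})

test_that("alanine truncation removes the side chain and nothing else", {
  tc <- toy(7)
  x <- tc$structure
  target <- tc$truth$hotspots[1]   # an ASP or LYS ring residue
  m <- build_alanine_mutant(x, target)
  idx_wt <- which(x$atoms$reskey == target)
  idx_mt <- which(m$atoms$reskey == target)
  expect_equal(m$atoms$resid[idx_mt[1]], "ALA")
  expect_lt(length(idx_mt), length(idx_wt))
  ## backbone atoms immobile, all other residues identical
  for (a in c("N", "CA", "C", "O", "CB")) {
    i <- idx_wt[x$atoms$name[idx_wt] == a]
    j <- idx_mt[m$atoms$name[idx_mt] == a]
    expect_equal(m$xyz[j, , 1], x$xyz[i, , 1])
  }
  others_wt <- x$xyz[x$atoms$reskey != target, , 1]
  others_mt <- m$xyz[m$atoms$reskey != target, , 1]
  expect_equal(others_mt, others_wt)
  ## repeated truncation and special cases are errors
  expect_error(build_alanine_mutant(m, target), "already ALA")
  with_gly <- build_point_mutant(x, "A:1:", "GLY")
  expect_error(build_alanine_mutant(with_gly, "A:1:"), "GLY")
})

test_that("point mutants grow ideal side chains on a fixed backbone", {
  tc <- toy(7)
  x <- tc$structure
  ## surface ALA -> GLU gains 4 heavy atoms (CB stays, +CG +CD +OE1 +OE2)
  ala <- x$atoms$reskey[x$atoms$resid == "ALA" & x$atoms$chain == "C"][1]
  heavy <- function(s, rk) sum(s$atoms$reskey == rk & s$atoms$element != "H")
  m <- build_point_mutant(x, ala, "GLU")
  expect_equal(heavy(m, ala) - heavy(x, ala), 4)
  expect_equal(m$atoms$resid[m$atoms$reskey == ala][1], "GLU")
  for (a in c("N", "CA", "C", "O", "CB")) {
    i <- which(x$atoms$reskey == ala & x$atoms$name == a)
    j <- which(m$atoms$reskey == ala & m$atoms$name == a)
    expect_equal(m$xyz[j, , 1], x$xyz[i, , 1])
  }
  ## identity mutation is a no-op
  expect_identical(build_point_mutant(x, ala, "ALA"), x)
  ## determinism
  m2 <- build_point_mutant(x, ala, "GLU")
  expect_identical(m$xyz, m2$xyz)
  ## mutant net charge updated
  q <- residue_charges(m)[ala]
  expect_equal(unname(round(q)), -1)
})

test_that("a mutation into a packed pocket reports the clash", {
  ## dense cage around a small residue: growing a bulky ring cannot fit
  tc <- toy(7)
  x <- tc$structure
  x <- build_point_mutant(x, "A:1:", "GLY")
  gly <- "A:1:"
  cage_dir <- expand.grid(a = seq(0, 300, 60), z = c(-2, 2))
  ca <- x$xyz[x$atoms$reskey == gly & x$atoms$name == "CA", , 1]
  extra <- t(vapply(seq_len(nrow(cage_dir)), function(i) {
    ca + c(3 * cospi(cage_dir$a[i] / 180), 3 * sinpi(cage_dir$a[i] / 180),
           cage_dir$z[i])
  }, numeric(3)))
  n0 <- nrow(x$atoms)
  row <- x$atoms[rep(which(x$atoms$name == "CB")[1], nrow(extra)), ]
  row$chain <- "C"; row$resno <- 900 + seq_len(nrow(extra))
  row$reskey <- paste0("C:", row$resno, ":")
  x$atoms <- rbind(x$atoms, row)
  arr <- array(NA_real_, dim = c(n0 + nrow(extra), 3, 1))
  arr[seq_len(n0), , 1] <- x$xyz[, , 1]
  arr[n0 + seq_len(nrow(extra)), , 1] <- extra
  x$xyz <- arr
  expect_error(build_point_mutant(x, gly, "TRP"), "clash")
})
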