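## Deterministic synthetic fixtures.
##
## make_toy_complex() builds a miniature TCR-pMHC-like complex with a known
## ("engineered") native orientation: a ring of charged residues on the
## ligand (the analog of the charged ring at the pMHC surface) faces a
## complementary ring on the receptor's CDR1/2-tagged loops, so the bound
## pose is an electrostatic lock at a known rotation angle. A short neutral
## "peptide" chain and neutral CDR3-tagged residues sit at the center. The
## fixtures are geometrically sane mini-complexes, not physically realistic
## proteins: they encode the statistical and geometric structure the
## estimators assume, nothing more.

## Place one template residue: CA at `ca`, side chain (CA->CB) pointing
## along `dir`, spun about `dir` by `spin` degrees.
.place_toy_residue <- function(template, ca, dir, spin = 0, chi = NULL,
                               azimuth_atom = NULL) {
  r <- build_residue(template, chi = chi)
  X <- r$xyz
  ca0 <- X[r$names == "CA", ]
  X <- sweep(X, 2, ca0)
  u <- if ("CB" %in% r$names) X[r$names == "CB", ] else X[r$names == "C", ]
  u <- .unit(u); dir <- .unit(dir)
  ax <- .cross(u, dir)
  if (.vnorm(ax) < 1e-8) {
    R1 <- if (sum(u * dir) > 0) diag(3) else rotation_matrix(c(1, 0, 0), 180)
  } else {
    ang <- acos(max(-1, min(1, sum(u * dir)))) * 180 / pi
    R1 <- rotation_matrix(ax, ang)
  }
  X <- X %*% t(R1)
  X <- X %*% t(rotation_matrix(dir, spin))
  X <- sweep(X, 2, ca, "+")
  if (!is.null(azimuth_atom)) {
    if (is.numeric(azimuth_atom)) {
      ## choose the spin that concentrates the charge distribution in the
      ## residue's radial-vertical plane: minimising the |q|-weighted squared
      ## tangential offset makes the charges (e.g. a carboxylate pair) as
      ## mirror-symmetric about the site azimuth as the geometry allows, so
      ## an engineered ring's angular energy profile is even about the lock
      q <- abs(azimuth_atom[r$names])
      u_t <- c(-ca[2], ca[1], 0)
      nt <- sqrt(sum(u_t^2))
      if (nt > 1e-6 && sum(q) > 0) {
        u_t <- u_t / nt
        Xc <- sweep(X, 2, ca)
        spins <- seq(0, 358, by = 2)
        pen <- vapply(spins, function(th) {
          d <- .rotate_coords(Xc, c(0, 0, 1), th) %*% u_t
          sum(q * d^2)
        }, numeric(1))
        X <- sweep(.rotate_coords(Xc, c(0, 0, 1), spins[which.min(pen)]),
                   2, ca, "+")
      }
    } else {
      tip <- colMeans(X[r$names %in% azimuth_atom, , drop = FALSE]) - ca
      if (sqrt(sum(tip[1:2]^2)) > 1e-6 && sqrt(sum(ca[1:2]^2)) > 1e-6) {
        want <- atan2(ca[2], ca[1]); have <- atan2(ca[2] + tip[2], ca[1] + tip[1])
        X <- sweep(.rotate_coords(sweep(X, 2, ca), c(0, 0, 1),
                                  (want - have) * 180 / pi), 2, ca, "+")
      }
    }
  }
  list(names = r$names, xyz = X)
}

## charge-bearing tip atom used to calibrate salt-bridge geometry, and the
## atoms whose centroid carries the side-chain charge (used to keep the
## charge centroid on the site azimuth)
.TIP_ATOM <- c(LYS = "NZ", ASP = "OD1", ARG = "NH1", GLU = "OE1")
.CHARGE_GROUP <- list(LYS = c("NZ", "HZ1", "HZ2", "HZ3"),
                      ASP = c("OD1", "OD2"),
                      ARG = c("NH1", "NH2", "NE"),
                      GLU = c("OE1", "OE2"))

#' Generate a synthetic TCR-pMHC-like toy complex
#'
#' Builds a deterministic mini-complex: ligand chain C ("MHC") carries a
#' ring of `n_lock` charged residues (LYS/ASP in a seed-derived aperiodic
#' +/- pattern, at least 3 of each sign) plus neutral groove residues;
#' chain A is a short neutral "peptide"; receptor chains D/E ("TCR alpha /
#' beta") carry the complementary charge ring on CDR1/2-tagged residues
#' plus neutral CDR3-tagged residues over the peptide. The complementary
#' ring is placed so the electrostatic lock closes when the receptor is at
#' rotation `native_angle` (0 = the pose as written). Salt-bridge tip
#' distances are calibrated to ~3.4 A.
#'
#' @param seed integer seed; all randomness (pattern, spins, jitter) derives
#'   from it, so equal seeds give byte-identical output.
#' @param n_lock number of charged ring sites (>= 6, even).
#' @param ring_radius ring radius, Angstrom.
#' @param native_angle rotation angle (degrees, in `[0, 360)`) at which the
#'   lock closes.
#' @param n_frames coordinate frames (jittered copies sharing the topology).
#' @param noise per-coordinate jitter standard deviation, Angstrom.
#' @param dir if non-NULL, directory into which the PDB, the truth JSON
#'   sidecar and the region-map YAML are written.
#' @param basename file basename used inside `dir`.
#' @return A list: `structure` (unparameterized `tcr_structure`),
#'   `receptor_chains`, `ligand_chains`, `region_map` (data frame), `truth`
#'   (native_angle, the construction axis -- the receptor here is a flat
#'   loop disk whose inertia axis is deliberately ambiguous, so scans of the
#'   toy should pass `axis = truth$axis` -- hotspots, pattern, expected
#'   interaction signs, seed),
#'   and file paths (`pdb`, `truth_json`, `region_yaml`) when `dir` given.
#' @export
make_toy_complex <- function(seed = 1, n_lock = 8, ring_radius = 14,
                             native_angle = 0, n_frames = 1, noise = 0.15,
                             dir = NULL, basename = "toy_complex") {
  if (n_lock < 6 || n_lock %% 2 != 0) stop("n_lock must be even and >= 6")
  if (native_angle < 0 || native_angle >= 360) stop("native_angle must be in [0, 360)")
  set.seed(as.integer(seed))

  ## aperiodic +/- pattern with at least 3 of each sign
  repeat {
    sgn <- sample(c(-1, 1), n_lock, replace = TRUE)
    if (sum(sgn > 0) < 3 || sum(sgn < 0) < 3) next
    periodic <- any(vapply(seq_len(n_lock - 1), function(r)
      all(sgn == sgn[((seq_len(n_lock) - 1 + r) %% n_lock) + 1]), logical(1)))
    if (!periodic) break
  }

  phi <- (seq_len(n_lock) - 1) * 360 / n_lock
  deg2xy <- function(a, r) c(r * cos(a * pi / 180), r * sin(a * pi / 180))

  ## placement attempt: random side-chain spins can collide in a disconnected
  ## mini-complex, so the whole placement is regenerated (new spins, new
  ## jitter) up to 10 times before giving up
  for (attempt in seq_len(30)) {
  atoms <- list(); xyz <- list()
  add_res <- function(chain, resno, template, ca, dirv, spin, region) {
    pr <- .place_toy_residue(template, ca, dirv, spin)
    n <- length(pr$names)
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = pr$names, resid = template, chain = chain, resno = resno,
      region = region, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- pr$xyz
  }

  ## ligand lock ring (chain C): LYS for +, ASP for -, side chains up,
  ## CA atoms coplanar at z = 0. Because complementary sites always pair a
  ## long LYS with a short ASP stalk, keeping both rings' CA planes flat
  ## makes every engineered tip gap identical by construction (and keeps
  ## the receptor's principal axis exactly perpendicular to the ring).
  ptab <- default_parameter_table()
  q_of <- function(t) stats::setNames(ptab$charge[ptab$template == t],
                                      ptab$atom[ptab$template == t])
  stalk <- vapply(c(LYS = "LYS", ASP = "ASP"), function(t) {
    r <- .place_toy_residue(t, c(0, 0, 0), c(0, 0, 1))
    r$xyz[r$names == .TIP_ATOM[t], 3]
  }, numeric(1))
  pep_tip <- 3.6
  for (k in seq_len(n_lock)) {
    template <- if (sgn[k] > 0) "LYS" else "ASP"
    ca <- c(deg2xy(phi[k], ring_radius), 0)
    pr <- .place_toy_residue(template, ca, c(0, 0, 1),
                             spin = stats::runif(1, 0, 360),
                             azimuth_atom = q_of(template))
    atoms[[length(atoms) + 1]] <- data.frame(
      name = pr$names, resid = template, chain = "C", resno = k,
      region = "MHC", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- pr$xyz
  }
  ## neutral groove residues (chain C), offset from the lock sites and
  ## slightly below the ring plane
  for (k in seq_len(4)) {
    a <- 22.5 + (k - 1) * 90
    add_res("C", n_lock + k, "ALA", c(deg2xy(a, 0.55 * ring_radius), -3),
            c(0, 0, 1), stats::runif(1, 0, 360), "MHC")
  }
  ## peptide (chain A); the central LEU is the ligand half of an engineered
  ## nonpolar patch (vdW contacts are not screened by the solvent model, so
  ## this is the fixture's strong hotspot)
  ## all-leucine peptide: each residue is the ligand half of an engineered
  ## nonpolar patch, with a fixed orientation so the contacts have
  ## reproducible magnitudes
  pep <- c("LEU", "LEU", "LEU", "LEU")
  pep_x <- c(-5.7, -1.9, 1.9, 5.7)
  pep_tops <- numeric(length(pep))
  for (k in seq_along(pep)) {
    pr <- .place_toy_residue(pep[k], c(pep_x[k], 0, 1.4), c(0, 0, 1), spin = 0)
    sc <- !pr$names %in% c("N", "CA", "C", "O", "H")
    pr$xyz[, 3] <- pr$xyz[, 3] + (pep_tip - max(pr$xyz[sc, 3]))
    pep_tops[k] <- max(pr$xyz[!grepl("^H", pr$names), 3])
    atoms[[length(atoms) + 1]] <- data.frame(
      name = pr$names, resid = pep[k], chain = "A", resno = k,
      region = "peptide", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- pr$xyz
  }

  ## receptor lock ring (chains D, E), complementary charge, side chains
  ## down, CA atoms coplanar at the height that sets every bridge tip gap
  ## to 5.5 A: the ring drives the long-range orientation signal and the
  ## sign fixtures, while the bound-state interface energetics are
  ## dominated by the engineered nonpolar patches below (as packing
  ## dominates a real TCR-pMHC interface)
  rec_height <- stalk[["LYS"]] + stalk[["ASP"]] + 5.5
  half <- n_lock / 2
  rec_regions <- c(rep(c("CDR1a", "CDR2a"), each = ceiling(half / 2))[seq_len(half)],
                   rep(c("CDR1b", "CDR2b"), each = ceiling(half / 2))[seq_len(half)])
  hotspots <- character(0)
  for (k in seq_len(n_lock)) {
    template <- if (sgn[k] > 0) "ASP" else "LYS"   # complementary
    chain <- if (k <= half) "D" else "E"
    resno <- if (k <= half) k else k - half
    ca <- c(deg2xy(phi[k] + native_angle, ring_radius), rec_height)
    pr <- .place_toy_residue(template, ca, c(0, 0, -1),
                             spin = stats::runif(1, 0, 360),
                             azimuth_atom = q_of(template))
    atoms[[length(atoms) + 1]] <- data.frame(
      name = pr$names, resid = template, chain = chain, resno = resno,
      region = rec_regions[k], stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- pr$xyz
    hotspots <- c(hotspots, .res_key(chain, resno))
  }
  ## CDR3 residues over the peptide: four engineered nonpolar patches of
  ## graded strength, one per peptide leucine (vdW contacts are not
  ## screened by the solvent model, so these are the interface's genuine
  ## hotspots), plus a small neutral serine with no engineered contact:
  ##   D:half+1  MET over peptide 2 (strong)    E:half+1  MET over peptide 1
  ##   D:half+2  ILE over peptide 3 (weak)      E:half+2  LEU over peptide 4
  ##   D:half+3  SER (near-zero anchor)
  np_hotspot <- .res_key("D", half + 1)
  rot2 <- function(x, y, a) {
    th <- a * pi / 180
    c(x * cos(th) - y * sin(th), x * sin(th) + y * cos(th))
  }
  ## patch side chains lean perpendicular to the peptide row, with one
  ## common spin so neighbouring patches are pure translates of each other
  ## (they cannot interfere); each residue is translated so its side-chain
  ## centroid sits over its peptide partner at the calibrated vertical gap
  cdr3 <- list(
    list(chain = "D", resno = half + 1, template = "MET", spin = 90,
         over = 2, tip = pep_tops[2] + 3.2, region = "CDR3a"),
    list(chain = "D", resno = half + 2, template = "ILE", spin = 90,
         over = 3, tip = pep_tops[3] + 4.0, region = "CDR3a"),
    list(chain = "E", resno = half + 1, template = "MET", spin = 90,
         over = 1, tip = pep_tops[1] + 3.6, region = "CDR3b"),
    list(chain = "E", resno = half + 2, template = "LEU", spin = 90,
         over = 4, tip = pep_tops[4] + 4.4, region = "CDR3b"),
    list(chain = "D", resno = half + 3, template = "SER", spin = NA,
         over = NA, tip = NA, region = "CDR3a"))
  for (cd in cdr3) {
    target <- if (is.na(cd$over)) deg2xy(247.5, 4.6) else c(pep_x[cd$over], 0)
    target <- rot2(target[1], target[2], native_angle)
    zca <- if (is.na(cd$over)) rec_height + 2 else rec_height - 1
    pr <- .place_toy_residue(cd$template, c(target, zca),
                             c(0, 0, -1),
                             spin = if (is.na(cd$spin)) stats::runif(1, 0, 360)
                                    else cd$spin + native_angle)
    if (!is.na(cd$tip)) {
      sc <- !pr$names %in% c("N", "CA", "C", "O", "H")
      pr$xyz[, 3] <- pr$xyz[, 3] + (cd$tip - min(pr$xyz[sc, 3]))
      cen <- colMeans(pr$xyz[sc, 1:2, drop = FALSE])
      pr$xyz[, 1] <- pr$xyz[, 1] + (target[1] - cen[1])
      pr$xyz[, 2] <- pr$xyz[, 2] + (target[2] - cen[2])
    }
    atoms[[length(atoms) + 1]] <- data.frame(
      name = pr$names, resid = cd$template, chain = cd$chain,
      resno = cd$resno, region = cd$region, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- pr$xyz
  }

  ## framework counterweight (chain D): one ALA above the loops placed so
  ## the receptor's lateral center of mass sits exactly on the ring axis --
  ## the scan rotates about the receptor COM, and a lateral COM offset
  ## would skew the angular landscape around the engineered lock
  {
    pr <- .place_toy_residue("ALA", c(0, 0, rec_height + 5), c(0, 0, 1),
                             spin = stats::runif(1, 0, 360))
    rec_rows <- do.call(rbind, atoms)
    rec_sel <- rec_rows$chain %in% c("D", "E")
    M <- colSums(do.call(rbind, xyz)[rec_sel, 1:2, drop = FALSE]) +
      colSums(pr$xyz[, 1:2, drop = FALSE])
    pr$xyz[, 1] <- pr$xyz[, 1] - M[1] / nrow(pr$xyz)
    pr$xyz[, 2] <- pr$xyz[, 2] - M[2] / nrow(pr$xyz)
    atoms[[length(atoms) + 1]] <- data.frame(
      name = pr$names, resid = "ALA", chain = "D", resno = half + 4,
      region = "framework", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- pr$xyz
  }

  at <- do.call(rbind, atoms)
  base <- do.call(rbind, xyz)
  ## order chains A, C, D, E
  ord <- order(match(at$chain, c("A", "C", "D", "E")), at$resno)
  at <- at[ord, , drop = FALSE]
  base <- base[ord, , drop = FALSE]
  at$icode <- ""
  at$het <- FALSE
  at$element <- .element_of(at$name)
  at$serial <- seq_len(nrow(at))
  at$charge <- at$rmin2 <- at$eps <- at$born <- NA_real_
  at$partner <- NA_character_
  at$reskey <- .res_key(at$chain, at$resno, at$icode)
  resblock <- at[, c("name", "resid", "reskey")]

  ## jittered frames with clash screening on frame 1
  heavy <- at$element != "H"
  rv <- .CLASH_RADII[at$element[heavy]]
  ## ignore intra-residue pairs, chain neighbours (nominally bonded) and
  ## same-partner ring neighbours (circularly adjacent lock sites, which
  ## never enter inter-partner energies)
  site <- rep(NA_real_, nrow(at))
  site[at$chain == "C" & at$resno <= n_lock] <-
    at$resno[at$chain == "C" & at$resno <= n_lock]
  site[at$chain == "D" & at$resno <= half] <-
    at$resno[at$chain == "D" & at$resno <= half]
  site[at$chain == "E" & at$resno <= half] <-
    at$resno[at$chain == "E" & at$resno <= half] + half
  ring <- ifelse(is.na(site), NA, ifelse(at$chain == "C", "lig", "rec"))
  sh <- site[heavy]; rh <- ring[heavy]
  dsite <- abs(outer(sh, sh, "-"))
  ring_adj <- !is.na(outer(rh, rh, paste)) &
    outer(rh, rh, "==") & !is.na(dsite) &
    (dsite == 1 | dsite == n_lock - 1)
  ring_adj[is.na(ring_adj)] <- FALSE
  same_res <- outer(at$reskey[heavy], at$reskey[heavy], "==") |
    (outer(at$chain[heavy], at$chain[heavy], "==") &
       abs(outer(at$resno[heavy], at$resno[heavy], "-")) == 1) |
    ring_adj
  ## strict clash bar across the interface (these poison inter-partner
  ## energies); looser bar within a partner (dense packing is tolerable)
  part <- ifelse(at$chain[heavy] %in% c("D", "E"), "rec", "lig")
  fac <- ifelse(outer(part, part, "=="), 0.45, 0.6)
  thr <- fac * outer(rv, rv, "+")
  arr <- array(NA_real_, dim = c(nrow(at), 3, n_frames))
  failed <- FALSE; last_bad <- NULL
  for (f in seq_len(n_frames)) {
    cand <- base + matrix(stats::rnorm(length(base), 0, noise), ncol = 3)
    D <- .cross_dist(cand[heavy, , drop = FALSE], cand[heavy, , drop = FALSE])
    bad <- which(D < thr & !same_res & upper.tri(D), arr.ind = TRUE)
    if (nrow(bad) > 0) { failed <- TRUE; last_bad <- bad; break }
    arr[, , f] <- cand
  }
  if (!failed) break
  if (attempt == 30) {
    hi <- which(heavy)
    stop("could not place a clash-free fixture; clashes: ",
         paste(utils::head(apply(last_bad, 1, function(p)
           paste0(at$reskey[hi[p[1]]], "/", at$name[hi[p[1]]], "~",
                  at$reskey[hi[p[2]]], "/", at$name[hi[p[2]]])), 8),
           collapse = ", "))
  }
  } # attempt loop

  keep_cols <- c("serial", "name", "resid", "chain", "resno", "icode", "het",
                 "element", "charge", "rmin2", "eps", "born", "region",
                 "partner", "reskey")
  x <- .new_structure(at[, keep_cols], arr)

  region_map <- rbind(
    data.frame(chain = "A", start = 1, end = length(pep), region = "peptide"),
    data.frame(chain = "C", start = 1, end = n_lock + 4, region = "MHC"),
    data.frame(chain = "D", start = 1, end = ceiling(half / 2), region = "CDR1a"),
    data.frame(chain = "D", start = ceiling(half / 2) + 1, end = half, region = "CDR2a"),
    data.frame(chain = "D", start = half + 1, end = half + 3, region = "CDR3a"),
    
    data.frame(chain = "D", start = half + 4, end = half + 4, region = "framework"),
    data.frame(chain = "E", start = 1, end = ceiling(half / 2), region = "CDR1b"),
    data.frame(chain = "E", start = ceiling(half / 2) + 1, end = half, region = "CDR2b"),
    data.frame(chain = "E", start = half + 1, end = half + 2, region = "CDR3b"))

  truth <- list(seed = seed, native_angle = native_angle, axis = c(0, 0, 1),
                pattern = sgn, hotspots = hotspots, np_hotspot = np_hotspot,
                expected_sign = "salt bridges: negative elec contribution",
                n_lock = n_lock, ring_radius = ring_radius,
                receptor_height = rec_height, noise = noise)

  out <- list(structure = x, receptor_chains = c("D", "E"),
              ligand_chains = c("A", "C"), region_map = region_map,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pdb <- file.path(dir, paste0(basename, ".pdb"))
    tj <- file.path(dir, paste0(basename, "_truth.json"))
    ry <- file.path(dir, paste0(basename, "_regions.yaml"))
    write_structure(x, pdb)
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(list(regions = lapply(seq_len(nrow(region_map)), function(i)
      as.list(region_map[i, ]))), ry)
    out$pdb <- pdb; out$truth_json <- tj; out$region_yaml <- ry
  }
  out
}

#' Ready-to-score toy complex
#'
#' Convenience wrapper: [make_toy_complex()] then parameterize, split
#' partners and tag regions.
#'
#' @inheritParams make_toy_complex
#' @param ... passed to [make_toy_complex()].
#' @return A list as from [make_toy_complex()] but with `structure`
#'   parameterized, partner-split and region-tagged.
#' @export
toy_structure <- function(seed = 1, ...) {
  tc <- make_toy_complex(seed = seed, ...)
  x <- assign_parameters(tc$structure)
  x <- split_partners(x, tc$receptor_chains, tc$ligand_chains)
  x <- tag_regions(x, tc$region_map)
  tc$structure <- x
  tc
}

#' Synthetic work ensembles with known reference free energy
#'
#' Endpoint work values drawn from a declared distribution, with the exact
#' Jarzynski free energy recorded: for Gaussian work,
#' dG = mu - beta sigma^2 / 2; for shifted-gamma work (shift s, shape k,
#' scale theta), dG = s + (k/beta) ln(1 + beta theta). The shifted-gamma
#' family has a shorter-than-Gaussian lower tail (positive skew), the
#' regime in which direct exponential averaging overestimates and the
#' cumulant expansion underestimates the true free energy. Defaults emulate
#' a strongly dissipative protein-protein unbinding at 300 K: work of order
#' 10^2 kJ/mol with dissipation far exceeding k_B T.
#'
#' @param kind `"gaussian"` or `"shifted-gamma"`.
#' @param params list: gaussian `mean`, `sd`; shifted-gamma `shape`,
#'   `scale`, `shift` (kJ/mol).
#' @param n number of trajectories (default 150).
#' @param seed integer seed.
#' @param context a [thermo_context()].
#' @param path optional TSV output (two-row work table: xi = 0, 1).
#' @return A list: `work` (kJ/mol), `truth_dg`, `kind`, `params`, and
#'   `profiles` (a 2-point [work_profile_set()]).
#' @export
make_work_ensemble <- function(kind = c("gaussian", "shifted-gamma"),
                               params = list(), n = 150, seed = 1,
                               context = thermo_context(), path = NULL) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  b <- context$beta_kj
  if (kind == "gaussian") {
    mu <- params$mean %||% 20; sd <- params$sd %||% 5
    if (sd < 0) stop("sd must be >= 0")
    w <- stats::rnorm(n, mu, sd)
    truth <- mu - b * sd^2 / 2
  } else {
    shape <- params$shape %||% 30; scale <- params$scale %||% 6
    shift <- params$shift %||% 5
    if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
    w <- shift + stats::rgamma(n, shape, scale = scale)
    truth <- shift + shape / b * log(1 + b * scale)
  }
  profiles <- work_profile_set(c(0, 1), rbind(0, w), units = "nm")
  out <- list(work = w, truth_dg = truth, kind = kind,
              params = params, n = n, seed = seed, profiles = profiles)
  if (!is.null(path))
    write_work_table(profiles, path,
                     header = sprintf("# kind=%s seed=%d truth_dg=%.6f",
                                      kind, seed, truth))
  out
}

#' Synthetic lambda series with known integral
#'
#' @param form `"constant"`, `"linear"`, `"pow34"` (c lambda^(-3/4)) or
#'   `"poly"` (coefficients of increasing powers).
#' @param coef numeric coefficient(s): constant value; linear `c(a, b)` for
#'   a + b lambda; pow34 scale c; poly coefficients.
#' @param grid `"paper11"` (the 11-point grid 0.02, 0.1, ..., 0.9, 0.98) or
#'   a numeric grid in (0, 1).
#' @param noise Gaussian noise sd added to dudl.
#' @param seed integer seed (used when noise > 0).
#' @return A list: `series` (a [lambda_series()]) and `truth` (the analytic
#'   integral over \[0, 1\]).
#' @param path optional TSV output.
#' @export
make_lambda_series <- function(form = c("constant", "linear", "pow34", "poly"),
                               coef = 1, grid = "paper11", noise = 0,
                               seed = 1, path = NULL) {
  form <- match.arg(form)
  lam <- if (identical(grid, "paper11")) .PAPER11 else as.numeric(grid)
  if (any(lam <= 0) || any(lam >= 1) || any(diff(lam) <= 0))
    stop("invalid lambda grid")
  f <- switch(form,
    constant = {
      truth <- coef[1]
      function(l) rep(coef[1], length(l))
    },
    linear = {
      if (length(coef) < 2) coef <- c(0, coef)
      truth <- coef[1] + coef[2] / 2
      function(l) coef[1] + coef[2] * l
    },
    pow34 = {
      truth <- 4 * coef[1]
      function(l) coef[1] * l^(-3 / 4)
    },
    poly = {
      truth <- sum(coef / seq_along(coef))
      function(l) drop(outer(l, seq_along(coef) - 1, "^") %*% coef)
    })
  y <- f(lam)
  if (noise > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, noise)
  }
  ser <- lambda_series(lam, y, se = if (noise > 0) rep(noise, length(y)) else NULL)
  if (!is.null(path))
    write_lambda_table(ser, path,
                       header = sprintf("# form=%s truth=%.6f", form, truth))
  list(series = ser, truth = truth)
}
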