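## MM-GBSA energetics.
##
## The binding energy is evaluated in the single-trajectory approximation:
## every term is computed on the complex and on each isolated partner using
## the same frames, so the conformational reorganisation term is zero by
## construction. Terms:
##   elec  inter-partner Coulomb energy (interior dielectric eps_in)
##   vdw   inter-partner Lennard-Jones energy
##   gb    Generalized Born electrostatic solvation (pairwise form, HCT
##         effective radii)
##   np    nonpolar solvation, gamma * SASA + b
## All energies kcal/mol, lengths Angstrom, charges elementary charges.

#' Dielectric model for the GB term
#'
#' @param eps_in solute (interior) dielectric, >= 1.
#' @param eps_out solvent dielectric.
#' @return A `dielectric_model` list.
#' @export
dielectric_model <- function(eps_in = 1, eps_out = 78.5) {
  if (eps_in < 1 || eps_out <= eps_in)
    stop("need eps_out > eps_in >= 1")
  structure(list(eps_in = eps_in, eps_out = eps_out),
            class = "dielectric_model")
}

#' Nonpolar solvation parameters
#'
#' The nonpolar solvation free energy is gamma * SASA + b, the conventional
#' surface-area model.
#'
#' @param gamma surface tension coefficient, kcal/mol/A^2.
#' @param b intercept, kcal/mol.
#' @param probe_radius solvent probe radius, Angstrom.
#' @return A `nonpolar_params` list.
#' @export
nonpolar_params <- function(gamma = 0.00542, b = 0.92, probe_radius = 1.4) {
  if (gamma < 0 || probe_radius <= 0) stop("need gamma >= 0 and probe_radius > 0")
  structure(list(gamma = gamma, b = b, probe_radius = probe_radius),
            class = "nonpolar_params")
}

.check_param <- function(x) {
  if (is.na(x$parameter_source)) stop("structure is not parameterized")
  invisible(x)
}

## resolve a group argument (residue keys, or NULL meaning a partner) to
## atom row indices
.group_idx <- function(x, group) {
  if (is.numeric(group)) return(as.integer(group))
  if (length(group) == 1 && group %in% c("receptor", "ligand"))
    return(which(x$atoms$partner %in% group))
  .atoms_of(x, group)
}

## cross distance matrix between two coordinate blocks
.cross_dist <- function(A, B) {
  a2 <- rowSums(A * A); b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Inter-group Coulomb energy
#'
#' Sum over atom pairs of k q_i q_j / (eps_in r_ij), averaged over frames.
#'
#' @param x a parameterized `tcr_structure`.
#' @param group_a,group_b residue key vectors, atom indices, or the strings
#'   `"receptor"` / `"ligand"`.
#' @param eps_in interior dielectric.
#' @return Energy in kcal/mol.
#' @export
pair_elec <- function(x, group_a = "receptor", group_b = "ligand", eps_in = 1) {
  .check_param(x)
  ia <- .group_idx(x, group_a); ib <- .group_idx(x, group_b)
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (length(ia) == 0 || length(ib) == 0) return(0)
  qa <- x$atoms$charge[ia]; qb <- x$atoms$charge[ib]
  tot <- 0
  for (f in seq_len(n_frames(x))) {
    D <- .cross_dist(matrix(x$xyz[ia, , f], ncol = 3),
                     matrix(x$xyz[ib, , f], ncol = 3))
    if (any(D < 1e-6)) stop("overlapping atoms (r < 1e-6 A)")
    tot <- tot + .K_COULOMB / eps_in * sum((qa %o% qb) / D)
  }
  tot / n_frames(x)
}

#' Inter-group Lennard-Jones energy
#'
#' 12-6 potential with Lorentz-Berthelot-style combination:
#' rmin_ij = rmin2_i + rmin2_j, eps_ij = sqrt(eps_i eps_j). Averaged over
#' frames.
#'
#' @inheritParams pair_elec
#' @return Energy in kcal/mol.
#' @export
pair_vdw <- function(x, group_a = "receptor", group_b = "ligand") {
  .check_param(x)
  ia <- .group_idx(x, group_a); ib <- .group_idx(x, group_b)
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (length(ia) == 0 || length(ib) == 0) return(0)
  rmin <- outer(x$atoms$rmin2[ia], x$atoms$rmin2[ib], "+")
  epsm <- sqrt(x$atoms$eps[ia] %o% x$atoms$eps[ib])
  tot <- 0
  for (f in seq_len(n_frames(x))) {
    D <- .cross_dist(matrix(x$xyz[ia, , f], ncol = 3),
                     matrix(x$xyz[ib, , f], ncol = 3))
    if (any(D < 1e-6)) stop("overlapping atoms (r < 1e-6 A)")
    s6 <- (rmin / D)^6
    tot <- tot + sum(epsm * (s6 * s6 - 2 * s6))
  }
  tot / n_frames(x)
}

## ---- Generalized Born ---------------------------------------------------

## HCT (pairwise descreening) scaling factors by element
.HCT_SCALE <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.80, P = 0.86)
.HCT_OFFSET <- 0.09

#' Effective Born radii (HCT pairwise descreening)
#'
#' Hawkins-Cramer-Truhlar analytic effective radii: each atom's intrinsic
#' (dielectric) radius, reduced by the descreening integral over all other
#' atoms in the chosen subset.
#'
#' @param x a parameterized `tcr_structure`.
#' @param idx atom indices forming the solute (defaults to all scored atoms).
#' @param frame frame number.
#' @return Numeric vector of effective radii (Angstrom) for `idx`.
#' @export
born_radii <- function(x, idx = NULL, frame = 1) {
  .check_param(x)
  if (is.null(idx)) idx <- seq_len(nrow(x$atoms))
  if (anyNA(x$atoms$born[idx])) stop("missing Born radius")
  rho <- x$atoms$born[idx] - .HCT_OFFSET
  if (any(rho <= 0)) stop("intrinsic radius below HCT offset")
  sc <- .HCT_SCALE[x$atoms$element[idx]]
  sc[is.na(sc)] <- 0.80
  n <- length(idx)
  if (n == 1) return(rho)
  X <- matrix(x$xyz[idx, , frame], ncol = 3)
  R <- .cross_dist(X, X)
  srj <- matrix(sc * rho, n, n, byrow = TRUE)    # scaled radius of atom j
  rhoi <- matrix(rho, n, n)                      # intrinsic radius of atom i
  U <- R + srj
  L <- pmax(abs(R - srj), rhoi)
  H <- (1 / L - 1 / U) +
    0.25 * (R - srj^2 / R) * (1 / U^2 - 1 / L^2) +
    0.5 / R * log(L / U)
  H[rhoi >= U] <- 0                              # atom j engulfed by i
  diag(H) <- 0
  inv <- 1 / rho - 0.5 * rowSums(H)
  ifelse(inv > 1e-3, 1 / inv, 1000)              # cap pathological radii
}

## pairwise GB interaction matrix (kcal/mol); entry (i,j) is the ordered-pair
## term, so total energy = sum of all entries (diagonal = self terms).
.gb_matrix <- function(x, idx, frame, diel, radii = NULL) {
  q <- x$atoms$charge[idx]
  a <- if (is.null(radii)) born_radii(x, idx, frame) else radii
  X <- matrix(x$xyz[idx, , frame], ncol = 3)
  R <- .cross_dist(X, X)
  aa <- a %o% a
  f <- sqrt(R^2 + aa * exp(-R^2 / (4 * aa)))
  diag(f) <- a
  -0.5 * .K_COULOMB * (1 / diel$eps_in - 1 / diel$eps_out) * (q %o% q) / f
}

#' Generalized Born solvation energy
#'
#' Pairwise GB with the standard smooth interpolation
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / 4 a_i a_j)) and self terms included:
#' E = -1/2 k (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB. Effective radii
#' come from [born_radii()] computed within the chosen subset (so removing a
#' partner changes the descreening, as it should), or can be supplied.
#'
#' @param x a parameterized `tcr_structure`.
#' @param subset atom indices, residue keys, `"receptor"`, `"ligand"`, or
#'   NULL for all scored atoms.
#' @param dielectric a [dielectric_model()].
#' @param radii optional precomputed effective radii.
#' @param details if TRUE, also return the per-pair matrix of the last frame.
#' @return Energy in kcal/mol (frame average), or a list if `details`.
#' @export
gb_energy <- function(x, subset = NULL, dielectric = dielectric_model(),
                      radii = NULL, details = FALSE) {
  .check_param(x)
  idx <- if (is.null(subset)) .scored_idx(x) else .group_idx(x, subset)
  if (length(idx) == 0) return(0)
  tot <- 0; M <- NULL
  for (f in seq_len(n_frames(x))) {
    M <- .gb_matrix(x, idx, f, dielectric, radii)
    tot <- tot + sum(M)
  }
  tot <- tot / n_frames(x)
  if (details) list(total = tot, pairs = M, idx = idx) else tot
}

## ---- SASA ---------------------------------------------------------------

## deterministic Fibonacci sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Body-fixed orientation for the SASA quadrature: gyration eigenvectors
## with signs canonicalised by the third moment along each axis. Rotating
## the whole molecule rotates this frame with it, so the numerical SASA is
## exactly invariant under rigid transforms (for generic, asymmetric
## structures; near-degenerate moments fall back to the lab frame).
.body_frame <- function(X) {
  if (nrow(X) < 4) return(diag(3))
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(S, symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    s3 <- sum((Xc %*% V[, k])^3)
    if (abs(s3) > 1e-6) V[, k] <- V[, k] * sign(s3)
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a fixed deterministic point set on each atom sphere
#' (radius = vdW radius + probe). Heavy atoms only; hydrogens are assigned
#' zero area (united-atom convention).
#'
#' @param x a parameterized `tcr_structure`.
#' @param subset atom indices / residue keys / partner name / NULL for all
#'   scored atoms.
#' @param probe_radius probe radius in Angstrom.
#' @param n_points sphere quadrature points per atom.
#' @param frame frame number (SASA is evaluated per frame; see
#'   [binding_energy()] for frame averaging).
#' @return A list with `total` (A^2) and `per_atom` (named by atom row index;
#'   non-negative, summing to total).
#' @export
sasa <- function(x, subset = NULL, probe_radius = 1.4, n_points = 512,
                 frame = 1) {
  .check_param(x)
  idx <- if (is.null(subset)) .scored_idx(x) else .group_idx(x, subset)
  heavy <- idx[x$atoms$element[idx] != "H"]
  per_atom <- stats::setNames(rep(0, length(idx)), idx)
  if (length(heavy) == 0) return(list(total = 0, per_atom = per_atom))
  r <- x$atoms$rmin2[heavy] + probe_radius
  X <- matrix(x$xyz[heavy, , frame], ncol = 3)
  pts <- .sphere_points(n_points) %*% t(.body_frame(X))
  D <- .cross_dist(X, X)
  areas <- numeric(length(heavy))
  for (i in seq_along(heavy)) {
    nb <- which(D[i, ] < r[i] + r & seq_along(heavy) != i)
    p <- pts * r[i]
    p <- sweep(p, 2, X[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - X[j, 1])^2 + (p[, 2] - X[j, 2])^2 + (p[, 3] - X[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  per_atom[as.character(heavy)] <- areas
  list(total = sum(areas), per_atom = per_atom)
}

## ---- assembled energies -------------------------------------------------

.energy_breakdown <- function(elec, vdw, gb, np, intra = 0) {
  structure(list(elec = elec, vdw = vdw, gb = gb, np = np, intra = intra,
                 total = elec + vdw + gb + np + intra),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("  elec %12.4f kcal/mol\n  vdw  %12.4f kcal/mol\n  gb   %12.4f kcal/mol\n  np   %12.4f kcal/mol\n  intra%12.4f kcal/mol\n  total%12.4f kcal/mol\n",
              x$elec, x$vdw, x$gb, x$np, x$intra, x$total))
  invisible(x)
}

#' Effective energy of a complex pose
#'
#' The sum of the inter-partner molecular-mechanics interaction energy and
#' the solvation free energy of the whole system: elec + vdw are
#' receptor-ligand interactions, gb + np are whole-system solvation.
#'
#' @param x a parameterized, partner-split `tcr_structure`.
#' @param mode `"full"` (all four terms) or `"polar"` (elec + gb only, the
#'   long-range orientation signal).
#' @param dielectric a [dielectric_model()].
#' @param nonpolar a [nonpolar_params()].
#' @return An `energy_breakdown` (frame-averaged).
#' @export
effective_energy <- function(x, mode = c("full", "polar"),
                             dielectric = dielectric_model(),
                             nonpolar = nonpolar_params()) {
  mode <- match.arg(mode)
  .check_param(x)
  if (is.null(x$receptor_chains)) stop("partner split not declared")
  elec <- pair_elec(x, eps_in = dielectric$eps_in)
  gb <- gb_energy(x, NULL, dielectric)
  if (mode == "polar") return(.energy_breakdown(elec, 0, gb, 0))
  vdw <- pair_vdw(x)
  np <- 0
  for (f in seq_len(n_frames(x)))
    np <- np + nonpolar$gamma * sasa(x, NULL, nonpolar$probe_radius,
                                     frame = f)$total + nonpolar$b
  .energy_breakdown(elec, vdw, gb, np / n_frames(x))
}

#' MM-GBSA binding energy (single-trajectory, no entropy)
#'
#' Delta X = X(complex) - X(receptor) - X(ligand) for each term, evaluated
#' on the same frames; the conformational term is zero by construction. In
#' this scheme the elec and vdw differences reduce exactly to the
#' inter-partner pair sums. An externally computed entropy contribution (in
#' kcal/mol, as -T*dS) can be supplied and is added to the total.
#'
#' @param x a parameterized, partner-split `tcr_structure`.
#' @param dielectric a [dielectric_model()].
#' @param nonpolar a [nonpolar_params()].
#' @param entropy optional externally supplied -T*dS term, kcal/mol.
#' @return An `energy_breakdown` with negative total = favourable binding.
#' @export
binding_energy <- function(x, dielectric = dielectric_model(),
                           nonpolar = nonpolar_params(), entropy = 0) {
  .check_param(x)
  if (is.null(x$receptor_chains)) stop("partner split not declared")
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  elec <- pair_elec(x, eps_in = dielectric$eps_in)
  vdw <- pair_vdw(x)
  gb <- np <- 0
  nfr <- n_frames(x)
  allidx <- sort(c(rec, lig))
  for (f in seq_len(nfr)) {
    gb <- gb + sum(.gb_matrix(x, allidx, f, dielectric)) -
      sum(.gb_matrix(x, rec, f, dielectric)) -
      sum(.gb_matrix(x, lig, f, dielectric))
    ds <- sasa(x, allidx, nonpolar$probe_radius, frame = f)$total -
      sasa(x, rec, nonpolar$probe_radius, frame = f)$total -
      sasa(x, lig, nonpolar$probe_radius, frame = f)$total
    ## the intercept b is treated as per-solute-molecule and cancels in the
    ## binding difference; only the area term survives
    np <- np + nonpolar$gamma * ds
  }
  out <- .energy_breakdown(elec, vdw, gb / nfr, np / nfr)
  out$total <- out$total + entropy
  out$entropy <- entropy
  out
}
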