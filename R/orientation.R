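## Rigid-body orientation scan: translate the receptor along its principal
## axis away from the ligand, rotate it through a full revolution, and map
## the effective energy. The polar-only mode (Coulomb + GB) carries the
## long-range orientation signal; the located minimum predicts the native
## docking angle.

#' Principal axis of the receptor
#'
#' The principal axis of the receptor's scored atoms: the gyration-tensor
#' eigenvector best aligned with the receptor-to-ligand center-of-mass
#' vector, sign-oriented from receptor toward ligand. Deterministic.
#'
#' @param x a partner-split `tcr_structure`.
#' @param frame frame used.
#' @param axis optional explicit axis (length-3), overriding the computation
#'   (used when the inertia tensor is degenerate).
#' @return A list with `axis` (unit 3-vector) and `anchor` (receptor center
#'   of mass).
#' @export
tcr_axis <- function(x, frame = 1, axis = NULL) {
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  if (length(rec) == 0) stop("no receptor atoms")
  com_r <- .com(x, rec, frame)
  com_l <- .com(x, lig, frame)
  if (!is.null(axis)) {
    a <- .unit(axis)
    if (sum(a * (com_l - com_r)) < 0) a <- -a
    return(list(axis = a, anchor = com_r))
  }
  X <- sweep(matrix(x$xyz[rec, , frame], ncol = 3), 2, com_r)
  S <- crossprod(X) / nrow(X)
  ev <- eigen(S, symmetric = TRUE)
  spread <- (ev$values[1] - ev$values[3]) / mean(ev$values)
  if (spread < 0.01)
    stop("degenerate inertia tensor (near-spherical receptor); supply an explicit axis")
  sep <- com_l - com_r
  al <- abs(as.numeric(t(ev$vectors) %*% sep))
  a <- ev$vectors[, which.max(al)]
  if (sum(a * sep) < 0) a <- -a
  list(axis = .unit(a), anchor = com_r)
}

#' Rigid translation + rotation scan of the receptor
#'
#' Moves the receptor rigidly along the principal axis by each offset in
#' `[d_min, d_max]`, then rotates it about that axis (through its displaced
#' center of mass) in steps of `angle_step` over a full revolution, with the
#' ligand fixed. At every grid point the effective energy is evaluated:
#' polar mode sums the inter-partner Coulomb term and the whole-system GB
#' solvation; full mode adds vdW and the SASA nonpolar term. Poses with a
#' steric overlap (any inter-partner heavy-atom pair closer than 0.5 x the
#' sum of vdW radii) are flagged and excluded from the minimum search.
#' Angle 0 is the pose as given in the input.
#'
#' @param x a parameterized, partner-split `tcr_structure` (frame 1 is
#'   scanned).
#' @param d_min,d_max,d_step displacement grid, Angstrom.
#' @param angle_step rotation step, degrees (grid covers `[0, 360)`).
#' @param mode `"polar"` or `"full"`.
#' @param dielectric a [dielectric_model()].
#' @param nonpolar a [nonpolar_params()] (full mode only).
#' @param axis optional explicit axis passed to [tcr_axis()].
#' @return An `orientation_landscape`: distances, angles, energy matrix
#'   (distance x angle), component matrices, flagged matrix, mode, minimum.
#' @export
rigid_scan <- function(x, d_min = 6, d_max = 12, d_step = 2, angle_step = 5,
                       mode = c("polar", "full"),
                       dielectric = dielectric_model(),
                       nonpolar = nonpolar_params(), axis = NULL) {
  mode <- match.arg(mode)
  .check_param(x)
  if (is.null(x$receptor_chains)) stop("partner split not declared")
  ax <- tcr_axis(x, 1, axis = axis)
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  distances <- seq(d_min, d_max, by = d_step)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  nd <- length(distances); na <- length(angles)
  E <- Eel <- Egb <- matrix(NA_real_, nd, na,
                            dimnames = list(distances, angles))
  flagged <- matrix(FALSE, nd, na, dimnames = list(distances, angles))
  rec_heavy <- x$atoms$element[rec] != "H"
  lig_heavy_idx <- lig[x$atoms$element[lig] != "H"]
  rv_rec <- x$atoms$rmin2[rec][rec_heavy]
  rv_lig <- x$atoms$rmin2[lig_heavy_idx]
  thr <- 0.5 * outer(rv_rec, rv_lig, "+")
  base <- .coords(x, 1)

  pose <- x
  for (i in seq_len(nd)) {
    shift <- -distances[i] * ax$axis
    rec_t <- sweep(base[rec, , drop = FALSE], 2, shift, "+")
    center <- colMeans(rec_t)
    for (j in seq_len(na)) {
      rec_p <- .rotate_coords(rec_t, ax$axis, angles[j], center)
      xyz <- base
      xyz[rec, ] <- rec_p
      pose$xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
      D <- .cross_dist(rec_p[rec_heavy, , drop = FALSE],
                       matrix(xyz[lig_heavy_idx, ], ncol = 3))
      flagged[i, j] <- any(D < thr)
      Eel[i, j] <- pair_elec(pose, eps_in = dielectric$eps_in)
      Egb[i, j] <- gb_energy(pose, NULL, dielectric)
      E[i, j] <- Eel[i, j] + Egb[i, j]
      if (mode == "full") {
        E[i, j] <- E[i, j] + pair_vdw(pose) +
          nonpolar$gamma * sasa(pose, NULL, nonpolar$probe_radius)$total +
          nonpolar$b
      }
    }
  }
  out <- structure(list(distances = distances, angles = angles,
                        energy = E, elec = Eel, gb = Egb, flagged = flagged,
                        mode = mode, axis = ax$axis, anchor = ax$anchor),
                   class = "orientation_landscape")
  out$minimum <- find_minimum(out)
  out
}

#' Locate the landscape minimum
#'
#' Global grid minimum over non-flagged poses; ties broken by smallest
#' angle, then smallest distance. The margin is the energy gap to the lowest
#' grid point lying more than one angle step away from the minimum.
#'
#' @param landscape an `orientation_landscape`.
#' @return A list: distance, angle, energy, margin.
#' @export
find_minimum <- function(landscape) {
  E <- landscape$energy
  ok <- is.finite(E) & !landscape$flagged
  if (!any(ok)) stop("all grid points are flagged or invalid")
  Ev <- E; Ev[!ok] <- Inf
  ## tie-break: order by energy, then angle, then distance
  idx <- which(Ev == min(Ev), arr.ind = TRUE)
  idx <- idx[order(landscape$angles[idx[, 2]], landscape$distances[idx[, 1]]), ,
             drop = FALSE]
  i <- idx[1, 1]; j <- idx[1, 2]
  astep <- if (length(landscape$angles) > 1)
    diff(landscape$angles[1:2]) else 360
  dang <- vapply(landscape$angles, angular_shift, numeric(1),
                 landscape$angles[j])
  far <- ok & matrix(dang > astep + 1e-9, nrow(E), ncol(E), byrow = TRUE)
  margin <- if (any(far)) min(E[far]) - E[i, j] else 0
  list(distance = landscape$distances[i], angle = landscape$angles[j],
       energy = E[i, j], margin = margin)
}

#' @export
print.orientation_landscape <- function(x, ...) {
  cat("orientation_landscape:", length(x$distances), "distances x",
      length(x$angles), "angles, mode", x$mode, "\n")
  m <- x$minimum
  cat(sprintf("  minimum: d = %g A, angle = %g deg, E = %.4f kcal/mol (margin %.4f)\n",
              m$distance, m$angle, m$energy, m$margin))
  invisible(x)
}

#' Sub-group contributions to the orientation profile
#'
#' Decomposes the inter-partner polar interaction profile (Coulomb + GB
#' cross terms) over receptor sub-groups defined by region tags, at a fixed
#' displacement. Group profiles sum to the total inter-partner polar profile
#' at every angle. Each group's `share` of the orientation signal is its
#' profile variance across angles as a fraction of the summed group
#' variances (in [0, 1], summing to 1 over groups); the raw ratio against
#' the total profile's variance is also returned as `var_ratio`.
#'
#' @param x a parameterized, partner-split, region-tagged `tcr_structure`.
#' @param groups named list mapping group label -> character vector of
#'   region tags; the default groups CDR1/2 loops, CDR3 loops and framework,
#'   keeping only groups with at least one tagged receptor residue.
#' @param distance displacement at which to evaluate, Angstrom.
#' @param angle_step rotation step, degrees.
#' @param dielectric a [dielectric_model()].
#' @param axis optional explicit axis.
#' @return A list with `angles`, `profiles` (matrix group x angle), `total`,
#'   and `share` (named vector).
#' @export
subgroup_contributions <- function(x, groups = NULL,
                                   distance = 8, angle_step = 5,
                                   dielectric = dielectric_model(),
                                   axis = NULL) {
  .check_param(x)
  if (all(is.na(x$atoms$region))) stop("regions not tagged")
  ax <- tcr_axis(x, 1, axis = axis)
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  if (is.null(groups)) {
    groups <- list("CDR1,2" = c("CDR1a", "CDR2a", "CDR1b", "CDR2b"),
                   "CDR3" = c("CDR3a", "CDR3b"),
                   "framework" = "framework")
    present <- unique(x$atoms$region[rec])
    groups <- groups[vapply(groups, function(g) any(g %in% present), logical(1))]
  }
  angles <- seq(0, 360 - angle_step, by = angle_step)
  glab <- names(groups)
  prof <- matrix(0, length(glab), length(angles),
                 dimnames = list(glab, angles))
  for (g in glab) {
    if (!any(x$atoms$region[rec] %in% groups[[g]]))
      stop("empty group: ", g)
  }
  base <- .coords(x, 1)
  pose <- x
  allidx <- sort(c(rec, lig))
  pos_in_all <- function(i) match(i, allidx)
  ql <- x$atoms$charge[lig]
  shift <- -distance * ax$axis
  rec_t <- sweep(base[rec, , drop = FALSE], 2, shift, "+")
  center <- colMeans(rec_t)
  for (j in seq_along(angles)) {
    rec_p <- .rotate_coords(rec_t, ax$axis, angles[j], center)
    xyz <- base
    xyz[rec, ] <- rec_p
    pose$xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
    ## Coulomb cross matrix receptor x ligand
    D <- .cross_dist(rec_p, matrix(xyz[lig, ], ncol = 3))
    Eel <- .K_COULOMB / dielectric$eps_in * (x$atoms$charge[rec] %o% ql) / D
    ## GB cross terms: ordered-pair matrix entries receptor->ligand and
    ## ligand->receptor sum to the full cross contribution
    M <- .gb_matrix(pose, allidx, 1, dielectric)
    cross <- 2 * M[pos_in_all(rec), pos_in_all(lig), drop = FALSE]
    per_atom <- rowSums(Eel) + rowSums(cross)
    for (g in glab) {
      sel <- x$atoms$region[rec] %in% groups[[g]]
      prof[g, j] <- sum(per_atom[sel])
    }
  }
  total <- colSums(prof)
  vg <- apply(prof, 1, stats::var)
  vt <- stats::var(total)
  ## share: each group's fraction of the summed group variances (a number
  ## in [0, 1] summing to 1); var_ratio is the raw ratio against the total
  ## profile's variance, which can exceed 1 through covariance terms
  share <- if (sum(vg) > 0) vg / sum(vg) else
    stats::setNames(rep(NA_real_, length(glab)), glab)
  var_ratio <- if (vt > 0) vg / vt else share * NA_real_
  list(angles = angles, profiles = prof, total = total, share = share,
       var_ratio = var_ratio)
}

#' Minimal circular difference between two angles
#'
#' @param predicted,reference angles in degrees.
#' @return Shift in degrees, in `[0, 180]`.
#' @export
angular_shift <- function(predicted, reference) {
  d <- abs((predicted - reference) %% 360)
  min(d, 360 - d)
}
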