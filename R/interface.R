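## Hydrogen-bond and nonpolar-contact detection, and occurrence maps over
## conformational ensembles binned by a separation coordinate xi.
##
## The geometric H-bond criterion (donor-acceptor distance and
## donor-H...acceptor angle) and the per-template donor/acceptor tables are
## toolkit choices, exposed through hbond_criteria(); they are conventional
## values, not a reconstruction of any specific analysis software.

#' Geometric hydrogen-bond criteria
#'
#' @param distance maximum donor-acceptor heavy-atom distance, Angstrom.
#' @param angle minimum donor-H...acceptor angle, degrees.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(distance = 3.5, angle = 120) {
  if (distance <= 0 || angle < 0 || angle > 180) stop("invalid criteria")
  structure(list(distance = distance, angle = angle), class = "hbond_criteria")
}

## donor (heavy, H) atom index pairs and acceptor indices for a set of rows
.donor_pairs <- function(x, idx) {
  out <- NULL
  for (rk in unique(x$atoms$reskey[idx])) {
    ridx <- idx[x$atoms$reskey[idx] == rk]
    don <- template_donors(x$atoms$resid[ridx[1]])
    if (is.null(don)) next
    for (i in seq_len(nrow(don))) {
      hv <- ridx[x$atoms$name[ridx] == don$heavy[i]]
      hh <- ridx[x$atoms$name[ridx] == don$h[i]]
      if (length(hv) == 1 && length(hh) == 1)
        out <- rbind(out, c(hv, hh))
    }
  }
  out
}

.acceptor_idx <- function(x, idx) {
  keep <- logical(length(idx))
  for (rk in unique(x$atoms$reskey[idx])) {
    sel <- x$atoms$reskey[idx] == rk
    acc <- template_acceptors(x$atoms$resid[idx[sel][1]])
    keep[sel] <- x$atoms$name[idx[sel]] %in% acc
  }
  idx[keep]
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor distance <= `criteria$distance` and
#' donor-H...acceptor angle >= `criteria$angle`. Donors and acceptors come
#' from the bundled per-template tables; polar hydrogens must be present
#' (they are constructed by [assign_parameters()]).
#'
#' @param x a parameterized `tcr_structure`.
#' @param frame frame number.
#' @param criteria an [hbond_criteria()].
#' @param across_partners_only if TRUE (default) only receptor-ligand bonds
#'   are reported.
#' @return A data frame: donor_res, donor_atom, h_atom, acceptor_res,
#'   acceptor_atom, distance, angle.
#' @export
detect_hbonds <- function(x, frame = 1, criteria = hbond_criteria(),
                          across_partners_only = TRUE) {
  .check_param(x)
  if (!any(x$atoms$element == "H"))
    stop("no hydrogens present; re-run assign_parameters() to build them")
  idx <- .scored_idx(x)
  if (length(idx) == 0) idx <- seq_len(nrow(x$atoms))
  sides <- if (across_partners_only) {
    list(list(d = .receptor_idx(x), a = .ligand_idx(x)),
         list(d = .ligand_idx(x), a = .receptor_idx(x)))
  } else list(list(d = idx, a = idx))
  out <- NULL
  for (s in sides) {
    dp <- .donor_pairs(x, s$d)
    ai <- .acceptor_idx(x, s$a)
    if (is.null(dp) || length(ai) == 0) next
    for (r in seq_len(nrow(dp))) {
      hv <- dp[r, 1]; hh <- dp[r, 2]
      pv <- x$xyz[hv, , frame]; ph <- x$xyz[hh, , frame]
      keep <- ai[x$atoms$reskey[ai] != x$atoms$reskey[hv]]
      if (length(keep) == 0) next
      d <- sqrt(colSums((t(matrix(x$xyz[keep, , frame], ncol = 3)) - pv)^2))
      hit <- which(d <= criteria$distance)
      for (j in hit) {
        aj <- keep[j]
        ang <- bond_angle(pv, ph, x$xyz[aj, , frame])
        if (ang >= criteria$angle) {
          out <- rbind(out, data.frame(
            donor_res = x$atoms$reskey[hv], donor_atom = x$atoms$name[hv],
            h_atom = x$atoms$name[hh],
            acceptor_res = x$atoms$reskey[aj], acceptor_atom = x$atoms$name[aj],
            distance = d[j], angle = ang, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out))
    out <- data.frame(donor_res = character(0), donor_atom = character(0),
                      h_atom = character(0), acceptor_res = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Detect nonpolar contacts in one frame
#'
#' Carbon/sulfur heavy-atom pairs across the partner interface within the
#' cutoff.
#'
#' @param x a parameterized, partner-split `tcr_structure`.
#' @param frame frame number.
#' @param cutoff distance cutoff, Angstrom.
#' @return A data frame: res_a, atom_a, res_b, atom_b, distance.
#' @export
detect_np_contacts <- function(x, frame = 1, cutoff = 4.5) {
  .check_param(x)
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  rec <- rec[x$atoms$element[rec] %in% c("C", "S")]
  lig <- lig[x$atoms$element[lig] %in% c("C", "S")]
  if (length(rec) == 0 || length(lig) == 0)
    return(data.frame(res_a = character(0), atom_a = character(0),
                      res_b = character(0), atom_b = character(0),
                      distance = numeric(0)))
  D <- .cross_dist(matrix(x$xyz[rec, , frame], ncol = 3),
                   matrix(x$xyz[lig, , frame], ncol = 3))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  data.frame(res_a = x$atoms$reskey[rec[hit[, 1]]],
             atom_a = x$atoms$name[rec[hit[, 1]]],
             res_b = x$atoms$reskey[lig[hit[, 2]]],
             atom_b = x$atoms$name[lig[hit[, 2]]],
             distance = D[hit], stringsAsFactors = FALSE)
}

#' Interaction occurrence map over a xi-binned ensemble
#'
#' For every frame (labelled with a separation coordinate xi) detects the
#' requested interaction type; reports, per xi bin, the fraction of frames
#' in which each interacting pair exists. Pairs never observed are not
#' listed; empty bins are dropped with a warning.
#'
#' @param x a parameterized, partner-split multi-frame `tcr_structure`.
#' @param xi numeric vector, one separation label per frame.
#' @param breaks bin edges for xi.
#' @param type `"hbond"` or `"np"`.
#' @param criteria an [hbond_criteria()] (hbond type).
#' @param cutoff contact cutoff (np type), Angstrom.
#' @return An `occurrence_map`: `fraction` (pairs x bins matrix in [0, 1]),
#'   `n_frames` per bin, `bins` (labels), `pairs`.
#' @export
occurrence_map <- function(x, xi, breaks, type = c("hbond", "np"),
                           criteria = hbond_criteria(), cutoff = 4.5) {
  type <- match.arg(type)
  .check_param(x)
  nfr <- n_frames(x)
  if (length(xi) != nfr) stop("need one xi label per frame")
  bin <- cut(xi, breaks = breaks, include.lowest = TRUE)
  if (anyNA(bin)) stop("xi values outside the bin range")
  per_frame <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    tab <- if (type == "hbond") {
      h <- detect_hbonds(x, f, criteria)
      if (nrow(h) > 0)
        paste(h$donor_res, h$donor_atom, "->", h$acceptor_res, h$acceptor_atom)
      else character(0)
    } else {
      c <- detect_np_contacts(x, f, cutoff)
      if (nrow(c) > 0) paste(c$res_a, c$atom_a, "--", c$res_b, c$atom_b)
      else character(0)
    }
    per_frame[[f]] <- unique(tab)
  }
  pairs <- sort(unique(unlist(per_frame)))
  lev <- levels(bin)
  counts <- table(bin)
  empty <- lev[counts == 0]
  if (length(empty) > 0) {
    warning("dropping empty xi bin(s): ", paste(empty, collapse = ", "))
    lev <- lev[counts > 0]
  }
  frac <- matrix(0, length(pairs), length(lev), dimnames = list(pairs, lev))
  for (b in lev) {
    fr <- which(bin == b)
    if (length(pairs) > 0)
      frac[, b] <- vapply(pairs, function(p)
        mean(vapply(per_frame[fr], function(s) p %in% s, logical(1))),
        numeric(1))
  }
  structure(list(fraction = frac, n_frames = as.integer(counts[lev]),
                 bins = lev, pairs = pairs, type = type),
            class = "occurrence_map")
}

#' @export
print.occurrence_map <- function(x, ...) {
  cat("occurrence_map (", x$type, "): ", length(x$pairs), " pair(s) x ",
      length(x$bins), " xi bin(s)\n", sep = "")
  if (length(x$pairs) > 0) print(round(x$fraction, 3))
  invisible(x)
}
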