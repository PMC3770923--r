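## Residue templates: idealised internal-coordinate definitions for the 20
## standard amino acids in a united-atom representation (heavy atoms plus
## polar hydrogens only; aliphatic hydrogens are folded into their carbons).
## These drive side-chain construction for point mutants, polar-hydrogen
## building at parameterisation time, and the synthetic fixture generator.
## Bond lengths / angles are idealised textbook values; ring closure is
## approximate (the templates are a deterministic stand-in for a refined
## builder, not a crystallographic reconstruction).

.zr <- function(atom, r1, r2, r3, b, ang, chi = 0L, tors = 0) {
  data.frame(atom = atom, r1 = r1, r2 = r2, r3 = r3, b = b, ang = ang,
             chi = as.integer(chi), tors = tors, stringsAsFactors = FALSE)
}

## Shared backbone rows (placed after N, CA, C which are seeded directly).
## torsion(N,CA,C,O) and torsion(C,CA,N,H) fixed at 180 for isolated residues;
## torsion(C,N,CA,CB) = -122.6 sets the L configuration.
.bb_rows <- function(gly = FALSE, pro = FALSE) {
  rows <- .zr("O", "C", "CA", "N", 1.231, 120.5, 0L, 180)
  if (!pro) rows <- rbind(rows, .zr("H", "N", "CA", "C", 1.00, 118.2, 0L, 180))
  if (!gly) rows <- rbind(rows, .zr("CB", "CA", "N", "C", 1.53, 110.4, 0L, -122.6))
  rows
}

.sidechain_rows <- list(
  GLY = NULL,
  ALA = NULL,
  SER = rbind(
    .zr("OG", "CB", "CA", "N", 1.417, 110.8, 1L),
    .zr("HG", "OG", "CB", "CA", 0.96, 109.5, 0L, 180)),
  CYS = rbind(
    .zr("SG", "CB", "CA", "N", 1.808, 113.8, 1L),
    .zr("HG", "SG", "CB", "CA", 1.33, 96.0, 0L, 180)),
  THR = rbind(
    .zr("OG1", "CB", "CA", "N", 1.433, 109.6, 1L),
    .zr("CG2", "CB", "CA", "N", 1.521, 110.5, 1L, -122.0),
    .zr("HG1", "OG1", "CB", "CA", 0.96, 109.5, 0L, 180)),
  VAL = rbind(
    .zr("CG1", "CB", "CA", "N", 1.521, 110.5, 1L),
    .zr("CG2", "CB", "CA", "N", 1.521, 110.5, 1L, 122.0)),
  LEU = rbind(
    .zr("CG", "CB", "CA", "N", 1.53, 116.3, 1L),
    .zr("CD1", "CG", "CB", "CA", 1.521, 110.7, 2L),
    .zr("CD2", "CG", "CB", "CA", 1.521, 110.7, 2L, 122.0)),
  ILE = rbind(
    .zr("CG1", "CB", "CA", "N", 1.53, 110.4, 1L),
    .zr("CG2", "CB", "CA", "N", 1.521, 110.5, 1L, -122.0),
    .zr("CD1", "CG1", "CB", "CA", 1.513, 113.8, 2L)),
  MET = rbind(
    .zr("CG", "CB", "CA", "N", 1.52, 114.1, 1L),
    .zr("SD", "CG", "CB", "CA", 1.803, 112.7, 2L),
    .zr("CE", "SD", "CG", "CB", 1.791, 100.9, 3L)),
  PRO = rbind(
    .zr("CG", "CB", "CA", "N", 1.492, 104.5, 0L, 30),
    .zr("CD", "CG", "CB", "CA", 1.503, 106.1, 0L, -35)),
  PHE = rbind(
    .zr("CG", "CB", "CA", "N", 1.502, 113.8, 1L),
    .zr("CD1", "CG", "CB", "CA", 1.384, 120.8, 2L),
    .zr("CD2", "CG", "CB", "CA", 1.384, 120.8, 2L, 180),
    .zr("CE1", "CD1", "CG", "CB", 1.382, 120.8, 0L, 180),
    .zr("CE2", "CD2", "CG", "CB", 1.382, 120.8, 0L, 180),
    .zr("CZ", "CE1", "CD1", "CG", 1.382, 120.0, 0L, 0)),
  TYR = rbind(
    .zr("CG", "CB", "CA", "N", 1.502, 113.8, 1L),
    .zr("CD1", "CG", "CB", "CA", 1.384, 120.8, 2L),
    .zr("CD2", "CG", "CB", "CA", 1.384, 120.8, 2L, 180),
    .zr("CE1", "CD1", "CG", "CB", 1.382, 120.8, 0L, 180),
    .zr("CE2", "CD2", "CG", "CB", 1.382, 120.8, 0L, 180),
    .zr("CZ", "CE1", "CD1", "CG", 1.382, 120.0, 0L, 0),
    .zr("OH", "CZ", "CE1", "CD1", 1.376, 119.9, 0L, 180),
    .zr("HH", "OH", "CZ", "CE1", 0.96, 109.5, 0L, 180)),
  TRP = rbind(
    .zr("CG", "CB", "CA", "N", 1.498, 113.6, 1L),
    .zr("CD1", "CG", "CB", "CA", 1.365, 126.9, 2L),
    .zr("CD2", "CG", "CB", "CA", 1.433, 126.7, 2L, 180),
    .zr("NE1", "CD1", "CG", "CB", 1.374, 110.2, 0L, 180),
    .zr("CE2", "CD2", "CG", "CB", 1.409, 107.2, 0L, 180),
    .zr("CE3", "CD2", "CG", "CB", 1.398, 133.9, 0L, 0),
    .zr("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, 0L, 180),
    .zr("CZ3", "CE3", "CD2", "CG", 1.382, 118.6, 0L, 180),
    .zr("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, 0L, 0),
    .zr("HE1", "NE1", "CD1", "CG", 1.01, 125.0, 0L, 180)),
  ASP = rbind(
    .zr("CG", "CB", "CA", "N", 1.516, 112.6, 1L),
    .zr("OD1", "CG", "CB", "CA", 1.249, 118.5, 2L),
    .zr("OD2", "CG", "CB", "CA", 1.249, 118.5, 2L, 180)),
  ASN = rbind(
    .zr("CG", "CB", "CA", "N", 1.516, 112.6, 1L),
    .zr("OD1", "CG", "CB", "CA", 1.231, 120.8, 2L),
    .zr("ND2", "CG", "CB", "CA", 1.328, 116.4, 2L, 180),
    .zr("HD21", "ND2", "CG", "CB", 1.00, 120.0, 0L, 0),
    .zr("HD22", "ND2", "CG", "CB", 1.00, 120.0, 0L, 180)),
  GLU = rbind(
    .zr("CG", "CB", "CA", "N", 1.52, 114.1, 1L),
    .zr("CD", "CG", "CB", "CA", 1.516, 112.6, 2L),
    .zr("OE1", "CD", "CG", "CB", 1.249, 118.5, 3L),
    .zr("OE2", "CD", "CG", "CB", 1.249, 118.5, 3L, 180)),
  GLN = rbind(
    .zr("CG", "CB", "CA", "N", 1.52, 114.1, 1L),
    .zr("CD", "CG", "CB", "CA", 1.516, 112.6, 2L),
    .zr("OE1", "CD", "CG", "CB", 1.231, 120.8, 3L),
    .zr("NE2", "CD", "CG", "CB", 1.328, 116.4, 3L, 180),
    .zr("HE21", "NE2", "CD", "CG", 1.00, 120.0, 0L, 0),
    .zr("HE22", "NE2", "CD", "CG", 1.00, 120.0, 0L, 180)),
  LYS = rbind(
    .zr("CG", "CB", "CA", "N", 1.52, 114.1, 1L),
    .zr("CD", "CG", "CB", "CA", 1.52, 111.3, 2L),
    .zr("CE", "CD", "CG", "CB", 1.52, 111.3, 3L),
    .zr("NZ", "CE", "CD", "CG", 1.489, 112.0, 4L),
    .zr("HZ1", "NZ", "CE", "CD", 1.01, 109.5, 0L, 180),
    .zr("HZ2", "NZ", "CE", "CD", 1.01, 109.5, 0L, 60),
    .zr("HZ3", "NZ", "CE", "CD", 1.01, 109.5, 0L, -60)),
  ARG = rbind(
    .zr("CG", "CB", "CA", "N", 1.52, 114.1, 1L),
    .zr("CD", "CG", "CB", "CA", 1.52, 111.3, 2L),
    .zr("NE", "CD", "CG", "CB", 1.461, 112.0, 3L),
    .zr("CZ", "NE", "CD", "CG", 1.329, 124.2, 4L),
    .zr("HE", "NE", "CD", "CG", 1.01, 118.0, 4L, 180),
    .zr("NH1", "CZ", "NE", "CD", 1.326, 120.0, 0L, 0),
    .zr("NH2", "CZ", "NE", "CD", 1.326, 120.0, 0L, 180),
    .zr("HH11", "NH1", "CZ", "NE", 1.00, 120.0, 0L, 0),
    .zr("HH12", "NH1", "CZ", "NE", 1.00, 120.0, 0L, 180),
    .zr("HH21", "NH2", "CZ", "NE", 1.00, 120.0, 0L, 0),
    .zr("HH22", "NH2", "CZ", "NE", 1.00, 120.0, 0L, 180)),
  HIS = rbind(
    .zr("CG", "CB", "CA", "N", 1.49, 113.7, 1L),
    .zr("ND1", "CG", "CB", "CA", 1.38, 122.7, 2L),
    .zr("CD2", "CG", "CB", "CA", 1.356, 131.0, 2L, 180),
    .zr("CE1", "ND1", "CG", "CB", 1.32, 109.0, 0L, 180),
    .zr("NE2", "CD2", "CG", "CB", 1.374, 107.2, 0L, 180),
    .zr("HD1", "ND1", "CE1", "NE2", 1.01, 125.0, 0L, 180))
)

.AA3 <- names(.sidechain_rows)

.N_CHI <- c(GLY = 0, ALA = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, LEU = 2,
            ILE = 2, MET = 3, PRO = 0, PHE = 2, TYR = 2, TRP = 2, ASP = 2,
            ASN = 2, GLU = 3, GLN = 3, LYS = 4, ARG = 4, HIS = 2)

.AROMATIC <- c("PHE", "TYR", "TRP", "HIS")

#' Residue template z-matrix
#'
#' Internal-coordinate build recipe for a standard residue: backbone rows
#' (O, amide H, CB) followed by side-chain rows. Rows with `chi > 0` take
#' their torsion from the corresponding chi angle plus the `tors` offset.
#'
#' @param template three-letter residue code.
#' @return A data frame with columns atom, r1, r2, r3, b, ang, chi, tors.
#' @keywords internal
residue_zmat <- function(template) {
  template <- toupper(template)
  if (!template %in% .AA3) stop("unknown residue template: ", template)
  rbind(.bb_rows(gly = template == "GLY", pro = template == "PRO"),
        .sidechain_rows[[template]])
}

#' Atom names of a residue template
#' @param template three-letter code.
#' @param include_h include polar hydrogens.
#' @return Character vector in build order (starting N, CA, C).
#' @keywords internal
template_atoms <- function(template, include_h = TRUE) {
  z <- residue_zmat(template)
  nm <- c("N", "CA", "C", z$atom)
  if (!include_h) nm <- nm[!grepl("^H", nm)]
  nm
}

#' Canonical rotamer chi sets
#'
#' A deterministic, small rotamer library: up to 9 chi combinations per
#' residue type (chi1 x chi2 staggered minima, chi2 perpendicular for
#' aromatics, distal chis extended).
#'
#' @param template three-letter code.
#' @return A matrix with one row per rotamer, `n_chi` columns (0-column
#'   matrix with a single row for chi-less residues).
#' @keywords internal
rotamer_set <- function(template) {
  template <- toupper(template)
  nchi <- .N_CHI[[template]]
  if (nchi == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  chi1 <- c(-60, 180, 60)
  if (nchi == 1) return(matrix(chi1, ncol = 1))
  chi2 <- if (template %in% .AROMATIC) c(90, -90) else c(180, 60, -60)
  g <- as.matrix(expand.grid(chi2 = chi2, chi1 = chi1))[, c("chi1", "chi2")]
  if (nchi > 2) g <- cbind(g, matrix(180, nrow(g), nchi - 2))
  colnames(g) <- paste0("chi", seq_len(nchi))
  unname(g)
}

#' Build a residue from its template
#'
#' Constructs idealised coordinates for a residue in a local frame: N at the
#' origin, CA on +x, C in the xy plane.
#'
#' @param template three-letter code.
#' @param chi numeric chi angles (degrees); defaults to the first rotamer.
#' @param include_h build polar hydrogens.
#' @return A list with `names` (character) and `xyz` (n x 3 matrix).
#' @keywords internal
build_residue <- function(template, chi = NULL, include_h = TRUE) {
  template <- toupper(template)
  z <- residue_zmat(template)
  nchi <- .N_CHI[[template]]
  if (is.null(chi)) chi <- rotamer_set(template)[1, ]
  if (length(chi) < nchi) stop(template, " needs ", nchi, " chi angles")
  pos <- list(
    N  = c(0, 0, 0),
    CA = c(1.458, 0, 0),
    C  = c(1.458, 0, 0) + 1.525 * c(cos(pi * (180 - 111.2) / 180),
                                    sin(pi * (180 - 111.2) / 180), 0)
  )
  for (i in seq_len(nrow(z))) {
    r <- z[i, ]
    if (!include_h && grepl("^H", r$atom)) next
    tors <- if (r$chi > 0) chi[r$chi] + r$tors else r$tors
    pos[[r$atom]] <- place_atom(pos[[r$r3]], pos[[r$r2]], pos[[r$r1]],
                                r$b, r$ang, tors)
  }
  list(names = names(pos), xyz = do.call(rbind, pos))
}

## ---- hydrogen-bond chemistry tables -------------------------------------

.SC_DONORS <- list(
  SER = data.frame(heavy = "OG", h = "HG"),
  THR = data.frame(heavy = "OG1", h = "HG1"),
  TYR = data.frame(heavy = "OH", h = "HH"),
  CYS = data.frame(heavy = "SG", h = "HG"),
  ASN = data.frame(heavy = c("ND2", "ND2"), h = c("HD21", "HD22")),
  GLN = data.frame(heavy = c("NE2", "NE2"), h = c("HE21", "HE22")),
  LYS = data.frame(heavy = c("NZ", "NZ", "NZ"), h = c("HZ1", "HZ2", "HZ3")),
  ARG = data.frame(heavy = c("NE", "NH1", "NH1", "NH2", "NH2"),
                   h = c("HE", "HH11", "HH12", "HH21", "HH22")),
  HIS = data.frame(heavy = "ND1", h = "HD1"),
  TRP = data.frame(heavy = "NE1", h = "HE1")
)

.SC_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = "NE2", MET = "SD", CYS = "SG"
)

#' Hydrogen-bond donors of a residue template
#' @param template three-letter code.
#' @return data.frame with columns heavy, h (includes the backbone amide).
#' @keywords internal
template_donors <- function(template) {
  template <- toupper(template)
  bb <- if (template == "PRO") NULL else data.frame(heavy = "N", h = "H")
  rbind(bb, .SC_DONORS[[template]])
}

#' Hydrogen-bond acceptors of a residue template
#' @param template three-letter code.
#' @return Character vector of heavy-atom names (includes the backbone O).
#' @keywords internal
template_acceptors <- function(template) {
  c("O", .SC_ACCEPTORS[[toupper(template)]])
}

## Element from a (stripped) PDB atom name in protein context.
.element_of <- function(name) {
  first <- substr(gsub("^[0-9']+", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

## Hard-sphere vdW radii by element, used for clash screening only.
.CLASH_RADII <- c(H = 1.0, C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 1.9)
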