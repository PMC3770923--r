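## The tcr_structure container and PDB input/output.
##
## A tcr_structure holds one topology (atom table) plus >= 1 coordinate
## frames. Frames stand in for snapshots extracted from a trajectory; a
## single X-ray model is a valid 1-frame ensemble. Residue identity is
## (chain, author residue number, insertion code) and is never renumbered.

.res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = ":")
}

## Parse "D:17" / "D:17:A" into chain/resno/icode.
.parse_res_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("residue id must be 'chain:resno' or 'chain:resno:icode'")
  list(chain = parts[1], resno = as.integer(parts[2]),
       icode = if (length(parts) >= 3) parts[3] else "")
}

.new_structure <- function(atoms, xyz, receptor_chains = NULL,
                           ligand_chains = NULL, parameter_source = NA_character_,
                           ptable = NULL) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz,
                 receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains,
                 parameter_source = parameter_source,
                 ptable = ptable),
            class = "tcr_structure")
}

#' Number of frames in a structure
#' @param x a `tcr_structure`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$xyz)[3]

## n x 3 coordinate matrix of frame f.
.coords <- function(x, frame = 1) matrix(x$xyz[, , frame], ncol = 3)

## Light line-level scan to validate MODEL blocks before handing the file
## to the parser: bio3d warns (rather than errors) on ragged models.
.scan_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no atoms found in ", path)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) <= 1) return(1L)
  bounds <- c(model_starts, length(lines) + 1L)
  counts <- vapply(seq_along(model_starts), function(i) {
    sum(is_atom[bounds[i]:(bounds[i + 1] - 1L)])
  }, integer(1))
  if (length(unique(counts)) != 1L)
    stop("inconsistent models: atom counts ", paste(counts, collapse = ", "))
  length(model_starts)
}

#' Read a protein structure from a PDB file
#'
#' Parses a (possibly multi-MODEL) PDB file into a [tcr_structure]. Models
#' become coordinate frames over a shared topology. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken alphabetically,
#' so 'A' wins). The structure is returned unparameterized; see
#' [assign_parameters()].
#'
#' @param path path to a PDB file.
#' @param frame_policy `"first"` keeps only the first MODEL; `"all"` keeps
#'   every MODEL as a frame.
#' @return A `tcr_structure`.
#' @export
read_structure <- function(path, frame_policy = c("first", "all")) {
  frame_policy <- match.arg(frame_policy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  nmodels <- .scan_models(path)
  multi <- frame_policy == "all" && nmodels > 1L
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- if (multi) pdb$xyz else matrix(pdb$xyz[1, ], nrow = 1)
  nfr <- nrow(xyz)

  chain <- ifelse(is.na(at$chain), " ", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)

  ## altloc resolution: highest occupancy, tie -> first alphabetically
  keep <- rep(TRUE, nrow(at))
  akey <- paste(chain, at$resno, icode, at$elety, sep = "|")
  dup <- akey[alt != "" & duplicated(akey) | alt != "" & duplicated(akey, fromLast = TRUE)]
  for (k in unique(dup)) {
    idx <- which(akey == k)
    ord <- idx[order(-occ[idx], alt[idx])]
    keep[setdiff(idx, ord[1])] <- FALSE
  }

  element <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                    toupper(trimws(at$elesy)), .element_of(at$elety))
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resid = at$resid,
    chain = chain, resno = at$resno, icode = icode,
    het = at$type == "HETATM", element = element,
    charge = NA_real_, rmin2 = NA_real_, eps = NA_real_, born = NA_real_,
    region = NA_character_, partner = NA_character_,
    stringsAsFactors = FALSE
  )
  atoms$reskey <- .res_key(atoms$chain, atoms$resno, atoms$icode)

  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  for (f in seq_len(nfr)) arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (any(!is.finite(arr))) stop("non-finite coordinates in ", path)

  atoms_kept <- atoms[keep, , drop = FALSE]
  .new_structure(atoms_kept, arr[keep, , , drop = FALSE])
}

#' Write a structure to a PDB file
#'
#' Writes all frames (as MODEL/ENDMDL blocks when there is more than one)
#' with TER records at chain breaks. Coordinates are written at standard PDB
#' precision (1e-3 Angstrom).
#'
#' @param x a `tcr_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path) {
  at <- x$atoms
  nfr <- n_frames(x)
  fmt_line <- function(i, xyz, serial) {
    rec <- if (at$het[i]) "HETATM" else "ATOM  "
    nm <- at$name[i]
    nm_f <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial %% 100000, nm_f, at$resid[i], at$chain[i], at$resno[i],
            ifelse(nchar(at$icode[i]) > 0, at$icode[i], " "),
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, at$element[i])
  }
  out <- character(0)
  for (f in seq_len(nfr)) {
    if (nfr > 1) out <- c(out, sprintf("MODEL     %4d", f))
    xyz <- .coords(x, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    serial <- 0L
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      out <- c(out, fmt_line(i, xyz, serial))
      last_of_chain <- i == nrow(at) || at$chain[i + 1] != at$chain[i]
      if (last_of_chain) out <- c(out, "TER")
    }
    if (nfr > 1) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Declare the receptor/ligand partner split
#'
#' Records which chains form the receptor (TCR) and which the ligand
#' (peptide + MHC). Residues outside either set are excluded from scoring.
#'
#' @param x a `tcr_structure`.
#' @param receptor_chains,ligand_chains character vectors of chain ids.
#' @return The structure with the partner split recorded.
#' @export
split_partners <- function(x, receptor_chains, ligand_chains) {
  have <- unique(x$atoms$chain)
  missing <- setdiff(c(receptor_chains, ligand_chains), have)
  if (length(missing) > 0)
    stop("missing chain: ", paste(missing, collapse = ", "))
  if (length(intersect(receptor_chains, ligand_chains)) > 0)
    stop("overlap: chains cannot be in both receptor and ligand")
  x$receptor_chains <- receptor_chains
  x$ligand_chains <- ligand_chains
  x$atoms$partner <- ifelse(x$atoms$chain %in% receptor_chains, "receptor",
                     ifelse(x$atoms$chain %in% ligand_chains, "ligand",
                            NA_character_))
  x
}

#' Tag residues with structural regions
#'
#' Assigns region labels (CDR loops, framework, peptide, MHC) from a region
#' map. Untagged receptor residues default to `"framework"`; untagged ligand
#' residues default to `"MHC"`.
#'
#' @param x a partner-split `tcr_structure`.
#' @param region_map a data frame with columns `chain`, `start`, `end`,
#'   `region`, or the path of a YAML file with a `regions:` list of such
#'   entries. Valid regions: CDR1a, CDR2a, CDR3a, CDR1b, CDR2b, CDR3b,
#'   framework, peptide, MHC, other.
#' @return The structure with `region` filled for every scored residue.
#' @export
tag_regions <- function(x, region_map) {
  if (is.character(region_map) && length(region_map) == 1) {
    cfg <- yaml::read_yaml(region_map)
    region_map <- do.call(rbind, lapply(cfg$regions, as.data.frame))
  }
  valid <- c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b", "CDR3b",
             "framework", "peptide", "MHC", "other")
  bad <- setdiff(region_map$region, valid)
  if (length(bad) > 0) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  ## non-overlap within a chain
  for (ch in unique(region_map$chain)) {
    rows <- region_map[region_map$chain == ch, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1 && any(rows$start[-1] <= rows$end[-nrow(rows)]))
      stop("overlapping region ranges on chain ", ch)
  }
  x$atoms$region <- ifelse(x$atoms$partner == "receptor", "framework",
                    ifelse(x$atoms$partner == "ligand", "MHC", NA_character_))
  for (i in seq_len(nrow(region_map))) {
    r <- region_map[i, ]
    if (!r$chain %in% x$atoms$chain) stop("region map names absent chain ", r$chain)
    in_chain <- x$atoms$chain == r$chain
    hit <- in_chain & x$atoms$resno >= r$start & x$atoms$resno <= r$end
    if (!any(hit))
      stop("region range ", r$start, "-", r$end, " outside chain ", r$chain)
    x$atoms$region[hit] <- r$region
  }
  x
}

#' @export
print.tcr_structure <- function(x, ...) {
  at <- x$atoms
  cat("tcr_structure:", nrow(at), "atoms,",
      length(unique(at$reskey)), "residues,",
      length(unique(at$chain)), "chains,", n_frames(x), "frame(s)\n")
  if (!is.null(x$receptor_chains))
    cat("  receptor:", paste(x$receptor_chains, collapse = ","),
        " ligand:", paste(x$ligand_chains, collapse = ","), "\n")
  cat("  parameterized:", !is.na(x$parameter_source),
      if (!is.na(x$parameter_source)) paste0("(", x$parameter_source, ")"), "\n")
  invisible(x)
}

## Atom indices of a set of residues (by reskey); scored = parameterized &
## assigned to a partner.
.atoms_of <- function(x, reskeys) which(x$atoms$reskey %in% reskeys)

.receptor_idx <- function(x) which(x$atoms$partner %in% "receptor")
.ligand_idx <- function(x) which(x$atoms$partner %in% "ligand")
.scored_idx <- function(x) {
  if (all(is.na(x$atoms$partner))) seq_len(nrow(x$atoms))
  else which(!is.na(x$atoms$partner))
}

.com <- function(x, idx, frame = 1) colMeans(x$xyz[idx, , frame, drop = FALSE])
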