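## Force-field parameter tables and structure parameterisation.
##
## The bundled table (inst/extdata/params_ua.tsv) is a self-contained
## united-atom protein parameter set: heavy atoms plus explicit polar
## hydrogens, with partial charges, Lennard-Jones (rmin/2, epsilon) and
## intrinsic Born radii. It is modelled on published all-atom protein force
## fields but is deliberately swappable: any TSV with the same columns and
## charge sums equal to the formal charges is a valid parameter source.

#' Read a residue parameter table
#'
#' @param path TSV file with columns `template`, `atom`, `charge`, `rmin2`
#'   (Angstrom), `eps` (kcal/mol), `born` (Angstrom), `formal` (integer
#'   formal charge of the template, repeated on every row).
#' @return A `parameter_table` (data frame) validated so that per-template
#'   charges sum to the declared formal charge within 1e-4 e.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("template", "atom", "charge", "rmin2", "eps", "born", "formal")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$rmin2 <= 0) || any(tab$born <= 0))
    stop("rmin2 and born radii must be positive")
  for (t in unique(tab$template)) {
    rows <- tab[tab$template == t, ]
    if (abs(sum(rows$charge) - rows$formal[1]) > 1e-4)
      stop("charges of template ", t, " do not sum to its formal charge")
  }
  attr(tab, "source") <- basename(path)
  class(tab) <- c("parameter_table", class(tab))
  tab
}

#' The bundled united-atom parameter table
#'
#' @return A `parameter_table`; see [read_parameter_table()].
#' @export
default_parameter_table <- function() {
  read_parameter_table(system.file("extdata", "params_ua.tsv",
                                   package = "tcrforge", mustWork = TRUE))
}

## Build the coordinates of one missing polar hydrogen for residue rows
## `ridx` in frame f, from its template z-matrix row. Returns NULL if a
## reference atom is missing.
.place_h <- function(x, ridx, zrow, zmat, frame) {
  nm <- x$atoms$name[ridx]
  ref <- function(a) {
    j <- ridx[nm == a]
    if (length(j) != 1) return(NULL)
    x$xyz[j, , frame]
  }
  p1 <- ref(zrow$r1); p2 <- ref(zrow$r2); p3 <- ref(zrow$r3)
  if (is.null(p1) || is.null(p2) || is.null(p3)) return(NULL)
  tors <- zrow$tors
  if (zrow$chi > 0) {
    ## chi-dependent hydrogens (e.g. HE of Arg): measure the current chi off
    ## the chi-defining heavy atom already present in the structure
    h0 <- zmat[zmat$chi == zrow$chi & zmat$tors == 0 & !grepl("^H", zmat$atom), ]
    if (nrow(h0) != 1) return(NULL)
    q1 <- ref(h0$r1[1]); q2 <- ref(h0$r2[1]); q3 <- ref(h0$r3[1]); q4 <- ref(h0$atom[1])
    if (is.null(q1) || is.null(q2) || is.null(q3) || is.null(q4)) return(NULL)
    tors <- torsion_angle(q3, q2, q1, q4) + zrow$tors
  }
  place_atom(p3, p2, p1, zrow$b, zrow$ang, tors)
}

#' Assign force-field parameters to a structure
#'
#' Looks every atom up in the parameter table by (residue template, atom
#' name), constructs missing polar hydrogens by ideal geometry, and drops
#' hydrogens present in the input that the united-atom table does not name
#' (nonpolar hydrogens), with a warning. Idempotent.
#'
#' @param x a `tcr_structure`.
#' @param table a `parameter_table`; defaults to the bundled one.
#' @param unknown_policy `"error"` fails on residues or atoms absent from
#'   the table; `"skip-residue"` drops such residues from scoring with a
#'   warning.
#' @return The parameterized structure.
#' @export
assign_parameters <- function(x, table = default_parameter_table(),
                              unknown_policy = c("error", "skip-residue")) {
  unknown_policy <- match.arg(unknown_policy)
  at <- x$atoms
  nfr <- n_frames(x)
  templates <- unique(at$resid)
  known <- templates %in% unique(table$template)
  skipped <- character(0)

  if (any(!known)) {
    bad_res <- unique(at$reskey[at$resid %in% templates[!known]])
    if (unknown_policy == "error")
      stop("unknown residue template(s): ",
           paste(templates[!known], collapse = ", "))
    skipped <- c(skipped, bad_res)
  }

  ## drop hydrogens the table does not name (united-atom input handling)
  tab_key <- paste(table$template, table$atom, sep = "|")
  at_key <- paste(at$resid, at$name, sep = "|")
  extra_h <- at$element == "H" & !(at_key %in% tab_key) &
    !(at$reskey %in% skipped) & at$resid %in% unique(table$template)
  if (any(extra_h)) {
    warning(sum(extra_h), " hydrogen(s) not in the united-atom table were dropped")
    x$atoms <- at <- at[!extra_h, , drop = FALSE]
    x$xyz <- x$xyz[!extra_h, , , drop = FALSE]
    at_key <- paste(at$resid, at$name, sep = "|")
  }

  ## unknown heavy atoms
  unknown_atom <- !(at_key %in% tab_key) & !(at$reskey %in% skipped) &
    at$resid %in% unique(table$template)
  if (any(unknown_atom)) {
    if (unknown_policy == "error")
      stop("atoms not in parameter table: ",
           paste(unique(paste(at$resid[unknown_atom], at$name[unknown_atom])),
                 collapse = ", "))
    skipped <- c(skipped, unique(at$reskey[unknown_atom]))
  }

  if (length(skipped) > 0) {
    warning("skipped residue(s): ", paste(skipped, collapse = ", "))
    keep <- !(at$reskey %in% skipped)
    x$atoms <- at <- at[keep, , drop = FALSE]
    x$xyz <- x$xyz[keep, , , drop = FALSE]
  }

  ## build missing polar hydrogens residue by residue
  new_rows <- list(); new_xyz <- list(); insert_after <- integer(0)
  for (rk in unique(at$reskey)) {
    ridx <- which(at$reskey == rk)
    template <- at$resid[ridx[1]]
    if (!template %in% .AA3) next   # custom templates carry their own atoms
    z <- residue_zmat(template)
    hz <- z[grepl("^H", z$atom), , drop = FALSE]
    if (nrow(hz) == 0) next
    have <- at$name[ridx]
    for (i in seq_len(nrow(hz))) {
      if (hz$atom[i] %in% have) next
      coords <- matrix(NA_real_, nfr, 3)
      ok <- TRUE
      for (f in seq_len(nfr)) {
        p <- .place_h(x, ridx, hz[i, ], z, f)
        if (is.null(p)) { ok <- FALSE; break }
        coords[f, ] <- p
      }
      if (!ok) next
      row <- at[ridx[1], , drop = FALSE]
      row$name <- hz$atom[i]; row$element <- "H"; row$serial <- NA_integer_
      new_rows[[length(new_rows) + 1]] <- row
      new_xyz[[length(new_xyz) + 1]] <- coords
      insert_after <- c(insert_after, ridx[length(ridx)])
    }
  }
  if (length(new_rows) > 0) {
    ord <- order(insert_after)
    at2 <- at
    arr <- x$xyz
    add_at <- do.call(rbind, new_rows[ord])
    add_xyz <- array(NA_real_, dim = c(nrow(add_at), 3, nfr))
    for (k in seq_along(ord))
      add_xyz[k, , ] <- t(new_xyz[[ord[k]]])
    ## append then re-sort into residue order
    at2 <- rbind(at2, add_at)
    arr2 <- array(NA_real_, dim = c(nrow(at2), 3, nfr))
    arr2[seq_len(nrow(at)), , ] <- arr
    arr2[nrow(at) + seq_len(nrow(add_at)), , ] <- add_xyz
    ord2 <- order(match(at2$reskey, unique(at$reskey)))
    x$atoms <- at <- at2[ord2, , drop = FALSE]
    x$xyz <- arr2[ord2, , , drop = FALSE]
  }

  ## parameter lookup
  at_key <- paste(at$resid, at$name, sep = "|")
  m <- match(at_key, paste(table$template, table$atom, sep = "|"))
  if (anyNA(m)) stop("internal: unmatched atoms after hydrogen build")
  x$atoms$charge <- table$charge[m]
  x$atoms$rmin2 <- table$rmin2[m]
  x$atoms$eps <- table$eps[m]
  x$atoms$born <- table$born[m]
  x$parameter_source <- attr(table, "source") %||% "custom"
  x$ptable <- table
  ## keep partner assignment in sync if chains were already split
  if (!is.null(x$receptor_chains))
    x <- split_partners(x, x$receptor_chains, x$ligand_chains)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net charge of each residue
#' @param x a parameterized `tcr_structure`.
#' @return Named numeric vector of per-residue charge sums.
#' @export
residue_charges <- function(x) {
  if (is.na(x$parameter_source)) stop("structure is not parameterized")
  tapply(x$atoms$charge, x$atoms$reskey, sum)
}
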