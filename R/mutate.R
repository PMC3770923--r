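## In-silico mutagenesis: alanine truncation and general point mutants.
## Backbone atoms are never moved; mutant side chains are grown from ideal
## internal geometry with chi angles taken from a small deterministic
## rotamer library, choosing the rotamer with the least steric overlap.

.BACKBONE <- c("N", "CA", "C", "O", "H")

.std_aa <- function(code) toupper(code) %in% .AA3

## indices of one residue, error if absent
.res_rows <- function(x, residue_id) {
  id <- .parse_res_id(residue_id)
  key <- .res_key(id$chain, id$resno, id$icode)
  idx <- which(x$atoms$reskey == key)
  if (length(idx) == 0) stop("residue not found: ", residue_id)
  idx
}

#' Truncate a residue to alanine
#'
#' Removes side-chain atoms beyond C-beta and retypes the residue as ALA.
#' Backbone coordinates (and every other residue) are untouched; all frames
#' are mutated consistently.
#'
#' @param x a `tcr_structure`.
#' @param residue_id residue as `"chain:resno"` (optionally `:icode`).
#' @return The mutated structure (re-parameterized if the input was).
#' @export
build_alanine_mutant <- function(x, residue_id) {
  idx <- .res_rows(x, residue_id)
  template <- x$atoms$resid[idx[1]]
  if (!.std_aa(template)) stop("not a standard amino acid: ", template)
  if (template == "ALA") stop("already ALA: ", residue_id)
  if (template == "GLY") stop("cannot alanine-mutate GLY (no C-beta): ", residue_id)
  if (template == "PRO") stop("cannot alanine-mutate PRO (ring spans backbone): ",
                              residue_id)
  keep_names <- c(.BACKBONE, "CB")
  drop <- idx[!(x$atoms$name[idx] %in% keep_names)]
  if (length(drop) > 0) {
    keep <- setdiff(seq_len(nrow(x$atoms)), drop)
    x$atoms <- x$atoms[keep, , drop = FALSE]
    x$xyz <- x$xyz[keep, , , drop = FALSE]
    idx <- .res_rows(x, residue_id)
  }
  x$atoms$resid[idx] <- "ALA"
  if (!is.na(x$parameter_source))
    x <- assign_parameters(x, x$ptable)
  x
}

## steric score of candidate side-chain coordinates against environment
.clash_score <- function(cand_xyz, cand_el, env_xyz, env_el) {
  if (nrow(env_xyz) == 0) return(list(n = 0L, depth = 0, pairs = NULL))
  rv_c <- .CLASH_RADII[cand_el]
  rv_e <- .CLASH_RADII[env_el]
  n <- 0L; depth <- 0; pairs <- NULL
  for (i in seq_len(nrow(cand_xyz))) {
    d <- sqrt(colSums((t(env_xyz) - cand_xyz[i, ])^2))
    thr <- 0.6 * (rv_c[i] + rv_e)
    hit <- which(d < thr)
    if (length(hit) > 0) {
      n <- n + length(hit)
      depth <- depth + sum(thr[hit] - d[hit])
      pairs <- c(pairs, hit)
    }
  }
  list(n = n, depth = depth, pairs = unique(pairs))
}

#' Build a point mutant
#'
#' Replaces one residue by another standard amino acid. Backbone atoms and
#' the shared side-chain prefix keep their wild-type coordinates (shared chi
#' angles are measured from the wild type, so the common stem is preserved);
#' remaining atoms are grown by ideal internal geometry, trying each rotamer
#' of a small canonical library for the new chi angles and keeping the one
#' with the least hard-sphere overlap (clash threshold 0.6 x sum of vdW
#' radii). Deterministic given inputs.
#'
#' @param x a `tcr_structure`.
#' @param residue_id residue as `"chain:resno"`.
#' @param new_template three-letter code of the replacement.
#' @return The mutated structure; identity mutations return `x` unchanged.
#' @export
build_point_mutant <- function(x, residue_id, new_template) {
  new_template <- toupper(new_template)
  idx <- .res_rows(x, residue_id)
  old_template <- x$atoms$resid[idx[1]]
  if (!.std_aa(old_template) || !.std_aa(new_template))
    stop("both templates must be standard amino acids")
  if (old_template == new_template) return(x)

  z_new <- residue_zmat(new_template)
  nm_old <- x$atoms$name[idx]

  ## shared prefix: atoms of the new template present in the wild type whose
  ## build references are themselves shared (walked in build order)
  shared <- intersect(c("N", "CA", "C"), nm_old)
  if (length(shared) < 3) stop("residue ", residue_id, " lacks backbone atoms")
  for (i in seq_len(nrow(z_new))) {
    r <- z_new[i, ]
    if (r$atom %in% nm_old && all(c(r$r1, r$r2, r$r3) %in% shared))
      shared <- c(shared, r$atom)
  }

  nchi <- .N_CHI[[new_template]]
  ## chi angles whose defining heavy atom is shared are measured, not sampled
  chi_defs <- z_new[z_new$chi > 0 & z_new$tors == 0 & !grepl("^H", z_new$atom), ]
  chi_defs <- chi_defs[!duplicated(chi_defs$chi), , drop = FALSE]
  wt_coord <- function(a, frame) {
    j <- idx[nm_old == a]
    if (length(j) != 1) NULL else x$xyz[j, , frame]
  }
  measured_chi <- function(frame) {
    out <- rep(NA_real_, nchi)
    for (i in seq_len(nrow(chi_defs))) {
      r <- chi_defs[i, ]
      if (!r$atom %in% shared) next
      out[r$chi] <- torsion_angle(wt_coord(r$r3, frame), wt_coord(r$r2, frame),
                                  wt_coord(r$r1, frame), wt_coord(r$atom, frame))
    }
    out
  }

  build_new <- function(rot_chi, frame) {
    chi <- measured_chi(frame)
    chi[is.na(chi)] <- rot_chi[is.na(chi)]
    pos <- list()
    for (a in shared) pos[[a]] <- wt_coord(a, frame)
    rows_todo <- z_new[!(z_new$atom %in% shared), , drop = FALSE]
    for (i in seq_len(nrow(rows_todo))) {
      r <- rows_todo[i, ]
      if (is.null(pos[[r$r1]]) || is.null(pos[[r$r2]]) || is.null(pos[[r$r3]]))
        stop("cannot build ", r$atom, ": missing reference atoms")
      tors <- if (r$chi > 0) chi[r$chi] + r$tors else r$tors
      pos[[r$atom]] <- place_atom(pos[[r$r3]], pos[[r$r2]], pos[[r$r1]],
                                  r$b, r$ang, tors)
    }
    pos
  }

  env <- setdiff(seq_len(nrow(x$atoms)), idx)
  env_heavy <- env[x$atoms$element[env] != "H"]
  rot <- rotamer_set(new_template)
  if (ncol(rot) < nchi) rot <- cbind(rot, matrix(180, nrow(rot), nchi - ncol(rot)))

  scores <- vector("list", nrow(rot))
  for (k in seq_len(nrow(rot))) {
    pos <- build_new(rot[k, ], 1)
    grown <- setdiff(names(pos), shared)
    grown_heavy <- grown[!grepl("^H", grown)]
    if (length(grown_heavy) == 0) {
      scores[[k]] <- list(n = 0L, depth = 0, pairs = NULL)
      next
    }
    cand <- do.call(rbind, pos[grown_heavy])
    scores[[k]] <- .clash_score(cand, .element_of(grown_heavy),
                                matrix(x$xyz[env_heavy, , 1], ncol = 3),
                                x$atoms$element[env_heavy])
  }
  nclash <- vapply(scores, `[[`, integer(1), "n")
  depth <- vapply(scores, `[[`, numeric(1), "depth")
  best <- order(nclash, depth)[1]
  if (nclash[best] > 0) {
    hit <- env_heavy[scores[[best]]$pairs]
    stop("unresolvable clash introducing ", new_template, " at ", residue_id,
         "; closest contacts: ",
         paste(unique(paste0(x$atoms$reskey[hit], "/", x$atoms$name[hit])),
               collapse = ", "))
  }

  ## assemble the mutated residue in template order, all frames
  nfr <- n_frames(x)
  template_order <- unique(c("N", "CA", "C", z_new$atom))
  ## keep the wild-type amide H only if the template build provides none extra
  proto <- x$atoms[idx[1], , drop = FALSE]
  res_xyz <- array(NA_real_, dim = c(length(template_order), 3, nfr))
  for (f in seq_len(nfr)) {
    pos <- build_new(rot[best, ], f)
    res_xyz[, , f] <- do.call(rbind, pos[template_order])
  }
  res_rows <- proto[rep(1, length(template_order)), , drop = FALSE]
  res_rows$name <- template_order
  res_rows$resid <- new_template
  res_rows$element <- .element_of(template_order)
  res_rows$serial <- NA_integer_

  before <- which(seq_len(nrow(x$atoms)) < idx[1])
  after <- setdiff(which(seq_len(nrow(x$atoms)) > idx[1]), idx)
  at2 <- rbind(x$atoms[before, , drop = FALSE], res_rows,
               x$atoms[after, , drop = FALSE])
  arr2 <- array(NA_real_, dim = c(nrow(at2), 3, nfr))
  arr2[seq_along(before), , ] <- x$xyz[before, , , drop = FALSE]
  arr2[length(before) + seq_along(template_order), , ] <- res_xyz
  arr2[length(before) + length(template_order) + seq_along(after), , ] <-
    x$xyz[after, , , drop = FALSE]
  x$atoms <- at2
  x$xyz <- arr2
  if (!is.na(x$parameter_source))
    x <- assign_parameters(x, x$ptable)
  x
}
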