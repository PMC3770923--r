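## Per-residue binding free energy decomposition (BFED), computational
## alanine scanning (CAS), the local-summation ddG rule for designed
## mutations, and experimental affinity fold-change bookkeeping.
##
## Sign conventions, stated once and used everywhere:
##   * BFED contribution dG_res  : negative = the residue favours binding.
##   * CAS / design  ddG         : ddG = dG(mutant) - dG(wild type); for
##     alanine scanning positive = the truncated side chain favoured
##     binding; for designed mutations negative = improved binding.

#' Per-residue binding free energy decomposition
#'
#' Splits the single-trajectory MM-GBSA binding energy over residues:
#' inter-partner pair terms (elec, vdw, GB cross terms) are attributed half
#' to each pair member's residue; GB self and intra-partner differences and
#' per-atom SASA changes are attributed to the owning residue. Contributions
#' sum exactly to the [binding_energy()] total.
#'
#' @param x a parameterized, partner-split `tcr_structure`.
#' @param dielectric a [dielectric_model()].
#' @param nonpolar a [nonpolar_params()].
#' @return A data frame (class `bfed`) with one row per scored residue and
#'   columns reskey, resid, chain, resno, region, partner, elec, vdw, gb,
#'   np, total; attribute `binding` holds the matching energy breakdown.
#' @export
bfed <- function(x, dielectric = dielectric_model(),
                 nonpolar = nonpolar_params()) {
  .check_param(x)
  if (is.null(x$receptor_chains)) stop("partner split not declared")
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  allidx <- sort(c(rec, lig))
  reskeys <- unique(x$atoms$reskey[allidx])
  nres <- length(reskeys)
  rk_of <- x$atoms$reskey[allidx]
  acc <- matrix(0, nres, 4, dimnames = list(reskeys, c("elec", "vdw", "gb", "np")))
  nfr <- n_frames(x)

  qa <- x$atoms$charge[rec]; qb <- x$atoms$charge[lig]
  rmin <- outer(x$atoms$rmin2[rec], x$atoms$rmin2[lig], "+")
  epsm <- sqrt(x$atoms$eps[rec] %o% x$atoms$eps[lig])
  rk_rec <- x$atoms$reskey[rec]; rk_lig <- x$atoms$reskey[lig]

  add <- function(col, keys, vals) {
    s <- tapply(vals, keys, sum)
    acc[names(s), col] <<- acc[names(s), col] + s
  }

  for (f in seq_len(nfr)) {
    D <- .cross_dist(matrix(x$xyz[rec, , f], ncol = 3),
                     matrix(x$xyz[lig, , f], ncol = 3))
    if (any(D < 1e-6)) stop("overlapping atoms (r < 1e-6 A)")
    ## elec: half of each inter pair to each side
    E <- .K_COULOMB / dielectric$eps_in * (qa %o% qb) / D
    add("elec", rk_rec, rowSums(E) / 2)
    add("elec", rk_lig, colSums(E) / 2)
    ## vdw
    s6 <- (rmin / D)^6
    V <- epsm * (s6 * s6 - 2 * s6)
    add("vdw", rk_rec, rowSums(V) / 2)
    add("vdw", rk_lig, colSums(V) / 2)
    ## gb: atom row sums of complex matrix minus the matching isolated-partner
    ## row sums; a symmetric matrix row sum splits every pair half/half
    MC <- .gb_matrix(x, allidx, f, dielectric)
    MR <- .gb_matrix(x, rec, f, dielectric)
    ML <- .gb_matrix(x, lig, f, dielectric)
    rsC <- rowSums(MC)
    names(rsC) <- as.character(allidx)
    dgb <- rsC
    dgb[as.character(rec)] <- dgb[as.character(rec)] - rowSums(MR)
    dgb[as.character(lig)] <- dgb[as.character(lig)] - rowSums(ML)
    add("gb", rk_of, dgb[as.character(allidx)])
    ## np: per-atom SASA change
    sC <- sasa(x, allidx, nonpolar$probe_radius, frame = f)$per_atom
    sR <- sasa(x, rec, nonpolar$probe_radius, frame = f)$per_atom
    sL <- sasa(x, lig, nonpolar$probe_radius, frame = f)$per_atom
    dsa <- sC
    dsa[names(sR)] <- dsa[names(sR)] - sR
    dsa[names(sL)] <- dsa[names(sL)] - sL
    add("np", x$atoms$reskey[as.integer(names(dsa))], nonpolar$gamma * dsa)
  }
  acc <- acc / nfr

  first <- match(reskeys, x$atoms$reskey)
  out <- data.frame(reskey = reskeys,
                    resid = x$atoms$resid[first],
                    chain = x$atoms$chain[first],
                    resno = x$atoms$resno[first],
                    region = x$atoms$region[first],
                    partner = x$atoms$partner[first],
                    elec = acc[, "elec"], vdw = acc[, "vdw"],
                    gb = acc[, "gb"], np = acc[, "np"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$total <- out$elec + out$vdw + out$gb + out$np
  attr(out, "binding") <- binding_energy(x, dielectric, nonpolar)
  class(out) <- c("bfed", class(out))
  out
}

## residues whose side chain can be truncated to alanine
.mutable <- function(resid) !(resid %in% c("GLY", "PRO", "ALA"))

#' Computational alanine scanning
#'
#' For each requested residue, truncates it to alanine and recomputes the
#' binding energy: ddG_CAS = dG_bind(Ala mutant) - dG_bind(wild type).
#' Positive values mean the wild-type side chain favours binding.
#' GLY/PRO/ALA targets are skipped with a warning.
#'
#' @param x a parameterized, partner-split `tcr_structure`.
#' @param residues residue keys to scan; default: every scored residue with
#'   a heavy atom within 5 A of the other partner (the interface).
#' @param dielectric,nonpolar energy model parameters.
#' @return A data frame (class `cas`) with reskey, resid, region, partner,
#'   ddg; attribute `skipped` lists unmutable residues.
#' @export
alanine_scan <- function(x, residues = NULL,
                         dielectric = dielectric_model(),
                         nonpolar = nonpolar_params()) {
  .check_param(x)
  if (is.null(x$receptor_chains)) stop("partner split not declared")
  if (is.null(residues)) residues <- interface_residues(x, 5)
  first <- match(residues, x$atoms$reskey)
  if (anyNA(first)) stop("unknown residue(s): ",
                         paste(residues[is.na(first)], collapse = ", "))
  resid <- x$atoms$resid[first]
  skip <- residues[!.mutable(resid)]
  if (length(skip) > 0)
    warning("skipped unmutable residue(s): ", paste(skip, collapse = ", "))
  todo <- residues[.mutable(resid)]
  wt <- binding_energy(x, dielectric, nonpolar)$total
  ddg <- vapply(todo, function(rk) {
    mut <- build_alanine_mutant(x, rk)
    binding_energy(mut, dielectric, nonpolar)$total - wt
  }, numeric(1))
  first <- match(todo, x$atoms$reskey)
  out <- data.frame(reskey = todo, resid = x$atoms$resid[first],
                    region = x$atoms$region[first],
                    partner = x$atoms$partner[first],
                    ddg = ddg, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skip
  class(out) <- c("cas", class(out))
  out
}

#' Interface residues by heavy-atom contact
#'
#' @param x a partner-split `tcr_structure`.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param frame frame used for the contact search.
#' @return Character vector of residue keys (both partners).
#' @export
interface_residues <- function(x, cutoff = 5, frame = 1) {
  rec <- .receptor_idx(x); lig <- .ligand_idx(x)
  rec <- rec[x$atoms$element[rec] != "H"]
  lig <- lig[x$atoms$element[lig] != "H"]
  D <- .cross_dist(matrix(x$xyz[rec, , frame], ncol = 3),
                   matrix(x$xyz[lig, , frame], ncol = 3))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  unique(c(x$atoms$reskey[rec[hit[, 1]]], x$atoms$reskey[lig[hit[, 2]]]))
}

#' Correlate alanine-scan and decomposition results
#'
#' Pearson correlation between CAS ddG values and BFED residue
#' contributions over the shared residues. Because a residue that favours
#' binding has a *negative* BFED contribution but a *positive* CAS ddG, the
#' BFED values are multiplied by `bfed_sign` (default -1) before
#' correlating; set `bfed_sign = 1` for the raw correlation.
#'
#' @param cas a `cas` table (or any data frame with reskey + ddg).
#' @param bfed_tab a `bfed` table (or data frame with reskey + total).
#' @param bfed_sign sign applied to BFED contributions (default -1).
#' @return A list with `r` (Pearson coefficient) and `table` (paired values).
#' @export
compare_cas_bfed <- function(cas, bfed_tab, bfed_sign = -1) {
  shared <- intersect(cas$reskey, bfed_tab$reskey)
  if (length(shared) < 3) stop("need at least 3 shared residues")
  a <- cas$ddg[match(shared, cas$reskey)]
  b <- bfed_sign * bfed_tab$total[match(shared, bfed_tab$reskey)]
  list(r = stats::cor(a, b),
       table = data.frame(reskey = shared, cas_ddg = a, bfed = b,
                          stringsAsFactors = FALSE))
}

#' Score a designed mutation by local summation
#'
#' Computes ddG_bind of a designed replacement as the sum of per-residue
#' contribution changes over the mutated residue and every residue in
#' contact with it (any heavy atom within `contact_cutoff` of a mutated-
#' residue heavy atom, in either structure). The local sum suppresses noise
#' from residues far from the site. Negative ddG = improved binding.
#'
#' @param wild,mutant parameterized, partner-split structures sharing
#'   numbering and differing at exactly one residue identity.
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom (Inf sums over
#'   all residues).
#' @param dielectric,nonpolar energy model parameters.
#' @return A `mutation_score` list: label, ddg, contacts, per_res.
#' @export
ddg_mutation <- function(wild, mutant, contact_cutoff = 4.5,
                         dielectric = dielectric_model(),
                         nonpolar = nonpolar_params()) {
  .check_param(wild); .check_param(mutant)
  wk <- unique(wild$atoms$reskey); mk <- unique(mutant$atoms$reskey)
  if (!identical(sort(wk), sort(mk))) stop("numbering mismatch between structures")
  wres <- wild$atoms$resid[match(wk, wild$atoms$reskey)]
  mres <- mutant$atoms$resid[match(wk, mutant$atoms$reskey)]
  diff <- wk[wres != mres]
  if (length(diff) == 0) stop("no differing residue between the structures")
  if (length(diff) > 1) stop("more than one differing residue: ",
                             paste(diff, collapse = ", "))
  site <- diff

  contact_set <- function(x) {
    i <- .atoms_of(x, site); i <- i[x$atoms$element[i] != "H"]
    o <- setdiff(.scored_idx(x), .atoms_of(x, site))
    o <- o[x$atoms$element[o] != "H"]
    if (is.infinite(contact_cutoff)) return(unique(x$atoms$reskey[o]))
    D <- .cross_dist(matrix(x$xyz[i, , 1], ncol = 3),
                     matrix(x$xyz[o, , 1], ncol = 3))
    unique(x$atoms$reskey[o[unique(which(D <= contact_cutoff, arr.ind = TRUE)[, 2])]])
  }
  contacts <- union(contact_set(wild), contact_set(mutant))
  local <- union(site, contacts)

  bw <- bfed(wild, dielectric, nonpolar)
  bm <- bfed(mutant, dielectric, nonpolar)
  per <- merge(bw[bw$reskey %in% local, c("reskey", "resid", "region", "total")],
               bm[bm$reskey %in% local, c("reskey", "resid", "total")],
               by = "reskey", suffixes = c("_wt", "_mut"))
  per$dddg <- per$total_mut - per$total_wt
  wt_code <- wres[wk == site]; mut_code <- mres[wk == site]
  structure(list(
    label = paste0(site, ":", wt_code, "->", mut_code),
    site = site, ddg = sum(per$dddg), contacts = contacts,
    n_contacts = length(contacts), per_res = per),
    class = "mutation_score")
}

#' @export
print.mutation_score <- function(x, ...) {
  cat(sprintf("mutation %s: ddG_bind = %.4f kcal/mol (%d contact residues; negative = improved binding)\n",
              x$label, x$ddg, x$n_contacts))
  invisible(x)
}

#' Rank designed mutations
#'
#' @param scores a list of `mutation_score` objects.
#' @return A data frame ordered by ascending ddG (most favourable first),
#'   ties broken by label.
#' @export
rank_designs <- function(scores) {
  if (length(scores) == 0) stop("no scores to rank")
  if (inherits(scores, "mutation_score")) scores <- list(scores)
  df <- data.frame(
    label = vapply(scores, `[[`, character(1), "label"),
    ddg = vapply(scores, `[[`, numeric(1), "ddg"),
    n_contacts = vapply(scores, `[[`, integer(1), "n_contacts"),
    stringsAsFactors = FALSE)
  df[order(df$ddg, df$label), , drop = FALSE]
}

#' Affinity fold change and its free-energy equivalent
#'
#' fold = K_D(wt) / K_D(mut) (>1 = the variant binds tighter) and
#' ddG_exp = R T ln(fold), the experimental binding free energy gain.
#'
#' @param kd_wt,kd_mut dissociation constants (same units, > 0).
#' @param temperature Kelvin.
#' @return A list with `fold` and `ddg_exp` (kcal/mol).
#' @export
kd_fold_change <- function(kd_wt, kd_mut, temperature = 298) {
  if (kd_wt <= 0 || kd_mut <= 0) stop("K_D values must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  fold <- kd_wt / kd_mut
  list(fold = fold, ddg_exp = .R_KCAL * temperature * log(fold))
}

#' Read an affinity (K_D) table
#'
#' @param path TSV with columns `variant` and `kd_um` (micromolar).
#' @return A data frame.
#' @export
read_affinity_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("variant", "kd_um") %in% names(tab)))
    stop("affinity table needs columns variant, kd_um")
  tab
}
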