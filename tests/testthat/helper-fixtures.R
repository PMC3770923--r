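## Shared test fixtures. Toy complexes are cached per (seed, frames) so the
## suite builds each one once.

.toy_cache <- new.env(parent = emptyenv())

toy <- function(seed = 7, n_frames = 1, ...) {
  key <- paste0("s", seed, "f", n_frames)
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- toy_structure(seed = seed, n_frames = n_frames, ...)
  .toy_cache[[key]]
}

## Minimal hand-built parameterized structure: one pseudo-atom per row.
## Used for closed-form energetics oracles (ions, spheres).
micro_structure <- function(xyz, charge = 0, rmin2 = 2, eps = 0.1, born = 2,
                            chain = "R", element = "C", name = NULL,
                            resno = NULL, receptor = NULL, ligand = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rep_n <- function(v) rep_len(v, n)
  if (is.null(name)) name <- paste0("X", seq_len(n))
  if (is.null(resno)) resno <- seq_len(n)
  at <- data.frame(serial = seq_len(n), name = name, resid = "XXX",
                   chain = rep_n(chain), resno = resno, icode = "",
                   het = FALSE, element = rep_n(element),
                   charge = rep_n(charge), rmin2 = rep_n(rmin2),
                   eps = rep_n(eps), born = rep_n(born),
                   region = NA_character_, partner = NA_character_,
                   stringsAsFactors = FALSE)
  at$reskey <- paste(at$chain, at$resno, "", sep = ":")
  x <- tcrforge:::.new_structure(at, array(xyz, dim = c(n, 3, 1)),
                                 parameter_source = "test")
  if (!is.null(receptor)) x <- split_partners(x, receptor, ligand)
  x
}

## Random rigid transform applied to every frame of a structure.
apply_rigid <- function(x, seed = 1) {
  set.seed(seed)
  R <- tcrforge:::rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
  t <- stats::rnorm(3, 0, 20)
  for (f in seq_len(n_frames(x)))
    x$xyz[, , f] <- sweep(x$xyz[, , f] %*% t(R), 2, t, "+")
  x
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "tcrforge.R", package = "tcrforge")

run_cli <- function(args) {
  out <- suppressWarnings(system2(rscript_bin(), c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
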