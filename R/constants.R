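## Physical constants used throughout the package.

#' Physical constants
#'
#' Constants used by the energetics and estimator modules:
#' \describe{
#'   \item{coulomb_k}{Coulomb constant, 332.0637 kcal A / (mol e^2).}
#'   \item{gas_r_kcal}{Gas constant, 1.9872e-3 kcal / (mol K).}
#'   \item{kb_kj}{Boltzmann constant times Avogadro, 0.0083144621 kJ / (mol K).}
#' }
#'
#' @format A named list of numbers.
#' @export
tcr_constants <- list(
  coulomb_k  = 332.0637,
  gas_r_kcal = 1.9872e-3,
  kb_kj      = 0.0083144621
)

.K_COULOMB <- 332.0637
.R_KCAL    <- 1.9872e-3
.KB_KJ     <- 0.0083144621
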