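#' Microscopic rate constants for an exosite enzyme
#'
#' Bundles the full microscopic rate-constant set of the two-step
#' substrate-recognition mechanism together with inhibitor binding and the
#' conformational exchange of the free enzyme.  The mechanism is:
#' substrate first docks at the exosite to form the encounter complex
#' (`E + S <-> SE`, rates `k1`/`k_m1`), the encounter complex rearranges
#' into the catalytically competent complex (`SE <-> ES`, rates
#' `k2`/`k_m2`), and turnover releases product irreversibly
#' (`ES -> E + P`, rate `kcat`).  A reversible active-site inhibitor binds
#' free enzyme and the encounter complex (`kon`/`koff`), and the free
#' enzyme exchanges between the substrate-accepting conformer E and an
#' alternative conformer F (`kfwd` for E to F, `kbkwd` for F to E).
#'
#' All concentrations are molar and all times are seconds throughout the
#' package; bimolecular rate constants are in 1/(M s), unimolecular ones
#' in 1/s.  Defaults are the constants used for the reference simulations:
#' they give a substrate Michaelis constant near 10 uM and an inhibitor
#' dissociation constant of exactly 1 uM.
#'
#' @param k1 exosite on-rate for substrate on conformer E, 1/(M s).
#' @param k_m1 exosite off-rate for substrate from SE, 1/s.
#' @param k2 rearrangement rate SE -> ES, 1/s.
#' @param k_m2 reverse rearrangement ES -> SE, 1/s.
#' @param kcat catalytic rate ES -> E + P, 1/s.
#' @param kon active-site on-rate for inhibitor, 1/(M s).
#' @param koff active-site off-rate for inhibitor, 1/s.
#' @param kfwd conformational conversion rate E -> F, 1/s.  `kfwd = 0`
#'   disables the F conformer (Keq = 0).
#' @param kbkwd conversion rate F -> E, 1/s; must be positive.
#' @param k_m1_SEI off-rate of substrate from the ternary SEI complex,
#'   1/s.  Defaults to `k_m1` under the assumption of complete
#'   independence between active site and exosite.
#' @param k1_F exosite on-rate for substrate on conformer F, 1/(M s); used
#'   only by the two-active-conformer scheme.  Defaults to `k1/10`, i.e. a
#'   10-fold higher Michaelis constant on F.
#' @param E_total total enzyme concentration, M.  Default 100 pM, far
#'   below every ligand concentration of interest so the pseudo
#'   first-order reduction is essentially exact.
#'
#' @return An object of class `exosite_params` (a named list).
#' @seealso [build_scheme()], [with_keq()], [keq()], [kd_inhibitor()]
#' @export
#' @examples
#' p <- exosite_params()
#' kd_inhibitor(p) * 1e6  # inhibitor Kd in uM
#' keq(p)                 # conformer equilibrium constant
exosite_params <- function(k1 = 1e7, k_m1 = 10, k2 = 1e3, k_m2 = 1,
                           kcat = 100, kon = 1e9, koff = 1e3,
                           kfwd = 1e3, kbkwd = 1e3,
                           k_m1_SEI = k_m1, k1_F = k1 / 10,
                           E_total = 1e-10) {
  p <- list(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2, kcat = kcat,
            kon = kon, koff = koff, kfwd = kfwd, kbkwd = kbkwd,
            k_m1_SEI = k_m1_SEI, k1_F = k1_F, E_total = E_total)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (x < 0)
      stop("parameter '", nm, "' must be >= 0", call. = FALSE)
    p[[nm]] <- as.numeric(x)  # guard against integer overflow downstream
  }
  if (p$kbkwd <= 0)
    stop("kbkwd must be > 0 (encode Keq = 0 as kfwd = 0)", call. = FALSE)
  if (p$E_total <= 0)
    stop("E_total must be > 0", call. = FALSE)
  structure(p, class = "exosite_params")
}

#' Reference parameter set
#'
#' The default microscopic constants: k1 = 1e7 1/(M s), k_m1 = 10 1/s,
#' k2 = 1e3 1/s, k_m2 = 1 1/s, kcat = 100 1/s, kon = 1e9 1/(M s),
#' koff = 1e3 1/s, kfwd = kbkwd = 1e3 1/s (Keq = 1), enzyme 100 pM.
#'
#' @return An `exosite_params` object.
#' @export
default_params <- function() exosite_params()

#' Conformer equilibrium constant
#'
#' Keq = kfwd / kbkwd, the equilibrium ratio \[F\]/\[E\] of the free
#' enzyme.  Keq = 0 means the free enzyme exists only as conformer E.
#'
#' @param params an `exosite_params` object.
#' @return A number.
#' @export
keq <- function(params) {
  stopifnot(inherits(params, "exosite_params"))
  params$kfwd / params$kbkwd
}

#' Inhibitor dissociation constant
#'
#' Kd = koff / kon for the active-site inhibitor (Inf when kon = 0,
#' i.e. no inhibitor is modelled).
#'
#' @param params an `exosite_params` object.
#' @return A number, M.
#' @export
kd_inhibitor <- function(params) {
  stopifnot(inherits(params, "exosite_params"))
  if (params$kon == 0) return(Inf)
  params$koff / params$kon
}

#' Set the conformer equilibrium constant
#'
#' Returns a copy of `params` with `kfwd = keq * kbkwd`, the conventional
#' way to scan the E/F equilibrium while keeping the F -> E rate fixed.
#'
#' @param params an `exosite_params` object.
#' @param keq desired equilibrium constant, >= 0.
#' @return An `exosite_params` object.
#' @export
#' @examples
#' p <- with_keq(default_params(), 1.5)
#' keq(p)
with_keq <- function(params, keq) {
  stopifnot(inherits(params, "exosite_params"))
  if (!is.numeric(keq) || length(keq) != 1L || !is.finite(keq) || keq < 0)
    stop("keq must be a single finite number >= 0", call. = FALSE)
  params$kfwd <- keq * params$kbkwd
  do.call(exosite_params, unclass(params))
}

#' @export
print.exosite_params <- function(x, ...) {
  cat("Exosite enzyme rate constants (M, s units)\n")
  cat(sprintf("  substrate:  k1 = %.3g  k-1 = %.3g  k2 = %.3g  k-2 = %.3g  kcat = %.3g\n",
              x$k1, x$k_m1, x$k2, x$k_m2, x$kcat))
  cat(sprintf("  inhibitor:  kon = %.3g  koff = %.3g  (Kd = %.3g uM)  k-1(SEI) = %.3g\n",
              x$kon, x$koff, kd_inhibitor(x) * 1e6, x$k_m1_SEI))
  cat(sprintf("  conformer:  kfwd = %.3g  kbkwd = %.3g  (Keq = %.3g)  k1(F) = %.3g\n",
              x$kfwd, x$kbkwd, keq(x), x$k1_F))
  cat(sprintf("  enzyme:     E_total = %.3g M\n", x$E_total))
  invisible(x)
}
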