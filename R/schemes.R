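#' Available reaction-scheme variants
#'
#' * `"base"` — free enzyme exchanges between a substrate-accepting
#'   conformer E and a fully closed conformer F; the inhibitor binds the
#'   active site of E and of the encounter complex SE, and substrate can
#'   still dock at the exosite of EI (ternary complex SEI).
#' * `"f-active-open"` — as base, but in conformer F the active site is
#'   properly formed while the exosite is closed, so the inhibitor also
#'   binds F (species FI).
#' * `"f-exosite-open"` — as base, but in conformer F the exosite stays
#'   open while the active site is closed: substrate (not inhibitor) binds
#'   F, forming a dead-end encounter complex SF that cannot rearrange into
#'   the catalytic pathway.
#' * `"two-conformer"` — both conformers are catalytically active with
#'   identical kinetics except a lower exosite on-rate on F (`k1_F`); the
#'   substrate/catalytic cycle is mirrored on F (species SF, FS), free and
#'   encounter forms exchange conformers, and the inhibitor binds the E
#'   conformer (optionally also F, see `inhibitor_on_F`).
#'
#' @return Character vector of variant identifiers.
#' @export
scheme_variants <- function() {
  c("base", "f-active-open", "f-exosite-open", "two-conformer")
}

#' Build a reaction scheme
#'
#' Assembles the mass-action [reaction_network()] for one of the four
#' scheme variants from a microscopic parameter set.  All variants share
#' the catalytic core `E + S <-> SE <-> ES -> E + P`, inhibitor binding
#' `E + I <-> EI`, `SE + I <-> SEI`, the ternary branch
#' `EI + S <-> SEI`, and the conformational step `E <-> F`.
#'
#' Conformational steps of ligand-bound forms mirror the free-enzyme step
#' (forward rate `kfwd` from the E-like to the F-like form) so that every
#' thermodynamic cycle closes with unit affinity whenever binding
#' affinities are equal on both conformers.  In the two-conformer scheme
#' the substrate affinities differ, so the backward rate of the
#' `SE <-> SF` exchange is rescaled by `k1/k1_F` to close the cycle
#' (`thermo_correct = FALSE` disables the rescaling for sensitivity
#' analyses; the cycle then reports affinity `k1/k1_F`).
#'
#' The initial state places all enzyme in conformer E, with free substrate
#' `S0` and free inhibitor `I0`.
#'
#' @param variant one of [scheme_variants()].
#' @param params an [exosite_params()] set.
#' @param S0 initial free substrate, M.
#' @param I0 initial free inhibitor, M.
#' @param thermo_correct rescale the bound-form exchange of the
#'   two-conformer scheme so all cycle affinities are 1 (default `TRUE`).
#' @param inhibitor_on_F two-conformer scheme only: also mirror the
#'   inhibitor cycle on conformer F (species FI and SFI, equal active-site
#'   affinity on both conformers).  Off by default: a conformer-neutral
#'   inhibitor cannot shift the E/F distribution, which provably abolishes
#'   activation-by-inhibition, so the default keeps inhibitor binding on
#'   the E conformer; the flag exists for sensitivity analyses.
#' @return A [reaction_network()]; `meta` records the variant and
#'   parameters.
#' @export
#' @examples
#' net <- build_scheme("base", default_params(), S0 = 1e-5)
#' net
#' detailed_balance_report(net)
build_scheme <- function(variant = scheme_variants(), params = default_params(),
                         S0 = 0, I0 = 0, thermo_correct = TRUE,
                         inhibitor_on_F = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "exosite_params"), S0 >= 0, I0 >= 0)
  if (I0 > 0 && params$kon == 0)
    stop("I0 > 0 requires kon > 0 (no inhibitor binding is modelled)",
         call. = FALSE)
  p <- params

  sp <- rbind(
    make_species("F", "enzyme-form"),
    make_species("E", "enzyme-form"),
    make_species("SE", "enzyme-form", carries_substrate = TRUE),
    make_species("ES", "enzyme-form", carries_substrate = TRUE),
    make_species("EI", "enzyme-form", carries_inhibitor = TRUE),
    make_species("SEI", "enzyme-form", carries_substrate = TRUE,
                 carries_inhibitor = TRUE),
    make_species("S", "free-ligand", carries_substrate = TRUE),
    make_species("I", "free-ligand", carries_inhibitor = TRUE),
    make_species("P", "product")
  )
  # E<->F with kfwd = 0 would violate k_forward > 0; encode Keq = 0 by an
  # irreversible F -> E step, which leaves F unreachable from the E pool.
  conf_step <- function(e_form, f_form) {
    if (p$kfwd > 0)
      reaction(stats::setNames(1, e_form), stats::setNames(1, f_form),
               p$kfwd, p$kbkwd, paste0(e_form, "<->", f_form))
    else
      reaction(stats::setNames(1, f_form), stats::setNames(1, e_form),
               p$kbkwd, 0, paste0(f_form, "->", e_form))
  }
  rx <- list(
    conf_step("E", "F"),
    reaction(c(E = 1, S = 1), c(SE = 1), p$k1, p$k_m1, "E+S<->SE"),
    reaction(c(SE = 1), c(ES = 1), p$k2, p$k_m2, "SE<->ES"),
    reaction(c(ES = 1), c(E = 1, P = 1), p$kcat, 0, "ES->E+P")
  )
  # kon = 0 means no inhibitor is modelled: drop the whole pathway
  has_inhibitor <- p$kon > 0
  if (has_inhibitor)
    rx <- c(rx, list(
      reaction(c(E = 1, I = 1), c(EI = 1), p$kon, p$koff, "E+I<->EI"),
      reaction(c(SE = 1, I = 1), c(SEI = 1), p$kon, p$koff, "SE+I<->SEI"),
      reaction(c(EI = 1, S = 1), c(SEI = 1), p$k1, p$k_m1_SEI, "EI+S<->SEI")
    ))

  if (variant == "f-active-open") {
    if (has_inhibitor) {
      sp <- rbind(sp, make_species("FI", "enzyme-form",
                                   carries_inhibitor = TRUE))
      rx <- c(rx, list(
        reaction(c(F = 1, I = 1), c(FI = 1), p$kon, p$koff, "F+I<->FI"),
        conf_step("EI", "FI")
      ))
    }
  } else if (variant == "f-exosite-open") {
    # SF is a dead-end encounter complex: the active site stays closed
    # while substrate occupies the exosite, so SF does not rearrange into
    # SE.  This is what raises the apparent Km (the SF pool sequesters
    # enzyme at high S) and lets the inhibitor recruit it through
    # F -> E -> EI, producing quasi-constitutive activation.
    sp <- rbind(sp, make_species("SF", "enzyme-form", carries_substrate = TRUE))
    rx <- c(rx, list(
      reaction(c(F = 1, S = 1), c(SF = 1), p$k1, p$k_m1, "F+S<->SF")
    ))
  } else if (variant == "two-conformer") {
    if (p$k1_F <= 0)
      stop("two-conformer scheme requires k1_F > 0", call. = FALSE)
    sp <- rbind(
      sp,
      make_species("SF", "enzyme-form", carries_substrate = TRUE),
      make_species("FS", "enzyme-form", carries_substrate = TRUE)
    )
    sf_back <- if (thermo_correct) p$kbkwd * p$k1 / p$k1_F else p$kbkwd
    rx <- c(rx, list(
      reaction(c(F = 1, S = 1), c(SF = 1), p$k1_F, p$k_m1, "F+S<->SF"),
      reaction(c(SF = 1), c(FS = 1), p$k2, p$k_m2, "SF<->FS"),
      reaction(c(FS = 1), c(F = 1, P = 1), p$kcat, 0, "FS->F+P"),
      if (p$kfwd > 0)
        reaction(c(SE = 1), c(SF = 1), p$kfwd, sf_back, "SE<->SF")
      else
        reaction(c(SF = 1), c(SE = 1), sf_back, 0, "SF->SE")
    ))
    if (inhibitor_on_F && has_inhibitor) {
      sp <- rbind(
        sp,
        make_species("FI", "enzyme-form", carries_inhibitor = TRUE),
        make_species("SFI", "enzyme-form", carries_substrate = TRUE,
                     carries_inhibitor = TRUE)
      )
      rx <- c(rx, list(
        reaction(c(F = 1, I = 1), c(FI = 1), p$kon, p$koff, "F+I<->FI"),
        reaction(c(SF = 1, I = 1), c(SFI = 1), p$kon, p$koff, "SF+I<->SFI"),
        reaction(c(FI = 1, S = 1), c(SFI = 1), p$k1_F, p$k_m1_SEI,
                 "FI+S<->SFI")
      ))
    }
  }

  # drop enzyme forms not referenced by any reaction (e.g. EI/SEI when no
  # inhibitor is modelled): they would be isolated states
  referenced <- unique(unlist(lapply(rx, function(r)
    c(names(r$reactants), names(r$products)))))
  sp <- sp[sp$role != "enzyme-form" | sp$name %in% referenced, ]

  init <- c(E = p$E_total, S = S0, I = I0)
  reaction_network(sp, rx, init = init,
                   meta = list(variant = variant, params = p,
                               thermo_correct = thermo_correct,
                               inhibitor_on_F = inhibitor_on_F))
}
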