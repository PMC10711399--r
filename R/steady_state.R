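#' Pseudo-first-order enzyme-state generator
#'
#' Reduces a reaction network to a continuous-time generator over the
#' enzyme forms by clamping the free ligand concentrations: bimolecular
#' binding steps become first-order transitions at rate `k * [ligand]`,
#' and the irreversible catalytic step enters as an `ES -> E` transition
#' at `kcat`.  The reduction is essentially exact when total enzyme is far
#' below the ligand concentrations (here 100 pM versus micromolar
#' ligands).
#'
#' The generator `Q` uses the column convention `d x / d t = Q x`, so
#' every column sums to zero.
#'
#' @param network a [reaction_network()].
#' @param S clamped free substrate concentration, M.
#' @param I clamped free inhibitor concentration, M.
#' @return An object of class `enzyme_state_matrix`: list with `states`
#'   (enzyme-form names) and `generator` (square matrix, 1/s).
#' @export
enzyme_state_matrix <- function(network, S, I) {
  stopifnot(S >= 0, I >= 0)
  enz <- network$species$name[network$species$role == "enzyme-form"]
  n <- length(enz)
  Q <- matrix(0, n, n, dimnames = list(enz, enz))
  clamp <- c(S = S, I = I)
  lig_factor <- function(stoich) {
    f <- 1
    for (nm in intersect(names(stoich), names(clamp)))
      f <- f * clamp[[nm]] ^ stoich[[nm]]
    f
  }
  for (r in network$reactions) {
    from <- intersect(names(r$reactants), enz)
    to <- intersect(names(r$products), enz)
    fwd <- r$k_forward * lig_factor(r$reactants)
    if (fwd > 0 && from != to) {
      Q[to, from] <- Q[to, from] + fwd
      Q[from, from] <- Q[from, from] - fwd
    }
    if (r$k_backward > 0) {
      bwd <- r$k_backward * lig_factor(r$products)
      if (bwd > 0 && from != to) {
        Q[from, to] <- Q[from, to] + bwd
        Q[to, to] <- Q[to, to] - bwd
      }
    }
  }
  structure(list(states = enz, generator = Q),
            class = "enzyme_state_matrix")
}

#' Stationary distribution of enzyme forms
#'
#' Solves `Q x = 0`, `sum(x) = 1` by a deterministic direct method: the
#' last balance row is replaced by the normalization row and the resulting
#' nonsingular system is solved exactly.  No iterative solver is involved,
#' so repeated runs are bit-reproducible.
#'
#' @param m an [enzyme_state_matrix()].
#' @param tol residual tolerance (relative to the largest generator
#'   entry); also the negativity floor for occupancies.
#' @return Named numeric vector of occupancy fractions (sums to 1).
#' @export
stationary_distribution <- function(m, tol = 1e-12) {
  stopifnot(inherits(m, "enzyme_state_matrix"))
  Q <- m$generator
  n <- nrow(Q)
  A <- Q
  A[n, ] <- 1
  b <- c(numeric(n - 1), 1)
  x <- tryCatch(solve(A, b), error = function(e)
    stop("disconnected scheme: stationary distribution is not unique (",
         conditionMessage(e), ")", call. = FALSE))
  scale <- max(abs(Q))
  if (scale > 0) {
    resid <- max(abs(Q %*% x)) / scale
    if (resid > 1e-8)
      stop("disconnected scheme: stationary residual ", signif(resid, 3),
           call. = FALSE)
  }
  if (any(x < -1e-9))
    stop("disconnected scheme: negative stationary occupancy", call. = FALSE)
  x[x < 0] <- 0
  x <- x / sum(x)
  stats::setNames(as.numeric(x), m$states)
}

#' Steady-state initial velocity
#'
#' Exact pseudo-steady-state initial velocity at fixed free ligand
#' concentrations: the stationary occupancies of the enzyme forms are
#' computed from the clamped-ligand generator and the velocity is
#' `kcat * E_total * (occupancy of the catalytic complexes)` (ES, plus FS
#' in the two-conformer scheme).  This linear solve is the default
#' velocity engine; ODE progress-curve integration ([velocity_ode()])
#' serves as the independent verification path.
#'
#' @param variant one of [scheme_variants()].
#' @param params an [exosite_params()] set.
#' @param S free substrate concentration, M.
#' @param I free inhibitor concentration, M.
#' @param network optional prebuilt network (avoids rebuilding in grid
#'   sweeps); must match `variant`/`params`.
#' @return One-row data frame with columns `S`, `I`, `v` (M/s) and
#'   `v_per_E` (1/s).
#' @export
#' @examples
#' velocity_ss("base", default_params(), S = 1e-5, I = 0)
velocity_ss <- function(variant, params, S, I, network = NULL) {
  if (is.null(network)) network <- build_scheme(variant, params)
  v <- velocity_from_network(network, S, I, params$E_total)
  data.frame(S = S, I = I, v = v, v_per_E = v / params$E_total)
}

#' @keywords internal
velocity_from_network <- function(network, S, I, E_total) {
  m <- enzyme_state_matrix(network, S, I)
  occ <- stationary_distribution(m)
  prod_sp <- network$species$name[network$species$role == "product"]
  v <- 0
  for (r in network$reactions) {
    if (any(names(r$products) %in% prod_sp)) {
      from <- intersect(names(r$reactants), m$states)
      v <- v + r$k_forward * occ[[from]]
    }
  }
  E_total * v
}

#' Closed-form Michaelis constant of the uninhibited three-state cycle
#'
#' King-Altman solution of the linear mechanism
#' `E + S <-> SE <-> ES -> E + P` (conformer exchange disabled, no
#' inhibitor).  The spanning-tree enumeration of the three-state diagram
#' gives
#' `Km = (k_m1*k_m2 + k_m1*kcat + k2*kcat) / (k1*(k2 + k_m2 + kcat))`
#' and the apparent catalytic constant
#' `kcat_app = kcat*k2 / (k2 + k_m2 + kcat)`.
#' With the default constants Km evaluates to about 9.17 uM (the nominal
#' reference value is 10 uM) and kcat_app to about 90.8 1/s.
#'
#' @param params an [exosite_params()] set.
#' @return Km in M.
#' @seealso [kcat_app_king_altman()], [velocity_king_altman()]
#' @export
km_king_altman <- function(params) {
  p <- params
  (p$k_m1 * p$k_m2 + p$k_m1 * p$kcat + p$k2 * p$kcat) /
    (p$k1 * (p$k2 + p$k_m2 + p$kcat))
}

#' @rdname km_king_altman
#' @return `kcat_app_king_altman`: apparent catalytic constant, 1/s.
#' @export
kcat_app_king_altman <- function(params) {
  p <- params
  p$kcat * p$k2 / (p$k2 + p$k_m2 + p$kcat)
}

#' Closed-form uninhibited velocity
#'
#' Exact rate law of the uninhibited mechanism.  With the conformer
#' exchange disabled this is the three-state King-Altman law
#' `v = E_total * kcat_app * S / (Km + S)`; with exchange enabled the
#' closed F conformer simply dilutes free E by the factor `1 + Keq`, so
#' the law is the same with `Km` replaced by `(1 + Keq) * Km` (exact,
#' because F exchanges only with E).
#'
#' @param params an [exosite_params()] set.
#' @param S substrate concentration(s), M.
#' @param keq conformer equilibrium constant (default 0).
#' @return Velocity, M/s (vectorized over `S`).
#' @export
velocity_king_altman <- function(params, S, keq = 0) {
  params$E_total * kcat_app_king_altman(params) * S /
    ((1 + keq) * km_king_altman(params) + S)
}

#' Closed-form apparent inhibition constants (Keq = 0)
#'
#' Limiting-behaviour analysis of the exact stationary rate law of the
#' base scheme with the conformer exchange disabled.  Writing the rate
#' law's low-substrate slope `s(I) = lim_{S->0} v/S` and the saturating
#' velocity `Vmax(I) = lim_{S->inf} v`, the mixed-inhibition form
#' `v = Vmax*S / (Km*(1 + I/Kic) + S*(1 + I/Kiu))` identifies
#' `1 + I/Kic` with `s(0)/s(I)` and `1 + I/Kiu` with `Vmax(0)/Vmax(I)`.
#'
#' `s(0)/s(I)` is a rational (not linear) function of `I`; its asymptotic
#' slope gives the competitive constant
#' `Kic = Kd * (k_m1 + k2*kcat/(k_m2 + kcat)) / k_m1_SEI`
#' (about 100 uM with the default constants).  `Vmax(0)/Vmax(I)` is
#' exactly linear, giving the uncompetitive constant
#' `Kiu = Kd * (1 + k2/(k_m2 + kcat))` (about 10.9 uM).
#'
#' @param params an [exosite_params()] set (requires `kon > 0`).
#' @return Kic (respectively Kiu) in M.
#' @seealso [fit_mixed_inhibition()] for the numerical-fit route.
#' @export
kic_closed_form <- function(params) {
  p <- params
  if (p$kon <= 0) stop("kon must be > 0", call. = FALSE)
  if (p$k_m1_SEI <= 0) stop("k_m1_SEI must be > 0", call. = FALSE)
  kd <- p$koff / p$kon
  kd * (p$k_m1 + p$k2 * p$kcat / (p$k_m2 + p$kcat)) / p$k_m1_SEI
}

#' @rdname kic_closed_form
#' @export
kiu_closed_form <- function(params) {
  p <- params
  if (p$kon <= 0) stop("kon must be > 0", call. = FALSE)
  (p$koff / p$kon) * (1 + p$k2 / (p$k_m2 + p$kcat))
}
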