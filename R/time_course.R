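#' Integrate the mass-action ODE system
#'
#' Stiff integration (lsoda) of the full network from its initial state.
#' Tolerances default to `rtol = 1e-8` and `atol = 1e-14` M: the
#' concentrations in play span 100 pM enzyme to 100 uM ligand, so the
#' absolute floor must sit well below the enzyme concentration.
#'
#' @param network a [reaction_network()].
#' @param t_end final time, s (> 0).
#' @param rtol,atol solver tolerances (positive).
#' @param n_out number of output intervals (default 500).
#' @param method deSolve method (default `"lsoda"`).
#' @return A data frame of class `kinetic_trajectory` with a `time`
#'   column and one column per species (M).  Attributes: `network`,
#'   `diagnostics` (solver record), `conservation_drift` (maximum
#'   relative drift of each conservation law along the trajectory).
#' @export
integrate_network <- function(network, t_end, rtol = 1e-8, atol = 1e-14,
                              n_out = 500, method = "lsoda") {
  stopifnot(t_end > 0, rtol > 0, atol > 0)
  spn <- network$species$name
  nsp <- length(spn)
  rxc <- lapply(network$reactions, function(r) list(
    ri = match(names(r$reactants), spn), rs = unname(r$reactants),
    pi = match(names(r$products), spn), ps = unname(r$products),
    kf = r$k_forward, kb = r$k_backward))
  rhs <- function(t, y, parms) {
    dx <- numeric(nsp)
    for (r in rxc) {
      vf <- r$kf * prod(y[r$ri] ^ r$rs)
      vb <- if (r$kb > 0) r$kb * prod(y[r$pi] ^ r$ps) else 0
      net <- vf - vb
      dx[r$ri] <- dx[r$ri] - net * r$rs
      dx[r$pi] <- dx[r$pi] + net * r$ps
    }
    list(dx)
  }
  times <- seq(0, t_end, length.out = n_out + 1)
  out <- deSolve::ode(y = network$init, times = times, func = rhs,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  diag <- list(istate = attr(out, "istate"), rstate = attr(out, "rstate"),
               type = attr(out, "type"))
  if (utils::tail(out[, "time"], 1) < t_end * (1 - 1e-8))
    stop("solver failure: integration stopped at t = ",
         utils::tail(out[, "time"], 1), " s", call. = FALSE)
  if (any(!is.finite(out)))
    stop("solver failure: non-finite state encountered", call. = FALSE)
  traj <- as.data.frame(out)
  names(traj)[1] <- "time"
  laws <- conservation_laws(network)
  drift <- vapply(laws, function(coef) {
    tot <- as.matrix(traj[spn]) %*% coef
    ref <- tot[1]
    if (ref == 0) max(abs(tot)) else max(abs(tot - ref)) / abs(ref)
  }, numeric(1))
  structure(traj, class = c("kinetic_trajectory", "data.frame"),
            network = network, diagnostics = diag,
            conservation_drift = drift, rtol = rtol, atol = atol)
}

# relaxation timescale of the clamped enzyme-state generator: 10 times the
# slowest nonzero relaxation time (from the generator's eigenvalues)
#' @keywords internal
transient_timescale <- function(network, S, I) {
  Q <- enzyme_state_matrix(network, S, I)$generator
  lam <- eigen(Q, only.values = TRUE)$values
  scale <- max(abs(lam))
  if (scale == 0) return(Inf)
  nz <- abs(Re(lam))[abs(lam) > 1e-10 * scale]
  if (!length(nz)) return(Inf)
  10 / min(nz)
}

#' Initial velocity from a progress curve
#'
#' Extracts the initial reaction velocity from a simulated trajectory as
#' the local slope of the product progress curve at the start of the
#' fitting window.  The window opens after the pre-steady-state transient
#' (ten times the slowest relaxation time of the clamped enzyme-state
#' generator) and closes when substrate depletion reaches
#' `depletion_max`.  Within the window the product curve is fitted with a
#' quadratic in time and the derivative is evaluated at the window start,
#' which removes the first-order bias that substrate depletion imposes on
#' a plain average slope.
#'
#' @param traj a [integrate_network()] trajectory.
#' @param depletion_max maximum allowed fraction of substrate consumed,
#'   in (0, 0.1] (default 0.01).
#' @return Initial velocity, M/s.
#' @export
initial_velocity_ode <- function(traj, depletion_max = 0.01) {
  stopifnot(inherits(traj, "kinetic_trajectory"),
            depletion_max > 0, depletion_max <= 0.1)
  network <- attr(traj, "network")
  prod_sp <- network$species$name[network$species$role == "product"]
  if (!length(prod_sp))
    stop("trajectory has no product species", call. = FALSE)
  P <- rowSums(traj[, prod_sp, drop = FALSE])
  laws <- conservation_laws(network)
  S_tot <- sum(network$init * laws$substrate)
  if (S_tot == 0) return(0)
  enz_tot <- sum(network$init * laws$enzyme)
  if (enz_tot > 0 && max(P) <= 0) {
    if (all(P == 0)) return(0)  # zero-enzyme or inert trajectory
    stop("product never increases despite S0 > 0: scheme error",
         call. = FALSE)
  }
  t_trans <- transient_timescale(network, network$init[["S"]],
                                 network$init[["I"]])
  in_window <- traj$time >= t_trans & P <= depletion_max * S_tot
  if (sum(in_window) < 5)
    stop("empty fitting window: t_end too short for the transient (",
         signif(t_trans, 3), " s) plus depletion window", call. = FALSE)
  tt <- traj$time[in_window]
  pp <- P[in_window]
  if (all(pp == pp[1])) return(0)
  t0 <- tt[1]
  fit <- stats::lm(pp ~ I(tt - t0) + I((tt - t0)^2))
  as.numeric(stats::coef(fit)[2])
}

#' Initial velocity by ODE integration
#'
#' Independent verification path for [velocity_ss()]: builds the network
#' at the requested ligand concentrations, integrates the progress curve
#' and extracts the initial velocity with [initial_velocity_ode()].  The
#' integration horizon is chosen in two stages: a short pilot run (20
#' transient timescales) estimates the velocity, then the production run
#' covers the transient plus the time to reach `depletion_max` substrate
#' depletion.
#'
#' @inheritParams velocity_ss
#' @inheritParams initial_velocity_ode
#' @inheritParams integrate_network
#' @param thermo_correct passed to [build_scheme()].
#' @return One-row data frame with columns `S`, `I`, `v`, `v_per_E`.
#' @export
velocity_ode <- function(variant, params, S, I, depletion_max = 0.01,
                         rtol = 1e-8, atol = 1e-14, thermo_correct = TRUE) {
  stopifnot(S >= 0, I >= 0)
  if (S == 0)
    return(data.frame(S = S, I = I, v = 0, v_per_E = 0))
  network <- build_scheme(variant, params, S0 = S, I0 = I,
                          thermo_correct = thermo_correct)
  t_trans <- transient_timescale(network, S, I)
  pilot <- integrate_network(network, t_end = 20 * t_trans,
                             rtol = rtol, atol = atol, n_out = 100)
  prod_sp <- network$species$name[network$species$role == "product"]
  P <- rowSums(pilot[, prod_sp, drop = FALSE])
  half <- pilot$time >= 10 * t_trans
  v_est <- stats::coef(stats::lm(P[half] ~ pilot$time[half]))[2]
  if (!is.finite(v_est) || v_est <= 0)
    stop("product never increases despite S0 > 0: scheme error", call. = FALSE)
  t_end <- t_trans + depletion_max * S / v_est
  traj <- integrate_network(network, t_end = t_end, rtol = rtol, atol = atol,
                            n_out = 400)
  v <- initial_velocity_ode(traj, depletion_max = depletion_max)
  data.frame(S = S, I = I, v = v, v_per_E = v / params$E_total)
}
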