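rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# base-scheme network with the F conformer removed entirely, for
# equivalence checks against the Keq = 0 encoding
base_without_F <- function(params) {
  net <- build_scheme("base", params)
  keep <- vapply(net$reactions, function(r)
    !any(c(names(r$reactants), names(r$products)) == "F"), logical(1))
  reaction_network(net$species[net$species$name != "F", ],
                   net$reactions[keep],
                   init = c(E = params$E_total, S = 0, I = 0))
}

# small two-state conformer-exchange network (no catalysis flux at S = 0)
two_state_net <- function(kfwd, kbkwd, E_total = 1e-10) {
  sp <- rbind(
    data.frame(name = "E", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE),
    data.frame(name = "F", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE)
  )
  reaction_network(sp, list(reaction(c(E = 1), c(F = 1), kfwd, kbkwd)),
                   init = c(E = E_total))
}

mixed_model_v <- function(S, I, Vmax, Km, Kic, Kiu) {
  Vmax * S / (Km * (1 + I / Kic) + S * (1 + I / Kiu))
}
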