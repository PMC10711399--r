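test_that("clamped generator entries are pseudo-first-order rates", {
  p <- default_params()
  net <- build_scheme("base", p)
  m <- enzyme_state_matrix(net, S = 1e-5, I = 0)
  Q <- m$generator
  expect_equal(Q["SE", "E"], p$k1 * 1e-5)   # 100 1/s
  expect_equal(Q["E", "ES"], p$kcat)        # catalysis as ES -> E
  expect_equal(Q["EI", "E"], 0)             # no inhibitor present
  expect_equal(colSums(Q), stats::setNames(numeric(6), m$states))

  # at S = I = 0 only the conformational exchange moves mass
  m0 <- enzyme_state_matrix(net, 0, 0)
  Q0 <- m0$generator
  expect_equal(Q0["F", "E"], p$kfwd)
  expect_equal(Q0["E", "F"], p$kbkwd)
  expect_equal(Q0["SE", "E"], 0)
})

test_that("two-state exchange has the textbook stationary split", {
  m <- enzyme_state_matrix(two_state_net(10, 10), 0, 0)
  expect_equal(stationary_distribution(m), c(E = 0.5, F = 0.5))
  m2 <- enzyme_state_matrix(two_state_net(20, 10), 0, 0)
  expect_equal(stationary_distribution(m2), c(E = 1 / 3, F = 2 / 3))
})

test_that("stationary distribution matches the long-time clamped ODE", {
  # integrate dx/dt = Q x directly: same reduction, independent solver
  net <- build_scheme("base", default_params())
  m <- enzyme_state_matrix(net, S = 1e-5, I = 0)
  Q <- m$generator
  x0 <- stats::setNames(c(0, 1, 0, 0, 0, 0), m$states)  # all enzyme in E
  sol <- deSolve::ode(y = x0, times = c(0, 5), parms = NULL,
                      func = function(t, y, p) list(as.numeric(Q %*% y)),
                      rtol = 1e-12, atol = 1e-16)
  x_inf <- sol[2, m$states]
  pi_hat <- stationary_distribution(m)
  expect_lt(max(rel_err(x_inf[pi_hat > 0], pi_hat[pi_hat > 0])), 1e-6)
})

test_that("velocity vanishes without substrate and scales with enzyme", {
  p <- default_params()
  expect_equal(velocity_ss("base", p, S = 0, I = 0)$v, 0)
  expect_equal(velocity_ss("base", p, S = 0, I = 1e-5)$v, 0)
  v1 <- velocity_ss("base", p, 1e-5, 1e-6)$v
  p10 <- exosite_params(E_total = 1e-9)
  v10 <- velocity_ss("base", p10, 1e-5, 1e-6)$v
  expect_equal(v10, 10 * v1, tolerance = 1e-12)
})

test_that("Keq = 0 velocities reproduce the King-Altman closed form", {
  p <- with_keq(default_params(), 0)
  km <- km_king_altman(p)
  expect_equal(km, 9.174387e-6, tolerance = 1e-6)
  expect_equal(kcat_app_king_altman(p), 90.82652, tolerance = 1e-6)
  # saturating limit: v/E -> k2*kcat/(k2 + k_m2 + kcat)
  v_sat <- velocity_ss("base", p, S = 1e-2, I = 0)$v_per_E
  expect_lt(rel_err(v_sat, kcat_app_king_altman(p)), 1e-3)
  for (S in km * 10 ^ seq(-2, 2, by = 0.5)) {
    v <- velocity_ss("base", p, S, 0)$v
    expect_lt(rel_err(v, velocity_king_altman(p, S)), 1e-9)
  }
})

test_that("the closed F conformer rescales Km by (1 + Keq) exactly", {
  p <- default_params()  # Keq = 1
  for (S in km_king_altman(p) * c(0.05, 0.3, 1, 3, 20)) {
    v <- velocity_ss("base", p, S, 0)$v
    expect_lt(rel_err(v, velocity_king_altman(p, S, keq = 1)), 1e-9)
  }
})

test_that("closed-form apparent inhibition constants match limiting slopes", {
  p <- with_keq(default_params(), 0)
  # competitive component from the S -> 0 slope ratio at large I
  S_tiny <- 1e-12
  I_big <- 1e-2  # 10^4 x Kd: deep in the asymptotic regime
  s0 <- velocity_ss("base", p, S_tiny, 0)$v / S_tiny
  sI <- velocity_ss("base", p, S_tiny, I_big)$v / S_tiny
  kic_num <- I_big / (s0 / sI - 1)
  expect_lt(rel_err(kic_closed_form(p), kic_num), 1e-2)
  # uncompetitive component from the saturating-velocity ratio
  S_big <- 1
  v0 <- velocity_ss("base", p, S_big, 0)$v
  vI <- velocity_ss("base", p, S_big, 1e-5)$v
  kiu_num <- 1e-5 / (v0 / vI - 1)
  expect_lt(rel_err(kiu_closed_form(p), kiu_num), 1e-2)
})

test_that("disconnected generators are reported as such", {
  # two conformers with no exchange at all: two closed classes
  sp <- rbind(
    data.frame(name = "E", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE),
    data.frame(name = "F", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE),
    data.frame(name = "X", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE),
    data.frame(name = "Y", role = "enzyme-form", carries_substrate = FALSE,
               carries_inhibitor = FALSE)
  )
  net <- reaction_network(
    sp,
    list(reaction(c(E = 1), c(F = 1), 5, 5),
         reaction(c(X = 1), c(Y = 1), 2, 2)),
    init = c(E = 1e-10, X = 1e-10))
  m <- enzyme_state_matrix(net, 0, 0)
  expect_error(stationary_distribution(m), "disconnected")
})
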