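test_that("problem assembly reflects the model and the effective state", {
  store <- local_toy_store()
  model <- get_model(store, "toy3")

  pr <- build_fba_problem(model)
  expect_equal(dim(pr$S), c(2, 3))
  expect_equal(pr$lb, model$reactions$lower_bound)
  expect_equal(pr$ub, model$reactions$upper_bound)

  f_ko <- store_mod(store, "koR1", "toy3", list(ko("R1")))
  st1 <- resolve_effective_state(list(f_ko), store)
  pr1 <- build_fba_problem(model, st1)
  i <- match("R1", pr1$reaction_ids)
  expect_equal(pr1$lb[i], 0)
  expect_equal(pr1$ub[i], 0)

  # a later set_bounds overrides the knockout through the effective state
  f_sb <- store_mod(store, "sbR1", "toy3", list(sb("R1", 0, 5)))
  pr2 <- build_fba_problem(model,
                           resolve_effective_state(list(f_ko, f_sb), store))
  expect_equal(pr2$lb[i], 0)
  expect_equal(pr2$ub[i], 5)

  ghost <- modification_file("g", "t", "toy3", list(ko("GHOST")))
  expect_error(build_fba_problem(model,
                                 resolve_effective_state(list(ghost), store)),
               class = "fluxtrace_consistency_error")
})

test_that("the chain fixture solves to the hand-derived optimum", {
  # EX_up in [-10, 0], R1 and EX_out in [0, 1000], maximise R1:
  # the uptake bound is the only active constraint, so v = (-10, 10, 10)
  sol <- solve_fba(build_fba_problem(generate_toy_model("chain", 3)$model))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(-10, 10, 10))
  expect_equal(sol$v_min, -10)
  expect_equal(sol$v_max, 10)
})

test_that("knocking out one parallel branch reroutes all flux through the other", {
  par <- generate_toy_model("parallel", 2)$model
  state <- structure(data.frame(target = "R1", operation = "knockout",
                                lower = NA_real_, upper = NA_real_,
                                provenance = "t", load_index = 1L,
                                stringsAsFactors = FALSE),
                     class = c("effective_state", "data.frame"))
  sol <- solve_fba(build_fba_problem(par, state))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes["R1"]), 0)
  expect_equal(unname(sol$fluxes["R2"]), 10)
})

test_that("forced-zero and infeasible problems are reported as results", {
  m <- generate_toy_model("chain", 3)$model
  m$reactions$lower_bound[] <- 0
  m$reactions$upper_bound[] <- 0
  sol <- solve_fba(build_fba_problem(m))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0)
  expect_true(all(sol$fluxes == 0))

  m2 <- generate_toy_model("chain", 3)$model
  m2$reactions$lower_bound[1] <- -10
  m2$reactions$upper_bound[1] <- -10   # force uptake
  m2$reactions$upper_bound[2:3] <- 0   # but close every outlet
  sol2 <- solve_fba(build_fba_problem(m2))
  expect_equal(sol2$status, "infeasible")
  expect_true(is.na(sol2$objective_value))
})

test_that("objectives agree with vertex enumeration on random fixtures", {
  for (seed in 1:20) {
    m <- generate_toy_model("random", n_reactions = sample(4:8, 1),
                            seed = seed)$model
    pr <- build_fba_problem(m)
    sol <- solve_fba(pr)
    oracle <- brute_force_fba(pr$c, pr$S, pr$lb, pr$ub)
    expect_equal(sol$status == "optimal", oracle$feasible)
    if (oracle$feasible)
      expect_equal(sol$objective_value, oracle$value,
                   tolerance = 1e-6, info = sprintf("seed %d", seed))
  }
})

test_that("optimal solutions satisfy mass balance and their bounds", {
  for (seed in 1:25) {
    m <- generate_toy_model("random", n_reactions = 4 + seed %% 5,
                            seed = 100 + seed)$model
    pr <- build_fba_problem(m)
    sol <- solve_fba(pr)
    expect_equal(sol$status, "optimal")
    v <- unname(sol$fluxes)
    expect_lte(max(abs(pr$S %*% v)), 1e-6)
    expect_true(all(v >= pr$lb - 1e-9 & v <= pr$ub + 1e-9))
  }
})

test_that("relaxing an upper bound never hurts; knockouts never help", {
  m <- synthetic_central_metabolism()$model
  base <- solve_fba(build_fba_problem(m))$objective_value
  for (i in seq_len(nrow(m$reactions))) {
    relaxed <- m
    relaxed$reactions$upper_bound[i] <- relaxed$reactions$upper_bound[i] + 500
    expect_gte(solve_fba(build_fba_problem(relaxed))$objective_value,
               base - 1e-9)

    state <- structure(data.frame(
      target = m$reactions$reaction_id[i], operation = "knockout",
      lower = NA_real_, upper = NA_real_, provenance = "t", load_index = 1L,
      stringsAsFactors = FALSE), class = c("effective_state", "data.frame"))
    kosol <- solve_fba(build_fba_problem(m, state))
    if (kosol$status == "optimal")
      expect_lte(kosol$objective_value, base + 1e-9)
  }
})

test_that("visual scalars implement the interpolation, clamp and debit rules", {
  # endpoints printed in the worked example: range [-45, 55], flux 10
  sol <- structure(list(status = "optimal",
                        fluxes = c(lo = -45, mid = 10, hi = 55, rest = 0),
                        objective_value = 1, v_min = -45, v_max = 55),
                   class = "flux_solution")
  vs <- compute_visual_scalars(sol, w_min = 0.5, w_max = 2, rate_per_flux = 3)
  expect_equal(vs$color_t[vs$reaction_id == "mid"], 0.55)
  expect_equal(vs$color_t[vs$reaction_id == "lo"], 0)
  expect_equal(vs$color_t[vs$reaction_id == "hi"], 1)
  expect_true(all(diff(vs$color_t[order(vs$flux)]) >= 0))
  expect_true(all(vs$width >= 0.5 & vs$width <= 2))
  expect_equal(vs$width[vs$reaction_id == "hi"], 2)
  expect_equal(vs$particle_rate, 3 * abs(unname(sol$fluxes)))
  expect_equal(vs$particle_rate[vs$reaction_id == "rest"], 0)

  # affine rescaling of the flux vector leaves color_t unchanged
  sol2 <- sol
  sol2$fluxes <- 2 * sol$fluxes + 7
  sol2$v_min <- 2 * sol$v_min + 7
  sol2$v_max <- 2 * sol$v_max + 7
  expect_equal(compute_visual_scalars(sol2)$color_t, vs$color_t)

  # degenerate range: all fluxes equal -> colour midpoint everywhere
  flat <- structure(list(status = "optimal", fluxes = c(a = 4, b = 4),
                         objective_value = 0, v_min = 4, v_max = 4),
                    class = "flux_solution")
  expect_equal(compute_visual_scalars(flat)$color_t, c(0.5, 0.5))

  infs <- structure(list(status = "infeasible", fluxes = NULL,
                         objective_value = NA_real_, v_min = NA_real_,
                         v_max = NA_real_), class = "flux_solution")
  expect_error(compute_visual_scalars(infs), class = "fluxtrace_state_error")
})

test_that("extrema can be restricted to the reactions mapped in a view", {
  syn <- synthetic_central_metabolism()
  sub <- '{"elements":{"nodes":[
    {"data":{"id":"glc_p"},"position":{"x":0,"y":0}},
    {"data":{"id":"GLCptspp"},"position":{"x":10,"y":0}}],
    "edges":[{"data":{"id":"e1","source":"glc_p","target":"GLCptspp"}}]}}'
  v <- parse_view(sub, syn$model)
  full <- solve_fba(build_fba_problem(syn$model))
  mapped <- solve_fba(build_fba_problem(syn$model), view = v)
  expect_equal(mapped$fluxes, full$fluxes)       # restriction is report-only
  expect_equal(mapped$v_min, unname(full$fluxes["GLCptspp"]))
  expect_equal(mapped$v_max, unname(full$fluxes["GLCptspp"]))
})
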