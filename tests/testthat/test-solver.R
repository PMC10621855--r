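# Small linear configurations used by several solver contracts
linear_mesh <- function() {
  if (is.null(.run_cache$linear_mesh))
    .run_cache$linear_mesh <- generate_mesh(get_map("A"), h_fine = 0.12,
                                            h_coarse = 3, h_lesion = 0.4)
  .run_cache$linear_mesh
}
linear_props <- tissue_properties(myo_sigma1 = 0.4)  # sigma0 == sigma1

test_that("hemispherical-electrode solution matches the closed form", {
  hp <- hemisphere_problem()
  expect_rel(hp$sol$I_delivered, hp$I_exact, 0.02)
  Rq <- c(3, 4, 6, 8)
  f <- field_at_points(hp$sol, Rq / sqrt(2), Rq / sqrt(2),
                       label = rep("BLOOD", length(Rq)))
  expect_true(all(abs(f$phi / hp$phi_exact(Rq) - 1) < 0.03))
})

test_that("a linear medium scales exactly with the applied voltage", {
  m <- linear_mesh()
  s1 <- solve_at_voltage(m, linear_props, 1000)
  s2 <- solve_at_voltage(m, linear_props, 2000)
  scale <- s2$phi / ifelse(abs(s1$phi) > 0, s1$phi, NA)
  expect_lt(max(abs(scale - 2), na.rm = TRUE), 1e-8)
  expect_rel(s2$I_delivered, 2 * s1$I_delivered, 1e-10)
})

test_that("current matching needs two voltage solves in a linear medium", {
  m <- linear_mesh()
  sol <- solve_at_current(m, linear_props, 10)
  expect_lte(sol$current_iters, 2)
  expect_lt(abs(sol$I_delivered - 10) / 10, solver_settings()$current_tol)
})

test_that("electrode and ground currents balance", {
  sol <- get_run("A", 22)
  expect_lt(charge_imbalance(sol), 0.005)
})

test_that("the Picard loop converges for the nonlinear wall model", {
  sol <- solve_at_voltage(linear_mesh(), tissue_properties(), 2000)
  expect_true(sol$converged)
  expect_lt(sol$picard_iters, solver_settings()$picard_max_iter)
  expect_lt(sol$residual, solver_settings()$picard_tol)
})

test_that("delivered current increases strictly with voltage", {
  m <- linear_mesh()
  props <- tissue_properties()
  I <- vapply(c(1500, 2000, 2500),
              function(V) solve_at_voltage(m, props, V)$I_delivered,
              numeric(1))
  expect_true(all(diff(I) > 0))
})

test_that("matched currents honour the requested tolerance", {
  sol <- get_run("A", 22)
  expect_lt(abs(sol$I_delivered - 22) / 22, solver_settings()$current_tol)
  expect_gt(sol$V_applied, 1000)  # order 2 kV
  expect_lt(sol$V_applied, 4000)
})

test_that("an insulating spherical inclusion carries the analytic interior field", {
  ip <- inclusion_problem()
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  f <- field_at_points(ip$sol, abs(0.5 * ip$a * cos(th)),
                       0.5 * ip$a * sin(th))
  expect_rel(mean(f$E_mag), ip$E_in_exact, 0.02)      # 3 sm/(2 sm + sf) E0
  expect_lt(diff(range(f$E_mag)) / ip$E_in_exact, 0.02)  # uniform interior
})
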