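test_that("leisure and work Q-values follow the AFR decomposition", {
  u1 <- leisure_utility("linear", 1)
  expect_equal(q_leisure(0, rho = 3.7, u1, V_pre = 2.5), 2.5)
  expect_equal(q_leisure(4, rho = 0.5, u1, V_pre = 0), 2)
  # linear C_L = rho: utility and AFR cancel for every duration
  expect_equal(q_leisure(c(0, 1, 6), rho = 1, u1, V_pre = 0.3), rep(0.3, 3))
  expect_error(q_leisure(11, 1, u1, tau_max = 10), "tau_max")

  task <- task_spec(10, 5)
  expect_equal(q_work(1, task), 5)
  expect_equal(q_work(10 / 5, task), 0)           # break-even
  expect_equal(q_work(1.2, task_spec(0, 5)), -6)  # zero reward
})

test_that("softmax policy handles the uniform limits and shift invariance", {
  pu <- softmax_policy(function(tau) -tau, beta = 0, tau_max = 10)
  expect_equal(pu$density, rep(0.1, length(pu$tau)))
  pc <- softmax_policy(function(tau) rep(3.2, length(tau)), beta = 5,
                       tau_max = 10)
  expect_equal(pc$density, rep(0.1, length(pc$tau)), tolerance = 1e-12)
  # adding a constant to q leaves the density unchanged
  p1 <- softmax_policy(function(tau) -0.8 * tau + log1p(tau), 1.7, 10)
  p2 <- softmax_policy(function(tau) -0.8 * tau + log1p(tau) + 123.4, 1.7, 10)
  expect_lt(max(abs(p1$density - p2$density)), 1e-12)
  expect_error(softmax_policy(function(tau) tau * NaN, 1, 10), "NaN")
})

test_that("softmax of q = -tau is the truncated exponential", {
  mean_exact <- 1 - 10 / (exp(10) - 1)
  # fine-grid quadrature oracle
  tg <- seq(0, 10, length.out = 1e5 + 1)
  w <- exp(-tg)
  expect_equal(trapz_o(tg, tg * w) / trapz_o(tg, w), mean_exact,
               tolerance = 1e-8)
  p <- softmax_policy(function(tau) -tau, beta = 1, tau_max = 10)
  m <- trapz_o(p$tau, p$tau * p$density)
  expect_equal(m, mean_exact, tolerance = 1e-5)
  d <- leisure_distribution("truncated_exponential", rate = 1,
                            truncation = 10)
  expect_lt(max(abs(p$density - ldist_density(d, p$tau))), 1e-5)
})

test_that("reward rate is cycle utility over cycle time", {
  task <- task_spec(10, 5, tau_max = 10)
  u0 <- leisure_utility("linear", 0)
  expect_equal(reward_rate(point_policy(5, 10), u0, task), 1.0)
  expect_equal(reward_rate(point_policy(0, 10), u0, task), 2.0)
  u1 <- leisure_utility("linear", 1)
  expect_equal(reward_rate(uniform_policy(10), u1, task), 1.5)
  bad <- uniform_policy(10)
  bad$density <- bad$density * 2
  expect_error(reward_rate(bad, u1, task), "normalized")
})

test_that("solved rate agrees with the closed-form fixed point", {
  # linear C_L = 0: policy is truncated exponential with rate beta*rho, so
  # rho solves rho = R_I / (P + m(rho)) with m the closed-form mean
  r <- ref_linear()
  g <- function(rho) r$task$R_I /
    (r$task$P + trunc_exp_mean_o(1 * rho, r$task$tau_max)) - rho
  rho_oracle <- uniroot(g, c(1e-6, 10), tol = 1e-14)$root
  pol <- solve_policy(r$task, r$u,
                      policy_settings(beta = 1, grid_n = 50001))
  expect_lt(abs(pol$rho - rho_oracle), 1e-8)
  expect_true(pol$converged)
})

test_that("damped iteration and bracketing root-finder agree", {
  task <- task_spec(8, 4, tau_max = 30)
  for (u in list(leisure_utility("linear", 0.8),
                 leisure_utility("log1p", 3))) {
    p1 <- solve_policy(task, u, policy_settings(beta = 1.5,
                                                solver = "iterate"))
    p2 <- solve_policy(task, u, policy_settings(beta = 1.5,
                                                solver = "root",
                                                max_iter = 0L))
    expect_lt(abs(p1$rho - p2$rho), 1e-8)
    expect_lt(abs(reward_rate(p1, u, task) - p1$rho), 1e-9)
  }
})

test_that("log-utility policy is the truncated gamma", {
  task <- task_spec(10, 5, tau_max = 20)
  u <- leisure_utility("log", 2)
  pol <- solve_policy(task, u, policy_settings(beta = 1))
  d <- closed_form_distribution(u, 1, pol$rho, 20)
  expect_equal(d$shape, 1 * 2 + 1)
  expect_equal(d$rate, 1 * pol$rho)
  expect_lt(max(abs(pol$density - ldist_density(d, pol$tau))), 1e-6)
})

test_that("linear-utility policy is the truncated exponential", {
  task <- task_spec(4, 6, tau_max = 10)
  u <- leisure_utility("linear", 0.25)
  pol <- solve_policy(task, u, policy_settings(beta = 1))
  d <- closed_form_distribution(u, 1, pol$rho, 10)
  expect_equal(d$rate, pol$rho - 0.25)
  expect_lt(max(abs(pol$density - ldist_density(d, pol$tau))), 1e-6)
})

test_that("deterministic policy finds corners and interior optima", {
  task <- task_spec(10, 5, tau_max = 10)
  # payoff 2 > C_L: all work
  p <- deterministic_policy(task, leisure_utility("linear", 0.2))
  expect_equal(p$atom, 0)
  expect_equal(p$rho, 2)
  expect_equal(time_allocation(p), 1)
  # payoff 2 < C_L: maximal leisure
  p2 <- deterministic_policy(task, leisure_utility("linear", 3))
  expect_equal(p2$atom, 10)
  # concave: interior optimum obeys marginal U_L(tau*) = rho
  u <- leisure_utility("log1p", 5)
  p3 <- deterministic_policy(task, u)
  expect_gt(p3$atom, 0); expect_lt(p3$atom, 10)
  expect_lt(abs(utility_marginal(u, p3$atom) - p3$rho), 1e-6)
  # grid argmax oracle at 1e5 points
  tg <- seq(0, 10, length.out = 1e5 + 1)
  rates <- (task$R_I + utility_value(u, tg)) / (task$P + tg)
  expect_lt(abs(tg[which.max(rates)] - p3$atom), 2e-4)
})

test_that("closed-form distribution parameters and moments are exact", {
  d <- closed_form_distribution(leisure_utility("linear", 0.5), 1, 2, 10)
  expect_equal(d$rate, 1.5)
  d2 <- closed_form_distribution(leisure_utility("log", 3), 2, 1, 10)
  expect_equal(d2$shape, 7); expect_equal(d2$rate, 2)
  expect_error(closed_form_distribution(leisure_utility("log1p", 1), 1, 1, 10),
               class = "timealloc_no_closed_form")
  # analytic moments vs fine quadrature of the density
  tg <- seq(0, 10, length.out = 2e5 + 1)
  for (d in list(d, d2,
                 leisure_distribution("truncated_exponential", rate = -0.4,
                                      truncation = 10))) {
    dens <- ldist_density(d, tg)
    expect_equal(trapz_o(tg, dens), 1, tolerance = 1e-8)
    expect_equal(trapz_o(tg, tg * dens), ldist_mean(d), tolerance = 1e-6)
  }
  expect_equal(ldist_mode(d2), 3)  # (7-1)/2
  expect_equal(
    ldist_mode(leisure_distribution("truncated_exponential", rate = -1,
                                    truncation = 10)), 10)
})

test_that("every solved density is normalized and self-consistent", {
  tasks <- list(task_spec(10, 5, tau_max = 10), task_spec(3, 8, tau_max = 40))
  us <- list(leisure_utility("linear", 0.5), leisure_utility("log1p", 2))
  for (task in tasks) for (u in us) for (beta in c(0, 0.3, 2)) {
    pol <- solve_policy(task, u, policy_settings(beta = beta, grid_n = 801))
    expect_lt(abs(trapz_o(pol$tau, pol$density) - 1), 1e-10)
    expect_true(all(pol$density >= 0))
    expect_gte(pol$mean_leisure, 0)
    expect_lte(pol$mean_leisure, task$tau_max)
    if (beta > 0) expect_lt(abs(reward_rate(pol, u, task) - pol$rho), 1e-9)
  }
})

test_that("solved policy maximizes the entropy-regularized objective", {
  task <- task_spec(6, 4, tau_max = 15)
  u <- leisure_utility("log1p", 2)
  beta <- 1.2
  pol <- solve_policy(task, u, policy_settings(beta = beta, grid_n = 801))
  q <- utility_value(u, pol$tau) - pol$rho * pol$tau
  objective <- function(dens) {
    h <- -trapz_o(pol$tau, ifelse(dens > 0, dens * log(dens), 0))
    trapz_o(pol$tau, dens * q) + h / beta
  }
  obj_star <- objective(pol$density)
  set.seed(42)
  for (i in 1:100) {
    pert <- pol$density * exp(0.3 * stats::rnorm(length(pol$tau)))
    pert <- pert / trapz_o(pol$tau, pert)
    expect_gte(obj_star, objective(pert))
  }
})

test_that("mean leisure falls as the payoff rises", {
  for (u in list(leisure_utility("linear", 1), leisure_utility("log1p", 3))) {
    means <- vapply(c(2, 4, 8, 16, 32), function(R_I) {
      solve_policy(task_spec(R_I, 5, tau_max = 40), u,
                   policy_settings(beta = 1, grid_n = 801))$mean_leisure
    }, numeric(1))
    expect_true(all(diff(means) < 0))
  }
})

test_that("beta limits recover the uniform and deterministic policies", {
  task <- task_spec(10, 5, tau_max = 10)
  u <- leisure_utility("log1p", 5)
  p0 <- solve_policy(task, u, policy_settings(beta = 1e-7, grid_n = 801))
  expect_lt(max(abs(p0$density - 1 / 10)), 1e-5)
  pdet <- deterministic_policy(task, u, grid_n = 801)
  pbig <- solve_policy(task, u, policy_settings(beta = 2000, grid_n = 2001))
  expect_lt(abs(pbig$mean_leisure - pdet$atom), 0.05)
  pinf <- solve_policy(task, u, policy_settings(beta = Inf))
  expect_equal(pinf$atom, pdet$atom, tolerance = 1e-6)
})

test_that("the rate fixed point converges under grid refinement", {
  task <- task_spec(10, 5, tau_max = 10)
  u <- leisure_utility("linear", 0.5)
  rhos <- vapply(c(501, 2001, 8001), function(n) {
    solve_policy(task, u, policy_settings(beta = 1, grid_n = n))$rho
  }, numeric(1))
  # O(h^2) quadrature: errors shrink ~16x per 4x refinement
  expect_lt(abs(rhos[3] - rhos[2]), abs(rhos[2] - rhos[1]))
  expect_lt(abs(rhos[2] - rhos[1]), 5e-5)
})
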