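test_that("constrained policy hits its target mean with a tuned multiplier", {
  u <- leisure_utility("linear", 0.7)
  # constant-Q landscape: lambda = C_L makes the density uniform, mean
  # tau_max/2
  cp <- constrained_policy(u, beta = 1, L_per_cycle = 10, tau_max = 20)
  expect_equal(cp$lambda, 0.7, tolerance = 1e-9)
  expect_lt(abs(cp$residual), 1e-8)
  # mean matches the target across targets and betas
  for (l in c(1, 5, 17)) {
    cp <- constrained_policy(u, 2, l, 20)
    m <- trapz_o(cp$policy$tau, cp$policy$tau * cp$policy$density)
    expect_lt(abs(m - l), 1e-8)
  }
  # larger lambda -> smaller mean (scan oracle)
  lams <- vapply(c(1, 3, 9), function(l)
    constrained_policy(u, 1, l, 20)$lambda, numeric(1))
  expect_true(all(diff(lams) < 0))
  expect_error(constrained_policy(u, 1, 25, 20), "achievable")
  expect_error(constrained_policy(u, 1, 0, 20), "achievable")
})

test_that("deterministic linear derivation is the perfect-substitutes form", {
  task <- task_spec(10, 5, tau_max = 20)
  w <- derive_macro_utility(leisure_utility("linear", 0.5), Inf, task)
  Ks <- c(1, 4, 9); Ls <- c(2, 11, 40)
  expect_equal(outer(Ks, Ls, w$evaluator),
               outer(Ks, Ls, function(K, L) 10 * K + 0.5 * L))
  # concave deterministic derivation is K (R_I + U_L(L/K))
  u <- leisure_utility("log1p", 5)
  w2 <- derive_macro_utility(u, Inf, task)
  expect_equal(w2$evaluator(4, 12), 4 * (10 + 5 * log1p(3)))
})

test_that("derived utility diverges at beta 0 and rejects bad inputs", {
  task <- task_spec(10, 5, tau_max = 20)
  expect_error(derive_macro_utility(leisure_utility("linear", 1), 0, task),
               "diverges")
  w <- derive_macro_utility(leisure_utility("linear", 1), 1, task,
                            grid_n = 401)
  expect_error(w$evaluator(-1, 5), ">= 0")
})

test_that("shadow price equals the reward rate across beta and payoff", {
  for (beta in c(0.5, 2, Inf)) for (R_I in c(4, 8, 16)) {
    task <- task_spec(R_I, 4, tau_max = 30)
    rep <- consistency_check(leisure_utility("linear", 0.8), beta, task,
                             grid_n = 1001)
    expect_lt(rep$delta_lambda_rho, 1e-8)
    expect_lt(rep$delta_TA, 1e-6)
  }
})

test_that("macro optimum reproduces the micro allocation for concave utility", {
  task <- task_spec(10, 5, tau_max = 20)
  u <- leisure_utility("log1p", 5)
  for (beta in c(1.5, Inf)) {
    rep <- consistency_check(u, beta, task, grid_n = 1001)
    expect_lt(rep$delta_TA, 1e-6)
    expect_lt(rep$delta_lambda_rho, 1e-8)
    expect_gt(rep$TA_macro, 0); expect_lt(rep$TA_macro, 1)
  }
})

test_that("deterministic linear macro optimum is all-or-none", {
  task <- task_spec(10, 5, tau_max = 20)  # payoff 2
  bc <- budget_constraint(task$T_trial, task$P)
  work <- macro_optimum(
    derive_macro_utility(leisure_utility("linear", 0.5), Inf, task), bc)
  expect_equal(work$TA, 1)
  leisure <- macro_optimum(
    derive_macro_utility(leisure_utility("linear", 4), Inf, task), bc)
  expect_equal(leisure$L_total / leisure$K, task$tau_max)
  # finite beta, same leisure utility: strictly partial allocation
  partial <- macro_optimum(
    derive_macro_utility(leisure_utility("linear", 0.5), 1, task,
                         grid_n = 1001), bc, report_utility = FALSE)
  expect_gt(partial$TA, 0); expect_lt(partial$TA, 1)
})

test_that("the macro optimum is a true maximum of the evaluator", {
  task <- task_spec(10, 5, tau_max = 20)
  w <- derive_macro_utility(leisure_utility("linear", 0.5), 1, task,
                            grid_n = 1001)
  bc <- budget_constraint(125, 5)
  opt <- macro_optimum(w, bc)
  l_hat <- opt$L_total / opt$K
  val <- function(l) { K <- 125 / (5 + l); w$evaluator(K, K * l) }
  v0 <- val(l_hat)
  expect_equal(v0, opt$utility, tolerance = 1e-8)
  for (d in c(-0.5, -0.05, 0.05, 0.5)) expect_gt(v0, val(l_hat + d))
})

test_that("finite-beta derived utility converges to the affine form", {
  task <- task_spec(10, 5, tau_max = 20)
  u <- leisure_utility("linear", 0.5)
  Ks <- c(5, 10, 20); Ls <- c(10, 30, 60)
  affine <- outer(Ks, Ls, function(K, L) 10 * K + 0.5 * L)
  dev <- vapply(c(10, 100, 1000), function(beta) {
    w <- derive_macro_utility(u, beta, task, grid_n = 801)
    max(abs(outer(Ks, Ls, w$evaluator) - affine))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3] / dev[1], 0.011)  # ~1/beta decay
})

test_that("derived IC slopes are non-constant at finite beta, constant at Inf", {
  task <- task_spec(10, 5, tau_max = 20)
  slope_along_ic <- function(w, lev, ls) {
    # along U(K,L) = K Psi(L/K) = lev: K = lev/Psi(l), L = l K
    pts <- vapply(ls, function(l) {
      K <- lev / w$evaluator(1, l)
      c(L = l * K, K = K)
    }, numeric(2))
    diff(pts["K", ]) / diff(pts["L", ])
  }
  w_inf <- derive_macro_utility(leisure_utility("linear", 0.5), Inf, task)
  s_inf <- slope_along_ic(w_inf, 100, c(1, 5, 12))
  expect_lt(max(abs(s_inf + 0.05)), 1e-9)   # constant -C_L/R_I
  w_fin <- derive_macro_utility(leisure_utility("linear", 0.5), 1, task,
                                grid_n = 801)
  s_fin <- slope_along_ic(w_fin, 100, c(1, 5, 12))
  expect_true(all(s_fin < 0))
  expect_gt(abs(diff(s_fin)), 0.01)
})

test_that("the AFR correction vanishes at beta = Inf and scales with K P + L", {
  task <- task_spec(10, 5, tau_max = 20)
  w_inf <- derive_macro_utility(leisure_utility("linear", 1), Inf, task)
  expect_equal(w_inf$afr_correction(3, 7), 0)
  w <- derive_macro_utility(leisure_utility("linear", 1), 1, task,
                            grid_n = 801)
  f1 <- w$afr_correction(2, 6)
  f2 <- w$afr_correction(4, 12)  # same l = L/K, doubled K P + L
  expect_equal(f2, 2 * f1, tolerance = 1e-9)
})
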