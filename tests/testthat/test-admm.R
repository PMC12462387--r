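# ADMM machinery: relaxation, projection, Lagrangian terms, updates,
# and the full per-region solve.

test_that("relaxation replaces discrete sets by their hulls", {
  sp <- default_space()
  box <- relax_space(sp)
  expect_equal(box$lower[["min_alt_count"]], 1)
  expect_equal(box$upper[["min_alt_count"]], 20)
  expect_equal(box$lower[["min_depth"]], 100)
  expect_equal(box$upper[["min_depth"]], 5000)
  expect_equal(box$lower[["min_vaf"]], 1e-5)  # continuous untouched
  expect_equal(box$upper[["min_vaf"]], 1e-2)
})

test_that("discrete projection is nearest-neighbor with the stated ties", {
  sp <- default_space()
  expect_equal(project_discrete(c(min_alt_count = 3.4), sp)[[1]], 3)
  expect_equal(project_discrete(c(min_alt_count = 3.5), sp)[[1]], 3)
  expect_equal(project_discrete(c(min_alt_count = 3.6), sp)[[1]], 4)
  expect_equal(project_discrete(c(min_depth = 5200), sp)[[1]], 5000)
  expect_equal(project_discrete(c(min_depth = 149), sp)[[1]], 100)
  expect_error(project_discrete(c(min_vaf = 1e-3), sp), "not a discrete")
})

test_that("constraint values and their boundary behave as defined", {
  cs <- constraint_state(0.5, 0.5)
  r <- compute_rates(list(tp = 9, fn = 1, fp = 2, tn = 18))
  cv <- constraint_values(r, cs)
  expect_equal(cv[["c_fp"]], 0.1 - 0.5)
  expect_equal(cv[["c_fn"]], 0.1 - 0.5)
  boundary <- constraint_values(
    compute_rates(list(tp = 1, fn = 1, fp = 10, tn = 10)),
    constraint_state(0.5, 0.5))
  expect_equal(boundary[["c_fp"]], 0)
  expect_error(constraint_values(
    compute_rates(list(tp = 0, fn = 0, fp = 0, tn = 5)), cs), "undefined")
  expect_equal(constraint_state(-2, 3), constraint_state(0.01, 1))
})

test_that("the augmented Lagrangian reduces to f at a consensus point", {
  state <- list(y1 = 0, y2 = 0, z1 = -0.3, z2 = -0.2, d = c(0.5, 0.5),
                rho = 1, rho_d = 2, M = 1e3)
  # duals zero, z_i = c_i <= 0, pd = d: every penalty term vanishes
  expect_equal(augmented_lagrangian(0.42, -0.3, -0.2, c(0.5, 0.5), state),
               0.42)
  # indicator fires when an auxiliary is positive
  state2 <- state; state2$z1 <- 0.2
  expect_gt(augmented_lagrangian(0, 0.2, -0.2, c(0.5, 0.5), state2), 1e3 - 1)
  # hand-computed constraint term: y(c - z) + rho/2 (c - z)^2 = 0.12
  # (M = 0 isolates the multiplier + quadratic pieces from the indicator)
  state3 <- list(y1 = 0.5, y2 = 0, z1 = 0.1, z2 = 0, d = c(0.5, 0.5),
                 rho = 1, rho_d = 2, M = 0)
  expect_equal(
    augmented_lagrangian(0, 0.3, 0, c(0.5, 0.5), state3),
    0.5 * 0.2 + 0.5 * 0.04)
})

test_that("auxiliary updates equal the subproblem minimizer", {
  st <- function(y1, y2, rho) list(y1 = y1, y2 = y2, rho = rho, M = 1e3)
  expect_equal(update_auxiliaries(-0.3, -0.3, st(0, 0, 1))[["z1"]], -0.3)
  expect_equal(update_auxiliaries(0.2, 0, st(0, 0, 1))[["z1"]], 0)
  expect_equal(update_auxiliaries(0.2, 0, st(-0.5, 0, 1))[["z1"]], -0.3)
  # 1-D grid oracle for the z-subproblem (M -> Inf: z restricted to <= 0)
  zgrid <- seq(-2, 0, by = 1e-4)
  obj <- function(z, c, y, rho) y * (c - z) + rho / 2 * (c - z)^2
  for (case in list(c(c = 0.2, y = -0.5, rho = 1),
                    c(c = -0.4, y = 0.3, rho = 2),
                    c(c = 0.1, y = 0.2, rho = 0.5))) {
    oracle <- zgrid[which.min(obj(zgrid, case[["c"]], case[["y"]],
                                  case[["rho"]]))]
    ours <- update_auxiliaries(case[["c"]], 0,
                               st(case[["y"]], 0, case[["rho"]]))[["z1"]]
    expect_lt(abs(ours - oracle), 1e-3)
  }
})

test_that("dual ascent follows r = c - z and leaves converged duals alone", {
  st <- list(y1 = 0, y2 = 0.5, rho = 1)
  du <- update_duals(0.2, -0.1, 0, -0.1, st)
  expect_equal(du$r_fp, 0.2)
  expect_equal(du$y1, 0.2)
  expect_equal(du$r_fn, 0)
  expect_equal(du$y2, 0.5)  # converged constraint: dual unchanged
  st2 <- list(y1 = 0.5, y2 = 0, rho = 2)
  expect_equal(update_duals(-0.2, 0, -0.1, 0, st2)$y1, 0.5 + 2 * (-0.1))
})

test_that("a feasible region converges within a few iterations", {
  task <- standard_fixture()
  res <- admm_solve(task, cs = constraint_state(0.5, 0.5), seed = 3)
  expect_true(res$feasible)
  expect_lte(res$state$iter, 3)
  last <- res$history[nrow(res$history), ]
  expect_lt(max(abs(last$r_fp), abs(last$r_fn), last$r_d), 1e-2)
  # returned config lies in the original mixed space
  expect_silent(validate_config(res$config, default_space()))
  # feasibility double-check straight from the pipeline
  r <- compute_rates(run_pipeline(task$evidence, task$truth, res$config))
  expect_lte(r$fpr, 0.5)
  expect_lte(r$fnr, 0.5)
})

test_that("budget bookkeeping: one iteration leaves one residual row", {
  task <- standard_fixture()
  res <- admm_solve(task, cs = constraint_state(0.5, 0.5),
                    max_iter = 1, bo_evals = 10, seed = 5)
  expect_equal(nrow(res$history), 1)
  expect_equal(res$state$iter, 1)
})

test_that("vacuous thresholds reduce to unconstrained minimization", {
  task <- standard_fixture()
  res <- admm_solve(task, cs = constraint_state(1, 1),
                    max_iter = 3, bo_evals = 25, seed = 17)
  expect_true(res$feasible)
  # oracle arm: plain BO on 1 - F1 over the same relaxed box
  sp <- default_space()
  box <- relax_space(sp)
  lo <- box$lower; hi <- box$upper
  lo[["min_vaf"]] <- log10(lo[["min_vaf"]])
  hi[["min_vaf"]] <- log10(hi[["min_vaf"]])
  fobj <- function(x) {
    x[["min_vaf"]] <- 10^x[["min_vaf"]]
    x[names(sp$discrete)] <- project_discrete(x[names(sp$discrete)], sp)
    r <- compute_rates(run_pipeline(task$evidence, task$truth, x, sp))
    if (is.na(r$f1)) 1 else 1 - r$f1
  }
  ic <- initial_config(sp); ic[["min_vaf"]] <- log10(ic[["min_vaf"]])
  un <- bo_minimize(fobj, lo, hi, n_evals = 75, seed = 17,
                    init_points = rbind(ic))
  expect_lt(abs((1 - res$f1) - un$best_y), 0.1)
})

test_that("an infeasible region is flagged and still returns a config", {
  # variants far below the detection limit: FNR cannot meet tau_fn = 0.05
  task <- suppressWarnings(tier_tasks(vaf = 1e-4, depth = 2000, n_regions = 1,
                                      error = 1e-4, seed = 31)[[1]])
  res <- admm_solve(task, cs = constraint_state(0.5, 0.05),
                    max_iter = 2, bo_evals = 10, seed = 3)
  expect_false(res$feasible)
  expect_silent(validate_config(res$config, default_space()))
})
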