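# Threshold-adaptation agent: action grid, clipping, rewards, TD
# training, and the joint loop over regions.

test_that("the action grid is the 3x3 delta product with a null action", {
  g <- default_action_grid()
  expect_equal(nrow(g), 9)
  expect_equal(ncol(g), 2)
  expect_false(anyDuplicated(g) > 0)
  expect_true(any(g[, 1] == 0 & g[, 2] == 0))
  expect_true(any(g[, 1] == -0.05 & g[, 2] == 0.05))
})

test_that("actions shift and clip thresholds to [0.01, 1]", {
  cs <- constraint_state(0.5, 0.5)
  moved <- apply_action(cs, c(-0.05, 0.05))
  expect_equal(c(moved$tau_fp, moved$tau_fn), c(0.45, 0.55))
  low <- apply_action(constraint_state(0.03, 0.5), c(-0.05, 0))
  expect_equal(low$tau_fp, 0.01)
  null <- apply_action(cs, c(0, 0))
  expect_equal(null, cs)
  # no admissible sequence can escape the box
  set.seed(1)
  g <- default_action_grid()
  s <- constraint_state(0.5, 0.5)
  for (i in 1:200) {
    s <- apply_action(s, g[sample.int(9, 1), ])
    expect_true(s$tau_fp >= 0.01 && s$tau_fp <= 1)
    expect_true(s$tau_fn >= 0.01 && s$tau_fn <= 1)
  }
})

test_that("the reward is the F1 delta minus the infeasibility penalty", {
  expect_equal(reward_f1_delta(0.6, 0.7, TRUE), 0.1)
  expect_equal(reward_f1_delta(0.7, 0.7, FALSE), -0.5)
  expect_equal(reward_f1_delta(0.7, 0.6, TRUE), -0.1, tolerance = 1e-12)
  r1 <- compute_rates(list(tp = 8, fn = 2, fp = 0, tn = 100))
  r2 <- compute_rates(list(tp = 9, fn = 1, fp = 0, tn = 100))
  expect_equal(reward_f1_delta(r1, r2, TRUE), r2$f1 - r1$f1)
})

test_that("action selection is greedy, tie-broken, and uniform at eps = 1", {
  set.seed(1)
  expect_equal(select_action(c(0.1, 0.9, 0.3), 0), 2)
  expect_equal(select_action(c(0.5, 0.5), 0), 1)
  # multinomial oracle: counts within 4 sigma of n/9
  n <- 10000
  counts <- with_seed(99, tabulate(vapply(seq_len(n), function(i)
    select_action(rep(0, 9), 1), 0L), nbins = 9))
  expect_equal(sum(counts), n)
  sigma <- sqrt(n * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - n / 9) < 4 * sigma))
})

test_that("TD targets obey the myopic and terminal limits", {
  net <- q_network(seed = 2)
  tgt <- q_network(seed = 3)
  s <- matrix(c(0.5, 0.5), 1)
  batch <- list(s = s, a = 4L, r = 1.5, s2 = s, terminal = FALSE)
  # gamma = 0: target is exactly r; after enough steps Q(s, a) -> r
  for (i in 1:600) {
    ts <- train_step(batch, net, tgt, gamma = 0, lr = 5e-3)
    net <- ts$net
  }
  expect_lt(ts$loss, 1e-3)
  expect_lt(abs(q_forward(net, s)[1, 4] - 1.5), 0.1)
  # terminal transitions ignore s' even with gamma > 0
  net2 <- q_network(seed = 2)
  t1 <- train_step(list(s = s, a = 1L, r = 2, s2 = s * 0, terminal = TRUE),
                   net2, tgt, gamma = 0.9, lr = 1e-3)
  t2 <- train_step(list(s = s, a = 1L, r = 2, s2 = s * 10, terminal = TRUE),
                   net2, tgt, gamma = 0.9, lr = 1e-3)
  expect_equal(t1$loss, t2$loss)
})

test_that("one step per region leaves one transition per region", {
  tasks <- two_regime_tasks()
  res <- run_agent(tasks, total_steps = 2,
                   agent_cfg = agent_config(seed = 5, batch_size = 32),
                   admm_args = list(max_iter = 1, bo_evals = 8))
  expect_equal(res$buffer_size, 2)
  expect_equal(nrow(res$log), 2)
  expect_equal(sort(unique(res$log$region)), c("region_hi", "region_lo"))
  # every region starts at the initial thresholds
  expect_true(all(vapply(res$trajectories, function(t)
    all(t[1, ] == c(0.5, 0.5)), NA)))
})

test_that("regions in different noise regimes end at different thresholds", {
  # oracle reasoning: in the high-noise region FNR cannot reach 0.5, so
  # feasibility (and reward) pushes tau_fn upward; the low-noise region
  # is feasible at 0.5 and has nothing to gain from moving far
  tasks <- two_regime_tasks()
  res <- run_agent(tasks, total_steps = 16,
                   agent_cfg = agent_config(seed = 5,
                                            epsilon_decay_steps = 10),
                   admm_args = list(max_iter = 2, bo_evals = 10))
  final_lo <- tail(res$trajectories[[1]], 1)
  final_hi <- tail(res$trajectories[[2]], 1)
  expect_gt(max(abs(final_lo - final_hi)), 0.05)
  expect_false(res$best[[1]]$f1 == 0)
})

test_that("threshold adaptation never loses to fixed thresholds", {
  # paired-seed comparison: the agent's first round per region probes the
  # initial (0.5, 0.5) thresholds with the same ADMM seed as the fixed
  # arm, so its best-seen config can only improve from there
  tasks <- two_regime_tasks(seed = 19)
  cfg <- agent_config(seed = 23)
  res <- run_agent(tasks, total_steps = 8, agent_cfg = cfg,
                   admm_args = list(max_iter = 2, bo_evals = 10))
  fixed <- vapply(seq_along(tasks), function(i) {
    s <- split_seed(cfg$seed, paste0(tasks[[i]]$region$region_id, "#", i))
    r <- admm_solve(tasks[[i]], cs = constraint_state(0.5, 0.5),
                    max_iter = 2, bo_evals = 10, seed = s)
    if (is.infinite(r$f1)) 0 else r$f1
  }, 0)
  agent <- vapply(res$best, `[[`, 0, "f1")
  expect_gte(mean(agent), mean(fixed))
})
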