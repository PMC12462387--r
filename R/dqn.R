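# Q-learning agent that adapts the FPR/FNR constraint thresholds between
# ADMM rounds. The state is the threshold pair, actions are threshold
# deltas, and the Q function is a small two-hidden-layer MLP trained by
# one-step TD with experience replay and a periodically synced target
# network (standard DQN ingredients, sized for a 2-D state).

#' Default action grid: threshold deltas
#'
#' Cartesian product \{-0.05, 0, +0.05\}^2 over (delta tau_fp,
#' delta tau_fn): 9 actions including the null action.
#'
#' @return matrix with columns d_fp, d_fn, one action per row.
#' @export
default_action_grid <- function() {
  g <- as.matrix(expand.grid(d_fp = c(-0.05, 0, 0.05),
                             d_fn = c(-0.05, 0, 0.05)))
  rownames(g) <- NULL
  g
}

#' Apply a threshold-delta action to a constraint state
#'
#' Componentwise addition, then clipping to [0.01, 1].
#'
#' @param cs a \code{\link{constraint_state}}.
#' @param action numeric length-2 (d_fp, d_fn).
#' @return new \code{constraint_state}.
#' @export
apply_action <- function(cs, action) {
  constraint_state(cs$tau_fp + action[[1]], cs$tau_fn + action[[2]])
}

#' Reward for a threshold adjustment
#'
#' \code{r = (f1_new - f1_prev) - 0.5 * I(infeasible)}. The F1 delta
#' rewards net detection improvement; the penalty discourages threshold
#' settings the ADMM round could not satisfy. Swappable: pass any
#' function with this signature to \code{\link{run_agent}}.
#'
#' @param prev_rates previous \code{rate_set} (or numeric F1).
#' @param new_rates new \code{rate_set} (or numeric F1).
#' @param new_feasible logical: did the new round satisfy both constraints.
#' @return scalar reward.
#' @export
reward_f1_delta <- function(prev_rates, new_rates, new_feasible) {
  f1_of <- function(r) {
    v <- if (inherits(r, "rate_set")) r$f1 else as.numeric(r)
    if (is.na(v)) 0 else v
  }
  (f1_of(new_rates) - f1_of(prev_rates)) - 0.5 * as.numeric(!new_feasible)
}

#' Agent hyperparameters
#'
#' @param epsilon_start,epsilon_end,epsilon_decay_steps linear
#'   exploration schedule over global steps.
#' @param gamma discount factor in [0, 1).
#' @param lr Adam learning rate for the Q network.
#' @param replay_capacity transition buffer size.
#' @param batch_size minibatch size per training step.
#' @param target_sync target-network sync period (training steps).
#' @param hidden hidden layer sizes.
#' @param seed agent seed.
#' @return list of class \code{agent_config}.
#' @export
agent_config <- function(epsilon_start = 1.0, epsilon_end = 0.05,
                         epsilon_decay_steps = 200L, gamma = 0.9,
                         lr = 5e-3, replay_capacity = 1000L,
                         batch_size = 32L, target_sync = 50L,
                         hidden = c(32L, 32L), seed = 1L) {
  stopifnot(gamma >= 0, gamma < 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= 1)
  cfg <- list(epsilon_start = epsilon_start, epsilon_end = epsilon_end,
              epsilon_decay_steps = as.integer(epsilon_decay_steps),
              gamma = gamma, lr = lr,
              replay_capacity = as.integer(replay_capacity),
              batch_size = as.integer(batch_size),
              target_sync = as.integer(target_sync),
              hidden = as.integer(hidden), seed = as.integer(seed))
  class(cfg) <- "agent_config"
  cfg
}

epsilon_at <- function(cfg, step) {
  frac <- min(1, max(0, step / cfg$epsilon_decay_steps))
  cfg$epsilon_start + frac * (cfg$epsilon_end - cfg$epsilon_start)
}

# ---- tiny MLP with Adam ---------------------------------------------------

#' Initialize a Q network
#'
#' @param n_in input dimension (2: the threshold pair).
#' @param n_out output dimension (number of actions).
#' @param hidden hidden layer sizes (two layers).
#' @param seed seed for He-scaled initialization.
#' @return list of weights plus Adam state, class \code{q_network}.
#' @export
q_network <- function(n_in = 2L, n_out = 9L, hidden = c(32L, 32L), seed = 1L) {
  dims <- c(n_in, hidden, n_out)
  with_seed(seed, {
    net <- list(dims = dims, W = list(), b = list(), t = 0L)
    for (i in seq_len(length(dims) - 1L)) {
      net$W[[i]] <- matrix(stats::rnorm(dims[i] * dims[i + 1],
                                        sd = sqrt(2 / dims[i])),
                           nrow = dims[i])
      net$b[[i]] <- rep(0, dims[i + 1])
    }
    net$mW <- lapply(net$W, function(w) w * 0)
    net$vW <- lapply(net$W, function(w) w * 0)
    net$mb <- lapply(net$b, function(b) b * 0)
    net$vb <- lapply(net$b, function(b) b * 0)
    class(net) <- "q_network"
    net
  })
}

relu <- function(x) pmax(x, 0)

#' Q values for a batch of states
#'
#' @param net a \code{q_network}.
#' @param states matrix (n x 2) or length-2 vector.
#' @return matrix n x n_actions of Q values.
#' @export
q_forward <- function(net, states) {
  S <- if (is.matrix(states)) states else matrix(states, nrow = 1)
  h <- S
  L <- length(net$W)
  for (i in seq_len(L - 1L)) {
    h <- relu(sweep(h %*% net$W[[i]], 2, net$b[[i]], "+"))
  }
  sweep(h %*% net$W[[L]], 2, net$b[[L]], "+")
}

# forward keeping activations for backprop
q_forward_full <- function(net, S) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- S
  for (i in seq_len(L - 1L)) {
    acts[[i + 1]] <- relu(sweep(acts[[i]] %*% net$W[[i]], 2, net$b[[i]], "+"))
  }
  acts[[L + 1]] <- sweep(acts[[L]] %*% net$W[[L]], 2, net$b[[L]], "+")
  acts
}

adam_update <- function(net, gW, gb, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  net$t <- net$t + 1L
  corr1 <- 1 - b1^net$t
  corr2 <- 1 - b2^net$t
  for (i in seq_along(net$W)) {
    net$mW[[i]] <- b1 * net$mW[[i]] + (1 - b1) * gW[[i]]
    net$vW[[i]] <- b2 * net$vW[[i]] + (1 - b2) * gW[[i]]^2
    net$W[[i]] <- net$W[[i]] - lr * (net$mW[[i]] / corr1) /
      (sqrt(net$vW[[i]] / corr2) + eps)
    net$mb[[i]] <- b1 * net$mb[[i]] + (1 - b1) * gb[[i]]
    net$vb[[i]] <- b2 * net$vb[[i]] + (1 - b2) * gb[[i]]^2
    net$b[[i]] <- net$b[[i]] - lr * (net$mb[[i]] / corr1) /
      (sqrt(net$vb[[i]] / corr2) + eps)
  }
  net
}

#' One TD training step on a replay minibatch
#'
#' Targets are \code{r + gamma * max_a Q_target(s', a)} (just \code{r} on
#' terminal transitions); one Adam step on the mean squared TD error.
#'
#' @param batch list with matrices/vectors s (n x 2), a (action index),
#'   r, s2 (n x 2), terminal (logical).
#' @param net online \code{q_network}.
#' @param target_net target \code{q_network}.
#' @param gamma discount factor.
#' @param lr learning rate.
#' @return list(net, loss).
#' @export
train_step <- function(batch, net, target_net, gamma, lr) {
  n <- length(batch$a)
  stopifnot(n >= 1L)
  q_next <- q_forward(target_net, batch$s2)
  target <- batch$r + gamma * apply(q_next, 1, max) * !batch$terminal
  acts <- q_forward_full(net, batch$s)
  L <- length(net$W)
  Q <- acts[[L + 1]]
  idx <- cbind(seq_len(n), batch$a)
  err <- Q[idx] - target
  loss <- mean(err^2)
  if (!is.finite(loss)) stop("non-finite TD loss; check rewards and Q values")
  dQ <- matrix(0, nrow = n, ncol = ncol(Q))
  dQ[idx] <- 2 * err / n
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dQ
  for (i in L:1) {
    gW[[i]] <- crossprod(acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% t(net$W[[i]])) * (acts[[i]] > 0)
    }
  }
  list(net = adam_update(net, gW, gb, lr), loss = loss)
}

#' Epsilon-greedy action selection
#'
#' With probability 1 - epsilon the greedy action (first occurrence wins
#' ties), otherwise uniform over the grid. Uses the current RNG stream.
#'
#' @param q_values numeric vector of Q values over the action grid.
#' @param epsilon exploration probability.
#' @return action index.
#' @export
select_action <- function(q_values, epsilon) {
  if (stats::runif(1) < epsilon) {
    sample.int(length(q_values), 1L)
  } else {
    which.max(q_values)  # first-occurrence tie-break
  }
}

# ring-buffer replay memory
replay_buffer <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$data <- vector("list", capacity)
  env$n <- 0L
  env$ptr <- 0L
  env$capacity <- capacity
  env
}

replay_push <- function(buf, transition) {
  buf$ptr <- (buf$ptr %% buf$capacity) + 1L
  buf$data[[buf$ptr]] <- transition
  buf$n <- min(buf$n + 1L, buf$capacity)
  invisible(buf)
}

replay_sample <- function(buf, k) {
  idx <- sample.int(buf$n, k, replace = buf$n < k)
  tr <- buf$data[idx]
  list(
    s = do.call(rbind, lapply(tr, `[[`, "s")),
    a = vapply(tr, `[[`, 0L, "a"),
    r = vapply(tr, `[[`, 0, "r"),
    s2 = do.call(rbind, lapply(tr, `[[`, "s2")),
    terminal = vapply(tr, `[[`, FALSE, "terminal")
  )
}

#' Joint ADMM + Q-learning optimization over a cohort of regions
#'
#' Steps are distributed round-robin over regions; every region starts at
#' thresholds (0.5, 0.5). Each step: the agent picks a threshold-delta
#' action for the region (epsilon-greedy; the first visit deliberately
#' plays the null action so the initial thresholds are probed), applies
#' it, runs ADMM under the new thresholds, computes the reward from the
#' observed F1 change and feasibility, stores the transition and takes
#' one TD training step. One shared agent serves all regions (the state
#' carries no region identity); \code{per_region_agent = TRUE} trains one
#' network per region instead. Episodes end with the step budget: the
#' problem has no natural terminal state.
#'
#' @param tasks list of region tasks (see \code{\link{simulate_cohort}}).
#' @param space parameter space.
#' @param total_steps total ADMM rounds across all regions (>= number of
#'   regions so each region is optimized at least once).
#' @param agent_cfg an \code{\link{agent_config}}.
#' @param cs_init initial constraint thresholds (both 0.5).
#' @param reward_fn reward function, see \code{\link{reward_f1_delta}}.
#' @param per_region_agent train one Q network per region.
#' @param admm_args list of arguments passed on to \code{\link{admm_solve}}
#'   (max_iter, bo_evals, rho, tol, ...).
#' @return list with per-region \code{best} (config, f1, rates, feasible),
#'   per-region threshold \code{trajectories}, the trained \code{net},
#'   the transition \code{log}, and bookkeeping counters.
#' @export
run_agent <- function(tasks, space = default_space(), total_steps = 200L,
                      agent_cfg = agent_config(), cs_init = constraint_state(),
                      reward_fn = reward_f1_delta, per_region_agent = FALSE,
                      admm_args = list()) {
  stopifnot(total_steps >= 1L, length(tasks) >= 1L)
  R <- length(tasks)
  n_actions <- nrow(default_action_grid())
  grid <- default_action_grid()

  make_net <- function(k) q_network(2L, n_actions, agent_cfg$hidden,
                                    seed = split_seed(agent_cfg$seed,
                                                      paste0("qnet", k)))
  nets <- if (per_region_agent) lapply(seq_len(R), make_net) else list(make_net(0L))
  targets <- nets
  buf <- replay_buffer(agent_cfg$replay_capacity)

  null_idx <- which(grid[, 1] == 0 & grid[, 2] == 0)

  rg <- lapply(tasks, function(t) list(
    cs = cs_init, prev_rates = NULL, best = NULL, visits = 0L,
    traj = list(c(cs_init$tau_fp, cs_init$tau_fn))
  ))
  log <- NULL
  train_calls <- 0L

  for (step in seq_len(total_steps)) {
    ri <- ((step - 1L) %% R) + 1L
    ni <- if (per_region_agent) ri else 1L
    task <- tasks[[ri]]
    st <- rg[[ri]]
    region_id <- task$region$region_id %||% as.character(ri)

    if (is.null(st$best)) {
      # baseline: the shared initial configuration under no optimization
      cfg0 <- initial_config(space)
      out0 <- run_pipeline(task$evidence, task$truth, cfg0, space)
      r0 <- compute_rates(out0)
      tb <- admm_args$tie_break %||% 1e-3
      st$prev_rates <- r0
      st$best <- list(config = cfg0,
                      f1 = if (is.na(r0$f1)) 0 else r0$f1,
                      obj = (if (is.na(r0$f1)) 1 else 1 - r0$f1) +
                        tb * config_strictness(cfg0, space),
                      rates = r0,
                      feasible = all(constraint_values(r0, st$cs) <= 0),
                      cs = st$cs)
    }

    s_now <- c(st$cs$tau_fp, st$cs$tau_fn)
    eps <- epsilon_at(agent_cfg, step)
    qv <- q_forward(nets[[ni]], s_now)[1, ]
    a <- if (st$visits == 0L) {
      null_idx  # probe the initial thresholds before moving
    } else {
      with_seed(split_seed(agent_cfg$seed, paste0("act", step)),
                select_action(qv, eps))
    }
    cs2 <- apply_action(st$cs, grid[a, ])
    s2 <- c(cs2$tau_fp, cs2$tau_fn)

    solve_seed <- split_seed(agent_cfg$seed, paste0(region_id, "#", step))
    res <- do.call(admm_solve, c(list(task = task, space = space, cs = cs2,
                                      seed = solve_seed,
                                      init_config = st$best$config),
                                 admm_args))
    f1 <- if (is.infinite(res$f1)) 0 else res$f1

    r <- reward_fn(st$prev_rates, res$rates, res$feasible)
    replay_push(buf, list(s = s_now, a = a, r = r, s2 = s2, terminal = FALSE))
    td_loss <- NA_real_
    if (buf$n >= agent_cfg$batch_size) {
      batch <- with_seed(split_seed(agent_cfg$seed, paste0("batch", step)),
                         replay_sample(buf, agent_cfg$batch_size))
      ts <- train_step(batch, nets[[ni]], targets[[ni]],
                       agent_cfg$gamma, agent_cfg$lr)
      nets[[ni]] <- ts$net
      train_calls <- train_calls + 1L
      if (train_calls %% agent_cfg$target_sync == 0L) targets <- nets
      td_loss <- ts$loss
    }

    if ((res$feasible && !st$best$feasible) ||
        (res$feasible == st$best$feasible && res$objective < st$best$obj)) {
      st$best <- list(config = res$config, f1 = f1, obj = res$objective,
                      rates = res$rates, feasible = res$feasible, cs = cs2)
    }
    st$prev_rates <- res$rates
    st$cs <- cs2
    st$visits <- st$visits + 1L
    st$history <- res$history
    st$traj[[length(st$traj) + 1L]] <- s2
    rg[[ri]] <- st

    log <- rbind(log, data.frame(
      step = step, region = region_id, tau_fp = s2[1], tau_fn = s2[2],
      f1 = f1, feasible = res$feasible, reward = r, td_loss = td_loss,
      epsilon = eps, admm_iters = res$state$iter, n_evals = res$n_evals,
      stringsAsFactors = FALSE
    ))
  }

  list(
    best = lapply(rg, `[[`, "best"),
    trajectories = lapply(rg, function(s) do.call(rbind, s$traj)),
    histories = lapply(rg, `[[`, "history"),
    net = if (per_region_agent) nets else nets[[1]],
    log = log,
    buffer_size = buf$n,
    train_calls = train_calls
  )
}
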