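# ADMM decoupling of the gradient-free detection objective from the
# black-box FPR/FNR constraints.
#
# Coupling a scalar auxiliary z_i directly to the parameter vector would
# be dimensionally inconsistent; consensus is therefore taken in
# *constraint space*:
#   L = f + (rho_d/2)||pd~ - d||^2
#       + sum_i [ M 1(z_i > 0) + y_i (c_i - z_i) + (rho/2)(c_i - z_i)^2 ]
# with z_i the auxiliary copy of constraint value c_i (z1 = c_FP, z2 =
# c_FN at the solution). The z-subproblem is solved in closed form in the
# M -> Inf limit (hard projection onto z <= 0); the finite-M minimizer is
# available behind `finite_m`. Discrete parameters are relaxed to their
# convex hulls; the d block is their projected copy, the consensus
# penalty and residual for that block are measured in unit-box-normalized
# coordinates so one step of any discrete grid has comparable size.

#' Constraint threshold state
#'
#' The FPR/FNR threshold pair managed by the learning agent. Values are
#' clipped to [0.01, 1]: a zero threshold would make every region
#' infeasible by definition at finite depth.
#'
#' @param tau_fp FPR threshold.
#' @param tau_fn FNR threshold.
#' @return object of class \code{constraint_state}.
#' @export
constraint_state <- function(tau_fp = 0.5, tau_fn = 0.5) {
  cs <- list(tau_fp = min(max(tau_fp, 0.01), 1),
             tau_fn = min(max(tau_fn, 0.01), 1))
  class(cs) <- "constraint_state"
  cs
}

#' @export
print.constraint_state <- function(x, ...) {
  cat(sprintf("constraint thresholds: tau_fp=%.3f tau_fn=%.3f\n",
              x$tau_fp, x$tau_fn))
  invisible(x)
}

#' Relax every discrete parameter set to its convex hull
#'
#' @param space a \code{param_space}.
#' @return list(lower, upper): named bound vectors over all parameters
#'   (continuous bounds unchanged, discrete sets replaced by
#'   [min, max]); singleton sets yield width-0 (fixed) dimensions.
#' @export
relax_space <- function(space) {
  nms <- param_names(space)
  lower <- c(space$continuous$lower,
             vapply(space$discrete, function(d) min(d$set), 0))
  upper <- c(space$continuous$upper,
             vapply(space$discrete, function(d) max(d$set), 0))
  names(lower) <- names(upper) <- nms
  list(lower = lower, upper = upper)
}

#' Project relaxed discrete values back onto their integer sets
#'
#' Nearest member; exact midpoints map to the smaller member;
#' out-of-hull values clamp to the nearest endpoint.
#'
#' @param pd_relaxed named numeric vector of relaxed discrete values.
#' @param space a \code{param_space}.
#' @return named numeric vector of discrete members.
#' @export
project_discrete <- function(pd_relaxed, space) {
  out <- pd_relaxed
  for (nm in names(pd_relaxed)) {
    set <- space$discrete[[nm]]$set
    if (is.null(set)) stop("not a discrete parameter: ", nm)
    dist <- abs(set - pd_relaxed[[nm]])
    # ties toward the smaller member: strict < keeps the first (smaller)
    out[[nm]] <- set[which.min(dist)]
  }
  out
}

#' Constraint values from a detection outcome
#'
#' \code{c_fp = fpr - tau_fp}, \code{c_fn = fnr - tau_fn}; values <= 0
#' are feasible.
#'
#' @param outcome a \code{detection_outcome} or \code{rate_set}.
#' @param cs a \code{constraint_state}.
#' @return named numeric c(c_fp, c_fn).
#' @export
constraint_values <- function(outcome, cs) {
  rates <- if (inherits(outcome, "rate_set")) outcome else compute_rates(outcome)
  if (is.na(rates$fpr) || is.na(rates$fnr)) {
    stop("undefined FPR or FNR: constraint values unavailable")
  }
  c(c_fp = rates$fpr - cs$tau_fp, c_fn = rates$fnr - cs$tau_fn)
}

#' Augmented Lagrangian of the constrained detection problem
#'
#' @param f_value objective value (detection error, 1 - F1).
#' @param c_fp,c_fn constraint values at the evaluated point.
#' @param pd_relaxed relaxed discrete block (normalized coordinates).
#' @param state ADMM state list with y1, y2, z1, z2, d (normalized), rho,
#'   rho_d, M.
#' @return scalar Lagrangian value.
#' @export
augmented_lagrangian <- function(f_value, c_fp, c_fn, pd_relaxed, state) {
  cons <- c(c_fp, c_fn)
  z <- c(state$z1, state$z2)
  y <- c(state$y1, state$y2)
  pen <- sum(state$M * (z > 0) + y * (cons - z) + state$rho / 2 * (cons - z)^2)
  f_value + state$rho_d / 2 * sum((pd_relaxed - state$d)^2) + pen
}

#' Closed-form update of the feasibility auxiliaries
#'
#' In the hard-constraint limit (M -> Inf) the z-subproblem minimizer is
#' \code{z_i = min(0, c_i + y_i / rho)}. With \code{finite_m = TRUE} the
#' exact finite-M minimizer is used (the unconstrained stationary point
#' is accepted when paying M beats the projection).
#'
#' @param c_fp,c_fn constraint values.
#' @param state ADMM state.
#' @param finite_m use the finite-M branch comparison.
#' @return named numeric c(z1, z2).
#' @export
update_auxiliaries <- function(c_fp, c_fn, state, finite_m = FALSE) {
  cons <- c(c_fp, c_fn)
  y <- c(state$y1, state$y2)
  zhat <- cons + y / state$rho
  z <- pmin(0, zhat)
  if (finite_m) {
    for (i in 1:2) {
      if (zhat[i] > 0) {
        val_proj <- y[i] * (cons[i] - 0) + state$rho / 2 * cons[i]^2
        val_free <- state$M + y[i] * (cons[i] - zhat[i]) +
          state$rho / 2 * (cons[i] - zhat[i])^2
        if (val_free < val_proj) z[i] <- zhat[i]
      }
    }
  }
  stats::setNames(z, c("z1", "z2"))
}

#' Dual ascent step and primal residuals
#'
#' \code{r_i = c_i - z_i}; \code{y_i <- y_i + rho r_i}.
#'
#' @param c_fp,c_fn constraint values.
#' @param z1,z2 auxiliaries.
#' @param state ADMM state.
#' @return list(y1, y2, r_fp, r_fn).
#' @export
update_duals <- function(c_fp, c_fn, z1, z2, state) {
  r_fp <- c_fp - z1
  r_fn <- c_fn - z2
  list(y1 = state$y1 + state$rho * r_fp,
       y2 = state$y2 + state$rho * r_fn,
       r_fp = r_fp, r_fn = r_fn)
}

# midpoint / median initial configuration (identical across regions)
#' Documented initial parameter configuration
#'
#' Midpoint of each continuous range (geometric midpoint for log-scaled
#' parameters); lower median of each discrete set.
#'
#' @param space a \code{param_space}.
#' @return named numeric config.
#' @export
initial_config <- function(space) {
  cc <- space$continuous
  islog <- if ("log" %in% names(cc)) cc$log else rep(FALSE, nrow(cc))
  cont <- ifelse(islog,
                 10^((log10(cc$lower) + log10(cc$upper)) / 2),
                 (cc$lower + cc$upper) / 2)
  names(cont) <- cc$name
  disc <- vapply(space$discrete, function(d) {
    s <- d$set
    s[ceiling(length(s) / 2)]
  }, 0)
  c(cont, disc)
}

# transform helpers: BO searches log-scaled continuous dims in log10 space
space_transform <- function(space) {
  cc <- space$continuous
  islog <- if ("log" %in% names(cc)) cc$log else rep(FALSE, nrow(cc))
  cc$name[islog]
}

to_search_scale <- function(x, log_dims) {
  x[log_dims] <- log10(x[log_dims])
  x
}

from_search_scale <- function(x, log_dims) {
  x[log_dims] <- 10^x[log_dims]
  x
}

# mean normalized strictness of a configuration (search scale): every
# parameter in the reference space is a "higher = stricter" threshold
config_strictness <- function(config, space) {
  box <- relax_space(space)
  log_dims <- space_transform(space)
  lo <- to_search_scale(box$lower, log_dims)
  hi <- pmax(to_search_scale(box$upper, log_dims), lo + 1e-12)
  x <- to_search_scale(config[names(lo)], log_dims)
  mean((x - lo) / (hi - lo))
}

#' Solve one region's constrained parameter optimization by ADMM
#'
#' Per iteration: (a) Bayesian optimization minimizes the augmented
#' Lagrangian over the relaxed box, warm-started from the previous
#' incumbent and its discrete-projected twin; (b) the d block is the
#' projection of the relaxed discrete block; (c) auxiliaries update in
#' closed form; (d) dual ascent. Stops when
#' \code{max(|r_fp|, |r_fn|, ||pd~ - d||_inf)} (d gap in normalized
#' coordinates) falls below \code{tol}, or the iteration budget is
#' exhausted. The returned configuration is always projected into the
#' original mixed space.
#'
#' @param task region task (list with \code{evidence}, \code{truth}).
#' @param space parameter space.
#' @param cs \code{constraint_state} thresholds.
#' @param max_iter maximum ADMM iterations.
#' @param bo_evals objective evaluations per BO subproblem.
#' @param rho penalty parameter (> 0) for the constraint blocks.
#' @param rho_d consensus penalty for the discrete block (normalized
#'   coordinates; large enough that one grid step costs more than typical
#'   objective differences).
#' @param M large penalty constant for the infeasible-auxiliary indicator.
#' @param tol residual tolerance.
#' @param seed integer seed.
#' @param init_config starting configuration (defaults to
#'   \code{\link{initial_config}}).
#' @param finite_m use the finite-M auxiliary update.
#' @param tie_break weight of the restrictiveness tie-breaker added to
#'   the detection error: among configurations with equal F1 the least
#'   restrictive thresholds win. Kept far below the smallest possible F1
#'   step so it never trades detection for permissiveness; it
#'   canonicalizes flat optima, which stabilizes the meta-model's
#'   training targets.
#' @return object of class \code{admm_result}: list(config, f1, rates,
#'   outcome, feasible, state, history, n_evals).
#' @export
admm_solve <- function(task, space = default_space(), cs = constraint_state(),
                       max_iter = 10L, bo_evals = 30L, rho = 1.0,
                       rho_d = 2, M = 1e3, tol = 1e-2, seed = 1L,
                       init_config = NULL, finite_m = FALSE,
                       tie_break = 1e-3) {
  stopifnot(max_iter >= 1L)
  box <- relax_space(space)
  nms <- param_names(space)
  disc_nms <- names(space$discrete)
  disc_width <- pmax(box$upper[disc_nms] - box$lower[disc_nms], 1e-12)
  norm_d <- function(v) (v - box$lower[disc_nms]) / disc_width
  log_dims <- space_transform(space)
  box_t <- list(lower = to_search_scale(box$lower, log_dims),
                upper = to_search_scale(box$upper, log_dims))

  x_prev <- init_config %||% initial_config(space)
  x_prev <- x_prev[nms]

  eval_count <- 0L
  pipeline_at <- function(config) {
    eval_count <<- eval_count + 1L
    outcome <- run_pipeline(task$evidence, task$truth, config, space)
    rates <- compute_rates(outcome)
    f <- if (is.na(rates$f1)) 1 else 1 - rates$f1
    f <- f + tie_break * config_strictness(config, space)
    list(outcome = outcome, rates = rates, f = f)
  }

  # initialize state at the projected starting configuration
  cfg0 <- x_prev
  cfg0[disc_nms] <- project_discrete(cfg0[disc_nms], space)
  ev0 <- pipeline_at(cfg0)
  c0 <- constraint_values(ev0$rates, cs)
  state <- list(
    y1 = 0, y2 = 0,
    z1 = min(0, c0[["c_fp"]]), z2 = min(0, c0[["c_fn"]]),
    d = norm_d(cfg0[disc_nms]),
    rho = rho, rho_d = rho_d, M = M,
    residual_history = data.frame(), iter = 0L
  )

  best <- list(config = cfg0, f1 = if (is.na(ev0$rates$f1)) -Inf else ev0$rates$f1,
               obj = ev0$f, rates = ev0$rates, outcome = ev0$outcome,
               feasible = all(c0 <= 0))
  history <- NULL

  for (t in seq_len(max_iter)) {
    lag_obj <- function(x) {
      xn <- from_search_scale(x, log_dims)
      ev <- pipeline_at(xn)
      cv <- constraint_values(ev$rates, cs)
      augmented_lagrangian(ev$f, cv[["c_fp"]], cv[["c_fn"]],
                           norm_d(xn[disc_nms]), state)
    }
    warm <- rbind(to_search_scale(x_prev, log_dims),
                  to_search_scale(replace(x_prev, disc_nms,
                                          box$lower[disc_nms] +
                                            state$d * disc_width),
                                  log_dims))
    bo <- bo_minimize(lag_obj, box_t$lower, box_t$upper, n_evals = bo_evals,
                      seed = split_seed(seed, paste0("bo-iter-", t)),
                      init_points = warm)
    x_star <- from_search_scale(bo$best_x[nms], log_dims)
    pd_rel <- x_star[disc_nms]
    pd_proj <- project_discrete(pd_rel, space)
    r_d <- if (length(disc_nms)) max(abs(norm_d(pd_rel) - norm_d(pd_proj))) else 0
    state$d <- norm_d(pd_proj)

    cfg_t <- x_star
    cfg_t[disc_nms] <- pd_proj
    ev_t <- pipeline_at(cfg_t)
    c_t <- constraint_values(ev_t$rates, cs)
    feas_t <- all(c_t <= 0)

    z <- update_auxiliaries(c_t[["c_fp"]], c_t[["c_fn"]], state,
                            finite_m = finite_m)
    state$z1 <- z[["z1"]]; state$z2 <- z[["z2"]]
    du <- update_duals(c_t[["c_fp"]], c_t[["c_fn"]], state$z1, state$z2, state)
    state$y1 <- du$y1; state$y2 <- du$y2
    state$iter <- t

    f1_t <- if (is.na(ev_t$rates$f1)) -Inf else ev_t$rates$f1
    history <- rbind(history, data.frame(
      iter = t, r_fp = du$r_fp, r_fn = du$r_fn, r_d = r_d,
      f1 = ev_t$rates$f1, fpr = ev_t$rates$fpr, fnr = ev_t$rates$fnr,
      feasible = feas_t
    ))

    better <- (feas_t && !best$feasible) ||
      (feas_t == best$feasible && ev_t$f < best$obj)
    if (better) {
      best <- list(config = cfg_t, f1 = f1_t, obj = ev_t$f,
                   rates = ev_t$rates, outcome = ev_t$outcome,
                   feasible = feas_t)
    }
    x_prev <- x_star

    if (max(abs(du$r_fp), abs(du$r_fn), r_d) < tol) break
  }
  state$residual_history <- history
  res <- list(config = best$config, f1 = best$f1, objective = best$obj,
              rates = best$rates, outcome = best$outcome,
              feasible = best$feasible, state = state, history = history,
              n_evals = eval_count)
  class(res) <- "admm_result"
  res
}

#' Canonicalize a configuration to the center of its flat optimum
#'
#' Detection landscapes are piecewise flat: a whole interval of each
#' threshold often gives identical F1 on a region, and which point an
#' optimizer returns is arbitrary. Arbitrary points transfer badly (a
#' value at the strict edge filters true variants elsewhere; one at the
#' permissive edge floods false positives), and they make noisy training
#' targets for the meta-model. This pass, per parameter, locates by
#' bisection the acceptable interval (F1 not below the incumbent,
#' feasibility not worsened) around the current value and moves to its
#' midpoint on the search scale (log10 for log-scaled parameters; the
#' median member for discrete sets).
#'
#' @param task region task providing evidence and truth.
#' @param config starting (optimized) configuration.
#' @param space parameter space.
#' @param cs constraint thresholds used for the feasibility guard.
#' @param n_bisect bisection depth per interval edge.
#' @return canonicalized configuration with F1 >= the input's.
#' @export
relax_config <- function(task, config, space = default_space(),
                         cs = constraint_state(), n_bisect = 5L) {
  score <- function(cfg) {
    r <- compute_rates(run_pipeline(task$evidence, task$truth, cfg, space))
    list(f1 = if (is.na(r$f1)) 0 else r$f1,
         feasible = !is.na(r$fpr) && !is.na(r$fnr) &&
           r$fpr <= cs$tau_fp && r$fnr <= cs$tau_fn)
  }
  cur <- score(config)
  ok_state <- function(s) s$f1 >= cur$f1 && (s$feasible || !cur$feasible)
  cc <- space$continuous
  log_dims <- space_transform(space)
  order_nms <- c("strand_p_min", "error_z_min", "min_alt_per_strand",
                 "min_baseq", "min_alt_count", "min_vaf", "min_depth")
  order_nms <- c(intersect(order_nms, param_names(space)),
                 setdiff(param_names(space), order_nms))
  for (nm in order_nms) {
    ok_at <- function(v) {
      trial <- config; trial[[nm]] <- v
      ok_state(score(trial))
    }
    if (nm %in% cc$name) {
      tr <- function(v) if (nm %in% log_dims) log10(v) else v
      untr <- function(u) if (nm %in% log_dims) 10^u else u
      u_cur <- tr(config[[nm]])
      u_min <- tr(cc$lower[cc$name == nm])
      u_max <- tr(cc$upper[cc$name == nm])
      edge <- function(target) {
        # largest step toward `target` that stays acceptable (the
        # acceptable set is an interval containing u_cur)
        if (ok_at(untr(target))) return(target)
        good <- u_cur; bad <- target
        for (i in seq_len(n_bisect)) {
          mid <- (good + bad) / 2
          if (ok_at(untr(mid))) good <- mid else bad <- mid
        }
        good
      }
      u_new <- (edge(u_min) + edge(u_max)) / 2
      if (ok_at(untr(u_new))) {
        config[[nm]] <- untr(u_new)
        cur <- score(config)
      }
    } else {
      set <- space$discrete[[nm]]$set
      i_cur <- which.min(abs(set - config[[nm]]))
      edge_i <- function(target) {
        if (ok_at(set[target])) return(target)
        good <- i_cur; bad <- target
        while (abs(good - bad) > 1L) {
          mid <- (good + bad) %/% 2
          if (ok_at(set[mid])) good <- mid else bad <- mid
        }
        good
      }
      i_new <- (edge_i(1L) + edge_i(length(set))) %/% 2
      if (ok_at(set[i_new])) {
        config[[nm]] <- set[i_new]
        cur <- score(config)
      }
    }
  }
  config
}

#' @export
print.admm_result <- function(x, ...) {
  cat(sprintf(
    "ADMM result: %d iterations, %d pipeline evaluations, %s\n",
    x$state$iter, x$n_evals,
    if (x$feasible) "feasible" else "best-effort (infeasible)"))
  cat(sprintf("  F1 = %.4f; final residuals r_fp=%.4g r_fn=%.4g r_d=%.4g\n",
              x$f1, utils::tail(x$history$r_fp, 1),
              utils::tail(x$history$r_fn, 1), utils::tail(x$history$r_d, 1)))
  invisible(x)
}
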