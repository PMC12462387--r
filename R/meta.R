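# Region meta-features and the CNN-based parameter recommender.
#
# Once a cohort of regions has been optimized, each region contributes an
# (X = meta-features, y = optimized configuration) pair; a small 1-D
# convolutional regressor learns the mapping and recommends
# configurations for new regions without any truth set. The "CNN over
# tabular features" is realized as 1-D convolutions (kernel 3, two blocks
# of 16 filters, dense head) over the fixed-order feature vector; an MLP
# head is available for ablation. Training minimizes MSE in normalized
# target coordinates plus squared-norm weight decay (lambda = 1e-4).

META_FEATURE_NAMES <- c(
  "mean_germline_dist", "trinuc_context_count", "small_gap_count",
  "middle_sv_pct", "large_sv_pct", "read_mismatch_bias",
  "mean_depth", "depth_cv", "mean_baseq", "bg_error_rate"
)

#' Extract the fixed-order meta-feature vector for one region
#'
#' Features (in order): mean distance to the nearest germline SNP;
#' distinct trinucleotide-context count; small gap count (indel signals
#' of length < 10); middle and large SV percentages (gap signals in the
#' 10-50 and > 50 bp bands, as fractions of all gap signals); read
#' mismatch bias (mean per-site mismatch fraction over non-germline
#' sites; at MRD-level VAFs the truth contribution is negligible); mean
#' depth; depth coefficient of variation; mean base quality; background
#' error rate (mean mismatch fraction below its own 99th percentile).
#' Permutation-invariant to site order.
#'
#' @param evidence site-evidence data.frame.
#' @param germline_positions optional 1-based germline SNP positions; if
#'   omitted, the evidence's germline flags are used.
#' @return named numeric vector of length 10.
#' @export
extract_meta_features <- function(evidence, germline_positions = NULL) {
  if (is.null(evidence) || nrow(evidence) == 0L) stop("empty evidence")
  if (is.null(germline_positions)) {
    germ_dist <- evidence$near_germline_dist
  } else if (length(germline_positions)) {
    germ_dist <- vapply(evidence$pos,
                        function(p) min(abs(p - germline_positions)), 0)
  } else {
    germ_dist <- rep(nrow(evidence), nrow(evidence))
  }
  gaps <- evidence$gap_len[evidence$gap_type != ""]
  n_gap <- length(gaps)
  tot_alt <- evidence$alt_A + evidence$alt_C + evidence$alt_G +
    evidence$alt_T + evidence$gap_count
  nong <- !evidence$germline
  frac <- ifelse(evidence$depth > 0, tot_alt / evidence$depth, 0)[nong]
  bg <- if (length(frac)) {
    cap <- stats::quantile(frac, 0.99, names = FALSE)
    mean(frac[frac <= cap])
  } else 0
  md <- mean(evidence$depth)
  c(
    mean_germline_dist = mean(germ_dist),
    trinuc_context_count = length(unique(evidence$trinuc)),
    small_gap_count = sum(gaps < 10),
    middle_sv_pct = if (n_gap) sum(gaps >= 10 & gaps <= 50) / n_gap else 0,
    large_sv_pct = if (n_gap) sum(gaps > 50) / n_gap else 0,
    read_mismatch_bias = if (length(frac)) mean(frac) else 0,
    mean_depth = md,
    depth_cv = if (md > 0) stats::sd(evidence$depth) / md else 0,
    mean_baseq = mean(evidence$mean_baseq),
    bg_error_rate = bg
  )
}

#' Assemble the meta-dataset from optimized region tasks
#'
#' @param tasks list of region tasks.
#' @param optimized_configs list of parameter configurations, one per
#'   task (same order), e.g. the \code{best} configs of
#'   \code{\link{run_agent}}.
#' @param space parameter space the configs live in.
#' @return object of class \code{meta_dataset}: list(X matrix n x 10,
#'   y matrix n x n_params, region_ids).
#' @export
build_meta_dataset <- function(tasks, optimized_configs, space = default_space()) {
  if (length(tasks) != length(optimized_configs)) {
    stop("need exactly one optimized config per task")
  }
  ids <- vapply(seq_along(tasks), function(i)
    tasks[[i]]$region$region_id %||% as.character(i), "")
  if (anyDuplicated(ids)) {
    stop("duplicate region id: ", ids[anyDuplicated(ids)])
  }
  nms <- param_names(space)
  X <- t(vapply(tasks, function(t) extract_meta_features(t$evidence),
                numeric(length(META_FEATURE_NAMES))))
  y <- t(vapply(seq_along(tasks), function(i) {
    cfg <- optimized_configs[[i]]
    if (is.null(cfg)) stop("missing optimized config for region ", ids[i])
    validate_config(cfg, space)
    as.numeric(cfg[nms])
  }, numeric(length(nms))))
  colnames(y) <- nms
  ds <- list(X = X, y = y, region_ids = ids)
  class(ds) <- "meta_dataset"
  ds
}

#' Persist / load a meta-dataset as a tab-separated table
#'
#' @param dataset a \code{meta_dataset}.
#' @param path file path.
#' @return the path (write) or the dataset (read).
#' @export
write_meta_dataset <- function(dataset, path) {
  df <- data.frame(region_id = dataset$region_ids,
                   dataset$X, dataset$y, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("region_id", paste0("X.", colnames(dataset$X)),
                 paste0("y.", colnames(dataset$y)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_meta_dataset
#' @export
read_meta_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  xc <- grep("^X\\.", names(df))
  yc <- grep("^y\\.", names(df))
  X <- as.matrix(df[, xc]); colnames(X) <- sub("^X\\.", "", names(df)[xc])
  y <- as.matrix(df[, yc]); colnames(y) <- sub("^y\\.", "", names(df)[yc])
  ds <- list(X = X, y = y, region_ids = df$region_id)
  class(ds) <- "meta_dataset"
  ds
}

#' Near-equal cross-validation folds
#'
#' Fold sizes differ by at most one (e.g. n = 474, 10 folds gives four
#' folds of 48 and six of 47); assignment is a seeded permutation.
#'
#' @param n number of observations.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..folds) of length n.
#' @export
make_folds <- function(n, folds, seed = 1L) {
  stopifnot(n >= folds)
  sizes <- rep(n %/% folds, folds)
  if (n %% folds) sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
  ids <- rep(seq_len(folds), times = sizes)
  with_seed(seed, sample(ids))
}

# ---- 1-D CNN regressor ----------------------------------------------------

conv_dims <- function(n_feat, kernel = 3L, filters = 16L) {
  l1 <- n_feat - kernel + 1L
  l2 <- l1 - kernel + 1L
  list(kernel = kernel, filters = filters, l1 = l1, l2 = l2,
       flat = l2 * filters)
}

init_cnn <- function(n_feat, n_out, seed, hidden_mlp = NULL) {
  cd <- conv_dims(n_feat)
  with_seed(seed, {
    if (is.null(hidden_mlp)) {
      list(
        arch = "cnn", cd = cd,
        W1 = matrix(stats::rnorm(cd$kernel * cd$filters,
                                 sd = sqrt(2 / cd$kernel)), nrow = cd$kernel),
        b1 = rep(0, cd$filters),
        W2 = matrix(stats::rnorm(cd$kernel * cd$filters * cd$filters,
                                 sd = sqrt(2 / (cd$kernel * cd$filters))),
                    nrow = cd$kernel * cd$filters),
        b2 = rep(0, cd$filters),
        W3 = matrix(stats::rnorm(cd$flat * n_out, sd = sqrt(1 / cd$flat)),
                    nrow = cd$flat),
        b3 = rep(0, n_out)
      )
    } else {
      list(
        arch = "mlp", cd = cd,
        W1 = matrix(stats::rnorm(n_feat * hidden_mlp, sd = sqrt(2 / n_feat)),
                    nrow = n_feat),
        b1 = rep(0, hidden_mlp),
        W2 = matrix(stats::rnorm(hidden_mlp * hidden_mlp,
                                 sd = sqrt(2 / hidden_mlp)), nrow = hidden_mlp),
        b2 = rep(0, hidden_mlp),
        W3 = matrix(stats::rnorm(hidden_mlp * n_out, sd = sqrt(1 / hidden_mlp)),
                    nrow = hidden_mlp),
        b3 = rep(0, n_out)
      )
    }
  })
}

# z-scored features are clamped to +/- 3: regions far outside the
# training distribution get a conservative (boundary) representation
# instead of an uncontrolled extrapolation
clamp_features <- function(Xn) pmin(pmax(Xn, -3), 3)

# unfold (im2col) a N x L x C array at output position p for kernel k:
# returns N x (k*C)
unfold_at <- function(A, p, k) {
  do.call(cbind, lapply(seq_len(k), function(o) A[, p + o - 1L, , drop = TRUE]))
}

cnn_forward <- function(net, X, keep = FALSE) {
  N <- nrow(X)
  if (net$arch == "mlp") {
    H1 <- relu(sweep(X %*% net$W1, 2, net$b1, "+"))
    H2 <- relu(sweep(H1 %*% net$W2, 2, net$b2, "+"))
    out <- sweep(H2 %*% net$W3, 2, net$b3, "+")
    if (keep) return(list(out = out, X = X, H1 = H1, H2 = H2))
    return(out)
  }
  cd <- net$cd
  A0 <- array(X, dim = c(N, ncol(X), 1L))
  Z1 <- array(0, dim = c(N, cd$l1, cd$filters))
  U1 <- vector("list", cd$l1)
  for (p in seq_len(cd$l1)) {
    u <- matrix(unfold_at(A0, p, cd$kernel), nrow = N)
    U1[[p]] <- u
    Z1[, p, ] <- sweep(u %*% net$W1, 2, net$b1, "+")
  }
  A1 <- array(relu(Z1), dim = dim(Z1))
  Z2 <- array(0, dim = c(N, cd$l2, cd$filters))
  U2 <- vector("list", cd$l2)
  for (p in seq_len(cd$l2)) {
    u <- matrix(unfold_at(A1, p, cd$kernel), nrow = N)
    U2[[p]] <- u
    Z2[, p, ] <- sweep(u %*% net$W2, 2, net$b2, "+")
  }
  A2 <- array(relu(Z2), dim = dim(Z2))
  flat <- matrix(A2, nrow = N)  # N x (l2*filters), column-major over (pos, filter)
  out <- sweep(flat %*% net$W3, 2, net$b3, "+")
  if (keep) {
    list(out = out, A0 = A0, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
         U1 = U1, U2 = U2, flat = flat)
  } else {
    out
  }
}

cnn_backward <- function(net, fwd, dOut, lambda) {
  N <- nrow(dOut)
  g <- list()
  if (net$arch == "mlp") {
    g$W3 <- crossprod(fwd$H2, dOut) + 2 * lambda * net$W3
    g$b3 <- colSums(dOut)
    d2 <- (dOut %*% t(net$W3)) * (fwd$H2 > 0)
    g$W2 <- crossprod(fwd$H1, d2) + 2 * lambda * net$W2
    g$b2 <- colSums(d2)
    d1 <- (d2 %*% t(net$W2)) * (fwd$H1 > 0)
    g$W1 <- crossprod(fwd$X, d1) + 2 * lambda * net$W1
    g$b1 <- colSums(d1)
    return(g)
  }
  cd <- net$cd
  g$W3 <- crossprod(fwd$flat, dOut) + 2 * lambda * net$W3
  g$b3 <- colSums(dOut)
  dflat <- dOut %*% t(net$W3)
  dA2 <- array(dflat, dim = c(N, cd$l2, cd$filters))
  dZ2 <- dA2 * (fwd$Z2 > 0)
  g$W2 <- 2 * lambda * net$W2
  g$b2 <- rep(0, cd$filters)
  dA1 <- array(0, dim = c(N, cd$l1, cd$filters))
  for (p in seq_len(cd$l2)) {
    dz <- matrix(dZ2[, p, ], nrow = N)
    g$W2 <- g$W2 + crossprod(fwd$U2[[p]], dz)
    g$b2 <- g$b2 + colSums(dz)
    du <- dz %*% t(net$W2)  # N x (k*filters)
    for (o in seq_len(cd$kernel)) {
      cols <- ((o - 1L) * cd$filters + 1L):(o * cd$filters)
      dA1[, p + o - 1L, ] <- dA1[, p + o - 1L, ] + du[, cols]
    }
  }
  dZ1 <- dA1 * (fwd$Z1 > 0)
  g$W1 <- 2 * lambda * net$W1
  g$b1 <- rep(0, cd$filters)
  for (p in seq_len(cd$l1)) {
    dz <- matrix(dZ1[, p, ], nrow = N)
    g$W1 <- g$W1 + crossprod(fwd$U1[[p]], dz)
    g$b1 <- g$b1 + colSums(dz)
  }
  g
}

cnn_train <- function(net, X, Y, epochs, lr, lambda) {
  adam <- list(m = lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3")],
                          function(w) w * 0),
               v = lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3")],
                          function(w) w * 0),
               t = 0L)
  keys <- c("W1", "b1", "W2", "b2", "W3", "b3")
  N <- nrow(X)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- cnn_forward(net, X, keep = TRUE)
    err <- fwd$out - Y
    losses[ep] <- mean(err^2)
    dOut <- 2 * err / (N * ncol(Y))
    g <- cnn_backward(net, fwd, dOut, lambda)
    adam$t <- adam$t + 1L
    c1 <- 1 - 0.9^adam$t; c2 <- 1 - 0.999^adam$t
    for (k in keys) {
      adam$m[[k]] <- 0.9 * adam$m[[k]] + 0.1 * g[[k]]
      adam$v[[k]] <- 0.999 * adam$v[[k]] + 0.001 * g[[k]]^2
      net[[k]] <- net[[k]] - lr * (adam$m[[k]] / c1) /
        (sqrt(adam$v[[k]] / c2) + 1e-8)
    }
  }
  list(net = net, losses = losses)
}

#' Train the CNN meta-model with k-fold cross-validation
#'
#' Features are z-scored and targets mapped to [0, 1] (discrete
#' parameters on their relaxed hulls) using training-set statistics; the
#' reported CV losses are in those normalized coordinates. After CV, a
#' final model is trained on the full dataset.
#'
#' @param dataset a \code{meta_dataset}.
#' @param space parameter space (for target scaling and projection).
#' @param folds number of CV folds (default 10).
#' @param epochs training epochs (full-batch Adam).
#' @param lr learning rate.
#' @param lambda squared-norm weight-decay coefficient.
#' @param seed integer seed.
#' @param arch "cnn" (default) or "mlp" (ablation baseline).
#' @return object of class \code{mrd_meta}: the fitted recommender with
#'   normalization constants and a per-fold CV report.
#' @export
train_meta_model <- function(dataset, space = default_space(), folds = 10L,
                             epochs = 400L, lr = 0.01, lambda = 1e-4,
                             seed = 1L, arch = c("cnn", "mlp")) {
  arch <- match.arg(arch)
  n <- nrow(dataset$X)
  if (n < folds) stop("dataset smaller than the number of folds")
  box <- relax_space(space)
  nms <- param_names(space)
  # targets are normalized on the search scale (log10 for log-scaled
  # parameters): averaging scale-spanning thresholds in linear units
  # would systematically bias recommendations upward
  log_dims <- space_transform(space)
  ylo <- to_search_scale(box$lower[nms], log_dims)
  yhi <- to_search_scale(box$upper[nms], log_dims)
  yhi <- pmax(yhi, ylo + 1e-12)
  Ys <- t(apply(dataset$y[, nms, drop = FALSE], 1, to_search_scale, log_dims))
  Yn <- sweep(sweep(Ys, 2, ylo), 2, yhi - ylo, "/")

  fold_id <- make_folds(n, folds, seed = split_seed(seed, "folds"))
  fit_one <- function(idx_train, net_seed) {
    mu <- colMeans(dataset$X[idx_train, , drop = FALSE])
    sd <- apply(dataset$X[idx_train, , drop = FALSE], 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    Xn <- clamp_features(
      sweep(sweep(dataset$X[idx_train, , drop = FALSE], 2, mu), 2, sd, "/"))
    net <- if (arch == "cnn") {
      init_cnn(ncol(dataset$X), length(nms), net_seed)
    } else {
      init_cnn(ncol(dataset$X), length(nms), net_seed, hidden_mlp = 32L)
    }
    tr <- cnn_train(net, Xn, Yn[idx_train, , drop = FALSE], epochs, lr, lambda)
    list(net = tr$net, mu = mu, sd = sd, losses = tr$losses)
  }

  cv <- lapply(seq_len(folds), function(k) {
    tr_idx <- which(fold_id != k)
    te_idx <- which(fold_id == k)
    f <- fit_one(tr_idx, split_seed(seed, paste0("fold", k)))
    Xte <- clamp_features(
      sweep(sweep(dataset$X[te_idx, , drop = FALSE], 2, f$mu), 2, f$sd, "/"))
    pred <- cnn_forward(f$net, Xte)
    err <- pred - Yn[te_idx, , drop = FALSE]
    list(fold = k, n_train = length(tr_idx), n_test = length(te_idx),
         mse = mean(err^2), mae_per_param = colMeans(abs(err)),
         final_train_loss = utils::tail(f$losses, 1))
  })
  final <- fit_one(seq_len(n), split_seed(seed, "final"))

  model <- list(
    net = final$net, mu = final$mu, sd = final$sd,
    y_lower = ylo, y_upper = yhi, log_dims = log_dims,
    # envelope of the training targets (normalized): recommendations are
    # kept inside the span of historically optimal configurations, so an
    # extrapolating network can never emit a threshold no optimized
    # region ever used
    y_env_lo = apply(Yn, 2, min), y_env_hi = apply(Yn, 2, max),
    param_names = nms, space = space,
    arch = arch, epochs = epochs, lr = lr, lambda = lambda,
    cv_report = data.frame(
      fold = vapply(cv, `[[`, 0L, "fold"),
      n_train = vapply(cv, `[[`, 0L, "n_train"),
      n_test = vapply(cv, `[[`, 0L, "n_test"),
      val_mse = vapply(cv, `[[`, 0, "mse")
    ),
    cv_mae = t(vapply(cv, `[[`, numeric(length(nms)), "mae_per_param")),
    feature_names = colnames(dataset$X) %||% META_FEATURE_NAMES,
    n_train = n
  )
  class(model) <- "mrd_meta"
  model
}

#' @export
print.mrd_meta <- function(x, ...) {
  cat(sprintf("Meta-model (%s) over %d features -> %d parameters; n = %d\n",
              toupper(x$arch), length(x$mu), length(x$param_names), x$n_train))
  cat(sprintf("  %d-fold CV: mean val MSE %.4g; mean normalized MAE %.4g\n",
              nrow(x$cv_report), mean(x$cv_report$val_mse), mean(x$cv_mae)))
  invisible(x)
}

#' Recommend a parameter configuration for new region features
#'
#' The raw regression output is clamped to the envelope of the training
#' targets (and [0, 1]), rescaled from the normalized search scale,
#' clamped to the continuous bounds and projected onto the discrete
#' sets, so the recommendation is always a valid configuration within
#' the span of historically optimized ones.
#'
#' @param model a trained \code{mrd_meta}.
#' @param features meta-feature vector (length 10) or matrix (rows =
#'   regions).
#' @return a single config (vector input) or list of configs.
#' @export
recommend <- function(model, features) {
  single <- !is.matrix(features)
  Xm <- if (single) matrix(features, nrow = 1) else features
  if (ncol(Xm) != length(model$mu)) {
    stop(sprintf("expected %d features, got %d", length(model$mu), ncol(Xm)))
  }
  Xn <- clamp_features(sweep(sweep(Xm, 2, model$mu), 2, model$sd, "/"))
  raw <- cnn_forward(model$net, Xn)
  env_lo <- model$y_env_lo %||% rep(0, ncol(raw))
  env_hi <- model$y_env_hi %||% rep(1, ncol(raw))
  raw <- pmin(pmax(sweep(sweep(raw, 2, env_lo, pmax), 2, env_hi, pmin),
                   0), 1)
  out <- lapply(seq_len(nrow(raw)), function(i) {
    v <- model$y_lower + raw[i, ] * (model$y_upper - model$y_lower)
    names(v) <- model$param_names
    v <- from_search_scale(v, model$log_dims)
    dn <- names(model$space$discrete)
    v[dn] <- project_discrete(v[dn], model$space)
    validate_config(v, model$space)
    v
  })
  if (single) out[[1]] else out
}

#' @export
predict.mrd_meta <- function(object, newdata, ...) {
  recommend(object, newdata)
}

#' Compare agent-optimized against meta-recommended configurations
#'
#' For each held-out task, runs the detection pipeline under both the
#' agent's optimized configuration and the meta-model's recommendation,
#' and reports mean F1 under each, the absolute gap, variances, RMSE
#' against the ideal score, and the wall-time ratio of producing the
#' configurations (recommendation time is measured here; the agent time
#' must be supplied by the caller, e.g. from the optimization log).
#'
#' @param test_tasks held-out region tasks (disjoint from training).
#' @param agent_configs list of agent-optimized configs, one per task.
#' @param meta_model a trained \code{mrd_meta}.
#' @param space parameter space.
#' @param agent_seconds optional wall time the agent spent producing
#'   \code{agent_configs} (for the runtime ratio).
#' @return list of class \code{agent_meta_comparison}.
#' @export
compare_agent_vs_meta <- function(test_tasks, agent_configs, meta_model,
                                  space = default_space(),
                                  agent_seconds = NA_real_) {
  if (!length(test_tasks)) stop("empty test set")
  stopifnot(length(agent_configs) == length(test_tasks))
  t0 <- proc.time()[["elapsed"]]
  recs <- lapply(test_tasks, function(t)
    recommend(meta_model, extract_meta_features(t$evidence)))
  meta_seconds <- proc.time()[["elapsed"]] - t0
  f1_of <- function(task, cfg) {
    r <- compute_rates(run_pipeline(task$evidence, task$truth, cfg, space))
    if (is.na(r$f1)) 0 else r$f1
  }
  f1_agent <- vapply(seq_along(test_tasks), function(i)
    f1_of(test_tasks[[i]], agent_configs[[i]]), 0)
  f1_meta <- vapply(seq_along(test_tasks), function(i)
    f1_of(test_tasks[[i]], recs[[i]]), 0)
  out <- list(
    mean_f1_agent = mean(f1_agent), mean_f1_meta = mean(f1_meta),
    gap = abs(mean(f1_agent) - mean(f1_meta)),
    var_agent = stats::var(f1_agent), var_meta = stats::var(f1_meta),
    rmse_agent = sqrt(mean((f1_agent - 1)^2)),
    rmse_meta = sqrt(mean((f1_meta - 1)^2)),
    agent_seconds = agent_seconds, meta_seconds = meta_seconds,
    time_ratio = if (is.na(agent_seconds)) NA_real_ else
      agent_seconds / max(meta_seconds, 1e-9),
    per_task = data.frame(
      region = vapply(test_tasks, function(t)
        t$region$region_id %||% "", ""),
      f1_agent = f1_agent, f1_meta = f1_meta, stringsAsFactors = FALSE),
    recommended = recs
  )
  class(out) <- "agent_meta_comparison"
  out
}

#' @export
print.agent_meta_comparison <- function(x, ...) {
  cat(sprintf(
    "Agent vs meta-model on %d held-out regions:\n", nrow(x$per_task)))
  cat(sprintf("  mean F1: agent %.4f, meta %.4f (|gap| = %.4f)\n",
              x$mean_f1_agent, x$mean_f1_meta, x$gap))
  cat(sprintf("  variance: agent %.5f, meta %.5f; RMSE vs ideal: %.4f / %.4f\n",
              x$var_agent, x$var_meta, x$rmse_agent, x$rmse_meta))
  if (!is.na(x$time_ratio)) {
    cat(sprintf("  wall time: agent %.1fs vs meta %.3fs (ratio %.0fx)\n",
                x$agent_seconds, x$meta_seconds, x$time_ratio))
  }
  invisible(x)
}
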