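# End-to-end orchestration: segmentation, initialization, the joint
# ADMM + agent optimization as a classed model fit, and reproducible run
# directories. The fitting function is mrd_optimize(); everything else
# (print/summary/coef/plot) hangs off the returned mrd_fit object, in the
# style of R modelling packages.

#' Split panel intervals into subregions of bounded length
#'
#' Overlapping input intervals on one chromosome are merged first (with a
#' message), then each interval is chopped into consecutive half-open
#' chunks of at most \code{max_len} bp. The union of the output equals
#' the union of the input.
#'
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @param max_len maximum subregion length in bp (default 1000).
#' @return data.frame with chrom, start, end, region_id.
#' @export
segment_sample <- function(regions, max_len = 1000L) {
  stopifnot(max_len >= 1L)
  merged <- NULL
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    cur_s <- r$start[1]; cur_e <- r$end[1]; did_merge <- FALSE
    for (i in seq_len(nrow(r))[-1]) {
      if (r$start[i] < cur_e) {
        cur_e <- max(cur_e, r$end[i]); did_merge <- TRUE
      } else {
        merged <- rbind(merged, data.frame(chrom = chr, start = cur_s,
                                           end = cur_e))
        cur_s <- r$start[i]; cur_e <- r$end[i]
      }
    }
    merged <- rbind(merged, data.frame(chrom = chr, start = cur_s, end = cur_e))
    if (did_merge) message("overlapping intervals on ", chr, " merged")
  }
  out <- NULL
  for (i in seq_len(nrow(merged))) {
    s <- merged$start[i]; e <- merged$end[i]
    cuts <- seq(s, e, by = max_len)
    if (utils::tail(cuts, 1) < e) cuts <- c(cuts, e)
    out <- rbind(out, data.frame(chrom = merged$chrom[i],
                                 start = cuts[-length(cuts)],
                                 end = cuts[-1]))
  }
  out$region_id <- sprintf("region_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Run configuration for a full optimization run
#'
#' @param profile a \code{\link{cohort_profile}} (simulated input), or
#'   NULL when loading from files.
#' @param bed,evidence_dir,truth_vcf input paths used when
#'   \code{profile} is NULL: a BED of panel intervals, a directory of
#'   per-region evidence tables named \code{<region_id>.tsv}, and a truth
#'   VCF.
#' @param space parameter space.
#' @param max_region_len segmentation bound for loaded BED intervals.
#' @param total_steps,admm_args,agent_cfg optimization budgets (see
#'   \code{\link{run_agent}}, \code{\link{admm_solve}}).
#' @param train_meta train the meta-model at the end of the run.
#' @param holdout_fraction fraction of regions held out of meta-model
#'   training for the agent-vs-meta comparison.
#' @param seed global seed.
#' @param outdir output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(profile = cohort_profile(), bed = NULL,
                       evidence_dir = NULL, truth_vcf = NULL,
                       space = default_space(), max_region_len = 1000L,
                       total_steps = 200L, admm_args = list(),
                       agent_cfg = NULL, train_meta = TRUE,
                       holdout_fraction = 0.2, seed = 1L, outdir = NULL) {
  if (is.null(profile)) {
    for (p in c(bed, truth_vcf)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    if (!dir.exists(evidence_dir)) stop("input path does not exist: ", evidence_dir)
  }
  stopifnot(total_steps >= 1L)
  cfg <- list(profile = profile, bed = bed, evidence_dir = evidence_dir,
              truth_vcf = truth_vcf, space = space,
              max_region_len = as.integer(max_region_len),
              total_steps = as.integer(total_steps), admm_args = admm_args,
              agent_cfg = agent_cfg %||% agent_config(seed = seed),
              train_meta = train_meta, holdout_fraction = holdout_fraction,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

#' Build region tasks and the shared initial state
#'
#' Every region receives the same documented initial configuration
#' (midpoint of each continuous range, lower median of each discrete
#' set) and initial constraint thresholds (0.5, 0.5).
#'
#' @param config a \code{\link{run_config}}.
#' @return list(tasks, init_config, cs).
#' @export
init_run <- function(config) {
  if (!inherits(config, "run_config")) stop("need a run_config")
  tasks <- if (!is.null(config$profile)) {
    simulate_cohort(config$profile)
  } else {
    regions <- segment_sample(read_bed(config$bed), config$max_region_len)
    truth_all <- read_vcf(config$truth_vcf)
    lapply(seq_len(nrow(regions)), function(i) {
      region <- regions[i, ]
      ev_path <- file.path(config$evidence_dir,
                           paste0(region$region_id, ".tsv"))
      if (!file.exists(ev_path)) stop("missing evidence table: ", ev_path)
      ev <- read_evidence(ev_path)
      lo <- bed0_to_pos1(region$start); hi <- region$end
      tv <- truth_all[truth_all$pos >= lo & truth_all$pos <= hi, , drop = FALSE]
      task <- list(region = region, evidence = ev, truth = tv,
                   seed = split_seed(config$seed, region$region_id))
      class(task) <- "mrd_task"
      task
    })
  }
  list(tasks = tasks, init_config = initial_config(config$space),
       cs = constraint_state(0.5, 0.5))
}

#' Fit region-specific detection parameters by joint ADMM + Q-learning
#'
#' The main fitting function: runs the feedback loop over all regions
#' and returns a classed fit with per-region optimized configurations,
#' threshold trajectories, ADMM residual histories and pooled/stability
#' metrics.
#'
#' @param tasks list of region tasks (from \code{\link{simulate_cohort}}
#'   or \code{\link{init_run}}).
#' @param space parameter space.
#' @param total_steps total optimization steps across regions.
#' @param agent_cfg an \code{\link{agent_config}}.
#' @param admm_args list of \code{\link{admm_solve}} arguments.
#' @param seed seed used when \code{agent_cfg} is not supplied.
#' @return object of class \code{mrd_fit}.
#' @export
mrd_optimize <- function(tasks, space = default_space(), total_steps = 200L,
                         agent_cfg = NULL, admm_args = list(), seed = 1L) {
  agent_cfg <- agent_cfg %||% agent_config(seed = seed)
  t0 <- proc.time()[["elapsed"]]
  res <- run_agent(tasks, space, total_steps = total_steps,
                   agent_cfg = agent_cfg, admm_args = admm_args)
  # canonicalize each region's optimum to its least restrictive
  # equivalent (stable meta-model targets, safer transfer)
  for (i in seq_along(res$best)) {
    b <- res$best[[i]]
    res$best[[i]]$config <- relax_config(tasks[[i]], b$config, space,
                                         cs = b$cs)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  per_region <- region_metrics(tasks, lapply(res$best, `[[`, "config"), space)
  fit <- list(
    tasks = tasks, space = space, best = res$best,
    configs = lapply(res$best, `[[`, "config"),
    per_region = per_region,
    trajectories = res$trajectories, histories = res$histories,
    log = res$log, net = res$net, agent_cfg = agent_cfg,
    total_steps = total_steps, elapsed = elapsed
  )
  class(fit) <- "mrd_fit"
  fit
}

# per-region outcome/rate table under given configs (single source of
# truth for reports)
region_metrics <- function(tasks, configs, space) {
  rows <- lapply(seq_along(tasks), function(i) {
    out <- run_pipeline(tasks[[i]]$evidence, tasks[[i]]$truth,
                        configs[[i]], space)
    r <- compute_rates(out)
    data.frame(region = tasks[[i]]$region$region_id %||% as.character(i),
               tp = out$tp, fp = out$fp, fn = out$fn, tn = out$tn,
               sensitivity = r$sensitivity, precision = r$precision,
               specificity = r$specificity, f1 = r$f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled detection rates across a fit's regions
#'
#' Sums TP/FP/FN/TN over regions, then computes rates once.
#'
#' @param fit an \code{mrd_fit}.
#' @return a \code{rate_set}.
#' @export
pooled_rates <- function(fit) {
  m <- fit$per_region
  compute_rates(list(tp = sum(m$tp), fp = sum(m$fp),
                     fn = sum(m$fn), tn = sum(m$tn)))
}

#' @export
print.mrd_fit <- function(x, ...) {
  pr <- pooled_rates(x)
  cat(sprintf("Region-adaptive detection fit: %d regions, %d steps (%.0fs)\n",
              length(x$tasks), x$total_steps, x$elapsed))
  cat("  pooled: "); print(pr)
  invisible(x)
}

#' @export
summary.mrd_fit <- function(object, ...) {
  st <- stability_stats(object$per_region$f1)
  out <- list(pooled = pooled_rates(object), stability = st,
              per_region = object$per_region,
              n_feasible = sum(vapply(object$best, `[[`, TRUE, "feasible")))
  class(out) <- "summary.mrd_fit"
  out
}

#' @export
print.summary.mrd_fit <- function(x, ...) {
  cat("Pooled rates:      "); print(x$pooled)
  cat("F1 stability:      "); print(x$stability)
  cat(sprintf("Feasible regions:  %d / %d\n", x$n_feasible,
              nrow(x$per_region)))
  invisible(x)
}

#' @export
coef.mrd_fit <- function(object, ...) {
  m <- do.call(rbind, object$configs)
  rownames(m) <- object$per_region$region
  m
}

#' @export
plot.mrd_fit <- function(x, which = c("residuals", "f1"), ...) {
  which <- match.arg(which)
  if (which == "residuals") {
    hs <- Filter(Negate(is.null), x$histories)
    if (!length(hs)) stop("no residual histories recorded")
    ymax <- max(vapply(hs, function(h) max(abs(c(h$r_fp, h$r_fn))), 0), 1e-3)
    plot(NULL, xlim = c(1, max(vapply(hs, nrow, 0L))), ylim = c(0, ymax),
         xlab = "ADMM iteration", ylab = "|primal residual|",
         main = "FPR/FNR constraint residuals")
    for (h in hs) {
      graphics::lines(h$iter, abs(h$r_fp), col = "steelblue")
      graphics::lines(h$iter, abs(h$r_fn), col = "tomato")
    }
    graphics::legend("topright", c("FPR", "FNR"), lty = 1,
                     col = c("steelblue", "tomato"), bty = "n")
  } else {
    graphics::barplot(x$per_region$f1, names.arg = x$per_region$region,
                      las = 2, ylab = "F1", main = "Per-region F1")
  }
  invisible(x)
}

#' Execute a full reproducible run into an output directory
#'
#' simulate-or-load, initialize, optimize every region, write per-region
#' configurations and metrics, optionally train the meta-model and
#' compare it against the agent on held-out regions. Artifacts: BED,
#' truth VCF, evidence tables, configs.tsv, metrics.tsv, stability.tsv,
#' residuals.tsv, agent_log.tsv, meta comparison, and a JSON manifest
#' carrying the seed, a config fingerprint and the failure point if any
#' stage failed (partial outputs are retained).
#'
#' @param config a \code{\link{run_config}} with \code{outdir} set.
#' @return the output directory, invisibly.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$outdir))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "mrdoptim",
    version = as.character(utils::packageVersion("mrdoptim")),
    seed = config$seed,
    config_hash = fnv1a_hex(paste(deparse(config[setdiff(names(config),
                                                         "outdir")]),
                                  collapse = "")),
    status = "running", failed_stage = NA
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  write_manifest()

  ini <- stage("init", init_run(config))
  tasks <- ini$tasks

  stage("write-inputs", {
    regions <- do.call(rbind, lapply(tasks, `[[`, "region"))
    write_bed(regions, file.path(config$outdir, "regions.bed"))
    truth <- do.call(rbind, lapply(tasks, `[[`, "truth"))
    truth <- truth[order(truth$pos), , drop = FALSE]
    write_truth_vcf(truth, regions$chrom[1],
                    file.path(config$outdir, "truth.vcf"))
    evdir <- file.path(config$outdir, "evidence")
    dir.create(evdir, showWarnings = FALSE)
    for (t in tasks) {
      write_evidence(t$evidence,
                     file.path(evdir, paste0(t$region$region_id, ".tsv")))
    }
  })

  fit <- stage("optimize", mrd_optimize(
    tasks, config$space, total_steps = config$total_steps,
    agent_cfg = config$agent_cfg, admm_args = config$admm_args))

  stage("report", {
    cfgs <- coef(fit)
    utils::write.table(
      data.frame(region = rownames(cfgs), cfgs, check.names = FALSE),
      file.path(config$outdir, "configs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    utils::write.table(fit$per_region, file.path(config$outdir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    st <- stability_stats(fit$per_region$f1)
    utils::write.table(
      data.frame(metric = "f1", mean = st$mean, variance = st$variance,
                 std = st$std, cv = st$cv, rmse = st$rmse, n = st$n),
      file.path(config$outdir, "stability.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    resid <- do.call(rbind, lapply(seq_along(fit$histories), function(i) {
      h <- fit$histories[[i]]
      if (is.null(h)) return(NULL)
      cbind(region = fit$per_region$region[i], h)
    }))
    utils::write.table(resid, file.path(config$outdir, "residuals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    utils::write.table(fit$log, file.path(config$outdir, "agent_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  })

  if (config$train_meta && length(tasks) >= 12L) {
    stage("meta", {
      n <- length(tasks)
      n_hold <- max(1L, round(config$holdout_fraction * n))
      hold <- with_seed(split_seed(config$seed, "holdout"),
                        sort(sample.int(n, n_hold)))
      train_idx <- setdiff(seq_len(n), hold)
      ds <- build_meta_dataset(tasks[train_idx], fit$configs[train_idx],
                               config$space)
      write_meta_dataset(ds, file.path(config$outdir, "meta_dataset.tsv"))
      folds <- min(10L, length(train_idx))
      mm <- train_meta_model(ds, config$space, folds = folds,
                             seed = split_seed(config$seed, "meta"))
      cmp <- compare_agent_vs_meta(tasks[hold], fit$configs[hold], mm,
                                   config$space, agent_seconds = fit$elapsed)
      utils::write.table(cmp$per_task,
                         file.path(config$outdir, "agent_vs_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         eol = "\n")
      jsonlite::write_json(
        list(mean_f1_agent = cmp$mean_f1_agent,
             mean_f1_meta = cmp$mean_f1_meta, gap = cmp$gap,
             var_agent = cmp$var_agent, var_meta = cmp$var_meta,
             rmse_agent = cmp$rmse_agent, rmse_meta = cmp$rmse_meta),
        file.path(config$outdir, "agent_vs_meta.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }

  manifest$status <- "complete"
  manifest$n_regions <- length(tasks)
  write_manifest()
  invisible(config$outdir)
}
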