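# Segmentation, initialization, and reproducible end-to-end runs.

test_that("segmentation chunks intervals and conserves covered bases", {
  r <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  out <- segment_sample(r, 1000)
  expect_equal(nrow(out), 10)
  expect_true(all(out$end - out$start == 1000))

  r2 <- data.frame(chrom = "chr1", start = 0L, end = 1500L)
  out2 <- segment_sample(r2, 1000)
  expect_equal(out2$start, c(0, 1000))
  expect_equal(out2$end, c(1000, 1500))

  small <- data.frame(chrom = "chr1", start = 5L, end = 800L)
  out3 <- segment_sample(small, 1000)
  expect_equal(out3[, c("start", "end")],
               data.frame(start = 5L, end = 800L), ignore_attr = TRUE)

  # overlapping inputs are merged first; total coverage is conserved
  ov <- data.frame(chrom = "chr1", start = c(0L, 500L, 3000L),
                   end = c(1000L, 1600L, 3500L))
  expect_message(out4 <- segment_sample(ov, 700), "merged")
  covered <- sum(out4$end - out4$start)
  expect_equal(covered, 1600 + 500)
  expect_true(all(out4$end - out4$start <= 700))
})

test_that("initialization gives every region the same documented start", {
  cfg <- run_config(profile = cohort_profile(n_regions = 3,
                                             region_length = 200, seed = 2),
                    seed = 2)
  ini <- init_run(cfg)
  expect_equal(ini$cs$tau_fp, 0.5)
  expect_equal(ini$cs$tau_fn, 0.5)
  sp <- default_space()
  ic <- ini$init_config
  expect_equal(ic[["min_baseq"]], 25)       # range midpoint
  expect_equal(ic[["strand_p_min"]], 0.25)
  expect_equal(ic[["min_vaf"]], sqrt(1e-5 * 1e-2))  # geometric midpoint
  expect_equal(ic[["min_alt_count"]], 10)   # lower median of 1..20
  expect_equal(ic[["min_depth"]], 2500)
  expect_equal(length(ini$tasks), 3)
  expect_silent(validate_config(ic, sp))
})

test_that("a full run writes complete, reproducible artifacts", {
  make_cfg <- function(outdir) run_config(
    profile = cohort_profile(n_regions = 4, region_length = 400,
                             depth_range = c(10000, 10000),
                             error_rate_range = c(2e-5, 2e-5),
                             vaf_set = 1e-3,
                             variants_per_region_range = c(5, 5),
                             indel_fraction = 0, seed = 12),
    total_steps = 8, admm_args = list(max_iter = 2, bo_evals = 10),
    train_meta = FALSE, seed = 12, outdir = outdir)

  d1 <- withr::local_tempdir()
  run_full(make_cfg(d1))
  for (f in c("regions.bed", "truth.vcf", "configs.tsv", "metrics.tsv",
              "stability.tsv", "residuals.tsv", "agent_log.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$status, "complete")
  expect_equal(man$n_regions, 4)

  metrics <- read.delim(file.path(d1, "metrics.tsv"))
  expect_equal(nrow(metrics), 4)  # an optimized config for every region
  cfgs <- read.delim(file.path(d1, "configs.tsv"))
  expect_equal(nrow(cfgs), 4)

  # the report's stability line equals stability_stats on per-region F1
  stab <- read.delim(file.path(d1, "stability.tsv"))
  st <- stability_stats(metrics$f1)
  expect_equal(stab$mean, st$mean, tolerance = 1e-9)
  expect_equal(stab$variance, st$variance, tolerance = 1e-9)
  expect_equal(stab$rmse, st$rmse, tolerance = 1e-9)

  # byte-identical rerun with the same config + seed
  d2 <- withr::local_tempdir()
  run_full(make_cfg(d2))
  for (f in c("metrics.tsv", "configs.tsv", "regions.bed", "truth.vcf",
              "stability.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("file-backed runs load evidence through the same task builder", {
  prof <- cohort_profile(n_regions = 2, region_length = 300,
                         vaf_set = 1e-3, depth_range = c(10000, 10000),
                         variants_per_region_range = c(3, 3),
                         indel_fraction = 0, seed = 44)
  tasks <- simulate_cohort(prof)
  d <- withr::local_tempdir()
  write_bed(do.call(rbind, lapply(tasks, `[[`, "region")),
            file.path(d, "panel.bed"))
  truth <- do.call(rbind, lapply(tasks, `[[`, "truth"))
  write_truth_vcf(truth[order(truth$pos), ], prof$contig,
                  file.path(d, "truth.vcf"))
  evdir <- file.path(d, "evidence"); dir.create(evdir)
  for (t in tasks) {
    write_evidence(t$evidence,
                   file.path(evdir, paste0(t$region$region_id, ".tsv")))
  }
  cfg <- run_config(profile = NULL, bed = file.path(d, "panel.bed"),
                    evidence_dir = evdir,
                    truth_vcf = file.path(d, "truth.vcf"),
                    max_region_len = 300, seed = 44)
  ini <- init_run(cfg)
  expect_equal(length(ini$tasks), 2)
  expect_equal(nrow(ini$tasks[[1]]$truth) + nrow(ini$tasks[[2]]$truth),
               nrow(truth))
  # evidence survives the round trip into the task
  expect_equal(ini$tasks[[1]]$evidence$depth, tasks[[1]]$evidence$depth)
})
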