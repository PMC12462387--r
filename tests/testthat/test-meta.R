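# Meta-features, meta-dataset plumbing, CNN recommender, and the
# agent-vs-meta comparison contract.

test_that("meta-features match hand-enumerated values", {
  ev <- make_evidence(pos = c(100L, 200L, 300L), ref = "A",
                      depth = 1000L, alt_base = "T",
                      alt_count = c(0L, 0L, 0L), fwd = c(0L, 0L, 0L))
  # one germline SNP exactly 100 bp from the only (other) sites
  f <- extract_meta_features(ev[1, ], germline_positions = 200L)
  expect_equal(f[["mean_germline_dist"]], 100)
  # a clean region has zero read mismatch bias
  f0 <- extract_meta_features(ev)
  expect_equal(f0[["read_mismatch_bias"]], 0)
  expect_equal(f0[["bg_error_rate"]], 0)
  expect_equal(f0[["mean_depth"]], 1000)
  expect_equal(f0[["depth_cv"]], 0)
  # gap signals of lengths {2, 20, 60}: one small, a third middle, a third large
  evg <- ev
  evg$gap_type <- c("INS", "DEL", "INS")
  evg$gap_len <- c(2L, 20L, 60L)
  evg$gap_count <- c(3L, 2L, 2L)
  fg <- extract_meta_features(evg)
  expect_equal(fg[["small_gap_count"]], 1)
  expect_equal(fg[["middle_sv_pct"]], 1 / 3)
  expect_equal(fg[["large_sv_pct"]], 1 / 3)
  expect_error(extract_meta_features(ev[0, ]), "empty")
})

test_that("meta-features are invariant to site order", {
  task <- tier_tasks(vaf = 1e-3, depth = 10000, n_regions = 1,
                     region_length = 300, seed = 15)[[1]]
  ev <- task$evidence
  shuffled <- ev[with_seed(3, sample(nrow(ev))), ]
  expect_equal(extract_meta_features(ev), extract_meta_features(shuffled))
})

test_that("meta-dataset assembly validates and round-trips", {
  tasks <- tier_tasks(vaf = 1e-3, depth = 10000, n_regions = 4,
                      region_length = 300, seed = 8)
  cfgs <- replicate(4, initial_config(default_space()), simplify = FALSE)
  ds <- build_meta_dataset(tasks, cfgs)
  expect_equal(nrow(ds$X), 4)
  expect_equal(colnames(ds$y), param_names(default_space()))

  expect_error(build_meta_dataset(tasks, cfgs[1:3]), "one optimized config")
  dup <- tasks; dup[[2]]$region$region_id <- dup[[1]]$region$region_id
  expect_error(build_meta_dataset(dup, cfgs), "duplicate region id")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_meta_dataset(ds, path)
  back <- read_meta_dataset(path)
  expect_equal(back$X, ds$X, ignore_attr = TRUE)
  expect_equal(back$y, ds$y, ignore_attr = TRUE)
  expect_equal(back$region_ids, ds$region_ids)
})

test_that("fold sizes are near-equal, reproducing the 427/47 split", {
  f <- make_folds(474, 10, seed = 4)
  sizes <- as.integer(table(f))
  expect_equal(sort(sizes), sort(c(rep(48L, 4), rep(47L, 6))))
  expect_true(all((474 - sizes) %in% c(426, 427)))
  expect_identical(f, make_folds(474, 10, seed = 4))
  expect_error(make_folds(5, 10), "n >= folds")
})

test_that("the CNN recovers a noiseless linear feature-parameter map", {
  ds <- linear_meta_dataset(200, noise_sd = 0, seed = 6)
  m <- train_meta_model(ds, folds = 10, epochs = 400, seed = 3)
  expect_equal(nrow(m$cv_report), 10)
  expect_true(all(colMeans(m$cv_mae) < 0.05))
})

test_that("a constant target is predicted within one percent", {
  sp <- default_space()
  cfg <- initial_config(sp)
  tasks <- tier_tasks(vaf = 1e-3, depth = 10000, n_regions = 20,
                      region_length = 200, seed = 51)
  ds <- build_meta_dataset(tasks, replicate(20, cfg, simplify = FALSE))
  m <- train_meta_model(ds, folds = 5, epochs = 300, seed = 2)
  rec <- recommend(m, extract_meta_features(tasks[[1]]$evidence))
  box <- relax_space(sp)
  norm_err <- abs(rec - cfg) / (box$upper - box$lower)[names(cfg)]
  # discrete parameters are projected, so exact; continuous within 1%
  expect_true(all(norm_err < 0.01 + 1e-9))
})

test_that("recommendations are always valid, pure, and length-checked", {
  ds <- linear_meta_dataset(60, noise_sd = 0.1, seed = 2)
  m <- train_meta_model(ds, folds = 5, epochs = 120, seed = 9)
  sp <- default_space()
  with_seed(10, for (i in 1:20) {
    x <- rnorm(10, sd = 3)
    cfg <- recommend(m, x)
    expect_silent(validate_config(cfg, sp))
  })
  x <- rep(0, 10)
  expect_identical(recommend(m, x), recommend(m, x))
  expect_error(recommend(m, rep(0, 4)), "expected 10 features")
})

test_that("the comparison report is complete and exact in the identity limit", {
  sp <- default_space()
  cfg <- open_config(min_alt = 4)
  tasks <- tier_tasks(vaf = 1e-3, depth = 10000, n_regions = 24,
                      region_length = 400, seed = 33)
  train_tasks <- tasks[1:20]; test_tasks <- tasks[21:24]
  ds <- build_meta_dataset(train_tasks, replicate(20, cfg, simplify = FALSE))
  m <- train_meta_model(ds, folds = 5, epochs = 500, seed = 4)
  cmp <- compare_agent_vs_meta(test_tasks,
                               replicate(4, cfg, simplify = FALSE), m, sp)
  for (fld in c("mean_f1_agent", "mean_f1_meta", "gap", "var_agent",
                "var_meta", "rmse_agent", "rmse_meta", "meta_seconds")) {
    expect_true(is.finite(cmp[[fld]]), info = fld)
  }
  # constant training target: the model reproduces the agent's config, so
  # both arms run (essentially) the same pipeline
  expect_lt(cmp$gap, 0.05)
  expect_error(compare_agent_vs_meta(list(), list(), m, sp), "empty")
})
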