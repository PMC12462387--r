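# Two-stage surrogate pipeline: threshold semantics, filtering rules,
# scoring, and the monotonicity/purity contracts the optimizer relies on.

test_that("the reference space has the documented shape", {
  sp <- default_space()
  expect_equal(nrow(sp$continuous), 4)
  expect_equal(length(sp$discrete), 3)
  stages <- c(sp$continuous$stage,
              vapply(sp$discrete, `[[`, "", "stage"))
  expect_setequal(unique(stages), c("calling", "filtering"))
  expect_equal(sum(stages == "calling"), 4)
  for (d in sp$discrete) {
    expect_false(is.unsorted(d$set, strictly = TRUE))
  }
  expect_error(validate_config(open_config()[-1], sp), "missing")
  bad <- open_config(); bad[["min_vaf"]] <- 0.5
  expect_error(validate_config(bad, sp), "outside")
  frac <- open_config(); frac[["min_alt_count"]] <- 2.5
  expect_error(validate_config(frac, sp), "discrete")
  expect_silent(validate_config(frac, sp, relaxed = TRUE))
})

test_that("calling-stage thresholds act as documented", {
  ev <- make_evidence(pos = c(101L, 102L, 103L),
                      ref = c("A", "A", "C"),
                      depth = c(10000L, 10000L, 50L),
                      alt_base = c("T", "G", "T"),
                      alt_count = c(10L, 2L, 5L),
                      fwd = c(5L, 1L, 3L))
  cfg <- open_config(min_alt = 3)
  cfg[["min_vaf"]] <- 1e-4
  cand <- call_variants(ev, cfg)
  # site 101 passes; 102 fails min_alt_count; 103 fails min_depth
  expect_equal(cand$pos, 101L)
  expect_equal(cand$alt, "T")
  expect_equal(cand$observed_vaf, 10 / 10000)

  cfg[["min_vaf"]] <- 2e-3  # above 10/10000
  expect_equal(nrow(call_variants(ev, cfg)), 0)

  zero <- make_evidence(101L, "A", 1000L, "T", 0L, 0L)
  expect_equal(nrow(call_variants(zero, open_config())), 0)

  germ <- make_evidence(101L, "A", 10000L, "T", 5000L, 2500L,
                        germline = TRUE)
  expect_equal(nrow(call_variants(germ, open_config())), 0)
})

test_that("strand-balance p-values match the exact binomial test", {
  ks <- c(0L, 1L, 3L, 5L, 10L, 17L)
  ns <- c(6L, 9L, 10L, 10L, 20L, 20L)
  ours <- strand_binom_p(ks, ns)
  oracle <- mapply(function(k, n) stats::binom.test(k, n, 0.5)$p.value,
                   ks, ns)
  expect_equal(ours, unname(oracle), tolerance = 1e-12)
  expect_equal(strand_binom_p(0L, 0L), 1)
})

test_that("the filter removes only what its three rules say", {
  ev <- make_evidence(pos = c(101L, 150L, 200L),
                      ref = c("A", "C", "G"),
                      depth = c(10000L, 10000L, 10000L),
                      alt_base = c("T", "A", "C"),
                      alt_count = c(10L, 8L, 12L),
                      fwd = c(5L, 8L, 6L))  # site 150: all on one strand
  cand <- call_variants(ev, open_config())
  expect_equal(nrow(cand), 3)

  noop <- open_config()
  expect_equal(filter_variants(cand, ev, noop), cand)

  per_strand <- open_config()
  per_strand[["min_alt_per_strand"]] <- 1
  kept <- filter_variants(cand, ev, per_strand)
  expect_setequal(kept$pos, c(101L, 200L))

  zcut <- open_config()
  zcut[["error_z_min"]] <- 8
  # background e is floored near 0.25/depth: z ~ (alt - .25)/.5 >> 8, all kept
  expect_equal(nrow(filter_variants(cand, ev, zcut)), 3)
  expect_error(filter_variants(cand, ev[0, ], open_config()), "empty evidence")
  # output is always a subset of the input
  expect_true(all(kept$pos %in% cand$pos))
})

test_that("scoring matches the enumeration oracle and degenerate cases", {
  task <- standard_fixture()
  truth <- task$truth
  # perfect calls
  calls <- data.frame(pos = truth$pos, alt = truth$alt,
                      stringsAsFactors = FALSE)
  out <- evaluate_calls(calls, truth, task$evidence)
  expect_equal(out$fp, 0); expect_equal(out$fn, 0)
  expect_equal(out$tp, nrow(truth))
  # no calls
  out0 <- evaluate_calls(calls[0, ], truth, task$evidence)
  expect_equal(out0$tp, 0); expect_equal(out0$fn, nrow(truth))
  # hand enumeration: 1000 sites, truth {101 A>T}, calls at 101 and 202
  ev <- make_evidence(pos = 1:1000 + 100L, ref = "A",
                      depth = 1000L, alt_base = "T",
                      alt_count = 0L, fwd = 0L)
  t1 <- data.frame(pos = 101L, ref = "A", alt = "T", vaf = 0.001,
                   vtype = "SNV", stringsAsFactors = FALSE)
  c2 <- data.frame(pos = c(101L, 202L), alt = c("T", "G"),
                   stringsAsFactors = FALSE)
  out2 <- evaluate_calls(c2, t1, ev)
  expect_equal(unlist(out2[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 0L, tn = 998L))
})

test_that("fp falls and fn rises monotonically in each strictness knob", {
  task <- tier_tasks(vaf = 3e-4, depth = 20000, n_regions = 1, seed = 21)[[1]]
  base <- open_config(min_alt = 2)
  grids <- list(
    min_vaf = c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3),
    min_alt_count = c(1, 3, 6, 10, 15),
    min_baseq = c(10, 20, 30, 35, 40),
    error_z_min = c(0, 2, 4, 6, 8)
  )
  for (par in names(grids)) {
    fps <- integer(0); fns <- integer(0)
    for (v in grids[[par]]) {
      cfg <- base; cfg[[par]] <- v
      out <- run_pipeline(task$evidence, task$truth, cfg)
      fps <- c(fps, out$fp); fns <- c(fns, out$fn)
      expect_equal(out$tp + out$fn, nrow(task$truth))
      expect_true(all(unlist(out[c("tp", "fp", "fn", "tn")]) >= 0))
    }
    expect_true(all(diff(fps) <= 0), info = paste("fp monotone in", par))
    expect_true(all(diff(fns) >= 0), info = paste("fn monotone in", par))
  }
})

test_that("the pipeline is pure and composes its two stages", {
  task <- standard_fixture()
  cfg <- initial_config(default_space())
  a <- run_pipeline(task$evidence, task$truth, cfg)
  b <- run_pipeline(task$evidence, task$truth, cfg)
  expect_identical(a, b)
  # with a no-op filter, outcome equals scoring the calling stage alone
  noop <- cfg
  noop[["strand_p_min"]] <- 0; noop[["error_z_min"]] <- 0
  noop[["min_alt_per_strand"]] <- 0
  direct <- evaluate_calls(call_variants(task$evidence, noop),
                           task$truth, task$evidence)
  expect_identical(run_pipeline(task$evidence, task$truth, noop), direct)
})
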