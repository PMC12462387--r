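# Shared fixtures: all built in code at test time.

# single-tier SNV-only cohort at fixed depth/error
tier_profile <- function(vaf, depth, n_regions = 2L, n_var = 10L,
                         error = 2e-5, region_length = 1000L, seed = 7L) {
  cohort_profile(
    n_regions = n_regions, region_length = region_length,
    depth_range = c(depth, depth), error_rate_range = c(error, error),
    vaf_set = vaf, variants_per_region_range = c(n_var, n_var),
    indel_fraction = 0, seed = seed
  )
}

tier_tasks <- function(...) simulate_cohort(tier_profile(...))

# the standard fixed-seed fixture used for ADMM convergence checks:
# comfortably detectable variants, feasible at the (0.5, 0.5) thresholds
standard_fixture <- function(seed = 7L) {
  tier_tasks(vaf = 1e-3, depth = 10000, n_regions = 1L, seed = seed)[[1]]
}

# two-regime cohort: region 1 easily detectable (low noise), region 2 has
# variants below the detection limit (high noise: FNR cannot reach 0.5),
# so the feasible threshold pairs differ materially between regions
two_regime_tasks <- function(seed = 7L) {
  lo <- tier_tasks(vaf = 1e-3, depth = 20000, n_regions = 1L,
                   error = 1e-5, seed = seed)[[1]]
  hi <- suppressWarnings(  # error rate >= VAF tier by construction
    tier_tasks(vaf = 1e-4, depth = 5000, n_regions = 1L,
               error = 1e-4, seed = seed + 1L)[[1]])
  hi$region$region_id <- "region_hi"
  lo$region$region_id <- "region_lo"
  list(lo, hi)
}

# hand-built evidence table: one row per entry of `alt` (named by allele)
make_evidence <- function(pos, ref, depth, alt_base, alt_count, fwd,
                          baseq = 37, mapq = 58, germline = FALSE) {
  n <- length(pos)
  ref <- rep_len(ref, n); depth <- rep_len(depth, n)
  alt_base <- rep_len(alt_base, n); alt_count <- rep_len(alt_count, n)
  fwd <- rep_len(fwd, n)
  ev <- data.frame(
    pos = pos, ref = ref, depth = depth,
    alt_A = 0L, alt_C = 0L, alt_G = 0L, alt_T = 0L,
    fwd_A = 0L, fwd_C = 0L, fwd_G = 0L, fwd_T = 0L,
    gap_type = "", gap_len = 0L, gap_count = 0L, fwd_gap = 0L,
    mean_baseq = baseq, mean_mapq = mapq,
    near_germline_dist = 500, germline = germline,
    trinuc = "ACA", stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (alt_count[i] > 0) {
      ev[[paste0("alt_", alt_base[i])]][i] <- alt_count[i]
      ev[[paste0("fwd_", alt_base[i])]][i] <- fwd[i]
    }
  }
  ev
}

# a permissive configuration that calls everything with >= `min_alt` reads
open_config <- function(min_alt = 1) {
  c(min_vaf = 1e-5, min_baseq = 10, strand_p_min = 0, error_z_min = 0,
    min_alt_count = min_alt, min_depth = 100, min_alt_per_strand = 0)
}

fast_admm <- list(max_iter = 3L, bo_evals = 15L)

# synthetic meta-dataset whose normalized targets are a linear function
# of the features (optionally noisy), mapped into the parameter box
linear_meta_dataset <- function(n, noise_sd = 0, seed = 1) {
  sp <- default_space()
  nms <- param_names(sp)
  box <- relax_space(sp)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, mrdoptim:::META_FEATURE_NAMES))
    A <- matrix(stats::runif(10 * length(nms), -0.15, 0.15), 10)
    Yn <- 0.5 + X %*% A  # exactly linear in normalized target coordinates
    Yn <- Yn + stats::rnorm(length(Yn), sd = noise_sd)
    # map through the search scale (log10 for min_vaf) so the linear
    # relation holds in the coordinates the model is trained in
    log_dims <- mrdoptim:::space_transform(sp)
    lo_s <- mrdoptim:::to_search_scale(box$lower[nms], log_dims)
    hi_s <- mrdoptim:::to_search_scale(box$upper[nms], log_dims)
    Ys <- sweep(sweep(Yn, 2, hi_s - lo_s, "*"), 2, lo_s, "+")
    colnames(Ys) <- nms
    Y <- t(apply(Ys, 1, mrdoptim:::from_search_scale, log_dims))
    structure(list(X = X, y = Y, region_ids = paste0("r", seq_len(n))),
              class = "meta_dataset")
  })
}
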