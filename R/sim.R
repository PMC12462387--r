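# Synthetic ctDNA cohort simulator.
#
# Evidence is simulated at the site-count level: per-site alternate-allele
# counts are binomial draws with success probability equal to the truth VAF
# at truth sites and to the per-region consensus error rate elsewhere.
# This emulates UMI-consensus panel sequencing summaries (pileup-level
# evidence), not reads; a read/BAM-backed evidence source is an extension
# point (any data.frame with the same columns can be fed to the pipeline).

BASES <- c("A", "C", "G", "T")

#' Cohort simulation profile
#'
#' Describes one heterogeneous synthetic panel-sequencing cohort: how many
#' regions, their length, and the axes of inter-/intra-sample heterogeneity
#' (depth, consensus error rate, VAF tiers, variant density, germline SNP
#' density, strand bias).
#'
#' @param n_regions number of panel regions.
#' @param region_length region length in bp.
#' @param depth_range (min, max) mean consensus depth per region; per-site
#'   depths are negative-binomial around the region mean.
#' @param error_rate_range (min, max) per-site consensus error probability;
#'   one rate is drawn per region (intra-cohort heterogeneity). The default
#'   1e-5 to 1e-4 emulates UMI-consensus panels so that VAF 1e-4 variants
#'   remain statistically detectable at 50,000x depth.
#' @param vaf_set VAF tiers for truth variants, fractions in (0, 1). The
#'   default spans the MRD regime 0.01\%-0.1\%.
#' @param variants_per_region_range (min, max) truth variants per region.
#' @param germline_density germline heterozygous SNP positions per kb.
#' @param strand_bias_prob probability that the supporting reads of any
#'   allele (true or artifact) are collapsed onto a single strand.
#' @param indel_fraction fraction of truth variants simulated as indels
#'   (length 1-10, same count model as SNVs).
#' @param gap_noise_rate per-site probability of an artifact gap signal
#'   (candidate indel/SV noise, lengths log-uniform in 1-100 bp).
#' @param contig name of the synthetic contig.
#' @param seed cohort seed; per-region seeds are derived via
#'   \code{\link{split_seed}}.
#' @return an object of class \code{cohort_profile}.
#' @export
cohort_profile <- function(n_regions = 20L,
                           region_length = 1000L,
                           depth_range = c(10000, 50000),
                           error_rate_range = c(1e-5, 1e-4),
                           vaf_set = c(1e-4, 3e-4, 5e-4, 7e-4, 1e-3),
                           variants_per_region_range = c(2L, 12L),
                           germline_density = 1,
                           strand_bias_prob = 0.3,
                           indel_fraction = 0.1,
                           gap_noise_rate = 0.002,
                           contig = "simct1",
                           seed = 1L) {
  prof <- list(
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    depth_range = as.numeric(depth_range),
    error_rate_range = as.numeric(error_rate_range),
    vaf_set = as.numeric(vaf_set),
    variants_per_region_range = as.integer(variants_per_region_range),
    germline_density = as.numeric(germline_density),
    strand_bias_prob = as.numeric(strand_bias_prob),
    indel_fraction = as.numeric(indel_fraction),
    gap_noise_rate = as.numeric(gap_noise_rate),
    contig = as.character(contig),
    seed = as.integer(seed)
  )
  class(prof) <- "cohort_profile"
  validate_profile(prof)
  prof
}

validate_profile <- function(profile) {
  if (!inherits(profile, "cohort_profile")) stop("not a cohort_profile")
  if (is.na(profile$n_regions) || profile$n_regions <= 0L) {
    stop("invalid profile: n_regions must be >= 1")
  }
  if (profile$region_length <= 0L) stop("invalid profile: region_length must be >= 1")
  for (fld in c("depth_range", "error_rate_range", "variants_per_region_range")) {
    r <- profile[[fld]]
    if (length(r) != 2L || r[1] > r[2]) stop("invalid profile: ", fld, " must be (min, max) with min <= max")
  }
  if (any(profile$vaf_set <= 0 | profile$vaf_set >= 1)) {
    stop("invalid profile: vaf_set values must lie in (0, 1)")
  }
  if (profile$strand_bias_prob < 0 || profile$strand_bias_prob > 1) {
    stop("invalid profile: strand_bias_prob must lie in [0, 1]")
  }
  invisible(profile)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("Synthetic ctDNA cohort profile\n")
  cat(sprintf("  regions: %d x %d bp on contig %s (seed %d)\n",
              x$n_regions, x$region_length, x$contig, x$seed))
  cat(sprintf("  depth %g-%gx, consensus error %.1e-%.1e\n",
              x$depth_range[1], x$depth_range[2],
              x$error_rate_range[1], x$error_rate_range[2]))
  cat(sprintf("  VAF tiers: %s; %d-%d variants/region (%.0f%% indels)\n",
              paste(format(x$vaf_set, scientific = TRUE), collapse = ", "),
              x$variants_per_region_range[1], x$variants_per_region_range[2],
              100 * x$indel_fraction))
  invisible(x)
}

# --- coordinate conversions: the single place BED 0-based half-open
#     coordinates meet 1-based VCF/pileup positions -------------------------

#' Convert BED 0-based starts to 1-based positions (and back)
#'
#' @param start0 0-based BED start coordinate(s).
#' @return 1-based position(s).
#' @export
bed0_to_pos1 <- function(start0) as.integer(start0) + 1L

#' @rdname bed0_to_pos1
#' @param pos1 1-based position(s).
#' @export
pos1_to_bed0 <- function(pos1) as.integer(pos1) - 1L

#' Generate a disjoint region set on the synthetic contig
#'
#' @param profile a \code{\link{cohort_profile}}.
#' @return data.frame with columns chrom, start (0-based), end (exclusive),
#'   region_id. Regions are consecutive, disjoint, each of
#'   \code{region_length} bp, deterministic given the profile seed.
#' @export
generate_region_set <- function(profile) {
  validate_profile(profile)
  n <- profile$n_regions
  len <- profile$region_length
  # regions separated by a small seeded gap so coordinates are not trivially
  # contiguous (exercises interval arithmetic downstream)
  gaps <- with_seed(split_seed(profile$seed, "region-gaps"),
                    sample(0:500, n, replace = TRUE))
  starts <- cumsum(c(0L, rep(len, n - 1L)) + gaps)
  data.frame(
    chrom = profile$contig,
    start = as.integer(starts),
    end = as.integer(starts + len),
    region_id = sprintf("region_%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# deterministic synthetic reference sequence for one region
region_reference <- function(region, profile) {
  with_seed(split_seed(profile$seed, paste0("ref::", region$region_id)),
            sample(BASES, region$end - region$start, replace = TRUE))
}

# split an artifact allele count onto strands: with prob strand_bias_prob
# all reads land on one strand (strand-specific damage/error processes),
# else a fair binomial split. True and germline alleles are always split
# binomially: genuine templates are sequenced from both strands.
split_strands <- function(k, bias_prob) {
  n <- length(k)
  skew <- stats::runif(n) < bias_prob
  side <- stats::runif(n) < 0.5
  fwd <- stats::rbinom(n, k, 0.5)
  fwd[skew & side] <- k[skew & side]
  fwd[skew & !side] <- 0L
  fwd
}

#' Simulate site evidence and truth variants for one region
#'
#' Per site, alternate counts are binomial in depth with success probability
#' equal to the truth VAF at truth sites and the region's consensus error
#' rate elsewhere; error counts are spread uniformly over the three non-
#' reference bases. Strand splits follow \code{strand_bias_prob}. Known
#' germline heterozygous SNP positions are marked (panels blacklist them)
#' and feed the distance-to-germline meta-feature.
#'
#' @param region one row of \code{\link{generate_region_set}} output (or any
#'   list with chrom/start/end/region_id).
#' @param profile the \code{\link{cohort_profile}}.
#' @param region_seed integer seed for this region (see
#'   \code{\link{split_seed}}).
#' @return list with elements \code{evidence} (one row per site) and
#'   \code{truth} (truth variants with pos, ref, alt, vaf, vtype).
#' @export
simulate_evidence <- function(region, profile, region_seed) {
  validate_profile(profile)
  with_seed(region_seed, {
    len <- region$end - region$start
    pos <- bed0_to_pos1(region$start) + seq_len(len) - 1L
    ref <- region_reference(region, profile)

    depth_mean <- stats::runif(1, profile$depth_range[1], profile$depth_range[2])
    err <- stats::runif(1, profile$error_rate_range[1], profile$error_rate_range[2])
    if (err >= min(profile$vaf_set)) {
      warning(sprintf(
        "region %s: consensus error rate %.2e >= min VAF %.2e; variants at that tier are statistically undetectable",
        region$region_id, err, min(profile$vaf_set)))
    }

    depth <- stats::rnbinom(len, size = 50, mu = depth_mean)

    # germline heterozygous SNPs
    n_germ <- stats::rpois(1, profile$germline_density * len / 1000)
    germ_idx <- sort(sample.int(len, min(n_germ, len)))
    germline <- logical(len)
    germline[germ_idx] <- TRUE

    # truth variants on non-germline sites
    vpr <- profile$variants_per_region_range
    n_var <- if (vpr[1] == vpr[2]) vpr[1] else sample(vpr[1]:vpr[2], 1)
    free <- setdiff(seq_len(len), germ_idx)
    var_idx <- sort(free[sample.int(length(free), min(n_var, length(free)))])
    truth_vaf <- profile$vaf_set[sample.int(length(profile$vaf_set),
                                            length(var_idx), replace = TRUE)]
    is_indel <- stats::runif(length(var_idx)) < profile$indel_fraction

    # per-site, per-allele alternate counts, artifact and genuine parts
    # tracked separately (only artifacts can be strand-skewed)
    err_allele <- matrix(0L, nrow = len, ncol = 4, dimnames = list(NULL, BASES))
    true_allele <- err_allele
    n_err <- stats::rbinom(len, depth, err)
    has_err <- which(n_err > 0L)
    for (i in has_err) {
      picks <- sample(setdiff(BASES, ref[i]), n_err[i], replace = TRUE)
      tb <- table(factor(picks, levels = BASES))
      err_allele[i, ] <- as.integer(tb)
    }
    # germline het alleles
    if (length(germ_idx)) {
      g_alt <- vapply(germ_idx, function(i) sample(setdiff(BASES, ref[i]), 1), "")
      g_cnt <- stats::rbinom(length(germ_idx), depth[germ_idx], 0.5)
      true_allele[cbind(germ_idx, match(g_alt, BASES))] <-
        true_allele[cbind(germ_idx, match(g_alt, BASES))] + g_cnt
    }

    # truth alleles
    truth_alt_base <- character(length(var_idx))
    truth_cnt <- integer(length(var_idx))
    gap_type <- character(len); gap_type[] <- ""
    gap_len <- integer(len)
    gap_count <- integer(len)
    truth <- NULL
    if (length(var_idx)) {
      truth_cnt <- stats::rbinom(length(var_idx), depth[var_idx], truth_vaf)
      ind_len <- sample(1:10, length(var_idx), replace = TRUE)
      ref_a <- character(length(var_idx))
      alt_a <- character(length(var_idx))
      vtype <- character(length(var_idx))
      for (j in seq_along(var_idx)) {
        i <- var_idx[j]
        if (!is_indel[j]) {
          vtype[j] <- "SNV"
          ref_a[j] <- ref[i]
          truth_alt_base[j] <- sample(setdiff(BASES, ref[i]), 1)
          alt_a[j] <- truth_alt_base[j]
          true_allele[i, truth_alt_base[j]] <-
            true_allele[i, truth_alt_base[j]] + truth_cnt[j]
        } else {
          ins <- stats::runif(1) < 0.5
          seqs <- paste(sample(BASES, ind_len[j], replace = TRUE), collapse = "")
          if (ins) {
            vtype[j] <- "INS"; ref_a[j] <- ref[i]; alt_a[j] <- paste0(ref[i], seqs)
          } else {
            vtype[j] <- "DEL"; ref_a[j] <- paste0(ref[i], seqs); alt_a[j] <- ref[i]
          }
          gap_type[i] <- vtype[j]
          gap_len[i] <- ind_len[j]
          gap_count[i] <- truth_cnt[j]
        }
      }
      truth <- data.frame(pos = pos[var_idx], ref = ref_a, alt = alt_a,
                          vaf = truth_vaf, vtype = vtype,
                          stringsAsFactors = FALSE)
    }
    if (is.null(truth)) {
      truth <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), vaf = numeric(0),
                          vtype = character(0), stringsAsFactors = FALSE)
    }

    # artifact gap noise (lengths log-uniform 1-100 bp -> small/middle/large)
    truth_gap <- gap_count
    noise_gap <- which(stats::runif(len) < profile$gap_noise_rate & gap_type == "")
    artifact_gap <- integer(len)
    if (length(noise_gap)) {
      gl <- pmax(1L, as.integer(round(exp(stats::runif(length(noise_gap), 0, log(100))))))
      gap_type[noise_gap] <- ifelse(stats::runif(length(noise_gap)) < 0.5, "INS", "DEL")
      gap_len[noise_gap] <- gl
      artifact_gap[noise_gap] <- 1L + stats::rpois(length(noise_gap), 0.5)
      gap_count <- truth_gap + artifact_gap
    }
    fwd_gap <- stats::rbinom(len, truth_gap, 0.5) +
      split_strands(artifact_gap, profile$strand_bias_prob)

    # cap: total alternate evidence can never exceed depth (relevant only
    # at extreme parameter combinations; errors yield first)
    over <- which(rowSums(true_allele + err_allele) + gap_count > depth)
    for (i in over) {
      deficit <- sum(true_allele[i, ] + err_allele[i, ]) + gap_count[i] - depth[i]
      while (deficit > 0 && sum(err_allele[i, ]) > 0) {
        j <- which.max(err_allele[i, ])
        cut <- min(err_allele[i, j], deficit)
        err_allele[i, j] <- err_allele[i, j] - cut
        deficit <- deficit - cut
      }
    }

    # strand split per base allele: binomial for genuine alleles,
    # possibly skewed for artifacts
    alt <- true_allele + err_allele
    fwd <- matrix(0L, nrow = len, ncol = 4, dimnames = list(NULL, BASES))
    for (b in seq_len(4)) {
      fwd[, b] <- stats::rbinom(len, true_allele[, b], 0.5) +
        split_strands(err_allele[, b], profile$strand_bias_prob)
    }

    mean_baseq <- pmin(41, pmax(10, stats::rnorm(len, 37, 2)))
    mean_mapq <- pmin(60, pmax(0, stats::rnorm(len, 58, 3)))

    near_germ <- if (length(germ_idx)) {
      vapply(seq_len(len), function(i) min(abs(i - germ_idx)), 0)
    } else {
      rep(len, len)
    }

    trinuc <- paste0(c("N", ref[-len]), ref, c(ref[-1], "N"))

    evidence <- data.frame(
      pos = pos, ref = ref, depth = as.integer(depth),
      alt_A = alt[, 1], alt_C = alt[, 2], alt_G = alt[, 3], alt_T = alt[, 4],
      fwd_A = fwd[, 1], fwd_C = fwd[, 2], fwd_G = fwd[, 3], fwd_T = fwd[, 4],
      gap_type = gap_type, gap_len = gap_len,
      gap_count = gap_count, fwd_gap = fwd_gap,
      mean_baseq = round(mean_baseq, 2), mean_mapq = round(mean_mapq, 2),
      near_germline_dist = as.numeric(near_germ),
      germline = germline, trinuc = trinuc,
      stringsAsFactors = FALSE
    )
    attr(evidence, "zero_depth_sites") <- sum(depth == 0L)
    attr(evidence, "error_rate") <- err
    list(evidence = evidence, truth = truth)
  })
}

#' Simulate a full cohort of region tasks
#'
#' @param profile a \code{\link{cohort_profile}}.
#' @return list of region tasks, each a list with \code{region},
#'   \code{evidence}, \code{truth}, \code{seed} (class \code{mrd_task}).
#' @export
simulate_cohort <- function(profile) {
  regions <- generate_region_set(profile)
  lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    rs <- split_seed(profile$seed, region$region_id)
    sim <- simulate_evidence(region, profile, rs)
    task <- list(region = region, evidence = sim$evidence,
                 truth = sim$truth, seed = rs)
    class(task) <- "mrd_task"
    task
  })
}

#' @export
print.mrd_task <- function(x, ...) {
  cat(sprintf("Region task %s (%s:%d-%d): %d sites, %d truth variants\n",
              x$region$region_id, x$region$chrom, x$region$start,
              x$region$end, nrow(x$evidence), nrow(x$truth)))
  invisible(x)
}
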