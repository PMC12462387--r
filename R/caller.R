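# Parameterized two-stage detection pipeline (calling + filtering).
#
# This is the black box the optimizer queries: set a parameter
# configuration, run both stages over a site-evidence table, score against
# truth, observe TP/FP/FN/TN. The optimizer sees nothing else (no
# gradients, no stage internals). The stage rules are deliberately chosen
# so the two stages are coupled the way real caller+filter pipelines are:
# permissive calling thresholds flood the filter with marginal candidates,
# strict ones destroy sensitivity before the filter ever runs.

#' The reference mixed parameter space
#'
#' Calling stage: \code{min_alt_count} (discrete 1..20), \code{min_depth}
#' (discrete 100..5000 by 100), \code{min_vaf} (continuous [1e-5, 1e-2]),
#' \code{min_baseq} (continuous [10, 40]). Filtering stage:
#' \code{strand_p_min} (continuous [0, 0.5]), \code{error_z_min}
#' (continuous [0, 8]), \code{min_alt_per_strand} (discrete 0..5).
#'
#' @return an object of class \code{param_space}: list with
#'   \code{continuous} (data.frame name/lower/upper/stage) and
#'   \code{discrete} (named list of sorted integer sets plus stage tags).
#' @export
default_space <- function() {
  space <- list(
    continuous = data.frame(
      name = c("min_vaf", "min_baseq", "strand_p_min", "error_z_min"),
      lower = c(1e-5, 10, 0, 0),
      upper = c(1e-2, 40, 0.5, 8),
      stage = c("calling", "calling", "filtering", "filtering"),
      # min_vaf spans three decades: searched (and initialized) on a
      # log10 scale; bounds and stored values stay in natural units
      log = c(TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    ),
    discrete = list(
      min_alt_count = list(set = 1:20, stage = "calling"),
      min_depth = list(set = seq(100L, 5000L, by = 100L), stage = "calling"),
      min_alt_per_strand = list(set = 0:5, stage = "filtering")
    )
  )
  class(space) <- "param_space"
  space
}

#' Names of all parameters in a space (continuous first, then discrete)
#' @param space a \code{param_space}.
#' @return character vector.
#' @export
param_names <- function(space) {
  c(space$continuous$name, names(space$discrete))
}

#' Validate a parameter configuration against a space
#'
#' @param config named numeric vector covering every parameter.
#' @param space a \code{param_space}.
#' @param relaxed if TRUE, discrete parameters need only lie inside the
#'   convex hull of their set (used while the ADMM relaxation is active);
#'   if FALSE they must be exact members.
#' @return the config, invisibly; error on violation.
#' @export
validate_config <- function(config, space, relaxed = FALSE) {
  missing <- setdiff(param_names(space), names(config))
  if (length(missing)) {
    stop("config missing parameters: ", paste(missing, collapse = ", "))
  }
  cc <- space$continuous
  for (i in seq_len(nrow(cc))) {
    v <- config[[cc$name[i]]]
    if (is.na(v) || v < cc$lower[i] - 1e-12 || v > cc$upper[i] + 1e-12) {
      stop(sprintf("parameter %s = %g outside [%g, %g]",
                   cc$name[i], v, cc$lower[i], cc$upper[i]))
    }
  }
  for (nm in names(space$discrete)) {
    set <- space$discrete[[nm]]$set
    v <- config[[nm]]
    if (relaxed) {
      if (is.na(v) || v < min(set) - 1e-9 || v > max(set) + 1e-9) {
        stop(sprintf("parameter %s = %g outside hull [%g, %g]",
                     nm, v, min(set), max(set)))
      }
    } else if (!isTRUE(any(abs(set - v) < 1e-9))) {
      stop(sprintf("parameter %s = %g is not a member of its discrete set", nm, v))
    }
  }
  invisible(config)
}

#' Exact two-sided binomial strand-balance p-value (p = 0.5)
#'
#' Vectorized closed form of \code{binom.test(k, n, 0.5)$p.value}: by
#' symmetry the two-sided p-value equals \code{2 P(X <= min(k, n - k))},
#' capped at 1.
#'
#' @param k forward-strand alternate count(s).
#' @param n total alternate count(s).
#' @return p-values in [0, 1]; sites with n = 0 return 1 (no evidence of
#'   imbalance).
#' @export
strand_binom_p <- function(k, n) {
  m <- pmin(k, n - k)
  p <- pmin(1, 2 * stats::pbinom(m, n, 0.5))
  p[n == 0] <- 1
  p
}

#' Calling stage: emit candidate variants from site evidence
#'
#' A (site, allele) pair becomes a candidate iff depth >= min_depth,
#' alt count >= min_alt_count, alt/depth >= min_vaf and the site's mean
#' base quality >= min_baseq. Germline-flagged positions are blacklisted
#' (panel SNP mask). Gap (indel) alleles obey the same count thresholds.
#'
#' @param evidence site-evidence data.frame.
#' @param config parameter configuration (validated against \code{space},
#'   relaxed values inside the discrete hulls are accepted: thresholds are
#'   naturally continuous).
#' @param space parameter space, default \code{\link{default_space}}.
#' @return data.frame of candidates: pos, ref, alt, alt_count, fwd_alt,
#'   rev_alt, depth, observed_vaf, strand_p, mean_baseq.
#' @export
call_variants <- function(evidence, config, space = default_space()) {
  validate_config(config, space, relaxed = TRUE)
  keep_site <- evidence$depth >= config[["min_depth"]] &
    evidence$mean_baseq >= config[["min_baseq"]] &
    !evidence$germline
  out <- list()
  for (b in BASES) {
    cnt <- evidence[[paste0("alt_", b)]]
    fwd <- evidence[[paste0("fwd_", b)]]
    sel <- which(keep_site & evidence$ref != b &
                   cnt >= config[["min_alt_count"]] &
                   cnt >= config[["min_vaf"]] * evidence$depth)
    if (length(sel)) {
      out[[b]] <- data.frame(
        pos = evidence$pos[sel], ref = evidence$ref[sel], alt = b,
        alt_count = cnt[sel], fwd_alt = fwd[sel],
        rev_alt = cnt[sel] - fwd[sel], depth = evidence$depth[sel],
        mean_baseq = evidence$mean_baseq[sel],
        stringsAsFactors = FALSE
      )
    }
  }
  # gap (indel) candidates: allele string reconstructed from gap type/length
  gsel <- which(keep_site & evidence$gap_count >= config[["min_alt_count"]] &
                  evidence$gap_count >= config[["min_vaf"]] * evidence$depth &
                  evidence$gap_type != "")
  if (length(gsel)) {
    alt_str <- ifelse(evidence$gap_type[gsel] == "INS",
                      paste0(evidence$ref[gsel], "<INS:", evidence$gap_len[gsel], ">"),
                      paste0(evidence$ref[gsel], "<DEL:", evidence$gap_len[gsel], ">"))
    out[["gap"]] <- data.frame(
      pos = evidence$pos[gsel], ref = evidence$ref[gsel], alt = alt_str,
      alt_count = evidence$gap_count[gsel], fwd_alt = evidence$fwd_gap[gsel],
      rev_alt = evidence$gap_count[gsel] - evidence$fwd_gap[gsel],
      depth = evidence$depth[gsel], mean_baseq = evidence$mean_baseq[gsel],
      stringsAsFactors = FALSE
    )
  }
  cand <- if (length(out)) do.call(rbind, out) else data.frame(
    pos = integer(0), ref = character(0), alt = character(0),
    alt_count = integer(0), fwd_alt = integer(0), rev_alt = integer(0),
    depth = integer(0), mean_baseq = numeric(0), stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$pos, cand$alt), , drop = FALSE]
  rownames(cand) <- NULL
  cand$observed_vaf <- ifelse(cand$depth > 0, cand$alt_count / cand$depth, NA_real_)
  cand$strand_p <- strand_binom_p(cand$fwd_alt, cand$alt_count)
  cand
}

# background error estimate: median off-target (non-candidate,
# non-germline) alternate fraction across the region, floored so the
# z-score denominator is never zero
estimate_error_rate <- function(evidence, exclude_pos = integer(0)) {
  keep <- !evidence$germline & !(evidence$pos %in% exclude_pos)
  tot_alt <- evidence$alt_A + evidence$alt_C + evidence$alt_G +
    evidence$alt_T + evidence$gap_count
  frac <- ifelse(evidence$depth > 0, tot_alt / evidence$depth, 0)[keep]
  e <- if (length(frac)) stats::median(frac) else 0
  max(e, 0.25 / max(mean(evidence$depth), 1))
}

#' Filtering stage: remove artifact-like candidates
#'
#' Keeps a candidate iff its strand-balance p-value >= strand_p_min, its
#' per-strand minimum alternate count >= min_alt_per_strand, and its
#' background z-score \code{(alt - depth e) / sqrt(depth e (1 - e))} >=
#' error_z_min, with e the region's background error estimate (median
#' off-target alternate fraction). Ties favour keeping (all comparisons
#' are >=). The output is always a subset of the input.
#'
#' @param candidates output of \code{\link{call_variants}}.
#' @param evidence the evidence the candidates came from.
#' @param config parameter configuration.
#' @param space parameter space.
#' @return filtered candidate data.frame.
#' @export
filter_variants <- function(candidates, evidence, config, space = default_space()) {
  if (is.null(evidence) || nrow(evidence) == 0L) stop("empty evidence")
  validate_config(config, space, relaxed = TRUE)
  if (nrow(candidates) == 0L) return(candidates)
  e <- estimate_error_rate(evidence, exclude_pos = candidates$pos)
  z <- (candidates$alt_count - candidates$depth * e) /
    sqrt(pmax(candidates$depth * e * (1 - e), 1e-12))
  keep <- candidates$strand_p >= config[["strand_p_min"]] &
    pmin(candidates$fwd_alt, candidates$rev_alt) >= config[["min_alt_per_strand"]] &
    z >= config[["error_z_min"]]
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score final calls against truth
#'
#' Matching is on (pos, alt) exactly (indels require the exact allele
#' string); VAF is ignored. The true-negative universe is every evaluated
#' site whose position carries no truth variant.
#'
#' @param final_calls data.frame with pos and alt columns.
#' @param truth truth-variant data.frame (pos, alt).
#' @param evidence evidence table defining the evaluated site universe.
#' @return object of class \code{detection_outcome}: list(tp, fp, fn, tn).
#' @export
evaluate_calls <- function(final_calls, truth, evidence) {
  truth_key <- paste(truth$pos, truth_alt_key(truth), sep = "/")
  call_key <- paste(final_calls$pos, final_calls$alt, sep = "/")
  tp <- sum(call_key %in% truth_key)
  fp <- sum(!(call_key %in% truth_key))
  fn <- sum(!(truth_key %in% call_key))
  n_sites <- nrow(evidence)
  fp_pos <- unique(final_calls$pos[!(call_key %in% truth_key)])
  tn <- n_sites - length(unique(truth$pos)) - length(fp_pos)
  out <- list(tp = as.integer(tp), fp = as.integer(fp),
              fn = as.integer(fn), tn = as.integer(tn))
  class(out) <- "detection_outcome"
  out
}

# truth alt alleles in the same encoding the caller emits: SNVs keep the
# base, indels use the symbolic <INS:len>/<DEL:len> form derived from the
# allele strings
truth_alt_key <- function(truth) {
  if (!nrow(truth)) return(character(0))
  key <- truth$alt
  ins <- truth$vtype == "INS"
  del <- truth$vtype == "DEL"
  key[ins] <- paste0(truth$ref[ins], "<INS:", nchar(truth$alt[ins]) - 1L, ">")
  key[del] <- paste0(truth$alt[del], "<DEL:", nchar(truth$ref[del]) - 1L, ">")
  key
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("Detection outcome: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Run the full two-stage pipeline and score it
#'
#' The single entry point the optimizer is allowed to query (black-box
#' contract): call, filter, evaluate. Pure: identical inputs give an
#' identical outcome.
#'
#' @param evidence site-evidence data.frame.
#' @param truth truth variants.
#' @param config parameter configuration.
#' @param space parameter space.
#' @return a \code{detection_outcome}.
#' @export
run_pipeline <- function(evidence, truth, config, space = default_space()) {
  cand <- call_variants(evidence, config, space)
  final <- filter_variants(cand, evidence, config, space)
  evaluate_calls(final, truth, evidence)
}
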