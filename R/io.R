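# Interval, variant and evidence-table I/O.
#
# BED is written/read 0-based half-open; VCF 1-based. All coordinate
# conversions between those conventions go through bed0_to_pos1() /
# pos1_to_bed0() in sim.R. Writers emit fully deterministic text (fixed
# column order, "\n" line endings, %.6g numeric formatting) so reruns with
# one seed are byte-identical. VCF parsing is delegated to vcfR.

#' Write a region set as a BED file
#'
#' @param regions data.frame with chrom, start, end and optionally
#'   region_id (written as the BED name column).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end)) stop("BED intervals require start < end")
  lines <- if ("region_id" %in% names(regions)) {
    sprintf("%s\t%d\t%d\t%s", regions$chrom, as.integer(regions$start),
            as.integer(regions$end), regions$region_id)
  } else {
    sprintf("%s\t%d\t%d", regions$chrom, as.integer(regions$start),
            as.integer(regions$end))
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a BED file into a region data.frame
#'
#' Accepts >= 3 tab-separated columns; a 4th column is taken as region_id,
#' otherwise ids are generated. Malformed lines raise an error naming the
#' line number.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end, region_id.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3L) stop("BED parse error at line ", i, ": fewer than 3 columns")
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end)) {
      stop("BED parse error at line ", i, ": non-integer coordinates")
    }
    if (start >= end) stop("BED parse error at line ", i, ": start >= end")
    list(chrom = p[1], start = start, end = end,
         region_id = if (length(p) >= 4L) p[4] else NA_character_)
  })
  df <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    region_id = vapply(out, `[[`, "", "region_id"),
    stringsAsFactors = FALSE
  )
  miss <- is.na(df$region_id)
  df$region_id[miss] <- sprintf("region_%03d", which(miss))
  df
}

#' Write truth variants as a VCF 4.2 file
#'
#' Records carry the simulated allele fraction and variant type in INFO
#' keys VAF and VTYPE. Input must be position-sorted.
#'
#' @param variants data.frame with pos (1-based), ref, alt, vaf, vtype.
#' @param contig contig name for the header.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_vcf <- function(variants, contig, path) {
  if (nrow(variants) && is.unsorted(variants$pos)) {
    stop("variants must be sorted by position before writing VCF")
  }
  if (nrow(variants) && any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mrdoptim-simulator",
    sprintf("##contig=<ID=%s>", contig),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Simulated variant allele fraction\">",
    "##INFO=<ID=VTYPE,Number=1,Type=String,Description=\"Variant type: SNV, INS or DEL\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%s;VTYPE=%s",
            contig, as.integer(variants$pos), variants$ref, variants$alt,
            sprintf("%.6g", variants$vaf), variants$vtype)
  } else {
    character(0)
  }
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a truth VCF back into a variant data.frame
#'
#' Parsing is done with \pkg{vcfR}; files written by this package must
#' carry a contig header line (an error otherwise).
#'
#' @param path VCF path.
#' @return data.frame with pos, ref, alt, vaf, vtype.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  if (!any(grepl("^##contig=", meta))) {
    stop("VCF is missing a ##contig header line")
  }
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), vaf = numeric(0),
                      vtype = character(0), stringsAsFactors = FALSE))
  }
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "VAF")))
  vtype <- vcfR::extract.info(vcf, "VTYPE")
  data.frame(
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    vaf = vaf,
    vtype = as.character(vtype),
    stringsAsFactors = FALSE
  )
}

EVIDENCE_COLUMNS <- c(
  "pos", "ref", "depth", "alt_A", "alt_C", "alt_G", "alt_T",
  "fwd_A", "fwd_C", "fwd_G", "fwd_T", "gap_type", "gap_len",
  "gap_count", "fwd_gap", "mean_baseq", "mean_mapq",
  "near_germline_dist", "germline", "trinuc"
)

#' Persist / load a site-evidence table (tab-separated, fixed column order)
#'
#' @param evidence evidence data.frame as produced by
#'   \code{\link{simulate_evidence}}.
#' @param path file path.
#' @return the path (write) or the evidence data.frame (read).
#' @export
write_evidence <- function(evidence, path) {
  stopifnot(all(EVIDENCE_COLUMNS %in% names(evidence)))
  utils::write.table(evidence[, EVIDENCE_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  header <- utils::read.table(path, sep = "\t", header = TRUE, nrows = 1)
  missing <- setdiff(EVIDENCE_COLUMNS, names(header))
  if (length(missing)) stop("evidence table missing columns: ",
                            paste(missing, collapse = ", "))
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(gap_type = "character",
                                         trinuc = "character",
                                         ref = "character"))
  ev[, EVIDENCE_COLUMNS]
}
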