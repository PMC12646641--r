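#' Quality-based post-filtering of a merged callset
#'
#' Retains a consensus record iff its representative meets every specified
#' threshold. A record missing an attribute for which a threshold was
#' specified is dropped and counted in the report.
#'
#' @param x an [SVCallSet-class] or [MergedSVSet-class].
#' @param min_qual minimum QUAL.
#' @param min_support_reads minimum variant-supporting read count (AD).
#' @param min_dp minimum total depth.
#' @param min_gq minimum genotype quality.
#' @return list with `callset` (same class as `x`, filtered) and `report`
#'   (list of input/kept/dropped counts, with drops broken down by
#'   criterion and by missing attribute).
#' @export
qualityFilter <- function(x, min_qual = NULL, min_support_reads = NULL,
                          min_dp = NULL, min_gq = NULL) {
  stopifnot(is(x, "SVCallSet"))
  rec <- x@records
  n <- nrow(rec)
  keep <- rep(TRUE, n)
  report <- list(input = n,
                 thresholds = list(qual = min_qual,
                                   support_reads = min_support_reads,
                                   dp = min_dp, gq = min_gq),
                 dropped_by = list(), dropped_missing = list())
  screen <- function(vals, thr, name) {
    if (is.null(thr)) return(invisible())
    miss <- is.na(vals)
    fail <- !miss & vals < thr
    report$dropped_by[[name]] <<- sum(fail & keep)
    report$dropped_missing[[name]] <<- sum(miss & keep)
    keep <<- keep & !miss & !fail
  }
  screen(rec$qual, min_qual, "qual")
  screen(rec$ad_alt, min_support_reads, "support_reads")
  screen(rec$dp, min_dp, "dp")
  screen(rec$gq, min_gq, "gq")
  report$kept <- sum(keep)
  report$dropped <- n - report$kept
  out <- if (is(x, "MergedSVSet")) {
    new("MergedSVSet",
        SVCallSet(records = rec[keep, , drop = FALSE],
                  sampleNames = x@sampleNames, metadata = x@metadata),
        members = x@members[keep], callers = x@callers)
  } else {
    SVCallSet(records = rec[keep, , drop = FALSE],
              sampleNames = x@sampleNames, metadata = x@metadata)
  }
  list(callset = out, report = report)
}
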