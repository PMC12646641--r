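#' Summary statistics of a callset
#'
#' @param x an [SVCallSet-class] (or subclass).
#' @param breaks size-histogram bin edges in bp.
#' @return list with `total`, `by_type`, `by_chrom`, `size_histogram`
#'   (TRA/BND carry no length and are excluded from the histogram) and
#'   `support_counts` (merged callsets only). Counts in `by_type` and
#'   `by_chrom` sum to `total`.
#' @export
svStats <- function(x, breaks = c(0, 50, 100, 500, 1000, 5000, 10000, Inf)) {
  rec <- if (is(x, "SVCallSet")) x@records else makeSVRecords(x)
  by_type <- as.list(table(rec$svtype))
  by_chrom <- as.list(table(rec$chrom))
  sizes <- abs(rec$svlen[!rec$svtype %in% c("TRA", "BND") & !is.na(rec$svlen)])
  h <- table(cut(sizes, breaks = breaks, right = FALSE,
                 labels = paste0("[", head(breaks, -1L), ",", breaks[-1L], ")")))
  out <- list(total = nrow(rec),
              by_type = lapply(by_type, as.integer),
              by_chrom = lapply(by_chrom, as.integer),
              size_histogram = lapply(as.list(h), as.integer))
  if (is(x, "MergedSVSet"))
    out$support_counts <- lapply(as.list(table(rec$support_count)), as.integer)
  out
}
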