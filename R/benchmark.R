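#' Benchmarking parameters
#'
#' @param position_threshold breakpoint distance in bp for non-TRA matching
#'   (default 500).
#' @param min_size_ratio minimum size similarity, smaller over larger
#'   |SVLEN|, in (0, 1] (default 0.7). Waived for translocations, which
#'   have no length.
#' @param require_type_match logical, only same-type call/truth pairs can
#'   match (default TRUE).
#' @param tra_position_threshold breakpoint distance for TRA/BND events,
#'   applied to both breakpoints (default 5000).
#' @return list of validated parameters of class `BenchParams`.
#' @export
benchParams <- function(position_threshold = 500, min_size_ratio = 0.7,
                        require_type_match = TRUE,
                        tra_position_threshold = 5000) {
  if (position_threshold <= 0) .stopValidation("position_threshold must be > 0")
  if (min_size_ratio <= 0 || min_size_ratio > 1)
    .stopValidation("min_size_ratio must be in (0, 1]")
  structure(list(position_threshold = position_threshold,
                 min_size_ratio = min_size_ratio,
                 require_type_match = require_type_match,
                 tra_position_threshold = tra_position_threshold),
            class = "BenchParams")
}

## candidate call/truth pairs with their matching distance; one pass over
## calls with vectorized comparison against the truth rows on the same
## chromosome
.benchCandidates <- function(calls, truth, params) {
  if (!nrow(calls) || !nrow(truth))
    return(cbind(integer(), integer(), numeric()))
  t_by_chrom <- split(seq_len(nrow(truth)), truth$chrom)
  cand <- vector("list", nrow(calls))
  truth_is_tra <- truth$svtype %in% c("TRA", "BND")
  for (i in seq_len(nrow(calls))) {
    js <- t_by_chrom[[calls$chrom[i]]]
    if (is.null(js)) next
    is_tra <- calls$svtype[i] %in% c("TRA", "BND")
    thr <- if (is_tra) params$tra_position_threshold else params$position_threshold
    if (params$require_type_match) js <- js[truth$svtype[js] == calls$svtype[i]]
    if (is_tra) {
      js <- js[truth_is_tra[js] & truth$chrom2[js] == calls$chrom2[i]]
      if (!length(js)) next
      d1 <- abs(calls$pos[i] - truth$pos[js])
      d2 <- abs(calls$pos2[i] - truth$pos2[js])
      ok <- d1 <= thr & d2 <= thr
    } else {
      js <- js[!truth_is_tra[js]]
      if (!length(js)) next
      d1 <- abs(calls$pos[i] - truth$pos[js])
      d2 <- abs(calls$end[i] - truth$end[js])
      ok <- d1 <= thr & d2 <= thr
      sa <- abs(calls$svlen[i]); sb <- abs(truth$svlen[js])
      ratio_known <- !is.na(sa) & !is.na(sb) & sa > 0 & sb > 0
      ok <- ok & (!ratio_known |
                    pmin(sa, sb) / pmax(sa, sb) >= params$min_size_ratio)
    }
    if (any(ok))
      cand[[i]] <- cbind(i, js[ok], pmax(d1, d2)[ok])
  }
  cand <- cand[!vapply(cand, is.null, logical(1L))]
  if (length(cand)) do.call(rbind, cand) else cbind(integer(), integer(), numeric())
}

#' Benchmark a callset against a truth set
#'
#' One-to-one greedy matching by ascending breakpoint distance (ties broken
#' by truth-record input order): a call matches a truth record iff the
#' types agree (when required), both breakpoints lie within the position
#' threshold (translocations use `tra_position_threshold` on both
#' breakpoints) and the size ratio (smaller/larger) is at least
#' `min_size_ratio` (waived for TRA). Each truth record is consumed at most
#' once. Precision, recall and F1 are reported overall and per SV type.
#'
#' @param calls an [SVCallSet-class] or [MergedSVSet-class] to evaluate.
#' @param truth an [SVCallSet-class] with the truth records.
#' @param params a [benchParams()] object.
#' @return A [BenchmarkReport-class].
#' @export
benchmarkCalls <- function(calls, truth, params = benchParams()) {
  crec <- if (is(calls, "SVCallSet")) calls@records else makeSVRecords(calls)
  trec <- if (is(truth, "SVCallSet")) truth@records else makeSVRecords(truth)
  if (!nrow(trec))
    warning("empty truth set: recall is undefined and reported as 0")
  cand <- .benchCandidates(crec, trec, params)
  matched_call <- integer(0)
  matched_truth <- integer(0)
  dist <- numeric(0)
  if (nrow(cand)) {
    cand <- cand[order(cand[, 3L], cand[, 2L], cand[, 1L]), , drop = FALSE]
    used_c <- rep(FALSE, nrow(crec))
    used_t <- rep(FALSE, nrow(trec))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (used_c[i] || used_t[j]) next
      used_c[i] <- TRUE; used_t[j] <- TRUE
      matched_call <- c(matched_call, i)
      matched_truth <- c(matched_truth, j)
      dist <- c(dist, cand[r, 3L])
    }
  }
  tp <- crec[matched_call, , drop = FALSE]
  if (nrow(tp)) {
    tp$truth_id <- trec$record_id[matched_truth]
    tp$distance <- dist
  } else {
    tp$truth_id <- character(0)
    tp$distance <- numeric(0)
  }
  fp <- crec[setdiff(seq_len(nrow(crec)), matched_call), , drop = FALSE]
  fn <- trec[setdiff(seq_len(nrow(trec)), matched_truth), , drop = FALSE]
  types <- sort(unique(c(crec$svtype, trec$svtype)))
  metric_row <- function(type) {
    if (identical(type, "overall")) {
      ntp <- nrow(tp); nfp <- nrow(fp); nfn <- nrow(fn)
    } else {
      ntp <- sum(tp$svtype == type)
      nfp <- sum(fp$svtype == type)
      nfn <- sum(fn$svtype == type)
    }
    p <- if (ntp + nfp > 0) ntp / (ntp + nfp) else 0
    r <- if (ntp + nfn > 0) ntp / (ntp + nfn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(svtype = type, tp = ntp, fp = nfp, fn = nfn,
               precision = p, recall = r, f1 = f1, stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, lapply(c(types, "overall"), metric_row))
  rownames(metrics) <- NULL
  new("BenchmarkReport", tp = tp, fp = fp, fn = fn, metrics = metrics,
      params = unclass(params))
}

#' Write benchmark outputs (TP/FP/FN VCFs + JSON statistics)
#'
#' @param report a [BenchmarkReport-class].
#' @param prefix output path prefix; writes `<prefix>.tp.vcf`,
#'   `<prefix>.fp.vcf`, `<prefix>.fn.vcf` and `<prefix>.stats.json`.
#' @return character vector of the four paths, invisibly.
#' @export
writeBenchmarkOutputs <- function(report, prefix) {
  stopifnot(is(report, "BenchmarkReport"))
  tp <- report@tp
  tp$truth_id <- NULL
  tp$distance <- NULL
  paths <- c(tp = paste0(prefix, ".tp.vcf"), fp = paste0(prefix, ".fp.vcf"),
             fn = paste0(prefix, ".fn.vcf"),
             stats = paste0(prefix, ".stats.json"))
  writeSVVcf(makeSVRecords(tp), paths[["tp"]])
  writeSVVcf(makeSVRecords(report@fp), paths[["fp"]])
  writeSVVcf(makeSVRecords(report@fn), paths[["fn"]])
  m <- report@metrics
  per_type <- lapply(split(m[m$svtype != "overall", ], m$svtype[m$svtype != "overall"]),
    function(r) list(tp = r$tp, fp = r$fp, fn = r$fn, precision = r$precision,
                     recall = r$recall, f1 = r$f1))
  ov <- m[m$svtype == "overall", ]
  stats <- list(
    schema = "svmeld-benchmark-1.0",
    parameters = report@params,
    overall = list(tp = ov$tp, fp = ov$fp, fn = ov$fn,
                   precision = ov$precision, recall = ov$recall, f1 = ov$f1),
    per_type = per_type)
  jsonlite::write_json(stats, paths[["stats"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
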