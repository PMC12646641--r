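#' Access the record table of a callset
#' @param x an [SVCallSet-class] (or subclass), [CorrectionResult-class] or
#'   [BenchmarkReport-class]
#' @return data.frame of normalized SV records.
#' @export
setGeneric("svRecords", function(x) standardGeneric("svRecords"))

#' Number of SV records
#' @param x an [SVCallSet-class]
#' @return integer count.
#' @export
setGeneric("nSV", function(x) standardGeneric("nSV"))

#' Rejected input lines of a callset
#' @param x an [SVCallSet-class]
#' @return data.frame with columns `line`, `id`, `reason`.
#' @export
setGeneric("svRejects", function(x) standardGeneric("svRejects"))

#' Audit trail of a breakend correction
#' @param x a [CorrectionResult-class]
#' @return data.frame accounting for every input record.
#' @export
setGeneric("svAudit", function(x) standardGeneric("svAudit"))

#' Canonical records produced by breakend correction
#' @param x a [CorrectionResult-class]
#' @return data.frame of records converted from BND to a canonical type.
#' @export
setGeneric("correctedRecords", function(x) standardGeneric("correctedRecords"))

#' Breakends retained after correction
#' @param x a [CorrectionResult-class]
#' @return data.frame of records kept in BND form.
#' @export
setGeneric("retainedBnd", function(x) standardGeneric("retainedBnd"))

#' Member records of each consensus SV
#' @param x a [MergedSVSet-class]
#' @return list of data.frames.
#' @export
setGeneric("svMembers", function(x) standardGeneric("svMembers"))

#' Supporting-caller sets of a merged callset
#' @param x a [MergedSVSet-class]
#' @return list of character vectors.
#' @export
setGeneric("svSupport", function(x) standardGeneric("svSupport"))

#' Precision/recall/F1 table of a benchmark report
#' @param x a [BenchmarkReport-class]
#' @return data.frame with per-type and overall rows.
#' @export
setGeneric("svMetrics", function(x) standardGeneric("svMetrics"))

#' @rdname svRecords
#' @export
setMethod("svRecords", "SVCallSet", function(x) x@records)
#' @rdname svRecords
#' @export
setMethod("svRecords", "CorrectionResult", function(x) x@callset@records)
#' @rdname nSV
#' @export
setMethod("nSV", "SVCallSet", function(x) nrow(x@records))
#' @rdname svRejects
#' @export
setMethod("svRejects", "SVCallSet", function(x) x@rejects)
#' @rdname svAudit
#' @export
setMethod("svAudit", "CorrectionResult", function(x) x@audit)
#' @rdname correctedRecords
#' @export
setMethod("correctedRecords", "CorrectionResult", function(x) {
  ids <- x@audit$output_id[x@audit$disposition == "converted"]
  rec <- x@callset@records
  rec[rec$record_id %in% ids, , drop = FALSE]
})
#' @rdname retainedBnd
#' @export
setMethod("retainedBnd", "CorrectionResult", function(x) {
  rec <- x@callset@records
  rec[rec$svtype == "BND", , drop = FALSE]
})
#' @rdname svMembers
#' @export
setMethod("svMembers", "MergedSVSet", function(x) x@members)
#' @rdname svSupport
#' @export
setMethod("svSupport", "MergedSVSet", function(x)
  strsplit(x@records$support, ",", fixed = TRUE))
#' @rdname svMetrics
#' @export
setMethod("svMetrics", "BenchmarkReport", function(x) x@metrics)

setMethod("show", "SVCallSet", function(object) {
  rec <- object@records
  cat(sprintf("%s with %d SV record(s)\n", class(object), nrow(rec)))
  if (nrow(rec)) {
    tab <- table(factor(rec$svtype, levels = .SVTYPES))
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  callers:", paste(unique(rec$source_caller), collapse = ", "), "\n")
  }
  if (nrow(object@rejects))
    cat(sprintf("  %d rejected input line(s)\n", nrow(object@rejects)))
})

setMethod("show", "MergedSVSet", function(object) {
  callNextMethod()
  if (nrow(object@records)) {
    cat("  support counts:",
        paste(sprintf("%s caller(s): %d",
                      names(table(object@records$support_count)),
                      table(object@records$support_count)), collapse = "; "), "\n")
  }
})

setMethod("show", "CorrectionResult", function(object) {
  a <- object@audit
  cat(sprintf("CorrectionResult: %d input record(s); %d converted, %d retained BND, %d pass-through\n",
              nrow(a), sum(a$disposition == "converted"),
              sum(a$disposition == "retained"),
              sum(a$disposition == "passthrough")))
})

setMethod("show", "BenchmarkReport", function(object) {
  m <- object@metrics[object@metrics$svtype == "overall", ]
  cat(sprintf("BenchmarkReport: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              m$tp, m$fp, m$fn, m$precision, m$recall, m$f1))
})
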