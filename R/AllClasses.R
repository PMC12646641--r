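#' SVCallSet: a normalized structural-variant callset
#'
#' Container for an ordered collection of normalized SV records as produced
#' by [readSVVcf()], the breakend corrector or the synthetic generator.
#' One row of `svRecords(x)` corresponds to one SV call: canonical types
#' DEL/INS/INV/DUP, translocations (TRA, two breakpoints in `chrom`/`pos`
#' and `chrom2`/`pos2`) or unresolved breakends (BND). Coordinates are
#' 1-based and fully closed, exactly as VCF prints them.
#'
#' @slot records data.frame with one row per SV call (fixed column schema).
#' @slot sampleNames character, sample columns of the originating VCF.
#' @slot rejects data.frame of body lines that could not be normalized,
#'   with columns `line`, `id` and `reason`.
#' @slot metadata list of free-form provenance (paths, parameters, seed).
#'
#' @aliases SVCallSet-class
#' @exportClass SVCallSet
setClass("SVCallSet",
  representation(records = "data.frame", sampleNames = "character",
                 rejects = "data.frame", metadata = "list"),
  prototype(records = data.frame(), sampleNames = character(),
            rejects = data.frame(line = integer(), id = character(),
                                 reason = character()),
            metadata = list()))

.validSVRecords <- function(rec) {
  msgs <- character()
  need <- setdiff(names(.REC_COLS), names(rec))
  if (length(need)) return(paste("missing record columns:", paste(need, collapse = ", ")))
  if (!nrow(rec)) return(TRUE)
  bad <- !rec$svtype %in% .SVTYPES
  if (any(bad)) msgs <- c(msgs, sprintf("invalid svtype: %s",
    paste(unique(rec$svtype[bad]), collapse = ", ")))
  if (any(rec$pos < 1L, na.rm = TRUE)) msgs <- c(msgs, "pos must be >= 1")
  intra <- rec$svtype %in% c("DEL", "INS", "INV", "DUP")
  if (any(intra & !is.na(rec$end) & rec$end < rec$pos))
    msgs <- c(msgs, "end < pos on a non-translocation record")
  two_bp <- rec$svtype %in% c("TRA", "BND")
  if (any(two_bp & (is.na(rec$chrom2) | is.na(rec$pos2))))
    msgs <- c(msgs, "TRA/BND record lacks chrom2/pos2")
  if (any(!two_bp & (!is.na(rec$chrom2) | !is.na(rec$pos2))))
    msgs <- c(msgs, "chrom2/pos2 set on a non-TRA/BND record")
  span <- rec$svtype %in% c("DEL", "DUP", "INV")
  chk <- which(span & !is.na(rec$end) & !is.na(rec$svlen))
  if (any(abs(rec$svlen[chk]) != rec$end[chk] - rec$pos[chk]))
    msgs <- c(msgs, "|svlen| != end - pos on a DEL/DUP/INV record")
  neg_ad <- (!is.na(rec$ad_ref) & rec$ad_ref < 0L) | (!is.na(rec$ad_alt) & rec$ad_alt < 0L)
  if (any(neg_ad)) msgs <- c(msgs, "negative allele depth")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}

setValidity("SVCallSet", function(object) .validSVRecords(object@records))

#' MergedSVSet: consensus SVs after multi-caller merging
#'
#' Extends [SVCallSet-class]. Each row of `svRecords(x)` is a consensus SV
#' whose representative fields come from the best-quality member; the member
#' records and the supporting-caller set are retained.
#'
#' @slot members list of data.frames, the member records of each consensus SV.
#' @slot callers character, all caller slots in input order.
#'
#' @aliases MergedSVSet-class
#' @exportClass MergedSVSet
setClass("MergedSVSet", contains = "SVCallSet",
  representation(members = "list", callers = "character"),
  prototype(members = list(), callers = character()))

setValidity("MergedSVSet", function(object) {
  rec <- object@records
  if (length(object@members) != nrow(rec))
    return("one member table required per merged record")
  sup <- strsplit(rec$support, ",", fixed = TRUE)
  if (nrow(rec) && !all(lengths(sup) == rec$support_count))
    return("support_count disagrees with support set")
  TRUE
})

#' CorrectionResult: outcome of breakend standardization
#'
#' @slot callset [SVCallSet-class] holding pass-through records, converted
#'   canonical records and retained BNDs, in that order.
#' @slot audit data.frame accounting for every input record: columns
#'   `input_id`, `input_svtype`, `disposition` (passthrough/converted/
#'   retained/rejected), `rule`, `evidence`, `output_id`.
#' @slot tolerance numeric, mate-pairing tolerance (bp) used.
#'
#' @aliases CorrectionResult-class
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  representation(callset = "SVCallSet", audit = "data.frame",
                 tolerance = "numeric"))

setValidity("CorrectionResult", function(object) {
  a <- object@audit
  need <- c("input_id", "input_svtype", "disposition", "rule", "evidence", "output_id")
  if (!all(need %in% names(a))) return("audit table lacks required columns")
  if (anyDuplicated(a$input_id)) return("audit must mention each input exactly once")
  TRUE
})

#' BenchmarkReport: callset-vs-truth evaluation
#'
#' @slot tp data.frame of matched calls with `truth_id` and `distance` columns.
#' @slot fp data.frame of unmatched calls.
#' @slot fn data.frame of unmatched truth records.
#' @slot metrics data.frame with one row per SV type plus an `overall` row:
#'   columns `svtype`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @slot params list echoing the matching parameters.
#'
#' @aliases BenchmarkReport-class
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  representation(tp = "data.frame", fp = "data.frame", fn = "data.frame",
                 metrics = "data.frame", params = "list"))

#' Construct an SVCallSet from a record table
#'
#' @param records data.frame in the package record schema (missing columns
#'   are filled with typed defaults, see [makeSVRecords()]).
#' @param sampleNames character vector of sample names.
#' @param rejects data.frame of rejected input lines.
#' @param metadata list of provenance.
#' @return An [SVCallSet-class].
#' @export
SVCallSet <- function(records = emptySVRecords(), sampleNames = character(),
                      rejects = NULL, metadata = list()) {
  records <- makeSVRecords(records)
  if (is.null(rejects))
    rejects <- data.frame(line = integer(), id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  new("SVCallSet", records = records, sampleNames = sampleNames,
      rejects = rejects, metadata = metadata)
}
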