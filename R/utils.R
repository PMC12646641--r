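`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rbinom setNames
#' @importFrom utils head read.table write.table
NULL

.stopValidation <- function(msg, ...) {
  stop(structure(class = c("svmeld_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.stopIO <- function(msg, ...) {
  stop(structure(class = c("svmeld_io_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

## Column schema of the normalized SV record table. One row per SV call.
## geno_raw preserves the original FORMAT + per-sample strings verbatim so
## VCF round trips are lossless even for tags the model does not interpret.
.REC_COLS <- c(
  record_id = "character", chrom = "character", pos = "integer",
  end = "integer", svtype = "character", svlen = "integer",
  chrom2 = "character", pos2 = "integer", strands = "character",
  ref = "character", alt = "character", qual = "numeric",
  filter = "character", info = "character", subtype = "character",
  gt = "character", ad_ref = "integer", ad_alt = "integer",
  dp = "integer", gq = "numeric", geno_raw = "character",
  source_caller = "character", source_file = "character",
  support = "character", support_count = "integer")

.SVTYPES <- c("DEL", "INS", "INV", "DUP", "TRA", "BND")

#' Empty SV record table
#' @return zero-row data.frame in the package record schema.
#' @export
emptySVRecords <- function() {
  cols <- lapply(.REC_COLS, function(t) vector(t, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Build an SV record table
#'
#' Assembles a record data.frame in the package schema from whatever
#' columns are supplied (recycled to a common length); the rest are filled
#' with typed defaults (`filter = "PASS"`, `gt = "./."`, `strands = "."`,
#' `support` = the source caller, symbolic ALT from `svtype`). Used by the
#' readers, the synthetic generator and tests.
#'
#' @param ... named record columns, or a single data.frame.
#' @return data.frame with the full record schema.
#' @export
makeSVRecords <- function(...) {
  given <- list(...)
  if (length(given) == 1L && is.data.frame(given[[1L]])) given <- as.list(given[[1L]])
  n <- if (length(given)) max(lengths(given)) else 0L
  out <- vector("list", length(.REC_COLS))
  names(out) <- names(.REC_COLS)
  for (col in names(.REC_COLS)) {
    ty <- .REC_COLS[[col]]
    v <- given[[col]]
    if (is.null(v)) {
      v <- rep(as.vector(NA, mode = ty), n)
    } else {
      v <- rep_len(v, n)
      storage.mode(v) <- ty
    }
    out[[col]] <- v
  }
  df <- list2DF(out)
  ## defaults for fields that are structural rather than optional
  if (n > 0L) {
    if (all(is.na(df$strands))) df$strands <- rep(".", n) else df$strands[is.na(df$strands)] <- "."
    df$ref[is.na(df$ref)] <- "N"
    df$filter[is.na(df$filter)] <- "PASS"
    df$info[is.na(df$info)] <- "."
    df$gt[is.na(df$gt)] <- "./."
    if (all(is.na(df$record_id))) df$record_id <- sprintf("sv_%d", seq_len(n))
    df$source_caller[is.na(df$source_caller)] <- "unknown"
    df$source_file[is.na(df$source_file)] <- "."
    miss_sup <- is.na(df$support)
    df$support[miss_sup] <- df$source_caller[miss_sup]
    df$support_count[is.na(df$support_count)] <- 1L
    if (all(is.na(df$alt))) df$alt <- paste0("<", df$svtype, ">")
  }
  rownames(df) <- NULL
  df
}

## normalize a genotype token: phased -> unphased, alleles sorted, "." kept
.normGT <- function(gt) {
  gt[is.na(gt) | gt == ""] <- "./."
  vapply(gt, function(g) {
    parts <- strsplit(g, "[/|]")[[1L]]
    if (length(parts) != 2L) return(g)
    suppressWarnings(num <- as.integer(parts))
    if (any(is.na(num) & parts != ".")) return(g)
    ord <- order(is.na(num), num)
    paste(parts[ord], collapse = "/")
  }, character(1L), USE.NAMES = FALSE)
}

.fmtNum <- function(x) {
  ifelse(is.na(x), ".", sub("\\.?0+$", "", sprintf("%.6f", x)))
}

.fmtInt <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Closed-interval Jaccard index
#'
#' Intersection length over union length of `[p1, e1]` and `[p2, e2]`,
#' both closed 1-based intervals.
#'
#' @param p1,e1,p2,e2 interval bounds (vectorized).
#' @return numeric in \[0, 1\].
#' @export
intervalJaccard <- function(p1, e1, p2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(p1, p2) + 1)
  uni <- (e1 - p1 + 1) + (e2 - p2 + 1) - inter
  ifelse(uni <= 0, 0, inter / uni)
}
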