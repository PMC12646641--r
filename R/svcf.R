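## SVCF: the package's tab-separated intermediate serialization of
## normalized SV records. One row per record, lossless with respect to the
## record model (including caller-support annotations added by merging).
## Layout: a version stamp line, a column header line, then data rows;
## missing values are ".". Sample FORMAT data, when present, travels in the
## GENO_RAW column with tabs escaped as "%09".

.SVCF_VERSION <- "svmeldSVCF-1.0"
.SVCF_COLS <- c("ID", "CHROM", "POS", "END", "SVTYPE", "SVLEN", "CHROM2",
                "POS2", "STRANDS", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "SUBTYPE", "GT", "AD_REF", "AD_ALT", "DP", "GQ", "GENO_RAW",
                "CALLER", "SOURCE", "SUPPORT", "SUPPORT_COUNT")

#' Write records to the SVCF tabular format
#'
#' @param x an [SVCallSet-class] (or subclass) or record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readSvcf()]
#' @export
writeSvcf <- function(x, path) {
  rec <- if (is(x, "SVCallSet")) x@records else makeSVRecords(x)
  samples <- if (is(x, "SVCallSet")) x@sampleNames else character()
  esc <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "."
    gsub("\t", "%09", v, fixed = TRUE)
  }
  rows <- cbind(esc(rec$record_id), esc(rec$chrom), esc(rec$pos), esc(rec$end),
                esc(rec$svtype), esc(rec$svlen), esc(rec$chrom2), esc(rec$pos2),
                esc(rec$strands), esc(rec$ref), esc(rec$alt),
                ifelse(is.na(rec$qual), ".", .fmtNum(rec$qual)),
                esc(rec$filter), esc(rec$info), esc(rec$subtype), esc(rec$gt),
                esc(rec$ad_ref), esc(rec$ad_alt), esc(rec$dp),
                ifelse(is.na(rec$gq), ".", .fmtNum(rec$gq)),
                esc(rec$geno_raw), esc(rec$source_caller), esc(rec$source_file),
                esc(rec$support), esc(rec$support_count))
  lines <- c(paste0("##", .SVCF_VERSION),
             if (length(samples)) paste0("##samples=", paste(samples, collapse = ",")),
             paste0("#", paste(.SVCF_COLS, collapse = "\t")),
             if (nrow(rec)) apply(rows, 1L, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopIO("cannot write SVCF to %s", path)
  invisible(path)
}

#' Read an SVCF file
#'
#' @param path path to an SVCF file written by [writeSvcf()].
#' @return An [SVCallSet-class] with the serialized records; `readSvcf()`
#'   after [writeSvcf()] is the identity on the record table.
#' @export
readSvcf <- function(path) {
  if (!file.exists(path)) .stopIO("SVCF file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !identical(lines[1L], paste0("##", .SVCF_VERSION)))
    .stopValidation("unsupported SVCF version stamp in %s (expected %s)",
                    path, .SVCF_VERSION)
  samples <- character()
  body_at <- 2L
  while (body_at <= length(lines) && startsWith(lines[body_at], "##")) {
    if (startsWith(lines[body_at], "##samples="))
      samples <- strsplit(sub("^##samples=", "", lines[body_at]), ",")[[1L]]
    body_at <- body_at + 1L
  }
  if (body_at > length(lines) ||
      !identical(lines[body_at], paste0("#", paste(.SVCF_COLS, collapse = "\t"))))
    .stopValidation("malformed SVCF column header in %s", path)
  body <- lines[-seq_len(body_at)]
  if (!length(body))
    return(SVCallSet(sampleNames = samples, metadata = list(path = path)))
  cells <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  if (ncol(cells) != length(.SVCF_COLS))
    .stopValidation("SVCF row with %d columns (expected %d) in %s",
                    ncol(cells), length(.SVCF_COLS), path)
  unesc <- function(v) gsub("%09", "\t", v, fixed = TRUE)
  ## "." is a real value for text fields like FILTER/INFO/STRANDS; only
  ## optional fields map "." back to NA
  cl <- function(i) unesc(cells[, i])
  opt <- function(i) { v <- cl(i); v[v == "."] <- NA_character_; v }
  rec <- makeSVRecords(
    record_id = cl(1), chrom = cl(2), pos = as.integer(opt(3)),
    end = as.integer(opt(4)), svtype = cl(5), svlen = as.integer(opt(6)),
    chrom2 = opt(7), pos2 = as.integer(opt(8)), strands = cl(9), ref = cl(10),
    alt = cl(11), qual = as.numeric(opt(12)), filter = cl(13), info = cl(14),
    subtype = opt(15), gt = cl(16), ad_ref = as.integer(opt(17)),
    ad_alt = as.integer(opt(18)), dp = as.integer(opt(19)),
    gq = as.numeric(opt(20)), geno_raw = opt(21), source_caller = cl(22),
    source_file = cl(23), support = cl(24), support_count = as.integer(opt(25)))
  SVCallSet(records = rec, sampleNames = samples, metadata = list(path = path))
}
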