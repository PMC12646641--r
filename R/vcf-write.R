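#' Write a normalized callset back to VCF
#'
#' Emits standard-compliant VCFv4.2 with header lines declaring every INFO
#' and FORMAT tag the writer produces. Translocations are written with a
#' symbolic `<TRA>` ALT carrying both breakpoints via `CHR2`/`POS2` INFO
#' tags; breakends keep their original bracket ALT. Records that were read
#' from a VCF carry their original FORMAT/sample columns verbatim; records
#' built in code get a `GT:AD:DP:GQ` column per sample.
#'
#' @param x an [SVCallSet-class] (or subclass) or a record data.frame.
#' @param path output file path.
#' @param sampleNames ordered sample names; defaults to the callset's.
#' @param fileDate logical, write a `##fileDate` header line (off by default
#'   so identical inputs give byte-identical outputs).
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(x, path, sampleNames = NULL, fileDate = FALSE) {
  rec <- if (is(x, "SVCallSet")) x@records else makeSVRecords(x)
  if (is.null(sampleNames))
    sampleNames <- if (is(x, "SVCallSet") && length(x@sampleNames))
      x@sampleNames else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (fileDate) format(Sys.Date(), "##fileDate=%Y%m%d"),
    sprintf("##source=svmeld-%s", as.character(utils::packageVersion("svmeld"))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of the second breakpoint\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Position of the second breakpoint\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakpoint strand orientation\">",
    "##INFO=<ID=SUBTYPE,Number=1,Type=String,Description=\"Translocation subtype (balanced/unbalanced/merging)\">",
    "##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,Description=\"Comma-separated supporting callers\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Number of supporting callers\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t"))
  lines <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) lines[i] <- .vcfLine(rec[i, ], sampleNames)
  ok <- tryCatch({
    writeLines(c(hdr, lines), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopIO("cannot write VCF to %s", path)
  invisible(path)
}

.vcfInfoString <- function(r) {
  parts <- c(sprintf("SVTYPE=%s", r$svtype))
  if (r$svtype %in% c("TRA", "BND")) {
    parts <- c(parts, sprintf("CHR2=%s", r$chrom2), sprintf("POS2=%d", r$pos2))
  } else {
    parts <- c(parts, sprintf("END=%d", r$end))
    if (!is.na(r$svlen)) parts <- c(parts, sprintf("SVLEN=%d", r$svlen))
  }
  if (!is.na(r$strands) && r$strands != ".")
    parts <- c(parts, sprintf("STRANDS=%s", r$strands))
  if (!is.na(r$subtype)) parts <- c(parts, sprintf("SUBTYPE=%s", r$subtype))
  if (!is.na(r$support)) parts <- c(parts, sprintf("SUPP_CALLERS=%s", r$support))
  if (!is.na(r$support_count)) parts <- c(parts, sprintf("SUPP=%d", r$support_count))
  if (!is.na(r$info) && r$info != ".") parts <- c(parts, r$info)
  paste(parts, collapse = ";")
}

.vcfLine <- function(r, sampleNames) {
  alt <- r$alt
  if (is.na(alt)) alt <- paste0("<", r$svtype, ">")
  geno <- if (!is.na(r$geno_raw)) {
    r$geno_raw
  } else {
    ad <- if (is.na(r$ad_ref) && is.na(r$ad_alt)) "." else
      paste0(.fmtInt(r$ad_ref), ",", .fmtInt(r$ad_alt))
    cell <- paste(r$gt, ad, .fmtInt(r$dp), .fmtInt(as.integer(r$gq)), sep = ":")
    paste(c("GT:AD:DP:GQ", rep(cell, length(sampleNames))), collapse = "\t")
  }
  paste(r$chrom, r$pos, r$record_id, r$ref, alt, .fmtNum(r$qual),
        r$filter, .vcfInfoString(r), geno, sep = "\t")
}
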