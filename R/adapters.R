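## Per-caller dialect adapters. SV callers agree on the VCF grammar but not
## on where they put second breakpoints, strands or supporting-read counts;
## each adapter says where to look. Unknown callers fall back to "generic",
## which tries the common conventions in a fixed order.

.ADAPTERS <- list(
  generic = list(
    support_tags = c("SUPPORT", "RE", "SR", "DV"),
    tra_pos2_from_end = TRUE,   # use END as POS2 when CHR2 present, POS2 absent
    strands_tags = c("STRANDS", "CT")),
  delly = list(
    # DELLY encodes the partner breakpoint of a BND/TRA as CHR2 + END and
    # orientation as CT=<3to5|5to3|3to3|5to5>
    support_tags = c("DV", "RV", "SR", "PE"),
    tra_pos2_from_end = TRUE,
    strands_tags = "CT"),
  lumpy = list(
    # LUMPY appends evidence counts to STRANDS, e.g. "STRANDS=+-:6"
    support_tags = c("SU", "PE", "SR"),
    tra_pos2_from_end = TRUE,
    strands_tags = "STRANDS"),
  sniffles = list(
    support_tags = c("SUPPORT", "RE"),
    tra_pos2_from_end = TRUE,
    strands_tags = "STRANDS"),
  svim = list(
    support_tags = "SUPPORT",
    tra_pos2_from_end = TRUE,
    strands_tags = "STRANDS"),
  cutesv = list(
    support_tags = "RE",
    tra_pos2_from_end = TRUE,
    strands_tags = "STRAND"),
  manta = list(
    support_tags = c("SR", "PR"),
    tra_pos2_from_end = TRUE,
    strands_tags = "STRANDS"),
  svaba = list(
    support_tags = c("SR", "DR", "AD"),
    tra_pos2_from_end = TRUE,
    strands_tags = "STRANDS"))

callerAdapter <- function(caller) {
  key <- tolower(caller %||% "generic")
  .ADAPTERS[[key]] %||% .ADAPTERS$generic
}

## get one tag's value out of a raw INFO string (NA when absent)
.infoGet <- function(info, tag) {
  pat <- paste0("(?:^|;)", tag, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  ok <- !is.na(info) & m != -1L
  if (any(ok)) {
    s <- regmatches(info, m)
    s <- sub(paste0("^;?", tag, "="), "", s)
    out[ok] <- s
  }
  out
}

## drop consumed tags from INFO, keep everything else verbatim (order kept)
.infoResidual <- function(info, tags) {
  vapply(info, function(s) {
    if (is.na(s) || s == "." || s == "") return(".")
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    keys <- sub("=.*$", "", parts)
    keep <- parts[!(keys %in% tags)]
    if (!length(keep)) "." else paste(keep, collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
}

## normalize a raw strand annotation to "++"/"+-"/"-+"/"--" or "."
.normStrands <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || s == "" || s == ".") return(".")
    s1 <- strsplit(s, ",", fixed = TRUE)[[1L]][1L]
    if (grepl("^[+-][+-]", s1)) return(substr(s1, 1L, 2L))
    switch(s1, "3to5" = "+-", "5to3" = "-+", "3to3" = "++", "5to5" = "--", ".")
  }, character(1L), USE.NAMES = FALSE)
}

## normalize an SVTYPE token (subtype suffixes, translocation synonyms)
.normSVType <- function(x) {
  x <- toupper(sub(":.*$", "", x))
  x[x %in% c("CTX", "TRX", "TRANS")] <- "TRA"
  x
}
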