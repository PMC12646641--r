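#' Read an SV caller VCF into a normalized callset
#'
#' Parses a VCF (plain or gzipped) produced by a structural-variant caller
#' and normalizes every body line into one record per ALT allele. Symbolic
#' ALTs map through the INFO `SVTYPE` tag (falling back to the ALT symbol);
#' breakend ALTs in bracket notation become `svtype = "BND"` with the mate
#' breakpoint in `chrom2`/`pos2`. Caller-specific conventions (second
#' breakpoint in `CHR2`+`END`, strand tags, supporting-read tags used when
#' `AD` is absent) are handled by a per-caller adapter table with a generic
#' fallback.
#'
#' Missing `SVLEN` for DEL/DUP/INV is derived from `END - POS` and missing
#' `END` from `POS + |SVLEN|`; records where both are missing are rejected
#' with a reason (see [svRejects()]), and parsing continues.
#'
#' @param path path to a VCF file.
#' @param caller caller identifier used for provenance and dialect lookup.
#' @param dialect adapter key, defaults to `caller`.
#' @return An [SVCallSet-class]; rejected lines are reported via
#'   [svRejects()].
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'   "chr1\t1000\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000"), vcf)
#' cs <- readSVVcf(vcf, caller = "manta")
#' svRecords(cs)[, c("svtype", "pos", "end", "svlen")]
#' @export
readSVVcf <- function(path, caller = "unknown", dialect = caller) {
  if (!file.exists(path)) .stopIO("VCF file not found: %s", path)
  .checkVcfHeader(path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) .stopIO("cannot parse VCF %s: %s",
                                            path, conditionMessage(e)))
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || length(dim(gt)) != 2L || ncol(gt) < 2L ||
      nrow(gt) != nrow(fix)) gt <- NULL
  samples <- if (!is.null(gt)) colnames(gt)[-1L] else character()
  if (is.null(fix) || nrow(fix) == 0L)
    return(SVCallSet(sampleNames = samples,
                     metadata = list(path = path, caller = caller)))
  adapter <- callerAdapter(dialect)

  rec <- list()
  rejects <- list()
  n <- nrow(fix)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%d", caller, which(is.na(ids) | ids == "."))
  ids <- make.unique(ids, sep = "_")

  for (i in seq_len(n)) {
    info <- fix[i, "INFO"]
    if (is.na(info)) info <- "."
    alts <- strsplit(fix[i, "ALT"] %||% ".", ",", fixed = TRUE)[[1L]]
    svlen_raw <- strsplit(.infoGet(info, "SVLEN") %||% NA_character_, ",")[[1L]]
    for (k in seq_along(alts)) {
      rid <- if (length(alts) > 1L) sprintf("%s_%d", ids[i], k) else ids[i]
      slen <- if (k <= length(svlen_raw)) svlen_raw[k] else svlen_raw[1L]
      parsed <- .parseBodyLine(
        chrom = fix[i, "CHROM"], pos = fix[i, "POS"], id = rid,
        ref = fix[i, "REF"], alt = alts[k], qual = fix[i, "QUAL"],
        filter = fix[i, "FILTER"], info = info, svlen_raw = slen,
        geno = if (!is.null(gt)) gt[i, , drop = TRUE] else NULL,
        adapter = adapter, caller = caller, path = path)
      if (is.character(parsed)) {
        rejects[[length(rejects) + 1L]] <-
          data.frame(line = i, id = rid, reason = parsed,
                     stringsAsFactors = FALSE)
      } else {
        rec[[length(rec) + 1L]] <- parsed
      }
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else emptySVRecords()
  rejects <- if (length(rejects)) do.call(rbind, rejects) else NULL
  SVCallSet(records = records, sampleNames = samples, rejects = rejects,
            metadata = list(path = path, caller = caller))
}

.checkVcfHeader <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first) || !grepl("^##fileformat=VCF", first))
    .stopIO("malformed VCF header at line 1 of %s: expected ##fileformat", path)
  lineno <- 1L
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) .stopIO("malformed VCF %s: no #CHROM header line", path)
    lineno <- lineno + 1L
    if (grepl("^#CHROM\t", l) || l == "#CHROM") return(invisible(TRUE))
    if (!grepl("^##", l))
      .stopIO("malformed VCF header at line %d of %s", lineno, path)
  }
}

## Normalize one body line (one ALT) into a one-row record data.frame,
## or return a character reason to reject it.
.parseBodyLine <- function(chrom, pos, id, ref, alt, qual, filter, info,
                           svlen_raw, geno, adapter, caller, path) {
  pos <- suppressWarnings(as.integer(pos))
  if (is.na(pos) || pos < 1L) return("unresolvable POS")
  if (is.na(alt)) alt <- "."
  is_bracket <- grepl("[][][A-Za-z0-9_.]+:[0-9]+[][]", alt)

  svtype <- .infoGet(info, "SVTYPE")
  if (is.na(svtype)) {
    if (grepl("^<.+>$", alt)) svtype <- gsub("[<>]", "", alt)
    else if (is_bracket) svtype <- "BND"
    else if (!is.na(ref) && nzchar(ref) && grepl("^[ACGTNacgtn]+$", alt)) {
      d <- nchar(alt) - nchar(ref)
      if (d > 0) svtype <- "INS" else if (d < 0) svtype <- "DEL"
      else return("cannot determine SVTYPE")
    } else return("cannot determine SVTYPE")
  }
  svtype <- .normSVType(svtype)
  if (!svtype %in% .SVTYPES) return(sprintf("unsupported SVTYPE '%s'", svtype))

  end <- suppressWarnings(as.integer(.infoGet(info, "END")))
  svlen <- suppressWarnings(as.integer(svlen_raw))
  chr2 <- .infoGet(info, "CHR2")
  pos2 <- suppressWarnings(as.integer(.infoGet(info, "POS2")))

  strands <- "."
  for (tag in adapter$strands_tags) {
    s <- .normStrands(.infoGet(info, tag))
    if (s != ".") { strands <- s; break }
  }

  if (svtype == "BND") {
    if (is_bracket) {
      bh <- parseBreakend(alt, chrom, pos)
      chr2 <- bh$mate_chrom
      pos2 <- bh$mate_pos
      if (strands == ".") strands <- bh$strands
    } else {
      if (is.na(chr2)) return("BND without parseable ALT or CHR2/POS2")
      if (is.na(pos2)) pos2 <- if (adapter$tra_pos2_from_end) end else NA_integer_
      if (is.na(pos2)) return("BND without parseable ALT or CHR2/POS2")
    }
    end <- pos
    svlen <- NA_integer_
  } else if (svtype == "TRA") {
    if (is.na(chr2)) return("TRA without CHR2")
    if (is.na(pos2) && adapter$tra_pos2_from_end) pos2 <- end
    if (is.na(pos2)) return("TRA without POS2/END")
    end <- pos
    svlen <- NA_integer_
    ## canonical breakpoint order: (chrom,pos) lexicographically first
    if (chr2 < chrom || (chr2 == chrom && pos2 < pos)) {
      tmp <- chrom; chrom <- chr2; chr2 <- tmp
      tmp <- pos; pos <- pos2; pos2 <- tmp
      if (strands != ".") strands <- paste0(substr(strands, 2, 2),
                                            substr(strands, 1, 1))
    }
  } else if (svtype == "INS") {
    if (is.na(end)) end <- pos
    if (!is.na(svlen)) svlen <- abs(svlen)
    chr2 <- NA_character_; pos2 <- NA_integer_
  } else { # DEL / DUP / INV
    if (is.na(end) && is.na(svlen)) return("neither END nor SVLEN present")
    if (is.na(end)) end <- pos + abs(svlen)
    if (is.na(svlen)) svlen <- end - pos
    if (end < pos) return("END < POS")
    svlen <- abs(svlen)
    if (svlen != end - pos) svlen <- end - pos  # END wins on disagreement
    if (svtype == "DEL") svlen <- -svlen
    chr2 <- NA_character_; pos2 <- NA_integer_
  }

  subtype <- .infoGet(info, "SUBTYPE")
  support <- .infoGet(info, "SUPP_CALLERS")
  supp_n <- suppressWarnings(as.integer(.infoGet(info, "SUPP")))

  g <- .parseGenotype(geno, info, adapter)
  consumed <- c("SVTYPE", "END", "SVLEN", "CHR2", "POS2", "STRANDS", "CT",
                "SUBTYPE", "SUPP_CALLERS", "SUPP")
  makeSVRecords(
    record_id = id, chrom = chrom, pos = pos, end = end, svtype = svtype,
    svlen = svlen, chrom2 = chr2, pos2 = pos2, strands = strands,
    ref = ref %||% "N", alt = alt,
    qual = suppressWarnings(as.numeric(qual)),
    filter = ifelse(is.na(filter) | filter == "", ".", filter),
    info = .infoResidual(info, consumed), subtype = subtype,
    gt = g$gt, ad_ref = g$ad_ref, ad_alt = g$ad_alt, dp = g$dp, gq = g$gq,
    geno_raw = g$raw, source_caller = caller, source_file = path,
    support = support, support_count = supp_n)
}

## first-sample FORMAT fields; AD falls back to the adapter's INFO tags
.parseGenotype <- function(geno, info, adapter) {
  out <- list(gt = "./.", ad_ref = NA_integer_, ad_alt = NA_integer_,
              dp = NA_integer_, gq = NA_real_, raw = NA_character_)
  if (!is.null(geno) && length(geno) >= 2L && !is.na(geno[[1L]])) {
    fmt <- strsplit(geno[[1L]], ":", fixed = TRUE)[[1L]]
    smp <- strsplit(geno[[2L]] %||% ".", ":", fixed = TRUE)[[1L]]
    val <- function(tag) {
      j <- match(tag, fmt)
      if (is.na(j) || j > length(smp)) NA_character_ else smp[j]
    }
    out$raw <- paste(unlist(geno), collapse = "\t")
    out$gt <- .normGT(val("GT"))
    ad <- val("AD")
    if (!is.na(ad) && grepl(",", ad)) {
      adp <- suppressWarnings(as.integer(strsplit(ad, ",")[[1L]]))
      out$ad_ref <- adp[1L]
      out$ad_alt <- adp[2L]
    }
    out$dp <- suppressWarnings(as.integer(val("DP")))
    out$gq <- suppressWarnings(as.numeric(val("GQ")))
  }
  if (is.na(out$ad_alt)) {
    for (tag in adapter$support_tags) {
      s <- suppressWarnings(as.integer(.infoGet(info, tag)))
      if (!is.na(s)) { out$ad_alt <- s; break }
    }
  }
  ## if the sample column is exactly what the writer would synthesize from
  ## the parsed fields, drop the raw copy so write/read is a fixed point
  if (!is.na(out$raw) && !is.null(geno) && length(geno) == 2L) {
    ad <- if (is.na(out$ad_ref) && is.na(out$ad_alt)) "." else
      paste0(.fmtInt(out$ad_ref), ",", .fmtInt(out$ad_alt))
    cell <- paste(out$gt, ad, .fmtInt(out$dp),
                  .fmtInt(suppressWarnings(as.integer(out$gq))), sep = ":")
    if (identical(out$raw, paste("GT:AD:DP:GQ", cell, sep = "\t")))
      out$raw <- NA_character_
  }
  out
}
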