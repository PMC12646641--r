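## Hierarchical BND standardization: route breakends by chromosomal
## context, pair mates, then classify junction topology into canonical SV
## types, retaining anything ambiguous in BND form.

.MIN_SV_SPAN <- 50L  # SVs are defined as events larger than 50 bp

## Decision table for a same-chromosome junction. With L the leftmost and R
## the rightmost breakpoint of the pair:
##   L: t[p[  +  R: ]p]t  -> DEL  (forward junction skips [L,R])
##   L: ]p]t  +  R: t[p[  -> DUP  (sequence after R rejoins before L: tandem)
##   both t]p] or both [p[t -> INV (same-strand joins)
##   anything else, or span < 50 bp -> retain the BND pair
.classifySameChromRule <- function(oL, oR) {
  if (is.na(oL) || is.na(oR)) return(NA_character_)
  if (oL == "t_bracket_right" && oR == "bracket_left_t") return("DEL")
  if (oL == "bracket_left_t" && oR == "t_bracket_right") return("DUP")
  if (oL == oR && oL %in% c("t_bracket_left", "bracket_right_t")) return("INV")
  NA_character_
}

## pick which member of a pair donates genotype fields: higher variant AD,
## falling back to the first in input order
.genoDonor <- function(rec_i, rec_j) {
  ai <- rec_i$ad_alt; aj <- rec_j$ad_alt
  if (!is.na(aj) && (is.na(ai) || aj > ai)) rec_j else rec_i
}

#' Classify a same-chromosome breakend pair
#'
#' Applies the junction-topology decision table: a forward junction that
#' skips the enclosed interval is a deletion, a junction running back
#' upstream is a tandem duplication, and same-strand joins on both halves
#' are an inversion; any other orientation combination, and any pair whose
#' span is below the 50 bp SV size definition, is retained in BND form.
#'
#' @param half_l,half_r the two breakend halves (lists/rows with `pos`,
#'   `orientation`); `half_l` need not be the leftmost, ordering is
#'   internal.
#' @param rec_l,rec_r the SV records carrying the halves (one-row
#'   data.frames), used for genotype and provenance.
#' @return list with `svtype` (`"DEL"`, `"DUP"`, `"INV"`, or `NA` for
#'   retained), `rule`, and for classified pairs the one-row canonical
#'   record.
#' @export
classifySameChromPair <- function(half_l, half_r, rec_l, rec_r) {
  if (half_r$pos < half_l$pos) {
    tmp <- half_l; half_l <- half_r; half_r <- tmp
    tmp <- rec_l; rec_l <- rec_r; rec_r <- tmp
  }
  L <- half_l$pos; R <- half_r$pos
  svtype <- .classifySameChromRule(half_l$orientation, half_r$orientation)
  if (is.na(svtype)) return(list(svtype = NA_character_, rule = "complex"))
  if (R - L < .MIN_SV_SPAN)
    return(list(svtype = NA_character_, rule = "min_span"))
  donor <- .genoDonor(rec_l, rec_r)
  strands <- switch(svtype, DEL = "+-", DUP = "-+",
                    INV = .ORIENT_STRANDS[[half_l$orientation]])
  svlen <- if (svtype == "DEL") -(R - L) else R - L
  out <- makeSVRecords(
    record_id = rec_l$record_id, chrom = rec_l$chrom, pos = L, end = R,
    svtype = svtype, svlen = svlen, strands = strands,
    ref = rec_l$ref, alt = paste0("<", svtype, ">"),
    qual = max(rec_l$qual, rec_r$qual, na.rm = !all(is.na(c(rec_l$qual, rec_r$qual)))),
    filter = rec_l$filter, info = rec_l$info,
    gt = donor$gt, ad_ref = donor$ad_ref, ad_alt = donor$ad_alt,
    dp = donor$dp, gq = donor$gq,
    source_caller = rec_l$source_caller, source_file = rec_l$source_file)
  list(svtype = svtype, rule = tolower(svtype), record = out)
}

## Collapse one cross-chromosome pairing into a single TRA record with the
## lexicographically smaller contig first.
.traFromPair <- function(half_i, half_j, rec_i, rec_j) {
  donor <- .genoDonor(rec_i, rec_j)
  a <- list(chrom = half_i$chrom, pos = half_i$pos)
  b <- list(chrom = half_j$chrom, pos = half_j$pos)
  strands <- .ORIENT_STRANDS[[half_i$orientation]] %||% "."
  if (is.na(strands)) strands <- "."
  if (b$chrom < a$chrom) {
    tmp <- a; a <- b; b <- tmp
    strands <- if (strands == ".") "." else
      paste0(substr(strands, 2, 2), substr(strands, 1, 1))
  }
  makeSVRecords(
    record_id = rec_i$record_id, chrom = a$chrom, pos = a$pos, end = a$pos,
    svtype = "TRA", chrom2 = b$chrom, pos2 = b$pos, strands = strands,
    ref = rec_i$ref, alt = "<TRA>",
    qual = max(rec_i$qual, rec_j$qual,
               na.rm = !all(is.na(c(rec_i$qual, rec_j$qual)))),
    filter = rec_i$filter, info = rec_i$info, subtype = "unbalanced",
    gt = donor$gt, ad_ref = donor$ad_ref, ad_alt = donor$ad_alt,
    dp = donor$dp, gq = donor$gq,
    source_caller = rec_i$source_caller, source_file = rec_i$source_file)
}

.strandComplement <- function(s) {
  comp <- c("+" = "-", "-" = "+")
  paste0(comp[[substr(s, 1, 1)]], comp[[substr(s, 2, 2)]])
}

#' Classify cross-chromosome breakend pairings into translocations
#'
#' Each mate pairing collapses to one TRA record. Two pairings whose four
#' coordinates agree pairwise within tolerance are either duplicate
#' representations of one junction (identical orientations; collapsed into
#' a single record, `subtype = "merging"`) or a reciprocal exchange
#' (complementary orientations; both records annotated
#' `subtype = "balanced"`). A lone pairing is an unbalanced transfer, and
#' an unpaired half becomes an unbalanced TRA flagged `no_mate` in the
#' audit.
#'
#' @param tra data.frame of collapsed TRA candidate records (internal use;
#'   see [correctBreakends()] for the user-facing entry point).
#' @param tolerance bp tolerance for reciprocal-coordinate comparison.
#' @return the records with `subtype` annotated and merged duplicates
#'   dropped; attribute `"merged_away"` maps dropped record ids to the id
#'   they merged into.
#' @keywords internal
.annotateTraSubtypes <- function(tra, tolerance) {
  merged_away <- character(0)
  if (nrow(tra) > 1L) {
    drop <- rep(FALSE, nrow(tra))
    key <- paste(tra$chrom, tra$chrom2)
    for (i in seq_len(nrow(tra) - 1L)) {
      if (drop[i]) next
      for (j in seq((i + 1L), nrow(tra))) {
        if (drop[j] || key[i] != key[j]) next
        if (abs(tra$pos[i] - tra$pos[j]) > tolerance ||
            abs(tra$pos2[i] - tra$pos2[j]) > tolerance) next
        si <- tra$strands[i]; sj <- tra$strands[j]
        if (si != "." && si == sj) {
          drop[j] <- TRUE
          tra$subtype[i] <- "merging"
          merged_away[tra$record_id[j]] <- tra$record_id[i]
        } else if (si != "." && sj == .strandComplement(si)) {
          tra$subtype[c(i, j)] <- "balanced"
        }
      }
    }
    tra <- tra[!drop, , drop = FALSE]
  }
  attr(tra, "merged_away") <- merged_away
  tra
}

#' Standardize breakend records into canonical SV types
#'
#' The hierarchical correction pipeline: non-BND records pass through
#' untouched; BND records are parsed, mates are paired (`MATEID` first,
#' then positionally within `tolerance`), same-chromosome junctions are
#' classified as DEL/DUP/INV by bracket-orientation topology, and
#' cross-chromosome junctions become TRA records with balanced /
#' unbalanced / merging subtypes. Breakends are never converted to INS,
#' and anything unparseable, unpaired on one chromosome, conflicting, or
#' below the 50 bp span definition is retained in BND form. Every input
#' record is accounted for in the audit table.
#'
#' @param x an [SVCallSet-class] (e.g. from [readSVVcf()]).
#' @param tolerance mate-pairing positional tolerance in bp (default 3).
#' @return A [CorrectionResult-class].
#' @examples
#' rec <- makeSVRecords(record_id = c("b1", "b2"), chrom = "chr1",
#'   pos = c(1000L, 5000L), end = c(1000L, 5000L), svtype = "BND",
#'   chrom2 = "chr1", pos2 = c(5000L, 1000L),
#'   alt = c("N[chr1:5000[", "]chr1:1000]N"))
#' res <- correctBreakends(SVCallSet(rec))
#' correctedRecords(res)[, c("svtype", "pos", "end", "svlen")]
#' @export
correctBreakends <- function(x, tolerance = 3) {
  stopifnot(is(x, "SVCallSet"), tolerance >= 0)
  rec <- x@records
  is_bnd <- rec$svtype == "BND"
  pass <- rec[!is_bnd, , drop = FALSE]
  audit <- data.frame(
    input_id = rec$record_id, input_svtype = rec$svtype,
    disposition = ifelse(is_bnd, NA_character_, "passthrough"),
    rule = NA_character_, evidence = NA_character_,
    output_id = ifelse(is_bnd, NA_character_, rec$record_id),
    stringsAsFactors = FALSE)
  setAudit <- function(ids, disposition, rule, evidence, output) {
    k <- match(ids, audit$input_id)
    audit$disposition[k] <<- disposition
    audit$rule[k] <<- rule
    audit$evidence[k] <<- evidence
    audit$output_id[k] <<- output
  }

  bnd <- rec[is_bnd, , drop = FALSE]
  corrected <- list()
  retained <- list()

  if (nrow(bnd)) {
    halves <- .breakendHalves(bnd)
    parseable <- !is.na(halves$orientation)
    if (any(!parseable)) {
      retained[[length(retained) + 1L]] <- bnd[!parseable, , drop = FALSE]
      setAudit(bnd$record_id[!parseable], "retained", "unparseable", NA,
               bnd$record_id[!parseable])
    }
    hv <- halves[parseable, , drop = FALSE]
    sub <- bnd[parseable, , drop = FALSE]
    pm <- pairMates(hv, tolerance = tolerance)

    tra_cand <- list()
    tra_prov <- list()  # input ids per TRA candidate
    for (r in seq_len(nrow(pm$pairs))) {
      i <- pm$pairs$i[r]; j <- pm$pairs$j[r]
      evid <- pm$pairs$evidence[r]
      hi <- hv[i, ]; hj <- hv[j, ]
      ri <- sub[i, ]; rj <- sub[j, ]
      if (hi$chrom == hj$chrom) {
        cls <- classifySameChromPair(hi, hj, ri, rj)
        if (is.na(cls$svtype)) {
          retained[[length(retained) + 1L]] <- rbind(ri, rj)
          setAudit(c(ri$record_id, rj$record_id), "retained", cls$rule,
                   evid, c(ri$record_id, rj$record_id))
        } else {
          corrected[[length(corrected) + 1L]] <- cls$record
          setAudit(c(ri$record_id, rj$record_id), "converted", cls$rule,
                   evid, cls$record$record_id)
        }
      } else {
        tra_cand[[length(tra_cand) + 1L]] <- .traFromPair(hi, hj, ri, rj)
        tra_prov[[length(tra_prov) + 1L]] <-
          list(ids = c(ri$record_id, rj$record_id), evidence = evid)
      }
    }
    ## unpaired halves: cross-chromosome ones become unbalanced TRAs,
    ## same-chromosome ones are retained as BND
    for (i in pm$unpaired) {
      hi <- hv[i, ]; ri <- sub[i, ]
      if (!is.na(hi$mate_chrom) && hi$mate_chrom != hi$chrom) {
        half_j <- list(chrom = hi$mate_chrom, pos = hi$mate_pos,
                       orientation = hi$orientation)
        tr <- .traFromPair(hi, half_j, ri, ri)
        tra_cand[[length(tra_cand) + 1L]] <- tr
        tra_prov[[length(tra_prov) + 1L]] <-
          list(ids = ri$record_id, evidence = NA_character_, no_mate = TRUE)
      } else {
        retained[[length(retained) + 1L]] <- ri
        setAudit(ri$record_id, "retained", "unpaired_same_chrom", NA,
                 ri$record_id)
      }
    }

    if (length(tra_cand)) {
      tra <- do.call(rbind, tra_cand)
      tra2 <- .annotateTraSubtypes(tra, tolerance)
      merged_away <- attr(tra2, "merged_away")
      keep_id <- tra2$record_id
      for (k in seq_along(tra_cand)) {
        prov <- tra_prov[[k]]
        rid <- tra_cand[[k]]$record_id
        out_id <- if (rid %in% names(merged_away)) merged_away[[rid]] else rid
        row <- match(out_id, tra2$record_id)
        rule <- if (!is.null(prov$no_mate)) "no_mate" else
          paste0("tra_", tra2$subtype[row])
        setAudit(prov$ids,
                 if (rid %in% keep_id || rid %in% names(merged_away))
                   "converted" else "retained",
                 rule, prov$evidence, out_id)
      }
      corrected[[length(corrected) + 1L]] <- tra2
    }
  }

  corrected <- if (length(corrected)) do.call(rbind, corrected) else emptySVRecords()
  retained <- if (length(retained)) do.call(rbind, retained) else emptySVRecords()
  all_rec <- rbind(makeSVRecords(pass), makeSVRecords(corrected),
                   makeSVRecords(retained))
  rownames(all_rec) <- NULL
  out <- SVCallSet(records = all_rec, sampleNames = x@sampleNames,
                   metadata = c(x@metadata, list(corrected = TRUE,
                                                 tolerance = tolerance)))
  new("CorrectionResult", callset = out, audit = audit,
      tolerance = as.numeric(tolerance))
}
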