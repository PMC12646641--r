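## Breakend ALT grammar and mate pairing.
##
## A breakend ALT is one of the four bracket patterns of the VCF spec,
## writing t for the sequence anchored at the record's own position and p
## for the partner coordinate:
## The derived strand pair is (own breakpoint, mate breakpoint): the own
## side is "+" when t precedes the bracket (the sequence left of the
## breakpoint is retained) and the mate side is "+" for "]" brackets (the
## mate's left side joins):
##   t[p[  piece extending right of p joins after t            ("+-")
##   t]p]  reverse-complement piece left of p joins after t    ("++")
##   ]p]t  piece left of p joins before t                      ("-+")
##   [p[t  reverse-complement piece right of p joins before t  ("--")

.BND_ORIENTATIONS <- c("t_bracket_right", "t_bracket_left",
                       "bracket_left_t", "bracket_right_t")

.ORIENT_STRANDS <- c(t_bracket_right = "+-", t_bracket_left = "++",
                     bracket_left_t = "-+", bracket_right_t = "--")

#' Parse a breakend ALT allele
#'
#' Decomposes a bracket-notation ALT into its orientation pattern, the mate
#' breakpoint and any inserted sequence.
#'
#' @param alt_allele ALT string, e.g. `"N[chr2:321682["`.
#' @param chrom,pos coordinates of the record carrying the ALT.
#' @return list with elements `chrom`, `pos`, `orientation` (one of
#'   `t_bracket_right`, `t_bracket_left`, `bracket_left_t`,
#'   `bracket_right_t`), `mate_chrom`, `mate_pos`, `inserted_seq` and the
#'   derived `strands` pair.
#' @examples
#' parseBreakend("N[chr2:321682[", "chr1", 1000)$orientation
#' @export
parseBreakend <- function(alt_allele, chrom, pos) {
  m <- regexec("^([A-Za-z.*]*)(\\[|\\])([A-Za-z0-9_.]+):([0-9]+)(\\[|\\])([A-Za-z.*]*)$",
               alt_allele)
  g <- regmatches(alt_allele, m)[[1L]]
  if (!length(g) || g[3L] != g[6L])
    .stopValidation("not a breakend ALT: '%s'", alt_allele)
  t_before <- g[2L]
  bracket <- g[3L]
  t_after <- g[7L]
  if (nzchar(t_before) == nzchar(t_after))
    .stopValidation("not a breakend ALT: '%s'", alt_allele)
  orientation <- if (nzchar(t_before)) {
    if (bracket == "[") "t_bracket_right" else "t_bracket_left"
  } else {
    if (bracket == "]") "bracket_left_t" else "bracket_right_t"
  }
  inserted <- if (nzchar(t_before)) substr(t_before, 2L, nchar(t_before))
              else substr(t_after, 1L, nchar(t_after) - 1L)
  list(chrom = chrom, pos = as.integer(pos), orientation = orientation,
       mate_chrom = g[4L], mate_pos = as.integer(g[5L]),
       inserted_seq = inserted, strands = .ORIENT_STRANDS[[orientation]])
}

## Build the breakend-half table for the BND rows of a record table.
## Unparseable ALTs yield orientation NA (handled upstream as "unparseable").
.breakendHalves <- function(rec) {
  halves <- data.frame(
    record_id = rec$record_id, chrom = rec$chrom, pos = rec$pos,
    mate_chrom = NA_character_, mate_pos = NA_integer_,
    orientation = NA_character_, inserted_seq = NA_character_,
    mate_id = .infoGet(rec$info, "MATEID"), row = seq_len(nrow(rec)),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rec))) {
    bh <- tryCatch(parseBreakend(rec$alt[i], rec$chrom[i], rec$pos[i]),
                   error = function(e) NULL)
    if (is.null(bh)) next
    halves$mate_chrom[i] <- bh$mate_chrom
    halves$mate_pos[i] <- bh$mate_pos
    halves$orientation[i] <- bh$orientation
    halves$inserted_seq[i] <- bh$inserted_seq
  }
  halves
}

#' Pair breakend halves into junctions
#'
#' `MATEID`-based pairings take priority; remaining halves are paired
#' greedily by smallest summed cross-distance, requiring both cross
#' distances (each half's stated mate position against the other half's
#' own position) within `tolerance` and cross-matching chromosomes. Each
#' half joins at most one pairing.
#'
#' @param halves data.frame of breakend halves (as built internally from
#'   BND records; columns `record_id`, `chrom`, `pos`, `mate_chrom`,
#'   `mate_pos`, `orientation`, `mate_id`).
#' @param tolerance non-negative positional tolerance in bp (default 3).
#' @return list with `pairs` (data.frame of index pairs `i`, `j` into
#'   `halves` plus `evidence` and `distance`) and `unpaired` (integer
#'   indices).
#' @export
pairMates <- function(halves, tolerance = 3) {
  stopifnot(tolerance >= 0)
  n <- nrow(halves)
  used <- rep(FALSE, n)
  pairs <- list()
  ok <- !is.na(halves$orientation)

  ## 1) MATEID evidence
  if (any(!is.na(halves$mate_id))) {
    for (i in seq_len(n)) {
      if (used[i] || !ok[i] || is.na(halves$mate_id[i])) next
      j <- match(halves$mate_id[i], halves$record_id)
      if (is.na(j) || j == i || used[j] || !ok[j]) next
      used[c(i, j)] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(i = min(i, j), j = max(i, j), evidence = "mate_id",
                   distance = NA_real_, stringsAsFactors = FALSE)
    }
  }

  ## 2) positional evidence among the rest
  idx <- which(!used & ok & !is.na(halves$mate_pos))
  if (length(idx) > 1L) {
    ## index halves by chromosome so each half only scans the window of
    ## positions near its stated mate coordinate
    by_chrom <- split(idx, halves$chrom[idx])
    by_chrom <- lapply(by_chrom, function(v) v[order(halves$pos[v])])
    cand <- list()
    for (i in idx) {
      grp <- by_chrom[[halves$mate_chrom[i]]]
      if (is.null(grp)) next
      p <- halves$pos[grp]
      lo <- findInterval(halves$mate_pos[i] - tolerance - 1L, p) + 1L
      hi <- findInterval(halves$mate_pos[i] + tolerance, p)
      if (hi < lo) next
      for (j in grp[lo:hi]) {
        if (j <= i) next
        if (halves$mate_chrom[j] != halves$chrom[i]) next
        d1 <- abs(halves$mate_pos[i] - halves$pos[j])
        d2 <- abs(halves$mate_pos[j] - halves$pos[i])
        if (d1 <= tolerance && d2 <= tolerance)
          cand[[length(cand) + 1L]] <- c(i, j, d1 + d2, max(d1, d2))
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      ## greedy order: worst cross-distance first (keeps the accepted set
      ## monotone in tolerance), then summed distance, then input order
      cand <- cand[order(cand[, 4L], cand[, 3L], cand[, 1L], cand[, 2L]),
                   , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (used[i] || used[j]) next
        used[c(i, j)] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(i = i, j = j, evidence = "positional",
                     distance = cand[r, 3L], stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(), j = integer(), evidence = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  list(pairs = pairs, unpaired = which(!used))
}
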