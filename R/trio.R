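#' Trio Mendelian-violation rate (truth-free evaluation)
#'
#' Jointly merges child, father and mother callsets (each input as one
#' support slot) and computes the Mendelian violation rate: the proportion
#' of child-supported consensus variants with neither parent in the
#' support set. Variants with |SVLEN| below `min_svlen` are excluded from
#' the denominator, except translocations and breakends which have no
#' length. A violation-free trio has MVR 0; a child callset disjoint from
#' both parents has MVR 1.
#'
#' @param child,father,mother [SVCallSet-class] objects.
#' @param params a [mergeParams()] object used for the joint merge.
#' @param min_svlen minimum |SVLEN| in bp (default 30); TRA/BND exempt.
#' @param exclude_bed optional path to a BED file; child variants whose
#'   first breakpoint falls in a masked region are excluded.
#' @param pass_only logical, additionally screen on the FILTER field
#'   (keep only PASS/`.`; default FALSE).
#' @return list with `mvr`, `n_child`, `n_violation`, `per_type`
#'   (data.frame with per-SV-type counts and rates) and `merged` (the
#'   joint [MergedSVSet-class]).
#' @export
trioMVR <- function(child, father, mother, params = mergeParams(),
                    min_svlen = 30, exclude_bed = NULL, pass_only = FALSE) {
  if (nSV(child) == 0L)
    .stopValidation("empty child callset: Mendelian violation rate is undefined")
  merged <- mergeSVSets(list(child, father, mother), params = params,
                        callers = c("child", "father", "mother"))
  rec <- merged@records
  sup <- svSupport(merged)
  in_child <- vapply(sup, function(s) "child" %in% s, logical(1L))
  rec$in_child <- in_child
  keep <- in_child
  lengthless <- rec$svtype %in% c("TRA", "BND")
  keep <- keep & (lengthless | (!is.na(rec$svlen) & abs(rec$svlen) >= min_svlen))
  if (pass_only) keep <- keep & rec$filter %in% c("PASS", ".")
  if (!is.null(exclude_bed)) {
    mask <- .readBed(exclude_bed)
    masked <- vapply(seq_len(nrow(rec)), function(i) {
      any(mask$chrom == rec$chrom[i] & rec$pos[i] > mask$start &
            rec$pos[i] <= mask$end)
    }, logical(1L))
    keep <- keep & !masked
  }
  idx <- which(keep)
  violation <- vapply(sup[idx], function(s)
    !("father" %in% s) && !("mother" %in% s), logical(1L))
  n_child <- length(idx)
  mvr <- if (n_child > 0) sum(violation) / n_child else NA_real_
  types <- sort(unique(rec$svtype[idx]))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    k <- rec$svtype[idx] == ty
    data.frame(svtype = ty, n = sum(k), violations = sum(violation & k),
               mvr = if (sum(k)) sum(violation & k) / sum(k) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(mvr = mvr, n_child = n_child, n_violation = sum(violation),
       per_type = per_type %||% data.frame(), merged = merged)
}

## minimal BED reader: chrom, 0-based start, end
.readBed <- function(path) {
  if (!file.exists(path)) .stopIO("BED file not found: %s", path)
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  data.frame(chrom = b[[1L]], start = as.integer(b[[2L]]),
             end = as.integer(b[[3L]]), stringsAsFactors = FALSE)
}
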