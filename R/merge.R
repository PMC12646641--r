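#' Merging parameters
#'
#' Matching criteria for multi-caller/multi-sample merging. Non-TRA events
#' match when start and end both lie within `max_distance`, the size ratio
#' (larger over smaller |SVLEN|) is at most `max_size_ratio` and the
#' closed-interval Jaccard index is at least `min_jaccard` (the Jaccard
#' test is waived for point-like INS events). Translocations and breakends
#' match when both breakpoints lie within `tra_distance` on the same
#' chromosome pair and, if required, strand orientations are consistent
#' (unknown strands are consistent with anything).
#'
#' @param max_distance start/end matching distance in bp (commonly 50-150;
#'   default 50, the strictest).
#' @param max_size_ratio maximum size ratio, >= 1 (default 1.3).
#' @param min_jaccard minimum interval Jaccard index in (0, 1] (default 0.7).
#' @param tra_distance breakpoint distance for TRA/BND events (default 500).
#' @param require_strand_match_tra logical, enforce strand consistency for
#'   TRA/BND matching (default TRUE).
#' @return list of validated parameters of class `MergeParams`.
#' @export
mergeParams <- function(max_distance = 50, max_size_ratio = 1.3,
                        min_jaccard = 0.7, tra_distance = 500,
                        require_strand_match_tra = TRUE) {
  if (max_distance <= 0) .stopValidation("max_distance must be > 0")
  if (max_size_ratio < 1) .stopValidation("max_size_ratio must be >= 1")
  if (min_jaccard <= 0 || min_jaccard > 1)
    .stopValidation("min_jaccard must be in (0, 1]")
  structure(list(max_distance = max_distance, max_size_ratio = max_size_ratio,
                 min_jaccard = min_jaccard, tra_distance = tra_distance,
                 require_strand_match_tra = require_strand_match_tra),
            class = "MergeParams")
}

.strandsConsistent <- function(a, b) a == "." | b == "." | a == b

#' Pairwise SV match predicate
#'
#' @param a,b one-row record data.frames of the same `svtype`.
#' @param params a [mergeParams()] object.
#' @return logical: do the two calls describe the same event under the
#'   matching criteria?
#' @export
svPairMatch <- function(a, b, params = mergeParams()) {
  if (a$svtype != b$svtype)
    .stopValidation("svPairMatch requires records of the same svtype")
  if (a$svtype %in% c("TRA", "BND")) {
    if (a$chrom != b$chrom || a$chrom2 != b$chrom2) return(FALSE)
    if (abs(a$pos - b$pos) > params$tra_distance) return(FALSE)
    if (abs(a$pos2 - b$pos2) > params$tra_distance) return(FALSE)
    if (params$require_strand_match_tra &&
        !.strandsConsistent(a$strands, b$strands)) return(FALSE)
    return(TRUE)
  }
  if (a$chrom != b$chrom) return(FALSE)
  if (abs(a$pos - b$pos) > params$max_distance) return(FALSE)
  if (abs(a$end - b$end) > params$max_distance) return(FALSE)
  sa <- abs(a$svlen); sb <- abs(b$svlen)
  if (!is.na(sa) && !is.na(sb) && sa > 0 && sb > 0 &&
      max(sa, sb) / min(sa, sb) > params$max_size_ratio) return(FALSE)
  if (a$svtype != "INS" &&
      intervalJaccard(a$pos, a$end, b$pos, b$end) < params$min_jaccard)
    return(FALSE)
  TRUE
}

## vectorized pairwise matching inside one (svtype, chromosome-pair)
## bucket: records sorted by pos, windowed by the start-distance bound
.bucketEdges <- function(rec, params) {
  n <- nrow(rec)
  if (n < 2L) return(cbind(integer(), integer()))
  is_tra <- rec$svtype[1L] %in% c("TRA", "BND")
  dmax <- if (is_tra) params$tra_distance else params$max_distance
  ord <- order(rec$pos)
  edges <- list()
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in seq((a + 1L), n)) {
      j <- ord[b]
      if (rec$pos[j] - rec$pos[i] > dmax) break
      if (is_tra) {
        if (abs(rec$pos2[i] - rec$pos2[j]) > dmax) next
        if (params$require_strand_match_tra &&
            !.strandsConsistent(rec$strands[i], rec$strands[j])) next
      } else {
        if (abs(rec$end[i] - rec$end[j]) > dmax) next
        si <- abs(rec$svlen[i]); sj <- abs(rec$svlen[j])
        if (!is.na(si) && !is.na(sj) && si > 0 && sj > 0 &&
            max(si, sj) / min(si, sj) > params$max_size_ratio) next
        if (rec$svtype[1L] != "INS" &&
            intervalJaccard(rec$pos[i], rec$end[i], rec$pos[j], rec$end[j]) <
              params$min_jaccard) next
      }
      edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges)) do.call(rbind, edges) else cbind(integer(), integer())
}

#' Hierarchical genotype resolution
#'
#' Resolves conflicting genotype calls across members of one consensus SV:
#' a strict plurality of GT tokens wins; on a tie, the genotype of the tied
#' member with the highest variant-supporting read count (AD); on a
#' remaining tie, the earliest member in caller input order.
#'
#' @param members data.frame of member records, ordered by caller input
#'   order.
#' @return list with `gt`, `ad_ref`, `ad_alt`, `dp`, `gq` from the winning
#'   member.
#' @export
resolveGenotype <- function(members) {
  stopifnot(nrow(members) >= 1L)
  ## missing genotypes only win when no member has a call
  voters <- members[members$gt != "./.", , drop = FALSE]
  if (!nrow(voters)) {
    w <- members[1L, ]
    return(list(gt = w$gt, ad_ref = w$ad_ref, ad_alt = w$ad_alt,
                dp = w$dp, gq = w$gq))
  }
  counts <- table(voters$gt)
  top <- names(counts)[counts == max(counts)]
  cand <- voters[voters$gt %in% top, , drop = FALSE]
  if (length(top) > 1L && any(!is.na(cand$ad_alt))) {
    best_ad <- max(cand$ad_alt, na.rm = TRUE)
    cand <- cand[!is.na(cand$ad_alt) & cand$ad_alt == best_ad, , drop = FALSE]
  }
  w <- cand[1L, ]
  list(gt = w$gt, ad_ref = w$ad_ref, ad_alt = w$ad_alt, dp = w$dp, gq = w$gq)
}

## representative member: highest QUAL, then highest variant AD, then
## caller input order
.pickRepresentative <- function(members) {
  q <- members$qual; q[is.na(q)] <- -Inf
  a <- members$ad_alt; a[is.na(a)] <- -Inf
  members[order(-q, -a, seq_len(nrow(members)))[1L], , drop = FALSE]
}

#' Merge SV callsets from multiple callers or samples
#'
#' Records are bucketed by SV type and chromosome (chromosome pair for
#' TRA/BND), pairwise-matched under the [mergeParams()] criteria, and
#' clustered as connected components of the match graph. Each component
#' becomes one consensus record whose representative is the best-quality
#' member and whose genotype is resolved hierarchically
#' ([resolveGenotype()]).
#'
#' @param callsets a list of [SVCallSet-class] objects (one per caller or
#'   sample, in input-file order), or a single callset.
#' @param params a [mergeParams()] object.
#' @param callers optional caller names overriding each callset's
#'   provenance (used for multi-sample mode, where each input file is one
#'   support slot).
#' @return A [MergedSVSet-class].
#' @export
mergeSVSets <- function(callsets, params = mergeParams(), callers = NULL) {
  if (is(callsets, "SVCallSet")) callsets <- list(callsets)
  stopifnot(all(vapply(callsets, is, logical(1L), "SVCallSet")))
  recs <- lapply(seq_along(callsets), function(k) {
    r <- callsets[[k]]@records
    if (!is.null(callers)) {
      if (nrow(r)) {
        r$source_caller <- callers[k]
        r$support <- callers[k]
      }
    }
    if (nrow(r)) r$caller_order <- k
    r
  })
  caller_names <- if (!is.null(callers)) callers else
    vapply(callsets, function(cs) {
      sc <- unique(cs@records$source_caller)
      if (length(sc) == 1L) sc else (cs@metadata$caller %||% sc[1L] %||% "unknown")
    }, character(1L))
  if (anyDuplicated(caller_names))
    caller_names <- make.unique(caller_names, sep = "_")
  for (k in seq_along(recs)) if (nrow(recs[[k]])) {
    recs[[k]]$source_caller <- caller_names[k]
    recs[[k]]$support <- caller_names[k]
  }
  rec <- do.call(rbind, recs)
  if (is.null(rec) || !nrow(rec))
    return(new("MergedSVSet", SVCallSet(), members = list(),
               callers = caller_names))
  rec$support_count <- 1L
  rec$.row <- seq_len(nrow(rec))

  bucket <- ifelse(rec$svtype %in% c("TRA", "BND"),
                   paste(rec$svtype, rec$chrom, rec$chrom2),
                   paste(rec$svtype, rec$chrom))
  comp_of <- integer(nrow(rec))
  n_comp <- 0L
  for (b in split(seq_len(nrow(rec)), bucket)) {
    sub <- rec[b, , drop = FALSE]
    edges <- .bucketEdges(sub, params)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[, 1L]),
                 to = as.character(edges[, 2L])),
      directed = FALSE,
      vertices = data.frame(name = as.character(seq_len(nrow(sub)))))
    memb <- igraph::components(g)$membership
    local_comp <- memb[as.character(seq_len(nrow(sub)))]
    comp_of[b] <- n_comp + as.integer(local_comp)
    n_comp <- n_comp + max(as.integer(local_comp))
  }

  groups <- split(seq_len(nrow(rec)), comp_of)
  ## deterministic output order: by first member's coordinates
  ord <- order(vapply(groups, function(ix) min(rec$.row[ix]), numeric(1L)))
  groups <- groups[ord]
  members <- vector("list", length(groups))
  out_rows <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    m <- rec[groups[[k]], , drop = FALSE]
    m <- m[order(m$caller_order, m$.row), , drop = FALSE]
    rep_rec <- .pickRepresentative(m)
    geno <- resolveGenotype(m)
    sup <- unique(m$source_caller)
    sup <- caller_names[sort(match(sup, caller_names))]
    r <- rep_rec
    r$gt <- geno$gt; r$ad_ref <- geno$ad_ref; r$ad_alt <- geno$ad_alt
    r$dp <- geno$dp; r$gq <- geno$gq
    r$support <- paste(sup, collapse = ",")
    r$support_count <- length(sup)
    r$geno_raw <- NA_character_
    m$.row <- NULL; m$caller_order <- NULL
    members[[k]] <- m
    r$.row <- NULL; r$caller_order <- NULL
    out_rows[[k]] <- r
  }
  out <- do.call(rbind, out_rows)
  out$record_id <- make.unique(out$record_id, sep = "_")
  rownames(out) <- NULL
  new("MergedSVSet",
      SVCallSet(records = out,
                sampleNames = unique(unlist(lapply(callsets, slot, "sampleNames"))),
                metadata = list(params = unclass(params))),
      members = members, callers = caller_names)
}
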