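# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# a small caller-style VCF written from raw lines
write_vcf_lines <- function(body, path = tempfile(fileext = ".vcf"),
                            samples = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"t\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"t\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# quick one-row canonical record
rec1 <- function(id, chrom, pos, end, svtype, svlen = NULL, caller = "c1",
                 gt = "0/1", ad_alt = NA_integer_, qual = 50, strands = NULL,
                 chrom2 = NULL, pos2 = NULL) {
  if (is.null(svlen) && svtype %in% c("DEL", "DUP", "INV"))
    svlen <- if (svtype == "DEL") -(end - pos) else end - pos
  makeSVRecords(record_id = id, chrom = chrom, pos = as.integer(pos),
                end = as.integer(end), svtype = svtype,
                svlen = if (is.null(svlen)) NA_integer_ else as.integer(svlen),
                chrom2 = chrom2, pos2 = if (is.null(pos2)) NULL else as.integer(pos2),
                strands = strands, gt = gt, ad_alt = ad_alt, qual = qual,
                source_caller = caller)
}

callset <- function(..., caller = NULL) {
  rec <- do.call(rbind, list(...))
  md <- if (is.null(caller)) list() else list(caller = caller)
  SVCallSet(records = rec, metadata = md)
}

# independent match-matrix oracle: vectorized re-statement of the matching
# criteria straight from their definition (no shared code with the
# clustering implementation)
oracle_match_matrix <- function(rec, params) {
  n <- nrow(rec)
  M <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { M[i, j] <- TRUE; next }
    if (rec$svtype[i] != rec$svtype[j]) next
    if (rec$svtype[i] %in% c("TRA", "BND")) {
      ok <- rec$chrom[i] == rec$chrom[j] && rec$chrom2[i] == rec$chrom2[j] &&
        abs(rec$pos[i] - rec$pos[j]) <= params$tra_distance &&
        abs(rec$pos2[i] - rec$pos2[j]) <= params$tra_distance &&
        (!params$require_strand_match_tra || rec$strands[i] == "." ||
           rec$strands[j] == "." || rec$strands[i] == rec$strands[j])
    } else {
      ok <- rec$chrom[i] == rec$chrom[j] &&
        abs(rec$pos[i] - rec$pos[j]) <= params$max_distance &&
        abs(rec$end[i] - rec$end[j]) <= params$max_distance
      if (ok) {
        si <- abs(rec$svlen[i]); sj <- abs(rec$svlen[j])
        if (!is.na(si) && !is.na(sj) && si > 0 && sj > 0)
          ok <- max(si, sj) / min(si, sj) <= params$max_size_ratio
      }
      if (ok && rec$svtype[i] != "INS") {
        inter <- max(0, min(rec$end[i], rec$end[j]) -
                       max(rec$pos[i], rec$pos[j]) + 1)
        uni <- (rec$end[i] - rec$pos[i] + 1) +
          (rec$end[j] - rec$pos[j] + 1) - inter
        ok <- inter / uni >= params$min_jaccard
      }
    }
    M[i, j] <- ok
  }
  M
}

# transitive closure by repeated boolean matrix multiplication
oracle_components <- function(M) {
  R <- M
  repeat {
    R2 <- (R %*% R) > 0 | R
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- integer(nrow(R))
  k <- 0L
  for (i in seq_len(nrow(R))) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[which(R[i, ])] <- k
    }
  }
  comp
}

# canonical form of a partition (sets of record ids) for comparison
partition_sets <- function(ids, comp) {
  s <- lapply(split(ids, comp), sort)
  unname(s[order(vapply(s, `[`, character(1L), 1L))])
}

# random record table for the clustering oracle comparisons
random_records <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("DEL", "DUP", "INV", "INS", "TRA"), n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ty <- types[i]
    chrom <- sample(c("chr1", "chr2"), 1L)
    if (ty == "TRA") {
      rows[[i]] <- rec1(sprintf("r%d", i), "chr1", sample(5000L, 1L), NA,
                        "TRA", caller = sprintf("c%d", sample(4L, 1L)),
                        strands = sample(c("+-", "-+", "++", "--", "."), 1L),
                        chrom2 = "chr2", pos2 = sample(5000L, 1L))
      rows[[i]]$end <- rows[[i]]$pos
    } else {
      pos <- sample(5000L, 1L)
      size <- sample(50:2000, 1L)
      rows[[i]] <- rec1(sprintf("r%d", i), chrom, pos, pos + size, ty,
                        svlen = if (ty == "INS") size else NULL,
                        caller = sprintf("c%d", sample(4L, 1L)))
      if (ty == "INS") rows[[i]]$end <- rows[[i]]$pos
    }
  }
  do.call(rbind, rows)
}
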