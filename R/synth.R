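## Synthetic caller-VCF generator with planted ground truth. Operates at
## call level (coordinates only, no reads, no reference FASTA): a truth set
## of canonical events is planted on a contig model, then per-"caller"
## emission applies false negatives, positional jitter, breakend encoding
## and false-positive padding, emulating how real callers disagree.

.DEFAULT_GENOME <- c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6)

#' Plant a ground-truth SV set
#'
#' Deterministically (for a fixed seed) places non-overlapping events of
#' each type on a coordinate-only genome model. Genotypes are drawn
#' heterozygous with probability `het_fraction` (default 0.7, i.e. a 30:70
#' homozygous-to-heterozygous ratio), else homozygous alternate.
#'
#' @param n_per_type named integer vector with counts for any of
#'   DEL/INS/INV/DUP/TRA.
#' @param size_range length bounds in bp (default c(50, 10000)).
#' @param het_fraction proportion of heterozygous genotypes (default 0.7).
#' @param seed integer seed; required for reproducibility.
#' @param genome named numeric vector of contig lengths.
#' @return An [SVCallSet-class] of truth records (`source_caller =
#'   "truth"`); metadata records seed and genome.
#' @export
plantEvents <- function(n_per_type = c(DEL = 100, INS = 100, INV = 100,
                                       DUP = 100, TRA = 100),
                        size_range = c(50, 10000), het_fraction = 0.7,
                        seed = 1L, genome = .DEFAULT_GENOME) {
  stopifnot(all(n_per_type >= 0), length(size_range) == 2L,
            size_range[1L] >= 50, het_fraction >= 0, het_fraction <= 1)
  if (size_range[2L] > max(genome))
    .stopValidation("size_range exceeds every contig length")
  set.seed(seed)
  types <- intersect(c("DEL", "INS", "INV", "DUP", "TRA"), names(n_per_type))
  rows <- list()
  occupied <- lapply(names(genome), function(g)
    list())  # per-contig taken intervals, per type
  names(occupied) <- names(genome)
  counter <- 0L

  place_interval <- function(type, size) {
    ## rejection-sample a contig position not overlapping a same-type event
    for (attempt in 1:200) {
      contig <- sample(names(genome), 1L)
      lim <- genome[[contig]] - size - 1L
      if (lim < 1) next
      start <- sample.int(as.integer(lim), 1L)
      iv <- occupied[[contig]][[type]]
      if (!is.null(iv) &&
          any(start <= iv[, 2L] & (start + size) >= iv[, 1L])) next
      occupied[[contig]][[type]] <<- rbind(iv, c(start, start + size))
      return(list(contig = contig, start = start))
    }
    .stopValidation("cannot place a %d bp %s event on contig model (%s)",
                    size, type, paste(names(genome), collapse = ","))
  }

  for (type in types) {
    n <- n_per_type[[type]]
    if (n == 0L) next
    for (e in seq_len(n)) {
      counter <- counter + 1L
      gt <- if (runif(1) < het_fraction) "0/1" else "1/1"
      if (type == "TRA") {
        cts <- sample(names(genome), 2L, replace = FALSE)
        cts <- cts[order(cts)]
        p1 <- sample.int(as.integer(genome[[cts[1L]]] - 1000L), 1L)
        p2 <- sample.int(as.integer(genome[[cts[2L]]] - 1000L), 1L)
        strands <- sample(c("+-", "-+", "++", "--"), 1L)
        rows[[counter]] <- makeSVRecords(
          record_id = sprintf("truth_TRA_%d", e), chrom = cts[1L], pos = p1,
          end = p1, svtype = "TRA", chrom2 = cts[2L], pos2 = p2,
          strands = strands, gt = gt, source_caller = "truth")
      } else {
        size <- sample(seq(size_range[1L], size_range[2L]), 1L)
        loc <- place_interval(type, if (type == "INS") 1L else size)
        pos <- loc$start
        if (type == "INS") {
          rows[[counter]] <- makeSVRecords(
            record_id = sprintf("truth_INS_%d", e), chrom = loc$contig,
            pos = pos, end = pos, svtype = "INS", svlen = size,
            gt = gt, source_caller = "truth")
        } else {
          strands <- switch(type, DEL = "+-", DUP = "-+",
                            INV = sample(c("++", "--"), 1L))
          rows[[counter]] <- makeSVRecords(
            record_id = sprintf("truth_%s_%d", type, e), chrom = loc$contig,
            pos = pos, end = pos + size, svtype = type,
            svlen = if (type == "DEL") -size else size, strands = strands,
            gt = gt, source_caller = "truth")
        }
      }
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else emptySVRecords()
  SVCallSet(records = rec, sampleNames = "TRUTH",
            metadata = list(seed = seed, genome = genome,
                            het_fraction = het_fraction))
}

#' Caller emission profile for the synthetic generator
#'
#' @param bnd_fraction proportion of non-INS events emitted as breakend
#'   pairs instead of canonical records.
#' @param jitter_sd positional jitter SD in bp, applied independently to
#'   both breakpoints.
#' @param fn_rate per-event false-negative (drop) probability.
#' @param fp_count number of false-positive events to add.
#' @param dialect caller identifier stamped on the output.
#' @param mateid_fraction proportion of emitted breakend pairs carrying
#'   MATEID cross-references (the rest must be paired positionally).
#' @return list of validated profile values.
#' @export
synthCallerProfile <- function(bnd_fraction = 0.3, jitter_sd = 5,
                               fn_rate = 0.1, fp_count = 10,
                               dialect = "synthcaller",
                               mateid_fraction = 1.0) {
  stopifnot(bnd_fraction >= 0, bnd_fraction <= 1, jitter_sd >= 0,
            fn_rate >= 0, fn_rate <= 1, fp_count >= 0,
            mateid_fraction >= 0, mateid_fraction <= 1)
  list(bnd_fraction = bnd_fraction, jitter_sd = jitter_sd, fn_rate = fn_rate,
       fp_count = fp_count, dialect = dialect,
       mateid_fraction = mateid_fraction)
}

## breakend pair encoding of one canonical event (two VCF body rows);
## DEL: s joins forward to e; DUP: junction runs back upstream;
## INV: same-strand join (one junction pair emitted per inversion)
.bndPairLines <- function(id, type, chrom, s, e, chrom2 = NULL,
                          strands = "+-", gt_cell, qual, with_mateid) {
  c2 <- chrom2 %||% chrom
  alts <- switch(type,
    DEL = c(sprintf("N[%s:%d[", c2, e), sprintf("]%s:%d]N", chrom, s)),
    DUP = c(sprintf("]%s:%d]N", c2, e), sprintf("N[%s:%d[", chrom, s)),
    INV = if (strands == "++")
            c(sprintf("N]%s:%d]", c2, e), sprintf("N]%s:%d]", chrom, s))
          else
            c(sprintf("[%s:%d[N", c2, e), sprintf("[%s:%d[N", chrom, s)),
    TRA = switch(strands,
      "+-" = c(sprintf("N[%s:%d[", c2, e), sprintf("]%s:%d]N", chrom, s)),
      "-+" = c(sprintf("]%s:%d]N", c2, e), sprintf("N[%s:%d[", chrom, s)),
      "++" = c(sprintf("N]%s:%d]", c2, e), sprintf("N]%s:%d]", chrom, s)),
      "--" = c(sprintf("[%s:%d[N", c2, e), sprintf("[%s:%d[N", chrom, s))))
  ids <- paste0(id, c("_bnd1", "_bnd2"))
  info1 <- if (with_mateid) sprintf("SVTYPE=BND;MATEID=%s", ids[2L]) else "SVTYPE=BND"
  info2 <- if (with_mateid) sprintf("SVTYPE=BND;MATEID=%s", ids[1L]) else "SVTYPE=BND"
  c(paste(chrom, s, ids[1L], "N", alts[1L], qual, "PASS", info1,
          "GT:AD:DP:GQ", gt_cell, sep = "\t"),
    paste(c2, e, ids[2L], "N", alts[2L], qual, "PASS", info2,
          "GT:AD:DP:GQ", gt_cell, sep = "\t"))
}

#' Emit a synthetic caller VCF from a truth set
#'
#' Each truth event surviving the false-negative draw is emitted either
#' canonically or as a breakend pair (per `bnd_fraction`), with Gaussian
#' positional jitter truncated to contig bounds. False positives are
#' placed uniformly at least 10 kb from any truth event of the same type.
#'
#' @param truth an [SVCallSet-class] from [plantEvents()].
#' @param profile a [synthCallerProfile()].
#' @param seed integer seed.
#' @param path output VCF path.
#' @param mapping_path optional TSV path linking emitted IDs to truth IDs.
#' @return list with `path`, `mapping` (data.frame `emitted_id`,
#'   `truth_id`) and `callset` (the emitted records re-read through
#'   [readSVVcf()]).
#' @export
emitCallerVcf <- function(truth, profile = synthCallerProfile(), seed = 1L,
                          path = tempfile(fileext = ".vcf"),
                          mapping_path = NULL) {
  stopifnot(is(truth, "SVCallSet"))
  set.seed(seed)
  genome <- truth@metadata$genome %||% .DEFAULT_GENOME
  rec <- truth@records
  lines <- list()
  mapping <- list()
  jit <- function(p, contig) {
    p2 <- p + as.integer(round(rnorm(1L, 0, profile$jitter_sd)))
    max(1L, min(as.integer(genome[[contig]]), p2))
  }
  gt_cell_of <- function(gt) {
    dp <- 20L + sample.int(30L, 1L)
    adv <- if (gt == "1/1") dp - sample.int(4L, 1L) else
      as.integer(round(dp * runif(1L, 0.35, 0.65)))
    sprintf("%s:%d,%d:%d:%d", gt, dp - adv, adv, dp, 20L + sample.int(40L, 1L))
  }

  for (i in seq_len(nrow(rec))) {
    if (runif(1L) < profile$fn_rate) next
    r <- rec[i, ]
    eid <- sprintf("%s_%s", profile$dialect, r$record_id)
    qual <- round(runif(1L, 30, 90), 1)
    gt_cell <- gt_cell_of(r$gt)
    as_bnd <- r$svtype != "INS" && runif(1L) < profile$bnd_fraction
    if (r$svtype == "TRA") {
      p1 <- jit(r$pos, r$chrom)
      p2 <- jit(r$pos2, r$chrom2)
      if (as_bnd) {
        new_lines <- .bndPairLines(eid, "TRA", r$chrom, p1, p2, r$chrom2,
                                   r$strands, gt_cell, qual,
                                   runif(1L) < profile$mateid_fraction)
        mapping[[length(mapping) + 1L]] <-
          data.frame(emitted_id = paste0(eid, c("_bnd1", "_bnd2")),
                     truth_id = r$record_id, stringsAsFactors = FALSE)
      } else {
        info <- sprintf("SVTYPE=TRA;CHR2=%s;POS2=%d;STRANDS=%s",
                        r$chrom2, p2, r$strands)
        new_lines <- paste(r$chrom, p1, eid, "N", "<TRA>", qual, "PASS",
                           info, "GT:AD:DP:GQ", gt_cell, sep = "\t")
        mapping[[length(mapping) + 1L]] <-
          data.frame(emitted_id = eid, truth_id = r$record_id,
                     stringsAsFactors = FALSE)
      }
    } else if (r$svtype == "INS") {
      p1 <- jit(r$pos, r$chrom)
      info <- sprintf("SVTYPE=INS;END=%d;SVLEN=%d", p1, r$svlen)
      new_lines <- paste(r$chrom, p1, eid, "N", "<INS>", qual, "PASS",
                         info, "GT:AD:DP:GQ", gt_cell, sep = "\t")
      mapping[[length(mapping) + 1L]] <-
        data.frame(emitted_id = eid, truth_id = r$record_id,
                   stringsAsFactors = FALSE)
    } else {
      p1 <- jit(r$pos, r$chrom)
      p2 <- jit(r$end, r$chrom)
      if (p2 <= p1) p2 <- p1 + abs(r$svlen)  # keep orientation under jitter
      if (as_bnd) {
        new_lines <- .bndPairLines(eid, r$svtype, r$chrom, p1, p2, NULL,
                                   r$strands, gt_cell, qual,
                                   runif(1L) < profile$mateid_fraction)
        mapping[[length(mapping) + 1L]] <-
          data.frame(emitted_id = paste0(eid, c("_bnd1", "_bnd2")),
                     truth_id = r$record_id, stringsAsFactors = FALSE)
      } else {
        svlen <- if (r$svtype == "DEL") -(p2 - p1) else p2 - p1
        info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;STRANDS=%s",
                        r$svtype, p2, svlen, r$strands)
        new_lines <- paste(r$chrom, p1, eid, "N",
                           sprintf("<%s>", r$svtype), qual, "PASS", info,
                           "GT:AD:DP:GQ", gt_cell, sep = "\t")
        mapping[[length(mapping) + 1L]] <-
          data.frame(emitted_id = eid, truth_id = r$record_id,
                     stringsAsFactors = FALSE)
      }
    }
    lines[[length(lines) + 1L]] <- new_lines
  }

  ## false positives, uniformly placed >= 10 kb from same-type truth events
  if (profile$fp_count > 0L) {
    for (f in seq_len(profile$fp_count)) {
      type <- sample(c("DEL", "INS", "INV", "DUP"), 1L)
      repeat {
        contig <- sample(names(genome), 1L)
        size <- sample(50:5000, 1L)
        p1 <- sample.int(as.integer(genome[[contig]] - size - 1L), 1L)
        same <- rec[rec$svtype == type & rec$chrom == contig, , drop = FALSE]
        if (!nrow(same) ||
            all(p1 > same$end + 10000L | (p1 + size) < same$pos - 10000L))
          break
      }
      eid <- sprintf("%s_fp_%d", profile$dialect, f)
      p2 <- if (type == "INS") p1 else p1 + size
      svlen <- if (type == "DEL") -size else size
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", type, p2, svlen)
      lines[[length(lines) + 1L]] <-
        paste(contig, p1, eid, "N", sprintf("<%s>", type),
              round(runif(1L, 30, 90), 1), "PASS", info,
              "GT:AD:DP:GQ", gt_cell_of("0/1"), sep = "\t")
      mapping[[length(mapping) + 1L]] <-
        data.frame(emitted_id = eid, truth_id = NA_character_,
                   stringsAsFactors = FALSE)
    }
  }

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=svmeld-synth;dialect=%s", profile$dialect),
           paste0("##contig=<ID=", names(genome), ",length=",
                  format(genome, scientific = FALSE, trim = TRUE), ">"),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Second chromosome\">",
           "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Second position\">",
           "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Strands\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "SAMPLE", sep = "\t"))
  writeLines(c(hdr, unlist(lines)), path)
  mapping <- if (length(mapping)) do.call(rbind, mapping) else
    data.frame(emitted_id = character(), truth_id = character(),
               stringsAsFactors = FALSE)
  if (!is.null(mapping_path))
    write.table(mapping, mapping_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(path = path,
       mapping = mapping,
       callset = readSVVcf(path, caller = profile$dialect))
}
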