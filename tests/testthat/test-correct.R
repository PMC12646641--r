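# helper: a same-chromosome BND pair with given ALT patterns
bnd_pair <- function(id, chrom, p1, p2, alt1, alt2, ad = c(NA, NA),
                     chrom2 = chrom) {
  makeSVRecords(
    record_id = paste0(id, c("_1", "_2")), chrom = c(chrom, chrom2),
    pos = as.integer(c(p1, p2)), end = as.integer(c(p1, p2)),
    svtype = "BND", chrom2 = c(chrom2, chrom), pos2 = as.integer(c(p2, p1)),
    alt = c(alt1, alt2), ad_alt = as.integer(ad),
    info = sprintf("MATEID=%s", paste0(id, c("_2", "_1"))))
}

test_that("same-chromosome decision table: DEL, DUP, INV, complex retention", {
  # forward junction skipping an interval deletes it
  del <- correctBreakends(SVCallSet(bnd_pair("d", "chr1", 1000, 5000,
                                             "N[chr1:5000[", "]chr1:1000]N")))
  r <- correctedRecords(del)
  expect_equal(r$svtype, "DEL")
  expect_equal(c(r$pos, r$end, r$svlen), c(1000, 5000, -4000))
  expect_equal(r$strands, "+-")

  # junction running back upstream is a tandem duplication
  dup <- correctBreakends(SVCallSet(bnd_pair("u", "chr1", 1000, 5000,
                                             "]chr1:5000]N", "N[chr1:1000[")))
  r <- correctedRecords(dup)
  expect_equal(r$svtype, "DUP")
  expect_equal(c(r$pos, r$end, r$svlen), c(1000, 5000, 4000))

  # same-orientation brackets on both halves imply inversion
  inv <- correctBreakends(SVCallSet(bnd_pair("v", "chr1", 1000, 5000,
                                             "N]chr1:5000]", "N]chr1:1000]")))
  r <- correctedRecords(inv)
  expect_equal(r$svtype, "INV")
  expect_equal(c(r$pos, r$end, r$svlen), c(1000, 5000, 4000))
  expect_equal(r$strands, "++")
  inv2 <- correctBreakends(SVCallSet(bnd_pair("w", "chr1", 1000, 5000,
                                              "[chr1:5000[N", "[chr1:1000[N")))
  expect_equal(correctedRecords(inv2)$svtype, "INV")
  expect_equal(correctedRecords(inv2)$strands, "--")

  # conflicting combination is retained as a BND pair with an audit reason
  cx <- correctBreakends(SVCallSet(bnd_pair("c", "chr1", 1000, 5000,
                                            "N[chr1:5000[", "N[chr1:1000[")))
  expect_equal(nrow(correctedRecords(cx)), 0L)
  expect_equal(nrow(retainedBnd(cx)), 2L)
  expect_true(all(svAudit(cx)$rule == "complex"))
})

test_that("pairs spanning less than 50 bp stay in BND form", {
  short <- correctBreakends(SVCallSet(bnd_pair("s", "chr1", 1000, 1049,
                                               "N[chr1:1049[", "]chr1:1000]N")))
  expect_equal(nrow(correctedRecords(short)), 0L)
  expect_true(all(svAudit(short)$rule == "min_span"))
  ok <- correctBreakends(SVCallSet(bnd_pair("s", "chr1", 1000, 1050,
                                            "N[chr1:1050[", "]chr1:1000]N")))
  expect_equal(correctedRecords(ok)$svtype, "DEL")
})

test_that("cross-chromosome pairings classify as balanced/unbalanced/merging TRA", {
  # lone pairing -> unbalanced
  lone <- correctBreakends(SVCallSet(bnd_pair("t", "chr1", 100, 900,
                                              "N[chr7:900[", "]chr1:100]N",
                                              chrom2 = "chr7")))
  r <- correctedRecords(lone)
  expect_equal(r$svtype, "TRA")
  expect_equal(r$subtype, "unbalanced")
  expect_equal(c(r$chrom, r$chrom2), c("chr1", "chr7"))
  expect_equal(c(r$pos, r$pos2), c(100, 900))

  # two reciprocal pairings with complementary orientations -> balanced
  bal <- correctBreakends(SVCallSet(rbind(
    bnd_pair("p", "chr1", 100, 900, "N[chr7:900[", "]chr1:100]N",
             chrom2 = "chr7"),
    bnd_pair("q", "chr1", 101, 901, "]chr7:901]N", "N[chr1:101[",
             chrom2 = "chr7"))))
  r <- correctedRecords(bal)
  expect_equal(nrow(r), 2L)
  expect_equal(r$subtype, c("balanced", "balanced"))

  # two pairings with identical coordinates and orientations -> one merged TRA
  mrg <- correctBreakends(SVCallSet(rbind(
    bnd_pair("m", "chr1", 100, 900, "N[chr7:900[", "]chr1:100]N",
             chrom2 = "chr7"),
    bnd_pair("n", "chr1", 102, 899, "N[chr7:899[", "]chr1:102]N",
             chrom2 = "chr7"))))
  r <- correctedRecords(mrg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$subtype, "merging")
  a <- svAudit(mrg)
  expect_true(all(a$output_id == r$record_id))

  # a half with no mate anywhere -> unbalanced TRA flagged no_mate
  solo <- makeSVRecords(record_id = "x", chrom = "chr1", pos = 100L,
                        end = 100L, svtype = "BND", chrom2 = "chr7",
                        pos2 = 900L, alt = "N[chr7:900[")
  nm <- correctBreakends(SVCallSet(solo))
  expect_equal(correctedRecords(nm)$svtype, "TRA")
  expect_equal(correctedRecords(nm)$subtype, "unbalanced")
  expect_equal(svAudit(nm)$rule, "no_mate")
})

test_that("non-BND records pass through untouched and BNDs are never INS", {
  cs <- callset(
    rec1("a", "chr1", 1000, 2000, "DEL"),
    rec1("b", "chr2", 100, 100, "INS", svlen = 200),
    bnd_pair("d", "chr1", 5000, 9000, "N[chr1:9000[", "]chr1:5000]N"))
  res <- correctBreakends(cs)
  out <- svRecords(res)
  expect_true(all(c("a", "b") %in% out$record_id))
  expect_equal(out[out$record_id == "a", ], svRecords(cs)[1, ],
               ignore_attr = TRUE)
  expect_equal(sum(out$svtype == "DEL"), 2L)  # pass-through + converted pair
  expect_true(all(out$svtype != "BND"))
  expect_equal(sum(out$svtype == "INS"), 1L)  # only the pass-through INS
  # identity on BND-free input
  res2 <- correctBreakends(callset(rec1("a", "chr1", 1000, 2000, "DEL")))
  expect_equal(svRecords(res2), svRecords(callset(rec1("a", "chr1", 1000, 2000, "DEL"))))
})

test_that("unparseable BND ALTs are retained with an audit reason", {
  solo <- makeSVRecords(record_id = "x", chrom = "chr1", pos = 100L,
                        end = 100L, svtype = "BND", chrom2 = "chr7",
                        pos2 = 900L, alt = "<BND>")
  res <- correctBreakends(SVCallSet(solo))
  expect_equal(nrow(retainedBnd(res)), 1L)
  expect_equal(svAudit(res)$rule, "unparseable")
})

test_that("audit conservation: every input appears exactly once, pairs collapse 2 to 1", {
  set.seed(5)
  truth <- plantEvents(c(DEL = 20, DUP = 20, INV = 20, TRA = 20), seed = 5)
  out <- emitCallerVcf(truth, synthCallerProfile(bnd_fraction = 1,
                                                 jitter_sd = 0, fn_rate = 0,
                                                 fp_count = 0), seed = 6)
  res <- correctBreakends(out$callset)
  a <- svAudit(res)
  expect_equal(sort(a$input_id), sort(svRecords(out$callset)$record_id))
  expect_equal(anyDuplicated(a$input_id), 0L)
  # each same-chromosome conversion consumed exactly two inputs
  conv <- a[a$disposition == "converted", ]
  expect_true(all(table(conv$output_id) == 2L))
  expect_equal(nSV(res@callset), 80L)
})

test_that("correction is idempotent", {
  cs <- callset(
    rec1("a", "chr1", 1000, 2000, "DEL"),
    bnd_pair("d", "chr1", 5000, 9000, "N[chr1:9000[", "]chr1:5000]N"),
    bnd_pair("c", "chr1", 11000, 15000, "N[chr1:15000[", "N[chr1:11000["),
    bnd_pair("s", "chr2", 100, 120, "N[chr2:120[", "]chr2:100]N"),
    makeSVRecords(record_id = "u", chrom = "chr1", pos = 99L, end = 99L,
                  svtype = "BND", chrom2 = "chr9", pos2 = 1L, alt = "<BND>"))
  once <- svRecords(correctBreakends(cs))
  twice <- svRecords(correctBreakends(SVCallSet(records = once)))
  ord <- function(d) { d <- d[order(d$record_id), ]; rownames(d) <- NULL; d }
  expect_equal(ord(twice), ord(once))
})

test_that("noiseless BND encodings recover every planted type with exact sizes", {
  truth <- plantEvents(c(DEL = 40, DUP = 40, INV = 40, TRA = 40), seed = 21)
  out <- emitCallerVcf(truth, synthCallerProfile(bnd_fraction = 1,
                                                 jitter_sd = 0, fn_rate = 0,
                                                 fp_count = 0), seed = 22)
  res <- correctBreakends(out$callset)
  corr <- svRecords(res)
  expect_equal(nrow(retainedBnd(res)), 0L)
  map <- out$mapping
  map$base <- sub("_bnd[12]$", "", map$emitted_id)
  tid <- map$truth_id[match(sub("_bnd[12]$", "", corr$record_id), map$base)]
  tr <- svRecords(truth)
  planted <- tr[match(tid, tr$record_id), ]
  expect_equal(corr$svtype, planted$svtype)
  nontra <- corr$svtype != "TRA"
  expect_equal(abs(corr$svlen[nontra]), abs(planted$svlen[nontra]))
  expect_equal(corr$pos[nontra], planted$pos[nontra])
  # translocation breakpoints match the planted junction exactly
  expect_equal(corr$pos[!nontra], planted$pos[!nontra])
  expect_equal(corr$pos2[!nontra], planted$pos2[!nontra])
  expect_equal(corr$strands, planted$strands)
})
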