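test_that("pairwise matching applies distance, size-ratio and Jaccard criteria", {
  p <- mergeParams()
  a <- rec1("a", "chr1", 1000, 2000, "DEL")
  expect_true(svPairMatch(a, a, p))  # reflexivity
  # distance 40 <= 50, equal sizes, Jaccard 961/1041 ~ 0.923 >= 0.7
  b <- rec1("b", "chr1", 1040, 2040, "DEL")
  expect_true(svPairMatch(a, b, p))
  # size ratio 1000/400 = 2.5 > 1.3
  c_ <- rec1("c", "chr1", 1000, 1400, "DEL")
  expect_false(svPairMatch(a, c_, p))
  # Jaccard alone can reject: same size but shifted by the full distance
  # budget on a short event
  s1 <- rec1("s1", "chr1", 1000, 1100, "DEL")
  s2 <- rec1("s2", "chr1", 1050, 1150, "DEL")
  expect_equal(intervalJaccard(1000, 1100, 1050, 1150), 51 / 151)
  expect_false(svPairMatch(s1, s2, p))
  # INS waives the Jaccard test: position + size ratio only
  i1 <- rec1("i1", "chr1", 1000, 1000, "INS", svlen = 300)
  i2 <- rec1("i2", "chr1", 1030, 1030, "INS", svlen = 320)
  expect_true(svPairMatch(i1, i2, p))
  # TRA: both breakpoints within tra_distance, strands consistent
  t1 <- rec1("t1", "chr1", 1000, 1000, "TRA", chrom2 = "chr7", pos2 = 5000,
             strands = "+-")
  t2 <- rec1("t2", "chr1", 1400, 1400, "TRA", chrom2 = "chr7", pos2 = 5400,
             strands = "+-")
  t3 <- rec1("t3", "chr1", 1400, 1400, "TRA", chrom2 = "chr7", pos2 = 5400,
             strands = "-+")
  t4 <- rec1("t4", "chr1", 1400, 1400, "TRA", chrom2 = "chr7", pos2 = 5400,
             strands = ".")
  expect_true(svPairMatch(t1, t2, p))
  expect_false(svPairMatch(t1, t3, p))
  expect_true(svPairMatch(t1, t4, p))  # unknown strands match anything
  expect_true(svPairMatch(t1, t3,
                          mergeParams(require_strand_match_tra = FALSE)))
  expect_error(svPairMatch(a, i1, p), class = "svmeld_validation_error")
})

test_that("clustering groups matching calls and keeps distinct events apart", {
  p <- mergeParams()
  cs1 <- callset(rec1("a", "chr1", 1000, 2000, "DEL", caller = "m"),
                 caller = "m")
  cs2 <- callset(rec1("b", "chr1", 1010, 2010, "DEL", caller = "l"),
                 caller = "l")
  cs3 <- callset(rec1("c", "chr1", 1020, 2020, "DEL", caller = "d"),
                 caller = "d")
  merged <- mergeSVSets(list(cs1, cs2, cs3), p)
  expect_equal(nSV(merged), 1L)
  expect_equal(svRecords(merged)$support_count, 3L)
  expect_equal(svSupport(merged)[[1L]], c("m", "l", "d"))

  far <- mergeSVSets(list(cs1, callset(rec1("z", "chr1", 12000, 13000, "DEL",
                                            caller = "l"), caller = "l")), p)
  expect_equal(nSV(far), 2L)

  # transitive chain A~B, B~C, A!~C merges into one component
  a <- rec1("a", "chr1", 1000, 3000, "DEL", caller = "m")
  b <- rec1("b", "chr1", 1045, 3045, "DEL", caller = "l")
  c_ <- rec1("c", "chr1", 1090, 3090, "DEL", caller = "d")
  expect_true(svPairMatch(a, b, p) && svPairMatch(b, c_, p) &&
                !svPairMatch(a, c_, p))
  chain <- mergeSVSets(list(callset(a, caller = "m"), callset(b, caller = "l"),
                            callset(c_, caller = "d")), p)
  expect_equal(nSV(chain), 1L)
  expect_equal(nrow(svMembers(chain)[[1L]]), 3L)
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  p <- mergeParams()
  for (seed in c(101, 202, 303, 404, 505)) {
    rec <- random_records(sample(c(30, 60, 120), 1L), seed)
    cs <- SVCallSet(records = rec)
    merged <- mergeSVSets(list(cs), p)
    # implementation partition
    got <- partition_sets(
      unlist(lapply(svMembers(merged), function(m) m$record_id)),
      rep(seq_along(svMembers(merged)),
          vapply(svMembers(merged), nrow, integer(1L))))
    # oracle partition restricted to same-bucket matches
    M <- oracle_match_matrix(rec, p)
    want <- partition_sets(rec$record_id, oracle_components(M))
    expect_equal(got, want)
    # partition property: every record in exactly one merged component
    expect_equal(sort(unlist(lapply(svMembers(merged), function(m) m$record_id))),
                 sort(rec$record_id))
  }
})

test_that("input order does not change the partition or support sets", {
  rec <- random_records(80, 77)
  p <- mergeParams()
  part_of <- function(r) {
    m <- mergeSVSets(list(SVCallSet(records = r)), p)
    lapply(svMembers(m), function(x) sort(x$record_id))
  }
  canon <- function(pp) unname(pp[order(vapply(pp, `[`, character(1L), 1L))])
  p1 <- canon(part_of(rec))
  set.seed(1)
  p2 <- canon(part_of(rec[sample(nrow(rec)), ]))
  expect_equal(p1, p2)
})

test_that("genotype resolution: majority, then variant AD, then input order", {
  # majority voting
  m <- rbind(rec1("a", "chr1", 1, 100, "DEL", gt = "0/1", caller = "x"),
             rec1("b", "chr1", 1, 100, "DEL", gt = "0/1", caller = "y"),
             rec1("c", "chr1", 1, 100, "DEL", gt = "1/1", caller = "z"))
  expect_equal(resolveGenotype(m)$gt, "0/1")
  # AD tie-break
  m2 <- rbind(rec1("a", "chr1", 1, 100, "DEL", gt = "0/1", ad_alt = 30L),
              rec1("b", "chr1", 1, 100, "DEL", gt = "1/1", ad_alt = 12L))
  expect_equal(resolveGenotype(m2)$gt, "0/1")
  m2b <- rbind(rec1("a", "chr1", 1, 100, "DEL", gt = "0/1", ad_alt = 5L),
               rec1("b", "chr1", 1, 100, "DEL", gt = "1/1", ad_alt = 40L))
  expect_equal(resolveGenotype(m2b)$gt, "1/1")
  # input-order tie-break when AD is missing
  m3 <- rbind(rec1("a", "chr1", 1, 100, "DEL", gt = "0/1", caller = "x"),
              rec1("b", "chr1", 1, 100, "DEL", gt = "1/1", caller = "y"))
  expect_equal(resolveGenotype(m3)$gt, "0/1")
  # missing genotypes never outvote a real call
  m4 <- rbind(rec1("a", "chr1", 1, 100, "DEL", gt = "./."),
              rec1("b", "chr1", 1, 100, "DEL", gt = "./."),
              rec1("c", "chr1", 1, 100, "DEL", gt = "1/1"))
  expect_equal(resolveGenotype(m4)$gt, "1/1")
  expect_equal(resolveGenotype(m4[1:2, ])$gt, "./.")
})

test_that("representative selection prefers QUAL, then AD, then input order", {
  cs1 <- callset(rec1("lowq", "chr1", 1000, 2000, "DEL", qual = 10,
                      caller = "m"), caller = "m")
  cs2 <- callset(rec1("highq", "chr1", 1005, 2005, "DEL", qual = 90,
                      caller = "l"), caller = "l")
  merged <- mergeSVSets(list(cs1, cs2))
  expect_equal(svRecords(merged)$record_id, "highq")
  expect_equal(svRecords(merged)$qual, 90)
})

test_that("quality filtering drops on threshold or missing attribute and reports counts", {
  cs1 <- callset(rec1("a", "chr1", 1000, 2000, "DEL", qual = 10, ad_alt = 3L,
                      caller = "m"), caller = "m")
  cs2 <- callset(rec1("b", "chr1", 9000, 9900, "DEL", qual = 30,
                      caller = "m"), caller = "m")
  merged <- mergeSVSets(list(cs1), callers = "m")
  merged2 <- mergeSVSets(list(SVCallSet(rbind(svRecords(cs1)[0, ],
                                              rbind(svRecords(cs1),
                                                    svRecords(cs2))))))
  # no thresholds: identity
  expect_equal(nSV(qualityFilter(merged2)$callset), 2L)
  # min QUAL 20 keeps one
  f <- qualityFilter(merged2, min_qual = 20)
  expect_equal(svRecords(f$callset)$record_id, "b")
  expect_equal(f$report$dropped_by$qual, 1L)
  # AD threshold with AD missing: dropped and counted as missing
  f2 <- qualityFilter(merged2, min_support_reads = 5)
  expect_equal(nSV(f2$callset), 0L)
  expect_equal(f2$report$dropped_by$support_reads, 1L)
  expect_equal(f2$report$dropped_missing$support_reads, 1L)
})
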