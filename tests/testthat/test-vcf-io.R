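test_that("symbolic, breakend and derived-field parsing normalize correctly", {
  p <- write_vcf_lines(c(
    "chr1\t1000\ta\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000;SVLEN=-1000\tGT\t0/1",
    "chr1\t1500\tb\tN\tN[chr5:5000[\t50\tPASS\tSVTYPE=BND\tGT\t0/1",
    "chr1\t4000\tc\tN\t<DEL>\t40\tPASS\tSVTYPE=DEL;END=4600\tGT\t1/1",
    "chr2\t100\td\tN\t<DUP>\t30\tPASS\tSVTYPE=DUP;SVLEN=300\tGT\t0/1",
    "chr2\t900\te\tN\t<INS>\t30\tPASS\tSVTYPE=INS;SVLEN=75\tGT\t0/1"))
  cs <- readSVVcf(p, caller = "manta")
  r <- svRecords(cs)
  expect_equal(nrow(r), 5L)
  expect_equal(r$svtype, c("DEL", "BND", "DEL", "DUP", "INS"))
  # direct field mapping
  expect_equal(r$pos[1], 1000L)
  expect_equal(r$end[1], 2000L)
  expect_equal(r$svlen[1], -1000L)
  # breakend grammar puts the mate in chrom2/pos2
  expect_equal(r$chrom2[2], "chr5")
  expect_equal(r$pos2[2], 5000L)
  # SVLEN derived from END - POS with the DEL sign convention
  expect_equal(r$svlen[3], -600L)
  # END derived from POS + |SVLEN|
  expect_equal(r$end[4], 400L)
  # INS is point-like
  expect_equal(r$end[5], r$pos[5])
  expect_equal(r$source_caller, rep("manta", 5))
})

test_that("records lacking coordinates are rejected individually, parsing continues", {
  p <- write_vcf_lines(c(
    "chr1\t1000\tok\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000\tGT\t0/1",
    "chr1\t2000\tbad\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL\tGT\t0/1",
    "chr1\t3000\tok2\tN\t<INV>\t60\tPASS\tSVTYPE=INV;END=3500\tGT\t0/1"))
  cs <- readSVVcf(p, "x")
  expect_equal(nSV(cs), 2L)
  rj <- svRejects(cs)
  expect_equal(rj$id, "bad")
  expect_match(rj$reason, "END nor SVLEN")
  # count conservation: records out + rejects = body lines
  expect_equal(nSV(cs) + nrow(rj), 3L)
})

test_that("a malformed header is a parse error naming the line", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "this is not a header",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), p)
  expect_error(readSVVcf(p, "x"), "line 2", class = "svmeld_io_error")
  p2 <- tempfile(fileext = ".vcf")
  writeLines("not a vcf", p2)
  expect_error(readSVVcf(p2, "x"), "line 1", class = "svmeld_io_error")
})

test_that("multi-allelic SV lines split into one record per ALT", {
  p <- write_vcf_lines(
    "chr1\t1000\tm\tN\t<DEL>,<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000;SVLEN=-1000,-1000\tGT\t0/1")
  cs <- readSVVcf(p, "x")
  expect_equal(nSV(cs), 2L)
  expect_equal(svRecords(cs)$record_id, c("m_1", "m_2"))
})

test_that("caller dialect adapters normalize strands, CHR2/END and support tags", {
  # DELLY: BND partner in CHR2 + END, orientation in CT, support in DV
  p <- write_vcf_lines(
    "chr1\t500\tdl\tN\t<BND>\t99\tPASS\tSVTYPE=BND;CHR2=chr9;END=4242;CT=3to5;DV=17\tGT\t0/1")
  r <- svRecords(readSVVcf(p, "delly"))
  expect_equal(r$chrom2, "chr9")
  expect_equal(r$pos2, 4242L)
  expect_equal(r$strands, "+-")
  expect_equal(r$ad_alt, 17L)
  # LUMPY: STRANDS carries evidence counts
  p2 <- write_vcf_lines(
    "chr1\t500\tlp\tN\t<DEL>\t99\tPASS\tSVTYPE=DEL;END=900;STRANDS=+-:6;SU=9\tGT\t0/1")
  r2 <- svRecords(readSVVcf(p2, "lumpy"))
  expect_equal(r2$strands, "+-")
  expect_equal(r2$ad_alt, 9L)
  # Sniffles: SUPPORT read count stands in for AD
  p3 <- write_vcf_lines(
    "chr1\t500\tsn\tN\t<INV>\t99\tPASS\tSVTYPE=INV;END=900;SUPPORT=23\tGT\t./.")
  expect_equal(svRecords(readSVVcf(p3, "sniffles"))$ad_alt, 23L)
  # unknown caller falls back to the generic adapter
  p4 <- write_vcf_lines(
    "chr1\t500\tgn\tN\t<INV>\t99\tPASS\tSVTYPE=INV;END=900;SUPPORT=5\tGT\t0/1")
  expect_equal(svRecords(readSVVcf(p4, "somenewcaller"))$ad_alt, 5L)
})

test_that("VCF round trip is field-equal, including two-breakpoint TRA records", {
  p <- write_vcf_lines(c(
    "chr1\t1000\tt1\tN\t<TRA>\t60\tPASS\tSVTYPE=TRA;CHR2=chr7;POS2=900\tGT:AD:DP:GQ\t0/1:10,20:30:40",
    "chr1\t2000\td1\tN\t<DEL>\t50.5\tPASS\tSVTYPE=DEL;END=3000;SVLEN=-1000\tGT:AD:DP:GQ\t1/1:2,28:30:60",
    "chr2\t100\tb1\tN\t]chr2:5000]N\t.\tlowqual\tSVTYPE=BND;MATEID=b2;EXTRA=zz\tGT:AD:DP:GQ\t0/1:.:.:."))
  cs <- readSVVcf(p, caller = "manta")
  out <- tempfile(fileext = ".vcf")
  writeSVVcf(cs, out)
  cs2 <- readSVVcf(out, caller = "manta")
  r1 <- svRecords(cs); r2 <- svRecords(cs2)
  r1$source_file <- r2$source_file <- "."
  expect_equal(r1, r2)
  # TRA carries both breakpoints on one line
  expect_equal(r1$chrom2[r1$svtype == "TRA"], "chr7")
  # unknown INFO tags survive verbatim
  expect_match(r1$info[r1$svtype == "BND"], "EXTRA=zz")
  # the TRA breakpoint pair is emitted with CHR2/POS2 on a single line
  tra_line <- grep("SVTYPE=TRA", readLines(out), value = TRUE)
  expect_length(tra_line, 1L)
  expect_match(tra_line, "CHR2=chr7;POS2=900")
})

test_that("SVCF round trip is the identity, and version mismatch errors", {
  p <- write_vcf_lines(c(
    "chr1\t1000\tt1\tN\t<TRA>\t60\tPASS\tSVTYPE=TRA;CHR2=chr7;POS2=900\tGT\t0/1",
    "chr1\t2000\td1\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=3000\tGT\t0/1"))
  cs <- readSVVcf(p, "manta")
  # add merge-style support annotations: they must survive serialization
  r <- svRecords(cs)
  r$support <- "manta,delly"
  r$support_count <- 2L
  cs <- SVCallSet(records = r, sampleNames = cs@sampleNames)
  f <- tempfile(fileext = ".svcf")
  writeSvcf(cs, f)
  back <- readSvcf(f)
  expect_equal(svRecords(back), svRecords(cs))
  expect_equal(svRecords(back)$support, rep("manta,delly", 2))
  # write(read(write(x))) is byte-stable
  f2 <- tempfile(fileext = ".svcf")
  writeSvcf(back, f2)
  expect_identical(readLines(f)[-1], readLines(f2)[-1])
  # version stamp is enforced
  bad <- tempfile(fileext = ".svcf")
  writeLines(c("##svmeldSVCF-99.0", readLines(f)[-1]), bad)
  expect_error(readSvcf(bad), "version", class = "svmeld_validation_error")
})

test_that("empty collections write header-only files that read back empty", {
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(SVCallSet(), f)
  expect_equal(nSV(readSVVcf(f, "x")), 0L)
  f2 <- tempfile(fileext = ".svcf")
  writeSvcf(SVCallSet(), f2)
  expect_equal(nSV(readSvcf(f2)), 0L)
})

test_that("normalization is idempotent: re-reading a written callset changes nothing", {
  set.seed(42)
  truth <- plantEvents(c(DEL = 10, INS = 10, INV = 10, DUP = 10, TRA = 10),
                       seed = 42)
  out <- emitCallerVcf(truth, synthCallerProfile(bnd_fraction = 0.5),
                       seed = 43)
  cs <- out$callset
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(cs, f)
  cs2 <- readSVVcf(f, caller = "synthcaller")
  r1 <- svRecords(cs); r2 <- svRecords(cs2)
  r1$source_file <- r2$source_file <- "."
  expect_equal(r1, r2)
})
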