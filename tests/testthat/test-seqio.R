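test_that("FASTQ reading decodes qualities at both offsets", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1 extra comment", "ACGT", "+", "IIII",
               "@r2", "ACGTN", "+", "!#%')"), f)
  rd <- read_fastq(f, library = "libX")
  expect_equal(rd$id, c("r1", "r2"))
  expect_equal(rd$quals[[1]], c(40L, 40L, 40L, 40L))
  expect_equal(rd$quals[[2]], c(0L, 2L, 4L, 6L, 8L))
  expect_equal(rd$library, rep("libX", 2))

  f64 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "hhhh"), f64)
  expect_equal(read_fastq(f64, offset = 64)$quals[[1]], rep(40L, 4))
  expect_error(read_fastq(f64, offset = 64 + 50), "offset")
})

test_that("empty and malformed FASTQ are handled per contract", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), f)
  expect_equal(nrow(read_fastq(f)), 0L)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@bad1", paste(rep("A", 35), collapse = ""), "+",
               paste(rep("I", 34), collapse = "")), bad)
  expect_error(read_fastq(bad), "bad1")
})

test_that("FASTQ and FASTA round-trips preserve bases and qualities", {
  set.seed(1)
  reads <- data.table::data.table(
    id = sprintf("r%03d", 1:25), library = "lib1",
    bases = vapply(1:25, function(i) rand_dna(sample(20:40, 1)),
                   character(1)))
  reads$quals <- lapply(nchar(reads$bases),
                        function(n) sample(0:41, n, TRUE))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f, library = "lib1")
  expect_equal(back$bases, reads$bases)
  expect_equal(back$quals, reads$quals)

  fa <- withr::local_tempfile(fileext = ".fa")
  ref <- reference_set(c(s1 = rand_dna(120), s2 = rand_dna(75)))
  write_fasta(ref, fa)
  expect_equal(unclass(read_fasta_reference(fa)), unclass(ref))
})

test_that("reference sets enforce their invariants", {
  expect_error(reference_set(c("ACGT")), "name")
  expect_error(reference_set(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(reference_set(c(a = "")), "empty")
  expect_error(reference_set(c(a = "ACGU")), "outside")
  r <- reference_set(c(a = "acgtn", b = "ACG"))
  expect_equal(unname(unclass(r)[1]), "ACGTN")
  expect_equal(total_length(r), 8L)
})

test_that("EST FASTA reading parses clones, directions and qualities", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">cloneA.f", "ACGT", ">cloneA.r", "GGCCA", ">anonymous1",
               "TTTT"), fa)
  est <- read_fasta_with_quals(fa)
  expect_equal(est$clone_id[1:2], c("cloneA", "cloneA"))
  expect_equal(est$direction, c("five_prime", "three_prime", "unknown"))
  expect_true(all(unlist(est$quals) == 20L))   # default constant quality

  qf <- withr::local_tempfile(fileext = ".qual")
  writeLines(c(">cloneA.f", "40 40 30 20", ">cloneA.r", "9 9 9 9 9",
               ">anonymous1", "1 2 3 4"), qf)
  est2 <- read_fasta_with_quals(fa, qf)
  expect_equal(est2$quals[[1]], c(40L, 40L, 30L, 20L))
  bad <- withr::local_tempfile(fileext = ".qual")
  writeLines(c(">cloneA.f", "40 40", ">cloneA.r", "9 9 9 9 9",
               ">anonymous1", "1 2 3 4"), bad)
  expect_error(read_fasta_with_quals(fa, bad), "cloneA.f")
})

test_that("variant export writes TSV and grammatical VCF with anchored indels", {
  # construct a deletion call from observations: deletion of "AC" with
  # the internal 0-based event position 10
  ref <- reference_set(c(chr = paste0(rand_dna(9), "TACAC", rand_dna(30))))
  obs <- data.table::data.table(
    ref = "chr", pos = 9L, ref_base = "T",
    library = rep(c("l1", "l2"), each = 6),
    allele = rep(c("-AC", "T"), 6),
    qual = 35L, aln = 1:12)
  p <- structure(list(obs = obs, reference = ref, libraries = c("l1", "l2")),
                 class = "pileup")
  v <- call_variants_two_stage(p, call_params())
  expect_equal(nrow(v), 1L)
  expect_equal(v$variant_type, "del")
  expect_equal(v$position, 10L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v, vcf, "vcf", reference = ref)
  expect_length(validate_vcf(vcf), 0)
  row <- strsplit(grep("^chr", readLines(vcf), value = TRUE), "\t")[[1]]
  expect_equal(as.integer(row[2]), 10L)          # 1-based anchor POS
  expect_equal(row[4], paste0("T", "AC"))        # anchor + deleted bases
  expect_equal(row[5], "T")
  expect_equal(row[10], "3,3")                   # per-library AD

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, tsv, "tsv")
  expect_equal(nrow(data.table::fread(tsv)), 1L)
  expect_error(write_variants(v, tsv, "xlsx"))

  # empty set gives a header-only, still-valid VCF
  v0 <- v[0]
  data.table::setattr(v0, "libraries", c("l1", "l2"))
  empty <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v0, empty, "vcf")
  expect_length(validate_vcf(empty), 0)
  expect_false(any(grepl("^chr", readLines(empty))))
})

test_that("the VCF validator flags broken files", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               paste(c("chr", "0", ".", "AX", "T", ".", "PASS", "."),
                     collapse = "\t")), f)
  probs <- validate_vcf(f)
  expect_true(any(grepl("POS", probs)))
  expect_true(any(grepl("REF", probs)))
})
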