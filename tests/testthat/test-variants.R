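test_that("pileups accumulate one observation per read and column", {
  set.seed(61)
  ref <- reference_set(c(u = rand_dna(600)))
  idx <- build_index(ref)
  # two overlapping reads disagreeing at one site
  r1 <- substr(unclass(ref)[["u"]], 101, 135)
  r2 <- substr(unclass(ref)[["u"]], 111, 145)
  substr(r2, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                              substr(r2, 8, 8))[1]      # ref pos 117 (0b)
  reads <- data.table::data.table(
    id = c("a", "b"), library = c("l1", "l2"), bases = c(r1, r2),
    quals = replicate(2, rep(35L, 35), simplify = FALSE))
  mr <- map_library(reads, idx)
  p <- build_pileups(mr, ref)
  col <- pileup_column(p, "u", 117L)
  expect_equal(nrow(col), 2L)
  expect_equal(length(unique(col$allele)), 2L)
  # single-covered columns carry the reference base once
  col2 <- pileup_column(p, "u", 101L)
  expect_equal(nrow(col2), 1L)
  expect_equal(col2$allele, attr(col2, "ref_base"))

  # brute-force accumulation oracle: per aligned M base, count rows
  segs <- mr$segments[op == "M"]
  expected_n <- sum(segs$len)
  expect_equal(nrow(p$obs), expected_n)
})

test_that("gap events become anchored, left-normalised indel observations", {
  set.seed(62)
  base <- rand_dna(300)
  # plant an unambiguous context: ...G T T A C A C G... delete one "AC"
  substr(base, 150, 157) <- "GTTACACG"
  ref <- reference_set(c(u = base))
  idx <- build_index(ref)
  readdel <- paste0(substr(base, 120, 152),                 # up to "..TT"
                    substr(base, 155, 170))                 # skip "AC"
  reads <- data.table::data.table(
    id = "d1", library = "l1", bases = readdel,
    quals = list(rep(35L, nchar(readdel))))
  mr <- map_library(reads, idx, align_params())
  p <- build_pileups(mr, ref)
  ind <- p$obs[startsWith(allele, "-")]
  expect_equal(nrow(ind), 1L)
  # deletion of "AC" in an (AC)x2 run left-normalises to the first copy
  # (0-based event position 152), observed at the anchor base 5' of it
  expect_equal(ind$pos, 151L)
  expect_equal(ind$allele, "-AC")
  # the anchoring read contributes exactly one observation at that column
  expect_equal(nrow(p$obs[pos == 151L]), 1L)
})

test_that("single-site decisions follow the d/ratio/quality rules", {
  p <- call_params()
  col <- function(r, a, q = 35L, lib = "l1", alt = "T")
    data.table::data.table(
      library = lib, allele = c(rep("A", r), rep(alt, a)),
      qual = q)
  # 4 ref / 3 alt at high quality -> called (ratio well inside 1:7..7:1)
  expect_false(is.null(call_site(col(4, 3), p, "per_library",
                                 ref_base = "A")))
  # 21:3 sits exactly on the inclusive 7:1 boundary -> still called
  expect_false(is.null(call_site(col(21, 3), p, "per_library",
                                 ref_base = "A")))
  # 22:3 exceeds it -> no call
  expect_null(call_site(col(22, 3), p, "per_library", ref_base = "A"))
  # alternate reads below quality 20 are invisible
  mixed <- rbind(col(4, 0), col(0, 3, q = 19L))
  expect_null(call_site(mixed, p, "per_library", ref_base = "A"))
  # all-alternate sites fail the ratio bound within the unit
  expect_null(call_site(col(0, 10), p, "per_library", ref_base = "A"))
  # provenance flags are reported
  r <- call_site(col(4, 3), p, "per_library", ref_base = "A")
  expect_true(r$flags$d_pass && r$flags$ratio_pass && r$flags$qual_pass)
  expect_equal(r$variant_type, "snp")
})

test_that("decisions match a brute-force filter oracle on random columns", {
  set.seed(71)
  p <- call_params()
  for (k in 1:400) {
    cl <- random_column()
    got_lib <- !is.null(call_site(data.table::as.data.table(cl), p,
                                  "per_library", ref_base = "A"))
    got_pool <- !is.null(call_site(data.table::as.data.table(cl), p,
                                   "pooled", ref_base = "A"))
    expect_equal(got_lib, brute_force_call(cl, "A", p, "per_library"))
    expect_equal(got_pool, brute_force_call(cl, "A", p, "pooled"))
  }
})

test_that("two-stage calling is the union of its stages", {
  libs <- c("l1", "l2", "l3")
  mkobs <- function(pos, spec) {
    # spec: list(lib = c(ref, alt))
    rows <- lapply(names(spec), function(lb)
      data.table::data.table(
        ref = "chr1", pos = as.integer(pos), ref_base = "A", library = lb,
        allele = c(rep("A", spec[[lb]][1]), rep("G", spec[[lb]][2])),
        qual = 35L))
    data.table::rbindlist(rows)
  }
  # site 10: only pooled passes (1+1+1 alternates, pooled ratio fine)
  # site 20: l1 passes alone, pooled ratio 30:3 = 10:1 fails
  # site 30: passes both ways
  obs <- rbind(mkobs(10, list(l1 = c(3, 1), l2 = c(3, 1), l3 = c(3, 1))),
               mkobs(20, list(l1 = c(4, 3), l2 = c(13, 0), l3 = c(13, 0))),
               mkobs(30, list(l1 = c(4, 4), l2 = c(4, 4), l3 = c(4, 4))))
  obs[, aln := .I]
  p <- make_pileup(obs)
  v <- call_variants_two_stage(p, call_params())
  expect_equal(v$position, c(10L, 20L, 30L))
  expect_equal(v$call_stage, c("pooled", "per_library", "both"))
  # union property: two-stage equals the union of the stages run alone
  v1 <- call_variants(p, call_params(), mode = "per_library")
  v2 <- call_variants(p, call_params(), mode = "pooled")
  expect_setequal(v$position, union(v1$position, v2$position))
  # no alternates anywhere -> empty table
  clean <- mkobs(40, list(l1 = c(5, 0)))
  clean[, aln := .I]
  expect_equal(nrow(call_variants_two_stage(make_pileup(clean))), 0L)
})

test_that("threshold monotonicity and the long-read d=2/l=2 mode hold", {
  set.seed(81)
  # fixed random observation set over 200 sites
  obs <- data.table::rbindlist(lapply(1:200, function(s) {
    cl <- random_column()
    if (nrow(cl) == 0) return(NULL)
    data.table::data.table(ref = "chr1", pos = as.integer(s),
                           ref_base = "A", library = cl$library,
                           allele = cl$allele, qual = cl$qual)
  }))
  obs[, aln := .I]
  p <- make_pileup(obs)
  n_at <- function(...) nrow(call_variants_two_stage(p, call_params(...)))
  base <- n_at()
  expect_lte(n_at(d = 4, l = 4), base)
  expect_lte(base, n_at(d = 2, l = 2))
  expect_lte(n_at(min_base_qual = 30), base)
  expect_lte(n_at(max_ratio = 3), base)
  expect_gte(n_at(max_ratio = 20), base)

  # d=3 calls are a subset of d=2 calls; EST mode flags lower confidence
  v3 <- call_variants_two_stage(p, call_params())
  v2 <- call_from_long_reads(p)
  expect_true(all(v3$position %in% v2$position))
  expect_true(all(v2$lower_confidence))
  # two alternate reads suffice at d=2 but not d=3
  two <- data.table::data.table(ref = "chr1", pos = 5L, ref_base = "A",
                                library = "l1",
                                allele = c(rep("A", 4), "G", "G"),
                                qual = 35L, aln = 1:6)
  expect_equal(nrow(call_from_long_reads(make_pileup(two))), 1L)
  expect_equal(nrow(call_variants_two_stage(make_pileup(two))), 0L)
})
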