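test_that("index samples words at the shift stride on both strands", {
  ref <- reference_set(c(r1 = "ACGTACGTACGTACGT"))   # 16 bp
  idx <- build_index(ref, word_size = 8, shift_size = 11)
  # offsets 0 and 11 are the stride positions; 11+8 > 16 so only 0 remains
  expect_equal(idx$words[strand == "+"]$offset, 0L)
  expect_equal(idx$words[strand == "-"]$offset, 0L)

  # a palindromic word is indexed once per strand with distinct tags
  pal <- reference_set(c(p = "ACGTACGTACGT"))
  ip <- build_index(pal, word_size = 12, shift_size = 12)
  expect_equal(sort(ip$words$strand), c("-", "+")[order(c("-", "+"))])
  expect_equal(length(unique(ip$words$word)), 1L)

  expect_error(build_index(ref, word_size = 3), "word_size")
  expect_error(build_index(ref, shift_size = 10), "shift_size")
  expect_warning(build_index(reference_set(c(s = "ACGT", l = rand_dna(40))),
                             word_size = 12, shift_size = 12), "shorter")
  # empty reference set -> empty index
  e <- build_index(reference_set(setNames(character(0), character(0))))
  expect_equal(nrow(e$words), 0L)
})

test_that("seed hits equal an exhaustive word-scan oracle", {
  set.seed(31)
  ref <- reference_set(c(a = rand_dna(300), b = rand_dna(260)))
  idx <- build_index(ref, word_size = 12, shift_size = 12)
  w <- 12L
  for (k in 1:25) {
    read <- if (k <= 15) {
      s <- sample(1:260, 1)
      substr(unclass(ref)[[sample(c("a", "b"), 1)]], s, s + 34)
    } else rand_dna(35)
    got <- seed_hits(read, idx, merge_dist = 0L)
    # oracle: enumerate indexed words by the stated rule, scan the read
    want <- list()
    m <- nchar(read)
    for (nm in names(ref)) {
      for (str in c("+", "-")) {
        s <- if (str == "+") unclass(ref)[[nm]] else revcomp(unclass(ref)[[nm]])
        L <- nchar(s)
        for (off in seq(0, L - w, by = 12)) {
          word <- substr(s, off + 1, off + w)
          for (ro in 0:(m - w)) {
            if (substr(read, ro + 1, ro + w) == word) {
              d <- if (str == "+") off - ro else L - off - m + ro
              want[[length(want) + 1]] <- data.frame(ref = nm, strand = str,
                                                     diag = d)
            }
          }
        }
      }
    }
    want <- if (length(want)) unique(do.call(rbind, want)) else
      data.frame(ref = character(), strand = character(), diag = integer())
    got_key <- sort(with(got, paste(ref, strand, diag)))
    want_key <- sort(with(want, paste(ref, strand, diag)))
    expect_equal(got_key, want_key)
  }
  # a read of all N yields no candidates
  expect_equal(nrow(seed_hits(strrep("N", 35), idx)), 0L)
})

test_that("banded extension honours identity, caps and the DP oracle", {
  set.seed(41)
  win <- rand_dna(80)
  read <- substr(win, 21, 55)
  a <- banded_sw(read, win, align_params(), diag_offset = 20)
  expect_equal(a$score, 35L)
  expect_equal(a$n_mismatch, 0L)
  expect_equal(c(a$win_start, a$win_end), c(20L, 55L))

  # three scattered mismatches exceed the two-mismatch cap
  r3 <- read
  for (p in c(6, 16, 26)) {
    cur <- substr(r3, p, p)
    substr(r3, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  expect_null(banded_sw(r3, win, align_params(), diag_offset = 20))
  # ...but a permissive cap accepts them
  expect_false(is.null(banded_sw(r3, win, align_params(max_mismatches = 3),
                                 diag_offset = 20)))

  # gapped read within the band; reported parts reproduce the score
  rg <- paste0(substr(read, 1, 15), substr(read, 18, 35))  # 2 bp deletion
  ag <- banded_sw(rg, win, align_params(), diag_offset = 20)
  expect_false(is.null(ag))
  expect_equal(ag$gap_total, 2L)
  expect_equal(score_from_alignment(ag), ag$score)

  # unbanded equivalence against the independent full-DP oracle
  for (k in 1:60) {
    m <- sample(15:35, 1); n <- sample(25:70, 1)
    r <- rand_dna(m); w <- rand_dna(n)
    perm <- align_params(max_mismatches = 1000, max_gap_len = 1000,
                         band_halfwidth = max(m, n, 1000), min_read_len = 1,
                         max_clip = 1000)
    got <- banded_sw(r, w, perm, diag_offset = 0)
    s <- if (is.null(got)) 0 else got$score
    expect_equal(s, sw_oracle_score(r, w))
    if (!is.null(got)) expect_equal(score_from_alignment(got), got$score)
  }
})

test_that("multi-hit resolution follows the end-weighted quality penalty", {
  mk <- function(score, read_pos = integer(0))
    list(score = score,
         mismatches = data.table::data.table(read_pos = read_pos))
  quals <- rep(30L, 35)
  # single candidate -> unique
  expect_equal(resolve_multihits(list(mk(30)), quals, 35)$status, "unique")
  # strict top score -> unique even with runners-up
  r <- resolve_multihits(list(mk(33), mk(31)), quals, 35)
  expect_equal(r$index, 1L)
  expect_equal(r$status, "unique")
  # tie: end mismatch (weight 0.5, penalty 15) beats mid-read (30)
  r2 <- resolve_multihits(list(mk(31, read_pos = 17L),
                               mk(31, read_pos = 1L)), quals, 35)
  expect_equal(r2$index, 2L)
  expect_equal(r2$status, "resolved")
  # identical score and penalty -> discarded
  r3 <- resolve_multihits(list(mk(31, read_pos = 8L),
                               mk(31, read_pos = 20L)), quals, 35)
  expect_equal(r3$status, "ambiguous_discarded")
  expect_true(is.na(r3$index))
})

test_that("library mapping categorises every read and is strand-symmetric", {
  set.seed(51)
  ref <- reference_set(c(g1 = rand_dna(2000), g2 = rand_dna(1500)))
  idx <- build_index(ref)
  starts <- sample(1:1400, 30)
  reads <- data.table::data.table(
    id = sprintf("r%02d", 1:30), library = "lib1",
    bases = substring(unclass(ref)[["g2"]], starts, starts + 34),
    quals = replicate(30, rep(35L, 35), simplify = FALSE))
  mr <- map_library(reads, idx)
  expect_equal(mr$stats$frac_mapped_unique, 1)
  expect_equal(mr$stats$total, 30L)
  expect_equal(mr$alignments$start, starts - 1L)

  rc <- data.table::copy(reads)
  rc[, bases := revcomp(bases)]
  m2 <- map_library(rc, idx)
  expect_equal(m2$alignments$start, mr$alignments$start)
  expect_true(all(m2$alignments$strand == "-"),
              info = "reverse-complemented reads map to the minus strand")

  # reads from a foreign sequence stay unmapped
  foreign <- data.table::data.table(
    id = sprintf("f%02d", 1:10), library = "lib1",
    bases = vapply(1:10, function(i) rand_dna(35), character(1)),
    quals = replicate(10, rep(35L, 35), simplify = FALSE))
  m3 <- map_library(foreign, idx)
  expect_equal(m3$stats$frac_unmapped, 1)
  # fractions sum to one with QC counts folded in
  m4 <- map_library(reads, idx, n_low_quality = c(lib1 = 10L))
  expect_equal(m4$stats$frac_mapped_unique + m4$stats$frac_multi_discarded +
                 m4$stats$frac_unmapped + m4$stats$frac_low_quality, 1)
})

test_that("error-free simulated reads are categorised like the truth", {
  cfg <- sim_config(seed = 77, genome_length = 60000, ploidies = c(4, 8),
                    site_coverage = 8, err_high = 0, err_low = 0,
                    low_tier_weight = 0)
  sim <- simulate_genome(cfg)
  idx <- build_index(sim$reference)
  lib <- simulate_rrl_reads(sim, 1)
  mr <- map_library(lib$reads, idx)
  mapped <- lib$truth$id %in% mr$alignments$read_id
  genic <- lib$truth$fully_genic
  expect_gte(mean(mapped[genic]), 0.99)
})
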