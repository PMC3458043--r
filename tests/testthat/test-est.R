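mk_est <- function(bases, quals = NULL, mask = NULL, id = "c1.f",
                   clone = "c1", direction = "five_prime") {
  if (is.null(quals)) quals <- rep(40L, nchar(bases))
  if (is.null(mask)) mask <- matrix(integer(0), ncol = 2)
  data.table::data.table(id = id, clone_id = clone, direction = direction,
                         bases = bases, quals = list(quals),
                         vector_mask = list(mask))
}

test_that("cleaning applies the ordered insertless/quality/tail/complexity rules", {
  p <- est_clean_params()
  # 250 bp of 5' vector -> insertless
  r <- mk_est(rand_dna(400), mask = matrix(c(0L, 250L), ncol = 2))
  expect_equal(clean_est(r, p)$reason, "insertless")
  # < 100 bp of non-vector sequence -> insertless
  r2 <- mk_est(rand_dna(250), mask = matrix(c(0L, 160L), ncol = 2))
  expect_equal(clean_est(r2, p)$reason, "insertless")
  # clean 150 bp read passes unchanged
  r3 <- mk_est(gsub("[AT]{6,}", "CGCGCG", rand_dna(150)))
  out3 <- clean_est(r3, p)
  expect_null(out3$reason)
  expect_equal(out3$read$bases, r3$bases[[1]])
  # quality split keeps the longest fragment left by sub-threshold windows
  q <- c(rep(40L, 120), rep(5L, 30), rep(40L, 200))
  r4 <- mk_est(rand_dna(350), quals = q)
  out4 <- clean_est(r4, p)
  expect_null(out4$reason)
  # oracle: flag every base covered by an 11-base window with mean < 15,
  # fragments are the unflagged runs, the longest one is retained
  flagged <- rep(FALSE, 350)
  for (s in 1:(350 - 10)) if (mean(q[s:(s + 10)]) < 15)
    flagged[s:(s + 10)] <- TRUE
  runs <- rle(!flagged)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  gi <- which(runs$values)[which.max(runs$lengths[which(runs$values)])]
  expect_equal(out4$read$bases,
               substr(r4$bases[[1]], starts[gi], ends[gi]))
  # a 30 bp poly-A tail is trimmed, the 120 bp remainder retained
  # (core ends in a GC-rich stretch so the greedy tail detector stops
  # exactly at the planted tail)
  core <- paste0(rand_dna(110), "CGCGCGCGCG")
  r5 <- mk_est(paste0(core, strrep("A", 30)))
  out5 <- clean_est(r5, p)
  expect_null(out5$reason)
  expect_equal(out5$read$bases, core)
  # mostly dinucleotide repeat -> low complexity
  r6 <- mk_est(paste0(rand_dna(60), strrep("AT", 100)))
  expect_equal(clean_est(r6, p)$reason, "low_complexity")
})

test_that("sister discards propagate only for insertless/contaminant reasons", {
  ests <- rbind(
    mk_est(rand_dna(300), mask = matrix(c(0L, 250L), ncol = 2),
           id = "c1.f", clone = "c1"),
    mk_est(rand_dna(300), id = "c1.r", clone = "c1",
           direction = "three_prime"),
    mk_est(rand_dna(300), quals = rep(5L, 300), id = "c2.f", clone = "c2"),
    mk_est(rand_dna(300), id = "c2.r", clone = "c2",
           direction = "three_prime"),
    mk_est(rand_dna(300), id = "c3.f", clone = "c3"),
    mk_est(rand_dna(300), id = "c3.r", clone = "c3",
           direction = "three_prime"))
  res <- clean_est_set(ests)
  # c1: insertless 5' kills the clean 3' sister too
  expect_true(all(c("c1.f", "c1.r") %in% res$discarded$id))
  expect_equal(res$discarded[id == "c1.r"]$reason, "sister_insertless")
  # c2: the quality failure is per-read; the sister survives
  expect_true("c2.f" %in% res$discarded$id)
  expect_true("c2.r" %in% res$reads$id)
  # c3: both clean, both retained
  expect_true(all(c("c3.f", "c3.r") %in% res$reads$id))
})

test_that("contaminant screening removes matching reads and their sisters", {
  set.seed(103)
  contam <- rand_dna(500)
  ests <- rbind(
    mk_est(paste0(rand_dna(100), substr(contam, 101, 180), rand_dna(120)),
           id = "c1.f", clone = "c1"),
    mk_est(rand_dna(300), id = "c1.r", clone = "c1",
           direction = "three_prime"),
    mk_est(rand_dna(300), id = "c2.f", clone = "c2"))
  res <- screen_contaminants(clean_est_set(ests), contam)
  expect_setequal(res$discarded$id, c("c1.f", "c1.r"))
  expect_equal(sort(res$discarded$reason),
               c("contaminant", "sister_contaminant"))
  expect_equal(res$reads$id, "c2.f")
})

test_that("clustering respects the identity cutoff and double linkage", {
  set.seed(101)
  s <- rand_dna(300)
  mut <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- vapply(ch[i], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  # identical pair clusters; a 95%-identical pair does not at 0.98
  cs1 <- cluster_ests(c(x = s, y = s), cluster_params())
  expect_equal(cs1$stats$n_clusters, 1L)
  cs2 <- cluster_ests(c(x = s, y = mut(s, 15)), cluster_params())
  expect_equal(cs2$stats$n_clusters, 2L)
  expect_equal(cluster_ests(c(x = s, y = mut(s, 15)),
                            cluster_params(min_identity = 0.94))$stats$n_clusters,
               1L)

  # double linkage: two gene groups, sisters bridging them
  g1 <- rand_dna(300); g2 <- rand_dna(300)
  seqs <- c(a.f = g1, a.r = g2, b.f = g1, b.r = g2, c.f = mut(g1, 2))
  clones <- c("a", "a", "b", "b", "c")
  merged <- cluster_ests(seqs, cluster_params(), clones = clones)
  expect_equal(max(merged$membership$cluster), 1L)   # >=2 bridging clones
  # with a single bridging clone the clusters stay apart
  seqs1 <- c(a.f = g1, a.r = g2, b.f = g1, c.f = mut(g1, 2))
  single <- cluster_ests(seqs1, cluster_params(),
                         clones = c("a", "a", "b", "c"))
  expect_equal(max(single$membership$cluster), 2L)
})

test_that("consensus building votes by majority and splits diverged members", {
  s <- rand_dna(250)
  # three identical members collapse to themselves
  cs <- build_consensus(c(a = s, b = s, c = s))
  expect_equal(cs$sequences, s)
  expect_equal(sort(cs$members[[1]]), c("a", "b", "c"))
  # 3 vs 2 at one column -> majority base wins
  alt <- s
  substr(alt, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, 100, 100))[1]
  cs2 <- build_consensus(c(a = s, b = s, c = s, d = alt, e = alt))
  expect_equal(cs2$sequences[1], s)
  # one member at ~90% identity splits into its own consensus
  ch <- strsplit(s, "")[[1]]
  i <- sample(length(ch), 25)
  ch[i] <- vapply(ch[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  far <- paste(ch, collapse = "")
  cs3 <- build_consensus(c(a = s, b = s, far = far), min_identity = 0.98)
  expect_equal(length(cs3$sequences), 2L)
  expect_equal(cs3$members[[2]], "far")
})

test_that("the identity-sweep selector picks the threshold below the jump", {
  # paper-shaped counts: modest growth then a spike
  sel <- select_identity_jump(c(0.96, 0.97, 0.98, 0.99),
                              c(102379, 104372, 109181, 128311))
  expect_true(sel$jump_found)
  expect_equal(sel$selected, 0.98)
  # equal increasing steps: earliest lower identity by the tie-break
  sel2 <- select_identity_jump(c(0.96, 0.97, 0.98, 0.99),
                               c(100, 110, 120, 130))
  expect_true(sel2$jump_found)
  expect_equal(sel2$selected, 0.96)
  # flat counts: no jump, configured default returned
  sel3 <- select_identity_jump(c(0.96, 0.97, 0.98, 0.99),
                               rep(50, 4), default = 0.98)
  expect_false(sel3$jump_found)
  expect_equal(sel3$selected, 0.98)
  # identical sequences at all thresholds -> flat, no jump
  s <- rand_dna(300)
  sw <- identity_sweep(setNames(rep(s, 3), c("a", "b", "c")),
                       cluster_params())
  expect_false(sw$jump_found)
  expect_equal(length(unique(sw$table$n_consensus)), 1L)
})

test_that("cluster counts are non-decreasing in identity and partition the input", {
  fam <- simulate_gene_families(n_loci = 6, seed = 7)
  sw <- identity_sweep(fam$seqs, cluster_params())
  expect_true(all(diff(sw$table$n_clusters) >= 0))
  cs <- cluster_ests(fam$seqs, cluster_params())
  expect_equal(sort(cs$membership$id), sort(names(fam$seqs)))
  expect_equal(anyDuplicated(cs$membership$id), 0L)
  s <- cs$stats
  expect_equal(s$n_clusters_singlet + s$n_clusters_not_singlet, s$n_clusters)
  expect_equal(s$n_consensus_singlet + s$n_consensus_not_singlet,
               s$n_consensus)
  # paralogs at exact 5% divergence never co-cluster at 98%
  mem <- merge(cs$membership, fam$truth, by = "id")
  pairs <- merge(mem, mem, by = "locus", allow.cartesian = TRUE)
  cross <- pairs[pairs$paralog.x != pairs$paralog.y, ]
  expect_true(all(cross$cluster.x != cross$cluster.y))
})
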