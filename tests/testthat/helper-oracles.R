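# Independent oracles and small generators used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Unbanded local-alignment score oracle: Biostrings' full-DP implementation
# with the package's scoring scheme (match +1, mismatch -1, a gap of
# length k costs 2 + k).
sw_oracle_score <- local({
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  function(read, window) {
    Biostrings::pairwiseAlignment(read, window, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 2, gapExtension = 1,
                                  scoreOnly = TRUE)
  }
})

# recompute an alignment's score from its own reported parts
score_from_alignment <- function(a) {
  segs <- a$segments
  nm <- sum(segs$len[segs$op == "M"])
  gaps <- segs[segs$op != "M", ]
  nm - 2 * a$n_mismatch -
    (if (nrow(gaps)) sum(2 + gaps$len) else 0)
}

# Brute-force re-implementation of the d/l/ratio/quality calling
# conjunction, written against the rules directly (no data.table).
brute_force_call <- function(column, ref_base, params, mode) {
  keep <- column$qual >= params$min_base_qual & column$allele != "N"
  col <- column[keep, , drop = FALSE]
  if (nrow(col) == 0 || ref_base == "N") return(FALSE)
  alts <- col[col$allele != ref_base, , drop = FALSE]
  if (nrow(alts) == 0) return(FALSE)
  alleles <- sort(unique(alts$allele))
  n <- vapply(alleles, function(a) sum(alts$allele == a), integer(1))
  q <- vapply(alleles, function(a) sum(alts$qual[alts$allele == a]),
              numeric(1))
  ord <- order(-n, -q, alleles)
  alt <- alleles[ord[1]]
  test_unit <- function(rn, an, dep, thr) {
    an >= thr && an > 0 && rn <= params$max_ratio * an &&
      an <= params$max_ratio * rn && dep >= params$min_depth_at_site
  }
  if (mode == "per_library") {
    any(vapply(unique(col$library), function(lb) {
      sub <- col[col$library == lb, , drop = FALSE]
      test_unit(sum(sub$allele == ref_base), sum(sub$allele == alt),
                nrow(sub), params$d)
    }, logical(1)))
  } else {
    test_unit(sum(col$allele == ref_base), sum(col$allele == alt),
              nrow(col), params$l)
  }
}

# Direct statement of the dominant-marker genotype rules.
genotype_oracle <- function(r, a, min_depth = 4) {
  if (r + a < min_depth) return("missing")
  if (r >= min_depth && a == 0) return("hom_ref")
  if (a >= min_depth && r == 0) return("hom_alt")
  if (r >= min_depth && a >= min_depth) return("het")
  "missing"
}

# Random pileup-column generator (3 libraries, mixed alleles/quals).
random_column <- function(ref_base = "A") {
  libs <- c("libA", "libB", "libC")
  rows <- do.call(rbind, lapply(libs, function(lb) {
    dep <- rpois(1, 6)
    if (dep == 0) return(NULL)
    data.frame(
      library = lb,
      allele = sample(c(ref_base, "G", "T", "+CA", "-G"), dep, TRUE,
                      prob = c(0.62, 0.2, 0.08, 0.05, 0.05)),
      qual = sample(c(15L, 19L, 20L, 25L, 35L), dep, TRUE),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(library = character(),
                                        allele = character(),
                                        qual = integer())
  rows
}

# Assemble a pileup object directly from an observation table (for caller
# tests that do not need a real mapping run).
make_pileup <- function(obs, ref_len = 1000L) {
  obs <- data.table::as.data.table(obs)
  if (!"aln" %in% names(obs)) obs[, aln := .I]
  if (!"ref" %in% names(obs)) obs[, ref := "chr1"]
  refs <- unique(obs$ref)
  reference <- rrsnp::reference_set(
    setNames(vapply(refs, function(r) rand_dna(ref_len), character(1)), refs))
  structure(list(obs = obs, reference = reference,
                 libraries = sort(unique(obs$library))),
            class = "pileup")
}

# A small cached simulation shared by several test files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- rrsnp::sim_config(seed = 404, genome_length = 60000,
                               ploidies = c(4, 4, 8), site_coverage = 12)
      sim <- rrsnp::simulate_genome(cfg)
      libs <- rrsnp::simulate_library_set(sim)
      cache <<- list(sim = sim, libs = libs)
    }
    cache
  }
})
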