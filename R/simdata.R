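# Seeded simulator of polyploid genomes, HpaII reduced-representation read
# libraries and EST sets, with complete ground truth, so every pipeline
# stage is testable without external data.
#
# Reads are cut-site anchored (RAD-like): every read starts at an
# unmethylated CCGG site and begins with the CGG overhang, because the
# enzyme-overhang prefix check presumes cut-site anchoring. Allele dosage
# is sampled per read from the individual's haplotype copies, which is
# what makes the 1:7 ratio filter exercisable.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the test suite:
#' a 500 kb genome, half of it genic, six libraries (three tetraploid,
#' three octoploid individuals), per-base heterozygosity theta = 0.005
#' (~5 variant sites per kb, 5% of them 1-3 bp indels), two CCGG sites per
#' kb of which 30% are methylated (invisible to HpaII), 35 bp reads at a
#' mean of 25 reads per cut-site end per library, and a two-tier quality
#' model (phred 35 at 0.1% substitution error, phred 15 at 3%, low tier
#' weight 3.5%, i.e. ~0.2% average error) so a quality-20 filter separates
#' the error classes sharply. The per-site coverage is calibrated to the
#' genotype rule: requiring four or more reads of each allele to declare a
#' heterozygote only has a fair chance of seeing the minor allele of a
#' single-dose octoploid site (expected 1 read in 8) when a site is
#' sampled a few dozen times per individual.
#'
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param genome_length Genome size in bases.
#' @param genic_fraction Fraction of the genome inside gene-like intervals
#'   (the unigene reference covers exactly these).
#' @param ploidies Integer vector, one individual/library per entry
#'   (4 = tetraploid, 8 = octoploid).
#' @param theta Per-base variant rate.
#' @param indel_fraction Fraction of variant sites that are 1-3 bp indels.
#' @param ccgg_rate Expected CCGG sites per kb.
#' @param methylation_rate Fraction of CCGG sites methylated (uncut).
#' @param read_length Read length in bases.
#' @param site_coverage Mean reads per cut-site end per library (Poisson).
#' @param low_tier_weight,q_high,q_low,err_high,err_low Two-tier quality/
#'   error model.
#' @param library_names Library tags (default lib01..).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 500000,
                       genic_fraction = 0.5,
                       ploidies = c(4, 4, 4, 8, 8, 8),
                       theta = 0.005, indel_fraction = 0.05,
                       ccgg_rate = 2, methylation_rate = 0.3,
                       read_length = 35, site_coverage = 25,
                       low_tier_weight = 0.035,
                       q_high = 35, q_low = 15,
                       err_high = 0.001, err_low = 0.03,
                       library_names = sprintf("lib%02d",
                                               seq_along(ploidies))) {
  stopifnot(all(ploidies %in% c(2, 4, 6, 8)), theta >= 0,
            genic_fraction > 0, genic_fraction <= 1,
            length(library_names) == length(ploidies))
  structure(as.list(environment()), class = "sim_config")
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulate a polyploid genome with ground truth
#'
#' Generates a random genome free of background CCGG motifs, plants CCGG
#' cut sites at the configured rate (so a motif scan recovers exactly the
#' planted sites), lays out gene-like intervals covering the genic
#' fraction (their sequences form the unigene reference), and draws
#' variant sites: each has a population alternate-allele frequency
#' p ~ U(0.1, 0.9) and a per-individual dosage ~ Binomial(ploidy, p).
#' Indels are planted left-normalised.
#'
#' @param config [sim_config()].
#' @return A `sim_genome`: genome string, sites/genes/variants tables,
#'   per-individual dosage matrix and the genic [reference_set()].
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # erase background CCGG motifs (replacement with A/T cannot create new
  # ones, so a single pass suffices)
  hit <- which(g[1:(L - 3)] == "C" & g[2:(L - 2)] == "C" &
                 g[3:(L - 1)] == "G" & g[4:L] == "G")
  if (length(hit))
    g[hit + 1L] <- sample(c("A", "T"), length(hit), replace = TRUE)

  # plant cut sites with enough spacing that fragments do not overlap
  n_sites <- round(config$ccgg_rate * L / 1000)
  margin <- config$read_length + 15L
  cand <- sort(sample((margin):(L - margin - 4L), min(4L * n_sites,
                                                      L %/% 100)))
  sites <- integer(0); last <- -1e9
  for (p in cand) {
    if (p - last >= config$read_length + 10L) {
      sites <- c(sites, p); last <- p
      if (length(sites) == n_sites) break
    }
  }
  for (s in sites) g[s:(s + 3L)] <- c("C", "C", "G", "G")
  sites0 <- sites - 1L                     # 0-based motif start positions
  methylated <- runif(length(sites)) < config$methylation_rate

  # gene-like intervals covering the genic fraction
  f <- config$genic_fraction
  genes <- list(); pos <- sample(0:200, 1)
  while (pos < L - 300) {
    glen <- sample(800:2000, 1)
    glen <- min(glen, L - pos)
    genes[[length(genes) + 1L]] <- c(pos, pos + glen)
    gap <- if (f < 1) round(glen * (1 - f) / f * runif(1, 0.7, 1.3)) else 0L
    pos <- pos + glen + gap
  }
  genes <- data.table(gene = sprintf("gene%04d", seq_along(genes)),
                      start = vapply(genes, `[`, numeric(1), 1),
                      end = vapply(genes, `[`, numeric(1), 2))
  genes[, start := as.integer(start)][, end := as.integer(end)]

  # variant sites (SNPs and short indels), left-normalised by construction
  n_var <- round(config$theta * L)
  motif_bases <- unlist(lapply(sites0, function(s) s:(s + 3L)))
  pool <- setdiff(seq.int(margin, L - margin), motif_bases)   # 0-based
  vpos <- sort(sample(pool, min(n_var * 2L, length(pool))))
  vpos <- vpos[c(TRUE, diff(vpos) >= 6L)]
  if (length(vpos) > n_var) vpos <- sort(sample(vpos, n_var))
  nv <- length(vpos)
  vtype <- sample(c("snp", "ins", "del"), nv, replace = TRUE,
                  prob = c(1 - config$indel_fraction,
                           config$indel_fraction / 2,
                           config$indel_fraction / 2))
  ref_a <- alt_a <- character(nv)
  ok <- rep(TRUE, nv)
  for (k in seq_len(nv)) {
    p <- vpos[k]
    if (vtype[k] == "snp") {
      ref_a[k] <- g[p + 1L]
      alt_a[k] <- sample(setdiff(c("A", "C", "G", "T"), ref_a[k]), 1)
    } else if (vtype[k] == "ins") {
      len <- sample(1:3, 1)
      sq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (sq[len] == g[p]) ok[k] <- FALSE      # would not be left-normal
      ref_a[k] <- "-"; alt_a[k] <- paste(sq, collapse = "")
    } else {
      len <- sample(1:3, 1)
      if (p + len >= L || g[p] == g[p + len]) { ok[k] <- FALSE }
      ref_a[k] <- paste(g[(p + 1L):(p + len)], collapse = "")
      alt_a[k] <- "-"
    }
  }
  variants <- data.table(variant_id = seq_len(nv), pos = vpos,
                         variant_type = vtype, ref_allele = ref_a,
                         alt_allele = alt_a)[ok]
  variants[, variant_id := seq_len(.N)]
  variants[, p := runif(.N, 0.1, 0.9)]

  dosage <- matrix(0L, nrow = nrow(variants),
                   ncol = length(config$ploidies),
                   dimnames = list(NULL, config$library_names))
  for (i in seq_along(config$ploidies))
    dosage[, i] <- rbinom(nrow(variants), config$ploidies[i], variants$p)

  gs <- paste(g, collapse = "")
  ref <- reference_set(setNames(
    substring(gs, genes$start + 1L, genes$end), genes$gene))
  structure(list(config = config, genome = gs,
                 sites = data.table(site = seq_along(sites0), pos = sites0,
                                    methylated = methylated),
                 genes = genes, variants = variants, dosage = dosage,
                 reference = ref),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", nchar(x$genome), "bp,", nrow(x$sites), "CCGG sites,",
      nrow(x$genes), "genes,", nrow(x$variants), "variant sites,",
      length(x$config$ploidies), "individuals\n")
  invisible(x)
}

# apply the edits a haplotype copy carries to genome segment [a, b)
# (0-based half-open); `vv` rows must fall strictly inside the segment
.apply_edits <- function(segment, a, vv) {
  if (nrow(vv) == 0) return(segment)
  vv <- vv[order(-pos)]
  for (k in seq_len(nrow(vv))) {
    rel <- vv$pos[k] - a            # 0-based within segment
    if (vv$variant_type[k] == "snp") {
      substr(segment, rel + 1L, rel + 1L) <- vv$alt_allele[k]
    } else if (vv$variant_type[k] == "ins") {
      segment <- paste0(substr(segment, 1L, rel), vv$alt_allele[k],
                        substr(segment, rel + 1L, nchar(segment)))
    } else {
      len <- nchar(vv$ref_allele[k])
      segment <- paste0(substr(segment, 1L, rel),
                        substr(segment, rel + len + 1L, nchar(segment)))
    }
  }
  segment
}

#' Simulate one reduced-representation read library
#'
#' For every unmethylated CCGG site, reads of the configured length are
#' generated from both fragment ends (both start with the CGG overhang;
#' the left fragment reads the bottom strand). Each read samples one
#' haplotype copy uniformly; copies 1..dosage carry the alternate allele
#' at each variant site. Substitution errors and qualities follow the
#' two-tier model.
#'
#' @param sim A [simulate_genome()] result.
#' @param individual Index of the individual/library (1-based).
#' @return `list(reads=, truth=, read_variants=)`: the FASTQ-ready read
#'   table, per-read origin truth, and the read x variant coverage table
#'   (carries_alt, observed allele class, emitted quality).
#' @export
simulate_rrl_reads <- function(sim, individual) {
  cfg <- sim$config
  set.seed(cfg$seed + 7919L * individual)
  lib <- cfg$library_names[individual]
  ploidy <- cfg$ploidies[individual]
  rl <- cfg$read_length
  gs <- sim$genome
  sites <- sim$sites[methylated == FALSE]
  empty <- list(
    reads = data.table(id = character(), library = character(),
                       bases = character(), quals = list()),
    truth = data.table(id = character(), library = character(),
                       site = integer(), dir = character(),
                       copy = integer(), fstart = integer(),
                       fend = integer(), fully_genic = logical()),
    read_variants = data.table(id = character(), library = character(),
                               variant_id = integer(), carries_alt = logical(),
                               observed = character(), qual = integer(),
                               fully_genic = logical()))
  if (nrow(sites) == 0) return(empty)
  nplus <- rpois(nrow(sites), cfg$site_coverage)
  nminus <- rpois(nrow(sites), cfg$site_coverage)
  rdt <- rbind(
    data.table(site = rep(sites$site, nplus), spos = rep(sites$pos, nplus),
               dir = "+"),
    data.table(site = rep(sites$site, nminus), spos = rep(sites$pos, nminus),
               dir = "-"))
  n <- nrow(rdt)
  if (n == 0) return(empty)
  rdt[, copy := sample.int(ploidy, n, replace = TRUE)]
  rdt[, id := sprintf("%s_s%05d%s%03d", lib, site, ifelse(dir == "+", "p", "m"),
                      seq_len(.N)), by = .(site, dir)]
  # footprints (0-based half-open source intervals before edits)
  pad <- 6L
  rdt[, fstart := ifelse(dir == "+", spos + 1L, spos + 3L - rl)]
  rdt[, fend := ifelse(dir == "+", spos + 1L + rl, spos + 3L)]
  rdt[, astart := ifelse(dir == "+", fstart, pmax(0L, fstart - pad))]
  rdt[, aend := ifelse(dir == "+", pmin(nchar(gs), fend + pad), fend)]

  # variants inside each footprint, carried by the sampled copy
  vv <- sim$variants
  dos <- sim$dosage[, individual]
  rv <- vv[rdt, on = .(pos >= fstart, pos < fend), allow.cartesian = TRUE,
           nomatch = NULL,
           .(id = i.id, variant_id = x.variant_id, vpos = x.pos,
             variant_type = x.variant_type, ref_allele = x.ref_allele,
             alt_allele = x.alt_allele, dir = i.dir, spos = i.spos,
             copy = i.copy)]
  rv[, carries_alt := dos[variant_id] >= copy]

  # sequences: plain extraction for reads with no carried edits, per-read
  # edit application otherwise
  seqs <- character(n)
  edited <- unique(rv[carries_alt == TRUE]$id)
  plain <- !(rdt$id %in% edited)
  pl <- which(plain)
  if (length(pl)) {
    pseq <- substring(gs, rdt$fstart[pl] + 1L, rdt$fend[pl])
    mn <- rdt$dir[pl] == "-"
    pseq[mn] <- revcomp(pseq[mn])
    seqs[pl] <- pseq
  }
  rvk <- rv[carries_alt == TRUE]
  setkey(rvk, id)
  for (k in which(!plain)) {
    a <- rdt$astart[k]; b <- rdt$aend[k]
    ed <- rvk[.(rdt$id[k])][vpos > a & vpos + nchar(ref_allele) < b - 1L,
              .(pos = vpos, variant_type, ref_allele, alt_allele)]
    segment <- .apply_edits(substring(gs, a + 1L, b), a, ed)
    if (rdt$dir[k] == "+") {
      seqs[k] <- substr(segment, 1L, rl)
    } else {
      nn <- nchar(segment)
      seqs[k] <- revcomp(substr(segment, max(1L, nn - rl + 1L), nn))
    }
  }
  short <- nchar(seqs) < rl
  if (any(short)) {  # deletions near the far end: pad from genome beyond
    for (k in which(short)) {
      need <- rl - nchar(seqs[k])
      if (rdt$dir[k] == "+") {
        extra <- substring(gs, rdt$aend[k] + 1L, rdt$aend[k] + need)
        seqs[k] <- paste0(seqs[k], extra)
      } else {
        extra <- substring(gs, rdt$astart[k] - need + 1L, rdt$astart[k])
        seqs[k] <- paste0(seqs[k], revcomp(extra))
      }
    }
  }
  seqs <- substr(seqs, 1L, rl)

  # two-tier qualities and substitution errors
  cm <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
               nrow = n, byrow = TRUE)
  low <- matrix(runif(n * rl) < cfg$low_tier_weight, nrow = n)
  qmat <- matrix(ifelse(low, cfg$q_low, cfg$q_high), nrow = n)
  err <- matrix(runif(n * rl), nrow = n) < ifelse(low, cfg$err_low,
                                                  cfg$err_high)
  if (any(err)) {
    wrong <- which(err)
    shift <- sample.int(3L, length(wrong), replace = TRUE)
    bmap <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 0L)
    cur <- bmap[cm[wrong]]
    cm[wrong] <- c("A", "C", "G", "T")[((cur + shift) %% 4L) + 1L]
  }
  seqs <- do.call(paste0, as.data.frame(cm, stringsAsFactors = FALSE))
  quals <- asplit(qmat, 1)
  quals <- lapply(quals, as.integer)

  # genic containment of the (unedited) footprint
  genes <- sim$genes
  gidx <- rep(NA_integer_, n)
  for (gk in seq_len(nrow(genes))) {
    inside <- rdt$fstart >= genes$start[gk] & rdt$fend <= genes$end[gk]
    gidx[inside] <- gk
  }
  rdt[, fully_genic := !is.na(gidx)]
  rdt[, gene := ifelse(is.na(gidx), NA_character_, genes$gene[gidx])]

  # observed allele class and emitted quality at each covered variant base
  rv[, read_pos := ifelse(dir == "+", vpos - (spos + 1L), (spos + 2L) - vpos)]
  rv <- rv[read_pos >= 0L & read_pos < rl]
  rdx <- match(rv$id, rdt$id)
  cellq <- qmat[cbind(rdx, rv$read_pos + 1L)]
  cellerr <- err[cbind(rdx, rv$read_pos + 1L)]
  rv[, qual := as.integer(cellq)]
  rv[, observed := fifelse(cellerr, "other",
                           fifelse(carries_alt, "alt", "ref"))]
  rv[, fully_genic := rdt$fully_genic[rdx]]
  rv[, library := lib]

  list(reads = data.table(id = rdt$id, library = lib, bases = seqs,
                          quals = quals),
       truth = data.table(id = rdt$id, library = lib, site = rdt$site,
                          dir = rdt$dir, copy = rdt$copy,
                          fstart = rdt$fstart, fend = rdt$fend,
                          fully_genic = rdt$fully_genic, gene = rdt$gene),
       read_variants = rv[, .(id, library, variant_id, carries_alt,
                              observed, qual, read_pos, fully_genic)])
}

#' Simulate all libraries of a configuration
#'
#' @param sim A [simulate_genome()] result.
#' @return `list(libraries=, truth=, read_variants=)` with one read table
#'   per configured library.
#' @export
simulate_library_set <- function(sim) {
  res <- lapply(seq_along(sim$config$ploidies),
                function(i) simulate_rrl_reads(sim, i))
  list(libraries = setNames(lapply(res, `[[`, "reads"),
                            sim$config$library_names),
       truth = rbindlist(lapply(res, `[[`, "truth")),
       read_variants = rbindlist(lapply(res, `[[`, "read_variants")))
}

#' Truth-based eligibility of variant sites
#'
#' A truth site is eligible for recovery when the caller's own conjunction
#' (alternate-depth threshold, inclusive ratio bound, minimum depth) holds
#' on the simulated high-quality read counts -- computed from ground truth
#' (reads fully inside one genic interval, emitted quality at the variant
#' base >= `min_base_qual`), independent of mapping or calling.
#'
#' @param sim A [simulate_genome()] result.
#' @param read_variants Combined read x variant truth table.
#' @param params [call_params()].
#' @return data.table of per-variant truth counts with an `eligible`
#'   column.
#' @export
eligible_truth_sites <- function(sim, read_variants, params = call_params()) {
  rv <- read_variants[fully_genic == TRUE & qual >= params$min_base_qual]
  cnt <- rv[, .(alt_hq = sum(observed == "alt"),
                ref_hq = sum(observed == "ref")),
            by = .(variant_id, library)]
  rmax <- params$max_ratio
  cnt[, pass := alt_hq >= params$d & alt_hq > 0 &
        ref_hq <= rmax * alt_hq & alt_hq <= rmax * ref_hq &
        (alt_hq + ref_hq) >= params$min_depth_at_site]
  site <- cnt[, .(lib_pass = any(pass), alt_hq = sum(alt_hq),
                  ref_hq = sum(ref_hq)), by = variant_id]
  site[, pool_pass := alt_hq >= params$l & alt_hq > 0 &
         ref_hq <= rmax * alt_hq & alt_hq <= rmax * ref_hq &
         (alt_hq + ref_hq) >= params$min_depth_at_site]
  site[, eligible := lib_pass | pool_pass]
  merge(sim$variants, site, by = "variant_id", all.x = TRUE)[
    , eligible := !is.na(eligible) & eligible][]
}

# genome coordinate and allele key of called variants ("gpos:type:allele")
.call_keys <- function(variants, sim) {
  if (nrow(variants) == 0) return(character(0))
  v <- as.data.table(variants)
  gstart <- setNames(sim$genes$start, sim$genes$gene)
  gpos <- gstart[v$ref_name] + v$position
  paste0(gpos, ":", v$variant_type, ":",
         fifelse(v$variant_type == "del", v$ref_allele, v$alt_allele))
}

.truth_keys <- function(truth_variants) {
  paste0(truth_variants$pos, ":", truth_variants$variant_type, ":",
         fifelse(truth_variants$variant_type == "del",
                 truth_variants$ref_allele, truth_variants$alt_allele))
}

#' Compare called variants against simulation truth
#'
#' @param variants A `variant_table` called from simulated reads.
#' @param sim The [simulate_genome()] truth.
#' @param eligible Output of [eligible_truth_sites()]; recall is computed
#'   over eligible truth sites only.
#' @return `list(recall=, precision=, n_eligible=, n_called=, n_tp=)`.
#' @export
variant_calls_vs_truth <- function(variants, sim, eligible) {
  ck <- .call_keys(variants, sim)
  tk_all <- .truth_keys(sim$variants)
  tk_eli <- .truth_keys(eligible[eligible == TRUE])
  n_tp <- sum(ck %in% tk_all)
  recall <- if (length(tk_eli)) mean(tk_eli %in% ck) else NA_real_
  precision <- if (length(ck)) n_tp / length(ck) else NA_real_
  list(recall = recall, precision = precision,
       n_eligible = length(tk_eli), n_called = length(ck), n_tp = n_tp)
}

#' True genotype categories from dosages
#'
#' @param sim A [simulate_genome()] result.
#' @return Matrix (variants x libraries) of hom_ref/het/hom_alt.
#' @export
genotype_truth <- function(sim) {
  pl <- matrix(rep(sim$config$ploidies, each = nrow(sim$dosage)),
               nrow = nrow(sim$dosage))
  out <- matrix("het", nrow = nrow(sim$dosage), ncol = ncol(sim$dosage),
                dimnames = dimnames(sim$dosage))
  out[sim$dosage == 0] <- "hom_ref"
  out[sim$dosage == pl] <- "hom_alt"
  out
}

#' Genotype accuracy against simulation truth
#'
#' @param gm A (complete-case) [genotype_matrix][call_genotypes()] from
#'   simulated reads.
#' @param sim The [simulate_genome()] truth.
#' @return `list(accuracy=, n_cells=, n_matched_variants=)`; accuracy over
#'   non-missing cells of truth-matched variant columns.
#' @export
genotype_accuracy <- function(gm, sim) {
  if (length(gm$variant_ids) == 0)
    return(list(accuracy = NA_real_, n_cells = 0L, n_matched_variants = 0L))
  parts <- strsplit(gm$variant_ids, ":", fixed = TRUE)
  gstart <- setNames(sim$genes$start, sim$genes$gene)
  gpos <- gstart[vapply(parts, `[`, character(1), 1)] +
    as.integer(vapply(parts, `[`, character(1), 2))
  alt <- vapply(parts, `[`, character(1), 3)
  ty <- fifelse(startsWith(alt, "+"), "ins",
                fifelse(startsWith(alt, "-"), "del", "snp"))
  tk <- .truth_keys(sim$variants)
  key <- paste0(gpos, ":", ty, ":", sub("^[+-]", "", alt))
  # called indel alleles carry +SEQ/-SEQ keys built from the table itself
  v <- sim$variants
  keyt <- match(key, tk)
  ok <- !is.na(keyt)
  if (!any(ok))
    return(list(accuracy = NA_real_, n_cells = 0L, n_matched_variants = 0L))
  truth <- genotype_truth(sim)
  acc <- 0L; tot <- 0L
  for (j in which(ok)) {
    calls <- gm$geno[, j]
    nm <- calls != "missing"
    tot <- tot + sum(nm)
    acc <- acc + sum(calls[nm] == truth[keyt[j], gm$libraries[nm]])
  }
  list(accuracy = if (tot) acc / tot else NA_real_, n_cells = tot,
       n_matched_variants = sum(ok))
}

#' Simulate per-site read counts under a dosage model
#'
#' `"binomial"` draws each read's haplotype copy independently;
#' `"balanced"` models deep uniform coverage where every copy contributes
#' equally (depth split as evenly as integer arithmetic allows), so the
#' ref:alt ratio equals the dosage ratio exactly.
#'
#' @param n Number of replicate sites.
#' @param depth Reads per site.
#' @param ploidy Haplotype copies.
#' @param dosage Copies carrying the alternate allele.
#' @param sampling `"binomial"` or `"balanced"`.
#' @param alt_fraction Optional override of the alternate-read probability
#'   (e.g. a systematic-error process), binomial sampling only.
#' @return data.table (ref_n, alt_n).
#' @export
simulate_site_counts <- function(n, depth, ploidy = 8, dosage = 1,
                                 sampling = c("binomial", "balanced"),
                                 alt_fraction = NULL) {
  sampling <- match.arg(sampling)
  if (sampling == "balanced") {
    if (!is.null(alt_fraction))
      stop("alt_fraction applies to binomial sampling only")
    per <- depth %/% ploidy; rem <- depth %% ploidy
    alt <- rep.int(dosage * per + min(rem, dosage), n)
  } else {
    p <- if (is.null(alt_fraction)) dosage / ploidy else alt_fraction
    alt <- rbinom(n, depth, p)
  }
  data.table(ref_n = as.integer(depth - alt), alt_n = as.integer(alt))
}

#' Simulate genotype matrices from two diverged subpopulations
#'
#' Two groups of libraries with alternate-allele frequencies diverged by
#' `delta` (group means p +/- delta/2, p ~ U(0.15, 0.85) clipped to
#' (0.02, 0.98)); per-individual dosage ~ Binomial(ploidy, group p), read
#' counts ~ Binomial(depth, dosage/ploidy), then the standard genotype
#' rule. Used for population-structure recovery checks.
#'
#' @param n1,n2 Libraries in each subpopulation.
#' @param n_variants Variant count.
#' @param delta Allele-frequency divergence between the groups.
#' @param ploidy Common ploidy.
#' @param depth Read depth per cell.
#' @param seed RNG seed.
#' @return A `genotype_matrix` with a `group` attribute.
#' @export
simulate_genotypes <- function(n1 = 8, n2 = 5, n_variants = 300,
                               delta = 0.3, ploidy = 4, depth = 30,
                               seed = 1) {
  set.seed(seed)
  nlib <- n1 + n2
  libs <- sprintf("lib%02d", seq_len(nlib))
  group <- rep(c(1L, 2L), c(n1, n2))
  p <- runif(n_variants, 0.15, 0.85)
  p1 <- pmin(pmax(p + delta / 2, 0.02), 0.98)
  p2 <- pmin(pmax(p - delta / 2, 0.02), 0.98)
  refd <- altd <- matrix(0L, nrow = nlib, ncol = n_variants,
                         dimnames = list(libs, sprintf("v%04d",
                                                       seq_len(n_variants))))
  for (i in seq_len(nlib)) {
    pg <- if (group[i] == 1L) p1 else p2
    dos <- rbinom(n_variants, ploidy, pg)
    alt <- rbinom(n_variants, depth, dos / ploidy)
    altd[i, ] <- alt
    refd[i, ] <- depth - alt
  }
  geno <- matrix(.genotype_rule(refd, altd, 4L), nrow = nlib,
                 dimnames = dimnames(refd))
  structure(list(geno = geno, ref_depth = refd, alt_depth = altd,
                 libraries = libs, variant_ids = colnames(refd),
                 min_depth = 4L, group = group),
            class = "genotype_matrix")
}

#' Simulate an EST set with corruption truth
#'
#' Clone pairs (5' and 3' reads) are drawn from the simulated genes;
#' configurable fractions carry typical Sanger-era defects: insertless
#' clones (long 5' vector), deep 3' quality decay, poly-A tails and
#' low-complexity inserts. Every defect is recorded in the truth table.
#'
#' @param sim A [simulate_genome()] result.
#' @param n_clones Number of cDNA clones.
#' @param read_len_mean Mean EST read length.
#' @param insertless_frac,lowqual_frac,polya_frac,lowcomplex_frac Defect
#'   fractions.
#' @param seed RNG seed.
#' @return `list(reads=, truth=)` in [read_fasta_with_quals()] layout.
#' @export
simulate_ests <- function(sim, n_clones = 100, read_len_mean = 450,
                          insertless_frac = 0, lowqual_frac = 0,
                          polya_frac = 0, lowcomplex_frac = 0,
                          seed = sim$config$seed + 500) {
  set.seed(seed)
  genes <- sim$genes
  rows <- list(); truths <- list()
  for (k in seq_len(n_clones)) {
    gk <- sample(nrow(genes), 1)
    gseq <- substring(sim$genome, genes$start[gk] + 1L, genes$end[gk])
    glen <- nchar(gseq)
    insertless <- runif(1) < insertless_frac
    lowqual <- runif(1) < lowqual_frac
    polya <- runif(1) < polya_frac
    lowc <- runif(1) < lowcomplex_frac
    clone <- sprintf("clone%04d", k)
    for (dirn in c("f", "r")) {
      L1 <- max(150L, min(glen, round(rnorm(1, read_len_mean, 50))))
      if (dirn == "f") {
        bases <- substr(gseq, 1L, L1)
      } else {
        bases <- revcomp(substr(gseq, glen - L1 + 1L, glen))
      }
      n1 <- nchar(bases)
      quals <- pmax(5L, pmin(45L, round(40 - pmax(0, seq_len(n1) - n1 + 150) *
                                          0.12 + rnorm(n1, 0, 2))))
      mask <- matrix(integer(0), ncol = 2)
      if (insertless && dirn == "f")
        mask <- matrix(c(0L, min(n1, 230L)), ncol = 2)
      if (lowqual && dirn == "r") {
        cut <- max(20L, round(n1 * 0.3))
        quals[cut:n1] <- pmax(2L, quals[cut:n1] - 25L)
      }
      if (polya && dirn == "r") {
        tail_len <- sample(15:30, 1)
        bases <- paste0(paste(rep("T", tail_len), collapse = ""), bases)
        quals <- c(rep(38L, tail_len), quals)
        n1 <- nchar(bases)
      }
      if (lowc && dirn == "f") {
        rep_len <- round(n1 * 0.7)
        repseq <- paste(rep(c("A", "T"), length.out = rep_len), collapse = "")
        bases <- paste0(substr(bases, 1L, n1 - rep_len), repseq)
      }
      rows[[length(rows) + 1L]] <- data.table(
        id = paste0(clone, ".", dirn), clone_id = clone,
        direction = if (dirn == "f") "five_prime" else "three_prime",
        bases = bases, quals = list(quals), vector_mask = list(mask))
    }
    truths[[length(truths) + 1L]] <- data.table(
      clone_id = clone, gene = genes$gene[gk], insertless = insertless,
      lowqual = lowqual, polya = polya, lowcomplex = lowc)
  }
  list(reads = rbindlist(rows), truth = rbindlist(truths))
}

#' Simulate EST gene families for the identity sweep
#'
#' Each locus has `n_paralogs` paralogs diverged pairwise by exactly
#' `paralog_div` (substitutions at fixed count) and `n_alleles` alleles
#' per paralog diverged stochastically at per-site rate `allele_div`;
#' each allele is sampled by several ESTs with small 5' offsets. At a 98%
#' clustering identity alleles of one paralog co-cluster while 5%-diverged
#' paralogs split; one step higher the alleles start splitting too and the
#' consensus count jumps.
#'
#' @param n_loci Number of loci.
#' @param len Locus length in bases.
#' @param paralog_div Exact pairwise paralog divergence.
#' @param allele_div Per-site allele mutation rate.
#' @param n_paralogs,n_alleles,ests_per_allele Family layout.
#' @param seed RNG seed.
#' @return `list(seqs=, truth=)`: named sequences and their
#'   locus/paralog/allele origin.
#' @export
simulate_gene_families <- function(n_loci = 30, len = 400,
                                   paralog_div = 0.05, allele_div = 0.01,
                                   n_paralogs = 2, n_alleles = 2,
                                   ests_per_allele = 2, seed = 1) {
  set.seed(seed)
  mutate_exact <- function(ch, k) {
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    ch
  }
  seqs <- character(0); truth <- list()
  for (lo in seq_len(n_loci)) {
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (pa in seq_len(n_paralogs)) {
      par <- if (pa == 1) anc else mutate_exact(anc, round(paralog_div * len))
      for (al in seq_len(n_alleles)) {
        alle <- if (al == 1) par else {
          k <- rbinom(1, len, allele_div)
          if (k > 0) mutate_exact(par, k) else par
        }
        for (e in seq_len(ests_per_allele)) {
          off <- sample(0:10, 1)
          nm <- sprintf("L%02dP%dA%dE%d", lo, pa, al, e)
          seqs[nm] <- paste(alle[(off + 1):len], collapse = "")
          truth[[length(truth) + 1L]] <- data.table(
            id = nm, locus = lo, paralog = pa, allele = al)
        }
      }
    }
  }
  list(seqs = seqs, truth = rbindlist(truth))
}
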