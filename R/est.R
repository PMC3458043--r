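# EST cleaning, k-mer overlap clustering with sister-EST double linkage,
# majority-vote consensus building, and the percent-identity sweep used to
# pick the clustering stringency.
#
# The overlap aligner honours the classic k-mer clustering parameters
# (k-mer 16, seed length 32, identity >= 98%) inside a standard
# seed-filter + pairwise-overlap-alignment scheme; consensus building is a
# star alignment with majority vote and an identity-based splitting rule
# (clusters may therefore yield more than one consensus sequence, e.g. for
# diverged members or assembly artefacts).

#' EST cleaning parameters
#'
#' @param max_5prime_vector Clone is insertless when more than this many
#'   vector bases sit at the 5' end.
#' @param min_nonvector Clone is insertless when fewer than this many
#'   non-vector bases remain.
#' @param qual_window Sliding-window width for quality trimming.
#' @param qual_threshold Minimum mean phred score per window.
#' @param min_clean_len Minimum length a read must keep after each
#'   cleaning step.
#' @param max_low_complexity_frac Discard when more than this fraction of
#'   bases is low-complexity.
#' @param polyat_min_run Minimum end-anchored poly-A/T run length.
#' @param polyat_mismatch_per 1 mismatch allowed per this many tail bases.
#' @param entropy_window,entropy_bits Low-complexity detection: 3-mer
#'   Shannon entropy computed in windows of `entropy_window` bases; a
#'   window below `entropy_bits` bits flags its bases.
#' @return An `est_clean_params` list.
#' @export
est_clean_params <- function(max_5prime_vector = 200, min_nonvector = 100,
                             qual_window = 11, qual_threshold = 15,
                             min_clean_len = 100,
                             max_low_complexity_frac = 0.5,
                             polyat_min_run = 8, polyat_mismatch_per = 10,
                             entropy_window = 64, entropy_bits = 1.5) {
  stopifnot(max_low_complexity_frac > 0, max_low_complexity_frac <= 1)
  structure(as.list(environment()), class = "est_clean_params")
}

#' EST clustering parameters
#'
#' @param kmer Shared-word size for candidate pair detection.
#' @param seed_len Minimum chained seed length (bases on one diagonal).
#' @param min_identity Minimum overlap-alignment identity for a cluster
#'   edge (inclusive).
#' @param sweep_identities Identity grid for [identity_sweep()].
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(kmer = 16, seed_len = 32, min_identity = 0.98,
                           sweep_identities = c(0.96, 0.97, 0.98, 0.99)) {
  stopifnot(kmer <= seed_len, all(sweep_identities > 0),
            all(sweep_identities <= 1))
  structure(list(kmer = as.integer(kmer), seed_len = as.integer(seed_len),
                 min_identity = min_identity,
                 sweep_identities = sort(sweep_identities)),
            class = "cluster_params")
}

# fraction of bases flagged low-complexity: 3-mer Shannon entropy in
# tiled windows
.low_complexity_frac <- function(bases, params) {
  n <- nchar(bases)
  if (n < 3) return(0)
  win <- params$entropy_window
  starts <- seq(1L, max(1L, n - 2L), by = win)
  flagged <- 0L
  for (s in starts) {
    e <- min(s + win - 1L, n)
    if (e - s + 1L < 3) { next }
    sub <- substr(bases, s, e)
    km <- substring(sub, 1:(nchar(sub) - 2), 3:nchar(sub))
    p <- table(km) / length(km)
    ent <- -sum(p * log2(p))
    if (ent < params$entropy_bits) flagged <- flagged + (e - s + 1L)
  }
  flagged / n
}

# longest end-anchored homopolymer-ish run of `base` (1 mismatch allowed
# per `per` bases); returns run length to trim (0 when below min_run)
.tail_run_len <- function(chars, base, min_run, per) {
  n <- length(chars)
  best <- 0L; mism <- 0L
  for (k in seq_len(n)) {
    if (chars[n - k + 1L] != base) mism <- mism + 1L
    if (mism > k %/% per) break
    if (chars[n - k + 1L] == base) best <- k
  }
  if (best >= min_run) best else 0L
}

#' Clean one EST read
#'
#' Applies the cleaning rules in order: (1) insertless check against the
#' supplied vector mask (>`max_5prime_vector` vector bases at the 5' end,
#' or <`min_nonvector` non-vector bases); (2) sliding-window quality trim
#' (split at every window whose mean quality falls below the threshold,
#' keep the longest fragment); (3) poly-A/poly-T tail trimming at either
#' end; (4) low-complexity fraction filter. Steps 2-4 each discard the
#' read when fewer than `min_clean_len` bases remain.
#'
#' @param read A one-row EST read (list or data.table row) with bases,
#'   quals and vector_mask (2-column matrix of 0-based half-open
#'   intervals).
#' @param params [est_clean_params()].
#' @return `list(read=, reason=NULL)` with the cleaned read, or
#'   `list(read=NULL, reason=)` naming the discard reason (`insertless`,
#'   `quality`, `polyat_short`, `low_complexity`).
#' @export
clean_est <- function(read, params = est_clean_params()) {
  bases <- read$bases[[1]]
  quals <- if (is.list(read$quals)) read$quals[[1]] else read$quals
  mask <- if (is.list(read$vector_mask)) read$vector_mask[[1]]
          else read$vector_mask
  n <- nchar(bases)
  discard <- function(reason) list(read = NULL, reason = reason)

  # (1) insertless
  vec5 <- 0L; vecbases <- 0L
  if (!is.null(mask) && nrow(mask) > 0) {
    vecbases <- sum(mask[, 2] - mask[, 1])
    at5 <- mask[mask[, 1] == 0L, , drop = FALSE]
    if (nrow(at5)) vec5 <- max(at5[, 2])
  }
  if (vec5 > params$max_5prime_vector ||
      (n - vecbases) < params$min_nonvector)
    return(discard("insertless"))
  # drop masked (vector) bases: keep the longest unmasked stretch
  if (vecbases > 0) {
    keepmask <- rep(TRUE, n)
    for (r in seq_len(nrow(mask)))
      keepmask[(mask[r, 1] + 1L):mask[r, 2]] <- FALSE
    rl <- rle(keepmask)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    good <- which(rl$values)
    gi <- good[which.max(rl$lengths[good])]
    bases <- substr(bases, starts[gi], ends[gi])
    quals <- quals[starts[gi]:ends[gi]]
    n <- nchar(bases)
  }

  # (2) sliding-window quality trim
  w <- params$qual_window
  if (n >= w) {
    cs <- cumsum(c(0, quals))
    means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    bad <- which(means < params$qual_threshold)
    if (length(bad)) {
      lowbase <- rep(FALSE, n)
      for (s in bad) lowbase[s:(s + w - 1L)] <- TRUE
      rl <- rle(!lowbase)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
      good <- which(rl$values)
      if (!length(good)) return(discard("quality"))
      gi <- good[which.max(rl$lengths[good])]
      bases <- substr(bases, starts[gi], ends[gi])
      quals <- quals[starts[gi]:ends[gi]]
      n <- nchar(bases)
    }
  }
  if (n < params$min_clean_len) return(discard("quality"))

  # (3) poly-A / poly-T tails at either read end
  for (pass in 1:2) {
    ch <- strsplit(bases, "")[[1]]
    t3 <- max(.tail_run_len(ch, "A", params$polyat_min_run,
                            params$polyat_mismatch_per),
              .tail_run_len(ch, "T", params$polyat_min_run,
                            params$polyat_mismatch_per))
    if (t3 > 0) {
      bases <- substr(bases, 1L, n - t3); quals <- quals[seq_len(n - t3)]
      n <- nchar(bases)
    }
    ch <- strsplit(bases, "")[[1]]
    t5 <- max(.tail_run_len(rev(ch), "A", params$polyat_min_run,
                            params$polyat_mismatch_per),
              .tail_run_len(rev(ch), "T", params$polyat_min_run,
                            params$polyat_mismatch_per))
    if (t5 > 0) {
      bases <- substr(bases, t5 + 1L, n); quals <- quals[(t5 + 1L):n]
      n <- nchar(bases)
    }
    if (t3 == 0 && t5 == 0) break
  }
  if (n < params$min_clean_len) return(discard("polyat_short"))

  # (4) low complexity
  if (.low_complexity_frac(bases, params) > params$max_low_complexity_frac)
    return(discard("low_complexity"))

  list(read = list(id = read$id[[1]], clone_id = read$clone_id[[1]],
                   direction = read$direction[[1]], bases = bases,
                   quals = quals),
       reason = NULL)
}

#' Clean a set of EST reads
#'
#' Runs [clean_est()] on every read, keeps the longest retained read per
#' (clone, direction), and applies [sister_propagate()].
#'
#' @param reads EST read table ([read_fasta_with_quals()]).
#' @param params [est_clean_params()].
#' @return `list(reads=, discarded=)`: the cleaned read table and a table
#'   of (id, reason) for every discarded read.
#' @export
clean_est_set <- function(reads, params = est_clean_params()) {
  reads <- as.data.table(reads)
  kept <- list(); disc <- list()
  for (k in seq_len(nrow(reads))) {
    r <- clean_est(reads[k], params)
    if (is.null(r$read)) {
      disc[[length(disc) + 1L]] <- data.table(id = reads$id[k],
                                              clone_id = reads$clone_id[k],
                                              direction = reads$direction[k],
                                              reason = r$reason)
    } else {
      kept[[length(kept) + 1L]] <- as.data.table(
        list(id = r$read$id, clone_id = r$read$clone_id,
             direction = r$read$direction, bases = r$read$bases,
             quals = list(r$read$quals)))
    }
  }
  kept <- if (length(kept)) rbindlist(kept) else
    data.table(id = character(), clone_id = character(),
               direction = character(), bases = character(), quals = list())
  disc <- if (length(disc)) rbindlist(disc) else
    data.table(id = character(), clone_id = character(),
               direction = character(), reason = character())
  # longest read per (clone, direction); direction-unknown reads kept as-is
  if (nrow(kept)) {
    known <- kept[!is.na(clone_id) & direction != "unknown"]
    unk <- kept[is.na(clone_id) | direction == "unknown"]
    if (nrow(known)) {
      setorder(known, clone_id, direction, -bases)
      known[, len := nchar(bases)]
      known <- known[known[, .I[which.max(len)], by = .(clone_id, direction)]$V1]
      known[, len := NULL]
    }
    kept <- rbind(known, unk)
  }
  sister_propagate(list(reads = kept, discarded = disc))
}

#' Screen ESTs against a contaminant sequence set
#'
#' Flags reads sharing an exact k-mer (default 32 bp) with any supplied
#' contaminant sequence (rRNA, vector, non-cellular sequence...). Used
#' between [clean_est_set()] steps when a contaminant set is available;
#' discards propagate to sisters via [sister_propagate()].
#'
#' @param cleaned `list(reads=, discarded=)` from [clean_est_set()].
#' @param contaminants Character vector of contaminant sequences.
#' @param k Exact-match word size.
#' @return The filtered `list(reads=, discarded=)` with sister
#'   propagation applied.
#' @export
screen_contaminants <- function(cleaned, contaminants, k = 32) {
  reads <- cleaned$reads
  if (nrow(reads) == 0 || length(contaminants) == 0) return(cleaned)
  words <- unique(unlist(lapply(toupper(contaminants), function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })))
  hit <- vapply(reads$bases, function(b) {
    L <- nchar(b)
    if (L < k) return(FALSE)
    any(substring(b, 1:(L - k + 1), k:L) %in% words)
  }, logical(1), USE.NAMES = FALSE)
  if (!any(hit)) return(cleaned)
  disc <- rbind(cleaned$discarded,
                data.table(id = reads$id[hit], clone_id = reads$clone_id[hit],
                           direction = reads$direction[hit],
                           reason = "contaminant"))
  sister_propagate(list(reads = reads[!hit], discarded = disc))
}

#' Propagate insertless/contaminant discards to sister ESTs
#'
#' When one read of a clone is discarded as insertless (or contaminant),
#' its sister is discarded too; quality, poly-A/T and complexity failures
#' are per-read and are not propagated.
#'
#' @param cleaned `list(reads=, discarded=)` from [clean_est_set()].
#' @return The same structure with sister discards applied (reason
#'   `sister_insertless` / `sister_contaminant`).
#' @export
sister_propagate <- function(cleaned) {
  disc <- cleaned$discarded
  reads <- cleaned$reads
  prop <- disc[reason %in% c("insertless", "contaminant") & !is.na(clone_id)]
  if (nrow(prop) && nrow(reads)) {
    hit <- reads$clone_id %in% prop$clone_id & !is.na(reads$clone_id)
    if (any(hit)) {
      reasons <- setNames(paste0("sister_", prop$reason), prop$clone_id)
      extra <- data.table(id = reads$id[hit],
                          clone_id = reads$clone_id[hit],
                          direction = reads$direction[hit],
                          reason = unname(reasons[reads$clone_id[hit]]))
      disc <- rbind(disc, extra)
      reads <- reads[!hit]
    }
  }
  list(reads = reads, discarded = disc)
}

# candidate pairs sharing a chained k-mer seed, plus their overlap
# identities (computed once; thresholds are applied afterwards)
.est_pair_identities <- function(seqs, params) {
  n <- length(seqs)
  empty <- data.table(a = integer(), b = integer(), identity = numeric())
  if (n < 2) return(empty)
  k <- params$kmer
  lens <- nchar(seqs)
  ok <- which(lens >= k)
  if (length(ok) < 2) return(empty)
  offs <- lapply(lens[ok], function(L) seq.int(0L, L - k))
  sid <- rep(ok, lengths(offs))
  off <- unlist(offs, use.names = FALSE)
  words <- data.table(word = substring(seqs[sid], off + 1L, off + k),
                      sid = sid, off = off)
  words <- words[!grepl("N", word, fixed = TRUE)]
  setkey(words, word)
  pairs <- words[words, on = "word", allow.cartesian = TRUE]
  pairs <- pairs[sid < i.sid]
  if (nrow(pairs) == 0) return(empty)
  pairs[, diag := off - i.off]
  # chained seed length on one diagonal: union of k-mer intervals
  cov <- pairs[, {
    o <- sort(unique(off))
    gaps <- c(0L, diff(o))
    run <- integer(length(o))
    cur <- k
    best <- k
    for (q in seq_along(o)) {
      if (q == 1L) cur <- k
      else if (gaps[q] <= k) cur <- cur + min(gaps[q], k)
      else cur <- k
      if (cur > best) best <- cur
    }
    .(cover = best)
  }, by = .(sid, i.sid, diag)]
  cand <- unique(cov[cover >= params$seed_len, .(a = sid, b = i.sid)])
  if (nrow(cand) == 0) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  idt <- numeric(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    al <- Biostrings::pairwiseAlignment(
      seqs[cand$a[q]], seqs[cand$b[q]], type = "overlap",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    idt[q] <- Biostrings::pid(al, type = "PID1") / 100
  }
  cand[, identity := idt]
  cand[]
}

# connected components at a given identity, then double-linkage merging of
# clusters sharing >= 2 clone sister-pairs (iterated to a fixed point)
.components_at <- function(n, pair_id, min_identity, clones = NULL) {
  edges <- pair_id[identity >= min_identity]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  comp <- igraph::components(g)$membership
  if (!is.null(clones)) {
    repeat {
      dt <- data.table(clone = clones, comp = comp)
      dt <- dt[!is.na(clone)]
      cl <- dt[, .(comps = list(unique(comp))), by = clone]
      cl <- cl[lengths(comps) == 2]
      if (nrow(cl) == 0) break
      links <- cl[, .(a = vapply(comps, function(x) min(x), numeric(1)),
                      b = vapply(comps, function(x) max(x), numeric(1)))]
      tab <- links[, .N, by = .(a, b)][N >= 2]
      if (nrow(tab) == 0) break
      for (q in seq_len(nrow(tab)))
        comp[comp == tab$b[q]] <- tab$a[q]
    }
  }
  match(comp, sort(unique(comp)))
}

#' Cluster ESTs by sequence overlap
#'
#' Candidate pairs share a chained k-mer seed of at least `seed_len` bases
#' on one diagonal; pairs whose overlap-alignment identity reaches
#' `min_identity` become edges and clusters are the connected components.
#' Clusters linked by two or more clone sister-pairs (one sister in each
#' cluster) are then merged ("double linkage").
#'
#' @param seqs Named character vector of cleaned EST sequences.
#' @param params [cluster_params()].
#' @param clones Optional clone id per sequence (for double linkage);
#'   `NA` entries are ignored.
#' @param build_consensus_seqs Also assemble consensus sequences per
#'   cluster (default TRUE).
#' @return A `cluster_set`: membership table, per-cluster consensus
#'   sequences and summary statistics (cluster/consensus counts, singlet
#'   counts, consensus-per-cluster means, largest cluster).
#' @export
cluster_ests <- function(seqs, params = cluster_params(), clones = NULL,
                         build_consensus_seqs = TRUE) {
  stopifnot(!is.null(names(seqs)))
  pair_id <- .est_pair_identities(seqs, params)
  .cluster_at(seqs, pair_id, params$min_identity, params, clones,
              build_consensus_seqs)
}

.cluster_at <- function(seqs, pair_id, min_identity, params, clones,
                        build_consensus_seqs = TRUE) {
  n <- length(seqs)
  comp <- .components_at(n, pair_id, min_identity, clones)
  membership <- data.table(id = names(seqs), cluster = comp)
  cons <- list()
  if (build_consensus_seqs) {
    for (cl in sort(unique(comp))) {
      mem <- which(comp == cl)
      cs <- build_consensus(seqs[mem], min_identity = min_identity)
      cons[[length(cons) + 1L]] <- data.table(
        cluster = cl,
        consensus_id = sprintf("cluster%04d_cons%d", cl, seq_along(cs$sequences)),
        sequence = cs$sequences,
        n_members = vapply(cs$members, length, integer(1)))
    }
  }
  cons <- if (length(cons)) rbindlist(cons) else
    data.table(cluster = integer(), consensus_id = character(),
               sequence = character(), n_members = integer())
  csize <- membership[, .N, by = cluster]
  stats <- list(
    n_sequences = n,
    n_clusters = nrow(csize),
    n_clusters_singlet = sum(csize$N == 1L),
    n_clusters_not_singlet = sum(csize$N > 1L),
    n_consensus = nrow(cons),
    n_consensus_singlet = sum(cons$n_members == 1L),
    n_consensus_not_singlet = sum(cons$n_members > 1L),
    consensus_per_cluster = if (nrow(csize)) nrow(cons) / nrow(csize)
                            else NA_real_,
    consensus_per_cluster_no_singlets =
      if (any(csize$N > 1L) && nrow(cons))
        nrow(cons[cluster %in% csize[N > 1L]$cluster]) / sum(csize$N > 1L)
      else NA_real_,
    largest_cluster = if (nrow(csize)) max(csize$N) else 0L,
    min_identity = min_identity)
  structure(list(membership = membership, consensus = cons, stats = stats,
                 pair_identities = pair_id),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "cluster_set: %d sequences -> %d clusters (%d singlets), %d consensus sequences at identity %.2f\n",
    s$n_sequences, s$n_clusters, s$n_clusters_singlet, s$n_consensus,
    s$min_identity))
  invisible(x)
}

#' Build consensus sequence(s) for one cluster
#'
#' Members are star-aligned to the longest member; each consensus column
#' takes the majority base (ties resolved to the longest member's base).
#' Members whose identity to the emerging consensus falls below
#' `min_identity` are split off and re-assembled into additional consensus
#' sequences, so a cluster can produce more than one consensus. A
#' singleton member is returned unchanged.
#'
#' @param members Named character vector of member sequences.
#' @param min_identity Identity below which a member is split off.
#' @return `list(sequences=, members=)`: consensus sequences and, for each,
#'   the names of the members it represents.
#' @export
build_consensus <- function(members, min_identity = 0.98) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1)
    return(list(sequences = unname(members), members = list(names(members))))
  center_i <- which.max(nchar(members))
  center <- members[[center_i]]
  others <- members[-center_i]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  L <- nchar(center)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  cc <- strsplit(center, "")[[1]]
  counts[cbind(match(cc, rownames(counts)), seq_len(L))] <- 1L
  aligned_cols <- vector("list", length(others))   # member base per center col
  for (q in seq_along(others)) {
    al <- Biostrings::pairwiseAlignment(others[[q]], center, type = "overlap",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    spos <- Biostrings::start(Biostrings::subject(al))  # 1-based on center
    colv <- rep(NA_character_, L)
    ci <- spos - 1L
    for (t in seq_along(as_)) {
      if (as_[t] != "-") {
        ci <- ci + 1L
        if (ap[t] != "-" && ci >= 1L && ci <= L) colv[ci] <- ap[t]
      }
    }
    aligned_cols[[q]] <- colv
    obs <- which(!is.na(colv) & colv %in% rownames(counts))
    if (length(obs))
      counts[cbind(match(colv[obs], rownames(counts)), obs)] <-
        counts[cbind(match(colv[obs], rownames(counts)), obs)] + 1L
  }
  best <- apply(counts, 2, max)
  maj <- apply(counts, 2, function(v) rownames(counts)[which.max(v)])
  nties <- apply(counts, 2, function(v) sum(v == max(v)))
  maj[nties > 1] <- cc[nties > 1]                  # ties -> center's base
  consensus <- paste(maj, collapse = "")

  # identity of each member against the consensus over its aligned columns
  idt <- vapply(seq_along(others), function(q) {
    colv <- aligned_cols[[q]]
    obs <- which(!is.na(colv))
    if (!length(obs)) return(0)
    mean(colv[obs] == maj[obs])
  }, numeric(1))
  split_off <- which(idt < min_identity)
  kept_names <- c(names(members)[center_i], names(others)[setdiff(
    seq_along(others), split_off)])
  out <- list(sequences = consensus, members = list(kept_names))
  if (length(split_off)) {
    sub <- build_consensus(others[split_off], min_identity)
    out$sequences <- c(out$sequences, sub$sequences)
    out$members <- c(out$members, sub$members)
  }
  out
}

#' Sweep clustering identity thresholds
#'
#' Clusters the input at each identity in the grid, reports per-identity
#' statistics, and selects the working threshold as the identity
#' immediately below the largest relative increase in consensus-sequence
#' count between adjacent identities (alleles of one locus should still
#' co-cluster at the selected identity; one step higher they split and the
#' count jumps). Ties take the earliest step; when counts never increase
#' the sweep reports "no jump" and returns the configured default.
#'
#' @param seqs Named character vector of cleaned EST sequences.
#' @param params [cluster_params()]; `sweep_identities` gives the grid.
#' @param clones Optional clone ids for double linkage.
#' @return `list(table=, selected=, jump_found=)`: per-identity statistics
#'   (consensus/cluster/singlet counts), the selected identity and whether
#'   a jump was found.
#' @export
identity_sweep <- function(seqs, params = cluster_params(), clones = NULL) {
  ids <- params$sweep_identities
  if (length(ids) < 2) stop("need at least 2 sweep identities")
  pair_id <- .est_pair_identities(seqs, params)
  rows <- lapply(ids, function(idt) {
    cs <- .cluster_at(seqs, pair_id, idt, params, clones,
                      build_consensus_seqs = TRUE)
    s <- cs$stats
    data.table(identity = idt, n_consensus = s$n_consensus,
               n_clusters = s$n_clusters,
               n_clusters_singlet = s$n_clusters_singlet,
               n_consensus_singlet = s$n_consensus_singlet,
               largest_cluster = s$largest_cluster)
  })
  tab <- rbindlist(rows)
  sel <- select_identity_jump(tab$identity, tab$n_consensus,
                              default = params$min_identity)
  c(list(table = tab), sel)
}

#' Select the identity below the largest relative jump in counts
#'
#' @param identities Ascending identity grid.
#' @param counts Consensus-sequence count at each identity.
#' @param default Returned when counts never increase ("no jump").
#' @return `list(selected=, jump_found=)`.
#' @export
select_identity_jump <- function(identities, counts, default = 0.98) {
  o <- order(identities)
  identities <- identities[o]; counts <- counts[o]
  prev <- head(counts, -1)
  inc <- diff(counts) / ifelse(prev > 0, prev, 1)
  if (all(diff(counts) <= 0))
    return(list(selected = default, jump_found = FALSE))
  k <- which.max(inc)                    # earliest on ties (which.max)
  list(selected = identities[k], jump_found = TRUE)
}
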