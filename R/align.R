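# Word-indexed banded Smith-Waterman read mapping.
#
# The reference is indexed with fixed-size words sampled every `shift_size`
# bases on both strands. Reads are scanned at stride 1, matching words give
# candidate (reference, diagonal, strand) loci, and each candidate is
# extended with a banded local aligner (Gotoh affine gaps, Rcpp). Reads with
# several equally good placements are resolved by mismatch base qualities
# weighted by their position in the read, or discarded as ambiguous.
#
# Minus-strand candidates are aligned as reverse-complemented read against
# the forward reference, so all downstream coordinates (and observed bases)
# are in the forward reference frame.

#' Alignment parameters
#'
#' The mismatch and gap caps are absolute (not length-proportional): the
#' defaults allow two mismatches and up to three gapped bases per read,
#' tuned to ~25 bp post-trimming read lengths. The scoring scheme (match
#' +1, mismatch -1, gap opening -2 plus -1 per gapped base) is chosen so
#' that the caps, not the scores, are the binding constraints; it is fully
#' configurable.
#'
#' @param max_mismatches Maximum mismatches per alignment.
#' @param max_gap_len Maximum total gapped bases per alignment (each single
#'   gap event is also limited to this length).
#' @param band_halfwidth Half-width of the alignment band; must be at least
#'   `max_gap_len`, otherwise permitted gaps would be unreachable.
#' @param min_read_len Minimum number of aligned read bases.
#' @param max_clip Maximum read bases the local alignment may leave
#'   unaligned (soft-clipped) at the two ends combined. Without this cap a
#'   chance seed-word match can anchor a 12-15 bp fragment of a read whose
#'   true locus is absent from the reference, and such fragments pile up
#'   at indexed positions and fabricate variant columns.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (a gap of
#'   length k costs `gap_open + k * gap_extend`).
#' @return An `align_params` list.
#' @export
align_params <- function(max_mismatches = 2, max_gap_len = 3,
                         band_halfwidth = NULL, min_read_len = 12,
                         max_clip = 6,
                         match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  if (is.null(band_halfwidth)) band_halfwidth <- max_gap_len
  if (band_halfwidth < max_gap_len)
    stop("band_halfwidth must be >= max_gap_len")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_gap_len = as.integer(max_gap_len),
                 band_halfwidth = as.integer(band_halfwidth),
                 min_read_len = as.integer(min_read_len),
                 max_clip = as.integer(max_clip),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

#' Build a word index over a reference set
#'
#' Words of `word_size` bases are sampled every `shift_size` bases from each
#' reference record and from its reverse complement; words containing N are
#' skipped. A record shorter than `word_size` contributes no words (with a
#' warning). Smaller shifts are slower but more sensitive; the supported
#' range is 11-16.
#'
#' @param reference A [reference_set()].
#' @param word_size Word length in bases (4-16).
#' @param shift_size Sampling stride in bases (11-16).
#' @return A `word_index` object.
#' @export
build_index <- function(reference, word_size = 12, shift_size = 12) {
  stopifnot(inherits(reference, "reference_set"))
  if (word_size < 4 || word_size > 16) stop("word_size must be in [4,16]")
  if (shift_size < 11 || shift_size > 16) stop("shift_size must be in [11,16]")
  seqs <- unclass(reference)
  lens <- nchar(seqs)
  if (any(lens < word_size))
    warning("reference records shorter than word_size contribute no words: ",
            paste(head(names(seqs)[lens < word_size], 5), collapse = ", "))
  rc <- setNames(revcomp(seqs), names(seqs))
  one_strand <- function(ss, strand) {
    offs <- lapply(nchar(ss), function(L)
      if (L >= word_size) seq.int(0L, L - word_size, by = shift_size)
      else integer(0))
    nm <- rep(names(ss), lengths(offs))
    off <- unlist(offs, use.names = FALSE)
    if (length(off) == 0)
      return(data.table(word = character(), ref = character(),
                        offset = integer(), strand = character()))
    data.table(word = substring(ss[nm], off + 1L, off + word_size),
               ref = nm, offset = as.integer(off), strand = strand)
  }
  words <- rbind(one_strand(seqs, "+"), one_strand(rc, "-"))
  words <- words[!grepl("N", word, fixed = TRUE)]
  setkey(words, word)
  structure(list(words = words, word_size = as.integer(word_size),
                 shift_size = as.integer(shift_size),
                 reference = seqs, rc = rc,
                 ref_len = setNames(as.integer(lens), names(seqs))),
            class = "word_index")
}

#' @export
print.word_index <- function(x, ...) {
  cat("word_index:", nrow(x$words), "words (size", x$word_size,
      ", shift", x$shift_size, ") over", length(x$reference), "records\n")
  invisible(x)
}

# Batch seed lookup. `bases` is a character vector of read sequences;
# returns a data.table (read_idx, ref, strand, diag) where `diag` is the
# 0-based forward-reference start position implied for the oriented read
# (the read itself on "+", its reverse complement on "-"). Candidates whose
# diagonals differ by at most `merge_dist` are collapsed to one.
.seed_hits_batch <- function(bases, index, merge_dist = 3L) {
  w <- index$word_size
  m <- nchar(bases)
  ok <- which(m >= w)
  if (length(ok) == 0)
    return(data.table(read_idx = integer(), ref = character(),
                      strand = character(), diag = integer()))
  offs <- lapply(m[ok], function(L) seq.int(0L, L - w))
  ridx <- rep(ok, lengths(offs))
  off <- unlist(offs, use.names = FALSE)
  qdt <- data.table(word = substring(bases[ridx], off + 1L, off + w),
                    read_idx = ridx, off = as.integer(off))
  hits <- index$words[qdt, on = "word", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0)
    return(data.table(read_idx = integer(), ref = character(),
                      strand = character(), diag = integer()))
  hits[, L := index$ref_len[ref]]
  hits[, m := nchar(bases[read_idx])]
  # forward-frame start of the oriented read implied by this word match
  hits[, diag := ifelse(strand == "+",
                        offset - off,
                        L - offset - m + off)]
  cand <- unique(hits[, .(read_idx, ref, strand, diag)])
  setorder(cand, read_idx, ref, strand, diag)
  cand[, grp := cumsum(c(1L, as.integer(
    diff(diag) > merge_dist |
      head(ref, -1) != tail(ref, -1) |
      head(strand, -1) != tail(strand, -1) |
      diff(read_idx) != 0L))),
    by = NULL]
  cand <- cand[, .(diag = diag[1L]), by = .(read_idx, ref, strand, grp)]
  cand[, grp := NULL]
  cand[]
}

#' Find candidate loci for one read
#'
#' Scans the read at stride 1 for words present in the index and reports
#' deduplicated candidate loci, one per (reference, diagonal, strand).
#'
#' @param bases Read sequence (single string).
#' @param index A [build_index()] word index.
#' @param merge_dist Collapse candidates whose diagonals differ by at most
#'   this many bases (gap tolerance).
#' @return data.table (ref, strand, diag); `diag` is the implied 0-based
#'   start of the oriented read on the forward reference.
#' @export
seed_hits <- function(bases, index, merge_dist = 3L) {
  .seed_hits_batch(bases, index, merge_dist)[, .(ref, strand, diag)]
}

#' Banded Smith-Waterman alignment of a read against a reference window
#'
#' Computes the best local alignment within the band and applies the
#' alignment caps: at most `max_mismatches` mismatches, at most
#' `max_gap_len` total gapped bases (each gap event 1..`max_gap_len`), and
#' at least `min_read_len` aligned read bases. With
#' `band_halfwidth >= max(nchar(read), nchar(window))` the result equals
#' unbanded Smith-Waterman.
#'
#' @param bases Read sequence.
#' @param window Reference window sequence.
#' @param params [align_params()].
#' @param diag_offset Expected window column minus read row of the seed
#'   diagonal (0 when the read is expected at the window start).
#' @param extend_ends Extend the local alignment gaplessly to the read
#'   ends (counting the extra mismatches) as [map_library()] does; with
#'   the default `FALSE` the result is the pure banded Smith-Waterman
#'   optimum.
#' @return `NULL` when no alignment satisfies the caps, otherwise a list
#'   with score, read/window intervals (0-based half-open), segments
#'   (M/I/D runs), mismatches and cigar.
#' @export
banded_sw <- function(bases, window, params = align_params(),
                      diag_offset = 0L, extend_ends = FALSE) {
  res <- .sw_banded_batch(bases, window, as.integer(diag_offset),
                          params$band_halfwidth,
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          extend = extend_ends)
  if (res$score[1] <= 0) return(NULL)
  segs <- data.table(op = res$seg_op, len = res$seg_len,
                     read_start = res$seg_read_start,
                     win_start = res$seg_win_start)
  aligned <- res$read_end[1] - res$read_start[1]
  if (res$n_mismatch[1] > params$max_mismatches ||
      res$gap_total[1] > params$max_gap_len ||
      res$gap_max[1] > params$max_gap_len ||
      aligned < params$min_read_len ||
      nchar(bases) - aligned > params$max_clip) return(NULL)
  list(score = res$score[1],
       read_start = res$read_start[1], read_end = res$read_end[1],
       win_start = res$win_start[1], win_end = res$win_end[1],
       n_mismatch = res$n_mismatch[1], gap_total = res$gap_total[1],
       segments = segs,
       mismatches = data.table(read_pos = res$mm_read_pos,
                               win_pos = res$mm_win_pos),
       cigar = paste0(segs$len, segs$op, collapse = ""))
}

#' Resolve multiple candidate alignments for one read
#'
#' A strictly best-scoring candidate wins outright (`unique`). Among
#' score-ties the penalty `sum(read_qual * end_weight)` over mismatch
#' positions decides, where `end_weight` is 0.5 within 3 bp of either read
#' end and 1 otherwise -- mismatches near the ends, where short-read error
#' rates are highest, count less against a placement. A strictly smallest
#' penalty gives `resolved`; any remaining tie discards the read
#' (`ambiguous_discarded`).
#'
#' @param candidates List of candidate alignments; each needs `$score` and
#'   `$mismatches` (data.table with `read_pos`).
#' @param quals Integer phred scores of the (oriented) read.
#' @param read_len Read length in bases.
#' @return `list(index=, status=)`: index of the winning candidate (NA when
#'   discarded) and one of `"unique"`, `"resolved"`,
#'   `"ambiguous_discarded"`.
#' @export
resolve_multihits <- function(candidates, quals, read_len) {
  stopifnot(length(candidates) >= 1)
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  top <- which(scores == max(scores))
  if (length(top) == 1)
    return(list(index = top, status = "unique"))
  pen <- vapply(top, function(i) {
    mm <- candidates[[i]]$mismatches
    if (is.null(mm) || nrow(mm) == 0) return(0)
    wt <- ifelse(mm$read_pos < 3 | mm$read_pos >= read_len - 3, 0.5, 1)
    sum(quals[mm$read_pos + 1L] * wt)
  }, numeric(1))
  best <- which(pen == min(pen))
  if (length(best) == 1)
    return(list(index = top[best], status = "resolved"))
  list(index = NA_integer_, status = "ambiguous_discarded")
}

#' Map a library of reads against an indexed reference
#'
#' Runs seed lookup, banded extension and multi-hit resolution for every
#' read and assigns each read exactly one category: `mapped_unique`
#' (status unique or resolved), `multi_discarded` (ambiguous placements) or
#' `unmapped` (no candidate alignment passed the caps). Reads removed
#' upstream by QC can be supplied as per-library counts so the
#' `low_quality_discarded` fraction appears in the mapping statistics.
#'
#' @param reads Read table ([read_fastq()] after [qc_filter_reads()]).
#' @param index A [build_index()] word index.
#' @param params [align_params()].
#' @param n_low_quality Optional named vector (library -> count) of reads
#'   discarded by QC, included in the per-library fractions.
#' @return `list(alignments=, mismatches=, segments=, stats=)`. Alignments
#'   carry the oriented read bases/quals; mismatch and segment tables refer
#'   to alignment row numbers and forward-reference coordinates.
#' @export
map_library <- function(reads, index, params = align_params(),
                        n_low_quality = NULL) {
  reads <- as.data.table(reads)
  n <- nrow(reads)
  empty_aln <- data.table(read_id = character(), library = character(),
                          ref = character(), start = integer(),
                          end = integer(), strand = character(),
                          score = integer(), cigar = character(),
                          n_mismatch = integer(), gap_total = integer(),
                          status = character(), bases = character(),
                          quals = list())
  if (n == 0) {
    return(list(alignments = empty_aln,
                mismatches = data.table(aln = integer(), ref_pos = integer(),
                                        read_pos = integer(),
                                        read_base = character(),
                                        ref_base = character(),
                                        qual = integer()),
                segments = data.table(aln = integer(), op = character(),
                                      len = integer(), read_start = integer(),
                                      ref_start = integer()),
                stats = .mapping_stats(character(), character(),
                                       n_low_quality)))
  }
  band <- params$band_halfwidth
  cand <- .seed_hits_batch(reads$bases, index, merge_dist = band)
  status <- rep("unmapped", n)
  if (nrow(cand) > 0) {
    m <- nchar(reads$bases)[cand$read_idx]
    L <- index$ref_len[cand$ref]
    ws <- pmax(0L, cand$diag - band)
    we <- pmin(L, cand$diag + m + band)
    cand <- cand[we - ws >= params$min_read_len]
    ws <- pmax(0L, cand$diag - band)
    we <- pmin(index$ref_len[cand$ref], cand$diag + m + band)
  }
  if (nrow(cand) == 0) {
    stats <- .mapping_stats(reads$library, status, n_low_quality)
    return(list(alignments = empty_aln,
                mismatches = data.table(aln = integer(), ref_pos = integer(),
                                        read_pos = integer(),
                                        read_base = character(),
                                        ref_base = character(),
                                        qual = integer()),
                segments = data.table(aln = integer(), op = character(),
                                      len = integer(), read_start = integer(),
                                      ref_start = integer()),
                stats = stats))
  }
  # oriented reads: reverse complement for minus-strand candidates
  need_rc <- unique(cand$read_idx[cand$strand == "-"])
  rc_bases <- character(0)
  if (length(need_rc)) {
    rc_bases <- setNames(revcomp(reads$bases[need_rc]), need_rc)
  }
  oriented <- ifelse(cand$strand == "+",
                     reads$bases[cand$read_idx],
                     rc_bases[as.character(cand$read_idx)])
  windows <- substring(index$reference[cand$ref], ws + 1L, we)
  # extend alignments gaplessly to the read ends so terminal variant bases
  # are observed as mismatches rather than soft-clipped
  res <- .sw_banded_batch(oriented, windows,
                          as.integer(cand$diag - ws), band,
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          extend = TRUE)
  aligned_len <- res$read_end - res$read_start
  pass <- which(res$score > 0 &
                res$n_mismatch <= params$max_mismatches &
                res$gap_total <= params$max_gap_len &
                res$gap_max <= params$max_gap_len &
                aligned_len >= params$min_read_len &
                nchar(oriented) - aligned_len <= params$max_clip)
  if (length(pass) == 0) {
    stats <- .mapping_stats(reads$library, status, n_low_quality)
    return(list(alignments = empty_aln,
                mismatches = data.table(aln = integer(), ref_pos = integer(),
                                        read_pos = integer(),
                                        read_base = character(),
                                        ref_base = character(),
                                        qual = integer()),
                segments = data.table(aln = integer(), op = character(),
                                      len = integer(), read_start = integer(),
                                      ref_start = integer()),
                stats = stats))
  }
  pdt <- data.table(pair = pass,
                    read_idx = cand$read_idx[pass],
                    ref = cand$ref[pass],
                    strand = cand$strand[pass],
                    ws = ws[pass],
                    score = res$score[pass],
                    nmm = res$n_mismatch[pass],
                    gt = res$gap_total[pass],
                    oriented = oriented[pass])
  # per-read resolution: strict top score wins; ties broken by the
  # end-weighted mismatch-quality penalty; residual ties are discarded
  mmdt <- data.table(pair = res$mm_pair + 1L, read_pos = res$mm_read_pos,
                     win_pos = res$mm_win_pos)
  mmdt <- mmdt[pair %in% pass]
  pdt[, m := nchar(oriented)]
  qflat <- lapply(seq_len(n), function(i) reads$quals[[i]])
  pen <- numeric(nrow(pdt))
  if (nrow(mmdt) > 0) {
    pp <- match(mmdt$pair, pdt$pair)
    ridx <- pdt$read_idx[pp]
    strnd <- pdt$strand[pp]
    mlen <- pdt$m[pp]
    # oriented qual at mismatch read position
    opos <- ifelse(strnd == "+", mmdt$read_pos, mlen - 1L - mmdt$read_pos)
    q <- mapply(function(i, p) qflat[[i]][p + 1L], ridx, opos)
    wt <- ifelse(mmdt$read_pos < 3 | mmdt$read_pos >= mlen - 3, 0.5, 1)
    psum <- data.table(pp = pp, v = q * wt)[, .(v = sum(v)), by = pp]
    pen[psum$pp] <- pen[psum$pp] + psum$v
  }
  pdt[, penalty := pen]
  pdt[, best := max(score), by = read_idx]
  tops <- pdt[score == best]
  tops[, ntop := .N, by = read_idx]
  winners <- tops[ntop == 1L]
  tied <- tops[ntop > 1L]
  if (nrow(tied)) {
    tied[, minpen := min(penalty), by = read_idx]
    tb <- tied[penalty == minpen]
    tb[, nmin := .N, by = read_idx]
    res_win <- tb[nmin == 1L]
    amb <- unique(tb[nmin > 1L]$read_idx)
    status[amb] <- "multi_discarded"
    winners <- rbind(winners[, .(pair, read_idx, ref, strand, ws, score,
                                 nmm, gt, oriented, m,
                                 status = "unique")],
                     res_win[, .(pair, read_idx, ref, strand, ws, score,
                                 nmm, gt, oriented, m,
                                 status = "resolved")])
  } else {
    winners <- winners[, .(pair, read_idx, ref, strand, ws, score, nmm, gt,
                           oriented, m, status = "unique")]
  }
  status[winners$read_idx] <- "mapped"

  # assemble alignment records in forward-reference coordinates
  ord <- order(winners$read_idx)
  winners <- winners[ord]
  pidx <- winners$pair
  aln <- data.table(
    read_id = reads$id[winners$read_idx],
    library = reads$library[winners$read_idx],
    ref = winners$ref,
    start = winners$ws + res$win_start[pidx],
    end = winners$ws + res$win_end[pidx],
    strand = winners$strand,
    score = res$score[pidx],
    cigar = "",
    n_mismatch = winners$nmm,
    gap_total = winners$gt,
    status = winners$status,
    bases = winners$oriented,
    quals = lapply(seq_len(nrow(winners)), function(k) {
      q <- qflat[[winners$read_idx[k]]]
      if (winners$strand[k] == "-") rev(q) else q
    }))

  segdt <- data.table(pair = res$seg_pair + 1L, op = res$seg_op,
                      len = res$seg_len, read_start = res$seg_read_start,
                      win_start = res$seg_win_start)
  amap <- match(segdt$pair, pidx)
  segs <- segdt[!is.na(amap)]
  segs[, aln := amap[!is.na(amap)]]
  segs[, ref_start := winners$ws[aln] + win_start]
  cig <- segs[order(aln, read_start), .(cigar = paste0(len, op, collapse = "")),
              by = aln]
  aln$cigar[cig$aln] <- cig$cigar

  mm_amap <- match(mmdt$pair, pidx)
  mms <- mmdt[!is.na(mm_amap)]
  mms[, aln := mm_amap[!is.na(mm_amap)]]
  if (nrow(mms)) {
    arow <- mms$aln
    mms[, ref_pos := winners$ws[arow] + win_pos]
    mms[, read_base := substring(winners$oriented[arow],
                                 read_pos + 1L, read_pos + 1L)]
    mms[, ref_base := substring(index$reference[winners$ref[arow]],
                                ref_pos + 1L, ref_pos + 1L)]
    alq <- aln$quals
    mms[, qual := mapply(function(a, p) alq[[a]][p + 1L], arow, read_pos)]
  } else {
    mms <- data.table(aln = integer(), ref_pos = integer(),
                      read_pos = integer(), read_base = character(),
                      ref_base = character(), qual = integer())
  }
  stats <- .mapping_stats(reads$library, status, n_low_quality)
  list(alignments = aln,
       mismatches = mms[, .(aln, ref_pos, read_pos, read_base, ref_base,
                            qual)],
       segments = segs[, .(aln, op, len, read_start, ref_start)],
       stats = stats)
}

# Per-library mapping statistics; fractions sum to 1 per library.
.mapping_stats <- function(libraries, status, n_low_quality = NULL) {
  if (length(libraries) == 0 && is.null(n_low_quality)) {
    return(data.table(library = character(), mapped_unique = integer(),
                      multi_discarded = integer(), unmapped = integer(),
                      low_quality_discarded = integer(), total = integer(),
                      frac_mapped_unique = numeric(),
                      frac_multi_discarded = numeric(),
                      frac_unmapped = numeric(),
                      frac_low_quality = numeric()))
  }
  dt <- data.table(library = libraries, status = status)
  tab <- dt[, .(mapped_unique = sum(status == "mapped"),
                multi_discarded = sum(status == "multi_discarded"),
                unmapped = sum(status == "unmapped")), by = library]
  if (!is.null(n_low_quality)) {
    lowq <- data.table(library = names(n_low_quality),
                       low_quality_discarded = as.integer(n_low_quality))
    tab <- merge(tab, lowq, by = "library", all = TRUE)
    for (col in c("mapped_unique", "multi_discarded", "unmapped",
                  "low_quality_discarded"))
      tab[is.na(get(col)), (col) := 0L]
  } else {
    tab[, low_quality_discarded := 0L]
  }
  tab[, total := mapped_unique + multi_discarded + unmapped +
        low_quality_discarded]
  tab[, frac_mapped_unique := ifelse(total > 0, mapped_unique / total, 0)]
  tab[, frac_multi_discarded := ifelse(total > 0, multi_discarded / total, 0)]
  tab[, frac_unmapped := ifelse(total > 0, unmapped / total, 0)]
  tab[, frac_low_quality := ifelse(total > 0,
                                   low_quality_discarded / total, 0)]
  tab[order(library)]
}
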