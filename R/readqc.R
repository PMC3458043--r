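# Pre-alignment QC for restriction-anchored short reads: the enzyme-overhang
# prefix check, the homopolymer prefilter, and 3' quality trimming.

#' Parameters for short-read QC
#'
#' Defaults reflect an HpaII reduced-representation protocol: reads must
#' begin with the CGG overhang the enzyme leaves; reads containing a
#' homopolymer longer than 16 bp are discarded; reads are 3'-trimmed so that
#' every remaining base has phred quality >= 10 and discarded when fewer
#' than 12 bases remain.
#'
#' @param expected_prefix Enzyme overhang the read must start with.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param min_qual Minimum phred score every retained base must reach.
#' @param min_len_after_trim Minimum read length after trimming.
#' @param enforce_prefix When `FALSE` the overhang check is tallied in the
#'   report but failing reads are kept.
#' @param trim_mode `"prefix"` cuts at the first base below `min_qual`
#'   (the longest prefix in which the minimum quality holds);
#'   `"tail_run"` only strips the trailing run of low-quality bases.
#' @return A `qc_params` list.
#' @export
qc_params <- function(expected_prefix = "CGG", max_homopolymer = 16,
                      min_qual = 10, min_len_after_trim = 12,
                      enforce_prefix = TRUE,
                      trim_mode = c("prefix", "tail_run")) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(min_len_after_trim >= 1, max_homopolymer >= 1)
  structure(list(expected_prefix = toupper(expected_prefix),
                 max_homopolymer = as.integer(max_homopolymer),
                 min_qual = as.integer(min_qual),
                 min_len_after_trim = as.integer(min_len_after_trim),
                 enforce_prefix = isTRUE(enforce_prefix),
                 trim_mode = trim_mode),
            class = "qc_params")
}

#' Check the restriction-enzyme overhang at the read start
#'
#' @param bases Character vector of read sequences.
#' @param params [qc_params()].
#' @return Logical vector: `TRUE` when the read begins with the expected
#'   overhang (case-insensitive exact match). Empty reads fail.
#' @export
check_overhang <- function(bases, params = qc_params()) {
  startsWith(toupper(bases), params$expected_prefix) &
    nchar(bases) >= nchar(params$expected_prefix)
}

#' Check for long homopolymers
#'
#' @param bases Character vector of read sequences.
#' @param params [qc_params()].
#' @return Logical vector: `TRUE` (pass) when no single-base run is longer
#'   than `max_homopolymer` anywhere in the read; a run of exactly
#'   `max_homopolymer` passes.
#' @export
check_homopolymer <- function(bases, params = qc_params()) {
  pat <- sprintf("([ACGTN])\\1{%d,}", params$max_homopolymer)
  !grepl(pat, toupper(bases))
}

#' Quality-trim the 3' end of a read
#'
#' In the default `"prefix"` mode the retained read is the longest prefix in
#' which every base has quality >= `min_qual` (cut at the first low-quality
#' base); `"tail_run"` mode instead strips only the trailing run of
#' low-quality bases.
#'
#' @param bases Read sequence (single string).
#' @param quals Integer phred scores, same length.
#' @param params [qc_params()].
#' @return `list(bases=, quals=)` for the trimmed read, or `NULL` when fewer
#'   than `min_len_after_trim` bases survive (read discarded).
#' @export
trim_3prime <- function(bases, quals, params = qc_params()) {
  n <- length(quals)
  if (params$trim_mode == "prefix") {
    low <- which(quals < params$min_qual)
    keep <- if (length(low)) low[1] - 1L else n
  } else {
    keep <- n
    while (keep > 0 && quals[keep] < params$min_qual) keep <- keep - 1L
  }
  if (keep < params$min_len_after_trim) return(NULL)
  list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)])
}

#' Run the full QC stage on a read table
#'
#' Filters are applied in a fixed order -- overhang prefix, homopolymer,
#' 3' quality trim -- so that the per-library report categories are
#' mutually exclusive and conserve the input count:
#' `input = prefix_fail + homopolymer_fail + too_short_after_trim + passed`.
#'
#' @param reads Read table from [read_fastq()].
#' @param params [qc_params()].
#' @return `list(reads=, report=)`: the surviving (possibly trimmed) reads
#'   and a per-library QC report data.table. When `enforce_prefix` is
#'   `FALSE` non-conforming reads are retained and only tallied in the
#'   `prefix_nonconforming` column.
#' @export
qc_filter_reads <- function(reads, params = qc_params()) {
  stopifnot(is.data.frame(reads))
  reads <- as.data.table(reads)
  n <- nrow(reads)
  if (n == 0) {
    rep0 <- data.table(library = character(), input = integer(),
                       prefix_fail = integer(), prefix_nonconforming = integer(),
                       homopolymer_fail = integer(),
                       too_short_after_trim = integer(), passed = integer(),
                       bases_trimmed = integer())
    return(list(reads = reads, report = rep0))
  }
  prefix_ok <- check_overhang(reads$bases, params)
  removed_prefix <- if (params$enforce_prefix) !prefix_ok else rep(FALSE, n)
  homo_ok <- check_homopolymer(reads$bases, params)
  removed_homo <- !removed_prefix & !homo_ok

  cand <- which(!removed_prefix & !removed_homo)
  keep_len <- integer(n)
  if (length(cand)) {
    if (params$trim_mode == "prefix") {
      keep_len[cand] <- vapply(reads$quals[cand], function(q) {
        low <- which(q < params$min_qual)
        if (length(low)) low[1] - 1L else length(q)
      }, integer(1))
    } else {
      keep_len[cand] <- vapply(reads$quals[cand], function(q) {
        k <- length(q)
        while (k > 0 && q[k] < params$min_qual) k <- k - 1L
        k
      }, integer(1))
    }
  }
  removed_short <- !removed_prefix & !removed_homo &
    keep_len < params$min_len_after_trim
  passed <- !(removed_prefix | removed_homo | removed_short)

  out <- reads[passed]
  kl <- keep_len[passed]
  full <- nchar(out$bases)
  trim_needed <- which(kl < full)
  if (length(trim_needed)) {
    out[trim_needed, bases := substr(bases, 1L, kl[trim_needed])]
    out$quals[trim_needed] <- Map(function(q, k) q[seq_len(k)],
                                  out$quals[trim_needed], kl[trim_needed])
  }
  rep_dt <- data.table(
    library = reads$library, removed_prefix, prefix_ok,
    removed_homo, removed_short, passed,
    trimmed = ifelse(passed, nchar(reads$bases) - keep_len, 0L)
  )[, .(input = .N,
        prefix_fail = sum(removed_prefix),
        prefix_nonconforming = sum(!prefix_ok),
        homopolymer_fail = sum(removed_homo),
        too_short_after_trim = sum(removed_short),
        passed = sum(passed),
        bases_trimmed = sum(trimmed)), by = library]
  list(reads = out, report = rep_dt[order(library)])
}
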