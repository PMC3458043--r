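# Pileup construction and the two-stage polyploid SNP/indel caller.
#
# Each aligned read contributes exactly one observation per reference
# column it covers. Indel events are anchored at the reference base
# immediately 5' of the event and left-normalised; the anchoring read's
# base observation at the anchor column is replaced by the indel
# observation, so per-column depths count each read once.

#' SNP/indel calling parameters
#'
#' Dosage-aware thresholds for polyploids: `d` alternate-carrying reads are
#' required within a single library (stage 1), `l` pooled across libraries
#' (stage 2). The reference:alternate ratio must lie within
#' `[1/max_ratio, max_ratio]`, boundaries included -- with `max_ratio = 7`
#' a single-dose allele in an octoploid (expected ratio 7:1) is still
#' admissible, while more extreme imbalances, typical of sequencing or
#' assembly error, are rejected. Bases below `min_base_qual` are excluded
#' before any counting, on reference- and alternate-supporting reads alike.
#'
#' @param d Minimum alternate-carrying reads within a single library.
#' @param l Minimum alternate-carrying reads pooled across libraries.
#' @param max_ratio Maximum of ref:alt and alt:ref (inclusive bound).
#' @param min_base_qual Minimum phred score for a base to be counted.
#' @param min_depth_at_site Minimum (filtered) read depth at the site,
#'   within the unit being tested.
#' @return A `call_params` list.
#' @export
call_params <- function(d = 3, l = 3, max_ratio = 7, min_base_qual = 20,
                        min_depth_at_site = 3) {
  stopifnot(d >= 1, l >= 1, max_ratio >= 1)
  structure(list(d = as.integer(d), l = as.integer(l),
                 max_ratio = as.numeric(max_ratio),
                 min_base_qual = as.integer(min_base_qual),
                 min_depth_at_site = as.integer(min_depth_at_site)),
            class = "call_params")
}

# shift an indel event to its leftmost equivalent position (standard
# left-normalisation): event of `seq` at 0-based position `pos`
.normalize_indel <- function(refseq, pos, seq) {
  len <- nchar(seq)
  while (pos > 1L) {
    prev <- substr(refseq, pos, pos)           # ref base at pos-1 (0-based)
    if (prev != substr(seq, len, len)) break
    seq <- paste0(prev, substr(seq, 1L, len - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

#' Build pileup observations from alignments
#'
#' @param map_results A [map_library()] result, or an (optionally nested)
#'   list of them covering several libraries.
#' @param reference The [reference_set()] that was mapped against.
#' @return A `pileup` object: `list(obs=, reference=, libraries=)` where
#'   `obs` has one row per (read, reference column) with columns ref, pos,
#'   ref_base, library, allele (base, `+SEQ` insertion or `-SEQ` deletion,
#'   anchored 5' of the event), qual and a read-unique `aln` id.
#' @export
build_pileups <- function(map_results, reference) {
  if (!is.null(map_results$alignments)) map_results <- list(map_results)
  alns <- list(); mms <- list(); segs <- list(); off <- 0L
  for (r in map_results) {
    a <- as.data.table(r$alignments)
    s <- as.data.table(r$segments)
    if (nrow(s)) s[, aln := aln + off]
    alns[[length(alns) + 1L]] <- a
    segs[[length(segs) + 1L]] <- s
    off <- off + nrow(a)
  }
  aln <- rbindlist(alns)
  seg <- rbindlist(segs)
  refseqs <- unclass(reference)
  if (nrow(aln)) {
    if (any(!aln$ref %in% names(refseqs)))
      stop("alignment references unknown sequence: aligner bug?")
    if (any(aln$end > nchar(refseqs)[aln$ref]) || any(aln$start < 0))
      stop("alignment outside the reference: aligner bug?")
    if (!all(aln$status %in% c("unique", "resolved", "mapped")))
      stop("pileups accept only unique/resolved alignments")
  }
  empty <- data.table(ref = character(), pos = integer(),
                      ref_base = character(), library = character(),
                      allele = character(), qual = integer(),
                      aln = integer())
  if (nrow(seg) == 0) {
    return(structure(list(obs = empty, reference = reference,
                          libraries = sort(unique(aln$library))),
                     class = "pileup"))
  }
  qlens <- lengths(aln$quals)
  qstart <- cumsum(c(0L, head(qlens, -1L)))
  qflat <- unlist(aln$quals, use.names = FALSE)

  segM <- seg[op == "M"]
  nper <- segM$len
  srow <- rep(seq_len(nrow(segM)), nper)
  idx <- sequence(nper) - 1L
  arow <- segM$aln[srow]
  refpos <- segM$ref_start[srow] + idx
  readpos <- segM$read_start[srow] + idx
  obs <- data.table(
    ref = aln$ref[arow],
    pos = as.integer(refpos),
    library = aln$library[arow],
    allele = substring(aln$bases[arow], readpos + 1L, readpos + 1L),
    qual = qflat[qstart[arow] + readpos + 1L],
    aln = arow)
  obs[, ref_base := substring(refseqs[ref], pos + 1L, pos + 1L)]

  segI <- seg[op != "M"]
  if (nrow(segI)) {
    ev <- vector("list", nrow(segI))
    for (k in seq_len(nrow(segI))) {
      a <- segI$aln[k]
      rs <- segI$read_start[k]; ps <- segI$ref_start[k]
      len <- segI$len[k]
      rseq <- refseqs[[aln$ref[a]]]
      if (segI$op[k] == "I") {
        sq <- substring(aln$bases[a], rs + 1L, rs + len)
      } else {
        sq <- substring(rseq, ps + 1L, ps + len)
      }
      nr <- .normalize_indel(rseq, ps, sq)
      if (nr$pos < 1L) next                      # no 5' anchor base; drop
      anchor <- nr$pos - 1L
      qpos <- max(0L, rs - 1L)
      ev[[k]] <- data.table(
        ref = aln$ref[a], pos = anchor,
        library = aln$library[a],
        allele = paste0(if (segI$op[k] == "I") "+" else "-", nr$seq),
        qual = qflat[qstart[a] + qpos + 1L],
        aln = a)
    }
    ev <- rbindlist(ev[!vapply(ev, is.null, logical(1))])
    if (nrow(ev)) {
      ev[, ref_base := substring(refseqs[ref], pos + 1L, pos + 1L)]
      # the indel observation replaces the read's base observation at the
      # anchor column: one observation per read per column
      obs <- obs[!ev, on = c("aln", "ref", "pos")]
      obs <- rbind(obs, ev, use.names = TRUE)
    }
  }
  obs <- obs[allele != "N"]
  setkey(obs, ref, pos)
  structure(list(obs = obs, reference = reference,
                 libraries = sort(unique(aln$library))),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", nrow(x$obs), "observations over",
      length(unique(x$obs$ref)), "reference records,",
      length(x$libraries), "libraries\n")
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup A [build_pileups()] object.
#' @param ref Reference record name.
#' @param pos 0-based position.
#' @return data.table of observations at that column (library, allele,
#'   qual), with the reference base as attribute `ref_base`.
#' @export
pileup_column <- function(pileup, ref, pos) {
  key <- data.table(ref = as.character(ref), pos = as.integer(pos))
  col <- pileup$obs[key, on = c("ref", "pos"), nomatch = NULL]
  rb <- substring(unclass(pileup$reference)[[as.character(ref)]],
                  pos + 1, pos + 1)
  setattr(col, "ref_base", rb)
  col
}

# the single-site decision rule; `column` holds library/allele/qual rows
# already restricted to one reference column
.site_decision <- function(column, ref_base, params, mode) {
  obs <- column[qual >= params$min_base_qual & allele != "N"]
  if (nrow(obs) == 0 || ref_base == "N") return(NULL)
  cand <- obs[allele != ref_base, .(n = .N, q = sum(qual)), by = allele]
  if (nrow(cand) == 0) return(NULL)
  setorder(cand, -n, -q, allele)
  alt <- cand$allele[1]
  per <- obs[, .(ref_n = sum(allele == ref_base),
                 alt_n = sum(allele == alt),
                 depth = .N), by = library]
  pooled <- per[, .(ref_n = sum(ref_n), alt_n = sum(alt_n),
                    depth = sum(depth))]
  ratio_ok <- function(r, a)
    a > 0 & r <= params$max_ratio * a & a <= params$max_ratio * r
  lib_pass <- per[, alt_n >= params$d & ratio_ok(ref_n, alt_n) &
                    depth >= params$min_depth_at_site]
  pool_pass <- pooled[, alt_n >= params$l & ratio_ok(ref_n, alt_n) &
                        depth >= params$min_depth_at_site]
  called <- if (mode == "per_library") any(lib_pass) else pool_pass
  if (!called) return(NULL)
  list(alt_allele = alt,
       variant_type = if (startsWith(alt, "+")) "ins"
                      else if (startsWith(alt, "-")) "del" else "snp",
       per_library = per, pooled = pooled,
       flags = list(
         d_pass = any(per$alt_n >= params$d),
         l_pass = pooled$alt_n >= params$l,
         ratio_pass = if (mode == "per_library")
           any(ratio_ok(per$ref_n, per$alt_n)) else
             ratio_ok(pooled$ref_n, pooled$alt_n),
         qual_pass = TRUE),
       n_other_alleles = nrow(cand) - 1L)
}

#' Decide a single pileup column
#'
#' Applies the full filter conjunction to one column: quality filtering,
#' alternate-allele selection (most frequent non-reference allele, ties
#' broken by summed base quality then lexicographically), then -- within a
#' single library (`per_library`) or across all libraries (`pooled`) -- the
#' alternate-depth threshold (`d` or `l`), the inclusive ref:alt ratio
#' bound and the minimum site depth.
#'
#' @param column A [pileup_column()] (or any data.table with library,
#'   allele, qual rows for one site).
#' @param params [call_params()].
#' @param mode `"per_library"` or `"pooled"`.
#' @param ref_base Reference base at the column; defaults to the column's
#'   `ref_base` attribute.
#' @return A list describing the call (alternate allele, per-library and
#'   pooled counts, filter provenance flags), or `NULL` for no call.
#' @export
call_site <- function(column, params = call_params(),
                      mode = c("per_library", "pooled"),
                      ref_base = attr(column, "ref_base")) {
  mode <- match.arg(mode)
  if (is.null(ref_base)) stop("ref_base is required")
  .site_decision(as.data.table(column), ref_base, params, mode)
}

#' Call variants from pileups
#'
#' `mode = "two_stage"` (the default analysis) is the union of per-library
#' calls (stage 1, threshold `d` within one library) and pooled calls
#' (stage 2, threshold `l` across libraries), each stage applying its own
#' ratio and depth tests; records are labelled `per_library`, `pooled` or
#' `both`. At most one variant (the top alternate allele) is reported per
#' site; further alleles are tallied in `n_other_alleles`.
#'
#' @param pileup A [build_pileups()] object.
#' @param params [call_params()].
#' @param mode `"two_stage"`, `"per_library"` or `"pooled"`.
#' @return A `variant_table` data.table: site fields (`ref_name`,
#'   0-based `position`, alleles, `variant_type`, `anchor_base` for
#'   indels), paired `<library>.ref_depth`/`<library>.alt_depth` columns,
#'   pooled depths, `call_stage` and filter provenance flags.
#' @export
call_variants <- function(pileup, params = call_params(),
                          mode = c("two_stage", "per_library", "pooled")) {
  mode <- match.arg(mode)
  libs <- pileup$libraries
  obs <- pileup$obs[qual >= params$min_base_qual & allele != "N" &
                      ref_base != "N"]
  out0 <- .empty_variant_table(libs, params)
  if (nrow(obs) == 0) return(out0)
  cand <- obs[allele != ref_base, .(n = .N, qsum = sum(qual)),
              by = .(ref, pos, allele)]
  if (nrow(cand) == 0) return(out0)
  setorder(cand, ref, pos, -n, -qsum, allele)
  top <- cand[, .(alt = allele[1L], n_other_alleles = .N - 1L),
              by = .(ref, pos)]
  obs <- obs[top, on = c("ref", "pos")]
  per <- obs[, .(ref_n = sum(allele == ref_base),
                 alt_n = sum(allele == alt),
                 depth = .N),
             by = .(ref, pos, alt, ref_base, library)]
  rmax <- params$max_ratio
  per[, pass := alt_n >= params$d & alt_n > 0 &
        ref_n <= rmax * alt_n & alt_n <= rmax * ref_n &
        depth >= params$min_depth_at_site]
  site <- per[, .(stage1 = any(pass),
                  pooled_ref_depth = sum(ref_n),
                  pooled_alt_depth = sum(alt_n),
                  pooled_depth = sum(depth),
                  ratio_pass_lib = any(alt_n > 0 & ref_n <= rmax * alt_n &
                                         alt_n <= rmax * ref_n),
                  d_pass = any(alt_n >= params$d)),
              by = .(ref, pos, alt, ref_base)]
  site[, l_pass := pooled_alt_depth >= params$l]
  site[, ratio_pass_pooled := pooled_alt_depth > 0 &
         pooled_ref_depth <= rmax * pooled_alt_depth &
         pooled_alt_depth <= rmax * pooled_ref_depth]
  site[, stage2 := l_pass & ratio_pass_pooled &
         pooled_depth >= params$min_depth_at_site]
  keep <- switch(mode,
                 two_stage = site[stage1 | stage2],
                 per_library = site[stage1 == TRUE],
                 pooled = site[stage2 == TRUE])
  if (nrow(keep) == 0) return(out0)
  keep[, call_stage := fifelse(stage1 & stage2, "both",
                               fifelse(stage1, "per_library", "pooled"))]
  if (mode == "per_library") keep[, call_stage := "per_library"]
  if (mode == "pooled") keep[, call_stage := "pooled"]
  keep[top, on = c("ref", "pos"), n_other_alleles := i.n_other_alleles]

  # wide per-library depth columns
  perk <- per[keep[, .(ref, pos)], on = c("ref", "pos")]
  wide_r <- dcast(perk, ref + pos ~ library, value.var = "ref_n", fill = 0L)
  wide_a <- dcast(perk, ref + pos ~ library, value.var = "alt_n", fill = 0L)
  for (l in setdiff(libs, names(wide_r))) {
    wide_r[, (l) := 0L]; wide_a[, (l) := 0L]
  }
  setnames(wide_r, libs, paste0(libs, ".ref_depth"))
  setnames(wide_a, libs, paste0(libs, ".alt_depth"))
  out <- merge(merge(keep, wide_r, by = c("ref", "pos")),
               wide_a, by = c("ref", "pos"))

  out[, variant_type := fifelse(startsWith(alt, "+"), "ins",
                                fifelse(startsWith(alt, "-"), "del", "snp"))]
  out[, anchor_base := fifelse(variant_type == "snp", NA_character_,
                               ref_base)]
  out[, ref_allele := fifelse(variant_type == "snp", ref_base,
                              fifelse(variant_type == "del",
                                      substring(alt, 2L), "-"))]
  out[, alt_allele := fifelse(variant_type == "snp", alt,
                              fifelse(variant_type == "ins",
                                      substring(alt, 2L), "-"))]
  out[, position := fifelse(variant_type == "snp", pos, pos + 1L)]
  setnames(out, "ref", "ref_name")
  out[, qual_pass := TRUE]
  out[, lower_confidence := FALSE]
  cols <- c("ref_name", "position", "ref_allele", "alt_allele",
            "variant_type", "anchor_base",
            paste0(rep(libs, each = 2), c(".ref_depth", ".alt_depth")),
            "pooled_ref_depth", "pooled_alt_depth", "call_stage",
            "d_pass", "l_pass", "ratio_pass_lib", "ratio_pass_pooled",
            "qual_pass", "n_other_alleles", "lower_confidence")
  out <- out[, ..cols]
  setorder(out, ref_name, position, alt_allele)
  setattr(out, "libraries", libs)
  setattr(out, "params", params)
  setattr(out, "class", c("variant_table", class(out)))
  out[]
}

.empty_variant_table <- function(libs, params) {
  out <- data.table(ref_name = character(), position = integer(),
                    ref_allele = character(), alt_allele = character(),
                    variant_type = character(), anchor_base = character())
  for (l in libs) {
    out[, (paste0(l, ".ref_depth")) := integer()]
    out[, (paste0(l, ".alt_depth")) := integer()]
  }
  out[, `:=`(pooled_ref_depth = integer(), pooled_alt_depth = integer(),
             call_stage = character(), d_pass = logical(),
             l_pass = logical(), ratio_pass_lib = logical(),
             ratio_pass_pooled = logical(), qual_pass = logical(),
             n_other_alleles = integer(), lower_confidence = logical())]
  setattr(out, "libraries", libs)
  setattr(out, "params", params)
  setattr(out, "class", c("variant_table", class(out)))
  out[]
}

#' Two-stage SNP/indel calling
#'
#' Convenience wrapper for [call_variants()] with `mode = "two_stage"`:
#' the union of per-library and pooled calls, the analysis mode used for
#' short-read libraries.
#'
#' @inheritParams call_variants
#' @return A `variant_table`; see [call_variants()].
#' @export
call_variants_two_stage <- function(pileup, params = call_params()) {
  call_variants(pileup, params, mode = "two_stage")
}

#' SNP calling from long (EST) reads
#'
#' ESTs aligned against the same reference are deep enough for only a
#' relaxed threshold: the identical caller is run with `d = 2, l = 2`, and
#' every resulting record is flagged `lower_confidence`.
#'
#' @param pileup Pileup built from EST alignments.
#' @param params [call_params()]; defaults to the d=2/l=2 long-read mode.
#' @return A `variant_table` with `lower_confidence = TRUE`.
#' @export
call_from_long_reads <- function(pileup,
                                 params = call_params(d = 2, l = 2)) {
  out <- call_variants(pileup, params, mode = "two_stage")
  if (nrow(out)) out[, lower_confidence := TRUE]
  out[]
}
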