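# Genotype calling, numeric encoding, PCA structure analysis and
# diversity/coverage summaries.

# the dominant-marker genotype rule for one depth pair
.genotype_rule <- function(ref_n, alt_n, min_depth = 4L) {
  ifelse(ref_n + alt_n < min_depth, "missing",
  ifelse(ref_n >= min_depth & alt_n == 0L, "hom_ref",
  ifelse(alt_n >= min_depth & ref_n == 0L, "hom_alt",
  ifelse(ref_n >= min_depth & alt_n >= min_depth, "het", "missing"))))
}

#' Call dominant-marker genotypes from variant depths
#'
#' Genotypes are treated as dominant-marker data: a call requires at least
#' `min_depth` reads for the individual at the locus; `>= min_depth` reads
#' of one allele and none of the other gives a homozygote; `>= min_depth`
#' reads of each allele gives a heterozygote. Any other depth pattern
#' (e.g. 5 reference + 2 alternate) is left undefined by these rules and
#' conservatively recorded as missing.
#'
#' @param variants A `variant_table` with per-library depth columns.
#' @param min_depth Minimum reads per allele class (default 4).
#' @return A `genotype_matrix`: libraries x variants categorical calls
#'   (`hom_ref`/`hom_alt`/`het`/`missing`) plus the underlying ref/alt
#'   depth matrices.
#' @export
call_genotypes <- function(variants, min_depth = 4) {
  libs <- attr(variants, "libraries")
  v <- as.data.table(variants)
  ids <- if (nrow(v)) paste0(v$ref_name, ":", v$position, ":", v$alt_allele)
         else character(0)
  nlib <- length(libs); nv <- nrow(v)
  refd <- altd <- matrix(0L, nrow = nlib, ncol = nv,
                         dimnames = list(libs, ids))
  for (l in libs) {
    refd[l, ] <- as.integer(v[[paste0(l, ".ref_depth")]])
    altd[l, ] <- as.integer(v[[paste0(l, ".alt_depth")]])
  }
  geno <- matrix(.genotype_rule(refd, altd, as.integer(min_depth)),
                 nrow = nlib, dimnames = list(libs, ids))
  structure(list(geno = geno, ref_depth = refd, alt_depth = altd,
                 libraries = libs, variant_ids = ids,
                 min_depth = as.integer(min_depth)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$libraries), "libraries x",
      length(x$variant_ids), "variants;",
      sum(x$geno == "missing"), "missing cells\n")
  invisible(x)
}

#' Restrict a genotype matrix to complete cases
#'
#' Keeps only variants with a non-missing genotype in every library
#' (variants with missing genotypes are excluded from structure analysis).
#'
#' @param gm A [call_genotypes()] matrix.
#' @return The filtered `genotype_matrix`; warns when nothing survives.
#' @export
complete_case_filter <- function(gm) {
  keep <- colSums(gm$geno == "missing") == 0
  if (!any(keep)) warning("no variant has complete genotype information")
  gm$geno <- gm$geno[, keep, drop = FALSE]
  gm$ref_depth <- gm$ref_depth[, keep, drop = FALSE]
  gm$alt_depth <- gm$alt_depth[, keep, drop = FALSE]
  gm$variant_ids <- gm$variant_ids[keep]
  gm
}

#' Encode genotypes numerically for PCA
#'
#' Homozygous reference is 0 and homozygous alternate is 2. For
#' heterozygotes the default `"dosage"` encoding is `2*alt/(ref+alt)`,
#' which stays on the 0-2 scale and uses the read ratio as an allele-dosage
#' estimate; `"literal_ratio"` encodes the raw reference:alternate read
#' ratio `ref/alt` instead (unbounded; retained for fidelity to the
#' historical coding).
#'
#' @param gm A complete-case [genotype_matrix][call_genotypes()].
#' @param het_encoding `"dosage"` or `"literal_ratio"`.
#' @return Numeric libraries x variants matrix.
#' @export
encode_numeric <- function(gm, het_encoding = c("dosage", "literal_ratio")) {
  het_encoding <- match.arg(het_encoding)
  if (any(gm$geno == "missing"))
    stop("encode_numeric expects a complete-case matrix; run ",
         "complete_case_filter() first")
  out <- matrix(0, nrow = nrow(gm$geno), ncol = ncol(gm$geno),
                dimnames = dimnames(gm$geno))
  out[gm$geno == "hom_alt"] <- 2
  het <- gm$geno == "het"
  if (any(het)) {
    r <- gm$ref_depth[het]; a <- gm$alt_depth[het]
    stopifnot(all(a > 0))                # guaranteed by the genotype rule
    out[het] <- if (het_encoding == "dosage") 2 * a / (r + a) else r / a
  }
  out
}

#' Principal-components analysis of a genotype matrix
#'
#' Columns are mean-centred (no variance scaling) and decomposed by SVD;
#' variance fractions are the squared singular values normalised to sum to
#' one.
#'
#' @param x Numeric libraries x variants matrix (from [encode_numeric()]).
#' @return `list(scores=, var_frac=, rotation=, sdev=)`; `scores` has one
#'   row per library.
#' @export
pca_genotypes <- function(x) {
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 libraries and 2 variants")
  if (all(apply(x, 2, function(c) diff(range(c))) == 0))
    stop("no variation in the genotype matrix")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, var_frac = var_frac, rotation = p$rotation,
       sdev = p$sdev)
}

#' Coverage and diversity summary
#'
#' Per library: breadth of the reference covered at depth >= x for
#' x in 1..`max_depth` (with the uncovered fraction reported as 0x),
#' SNPs/Kb (variants for which the library itself satisfies the
#' per-library calling conjunction, divided by the kilobases it covers at
#' the calling depth), and the ordinary least-squares regression of
#' SNPs/Kb on mapped-read count across libraries.
#'
#' @param pileup A [build_pileups()] object.
#' @param variants A `variant_table`.
#' @param reference The [reference_set()].
#' @param params [call_params()] used for the per-library SNP attribution
#'   and the calling-depth denominator.
#' @param max_depth Largest depth stratum reported.
#' @return A `diversity_summary`: `list(per_library=, pooled=,
#'   regression=)`.
#' @export
diversity_summary <- function(pileup, variants, reference,
                              params = call_params(), max_depth = 5) {
  tot <- total_length(reference)
  base_obs <- pileup$obs[!startsWith(allele, "+") & !startsWith(allele, "-")]
  libs <- pileup$libraries
  dep <- base_obs[, .(depth = .N), by = .(ref, pos, library)]
  breadth <- function(d) {
    vapply(1:max_depth, function(x) sum(d >= x), integer(1))
  }
  per <- dep[, {
    b <- breadth(depth)
    c(list(mapped_reads = length(unique(base_obs[library == .BY$library]$aln)),
           breadth_0 = tot - b[1]),
      setNames(as.list(b), paste0("breadth_", 1:max_depth)))
  }, by = library]
  pooled_dep <- dep[, .(depth = sum(depth)), by = .(ref, pos)]
  bp <- breadth(pooled_dep$depth)
  pooled <- data.table(breadth_0 = tot - bp[1],
                       t(setNames(bp, paste0("breadth_", 1:max_depth))))

  v <- as.data.table(variants)
  rmax <- params$max_ratio
  snp_n <- setNames(integer(length(libs)), libs)
  for (l in libs) {
    if (nrow(v) == 0) break
    r <- v[[paste0(l, ".ref_depth")]]
    a <- v[[paste0(l, ".alt_depth")]]
    snp_n[l] <- sum(a >= params$d & a > 0 & r <= rmax * a & a <= rmax * r &
                      (r + a) >= params$min_depth_at_site)
  }
  dcol <- paste0("breadth_", min(params$min_depth_at_site, max_depth))
  per[, snps := snp_n[library]]
  per[, snps_per_kb := ifelse(get(dcol) > 0, snps / (get(dcol) / 1000), 0)]

  reg <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)
  if (nrow(per) >= 3 && stats::sd(per$snps_per_kb) > 0 &&
      stats::sd(per$mapped_reads) > 0) {
    fit <- lm(snps_per_kb ~ mapped_reads, data = per)
    reg <- list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r_squared = summary(fit)$r.squared)
  }
  structure(list(per_library = per[order(library)], pooled = pooled,
                 regression = reg),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("diversity_summary over", nrow(x$per_library), "libraries\n")
  print(x$per_library)
  invisible(x)
}
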