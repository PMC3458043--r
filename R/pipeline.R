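# Single entry point wiring the stages together, with plain-file handoff
# so every stage stays independently testable.

#' Assemble a run configuration
#'
#' @param reference Path to a reference FASTA, or a [reference_set()], or
#'   `NULL` when `sim` is given (the simulated genic reference is used).
#' @param fastq Named character vector (library -> FASTQ path); ignored
#'   when `sim` is given.
#' @param sim Optional [sim_config()]: simulate genome and libraries
#'   instead of reading files.
#' @param qc,align,call [qc_params()], [align_params()], [call_params()].
#' @param word_size,shift_size Index parameters.
#' @param genotype_min_depth Minimum depth for genotype calls.
#' @param het_encoding PCA heterozygote encoding (see [encode_numeric()]).
#' @param offset FASTQ quality offset.
#' @return A validated `run_config` list.
#' @export
run_config <- function(reference = NULL, fastq = NULL, sim = NULL,
                       qc = qc_params(), align = align_params(),
                       call = call_params(), word_size = 12,
                       shift_size = 12, genotype_min_depth = 4,
                       het_encoding = "dosage", offset = 33) {
  if (is.null(sim)) {
    if (is.null(reference))
      stop("config error: either a reference or a sim block is required")
    if (is.character(reference) && !file.exists(reference))
      stop("config error: reference file not found: ", reference)
    if (is.null(fastq) || length(fastq) == 0 || is.null(names(fastq)))
      stop("config error: fastq must be a named (library -> path) vector")
    missing <- fastq[!file.exists(fastq)]
    if (length(missing))
      stop("config error: FASTQ not found: ", paste(missing, collapse = ", "))
  }
  structure(list(reference = reference, fastq = fastq, sim = sim,
                 qc = qc, align = align, call = call,
                 word_size = word_size, shift_size = shift_size,
                 genotype_min_depth = genotype_min_depth,
                 het_encoding = het_encoding, offset = offset),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys (at the top level or inside a parameter block) are
#' rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("reference", "fastq", "sim", "qc", "align", "call",
             "word_size", "shift_size", "genotype_min_depth",
             "het_encoding", "offset")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  block <- function(x, fn) {
    if (is.null(x)) return(fn())
    unknown <- setdiff(names(x), names(formals(fn)))
    if (length(unknown))
      stop("config error: unknown keys: ", paste(unknown, collapse = ", "))
    do.call(fn, x)
  }
  fq <- if (!is.null(y$fastq)) unlist(y$fastq) else NULL
  run_config(reference = y$reference, fastq = fq,
             sim = if (!is.null(y$sim)) block(y$sim, sim_config) else NULL,
             qc = block(y$qc, qc_params),
             align = block(y$align, align_params),
             call = block(y$call, call_params),
             word_size = y$word_size %||% 12,
             shift_size = y$shift_size %||% 12,
             genotype_min_depth = y$genotype_min_depth %||% 4,
             het_encoding = y$het_encoding %||% "dosage",
             offset = y$offset %||% 33)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes QC, mapping, pileup, two-stage calling, genotyping,
#' complete-case PCA and the diversity summary in dependency order,
#' returning every intermediate plus a summary report. With an output
#' directory the stage outputs are written as plain files (TSV/VCF/YAML);
#' a rerun with an identical configuration is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional run directory.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result` list: reference, qc reports, mapping stats,
#'   pileup, variants, genotypes, pca, diversity, summary (and `sim` truth
#'   when simulating).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[rrsnp] ", ...)
  sim <- NULL
  if (!is.null(config$sim)) {
    say("simulating genome and libraries (seed ", config$sim$seed, ")")
    sim <- simulate_genome(config$sim)
    libset <- simulate_library_set(sim)
    reference <- sim$reference
    raw <- libset$libraries
  } else {
    reference <- if (inherits(config$reference, "reference_set"))
      config$reference else read_fasta_reference(config$reference)
    raw <- lapply(names(config$fastq), function(l)
      read_fastq(config$fastq[[l]], library = l, offset = config$offset))
    names(raw) <- names(config$fastq)
  }

  say("QC on ", length(raw), " libraries")
  qc <- lapply(raw, qc_filter_reads, params = config$qc)
  qc_report <- rbindlist(lapply(qc, `[[`, "report"))
  lowq <- setNames(qc_report$input - qc_report$passed, qc_report$library)

  say("indexing reference (", length(reference), " records)")
  index <- build_index(reference, config$word_size, config$shift_size)
  say("mapping")
  maps <- lapply(names(raw), function(l)
    map_library(qc[[l]]$reads, index, config$align,
                n_low_quality = lowq[l]))
  names(maps) <- names(raw)
  mapping_stats <- rbindlist(lapply(maps, `[[`, "stats"))

  say("building pileups and calling variants")
  pileup <- build_pileups(maps, reference)
  variants <- call_variants_two_stage(pileup, config$call)

  say("genotyping ", nrow(variants), " variants")
  gm <- call_genotypes(variants, min_depth = config$genotype_min_depth)
  gmc <- suppressWarnings(complete_case_filter(gm))
  pca <- NULL
  if (length(gmc$variant_ids) >= 2 && length(gmc$libraries) >= 2) {
    num <- encode_numeric(gmc, het_encoding = config$het_encoding)
    pca <- tryCatch(pca_genotypes(num), error = function(e) NULL)
  }
  div <- diversity_summary(pileup, variants, reference, config$call)

  summary <- list(
    n_libraries = length(raw),
    n_reads = sum(vapply(raw, nrow, integer(1))),
    n_reads_passed_qc = sum(qc_report$passed),
    reference_records = length(reference),
    reference_length = total_length(reference),
    frac_mapped_unique = sum(mapping_stats$mapped_unique) /
      max(1, sum(mapping_stats$total)),
    frac_multi_discarded = sum(mapping_stats$multi_discarded) /
      max(1, sum(mapping_stats$total)),
    frac_unmapped = sum(mapping_stats$unmapped) /
      max(1, sum(mapping_stats$total)),
    frac_low_quality = sum(mapping_stats$low_quality_discarded) /
      max(1, sum(mapping_stats$total)),
    n_variants = nrow(variants),
    n_snps = sum(variants$variant_type == "snp"),
    n_indels = sum(variants$variant_type != "snp"),
    n_complete_case = length(gmc$variant_ids),
    mean_snps_per_kb = mean(div$per_library$snps_per_kb),
    pc1_var_frac = if (!is.null(pca)) pca$var_frac[1] else NA_real_,
    pc2_var_frac = if (!is.null(pca) && length(pca$var_frac) > 1)
      pca$var_frac[2] else NA_real_)

  res <- structure(list(reference = reference, qc = qc,
                        qc_report = qc_report, mapping_stats = mapping_stats,
                        maps = maps, pileup = pileup, variants = variants,
                        genotypes = gm, genotypes_complete = gmc, pca = pca,
                        diversity = div, summary = summary, sim = sim,
                        libset = if (!is.null(sim)) libset else NULL),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, config, out_dir)
  res
}

.write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(res$qc_report, file.path(out_dir, "qc_report.tsv"), sep = "\t")
  fwrite(res$mapping_stats, file.path(out_dir, "mapping_stats.tsv"),
         sep = "\t")
  write_variants(res$variants, file.path(out_dir, "variants.tsv"), "tsv")
  write_variants(res$variants, file.path(out_dir, "variants.vcf"), "vcf",
                 reference = res$reference)
  geno <- data.table(library = res$genotypes$libraries)
  g <- res$genotypes
  for (j in seq_along(g$variant_ids))
    geno[, (g$variant_ids[j]) := paste0(g$geno[, j], ":", g$ref_depth[, j],
                                        ":", g$alt_depth[, j])]
  fwrite(geno, file.path(out_dir, "genotypes.tsv"), sep = "\t")
  if (!is.null(res$pca)) {
    sc <- as.data.table(res$pca$scores, keep.rownames = "library")
    fwrite(sc, file.path(out_dir, "pca_scores.tsv"), sep = "\t")
  }
  fwrite(res$diversity$per_library, file.path(out_dir, "diversity.tsv"),
         sep = "\t")
  cfg <- config
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  cfg <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
  yaml::write_yaml(res$summary, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline_result:\n")
  for (k in names(s)) cat(sprintf("  %-22s %s\n", k,
                                  format(s[[k]], digits = 4)))
  invisible(x)
}
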