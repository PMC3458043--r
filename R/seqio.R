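# Sequence/quality I/O and the shared data model.
#
# Conventions used throughout the package:
#   * coordinates are 0-based, half-open; VCF export converts to 1-based
#   * reads are data.tables with columns id, library, bases, quals
#     (quals is a list column of integer phred scores, one per base)
#   * "N" is permitted in references but never counts as a match or allele

#' Construct a reference set of unigene consensus sequences
#'
#' A reference set is the mapping scaffold ("gene space"): a named collection
#' of uppercase DNA sequences over \{A,C,G,T,N\}. Names must be unique and
#' sequences non-empty.
#'
#' @param sequences Named character vector of DNA sequences.
#' @return A `reference_set` object (named character vector with a class
#'   attribute); `total_length()` gives the summed length.
#' @export
reference_set <- function(sequences) {
  if (!is.character(sequences)) stop("sequences must be a character vector")
  nm <- names(sequences)
  if (length(sequences) > 0 &&
      (is.null(nm) || anyNA(nm) || any(nm == "")))
    stop("every reference record needs a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate reference names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L))
    stop("empty reference sequence: ", nm[which(nchar(sequences) == 0L)[1]])
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("reference sequence with characters outside {A,C,G,T,N}: ",
         nm[which(bad)[1]])
  structure(sequences, class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x), "records,",
      total_length(x), "bases total\n")
  invisible(x)
}

#' Total length of a reference set
#' @param reference A [reference_set()].
#' @return Total bases across records.
#' @export
total_length <- function(reference) sum(nchar(unclass(reference)))

#' Read a FASTA file as a reference set
#' @param path FASTA file.
#' @return A [reference_set()].
#' @export
read_fasta_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  reference_set(s)
}

#' Write named sequences to FASTA
#' @param sequences Named character vector (or `reference_set`).
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(sequences)), filepath = path)
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file of short reads
#'
#' Parses 4-line FASTQ records and decodes qualities to integer phred
#' scores. The quality encoding offset is explicit (33 default, 64
#' selectable) because first-generation Illumina data may carry either; the
#' reader never guesses. The library tag is supplied by the caller, not
#' taken from the file.
#'
#' @param path FASTQ file.
#' @param library Library tag to attach to every read.
#' @param offset Phred encoding offset, 33 or 64.
#' @return data.table with columns id, library, bases, quals (list column of
#'   integer vectors). Empty file gives an empty table.
#' @export
read_fastq <- function(path, library = "lib1", offset = 33) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines) - 1 & lines == "")]
  if (length(lines) == 0)
    return(data.table(id = character(), library = character(),
                      bases = character(), quals = list()))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: number of lines not a multiple of 4 in ", path)
  ii <- seq(1, length(lines), by = 4)
  hdr <- lines[ii]
  if (any(substr(hdr, 1, 1) != "@"))
    stop("malformed FASTQ: record header missing '@' near line ",
         ii[which(substr(hdr, 1, 1) != "@")[1]])
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  bases <- toupper(lines[ii + 1])
  qstr <- lines[ii + 3]
  mism <- nchar(bases) != nchar(qstr)
  if (any(mism))
    stop("FASTQ record with different sequence and quality lengths: ",
         ids[which(mism)[1]])
  offset <- as.integer(offset)
  quals <- lapply(qstr, function(q) utf8ToInt(q) - offset)
  if (any(vapply(quals, function(q) any(q < 0), logical(1))))
    stop("negative phred score decoded; wrong quality offset (", offset,
         ") for ", path, "?")
  data.table(id = ids, library = library, bases = bases, quals = quals)
}

#' Write short reads to FASTQ
#' @param reads Read table as produced by [read_fastq()].
#' @param path Output file.
#' @param offset Phred encoding offset.
#' @export
write_fastq <- function(reads, path, offset = 33) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + offset), character(1))
  out <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
  writeLines(out, path)
  invisible(path)
}

#' Read EST reads from FASTA with optional phred quality file
#'
#' ESTs are Sanger-style reads delivered as FASTA plus a parallel `.qual`
#' file of space-separated integer scores. Clone id and read direction
#' (5'/3') are parsed from the record id with a configurable pattern; ids
#' that do not match are flagged direction `"unknown"` (excluded from
#' sister-EST logic downstream but otherwise retained).
#'
#' @param seq_path FASTA file of EST sequences.
#' @param qual_path Optional `.qual` file aligned record-by-record with the
#'   FASTA; when absent every base receives `default_qual`.
#' @param default_qual Constant quality used when no quality file is given.
#' @param clone_pattern Regular expression with two capture groups: clone id
#'   and direction code.
#' @param dir_codes Named character vector mapping direction codes to
#'   `five_prime` / `three_prime`.
#' @return data.table with columns id, clone_id, direction, bases, quals
#'   (list), vector_mask (list of 2-column start/end matrices, 0-based
#'   half-open; empty by default).
#' @export
read_fasta_with_quals <- function(seq_path, qual_path = NULL,
                                  default_qual = 20,
                                  clone_pattern = "^(.*)\\.([fr])$",
                                  dir_codes = c(f = "five_prime",
                                                r = "three_prime")) {
  x <- Biostrings::readDNAStringSet(seq_path)
  ids <- sub("\\s.*$", "", names(x))
  bases <- toupper(as.character(x))
  names(bases) <- NULL
  if (!is.null(qual_path)) {
    qr <- .read_qual_file(qual_path)
    if (length(qr$ids) != length(ids))
      stop("quality file has ", length(qr$ids), " records, FASTA has ",
           length(ids))
    bad <- which(lengths(qr$quals) != nchar(bases))
    if (length(bad))
      stop("quality length mismatch for record ", ids[bad[1]])
    quals <- qr$quals
  } else {
    quals <- lapply(nchar(bases), function(n) rep.int(default_qual, n))
  }
  m <- regmatches(ids, regexec(clone_pattern, ids))
  clone_id <- vapply(m, function(g) if (length(g) >= 3) g[2] else NA_character_,
                     character(1))
  code <- vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_,
                 character(1))
  direction <- ifelse(is.na(code), "unknown",
                      unname(dir_codes[code]))
  direction[is.na(direction)] <- "unknown"
  data.table(id = ids, clone_id = clone_id, direction = direction,
             bases = bases, quals = quals,
             vector_mask = rep(list(matrix(integer(0), ncol = 2)),
                               length(ids)))
}

.read_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA-style quality file: ", path)
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", substring(lines[hdr], 2))
  body <- split(lines[!hdr], rec[!hdr])
  quals <- lapply(body, function(b)
    as.integer(unlist(strsplit(paste(b, collapse = " "), "\\s+"))))
  quals <- lapply(quals, function(q) q[!is.na(q)])
  list(ids = ids, quals = quals)
}

#' Write a variant table to TSV or minimal VCF 4.2
#'
#' TSV writes one row per variant with all fields, including paired
#' per-library depth columns. VCF writes a minimal VCF 4.2 with per-library
#' allele depths (`AD`) in the sample columns; indels are left-normalised
#' and written with one anchor base, converting the internal 0-based
#' positions to 1-based VCF coordinates.
#'
#' @param variants A `variant_table` from [call_variants_two_stage()].
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param reference Optional [reference_set()]; when given, `##contig` lines
#'   are emitted.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf"),
                           reference = NULL) {
  format <- match.arg(format)
  libs <- attr(variants, "libraries")
  if (is.null(libs)) {
    libs <- sub("\\.ref_depth$", "",
                grep("\\.ref_depth$", names(variants), value = TRUE))
  }
  if (format == "tsv") {
    fwrite(as.data.table(variants), path, sep = "\t")
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rrsnp")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), nchar(unclass(reference))))
  }
  hdr <- c(hdr,
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=STAGE,Number=1,Type=String,Description=\"Calling stage\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", libs), collapse = "\t"))
  if (nrow(variants) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  v <- as.data.table(variants)
  pos1 <- integer(nrow(v))
  refa <- alta <- character(nrow(v))
  for (k in seq_len(nrow(v))) {
    ty <- v$variant_type[k]
    if (ty == "snp") {
      pos1[k] <- v$position[k] + 1L
      refa[k] <- v$ref_allele[k]
      alta[k] <- v$alt_allele[k]
    } else if (ty == "ins") {
      # insertion before `position`; anchor base is at position-1 (0-based),
      # i.e. 1-based POS equal to the internal 0-based event position
      pos1[k] <- v$position[k]
      refa[k] <- v$anchor_base[k]
      alta[k] <- paste0(v$anchor_base[k], v$alt_allele[k])
    } else {
      pos1[k] <- v$position[k]
      refa[k] <- paste0(v$anchor_base[k], v$ref_allele[k])
      alta[k] <- v$anchor_base[k]
    }
  }
  ad <- sapply(libs, function(l)
    paste0(v[[paste0(l, ".ref_depth")]], ",", v[[paste0(l, ".alt_depth")]]))
  ad <- matrix(ad, nrow = nrow(v))
  rows <- paste(v$ref_name, pos1, ".", refa, alta, ".", "PASS",
                paste0("TYPE=", v$variant_type, ";STAGE=", v$call_stage),
                "AD", apply(ad, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Validate a file against the VCF 4.2 column grammar
#'
#' Checks the meta-header, the `#CHROM` header line (8 fixed fields plus
#' FORMAT and sample columns), and every data row (column counts, integer
#' POS, REF/ALT alphabet, sample fields matching FORMAT arity).
#'
#' @param path VCF file.
#' @return Character vector of problems; `character(0)` when the file is
#'   grammatically valid.
#' @export
validate_vcf <- function(path) {
  lines <- readLines(path)
  probs <- character(0)
  if (length(lines) == 0 || !grepl("^##fileformat=VCFv4", lines[1]))
    probs <- c(probs, "missing ##fileformat=VCFv4.x first line")
  meta <- grepl("^##", lines)
  hdr_i <- which(grepl("^#CHROM\t", lines))
  if (length(hdr_i) != 1) {
    return(c(probs, "missing or duplicated #CHROM header line"))
  }
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  fixed8 <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(hdr) < 8 || !identical(hdr[1:8], fixed8))
    probs <- c(probs, "header does not start with the 8 fixed VCF columns")
  if (length(hdr) > 8 && hdr[9] != "FORMAT")
    probs <- c(probs, "9th header column must be FORMAT when samples present")
  ncol_exp <- length(hdr)
  data <- lines[seq_along(lines) > hdr_i]
  data <- data[data != ""]
  for (k in seq_along(data)) {
    f <- strsplit(data[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol_exp) {
      probs <- c(probs, sprintf("row %d: %d columns, expected %d",
                                k, length(f), ncol_exp))
      next
    }
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        as.integer(f[2]) < 1)
      probs <- c(probs, sprintf("row %d: POS not a positive integer", k))
    if (!grepl("^[ACGTN]+$", f[4]))
      probs <- c(probs, sprintf("row %d: bad REF '%s'", k, f[4]))
    if (!grepl("^([ACGTN]+|\\.)(,[ACGTN]+)*$", f[5]))
      probs <- c(probs, sprintf("row %d: bad ALT '%s'", k, f[5]))
    if (!(f[6] == "." || !is.na(suppressWarnings(as.numeric(f[6])))))
      probs <- c(probs, sprintf("row %d: bad QUAL '%s'", k, f[6]))
    if (ncol_exp > 9) {
      nfmt <- length(strsplit(f[9], ":", fixed = TRUE)[[1]])
      for (s in 10:ncol_exp) {
        nfs <- length(strsplit(f[s], ":", fixed = TRUE)[[1]])
        if (nfs > nfmt)
          probs <- c(probs,
                     sprintf("row %d: sample %d has more fields than FORMAT",
                             k, s - 9))
      }
    }
  }
  probs
}
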