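# Interchange formats: count tables, call tables, minimal per-sample VCF.

#' Write a position-count table as TSV
#'
#' One line per sample per position: `sample chrom pos ref_base A C G T
#' [ins:<seq>:<count> ...] [del:<len>:<count> ...] depth`. Indel tokens are
#' optional and variable in number, so the file is read back with
#' [read_counts_tsv()] rather than a rectangular reader.
#'
#' @param counts a `position_counts` object
#' @param path output file
#' @export
write_counts_tsv <- function(counts, path) {
  bases <- counts$bases
  indels <- counts$indels
  ikey <- if (nrow(indels)) {
    tok <- ifelse(indels$kind == "INS",
                  sprintf("ins:%s:%d", indels$allele, indels$count),
                  sprintf("del:%s:%d", indels$allele, indels$count))
    tapply(tok, paste(indels$sample, indels$chrom, indels$pos),
           paste, collapse = "\t")
  } else character(0)
  rowkey <- paste(bases$sample, bases$chrom, bases$pos)
  extra <- ikey[rowkey]
  extra[is.na(extra)] <- NA_character_
  fixed <- sprintf("%s\t%s\t%d\t%s\t%d\t%d\t%d\t%d", bases$sample,
                   bases$chrom, bases$pos, bases$ref, bases$A, bases$C,
                   bases$G, bases$T)
  lines <- ifelse(is.na(extra),
                  sprintf("%s\t%d", fixed, bases$depth),
                  sprintf("%s\t%s\t%d", fixed, extra, bases$depth))
  writeLines(c(paste("sample", "chrom", "pos", "ref_base", "A", "C", "G",
                     "T", "indels...", "depth", sep = "\t"), lines), path)
  invisible(path)
}

#' Read a position-count TSV written by [write_counts_tsv()]
#'
#' @param path input file
#' @param samples optional sample ordering; defaults to order of first
#'   appearance
#' @return a `position_counts` object
#' @export
read_counts_tsv <- function(path, samples = NULL) {
  lines <- readLines(path)
  lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  assert_that(all(nf >= 9), "malformed counts TSV")
  fixed <- t(vapply(parts, function(p) p[1:8], character(8)))
  depth <- as.integer(vapply(parts, function(p) p[length(p)], character(1)))
  bases <- data.table::data.table(
    sample = fixed[, 1], chrom = fixed[, 2], pos = as.integer(fixed[, 3]),
    ref = fixed[, 4], A = as.integer(fixed[, 5]), C = as.integer(fixed[, 6]),
    G = as.integer(fixed[, 7]), T = as.integer(fixed[, 8]), depth = depth)
  irows <- list()
  withidx <- which(nf > 9)
  for (i in withidx) {
    p <- parts[[i]]
    toks <- p[9:(length(p) - 1)]
    f <- strsplit(toks, ":", fixed = TRUE)
    irows[[length(irows) + 1L]] <- data.table::data.table(
      sample = p[1], chrom = p[2], pos = as.integer(p[3]),
      kind = ifelse(vapply(f, `[`, character(1), 1) == "ins", "INS", "DEL"),
      allele = vapply(f, `[`, character(1), 2),
      count = as.integer(vapply(f, `[`, character(1), 3)))
  }
  indels <- if (length(irows)) data.table::rbindlist(irows) else
    data.table::data.table(sample = character(0), chrom = character(0),
                           pos = integer(0), kind = character(0),
                           allele = character(0), count = integer(0))
  if (is.null(samples)) samples <- unique(bases$sample)
  structure(list(bases = bases, indels = indels, samples = samples),
            class = "position_counts")
}

#' Write / read the cohort-wide call table
#'
#' TSV with columns sample, chrom, pos, ref, alt, type, af, depth, score,
#' comparison_sample.
#' @param calls call data.table from [call_unique_mutations()]
#' @param path file path
#' @rdname calls_io
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname calls_io
#' @export
read_calls_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("sample", "chrom", "ref", "alt", "type",
                  "comparison_sample")))
  dt
}

#' Write minimal per-sample VCF v4.2 files
#'
#' One file `<sample>.vcf` per sample with the essential fixed columns; the
#' quality column carries the caller's `-log10` Fisher score and INFO holds
#' type, allele fraction and depth.
#'
#' @param calls call table from [call_unique_mutations()]
#' @param reference [Biostrings::DNAStringSet] used for the contig headers
#' @param dir output directory
#' @return paths of the written files (invisibly)
#' @export
write_vcf <- function(calls, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- Biostrings::width(reference)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(reference), lens),
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNV, INS or DEL\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth of the mutated sample\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  paths <- character(0)
  for (s in unique(calls$sample)) {
    sc <- calls[calls$sample == s, ]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tTYPE=%s;AF=%.4f;DP=%d",
                    sc$chrom, sc$pos, sc$ref, sc$alt, sc$score, sc$type,
                    sc$af, sc$depth)
    p <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(hdr, body), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path VCF file
#' @return data.table with sample-independent call columns
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  score = numeric(0), type = character(0),
                                  af = numeric(0), depth = integer(0)))
  }
  p <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(p, `[`, character(1), 8)
  getf <- function(tag) sub(sprintf(".*%s=([^;]+).*", tag), "\\1", info)
  data.table::data.table(
    chrom = vapply(p, `[`, character(1), 1),
    pos = as.integer(vapply(p, `[`, character(1), 2)),
    ref = vapply(p, `[`, character(1), 4),
    alt = vapply(p, `[`, character(1), 5),
    score = as.numeric(vapply(p, `[`, character(1), 6)),
    type = getf("TYPE"), af = as.numeric(getf("AF")),
    depth = as.integer(getf("DP")))
}
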