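#' Read a RepeatMasker .out annotation
#'
#' Parses the standard whitespace-delimited RepeatMasker `.out` layout
#' (three header lines, then one row per hit) into a repeat-hit table.
#' Genomic coordinates are converted from RepeatMasker's 1-based inclusive
#' convention to 0-based half-open. Rows in 'C' orientation become strand
#' `-` and their consensus coordinates (reported as `(left) end begin`) are
#' reordered so that `cons_begin <= cons_end`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A `data.frame` with one row per hit, in file order: `contig`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `family`,
#'   `cons_begin`, `cons_end` (1-based inclusive on the family consensus),
#'   `divergence_pct`, `linkage_id` (RepeatMasker block ID, `NA` if absent).
#' @examples
#' out <- tempfile(fileext = ".out")
#' writeLines(c("   SW  perc perc perc  query", "score  div. del. ins. sequence",
#'   "",
#'   "  239 10.5  0.0  0.0 chr1    101    200 (800) +  mdg4  LTR/Gypsy  1  100  (50) 1"),
#'   out)
#' read_repeatmasker_out(out)
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) >= 3L, "RepeatMasker .out '%s': fewer than 3 header lines", path)
  body <- lines[-(1:3)]
  keep <- which(nzchar(trimws(body)))
  if (length(keep) == 0L) return(.empty_hits())
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1L]]
    lineno <- i + 3L
    if (length(f) < 14L)
      .stopf("RepeatMasker .out line %d: expected >= 14 columns, got %d", lineno, length(f))
    begin <- suppressWarnings(as.integer(f[6L]))
    end <- suppressWarnings(as.integer(f[7L]))
    div <- suppressWarnings(as.numeric(f[2L]))
    if (anyNA(c(begin, end, div)))
      .stopf("RepeatMasker .out line %d: non-numeric coordinate or divergence", lineno)
    if (end < begin)
      .stopf("RepeatMasker .out line %d: end (%d) < begin (%d)", lineno, end, begin)
    orient <- f[9L]
    if (!orient %in% c("+", "C"))
      .stopf("RepeatMasker .out line %d: orientation '%s' is not '+' or 'C'", lineno, orient)
    strip <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
    if (orient == "+") {
      cb <- strip(f[12L]); ce <- strip(f[13L])
    } else {
      # C rows report (left) end begin
      ce <- strip(f[13L]); cb <- strip(f[14L])
    }
    if (anyNA(c(cb, ce)))
      .stopf("RepeatMasker .out line %d: non-numeric consensus coordinates", lineno)
    if (cb > ce)
      .stopf("RepeatMasker .out line %d: cons_begin (%d) > cons_end (%d)", lineno, cb, ce)
    data.frame(contig = f[5L], start = begin - 1L, end = end,
               strand = if (orient == "+") "+" else "-",
               family = f[10L],
               cons_begin = cb, cons_end = ce,
               divergence_pct = div,
               linkage_id = if (length(f) >= 15L) suppressWarnings(as.integer(f[15L])) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.empty_hits <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), family = character(),
             cons_begin = integer(), cons_end = integer(),
             divergence_pct = numeric(), linkage_id = integer(),
             stringsAsFactors = FALSE)
}

#' Write / read repeat hits as an extended BED dialect
#'
#' BED6+3: `chrom start end name score strand cons_begin cons_end linkage_id`
#' with the repeat family as `name` and percent divergence as `score`.
#' `read_repeat_bed(write_repeat_bed(x))` reproduces `x` field for field.
#'
#' @param hits A repeat-hit `data.frame` as from [read_repeatmasker_out()].
#' @param path Output (input) path.
#' @return `write_repeat_bed`: `path`, invisibly. `read_repeat_bed`: the
#'   repeat-hit `data.frame`.
#' @export
write_repeat_bed <- function(hits, path) {
  df <- data.frame(hits$contig, hits$start, hits$end, hits$family,
                   hits$divergence_pct, hits$strand,
                   hits$cons_begin, hits$cons_end,
                   ifelse(is.na(hits$linkage_id), ".", as.character(hits$linkage_id)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_repeat_bed
#' @export
read_repeat_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = c("character", "integer", "integer", "character",
                                  "numeric", "character", "integer", "integer",
                                  "character"))
  .assert(all(df[[2L]] >= 0 & df[[2L]] < df[[3L]]),
          "repeat BED '%s': requires 0 <= start < end", path)
  data.frame(contig = df[[1L]], start = df[[2L]], end = df[[3L]],
             strand = .check_strand(df[[6L]]), family = df[[4L]],
             cons_begin = df[[7L]], cons_end = df[[8L]],
             divergence_pct = df[[5L]],
             linkage_id = suppressWarnings(as.integer(ifelse(df[[9L]] == ".", NA, df[[9L]]))),
             stringsAsFactors = FALSE)
}

#' Read small-RNA alignments (SAM subset or tabular dialect)
#'
#' Ingests either a SAM file (header optional; FLAG for strand and the
#' unmapped bit, POS/CIGAR for the reference span, optional `NH:i:` tag for
#' the per-read number of placements) or the package's 7-column tabular
#' dialect: `read_id  contig  five_prime_pos  strand  length  sequence
#' n_hits`, tab-separated with `#` comments. Only reads whose length lies in
#' `[min_len, max_len]` are retained (default 23-29 nt, the retention window
#' used for piRNA libraries; piRNAs are often described as ~24-32 nt, so
#' both bounds are caller-settable).
#'
#' The 5' end is the leftmost aligned base for `+` reads and the rightmost
#' for `-` reads, reported 0-based. `first_nt`/`tenth_nt` are taken from the
#' read sequence in read orientation (SAM stores minus-strand reads
#' reverse-complemented; they are flipped back). When no NH-style count is
#' present, `n_hits` is the number of records sharing the read id, else 1.
#'
#' @param path Input path.
#' @param min_len,max_len Inclusive read-length window in nt.
#' @return A `data.frame`: `read_id`, `contig`, `five_prime_pos`, `strand`,
#'   `length`, `first_nt`, `tenth_nt`, `n_hits`, `seq`. Unmapped SAM records
#'   are skipped; their count is available as `attr(, "n_unmapped")`.
#' @export
read_small_rna <- function(path, min_len = 23L, max_len = 29L) {
  .assert(min_len <= max_len, "min_len must be <= max_len")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  probe <- lines[!startsWith(lines, "@") & !startsWith(lines, "#")]
  is_sam <- length(probe) > 0L && {
    f <- strsplit(probe[[1L]], "\t", fixed = TRUE)[[1L]]
    length(f) >= 11L && !is.na(suppressWarnings(as.integer(f[2L])))
  }
  rec <- if (is_sam) .parse_sam(lines) else .parse_tab(lines)
  n_un <- attr(rec, "n_unmapped") %||% 0L
  keep <- rec$length >= min_len & rec$length <= max_len
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_un
  out
}

.srna_df <- function(read_id, contig, five_prime_pos, strand, length, seq, n_hits) {
  data.frame(read_id = read_id, contig = contig,
             five_prime_pos = as.integer(five_prime_pos),
             strand = .check_strand(strand),
             length = as.integer(length),
             first_nt = substr(seq, 1L, 1L),
             tenth_nt = ifelse(nchar(seq) >= 10L, substr(seq, 10L, 10L), NA_character_),
             n_hits = as.integer(n_hits), seq = seq,
             stringsAsFactors = FALSE)
}

.parse_tab <- function(lines) {
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L)
    return(.srna_df(character(), character(), integer(), character(),
                    integer(), character(), integer()))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 7L)
  if (length(bad))
    .stopf("tabular small-RNA record %d: expected 7 tab-separated fields", bad[1L])
  m <- do.call(rbind, f)
  pos <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(pos) || any(pos < 0L))
    .stopf("tabular small-RNA record %d: negative or non-numeric coordinate",
           which(is.na(pos) | pos < 0L)[1L])
  .srna_df(m[, 1L], m[, 2L], pos, m[, 4L],
           suppressWarnings(as.integer(m[, 5L])), toupper(m[, 6L]),
           suppressWarnings(as.integer(m[, 7L])))
}

.parse_sam <- function(lines) {
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad))
    .stopf("SAM record %d: fewer than 11 fields", bad[1L])
  flag <- vapply(f, function(x) as.integer(x[2L]), integer(1L))
  unmapped <- bitwAnd(flag, 4L) > 0L
  n_un <- sum(unmapped)
  if (n_un > 0L) message(sprintf("read_small_rna: skipped %d unmapped record(s)", n_un))
  f <- f[!unmapped]
  flag <- flag[!unmapped]
  if (length(f) == 0L) {
    out <- .srna_df(character(), character(), integer(), character(),
                    integer(), character(), integer())
    attr(out, "n_unmapped") <- n_un
    return(out)
  }
  pos1 <- vapply(f, function(x) suppressWarnings(as.integer(x[4L])), integer(1L))
  if (anyNA(pos1) || any(pos1 < 1L))
    .stopf("SAM record: negative or non-numeric POS")
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  cigar <- vapply(f, `[[`, character(1L), 6L)
  refspan <- vapply(cigar, .cigar_refspan, integer(1L), USE.NAMES = FALSE)
  seq_aln <- toupper(vapply(f, `[[`, character(1L), 10L))
  qname <- vapply(f, `[[`, character(1L), 1L)
  nh <- vapply(f, function(x) {
    tag <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1L])) else NA_integer_
  }, integer(1L))
  if (anyNA(nh)) {
    cnt <- table(qname)
    nh[is.na(nh)] <- as.integer(cnt[qname[is.na(nh)]])
  }
  seq_read <- ifelse(strand == "-", .revcomp(seq_aln), seq_aln)
  five <- ifelse(strand == "+", pos1 - 1L, pos1 - 1L + refspan - 1L)
  .structure_unmapped(
    .srna_df(qname, vapply(f, `[[`, character(1L), 3L), five, strand,
             nchar(seq_aln), seq_read, nh),
    n_un)
}

.structure_unmapped <- function(df, n) { attr(df, "n_unmapped") <- n; df }

# Reference-consuming span of a CIGAR string (M, D, N, =, X).
.cigar_refspan <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  .assert(ops[1L] != -1L, "malformed CIGAR '%s'", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

# Fraction of SAM read ends (per record, both ends) that are soft-clipped.
.cigar_softclip_ends <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  op <- sub("^\\d+", "", toks)
  c(head = op[1L] == "S", tail = op[length(op)] == "S")
}

#' Write small-RNA records in the tabular dialect
#'
#' @param records Small-RNA `data.frame` as from [read_small_rna()].
#' @param path Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_small_rna_tab <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(records$read_id, records$contig, records$five_prime_pos,
                   records$strand, records$length, records$seq, records$n_hits)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write genome sequences as FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors
#' (one element per contig, names unique).
#'
#' @param path FASTA path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta`: named character vector. `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  .assert(!anyDuplicated(names(ss)), "FASTA '%s': duplicate contig ids", path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a TE family metadata table
#'
#' Tab-separated with header: `name  te_class  consensus_len  ltr_len`.
#' `ltr_len` is 0 for non-LTR classes.
#'
#' @param path Input path.
#' @return A `data.frame` with those columns.
#' @export
read_family_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  .assert(all(c("name", "te_class", "consensus_len", "ltr_len") %in% names(df)),
          "family table '%s': missing required columns", path)
  validate_family_table(df)
}

#' @rdname read_family_table
#' @param families A family `data.frame` to validate.
#' @export
validate_family_table <- function(families) {
  .assert(all(families$consensus_len >= 1L), "consensus_len must be >= 1")
  is_ltr <- families$te_class == "LTR"
  .assert(all(families$ltr_len[!is_ltr] == 0L), "ltr_len must be 0 for non-LTR classes")
  .assert(all(families$ltr_len[is_ltr] > 0L &
                families$ltr_len[is_ltr] < families$consensus_len[is_ltr] / 2),
          "LTR families require 0 < ltr_len < consensus_len/2")
  families
}

#' Read a sectioned key/value configuration file (YAML)
#'
#' Each top-level section corresponds to one parameter group (e.g.
#' `cluster`, `merge`, `pingpong`, `simulate`); keys override the package
#' defaults when passed to the corresponding functions.
#'
#' @param path YAML path.
#' @return Named list of sections.
#' @export
read_config <- function(path) yaml::read_yaml(path)
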