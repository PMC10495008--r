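# Shared internal helpers. Coordinates: genomic intervals are 0-based
# half-open; consensus intervals are 1-based inclusive.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(ok, ...) if (!ok) .stopf(...)

# Total length covered by the union of 1-based inclusive intervals.
.union_len <- function(begin, end) {
  if (length(begin) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = begin, end = end))))
}

# Length of the union of 1-based intervals restricted to [lo, hi].
.union_len_within <- function(begin, end, lo, hi) {
  if (hi < lo || length(begin) == 0L) return(0L)
  ir <- IRanges::restrict(IRanges::IRanges(start = begin, end = end),
                          start = lo, end = hi)
  sum(IRanges::width(IRanges::reduce(ir)))
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.check_strand <- function(strand) {
  .assert(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  strand
}

# Random DNA string(s) of the given lengths (one draw, then split).
.random_dna <- function(n_len) {
  if (length(n_len) == 0L) return(character())
  s <- paste(sample(c("A", "C", "G", "T"), sum(n_len), replace = TRUE),
             collapse = "")
  ends <- cumsum(n_len)
  substring(s, ends - n_len + 1L, ends)
}

# Mutate a sequence by iid substitutions at `rate`; returns list(seq, n_sub).
.mutate_seq <- function(seq, rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(alt, b), 1L)
    }, character(1L))
  }
  list(seq = paste(bases, collapse = ""), n_sub = sum(hit))
}

# Strip LTR/internal suffixes so FAMILY_LTR / FAMILY_I resolve to FAMILY.
# Extra user mappings (named character vector raw -> family) take precedence.
.map_family <- function(name, extra = NULL) {
  out <- name
  if (!is.null(extra)) {
    hit <- match(out, names(extra))
    out[!is.na(hit)] <- extra[hit[!is.na(hit)]]
  }
  sub("([_-](LTR|ltr|I|int|INT))$", "", out)
}

# Which part of the consensus a raw RepeatMasker name annotates.
.family_part <- function(name) {
  ifelse(grepl("[_-](LTR|ltr)$", name), "ltr",
         ifelse(grepl("[_-](I|int|INT)$", name), "internal", "whole"))
}
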