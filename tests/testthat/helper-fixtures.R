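# Shared fixtures and independent oracles.

# Build a small-RNA record table directly (mirrors the reader's layout).
make_records <- function(pos, strand, len = 26L, first = "T", tenth = "A",
                         n_hits = 1L, seq = NULL, contig = "chr") {
  n <- length(pos)
  strand <- rep_len(strand, n)
  len <- rep_len(as.integer(len), n)
  if (is.null(seq)) {
    seq <- vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                 collapse = "")
      substr(s, 1L, 1L) <- rep_len(first, n)[i]
      substr(s, 10L, 10L) <- rep_len(tenth, n)[i]
      s
    }, character(1L))
  }
  data.frame(read_id = sprintf("t%05d", seq_len(n)), contig = contig,
             five_prime_pos = as.integer(pos), strand = strand, length = len,
             first_nt = substr(seq, 1L, 1L), tenth_nt = substr(seq, 10L, 10L),
             n_hits = rep_len(as.integer(n_hits), n), seq = seq,
             stringsAsFactors = FALSE)
}

# Write a minimal RepeatMasker .out file from row strings.
write_rm_out <- function(rows, path = tempfile(fileext = ".out")) {
  writeLines(c("   SW   perc perc perc  query     position in query",
               "score   div. del. ins.  sequence  begin end (left)",
               ""), path)
  cat(rows, file = path, sep = "\n", append = TRUE)
  path
}

rm_row <- function(contig, begin, end, orient, family, c1, c2, c3,
                   div = 5.0, id = 1L) {
  sprintf("  239 %.1f 0.0 0.0 %s %d %d (0) %s %s Unknown %s %s %s %d",
          div, contig, begin, end, orient, family, c1, c2, c3, id)
}

# Minimal SAM writer: list of lists with qname, flag, rname, pos (1-based),
# cigar, seq, nh (optional).
write_sam <- function(recs, path = tempfile(fileext = ".sam"),
                      header = "@HD\tVN:1.6") {
  lines <- c(header, vapply(recs, function(r) {
    base <- paste(r$qname, r$flag, r$rname, r$pos, 255, r$cigar, "*", 0, 0,
                  r$seq, "*", sep = "\t")
    if (!is.null(r$nh)) base <- paste0(base, "\tNH:i:", r$nh)
    base
  }, character(1L)))
  writeLines(lines, path)
  path
}

# Independent brute-force oracle for annotation alignment: enumerates every
# monotone pairing (ordered subsets of a and b of equal size, paired in
# order) and returns the maximum total score.
bf_align_score <- function(a, b, params = align_params()) {
  n <- nrow(a); m <- nrow(b)
  gp <- params$gap_penalty
  if (n == 0L || m == 0L) return(-(n + m) * gp)
  fa <- a$family; fb <- b$family
  if (!is.null(params$family_equivalence)) {
    fe <- params$family_equivalence
    fa <- ifelse(fa %in% names(fe), fe[fa], fa)
    fb <- ifelse(fb %in% names(fe), fe[fb], fb)
  }
  ok <- outer(fa, fb, "==")
  if (params$require_same_strand) ok <- ok & outer(a$strand, b$strand, "==")
  S <- ifelse(ok, params$match_score, -params$mismatch_penalty)
  best <- -(n + m) * gp
  for (k in seq_len(min(n, m))) {
    A <- utils::combn(n, k)
    B <- utils::combn(m, k)
    tot <- matrix(0, ncol(A), ncol(B))
    for (i in seq_len(k))
      tot <- tot + matrix(S[A[i, ], B[i, ]], ncol(A), ncol(B))
    best <- max(best, max(tot) - gp * (n + m - 2L * k))
  }
  best
}

# Random annotation token lists for the DP property tests.
random_tokens <- function(n, n_families = 4L) {
  data.frame(family = sample(LETTERS[seq_len(n_families)], n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             start = seq_len(n) * 10L,
             category = rep("fragment", n),
             stringsAsFactors = FALSE)
}

# Small family table for classification tests.
toy_families <- function() {
  data.frame(name = c("LINE1", "GYP1"),
             te_class = c("LINE", "LTR"),
             consensus_len = c(1000L, 1000L),
             ltr_len = c(0L, 100L),
             stringsAsFactors = FALSE)
}

# One repeat hit row in the internal layout.
hit_row <- function(contig = "chr", start, end, strand = "+", family,
                    cons_begin, cons_end, div = 5, linkage_id = NA_integer_) {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, family = family,
             cons_begin = as.integer(cons_begin), cons_end = as.integer(cons_end),
             divergence_pct = div, linkage_id = linkage_id,
             stringsAsFactors = FALSE)
}
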