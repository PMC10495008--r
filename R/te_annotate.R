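#' Parameters for fragment merging and full-length classification
#'
#' @param max_gap Maximum genomic distance (nt) between two fragments of one
#'   TE copy. Default 5000.
#' @param max_overlap_cons Tolerated overlap (nt) between the consensus
#'   intervals of consecutive fragments. Default 30.
#' @param full_len_threshold Minimum fraction of the family consensus that a
#'   copy must cover to be called full length. Default 0.70, the standard
#'   "at least 70% of reference length" rule; the boundary is inclusive.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(max_gap = 5000L, max_overlap_cons = 30L,
                         full_len_threshold = 0.70) {
  .assert(max_gap >= 0 && max_overlap_cons >= 0, "gap/overlap must be non-negative")
  .assert(full_len_threshold > 0 && full_len_threshold <= 1,
          "full_len_threshold must be in (0, 1]")
  structure(list(max_gap = as.integer(max_gap),
                 max_overlap_cons = as.integer(max_overlap_cons),
                 full_len_threshold = full_len_threshold),
            class = "merge_params")
}

#' Merge RepeatMasker fragments into TE copies
#'
#' Chains repeat hits into copies when they lie on the same contig, resolve
#' to the same family, share a strand, are separated by at most
#' `params$max_gap` nt of genome, and advance consistently along the family
#' consensus (non-decreasing consensus intervals for `+` copies,
#' non-increasing for `-`, tolerating `params$max_overlap_cons` nt of
#' overlap). LTR/internal annotation pairs named `FAMILY_LTR` / `FAMILY_I`
#' (also `-LTR`, `_int`) are resolved to one family first; internal-segment
#' consensus coordinates are shifted past the 5' LTR, and LTR-segment hits
#' are assigned to the 5' or 3' LTR according to whether internal sequence
#' precedes them in element orientation.
#'
#' Every input hit is placed in exactly one copy. Copy completeness is the
#' covered fraction of the consensus (union of fragment consensus
#' intervals); mean divergence is the fragment-length-weighted mean. The
#' returned copies are classified via [classify_copies()].
#'
#' @param hits Repeat-hit `data.frame` ([read_repeatmasker_out()]), sorted
#'   by (contig, start).
#' @param families Family table ([read_family_table()]); every family
#'   occurring in `hits` (after LTR/internal mapping) must be present.
#' @param params A [merge_params()] list.
#' @param name_map Optional named character vector of extra raw-name to
#'   family mappings, applied before suffix stripping.
#' @return A `data.frame` of TE copies: `copy_id`, `family`, `contig`,
#'   `start`, `end`, `strand`, `n_fragments`, `completeness`,
#'   `mean_divergence_pct`, `has_5ltr`, `has_3ltr`, `has_internal`,
#'   `category`, plus a `fragments` list-column holding each copy's member
#'   hits with mapped family names and remapped consensus coordinates.
#' @export
merge_fragments <- function(hits, families, params = merge_params(),
                            name_map = NULL) {
  families <- validate_family_table(families)
  if (nrow(hits) == 0L) return(.empty_copies())
  ord <- order(hits$contig, hits$start)
  .assert(identical(ord, seq_len(nrow(hits))) ||
            !is.unsorted(order(hits$contig, hits$start)),
          "hits must be sorted by (contig, start)")
  hits <- hits[ord, , drop = FALSE]

  fam <- .map_family(hits$family, name_map)
  part <- .family_part(hits$family)
  unknown <- setdiff(unique(fam), families$name)
  if (length(unknown))
    .stopf("families absent from library: %s", paste(unknown, collapse = ", "))
  fi <- match(fam, families$name)
  cons_len <- families$consensus_len[fi]
  ltr_len <- families$ltr_len[fi]

  h <- hits
  h$family <- fam
  h$.part <- part
  h$.cons_len <- cons_len
  h$.ltr_len <- ltr_len

  key <- paste(h$contig, h$family, h$strand, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(h)), key), function(idx) {
    g <- h[idx, , drop = FALSE]
    g <- .remap_ltr_parts(g, params)
    .chain_group(g, params)
  })
  copies <- do.call(rbind, unlist(pieces, recursive = FALSE))
  copies <- copies[order(copies$contig, copies$start), , drop = FALSE]
  copies$copy_id <- seq_len(nrow(copies))
  rownames(copies) <- NULL
  classify_copies(copies, families, params)
}

# Shift consensus coordinates of _I/_LTR component hits onto the unified
# family consensus. Element orientation: genomic order for +, reversed for -.
# An LTR-component hit is the 3' LTR iff internal sequence of the same
# element (i.e. within max_gap, uninterrupted by whole-model hits) precedes
# it in element orientation; otherwise it is the 5' LTR.
.remap_ltr_parts <- function(g, params) {
  fwd <- g$strand[1L] == "+"
  ord <- if (fwd) order(g$start) else order(-g$start)
  g <- g[ord, , drop = FALSE]
  ltr <- g$.ltr_len[1L]
  clen <- g$.cons_len[1L]
  seen_internal <- FALSE
  for (i in seq_len(nrow(g))) {
    if (i > 1L) {
      gap <- if (fwd) g$start[i] - g$end[i - 1L] else g$start[i - 1L] - g$end[i]
      if (gap > params$max_gap) seen_internal <- FALSE
    }
    if (g$.part[i] == "internal") {
      g$cons_begin[i] <- g$cons_begin[i] + ltr
      g$cons_end[i] <- min(g$cons_end[i] + ltr, clen)
      seen_internal <- TRUE
    } else if (g$.part[i] == "ltr") {
      if (seen_internal) {
        off <- clen - ltr
        g$cons_begin[i] <- g$cons_begin[i] + off
        g$cons_end[i] <- min(g$cons_end[i] + off, clen)
      }
      seen_internal <- FALSE   # an LTR bounds the element either way
    } else {
      seen_internal <- FALSE   # whole-model hits are not element components
    }
  }
  g[order(g$start), , drop = FALSE]
}

# Greedy chaining of one (contig, family, strand) group, genomic order.
.chain_group <- function(g, params) {
  n <- nrow(g)
  copy_of <- integer(n)
  copy_of[1L] <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      prev <- i - 1L
      gap <- g$start[i] - g$end[prev]
      ok <- gap <= params$max_gap
      if (ok) {
        if (g$strand[i] == "+") {
          ok <- g$cons_begin[i] >= g$cons_end[prev] + 1L - params$max_overlap_cons
        } else {
          ok <- g$cons_end[i] <= g$cons_begin[prev] - 1L + params$max_overlap_cons
        }
      }
      copy_of[i] <- if (ok) copy_of[prev] else copy_of[prev] + 1L
    }
  }
  lapply(split(seq_len(n), copy_of), function(idx) {
    fr <- g[idx, , drop = FALSE]
    clen <- fr$.cons_len[1L]
    cb <- pmax(1L, pmin(fr$cons_begin, clen))
    ce <- pmax(1L, pmin(fr$cons_end, clen))
    w <- fr$end - fr$start
    frag_cols <- fr[, c("contig", "start", "end", "strand", "family",
                        "cons_begin", "cons_end", "divergence_pct", "linkage_id")]
    rownames(frag_cols) <- NULL
    data.frame(copy_id = NA_integer_,
               family = fr$family[1L], contig = fr$contig[1L],
               start = min(fr$start), end = max(fr$end),
               strand = fr$strand[1L], n_fragments = nrow(fr),
               completeness = .union_len(cb, ce) / clen,
               mean_divergence_pct = sum(fr$divergence_pct * w) / sum(w),
               has_5ltr = NA, has_3ltr = NA, has_internal = NA,
               category = NA_character_,
               fragments = I(list(frag_cols)),
               stringsAsFactors = FALSE)
  })
}

.empty_copies <- function() {
  data.frame(copy_id = integer(), family = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             n_fragments = integer(), completeness = numeric(),
             mean_divergence_pct = numeric(), has_5ltr = logical(),
             has_3ltr = logical(), has_internal = logical(),
             category = character(), fragments = I(list()),
             stringsAsFactors = FALSE)
}

#' Classify TE copies as full-length, solo-LTR or fragment
#'
#' Non-LTR families are full length iff completeness is at least
#' `params$full_len_threshold` (inclusive). LTR families additionally need
#' both LTRs and internal sequence: each of the 5' LTR region
#' `[1, ltr_len]`, the 3' LTR region `[consensus_len - ltr_len + 1,
#' consensus_len]` and the interior must be at least half covered by the
#' copy's consensus intervals. An LTR-family copy with LTR-region coverage
#' only (no interior coverage at all) is a solo LTR; everything else is a
#' fragment.
#'
#' @param copies Copy `data.frame` from [merge_fragments()].
#' @param families Family table.
#' @param params A [merge_params()] list.
#' @return `copies` with `has_5ltr`, `has_3ltr`, `has_internal` and
#'   `category` filled in.
#' @export
classify_copies <- function(copies, families, params = merge_params()) {
  if (nrow(copies) == 0L) return(copies)
  fi <- match(copies$family, families$name)
  .assert(!anyNA(fi), "copy families absent from library")
  thr <- params$full_len_threshold
  for (i in seq_len(nrow(copies))) {
    clen <- families$consensus_len[fi[i]]
    fr <- copies$fragments[[i]]
    cb <- pmax(1L, pmin(fr$cons_begin, clen))
    ce <- pmax(1L, pmin(fr$cons_end, clen))
    if (families$te_class[fi[i]] != "LTR") {
      copies$has_5ltr[i] <- copies$has_3ltr[i] <- copies$has_internal[i] <- NA
      copies$category[i] <-
        if (copies$completeness[i] >= thr) "full_length" else "fragment"
      next
    }
    ltr <- families$ltr_len[fi[i]]
    int_lo <- ltr + 1L
    int_hi <- clen - ltr
    cov5 <- .union_len_within(cb, ce, 1L, ltr)
    cov3 <- .union_len_within(cb, ce, clen - ltr + 1L, clen)
    covI <- .union_len_within(cb, ce, int_lo, int_hi)
    copies$has_5ltr[i] <- cov5 >= 0.5 * ltr
    copies$has_3ltr[i] <- cov3 >= 0.5 * ltr
    copies$has_internal[i] <- covI >= 0.5 * (int_hi - int_lo + 1L)
    copies$category[i] <- if (copies$completeness[i] >= thr &&
                              copies$has_5ltr[i] && copies$has_3ltr[i] &&
                              copies$has_internal[i]) {
      "full_length"
    } else if (covI == 0L && (cov5 > 0L || cov3 > 0L)) {
      "solo_LTR"
    } else {
      "fragment"
    }
  }
  copies
}

#' Locus composition relative to the cluster strand
#'
#' Summarizes a classified copy set the way piRNA-cluster composition is
#' reported: the percentage of copies antisense to the cluster's
#' transcription strand, the percentage of those antisense copies belonging
#' to LTR-class families (at canonical *flamenco* these run around 79% and
#' 85%), and a per-family copy-number table.
#'
#' @param copies Classified copy `data.frame`.
#' @param families Family table (for the class lookup).
#' @param cluster_strand Transcription strand of the cluster, `"+"` or
#'   `"-"`; a copy is antisense iff its strand differs.
#' @return A list: `n_copies`, `pct_antisense`, `pct_antisense_that_are_LTR`
#'   (`NA` when there are no antisense copies), and `per_family`, a
#'   `data.frame` with `family`, `te_class`, `n_copies`, `n_full_length`,
#'   `n_solo_ltr`, `n_fragment`, `n_antisense`.
#' @export
composition_stats <- function(copies, families, cluster_strand = "+") {
  .assert(nrow(copies) > 0L, "composition_stats: empty copy list")
  .check_strand(cluster_strand)
  fi <- match(copies$family, families$name)
  cls <- families$te_class[fi]
  anti <- copies$strand != cluster_strand
  pct_anti <- 100 * mean(anti)
  pct_anti_ltr <- if (any(anti)) 100 * mean(cls[anti] == "LTR") else NA_real_
  per_family <- do.call(rbind, lapply(split(seq_len(nrow(copies)), copies$family),
    function(idx) {
      data.frame(family = copies$family[idx[1L]],
                 te_class = cls[idx[1L]],
                 n_copies = length(idx),
                 n_full_length = sum(copies$category[idx] == "full_length"),
                 n_solo_ltr = sum(copies$category[idx] == "solo_LTR"),
                 n_fragment = sum(copies$category[idx] == "fragment"),
                 n_antisense = sum(anti[idx]),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_family) <- NULL
  list(n_copies = nrow(copies), pct_antisense = pct_anti,
       pct_antisense_that_are_LTR = pct_anti_ltr, per_family = per_family)
}

#' Per-window element counts along a contig
#'
#' Tiles `[0, contig_len)` with windows of `window` nt (the last window may
#' be short) and counts elements by their start coordinate — the convention
#' used for, e.g., Ty3/mdg4 enrichment profiles in 100-kb windows.
#'
#' @param x `data.frame` with `start` and `family` columns (repeat hits or
#'   TE copies), optionally `contig`.
#' @param contig_len Contig length, nt.
#' @param window Window size, nt (default 100000).
#' @param family_filter Optional character vector; only elements whose
#'   family is in the set are counted.
#' @param contig Optional contig id to subset `x`.
#' @return `data.frame` with `window_start`, `window_end`, `count`, covering
#'   every window including zeros.
#' @export
window_enrichment <- function(x, contig_len, window = 100000L,
                              family_filter = NULL, contig = NULL) {
  .assert(window >= 1L, "window must be >= 1")
  if (!is.null(contig) && nrow(x) > 0L && "contig" %in% names(x))
    x <- x[x$contig == contig, , drop = FALSE]
  if (!is.null(family_filter) && nrow(x) > 0L)
    x <- x[x$family %in% family_filter, , drop = FALSE]
  n_win <- ceiling(contig_len / window)
  counts <- integer(n_win)
  if (nrow(x) > 0L) {
    idx <- pmin(x$start %/% window, n_win - 1L) + 1L
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  ws <- (seq_len(n_win) - 1L) * window
  data.frame(window_start = ws,
             window_end = pmin(ws + window, contig_len),
             count = counts)
}

#' Transposon-trap diagnostics for a classified locus
#'
#' Reports the two family sets used to argue a locus acts as a transposon
#' trap: families with at least two full-length antisense copies, and
#' families with at least one full-length copy plus at least one antisense
#' fragment diverged by less than `max_div` percent from the consensus
#' (strict inequality; a fragment at exactly `max_div` does not count).
#'
#' @param copies Classified copy `data.frame`.
#' @param cluster_strand Cluster transcription strand.
#' @param max_div Divergence ceiling for trap fragments, percent
#'   (default 10).
#' @return A list of two sorted character vectors:
#'   `multicopy_antisense_families` and `trap_fragment_families`.
#' @export
trap_model_report <- function(copies, cluster_strand = "+", max_div = 10) {
  .check_strand(cluster_strand)
  if (nrow(copies) == 0L)
    return(list(multicopy_antisense_families = character(),
                trap_fragment_families = character()))
  anti <- copies$strand != cluster_strand
  fl <- copies$category == "full_length"
  set1 <- names(which(tapply(fl & anti, copies$family, sum) >= 2L))
  has_fl <- tapply(fl, copies$family, any)
  trap_frag <- copies$category == "fragment" & anti &
    copies$mean_divergence_pct < max_div
  has_frag <- tapply(trap_frag, copies$family, any)
  set2 <- names(which(has_fl & has_frag))
  list(multicopy_antisense_families = sort(unname(set1)),
       trap_fragment_families = sort(unname(set2)))
}
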