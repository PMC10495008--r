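# Multimapper-weighted small-RNA counting and ping-pong signature scoring.

# Per-record weights under a counting mode: weighted = 1/n_hits per
# placement (a read at 50 places contributes 1/50 each), unique = 1 for
# single-placement reads and 0 otherwise.
.count_weights <- function(records, mode = c("weighted", "unique")) {
  mode <- match.arg(mode)
  if (mode == "weighted") 1 / records$n_hits
  else as.numeric(records$n_hits == 1L)
}

#' Per-region, per-strand small-RNA counts
#'
#' Assigns each record to the region containing its 5' end. In `weighted`
#' mode each record contributes `1/n_hits` (so a read mapping to 50 places
#' counts 1/50 per placement); in `unique` mode multimappers contribute 0.
#' Records whose 5' end falls in no region are accumulated in an `*outside*`
#' row, so column sums conserve total read mass.
#'
#' @param records Small-RNA `data.frame` ([read_small_rna()]).
#' @param regions `data.frame` with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `name`; regions must not overlap.
#' @param mode `"weighted"` (default) or `"unique"`.
#' @return `data.frame` with `region`, `count_plus`, `count_minus`, `count`.
#' @export
feature_counts <- function(records, regions, mode = c("weighted", "unique")) {
  mode <- match.arg(mode)
  .assert(all(regions$start < regions$end), "regions require start < end")
  for (ctg in unique(regions$contig)) {
    r <- regions[regions$contig == ctg, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      .stopf("feature_counts: overlapping regions on contig '%s'", ctg)
  }
  nm <- if ("name" %in% names(regions)) regions$name
        else sprintf("%s:%d-%d", regions$contig, regions$start, regions$end)
  w <- .count_weights(records, mode)
  assign_to <- rep("*outside*", nrow(records))
  for (j in seq_len(nrow(regions))) {
    inside <- records$contig == regions$contig[j] &
      records$five_prime_pos >= regions$start[j] &
      records$five_prime_pos < regions$end[j]
    assign_to[inside] <- nm[j]
  }
  lev <- c(nm, "*outside*")
  sum_by <- function(sel) {
    v <- tapply(w[sel], factor(assign_to[sel], levels = lev), sum, default = 0)
    as.numeric(v)
  }
  out <- data.frame(region = lev,
                    count_plus = sum_by(records$strand == "+"),
                    count_minus = sum_by(records$strand == "-"))
  out$count <- out$count_plus + out$count_minus
  out
}

#' Read-length histogram and modal length
#'
#' @param records Small-RNA `data.frame`, non-empty.
#' @param mode Counting mode, `"weighted"` or `"unique"`.
#' @return A list: `histogram` (`data.frame` of `length`, `count`) and
#'   `modal_length` (smallest length on ties). piRNA libraries typically
#'   peak near 26 nt.
#' @export
length_histogram <- function(records, mode = c("weighted", "unique")) {
  .assert(nrow(records) > 0L, "length_histogram: empty record set")
  w <- .count_weights(records, mode)
  agg <- tapply(w, records$length, sum)
  hist <- data.frame(length = as.integer(names(agg)), count = as.numeric(agg))
  hist <- hist[order(hist$length), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist,
       modal_length = hist$length[which.max(hist$count)])
}

#' Parameters for ping-pong scoring
#'
#' @param score_threshold Score cut used in downstream reporting; 0.8 and
#'   0.9 are the conventional reporting thresholds.
#' @param count_mode `"weighted"` or `"unique"`.
#' @return List of class `pingpong_params`.
#' @export
pingpong_params <- function(score_threshold = 0.9,
                            count_mode = c("weighted", "unique")) {
  .assert(score_threshold >= 0 && score_threshold <= 1,
          "score_threshold must be in [0, 1]")
  structure(list(score_threshold = score_threshold,
                 count_mode = match.arg(count_mode)),
            class = "pingpong_params")
}

#' Ping-pong signature scores from 10-nt 5'-end overlaps
#'
#' Secondary piRNA biogenesis (the ping-pong cycle) leaves pairs of reads on
#' opposite strands whose 5' ends overlap by exactly 10 nt. For every
#' `+`-strand 5'-end stack at position `p`, this computes the weighted
#' `-`-strand 5'-end count `c_o` at `p + o - 1` for offsets `o = 1..20`
#' (`o = 10` is the ping-pong configuration) and scores the offset-10 count
#' by its mid-rank among the 19 other offsets:
#' `score = (#\{c_o < c_10\} + 0.5 #\{c_o = c_10\}) / 19`, in `[0, 1]`. A
#' site is emitted only when both the anchor stack and the offset-10 partner
#' stack are non-empty. Anchoring on `+` stacks counts each pair once.
#' `a10_fraction` is the weighted fraction of partner-stack reads carrying
#' the ping-pong adenine at read position 10; it is reported alongside the
#' score, not folded into it.
#'
#' @param records Small-RNA `data.frame` from one genome.
#' @param contig Contig to scan (default: all contigs in `records`).
#' @param params [pingpong_params()].
#' @return `data.frame` with one row per emitted site: `contig`, `pos` (the
#'   `+` stack position, 0-based), `h_plus`, `c10`, `score`, `a10_fraction`,
#'   and offset columns `c_off1` .. `c_off20`.
#' @export
pingpong_scores <- function(records, contig = NULL, params = pingpong_params()) {
  contigs <- contig %||% unique(records$contig)
  out <- lapply(contigs, function(ctg) {
    .pingpong_one(records[records$contig == ctg, , drop = FALSE], ctg, params)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_pp()
  rownames(res) <- NULL
  res
}

.empty_pp <- function() {
  base <- data.frame(contig = character(), pos = integer(), h_plus = numeric(),
                     c10 = numeric(), score = numeric(), a10_fraction = numeric())
  for (o in 1:20) base[[paste0("c_off", o)]] <- numeric()
  base
}

.pingpong_one <- function(records, ctg, params) {
  w <- .count_weights(records, params$count_mode)
  keep <- w > 0
  records <- records[keep, , drop = FALSE]
  w <- w[keep]
  plus <- records$strand == "+"
  if (!any(plus) || all(plus)) return(NULL)
  p_pos <- records$five_prime_pos[plus]
  p_w <- w[plus]
  h <- tapply(p_w, p_pos, sum)
  anchor <- as.integer(names(h))
  h_plus <- as.numeric(h)

  m_pos <- records$five_prime_pos[!plus]
  m_w <- w[!plus]
  mc <- tapply(m_w, m_pos, sum)
  m_uni <- as.integer(names(mc))
  m_cnt <- as.numeric(mc)

  # c[o, i]: minus-strand 5' count at anchor[i] + o - 1
  C <- matrix(0, nrow = 20L, ncol = length(anchor))
  for (o in 1:20) {
    idx <- match(anchor + o - 1L, m_uni)
    hit <- !is.na(idx)
    C[o, hit] <- m_cnt[idx[hit]]
  }
  keep_site <- C[10L, ] > 0
  if (!any(keep_site)) return(NULL)
  anchor <- anchor[keep_site]
  h_plus <- h_plus[keep_site]
  C <- C[, keep_site, drop = FALSE]
  c10 <- C[10L, ]
  bg <- C[-10L, , drop = FALSE]
  less <- colSums(bg < rep(c10, each = 19L))
  ties <- colSums(bg == rep(c10, each = 19L))
  score <- pmin(1, pmax(0, (less + 0.5 * ties) / 19))

  # 10A fraction of the offset-10 partner stack
  minus_rec <- records[!plus, , drop = FALSE]
  a10 <- vapply(seq_along(anchor), function(i) {
    sel <- minus_rec$five_prime_pos == anchor[i] + 9L
    ww <- m_w[sel]
    if (!length(ww)) return(NA_real_)
    sum(ww * (minus_rec$tenth_nt[sel] %in% "A")) / sum(ww)
  }, numeric(1L))

  res <- data.frame(contig = ctg, pos = anchor, h_plus = h_plus, c10 = c10,
                    score = score, a10_fraction = a10)
  for (o in 1:20) res[[paste0("c_off", o)]] <- C[o, ]
  res
}

#' Fraction of high-scoring ping-pong sites inside a region
#'
#' The locus-attribution statistic used to ask what share of a contig's
#' ping-pong activity falls within a candidate cluster: of all sites on the
#' contig with `score >= threshold`, the fraction lying inside `region`.
#'
#' @param sites Site `data.frame` from [pingpong_scores()], one contig.
#' @param region `c(start, end)`, 0-based half-open.
#' @param threshold Score threshold (default 0.9).
#' @return Fraction in `[0, 1]`, or `NA` if no site reaches the threshold.
#' @export
region_signal_fraction <- function(sites, region, threshold = 0.9) {
  .assert(length(unique(sites$contig)) <= 1L,
          "region_signal_fraction: sites must come from one contig")
  hi <- sites$score >= threshold
  if (!any(hi)) return(NA_real_)
  inside <- hi & sites$pos >= region[1L] & sites$pos < region[2L]
  sum(inside) / sum(hi)
}
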