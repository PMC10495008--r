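#' Parameters for piRNA cluster calling
#'
#' Defaults follow the conventional proTRAC-style option set: minimum
#' cluster size 1 kb, density p-value 0.07, minimum 1U-or-10A fraction 0.33,
#' rejection when the top 1% of distinct read sequences hold more than 90%
#' of the locus read mass, and minimum main-strand fraction 0.25.
#'
#' @param min_size Minimum cluster length, nt (default 1000).
#' @param density_p Significance level for the window read-density test
#'   (default 0.07). See [call_clusters()] for the null model.
#' @param u10a_min Minimum weighted fraction of reads with 1U (first base T
#'   on the genome-forward read) or 10A (default 0.33).
#' @param top1_max_share Maximum share of locus read mass allowed in the top
#'   1% of distinct read sequences (default 0.90).
#' @param mainstrand_min Minimum fraction of weighted reads on the main
#'   strand (default 0.25).
#' @param uni_strand_cutoff Main-strand fraction at or above which a cluster
#'   is classified uni-strand rather than dual-strand (default 0.75; this
#'   cutoff is a package convention, not a proTRAC option).
#' @param window,step Sliding-window size and step for the density scan, nt
#'   (defaults 1000 and 500).
#' @param count_mode `"weighted"` or `"unique"`.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(min_size = 1000L, density_p = 0.07,
                           u10a_min = 0.33, top1_max_share = 0.90,
                           mainstrand_min = 0.25, uni_strand_cutoff = 0.75,
                           window = 1000L, step = 500L,
                           count_mode = c("weighted", "unique")) {
  fr <- c(density_p, u10a_min, top1_max_share, mainstrand_min, uni_strand_cutoff)
  .assert(all(fr > 0 & fr <= 1), "fractions must be in (0, 1]")
  .assert(step <= window, "step must be <= window")
  structure(list(min_size = as.integer(min_size), density_p = density_p,
                 u10a_min = u10a_min, top1_max_share = top1_max_share,
                 mainstrand_min = mainstrand_min,
                 uni_strand_cutoff = uni_strand_cutoff,
                 window = as.integer(window), step = as.integer(step),
                 count_mode = match.arg(count_mode)),
            class = "cluster_params")
}

#' Call piRNA clusters from small-RNA alignments
#'
#' Sliding windows (`window`, `step`) along each contig are scored by their
#' weighted 5'-end read count `k`. Under the uniform-placement null the
#' per-window count is Poisson with mean `lambda = N * window / L_total`
#' (`N` = total weighted reads, `L_total` = summed contig lengths); a window
#' seeds a cluster when its Bonferroni-adjusted upper tail is significant,
#' i.e. `n_tests * P(X >= k) <= density_p`, where `n_tests` is the number
#' of sliding windows evaluated genome-wide (one per `step` along every
#' contig). The genome-wide adjustment calibrates the minimum read density
#' against the whole scanned genome the way proTRAC's density threshold is,
#' and keeps the expected number of falsely significant windows below
#' `density_p` per scan regardless of genome size. Overlapping
#' significant windows are merged, and each merged locus is kept iff
#' (a) it is at least `min_size` nt long, (b) its weighted 1U-or-10A
#' fraction is at least `u10a_min`, (c) the top `ceiling(0.01 * D)` of its
#' `D` distinct read sequences hold at most `top1_max_share` of its weighted
#' read mass, and (d) its main-strand fraction is at least
#' `mainstrand_min`. Clusters are classified `uni` when the main-strand
#' fraction reaches `uni_strand_cutoff`, else `dual`.
#'
#' @param records Small-RNA `data.frame` ([read_small_rna()]).
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param params [cluster_params()].
#' @param all_candidates If `TRUE`, also return merged loci that failed the
#'   post-density criteria (with `passed = FALSE`).
#' @return `data.frame` with one row per cluster: `contig`, `start`, `end`,
#'   `norm_reads`, `mainstrand_frac`, `u10a_frac`, `top1_share`,
#'   `classification`, per-criterion flags `pass_size`, `pass_u10a`,
#'   `pass_top1`, `pass_mainstrand`, and `passed`.
#' @export
call_clusters <- function(records, contig_lengths, params = cluster_params(),
                          all_candidates = FALSE) {
  .assert(all(contig_lengths > 0), "zero-length contigs")
  if (nrow(records) > 0L)
    .assert(all(records$contig %in% names(contig_lengths)),
            "records mapped to contigs absent from contig_lengths")
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      norm_reads = numeric(), mainstrand_frac = numeric(),
                      u10a_frac = numeric(), top1_share = numeric(),
                      classification = character(), pass_size = logical(),
                      pass_u10a = logical(), pass_top1 = logical(),
                      pass_mainstrand = logical(), passed = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  w_all <- .count_weights(records, params$count_mode)
  N <- sum(w_all)
  L_total <- sum(contig_lengths)
  lambda <- N * params$window / L_total
  n_tests <- sum(vapply(contig_lengths, function(L) {
    ceiling(max(1, L) / params$step)
  }, numeric(1L)))

  loci <- list()
  for (ctg in names(contig_lengths)) {
    sel <- records$contig == ctg
    if (!any(sel)) next
    pos <- records$five_prime_pos[sel]
    w <- w_all[sel]
    L <- contig_lengths[[ctg]]
    starts <- seq(0L, max(0L, L - 1L), by = params$step)
    # weighted count per sliding window via cumulative sums over sorted positions
    o <- order(pos)
    pos_s <- pos[o]; w_s <- w[o]
    cw <- c(0, cumsum(w_s))
    lo <- findInterval(starts - 0.5, pos_s)           # reads strictly before start
    hi <- findInterval(starts + params$window - 0.5, pos_s)  # reads < start+window
    k <- cw[hi + 1L] - cw[lo + 1L]
    pval <- ppois(ceiling(k) - 1L, lambda, lower.tail = FALSE)
    sig <- n_tests * pval <= params$density_p & k > 0
    if (!any(sig)) next
    # merge overlapping significant windows
    ws <- starts[sig]; we <- pmin(ws + params$window, L)
    merged_s <- ws[1L]; merged_e <- we[1L]
    ms <- integer(0); me <- integer(0)
    if (length(ws) > 1L) {
      for (i in 2:length(ws)) {
        if (ws[i] <= merged_e) merged_e <- max(merged_e, we[i])
        else { ms <- c(ms, merged_s); me <- c(me, merged_e)
               merged_s <- ws[i]; merged_e <- we[i] }
      }
    }
    ms <- c(ms, merged_s); me <- c(me, merged_e)
    for (i in seq_along(ms))
      loci[[length(loci) + 1L]] <- list(contig = ctg, start = ms[i], end = me[i])
  }
  if (!length(loci)) return(empty)

  rows <- lapply(loci, function(lc) {
    sel <- records$contig == lc$contig &
      records$five_prime_pos >= lc$start & records$five_prime_pos < lc$end
    rec <- records[sel, , drop = FALSE]
    w <- w_all[sel]
    tot <- sum(w)
    w_plus <- sum(w[rec$strand == "+"])
    main_frac <- max(w_plus, tot - w_plus) / tot
    u10a <- sum(w[rec$first_nt %in% "T" | rec$tenth_nt %in% "A"]) / tot
    seqs <- if ("seq" %in% names(rec) && !anyNA(rec$seq)) rec$seq else rec$read_id
    by_seq <- sort(tapply(w, seqs, sum), decreasing = TRUE)
    n_top <- ceiling(0.01 * length(by_seq))
    top1 <- sum(by_seq[seq_len(n_top)]) / tot
    data.frame(contig = lc$contig, start = lc$start, end = lc$end,
               norm_reads = tot, mainstrand_frac = main_frac,
               u10a_frac = u10a, top1_share = top1,
               classification = if (main_frac >= params$uni_strand_cutoff) "uni" else "dual",
               pass_size = (lc$end - lc$start) >= params$min_size,
               pass_u10a = u10a >= params$u10a_min,
               pass_top1 = top1 <= params$top1_max_share,
               pass_mainstrand = main_frac >= params$mainstrand_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$passed <- out$pass_size & out$pass_u10a & out$pass_top1 & out$pass_mainstrand
  if (!all_candidates) out <- out[out$passed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate a promoter (or other anchor) sequence in a genome
#'
#' Exhaustive ungapped scan for `promoter_seq` and its reverse complement
#' with at most `max_mismatch` mismatches — used to anchor a cluster such as
#' *flamenco* by its conserved core promoter.
#'
#' @param genome Named character vector of contig sequences, or a single
#'   sequence.
#' @param promoter_seq Query, length >= 20 nt.
#' @param max_mismatch Maximum mismatches (default 0).
#' @return `data.frame`: `contig`, `pos` (0-based start of the match on the
#'   forward strand), `orientation` (`+`/`-`), `mismatches`.
#' @export
find_anchor <- function(genome, promoter_seq, max_mismatch = 0L) {
  .assert(nchar(promoter_seq) >= 20L, "promoter_seq must be >= 20 nt")
  .assert(max_mismatch >= 0L, "max_mismatch must be >= 0")
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  out <- list()
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    for (orient in c("+", "-")) {
      q <- if (orient == "+") promoter_seq else .revcomp(promoter_seq)
      m <- Biostrings::matchPattern(q, subject, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      mm <- vapply(seq_along(m), function(i) {
        sum(strsplit(as.character(m[[i]]), "")[[1L]] !=
              strsplit(q, "")[[1L]])
      }, integer(1L))
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, pos = Biostrings::start(m) - 1L,
        orientation = orient, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), pos = integer(),
                      orientation = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Delimit a locus from an anchor and a window enrichment profile
#'
#' Starting at the window containing the anchor, extends in the anchor's
#' transcription direction (`+` = increasing coordinates) while windows have
#' `count >= min_window_count`, tolerating up to `max_gap_windows`
#' consecutive below-threshold windows. The anchor window is always
#' included. Reports why extension stopped.
#'
#' @param anchor One row of [find_anchor()] output (or a list with `pos`
#'   and `orientation`).
#' @param enrichment Per-window counts ([window_enrichment()]) tiling the
#'   anchor's contig.
#' @param min_window_count Minimum count for a window to qualify.
#' @param max_gap_windows Tolerated consecutive below-threshold windows
#'   (default 0).
#' @return A list: `start`, `end` (0-based half-open), `stop_reason`
#'   (`"below_threshold"` or `"contig_end"`).
#' @export
delimit_locus <- function(anchor, enrichment, min_window_count,
                          max_gap_windows = 0L) {
  n <- nrow(enrichment)
  win <- enrichment$window_end[n]  # contig length
  .assert(anchor$pos >= 0 && anchor$pos < win, "anchor outside contig")
  a_idx <- findInterval(anchor$pos, enrichment$window_start)
  dir <- if (anchor$orientation == "+") 1L else -1L
  last_good <- a_idx
  i <- a_idx + dir
  gap <- 0L
  stop_reason <- "contig_end"
  while (i >= 1L && i <= n) {
    if (enrichment$count[i] >= min_window_count) {
      last_good <- i
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > max_gap_windows) { stop_reason <- "below_threshold"; break }
    }
    i <- i + dir
  }
  idx <- sort(c(a_idx, last_good))
  list(start = enrichment$window_start[idx[1L]],
       end = enrichment$window_end[idx[2L]],
       stop_reason = stop_reason)
}

#' Benchmark quantiles for assembly QC
#'
#' Computes the 99% quantiles of per-window coverage and soft-clip rate over
#' benchmark windows (windows overlapping conserved single-copy genes, e.g.
#' a BUSCO set). Repetitive loci are then compared against these, the idea
#' being that a well-assembled cluster should not exceed what the easy,
#' single-copy fraction of the assembly shows.
#'
#' @param profile `data.frame` with `contig`, `window_start`, `mean_cov`,
#'   `clip_rate`.
#' @param benchmark Logical vector marking benchmark windows, or a
#'   `data.frame` of intervals (`contig`, `start`, `end`) intersected with
#'   window starts. At least 20 benchmark windows are required.
#' @param q Quantile level (default 0.99).
#' @return A list: `cov_q`, `clip_q`, `n_benchmark`.
#' @export
qc_benchmark_quantiles <- function(profile, benchmark, q = 0.99) {
  if (is.data.frame(benchmark)) {
    sel <- rep(FALSE, nrow(profile))
    for (j in seq_len(nrow(benchmark))) {
      sel <- sel | (profile$contig == benchmark$contig[j] &
                      profile$window_start >= benchmark$start[j] &
                      profile$window_start < benchmark$end[j])
    }
    benchmark <- sel
  }
  .assert(sum(benchmark) >= 20L,
          "qc: fewer than 20 benchmark windows (quantile unstable)")
  list(cov_q = unname(quantile(profile$mean_cov[benchmark], q)),
       clip_q = unname(quantile(profile$clip_rate[benchmark], q)),
       n_benchmark = sum(benchmark))
}

#' Flag target windows exceeding benchmark coverage/soft-clip quantiles
#'
#' @param profile Per-window QC `data.frame` (`contig`, `window_start`,
#'   `mean_cov`, `clip_rate`).
#' @param quantiles Output of [qc_benchmark_quantiles()].
#' @param target_region List or vector `(contig, start, end)`; rows of
#'   `profile` whose window start lies inside are tested.
#' @return `data.frame` of flagged windows with a `flag` column naming the
#'   violated quantile (`"coverage"`, `"soft_clip"` or
#'   `"coverage+soft_clip"`).
#' @export
qc_flag <- function(profile, quantiles, target_region) {
  tr <- as.list(target_region)
  names(tr) <- c("contig", "start", "end")[seq_along(tr)]
  sel <- profile$contig == tr$contig &
    profile$window_start >= as.numeric(tr$start) &
    profile$window_start < as.numeric(tr$end)
  tw <- profile[sel, , drop = FALSE]
  over_cov <- tw$mean_cov > quantiles$cov_q
  over_clip <- tw$clip_rate > quantiles$clip_q
  flagged <- tw[over_cov | over_clip, , drop = FALSE]
  flagged$flag <- paste0(ifelse(over_cov[over_cov | over_clip], "coverage", ""),
                         ifelse(over_cov[over_cov | over_clip] &
                                  over_clip[over_cov | over_clip], "+", ""),
                         ifelse(over_clip[over_cov | over_clip], "soft_clip", ""))
  rownames(flagged) <- NULL
  flagged
}
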