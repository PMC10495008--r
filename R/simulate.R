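#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator
#' ([simulate_locus()], [simulate_panel()], [simulate_small_rna()],
#' [simulate_pingpong_stacks()], [simulate_qc()]). Defaults encode the
#' study conditions the package's recovery tests assume: a cluster-like
#' locus whose TE complement is 79% antisense, a seven-genotype panel with
#' 54% private insertions, small-RNA libraries with modal length 26 nt and
#' strong 1U/10A biases, and 1/n multimapper weighting up to 50 placements.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param genome_len Background genome length, nt (default 2e6, sized so
#'   that default insertion sets fit with inter-insertion spacing above the
#'   fragment-merging gap).
#' @param n_families,ltr_fraction,consensus_len_range,ltr_len TE library
#'   dials: number of families, fraction LTR-class, consensus length range,
#'   LTR length.
#' @param n_insertions,antisense_prob,full_length_prob,solo_ltr_prob
#'   Insertion dials. Non-full-length LTR-family copies become solo LTRs
#'   with `solo_ltr_prob`, otherwise truncated fragments.
#' @param divergence_rate Per-base substitution rate applied to planted
#'   copies.
#' @param frag_split_prob Probability a full-length non-LTR copy is emitted
#'   as two annotation rows instead of one.
#' @param min_spacing Minimum genomic distance between planted insertions,
#'   nt. Kept above [merge_params()]'s `max_gap` so planted copies map
#'   one-to-one onto merged copies.
#' @param panel_size,n_columns,sharing_probs,downgrade_prob Panel dials:
#'   genotype count, insertion columns, distribution of the number of
#'   genotypes carrying each insertion (names = k, must sum to 1), and the
#'   probability that a shared full-length insertion is degraded to a
#'   fragment in a given carrier.
#' @param panel_n_families Size of the family pool used for panel columns
#'   (default 30, large enough that order plus family identity determines
#'   insertion homology, as with the family-rich libraries of real loci).
#' @param n_reads,cluster_reads Background and in-cluster read counts for
#'   [simulate_small_rna()].
#' @param read_len_mode Modal read length, nt (default 26).
#' @param u1_prob,a10_prob 1U bias of reads, 10A bias of ping-pong partner
#'   reads.
#' @param cluster_strand_bias Probability an in-cluster read maps to the
#'   cluster main strand.
#' @param pingpong_pair_prob Fraction of cluster reads emitted as +/- pairs
#'   with 5' ends exactly 10 nt apart.
#' @param n_pingpong_sites Number of planted pair positions.
#' @param multimap_max Cap on simulated `n_hits` (default 50).
#' @param pp_region_len,pp_stack_height,pp_background_rate Dials for the
#'   stack-level ping-pong calibration generator: region length, planted
#'   stack height, and the per-position rate of background stacks (total
#'   across both strands).
#' @param coverage_mean,clip_rate,qc_window,qc_n_windows,qc_n_benchmark,n_anomalies
#'   QC-profile dials: mean coverage, mean soft-clip rate, window size,
#'   window count, benchmark-window count, planted anomaly windows.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_len = 2e6, n_families = 8L, ltr_fraction = 0.5,
                       consensus_len_range = c(2000L, 6000L), ltr_len = 300L,
                       n_insertions = 200L, antisense_prob = 0.79,
                       full_length_prob = 0.30, solo_ltr_prob = 0.15,
                       divergence_rate = 0.05, frag_split_prob = 0.5,
                       min_spacing = 5001L,
                       panel_size = 7L, n_columns = 200L, panel_n_families = 30L,
                       sharing_probs = c("1" = 0.54, "7" = 0.46),
                       downgrade_prob = 0.2,
                       n_reads = 10000L, cluster_reads = 5000L,
                       read_len_mode = 26L, u1_prob = 0.8, a10_prob = 0.8,
                       cluster_strand_bias = 0.9,
                       pingpong_pair_prob = 0, n_pingpong_sites = 20L,
                       multimap_max = 50L,
                       pp_region_len = 20000L, pp_stack_height = 15L,
                       pp_background_rate = 0.2,
                       coverage_mean = 30, clip_rate = 0.02,
                       qc_window = 10000L, qc_n_windows = 100L,
                       qc_n_benchmark = 50L, n_anomalies = 0L) {
  cfg <- as.list(environment())
  fr <- c(ltr_fraction, antisense_prob, full_length_prob, solo_ltr_prob,
          u1_prob, a10_prob, cluster_strand_bias, pingpong_pair_prob,
          divergence_rate, frag_split_prob, downgrade_prob)
  .assert(all(fr >= 0 & fr <= 1), "sim_config: fractions must be in [0, 1]")
  .assert(abs(sum(sharing_probs) - 1) < 1e-9, "sharing_probs must sum to 1")
  .assert(!is.null(names(sharing_probs)), "sharing_probs must be named by k")
  .assert(read_len_mode >= 23L && read_len_mode <= 29L,
          "read_len_mode outside the simulated 23-29 nt window")
  structure(cfg, class = "sim_config")
}

# Family library with random consensus sequences.
.sim_families <- function(cfg) {
  n <- cfg$n_families
  n_ltr <- round(cfg$ltr_fraction * n)
  clen <- sample(seq(cfg$consensus_len_range[1L], cfg$consensus_len_range[2L]), n,
                 replace = TRUE)
  data.frame(name = sprintf("FAM%02d", seq_len(n)),
             te_class = c(rep("LTR", n_ltr), rep("LINE", n - n_ltr)),
             consensus_len = clen,
             ltr_len = c(rep(cfg$ltr_len, n_ltr), rep(0L, n - n_ltr)),
             consensus_seq = .random_dna(clen),
             stringsAsFactors = FALSE)
}

#' Simulate a cluster-like locus with planted TE insertions
#'
#' Generates a random background genome, a TE family library, and
#' `n_insertions` planted copies at uniformly placed, non-overlapping
#' positions separated by at least `min_spacing` nt. Each copy is
#' independently antisense with `antisense_prob` (the cluster strand is
#' `+`), full length with `full_length_prob`, otherwise a solo LTR (LTR
#' families, with `solo_ltr_prob`) or a uniformly truncated fragment.
#' Substitutions are applied at `divergence_rate`. Emitted annotation rows
#' mimic RepeatMasker output: full-length LTR copies appear as
#' LTR + internal + LTR rows under `FAMILY_LTR`/`FAMILY_I` names, and
#' full-length non-LTR copies may be split in two. Every row carries its
#' insertion's id in `linkage_id`, so all records trace to the truth table.
#'
#' @param config [sim_config()].
#' @return A list: `genome` (named character vector, contig `sim`), `hits`
#'   (repeat-hit `data.frame` in [read_repeatmasker_out()] layout),
#'   `families` (family table with `consensus_seq`), and `truth` with
#'   `insertions` (`copy_id`, `family`, `start`, `end`, `strand`,
#'   `category`, `divergence_pct`), `clusters`, `contig_len` and
#'   `cluster_strand`.
#' @export
simulate_locus <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  fams <- .sim_families(cfg)
  genome_bg <- .random_dna(cfg$genome_len)
  n <- cfg$n_insertions
  truth0 <- data.frame(copy_id = integer(), family = character(),
                       start = integer(), end = integer(), strand = character(),
                       category = character(), divergence_pct = numeric(),
                       stringsAsFactors = FALSE)
  base_truth <- list(clusters = data.frame(contig = "sim", start = 0L,
                                           end = cfg$genome_len),
                     contig_len = c(sim = cfg$genome_len),
                     cluster_strand = "+")
  if (n == 0L)
    return(list(genome = c(sim = genome_bg), hits = .empty_hits(),
                families = fams,
                truth = c(list(insertions = truth0), base_truth)))

  fi <- sample.int(nrow(fams), n, replace = TRUE)
  strand <- ifelse(runif(n) < cfg$antisense_prob, "-", "+")
  is_ltr <- fams$te_class[fi] == "LTR"
  u <- runif(n)
  category <- ifelse(u < cfg$full_length_prob, "full_length",
                     ifelse(is_ltr & runif(n) < cfg$solo_ltr_prob,
                            "solo_LTR", "fragment"))

  ins <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fams[fi[i], ]
    ins[[i]] <- .plant_copy(i, f, strand[i], category[i], cfg)
  }
  ilen <- vapply(ins, function(x) x$len, integer(1L))
  need <- sum(ilen) + (n + 1L) * cfg$min_spacing
  .assert(need <= cfg$genome_len,
          "insertions exceed genome capacity (%d needed, %d available)",
          need, cfg$genome_len)
  free <- cfg$genome_len - sum(ilen) - (n + 1L) * cfg$min_spacing
  raw <- runif(n + 1L)
  extra <- floor(raw / sum(raw) * free)
  gaps <- cfg$min_spacing + extra
  starts <- cumsum(gaps[seq_len(n)] + c(0L, ilen[-n]))  # start of each insertion

  pieces <- character(2L * n + 1L)
  pos <- 1L
  hit_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- starts[i]
    pieces[2L * i - 1L] <- substr(genome_bg, pos, s)        # background up to s (0-based)
    pieces[2L * i] <- ins[[i]]$seq
    pos <- s + ilen[i] + 1L
    rows <- ins[[i]]$rows
    rows$start <- rows$start + s
    rows$end <- rows$end + s
    hit_rows[[i]] <- rows
  }
  pieces[2L * n + 1L] <- substr(genome_bg, pos, cfg$genome_len)
  genome <- paste(pieces, collapse = "")

  hits <- do.call(rbind, hit_rows)
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  truth <- data.frame(copy_id = seq_len(n), family = fams$name[fi],
                      start = starts, end = starts + ilen, strand = strand,
                      category = category,
                      divergence_pct = vapply(ins, function(x) x$div, numeric(1L)),
                      stringsAsFactors = FALSE)
  list(genome = c(sim = genome), hits = hits, families = fams,
       truth = c(list(insertions = truth), base_truth))
}

# Build one insertion: its sequence (genome-forward), occupied length, and
# annotation rows with 0-based genomic coordinates relative to the
# insertion start. Raw consensus coordinates follow RepeatMasker component
# naming: FAM_LTR rows are 1..ltr on the LTR model, FAM_I rows are on the
# internal model.
.plant_copy <- function(id, fam, strand, category, cfg) {
  clen <- fam$consensus_len
  ltr <- fam$ltr_len
  segs <- switch(category,
    full_length = {
      if (fam$te_class == "LTR") {
        list(list(name = paste0(fam$name, "_LTR"), cb = 1L, ce = ltr,
                  ub = 1L, ue = ltr),
             list(name = paste0(fam$name, "_I"), cb = 1L, ce = clen - 2L * ltr,
                  ub = ltr + 1L, ue = clen - ltr),
             list(name = paste0(fam$name, "_LTR"), cb = 1L, ce = ltr,
                  ub = clen - ltr + 1L, ue = clen))
      } else if (runif(1L) < cfg$frag_split_prob) {
        bp <- as.integer(floor(clen * runif(1L, 0.2, 0.8)))
        list(list(name = fam$name, cb = 1L, ce = bp, ub = 1L, ue = bp),
             list(name = fam$name, cb = bp + 1L, ce = clen,
                  ub = bp + 1L, ue = clen))
      } else {
        list(list(name = fam$name, cb = 1L, ce = clen, ub = 1L, ue = clen))
      }
    },
    solo_LTR = list(list(name = paste0(fam$name, "_LTR"), cb = 1L, ce = ltr,
                         ub = 1L, ue = ltr)),
    fragment = {
      flen <- as.integer(max(2L, round(runif(1L, 0.15, 0.60) * clen)))
      if (fam$te_class == "LTR") {
        lo <- max(1L, ltr + 2L - flen)
        hi <- min(clen - flen + 1L, clen - ltr)
        cb <- if (hi > lo) sample(lo:hi, 1L) else lo
      } else {
        cb <- sample.int(clen - flen + 1L, 1L)
      }
      list(list(name = fam$name, cb = cb, ce = cb + flen - 1L,
                ub = cb, ue = cb + flen - 1L))
    })
  # element-forward sequence and per-segment divergence (ub/ue index the
  # unified consensus)
  seq_parts <- character(length(segs))
  div <- numeric(length(segs))
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    mut <- .mutate_seq(substr(fam$consensus_seq, sg$ub, sg$ue), cfg$divergence_rate)
    seq_parts[k] <- mut$seq
    div[k] <- 100 * mut$n_sub / (sg$ue - sg$ub + 1L)
  }
  elem_seq <- paste(seq_parts, collapse = "")
  len <- nchar(elem_seq)
  # genomic layout: element-forward for +, reversed for -
  seg_len <- vapply(segs, function(s) s$ue - s$ub + 1L, integer(1L))
  if (strand == "+") {
    g_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
    out_seq <- elem_seq
    ord <- seq_along(segs)
  } else {
    rev_len <- rev(seg_len)
    g_start_rev <- cumsum(c(0L, rev_len[-length(rev_len)]))
    ord <- rev(seq_along(segs))
    g_start <- g_start_rev
    out_seq <- .revcomp(elem_seq)
  }
  rows <- do.call(rbind, lapply(seq_along(ord), function(k) {
    sg <- segs[[ord[k]]]
    data.frame(contig = "sim", start = g_start[k],
               end = g_start[k] + (sg$ue - sg$ub + 1L),
               strand = strand, family = sg$name,
               cons_begin = sg$cb, cons_end = sg$ce,
               divergence_pct = div[ord[k]], linkage_id = id,
               stringsAsFactors = FALSE)
  }))
  list(seq = out_seq, len = len, rows = rows,
       div = 100 * sum(div * seg_len / 100) / sum(seg_len))
}

#' Simulate a genotype panel with a controlled sharing spectrum
#'
#' Draws `n_columns` homologous insertion sites; each is carried by `k`
#' genotypes with probability `sharing_probs[as.character(k)]`, the carrier
#' subset chosen uniformly. Each insertion is full length with
#' `full_length_prob` (degraded to a fragment in individual carriers with
#' `downgrade_prob`, always retaining one full-length carrier), otherwise a
#' fragment everywhere. Carriers hold the copy at the same homologous
#' position, so panel construction can rely on synteny.
#'
#' @param config [sim_config()].
#' @return A list: `genotypes` (named list of ordered TE-copy tables with
#'   `family`, `strand`, `category`, `start`, `end`, `contig`) and `truth`
#'   (`columns` table with `column_id`, `family`, `k`, `base_category`, and
#'   per-genotype `state_*` columns).
#' @export
simulate_panel <- function(config = sim_config()) {
  cfg <- config
  .assert(cfg$panel_size >= 2L, "panel_size must be >= 2")
  ks_avail <- as.integer(names(cfg$sharing_probs))
  .assert(all(ks_avail >= 1L & ks_avail <= cfg$panel_size),
          "sharing_probs keys outside 1..panel_size")
  set.seed(cfg$seed + 11L)
  genos <- sprintf("G%d", seq_len(cfg$panel_size))
  # a family pool rich enough that order + family identity pins down
  # insertion homology, as it does for the ~100-family libraries of real loci
  pcfg <- cfg
  pcfg$n_families <- cfg$panel_n_families
  fams <- .sim_families(pcfg)
  n <- cfg$n_columns
  k <- ks_avail[sample.int(length(ks_avail), n, replace = TRUE,
                           prob = cfg$sharing_probs)]
  fam <- sample(fams$name, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  base_cat <- ifelse(runif(n) < cfg$full_length_prob, "full_length", "fragment")
  states <- matrix("absent", n, cfg$panel_size, dimnames = list(NULL, genos))
  for (j in seq_len(n)) {
    carriers <- sample.int(cfg$panel_size, k[j])
    st <- rep(base_cat[j], k[j])
    if (base_cat[j] == "full_length" && k[j] > 1L) {
      down <- runif(k[j]) < cfg$downgrade_prob
      if (all(down)) down[1L] <- FALSE
      st[down] <- "fragment"
    }
    states[j, carriers] <- st
  }
  start <- 1000L * seq_len(n)
  genotypes <- setNames(lapply(genos, function(g) {
    sel <- states[, g] != "absent"
    data.frame(contig = "locus", start = start[sel], end = start[sel] + 600L,
               family = fam[sel], strand = strand[sel],
               category = states[sel, g], stringsAsFactors = FALSE)
  }), genos)
  columns <- data.frame(column_id = seq_len(n), family = fam, k = k,
                        base_category = base_cat, stringsAsFactors = FALSE)
  columns <- cbind(columns,
                   as.data.frame(states, stringsAsFactors = FALSE) |>
                     setNames(paste0("state_", genos)))
  list(genotypes = genotypes, truth = list(columns = columns))
}

#' Simulate a small-RNA read set over planted clusters
#'
#' Emits `n_reads` background reads uniform over the contig plus
#' `cluster_reads` reads inside the truth's cluster intervals. Read lengths
#' peak at `read_len_mode`; first bases are `T` with `u1_prob`. A fraction
#' `pingpong_pair_prob` of cluster reads is emitted as +/- pairs whose 5'
#' ends are exactly 10 nt apart (stacked at `n_pingpong_sites` planted
#' positions, partner tenth base `A` with `a10_prob`). Reads whose 5' end
#' falls inside a planted repeat copy receive `n_hits` equal to the
#' family's copy number, capped at `multimap_max`; all other reads map
#' uniquely.
#'
#' @param truth Truth list containing `clusters` (`contig`, `start`, `end`)
#'   and `contig_len` (named vector); typically `simulate_locus()$truth`.
#' @param config [sim_config()].
#' @return A list: `records` (small-RNA `data.frame`) and `truth` (the
#'   input truth plus `pingpong_anchor_positions`).
#' @export
simulate_small_rna <- function(truth, config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed + 23L)
  cl <- truth$clusters
  .assert(!is.null(cl) && nrow(cl) > 0L || cfg$n_reads > 0L,
          "no cluster intervals in truth and zero background reads")
  ctg <- names(truth$contig_len)[1L]
  L <- truth$contig_len[[1L]]

  n_bg <- cfg$n_reads
  bg_pos <- if (n_bg > 0L) sample.int(L, n_bg, replace = TRUE) - 1L else integer()
  bg_str <- sample(c("+", "-"), n_bg, replace = TRUE)

  n_cl <- cfg$cluster_reads
  n_pair_reads <- round(cfg$pingpong_pair_prob * n_cl)
  n_pairs <- floor(n_pair_reads / 2)
  n_free <- n_cl - 2L * n_pairs

  cl <- cl[cl$contig == ctg, , drop = FALSE]
  pick_cluster_pos <- function(m) {
    if (m == 0L || nrow(cl) == 0L) return(integer())
    wl <- cl$end - cl$start
    ci <- sample.int(nrow(cl), m, replace = TRUE, prob = wl)
    cl$start[ci] + floor(runif(m) * wl[ci])
  }
  free_pos <- pick_cluster_pos(n_free)
  free_str <- ifelse(runif(n_free) < cfg$cluster_strand_bias, "+", "-")

  pp_sites <- integer()
  pair_anchor <- integer()
  if (n_pairs > 0L) {
    grid <- unlist(lapply(seq_len(nrow(cl)), function(i) {
      seq(cl$start[i] + 50L, cl$end[i] - 50L, by = 50L)
    }))
    pp_sites <- sort(sample(grid, min(cfg$n_pingpong_sites, length(grid))))
    pair_anchor <- pp_sites[1L + (seq_len(n_pairs) - 1L) %% length(pp_sites)]
  }

  pos <- c(bg_pos, free_pos, pair_anchor, pair_anchor + 9L)
  strand <- c(bg_str, free_str, rep("+", n_pairs), rep("-", n_pairs))
  n_tot <- length(pos)
  len <- .sample_lengths(n_tot, cfg)
  first <- ifelse(runif(n_tot) < cfg$u1_prob, "T",
                  sample(c("A", "C", "G"), n_tot, replace = TRUE))
  tenth <- sample(c("A", "C", "G", "T"), n_tot, replace = TRUE)
  if (n_pairs > 0L) {
    partner_idx <- n_bg + n_free + n_pairs + seq_len(n_pairs)
    tenth[partner_idx] <- ifelse(runif(n_pairs) < cfg$a10_prob, "A",
                                 sample(c("C", "G", "T"), n_pairs, replace = TRUE))
  }
  seqs <- .random_dna(len)
  substr(seqs, 1L, 1L) <- first
  substr(seqs, 10L, 10L) <- tenth

  n_hits <- rep(1L, n_tot)
  if (!is.null(truth$insertions) && nrow(truth$insertions) > 0L) {
    ins <- truth$insertions
    copy_number <- table(ins$family)
    idx <- findInterval(pos, ins$start)
    inside <- idx >= 1L & pos < ins$end[pmax(idx, 1L)]
    n_hits[inside] <- pmin(as.integer(copy_number[ins$family[idx[inside]]]),
                           cfg$multimap_max)
  }
  rec <- .srna_df(sprintf("r%06d", seq_len(n_tot)), ctg, pos, strand, len,
                  seqs, n_hits)
  truth$pingpong_anchor_positions <- pp_sites
  list(records = rec, truth = truth)
}

.sample_lengths <- function(n, cfg) {
  lens <- 23:29
  w <- exp(-0.5 * ((lens - cfg$read_len_mode) / 1.2)^2)
  sample(lens, n, replace = TRUE, prob = w)
}

#' Simulate 5'-end stacks for ping-pong score calibration
#'
#' Stack-level generator for measuring planted-signal recall and background
#' specificity of [pingpong_scores()]: background 5'-end stacks appear at a
#' rate of `pp_background_rate` stacks per position (heights Poisson, split
#' evenly between strands), and `n_pingpong_sites` planted positions carry
#' a `+` stack of height `pp_stack_height` paired with a `-` stack of the
#' same height 10 nt into the read (5' ends offset by 10, partner tenth
#' base `A` with `a10_prob`).
#'
#' @param config [sim_config()].
#' @return A list: `records` and `truth` with `planted_positions` (the `+`
#'   anchor coordinates) and `region_len`.
#' @export
simulate_pingpong_stacks <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed + 31L)
  L <- cfg$pp_region_len
  lam <- cfg$pp_background_rate / 2
  planted <- sort(sample(seq(100L, L - 100L, by = 50L), cfg$n_pingpong_sites))
  mk_bg <- function(strand) {
    h <- rpois(L, lam)
    nz <- which(h > 0L)
    data.frame(pos = rep(nz - 1L, h[nz]), strand = strand,
               stringsAsFactors = FALSE)
  }
  bg <- rbind(mk_bg("+"), mk_bg("-"))
  h <- cfg$pp_stack_height
  pl <- data.frame(pos = c(rep(planted, each = h), rep(planted + 9L, each = h)),
                   strand = rep(c("+", "-"), each = h * length(planted)),
                   stringsAsFactors = FALSE)
  all_r <- rbind(bg, pl)
  n <- nrow(all_r)
  is_partner <- c(rep(FALSE, nrow(bg) + h * length(planted)),
                  rep(TRUE, h * length(planted)))
  len <- .sample_lengths(n, cfg)
  tenth <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  tenth[is_partner] <- ifelse(runif(sum(is_partner)) < cfg$a10_prob, "A",
                              sample(c("C", "G", "T"), sum(is_partner),
                                     replace = TRUE))
  seqs <- .random_dna(len)
  substr(seqs, 10L, 10L) <- tenth
  rec <- .srna_df(sprintf("p%06d", seq_len(n)), "pp", all_r$pos, all_r$strand,
                  len, seqs, rep(1L, n))
  list(records = rec,
       truth = list(planted_positions = planted, region_len = L))
}

#' Simulate a per-window coverage and soft-clip QC profile
#'
#' Draws per-window mean coverage around `coverage_mean` and soft-clip
#' rates around `clip_rate`, marks `qc_n_benchmark` windows as the
#' benchmark (single-copy gene) set, and optionally plants `n_anomalies`
#' non-benchmark windows with 4x coverage and strongly elevated clipping —
#' the signature of a collapsed or misjoined repeat region.
#'
#' @param config [sim_config()].
#' @return A list: `profile` (`contig`, `window_start`, `mean_cov`,
#'   `clip_rate`, `is_benchmark`) and `truth` with `anomaly_windows`
#'   (window starts).
#' @export
simulate_qc <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed + 41L)
  n <- cfg$qc_n_windows
  cov <- pmax(0, rnorm(n, cfg$coverage_mean, 0.1 * cfg$coverage_mean))
  clip <- pmin(1, pmax(0, rnorm(n, cfg$clip_rate, 0.3 * cfg$clip_rate)))
  bench <- rep(FALSE, n)
  bench[sample.int(n, cfg$qc_n_benchmark)] <- TRUE
  anom <- integer()
  if (cfg$n_anomalies > 0L) {
    anom <- sample(which(!bench), cfg$n_anomalies)
    cov[anom] <- cov[anom] * 4
    clip[anom] <- pmin(1, clip[anom] + 0.3)
  }
  ws <- (seq_len(n) - 1L) * cfg$qc_window
  list(profile = data.frame(contig = "qc", window_start = ws,
                            mean_cov = cov, clip_rate = clip,
                            is_benchmark = bench),
       truth = list(anomaly_windows = ws[anom]))
}
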