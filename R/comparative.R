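#' Parameters for synteny alignment of TE annotations
#'
#' Score conventions follow the annotation-alignment usage: `+match_score`
#' for pairing two tokens of the same family group (and strand, when
#' required), `-mismatch_penalty` for pairing tokens that do not match, and
#' `-gap_penalty` per unpaired token, maximized globally. Defaults 0.2 /
#' 0.1 / 0.09 are the conventional settings for this kind of annotation
#' alignment.
#'
#' @param match_score Positive score for a matched pair (default 0.2).
#' @param mismatch_penalty Penalty for pairing non-matching tokens
#'   (default 0.1).
#' @param gap_penalty Penalty per unpaired token (default 0.09).
#' @param require_same_strand Must matched tokens share a strand
#'   (default `TRUE`)?
#' @param family_equivalence Optional named character vector mapping
#'   near-identical family names (e.g. `mdg4-3`, `mdg4-5`) to one group
#'   label.
#' @return List of class `align_params`.
#' @export
align_params <- function(match_score = 0.2, mismatch_penalty = 0.1,
                         gap_penalty = 0.09, require_same_strand = TRUE,
                         family_equivalence = NULL) {
  .assert(match_score > 0, "match_score must be positive")
  .assert(mismatch_penalty >= 0 && gap_penalty >= 0, "penalties must be >= 0")
  structure(list(match_score = match_score, mismatch_penalty = mismatch_penalty,
                 gap_penalty = gap_penalty,
                 require_same_strand = require_same_strand,
                 family_equivalence = family_equivalence),
            class = "align_params")
}

.family_group <- function(family, params) {
  fe <- params$family_equivalence
  if (is.null(fe)) return(family)
  hit <- match(family, names(fe))
  family[!is.na(hit)] <- fe[hit[!is.na(hit)]]
  family
}

#' Globally align two ordered TE-annotation token lists
#'
#' Needleman-Wunsch over annotation tokens (TE copies ordered by genomic
#' start within one homologous locus), maximizing total score under
#' [align_params()]. Two tokens match iff they resolve to the same family
#' group and — if required — the same strand. Ties are broken preferring
#' match over mismatch over gap, then leftmost.
#'
#' @param a,b `data.frame`s of TE copies with at least `family`, `strand`
#'   and `start` columns, each ordered by `start`.
#' @param params [align_params()].
#' @return A list: `score` (total) and `columns`, a `data.frame` with
#'   `a_index`, `b_index` (`NA` at gaps) and `type`
#'   (`match`/`mismatch`/`gap_a`/`gap_b`), in alignment order.
#' @export
align_annotation_pair <- function(a, b, params = align_params()) {
  for (x in list(a, b))
    .assert(nrow(x) < 2L || !is.unsorted(x$start),
            "annotation lists must be ordered by genomic start")
  n <- nrow(a); m <- nrow(b)
  ga <- .family_group(a$family, params)
  gb <- .family_group(b$family, params)
  is_match <- outer(ga, gb, "==")
  if (params$require_same_strand && n > 0L && m > 0L)
    is_match <- is_match & outer(a$strand, b$strand, "==")
  S <- ifelse(is_match, params$match_score, -params$mismatch_penalty)
  gp <- params$gap_penalty
  dp <- matrix(0, n + 1L, m + 1L)
  dp[, 1L] <- -(0:n) * gp
  dp[1L, ] <- -(0:m) * gp
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        dp[i + 1L, j + 1L] <- max(dp[i, j] + S[i, j],
                                  dp[i, j + 1L] - gp,
                                  dp[i + 1L, j] - gp)
      }
    }
  }
  # traceback, preferring diagonal match > diagonal mismatch > gap in b > gap in a
  i <- n; j <- m
  cols <- list()
  repeat {
    if (i == 0L && j == 0L) break
    cur <- dp[i + 1L, j + 1L]
    if (i > 0L && j > 0L && isTRUE(all.equal(cur, dp[i, j] + S[i, j]))) {
      cols[[length(cols) + 1L]] <- data.frame(
        a_index = i, b_index = j,
        type = if (is_match[i, j]) "match" else "mismatch",
        stringsAsFactors = FALSE)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && isTRUE(all.equal(cur, dp[i, j + 1L] - gp))) {
      cols[[length(cols) + 1L]] <- data.frame(a_index = i, b_index = NA_integer_,
                                              type = "gap_b", stringsAsFactors = FALSE)
      i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- data.frame(a_index = NA_integer_, b_index = j,
                                              type = "gap_a", stringsAsFactors = FALSE)
      j <- j - 1L
    }
  }
  columns <- if (length(cols)) do.call(rbind, rev(cols))
             else data.frame(a_index = integer(), b_index = integer(),
                             type = character(), stringsAsFactors = FALSE)
  rownames(columns) <- NULL
  list(score = dp[n + 1L, m + 1L], columns = columns)
}

#' Build an insertion presence/absence panel around a reference genotype
#'
#' Star-progressive panel construction: every non-reference genotype's TE
#' annotation is aligned to the reference with [align_annotation_pair()];
#' matched tokens join the column seeded by their reference token, unmatched
#' tokens form insertion columns placed between their flanking matched
#' reference tokens and merged across genotypes when they share the same
#' family group, flanking slot and occurrence order. A column's state per
#' genotype is the copy's structural category (`full_length`, `fragment`,
#' `solo_LTR`), `absent` otherwise. Mismatch pairings (different families
#' forced together) are not treated as homology; such tokens get their own
#' columns.
#'
#' @param copies_by_genotype Named list of TE-copy `data.frame`s (each with
#'   `family`, `strand`, `category`, `start`, ordered by `start`).
#' @param reference Name of the reference genotype (default: first).
#' @param params [align_params()].
#' @return `data.frame` with `column_id`, `family`, `n_present` and one
#'   `state_<genotype>` column per genotype. Every input copy contributes to
#'   exactly one column.
#' @export
build_panel <- function(copies_by_genotype, reference = names(copies_by_genotype)[1L],
                        params = align_params()) {
  .assert(length(copies_by_genotype) >= 2L, "panel requires >= 2 genotypes")
  .assert(reference %in% names(copies_by_genotype), "unknown reference genotype")
  genos <- names(copies_by_genotype)
  ref <- copies_by_genotype[[reference]]
  n_ref <- nrow(ref)

  # column registry: ref columns keyed by ref index; insertion columns keyed
  # by (prev matched ref index, family group, occurrence number)
  ref_grp <- .family_group(ref$family, params)
  cols <- lapply(seq_len(n_ref), function(i) {
    st <- setNames(rep("absent", length(genos)), genos)
    st[reference] <- ref$category[i]
    list(sort_key = c(i, 0, 0), family = ref_grp[i], states = st)
  })
  ins_index <- new.env(parent = emptyenv())

  for (g in setdiff(genos, reference)) {
    gc <- copies_by_genotype[[g]]
    if (nrow(gc) == 0L) next
    aln <- align_annotation_pair(ref, gc, params)$columns
    g_grp <- .family_group(gc$family, params)
    prev_ref <- 0L
    occ <- list()  # occurrence counters per (prev_ref, group)
    for (r in seq_len(nrow(aln))) {
      ty <- aln$type[r]
      if (ty == "match") {
        i <- aln$a_index[r]; j <- aln$b_index[r]
        if (cols[[i]]$states[g] != "absent")
          .stopf("build_panel: genotype '%s' assigned twice to reference column %d", g, i)
        cols[[i]]$states[g] <- gc$category[j]
        prev_ref <- i
      } else if (ty == "gap_b") {
        prev_ref <- aln$a_index[r]
      } else if (ty %in% c("gap_a", "mismatch")) {
        if (ty == "mismatch") prev_ref_next <- aln$a_index[r] else prev_ref_next <- prev_ref
        j <- aln$b_index[r]
        key0 <- paste(prev_ref, g_grp[j], gc$strand[j], sep = "\r")
        k <- (occ[[key0]] %||% 0L) + 1L
        occ[[key0]] <- k
        key <- paste(key0, k, sep = "\r")
        idx <- ins_index[[key]]
        if (is.null(idx)) {
          st <- setNames(rep("absent", length(genos)), genos)
          st[g] <- gc$category[j]
          cols[[length(cols) + 1L]] <- list(sort_key = c(prev_ref, 1, k),
                                            family = g_grp[j], states = st)
          ins_index[[key]] <- length(cols)
        } else {
          if (cols[[idx]]$states[g] != "absent")
            .stopf("build_panel: genotype '%s' merged twice into one insertion column", g)
          cols[[idx]]$states[g] <- gc$category[j]
        }
        if (ty == "mismatch") prev_ref <- prev_ref_next
      }
    }
  }

  keys <- t(vapply(cols, `[[`, numeric(3L), "sort_key"))
  ord <- order(keys[, 1L], keys[, 2L], keys[, 3L])
  cols <- cols[ord]
  states <- t(vapply(cols, `[[`, character(length(genos)), "states"))
  colnames(states) <- paste0("state_", genos)
  out <- data.frame(column_id = seq_along(cols),
                    family = vapply(cols, `[[`, character(1L), "family"),
                    n_present = rowSums(states != "absent"),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(states, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Sharing spectrum of panel insertion columns
#'
#' The proportion of insertion columns present in exactly `k` of the
#' `panel_size` genotypes, `k = 1..panel_size`. With
#' `full_length_only = TRUE`, only columns that are full length in at least
#' one genotype are counted — a copy full length in one genotype but
#' fragmented in others still counts as shared, matching the convention
#' used for private/shared full-length TE reporting.
#'
#' @param columns Panel `data.frame` from [build_panel()].
#' @param panel_size Number of genotypes.
#' @param full_length_only Restrict to columns full length somewhere.
#' @return Named numeric vector of proportions (`"1"` .. `panel_size`),
#'   summing to 1.
#' @export
sharing_spectrum <- function(columns, panel_size, full_length_only = FALSE) {
  .assert(panel_size >= 2L, "panel_size must be >= 2")
  .assert(nrow(columns) > 0L, "sharing_spectrum: empty column set")
  if (full_length_only) {
    st <- as.matrix(columns[, grep("^state_", names(columns)), drop = FALSE])
    columns <- columns[rowSums(st == "full_length") > 0L, , drop = FALSE]
    .assert(nrow(columns) > 0L, "sharing_spectrum: no full-length columns")
  }
  tab <- table(factor(columns$n_present, levels = seq_len(panel_size)))
  prop <- as.numeric(tab) / nrow(columns)
  setNames(prop, seq_len(panel_size))
}

#' Percent identity between two sequences
#'
#' Global (Needleman-Wunsch) alignment with unit match/mismatch scores and
#' a flat unit gap cost, then identity = matching columns / columns where
#' both sequences have a base (gap columns excluded by default). The pair is
#' canonically ordered before aligning, so the result is exactly symmetric
#' in its arguments.
#'
#' @param seq_a,seq_b Nucleotide strings, non-empty.
#' @param include_gap_columns Count gap columns in the denominator
#'   (default `FALSE`).
#' @return Identity fraction in `[0, 1]`.
#' @export
percent_identity <- function(seq_a, seq_b, include_gap_columns = FALSE) {
  .assert(nchar(seq_a) >= 1L && nchar(seq_b) >= 1L, "empty sequence")
  pair <- sort(c(toupper(seq_a), toupper(seq_b)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(pair[1L], pair[2L], type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  both <- p != "-" & s != "-"
  matches <- sum(p[both] == s[both])
  denom <- if (include_gap_columns) length(p) else sum(both)
  matches / denom
}

#' Parameters for horizontal-transfer calling
#'
#' @param ht_threshold Identity above which (strictly) a cross-species TE
#'   pair is called horizontally transferred (default 0.98).
#' @param baseline_range Identity range expected under vertical descent,
#'   e.g. 0.93-0.97 as observed for the strictly vertically transmitted R1
#'   element across the melanogaster subgroup. A warning is emitted when the
#'   baseline reaches the threshold.
#' @return List of class `ht_params`.
#' @export
ht_params <- function(ht_threshold = 0.98, baseline_range = c(0.93, 0.97)) {
  .assert(ht_threshold > 0 && ht_threshold <= 1, "ht_threshold must be in (0,1]")
  if (max(baseline_range) >= ht_threshold)
    warning("vertical-descent baseline overlaps ht_threshold; calls may be unreliable")
  structure(list(ht_threshold = ht_threshold, baseline_range = baseline_range),
            class = "ht_params")
}

#' Classify a TE pair as horizontally or vertically transferred
#'
#' Horizontal iff identity is strictly greater than the threshold (`> 98%`
#' by default); identity exactly at the threshold is vertical. Direction of
#' transfer is never inferred.
#'
#' @param identity Fraction in `[0, 1]` ([percent_identity()]).
#' @param params [ht_params()].
#' @return `"horizontal"` or `"vertical"` (vectorized over `identity`).
#' @export
ht_classify <- function(identity, params = ht_params()) {
  .assert(all(identity >= 0 & identity <= 1), "identity must be in [0, 1]")
  ifelse(identity > params$ht_threshold, "horizontal", "vertical")
}

#' In-silico restriction digest with a degenerate recognition motif
#'
#' Finds every match of an IUPAC motif on the forward strand of `seq`
#' (case-insensitive), places a cut `cut_offset` bases into each match, and
#' returns fragment lengths 5' to 3'. E.g. BsaAI recognizes `YACGTR` and
#' cuts after position 3 (`YAC^GTR`); a 1-kb amplicon with one site at cut
#' coordinate 750 yields fragments of 750 and 250 bp.
#'
#' @param seq Nucleotide string.
#' @param motif IUPAC motif (e.g. `"YACGTR"`).
#' @param cut_offset Bases into the motif at which the cut falls, in
#'   `[0, nchar(motif)]`.
#' @return Integer vector of fragment lengths, summing to `nchar(seq)`.
#' @export
digest_fragments <- function(seq, motif, cut_offset) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  .assert(all(strsplit(motif, "")[[1L]] %in% names(.IUPAC)),
          "invalid IUPAC character in motif")
  .assert(cut_offset >= 0 && cut_offset <= nchar(motif),
          "cut_offset must be in [0, motif length]")
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(seq), fixed = FALSE)
  len <- nchar(seq)
  cuts <- sort(unique(Biostrings::start(m) - 1L + as.integer(cut_offset)))
  cuts <- cuts[cuts > 0L & cuts < len]
  as.integer(diff(c(0L, cuts, len)))
}
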