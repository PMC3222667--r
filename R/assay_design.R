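## assay_design: flank extraction, Q score, surrogate design score, panel
## selection.

#' Assay design criteria
#'
#' Thresholds for panel selection: candidates need a full `flank_bp` flank on
#' both sides (the bead-array genotyping assay requires 60 clean bases either
#' side of the SNP), a design score of at least `score_floor` (0.4; scores
#' above `score_preferred`, 0.7, are preferentially selected), and — unless
#' `allow_ie_intron` — an intron-exon code other than "0" (intron predicted
#' inside the target region).
#'
#' @param flank_bp flank length either side of the SNP (default 60).
#' @param score_floor minimum design score (default 0.4).
#' @param score_preferred preferred design score (default 0.7).
#' @param q_max optional maximum flank mismatch count Q.
#' @param allow_ie_intron keep candidates with a predicted intron in the
#'   target region (default FALSE).
#' @return list of class `design_criteria`.
#' @export
design_criteria <- function(flank_bp = 60L, score_floor = 0.4,
                            score_preferred = 0.7, q_max = NULL,
                            allow_ie_intron = FALSE) {
  stopifnot(flank_bp >= 1, score_floor >= 0, score_floor <= score_preferred,
            score_preferred <= 1)
  structure(list(flank_bp = as.integer(flank_bp), score_floor = score_floor,
                 score_preferred = score_preferred, q_max = q_max,
                 allow_ie_intron = isTRUE(allow_ie_intron)),
            class = "design_criteria")
}

#' Extract the target region around a SNP
#'
#' Returns the `2 * flank + 1` base window centred on the SNP when both
#' flanks fit inside the contig, `NA` otherwise (absence is a value: such
#' candidates are unsuitable for assay design, not errors).
#'
#' @param sequence contig sequence.
#' @param position 0-based SNP position.
#' @param flank flank length (default 60).
#' @return target string, or `NA_character_`.
#' @export
extract_target <- function(sequence, position, flank = 60L) {
  n <- nchar(sequence)
  stopifnot(position >= 0, position < n)
  if (position - flank < 0 || position + flank > n - 1) return(NA_character_)
  substr(sequence, position - flank + 1L, position + flank + 1L)
}

#' Flank mismatch count Q
#'
#' Q counts the positions within `window` bases of a SNP (the SNP column
#' itself excluded) at which at least one aligned read disagrees with the
#' column consensus. The consensus is the plurality nucleotide (ties broken
#' lexicographically); ambiguous (`N`) and gap observations always count as
#' disagreeing. Q is a sequence-quality predictor of assay outcome: the more
#' mismatch-bearing flank columns, the poorer the local alignment. Mode
#' `"bases"` counts disagreeing bases instead of affected positions.
#'
#' @param pileup pileup rows of one contig.
#' @param position 0-based SNP position.
#' @param window flank window either side (default 60).
#' @param mode `"positions"` (default) or `"bases"`.
#' @return non-negative integer.
#' @export
compute_q <- function(pileup, position, window = 60L,
                      mode = c("positions", "bases")) {
  mode <- match.arg(mode)
  if (uniqueN(pileup$contig_id) > 1) stop("pileup must cover a single contig")
  win <- pileup[pos != position & abs(pos - position) <= window]
  if (nrow(win) == 0) return(0L)
  per_col <- win[, {
    nuc <- base[base %chin% CALL_BASES]
    if (length(nuc)) {
      tab <- table(nuc)
      cons <- sort(names(tab)[tab == max(tab)])[1]
      mism <- sum(base != cons)
    } else {
      mism <- .N   # only ambiguous/gap observations: all disagree
    }
    list(mism = mism)
  }, by = pos]
  if (mode == "positions") sum(per_col$mism > 0L) else sum(per_col$mism)
}

#' Canonical k-mer index over a contig set
#'
#' Counts occurrences of each canonical k-mer (the lexicographic minimum of a
#' k-mer and its reverse complement) across all contigs; used by the
#' uniqueness component of [surrogate_design_score()].
#'
#' @param contigs named character vector of contig sequences.
#' @param k k-mer size (default 15).
#' @return data.table with columns `kmer`, `n`, and attribute `k`.
#' @export
kmer_index <- function(contigs, k = 15L) {
  km <- unlist(lapply(contigs, seq_kmers, k = k), use.names = FALSE)
  if (length(km) == 0) {
    idx <- data.table(kmer = character(), n = integer())
  } else {
    km <- pmin(km, revcomp(km))
    idx <- data.table(kmer = km)[, .(n = .N), by = kmer]
  }
  setattr(idx, "k", as.integer(k))
  setkey(idx, kmer)
  idx[]
}

## longest self-complementary stem with a loop of >= min_loop bases.
## Runs of complementary pairs (i, j), i < j, lie on anti-diagonals of
## constant i + j, so each anti-diagonal is scanned for its longest
## consecutive run subject to the innermost-pair loop constraint.
longest_stem <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  if (n < 2L * 1L + min_loop) return(0L)
  v <- utf8ToInt(toupper(seq))
  comp <- integer(128)
  comp[utf8ToInt("A")] <- utf8ToInt("T"); comp[utf8ToInt("T")] <- utf8ToInt("A")
  comp[utf8ToInt("C")] <- utf8ToInt("G"); comp[utf8ToInt("G")] <- utf8ToInt("C")
  best <- 0L
  for (s in 3:(2L * n - 1L)) {            # s = i + j (1-based indices)
    tmax <- floor((s - 1L - min_loop) / 2)
    if (tmax < 1L) next
    t <- seq_len(min(tmax, n))
    j <- s - t
    ok <- j >= 1L & j <= n & j > t
    t <- t[ok]
    if (!length(t)) next
    pair <- comp[v[t]] == v[s - t] & v[t] %in% comp[comp > 0]
    if (!any(pair)) next
    r <- rle(pair)
    best <- max(best, max(r$lengths[r$values]))
  }
  as.integer(best)
}

#' Surrogate assay design score
#'
#' A documented, deterministic stand-in for proprietary assay-design scoring,
#' range-matched to \[0, 1\] so the standard thresholds (floor 0.4, preferred
#' 0.7) apply unchanged. Weighted mean of four sub-scores:
#'
#' * **gc** — proximity of target GC content to the \[0.35, 0.65\] band
#'   (linear decay, zero at 0.35 outside the band).
#' * **tm** — proximity of each 60-mer flank's GC-approximated melting
#'   temperature (64.9 + 41 (GC - 16.4) / L) to the common window
#'   \[70, 80\] degrees C (linear decay over 15 degrees).
#' * **uniqueness** — 1 minus the fraction of the target's canonical 15-mers
#'   that occur elsewhere in the contig set (1 when no index is supplied).
#' * **hairpin** — 1 minus the normalized longest self-complementary stem
#'   (loop of at least 3 bases); stems shorter than 6 bases are ignored.
#'
#' @param target target region string (odd length, SNP centred), see
#'   [extract_target()].
#' @param index optional [kmer_index()] over the contig set.
#' @param weights numeric length-4 weights for (gc, tm, uniqueness, hairpin);
#'   default equal.
#' @param max_ambiguous maximum tolerated ambiguous (`N`) bases (default 2).
#' @return score in \[0, 1\] with attribute `components`.
#' @export
surrogate_design_score <- function(target, index = NULL,
                                   weights = rep(0.25, 4), max_ambiguous = 2L) {
  if (is.na(target) || !nzchar(target)) {
    stop("target region absent; filter such candidates upstream")
  }
  target <- toupper(target)
  n <- nchar(target)
  if (n %% 2L == 0L) stop("target must have odd length (SNP centred)")
  ch <- strsplit(target, "")[[1]]
  n_amb <- sum(!ch %in% CALL_BASES)
  if (n_amb > max_ambiguous) {
    stop("target has ", n_amb, " ambiguous bases (max ", max_ambiguous, ")")
  }
  stopifnot(length(weights) == 4, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  band_dist <- function(x, lo, hi) pmax(0, pmax(lo - x, x - hi))
  gc_frac <- function(x) {
    v <- strsplit(x, "")[[1]]
    mean(v %in% c("G", "C"))
  }
  s_gc <- max(0, 1 - band_dist(gc_frac(target), 0.35, 0.65) / 0.35)
  flank_len <- (n - 1L) / 2L
  fl <- substr(target, 1L, flank_len)
  fr <- substr(target, flank_len + 2L, n)
  tm <- function(x) {
    L <- nchar(x)
    64.9 + 41 * (sum(strsplit(x, "")[[1]] %in% c("G", "C")) - 16.4) / L
  }
  s_tm <- mean(vapply(c(fl, fr), function(x) {
    max(0, 1 - band_dist(tm(x), 70, 80) / 15)
  }, numeric(1)))
  ## uniqueness: a target k-mer position is non-unique when its canonical
  ## k-mer occurs anywhere else — elsewhere in the contig set when an index
  ## is supplied, or at another position of the target itself otherwise
  k <- if (is.null(index)) 15L else attr(index, "k")
  tk <- seq_kmers(target, k)
  if (length(tk) == 0) {
    s_uniq <- 1
  } else {
    tk_canon <- pmin(tk, revcomp(tk))
    own <- data.table(kmer = tk_canon)[, .(n_own = .N), by = kmer]
    if (is.null(index)) {
      own[, n := n_own]
    } else {
      own <- index[own, on = "kmer"]
      own[is.na(n), n := n_own]
      own[, n := pmax(n, n_own)]
    }
    s_uniq <- 1 - own[, sum(n_own * (n > 1L))] / length(tk)
  }
  stem <- longest_stem(target)
  max_stem <- floor((n - 3L) / 2)
  s_hp <- if (stem < 6L) 1 else 1 - (stem - 5L) / max(1L, max_stem - 5L)
  comp <- c(gc = s_gc, tm = s_tm, uniqueness = s_uniq, hairpin = max(0, s_hp))
  out <- sum(weights * comp)
  attr(out, "components") <- comp
  out
}

## deterministic composite ordering used for within-contig ranks and global
## fill: lower Q, preferred-score tier, higher score, greater distance to the
## nearest other candidate in the contig, higher depth, then position.
composite_order <- function(cand, criteria) {
  q <- fifelse(is.na(cand$q_score), Inf, as.numeric(cand$q_score))
  preferred <- fifelse(is.na(cand$snp_score), 0,
                       as.numeric(cand$snp_score > criteria$score_preferred))
  scr <- fifelse(is.na(cand$snp_score), -Inf, cand$snp_score)
  dist <- fifelse(is.na(cand$nn_dist), Inf, as.numeric(cand$nn_dist))
  order(q, -preferred, -scr, -dist, -cand$depth, cand$contig_id, cand$pos)
}

#' Select and rank a genotyping assay panel
#'
#' Drops candidates with an absent target region, design score below
#' `score_floor`, a predicted intron in the target region (unless
#' `allow_ie_intron`), or Q above `q_max` (when set; candidates without a
#' computed Q are kept). Survivors are ranked within each contig by a
#' deterministic composite — lower Q first, candidates above
#' `score_preferred` outrank others at equal Q, then higher score, greater
#' distance to the nearest other surviving candidate in the contig, higher
#' depth. The panel takes the best-ranked candidate of each contig first
#' (spreading loci across contigs), then fills by the same global composite
#' until `panel_size`.
#'
#' @param candidates descriptor table (needs `target_region`, `snp_score`,
#'   `q_score`, `ie_code` filled as available).
#' @param criteria [design_criteria()].
#' @param panel_size number of assays to select.
#' @return data.table of selected candidates with `rank` (within-contig,
#'   1 = best) and `panel_order` columns, ordered by `panel_order`. If fewer
#'   candidates survive than `panel_size`, all survivors are returned with a
#'   warning.
#' @export
select_panel <- function(candidates, criteria = design_criteria(),
                         panel_size) {
  stopifnot(panel_size >= 1)
  cand <- as.data.table(copy(candidates))
  keep <- !is.na(cand$target_region) &
    !is.na(cand$snp_score) & cand$snp_score >= criteria$score_floor &
    (criteria$allow_ie_intron | is.na(cand$ie_code) | cand$ie_code != "0")
  if (!is.null(criteria$q_max)) {
    keep <- keep & (is.na(cand$q_score) | cand$q_score <= criteria$q_max)
  }
  cand <- cand[keep]
  if (nrow(cand) == 0) {
    warning("no candidates survive the design criteria")
    cand[, `:=`(nn_dist = integer(), panel_order = integer())]
    return(cand[])
  }
  ## distance to nearest other surviving candidate in the same contig
  cand[, nn_dist := {
    if (.N == 1L) NA_integer_ else {
      d <- vapply(seq_len(.N), function(i) min(abs(pos[i] - pos[-i])), numeric(1))
      as.integer(d)
    }
  }, by = contig_id]
  ord <- composite_order(cand, criteria)
  cand <- cand[ord]
  cand[, rank := seq_len(.N), by = contig_id]
  ## rows are in global composite order; a stable sort by within-contig rank
  ## puts every contig's best candidate first (in composite order), then the
  ## second-best tier, and so on
  cand <- cand[order(rank)]
  if (nrow(cand) < panel_size) {
    warning("only ", nrow(cand), " candidates survive; panel_size was ",
            panel_size)
    panel_size <- nrow(cand)
  }
  panel <- cand[seq_len(panel_size)]
  panel[, panel_order := seq_len(.N)]
  panel[, nn_dist := NULL]
  panel[]
}
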