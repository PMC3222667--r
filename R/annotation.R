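## comparative_annotation: reference sets, intron-exon boundary prediction,
## effect classification, mitochondrial flagging, GO enrichment.

#' Reference sequence set of one model species
#'
#' Container for the comparative-annotation resources of one species: genome
#' scaffolds, transcriptome, an optional transcript-to-genome exon map, and a
#' proteome.
#'
#' @param species_id species label.
#' @param genome named character vector of genome scaffolds.
#' @param transcriptome named character vector of transcripts.
#' @param exon_map optional data.frame with columns `transcript_id`,
#'   `t_start`, `t_end` (0-based half-open transcript coordinates of each
#'   exon, in transcript order), and optionally `genome_id`, `g_start`,
#'   `g_end`, `strand`.
#' @param proteome named character vector of peptide sequences.
#' @return list of class `reference_set`.
#' @export
reference_set <- function(species_id, genome = NULL, transcriptome = NULL,
                          exon_map = NULL, proteome = NULL) {
  if (!is.null(exon_map)) {
    exon_map <- as.data.table(exon_map)
    stopifnot(all(c("transcript_id", "t_start", "t_end") %in% names(exon_map)))
    bad <- exon_map[, {
      o <- order(t_start)
      any(diff(t_start[o]) <= 0) || any(t_end[o][-.N] > t_start[o][-1]) ||
        any(t_end <= t_start)
    }, by = transcript_id]
    if (any(bad$V1)) {
      stop("exon map intervals must be non-overlapping and ordered per transcript")
    }
  }
  structure(list(species_id = species_id, genome = genome,
                 transcriptome = transcriptome, exon_map = exon_map,
                 proteome = proteome),
            class = "reference_set")
}

#' Read external tabular alignment hits
#'
#' Adapter for the standard 12-column tabular hit layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score; 1-based closed coordinates, subject
#' coordinates reversed on minus-strand hits). Converts to the package's HSP
#' schema so an external aligner can stand in for the built-in one.
#'
#' @param path tabular hits file (no header).
#' @param max_evalue significance cutoff (default 1e-5).
#' @return data.table in [find_hsps()] layout plus `query_id` and `evalue`.
#' @export
read_tabular_hits <- function(path, max_evalue = 1e-5) {
  x <- fread(path, header = FALSE, sep = "\t", showProgress = FALSE)
  setnames(x, c("query_id", "subject_id", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore"))
  x <- x[evalue <= max_evalue]
  minus <- x$sstart > x$send
  ss <- ifelse(minus, x$send, x$sstart)
  se <- ifelse(minus, x$sstart, x$send)
  data.table(
    query_id = x$query_id, subject_id = x$subject_id,
    strand = ifelse(minus, "-", "+"),
    qstart = x$qstart - 1L, qend = x$qend,
    sstart = ss - 1L, send = se,
    score = x$bitscore, n_ident = round(x$length * x$pident / 100),
    length = x$length, evalue = x$evalue
  )
}

#' Intron-exon boundary prediction, genome route
#'
#' Compares the SNP-containing contig against a species' genome scaffolds.
#' If any single local hit's query span contains the full SNP window
#' (`flank` bases either side), the SNP is coded `"1"` (embedded in a single
#' exon); if significant hits exist but none covers the window, an intron is
#' assumed inside the target region and the code is `"0"`; with no
#' significant hit the code is `"no"`.
#'
#' @param contig contig sequence.
#' @param position 0-based SNP position (must have a full target region).
#' @param genome named character vector of genome scaffolds.
#' @param flank window half-width (default 60).
#' @param hits optional precomputed hit table ([find_hsps()] layout, e.g.
#'   from [read_tabular_hits()]) replacing the built-in aligner.
#' @param ... passed to [find_hsps()].
#' @return one of `"1"`, `"0"`, `"no"`.
#' @export
ie_route_a <- function(contig, position, genome, flank = 60L, hits = NULL, ...) {
  if (is.null(hits)) {
    if (length(genome) == 0) return("no")
    hits <- find_hsps(contig, genome, ...)
  }
  if (nrow(hits) == 0) return("no")
  covered <- any(hits$qstart <= position - flank &
                   hits$qend >= position + flank + 1L)
  if (covered) "1" else "0"
}

#' Intron-exon boundary prediction, transcript route
#'
#' Maps the SNP onto the best-matching homolog transcript via the alignment
#' coordinates, then locates the mapped position within the transcript's exon
#' structure: from the reference exon map when available, otherwise from
#' aligning the transcript to its own genome (each resulting local hit span
#' is treated as one exon). Coded `"1"` when the window of `flank` transcript
#' bases either side of the mapped position (clipped at the transcript ends)
#' lies in one exon, `"0"` when an exon boundary interrupts it, `"no"` when
#' there is no significant homolog or the SNP falls outside the aligned
#' region.
#'
#' @inheritParams ie_route_a
#' @param refset [reference_set()] with a transcriptome (and exon map or
#'   genome).
#' @param tx_index optional prebuilt [subject_index()] of the transcriptome
#'   (speeds up repeated calls).
#' @return one of `"1"`, `"0"`, `"no"`.
#' @export
ie_route_b <- function(contig, position, refset, flank = 60L,
                       tx_index = NULL, ...) {
  if (is.null(refset$transcriptome) || length(refset$transcriptome) == 0) {
    return("no")
  }
  best <- local_align(contig, refset$transcriptome, index = tx_index, ...)
  if (is.null(best)) return("no")
  if (position < best$qstart || position >= best$qend) return("no")
  tpos <- if (best$strand == "+") {
    best$sstart + (position - best$qstart)
  } else {
    best$send - 1L - (position - best$qstart)
  }
  tid <- best$subject_id
  tlen <- nchar(refset$transcriptome[[tid]])
  w0 <- max(0L, tpos - flank)
  w1 <- min(tlen - 1L, tpos + flank)
  exons <- NULL
  if (!is.null(refset$exon_map) && tid %in% refset$exon_map$transcript_id) {
    em <- refset$exon_map[refset$exon_map$transcript_id == tid]
    exons <- em[order(em$t_start), .(t_start, t_end)]
  } else if (!is.null(refset$genome) && length(refset$genome)) {
    th <- find_hsps(refset$transcriptome[[tid]], refset$genome, ...)
    if (nrow(th)) exons <- th[order(qstart), .(t_start = qstart, t_end = qend)]
  }
  if (is.null(exons) || nrow(exons) == 0) return("no")
  ## single exon iff one exon span contains the whole (clipped) window
  covered <- any(exons$t_start <= w0 & exons$t_end >= w1 + 1L)
  if (covered) "1" else "0"
}

#' Combine per-species intron-exon codes
#'
#' Precedence `1 > 0 > no`: the SNP is coded single-exon as soon as at least
#' one comparison places its full window in one exon; otherwise
#' intron-disrupted if any comparison predicts an intron; `no` only when no
#' species gave a significant match. Codes from both prediction routes are
#' pooled before applying precedence. `ie_species_match` counts species with
#' a significant match in any route, and is 0 exactly when the combined code
#' is `"no"`.
#'
#' @param codes data.frame with columns `species` and `code` (one row per
#'   species per route; codes in `"1"`, `"0"`, `"no"`).
#' @return list with `ie_code` and `ie_species_match`.
#' @export
combine_ie <- function(codes) {
  codes <- as.data.table(codes)
  if (nrow(codes) == 0) return(list(ie_code = "no", ie_species_match = 0L))
  stopifnot(all(codes$code %in% c("1", "0", "no")))
  ie <- if (any(codes$code == "1")) "1" else if (any(codes$code == "0")) "0" else "no"
  nm <- uniqueN(codes[code != "no", species])
  list(ie_code = ie, ie_species_match = as.integer(nm))
}

## five physico-chemical amino-acid classes
AA_CLASSES <- list(
  nonpolar = c("G", "A", "V", "L", "I", "P", "M", "C"),
  polar    = c("S", "T", "N", "Q"),
  negative = c("D", "E"),
  positive = c("K", "R", "H"),
  aromatic = c("F", "W", "Y")
)

aa_class <- function(aa, classes = AA_CLASSES) {
  hit <- names(classes)[vapply(classes, function(cl) aa %in% cl, logical(1))]
  if (length(hit)) hit[1] else NA_character_
}

#' Classify a codon substitution
#'
#' Translates both codons with the standard genetic code and classifies the
#' substitution: `SYNONYMOUS` (same residue), `NONSYN_CONSERVATIVE`
#' (different residue, same physico-chemical class among non-polar, polar,
#' negative, positive, aromatic), `NONSYN_NONCONSERVATIVE` (class change; a
#' gained or lost stop codon is non-conservative with `nonsense = TRUE`).
#'
#' @param codon_ref,codon_alt three-base codons differing at one position.
#' @param classes amino-acid class table (default the five-class scheme with
#'   His positive and Cys/Met non-polar).
#' @return list: `aa_ref`, `aa_alt`, `classification`, `nonsense`.
#' @export
classify_codon_pair <- function(codon_ref, codon_alt, classes = AA_CLASSES) {
  gc_tab <- Biostrings::GENETIC_CODE
  aa_r <- unname(gc_tab[toupper(codon_ref)])
  aa_a <- unname(gc_tab[toupper(codon_alt)])
  if (is.na(aa_r) || is.na(aa_a)) {
    return(list(aa_ref = NA_character_, aa_alt = NA_character_,
                classification = "UNKNOWN", nonsense = FALSE))
  }
  if (aa_r == aa_a) {
    cls <- "SYNONYMOUS"; nons <- FALSE
  } else if (aa_r == "*" || aa_a == "*") {
    cls <- "NONSYN_NONCONSERVATIVE"; nons <- TRUE
  } else if (identical(aa_class(aa_r, classes), aa_class(aa_a, classes))) {
    cls <- "NONSYN_CONSERVATIVE"; nons <- FALSE
  } else {
    cls <- "NONSYN_NONCONSERVATIVE"; nons <- FALSE
  }
  list(aa_ref = aa_r, aa_alt = aa_a, classification = cls, nonsense = nons)
}

#' Amino-acid effect of a SNP
#'
#' Infers the contig's reading frame by translating all six frames and
#' locally aligning each translation against the supplied peptides (BLOSUM62,
#' affine gaps); the best-scoring frame/peptide pair above `min_score` fixes
#' frame and strand. The codon containing the SNP is then translated for both
#' alleles and the substitution classified with [classify_codon_pair()].
#' `UNKNOWN` results when no peptide match passes the cutoff or the SNP codon
#' falls outside the aligned coding region.
#'
#' @param contig contig sequence.
#' @param position 0-based SNP position.
#' @param major,minor the two alleles (major = contig consensus base).
#' @param proteome named character vector of peptide sequences (pool several
#'   species' peptides to raise the chance of a match).
#' @param min_score minimum protein-alignment score (default 50).
#' @param classes amino-acid class table.
#' @return list of class `effect_call`: `classification`, `strand`, `frame`,
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `nonsense`, `subject_id`,
#'   `score`.
#' @export
classify_effect <- function(contig, position, major, minor, proteome,
                            min_score = 50, classes = AA_CLASSES) {
  unknown <- structure(list(classification = "UNKNOWN", strand = NA_character_,
                            frame = NA_integer_, codon_ref = NA_character_,
                            codon_alt = NA_character_, aa_ref = NA_character_,
                            aa_alt = NA_character_, nonsense = FALSE,
                            subject_id = NA_character_, score = NA_real_),
                       class = "effect_call")
  if (length(proteome) == 0) return(unknown)
  contig <- toupper(contig)
  n <- nchar(contig)
  subj <- Biostrings::AAStringSet(toupper(proteome))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (f in 0:2) {
      len <- ((n - f) %/% 3L) * 3L
      if (len < 30L) next
      pep <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1L, f + len)),
        if.fuzzy.codon = "X")))
      al <- Biostrings::pairwiseAlignment(
        subj, Biostrings::AAString(pep), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4)
      sc <- Biostrings::score(al)
      j <- which.max(sc)
      if (length(j) && sc[j] >= min_score &&
          (is.null(best) || sc[j] > best$score)) {
        sr <- al[j]
        best <- list(strand = strand, frame = f, score = sc[j],
                     subject_id = names(proteome)[j],
                     pep_start = Biostrings::start(Biostrings::subject(sr)),
                     pep_end = Biostrings::end(Biostrings::subject(sr)))
      }
    }
  }
  if (is.null(best)) return(unknown)
  s <- if (best$strand == "+") contig else revcomp(contig)
  p <- if (best$strand == "+") position else n - 1L - position
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  alt <- if (best$strand == "+") toupper(minor) else comp[[toupper(minor)]]
  if (p < best$frame) return(unknown)
  codon_idx <- (p - best$frame) %/% 3L
  c0 <- best$frame + 3L * codon_idx             # 0-based codon start
  if (c0 + 3L > n) return(unknown)
  pep_pos <- codon_idx + 1L
  if (pep_pos < best$pep_start || pep_pos > best$pep_end) return(unknown)
  codon_ref <- substr(s, c0 + 1L, c0 + 3L)
  off <- p - c0
  codon_alt <- codon_ref
  substr(codon_alt, off + 1L, off + 1L) <- alt
  cl <- classify_codon_pair(codon_ref, codon_alt, classes)
  structure(list(classification = cl$classification, strand = best$strand,
                 frame = best$frame, codon_ref = codon_ref,
                 codon_alt = codon_alt, aa_ref = cl$aa_ref, aa_alt = cl$aa_alt,
                 nonsense = cl$nonsense, subject_id = best$subject_id,
                 score = best$score),
            class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat("<effect_call> ", x$classification,
      if (!is.na(x$codon_ref)) paste0("  ", x$codon_ref, ">", x$codon_alt,
                                      " (", x$aa_ref, ">", x$aa_alt, ")"),
      if (x$nonsense) "  [nonsense]", "\n", sep = "")
  invisible(x)
}

#' Flag mitochondrial contigs
#'
#' A contig is flagged mitochondrial when its best local hit against the
#' mitochondrial reference passes the score cutoff. Flagged contigs are
#' excluded from nuclear panels and nuclear statistics downstream.
#'
#' @param contigs named character vector of contig sequences.
#' @param mito_reference mitochondrial genome sequence(s).
#' @param min_score minimum hit score (default 60).
#' @param ... passed to [local_align()].
#' @return named logical vector.
#' @export
flag_mitochondrial <- function(contigs, mito_reference, min_score = 60L, ...) {
  if (is.null(names(mito_reference))) names(mito_reference) <- "mito"
  idx <- subject_index(mito_reference)
  vapply(contigs, function(s) {
    !is.null(local_align(s, index = idx, min_score = min_score, ...))
  }, logical(1))
}

#' Term enrichment of a test contig set against a reference set
#'
#' For every annotation term, a 2x2 table (test vs reference x has-term vs
#' not, counting contigs) is tested with Fisher's exact test; p-values are
#' corrected with the Benjamini-Hochberg false discovery rate. Terms absent
#' from both sets are skipped.
#'
#' @param test_annotations data.frame (`contig_id`, `term`) for the test set
#'   (e.g. SNP-containing contigs).
#' @param reference_annotations same layout for the reference set (e.g. all
#'   contigs).
#' @param fdr_threshold enrichment call threshold (default 0.05).
#' @return data.table per term: counts, `odds`, `p`, `fdr`, `enriched`,
#'   sorted by `p`.
#' @export
go_enrichment <- function(test_annotations, reference_annotations,
                          fdr_threshold = 0.05) {
  te <- as.data.table(test_annotations)
  re <- as.data.table(reference_annotations)
  stopifnot(all(c("contig_id", "term") %in% names(te)),
            all(c("contig_id", "term") %in% names(re)))
  n_test <- uniqueN(te$contig_id)
  n_ref <- uniqueN(re$contig_id)
  terms <- union(unique(te$term), unique(re$term))
  if (length(terms) == 0 || n_test == 0 || n_ref == 0) {
    return(data.table(term = character(), test_with = integer(),
                      test_without = integer(), ref_with = integer(),
                      ref_without = integer(), odds = numeric(),
                      p = numeric(), fdr = numeric(), enriched = logical()))
  }
  te_n <- te[, .(a = uniqueN(contig_id)), by = term]
  re_n <- re[, .(c = uniqueN(contig_id)), by = term]
  tab <- data.table(term = terms)
  tab <- te_n[tab, on = "term"]
  tab <- re_n[tab, on = "term"]
  tab[is.na(a), a := 0L]; tab[is.na(c), c := 0L]
  tab[, `:=`(b = n_test - a, d = n_ref - c)]
  tab[, p := mapply(function(a, b, c, d) {
    fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }, a, b, c, d)]
  tab[, odds := (a / pmax(b, 1)) / pmax(c / pmax(d, 1), .Machine$double.eps)]
  tab[, fdr := p.adjust(p, method = "BH")]
  tab[, enriched := fdr < fdr_threshold & odds > 1]
  out <- tab[, .(term, test_with = a, test_without = b, ref_with = c,
                 ref_without = d, odds, p, fdr, enriched)]
  setorder(out, p)
  out[]
}

#' Annotate a candidate table with intron-exon codes and mitochondrial flags
#'
#' Convenience wrapper running both intron-exon prediction routes against
#' every supplied reference set, pooling the per-species codes with
#' [combine_ie()], and (when a mitochondrial reference is given) adding an
#' `is_mito` column from [flag_mitochondrial()]. Candidates without a full
#' target region keep `ie_code = NA`.
#'
#' @param candidates candidate table (needs `contig_id`, `pos`).
#' @param contigs named character vector of contig sequences.
#' @param refsets list of [reference_set()] objects (one per model species).
#' @param mito_reference optional mitochondrial reference sequence(s).
#' @param flank window half-width (default 60).
#' @param ... passed to the aligner ([find_hsps()]).
#' @return the candidate table with `ie_code`, `ie_species_match` (and
#'   `is_mito`) filled.
#' @export
annotate_candidates <- function(candidates, contigs, refsets,
                                mito_reference = NULL, flank = 60L, ...) {
  cand <- copy(as.data.table(candidates))
  stopifnot(all(cand$contig_id %in% names(contigs)))
  has_target <- cand$pos >= flank &
    cand$pos <= nchar(contigs[cand$contig_id]) - flank - 1L
  g_idx <- lapply(refsets, function(rs) {
    if (!is.null(rs$genome)) subject_index(rs$genome) else NULL
  })
  t_idx <- lapply(refsets, function(rs) {
    if (!is.null(rs$transcriptome)) subject_index(rs$transcriptome) else NULL
  })
  ## genome-route hits are a per-(contig, species) property; cache them
  hit_cache <- new.env(parent = emptyenv())
  codes <- lapply(which(has_target), function(i) {
    cid <- cand$contig_id[i]; p <- cand$pos[i]
    per <- lapply(seq_along(refsets), function(r) {
      rs <- refsets[[r]]
      a <- if (!is.null(rs$genome)) {
        key <- paste0(r, "|", cid)
        hits <- if (exists(key, hit_cache)) get(key, hit_cache) else {
          h <- find_hsps(contigs[[cid]], index = g_idx[[r]], ...)
          assign(key, h, hit_cache); h
        }
        ie_route_a(contigs[[cid]], p, rs$genome, flank = flank, hits = hits)
      } else NULL
      b <- if (!is.null(rs$transcriptome)) {
        ie_route_b(contigs[[cid]], p, rs, flank = flank,
                   tx_index = t_idx[[r]], ...)
      } else NULL
      data.table(species = rs$species_id, code = c(a, b))
    })
    combine_ie(rbindlist(per))
  })
  cand[, ie_code := NA_character_]
  cand[, ie_species_match := NA_integer_]
  if (length(codes)) {
    cand$ie_code[has_target] <- vapply(codes, `[[`, character(1), "ie_code")
    cand$ie_species_match[has_target] <-
      vapply(codes, `[[`, integer(1), "ie_species_match")
  }
  if (!is.null(mito_reference)) {
    mito <- flag_mitochondrial(contigs[unique(cand$contig_id)], mito_reference, ...)
    cand[, is_mito := mito[contig_id]]
  }
  cand[]
}
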