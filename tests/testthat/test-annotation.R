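test_that("route A codes single-exon, intron-disrupted and no-match cases", {
  set.seed(31)
  ctg <- rnd_seq(400)
  ## genome identical to the contig: every full-flank SNP is single-exon
  for (p in c(60L, 200L, 339L)) {
    expect_equal(ie_route_a(ctg, p, c(g = ctg)), "1")
  }
  ## 500-bp insert 10 bp downstream of the SNP disrupts the target region
  snp <- 200L
  cut <- snp + 10L
  gen <- paste0(substr(ctg, 1, cut), rnd_seq(500),
                substr(ctg, cut + 1, nchar(ctg)))
  expect_equal(ie_route_a(ctg, snp, c(g = gen)), "0")
  ## but a SNP far from the insert stays single-exon
  expect_equal(ie_route_a(ctg, 100L, c(g = gen)), "1")
  ## unrelated genome: no significant match
  expect_equal(ie_route_a(ctg, snp, c(g = rnd_seq(400))), "no")
})

test_that("route B maps the SNP through the homolog and its exon structure", {
  set.seed(32)
  ctg <- rnd_seq(300)
  ## single-exon transcript identical to the contig
  rs1 <- reference_set("sp1", transcriptome = c(t1 = ctg),
                       exon_map = data.frame(transcript_id = "t1",
                                             t_start = 0L, t_end = 300L))
  expect_equal(ie_route_b(ctg, 150L, rs1), "1")
  ## exon boundary 20 bp from the mapped position interrupts the window
  rs2 <- reference_set("sp2", transcriptome = c(t1 = ctg),
                       exon_map = data.frame(transcript_id = "t1",
                                             t_start = c(0L, 170L),
                                             t_end = c(170L, 300L)))
  expect_equal(ie_route_b(ctg, 150L, rs2), "0")
  expect_equal(ie_route_b(ctg, 100L, rs2), "1")
  ## species lacking a homolog
  rs3 <- reference_set("sp3", transcriptome = c(t1 = rnd_seq(300)))
  expect_equal(ie_route_b(ctg, 150L, rs3), "no")
})

test_that("route B falls back to transcript-vs-genome alignment without a map", {
  set.seed(33)
  ctg <- rnd_seq(300)
  cut <- 160L
  gen <- paste0(rnd_seq(80), substr(ctg, 1, cut), rnd_seq(600),
                substr(ctg, cut + 1, 300), rnd_seq(80))
  rs <- reference_set("sp", genome = c(g1 = gen), transcriptome = c(t1 = ctg))
  expect_equal(ie_route_b(ctg, 150L, rs), "0")   # boundary 10 bp away
  expect_equal(ie_route_b(ctg, 80L, rs), "1")
})

test_that("intron-exon codes combine with precedence 1 > 0 > no", {
  expect_equal(
    combine_ie(data.frame(species = c("a", "b", "c"),
                          code = c("1", "0", "no"))),
    list(ie_code = "1", ie_species_match = 2L))
  expect_equal(
    combine_ie(data.frame(species = c("a", "b"), code = c("no", "no"))),
    list(ie_code = "no", ie_species_match = 0L))
  ## enumeration oracle over random code sets
  set.seed(34)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    codes <- data.frame(species = paste0("s", sample(1:4, n, replace = TRUE)),
                        code = sample(c("1", "0", "no"), n, replace = TRUE))
    got <- combine_ie(codes)
    want <- if (any(codes$code == "1")) "1" else
      if (any(codes$code == "0")) "0" else "no"
    expect_equal(got$ie_code, want)
    expect_equal(got$ie_species_match,
                 length(unique(codes$species[codes$code != "no"])))
    expect_equal(got$ie_species_match == 0L, got$ie_code == "no")
  }
})

test_that("codon-pair classification matches a genetic-code oracle on all 576 changes", {
  classes <- list(nonpolar = c("G", "A", "V", "L", "I", "P", "M", "C"),
                  polar = c("S", "T", "N", "Q"), negative = c("D", "E"),
                  positive = c("K", "R", "H"), aromatic = c("F", "W", "Y"))
  lookup <- unlist(lapply(names(classes), function(cl)
    setNames(rep(cl, length(classes[[cl]])), classes[[cl]])))
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  n_cases <- 0L
  for (cod in codons) {
    for (at in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), substr(cod, at, at))) {
        alt <- cod
        substr(alt, at, at) <- nb
        got <- classify_codon_pair(cod, alt)
        aa1 <- gc_tab[[cod]]; aa2 <- gc_tab[[alt]]
        want <- if (aa1 == aa2) "SYNONYMOUS" else
          if (aa1 == "*" || aa2 == "*") "NONSYN_NONCONSERVATIVE" else
            if (lookup[[aa1]] == lookup[[aa2]]) "NONSYN_CONSERVATIVE" else
              "NONSYN_NONCONSERVATIVE"
        expect_equal(got$classification, want, info = paste(cod, alt))
        expect_equal(got$nonsense, aa1 != aa2 && (aa1 == "*" || aa2 == "*"))
        n_cases <- n_cases + 1L
      }
    }
  }
  expect_equal(n_cases, 576L)
})

## a contig whose coding frame and peptide are known by construction
make_coding_contig <- function(n_codons = 60, offset = 1, seed = 35) {
  set.seed(seed)
  sense <- setdiff(as.vector(outer(outer(BASES4, BASES4, paste0), BASES4,
                                   paste0)), c("TAA", "TAG", "TGA"))
  core <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  list(seq = paste0(rnd_seq(offset), core, rnd_seq(2)),
       offset = offset,
       pep = as.character(Biostrings::translate(Biostrings::DNAString(core))))
}

test_that("effect classification recovers frame, codons and class", {
  cc <- make_coding_contig()
  ## force a known codon at codon 20: GGA (Gly)
  s <- cc$seq
  c0 <- cc$offset + 3 * 19
  substr(s, c0 + 1, c0 + 3) <- "GGA"
  prot <- c(hom = as.character(Biostrings::translate(Biostrings::DNAString(
    substr(s, cc$offset + 1, cc$offset + 180)))))
  ## third codon position G>G synonymous wobble
  ec <- classify_effect(s, c0 + 2L, "A", "G", prot)
  expect_equal(ec$classification, "SYNONYMOUS")
  expect_equal(ec$codon_ref, "GGA")
  expect_equal(ec$codon_alt, "GGG")
  expect_equal(ec$frame, cc$offset)
  ## plant AAA and test the charge-reversing first-position change
  substr(s, c0 + 1, c0 + 3) <- "AAA"
  prot2 <- c(hom = as.character(Biostrings::translate(Biostrings::DNAString(
    substr(s, cc$offset + 1, cc$offset + 180)))))
  ec2 <- classify_effect(s, c0, "A", "G", prot2)
  expect_equal(ec2$classification, "NONSYN_NONCONSERVATIVE")
  expect_equal(ec2$aa_ref, "K")
  expect_equal(ec2$aa_alt, "E")
  ## introduced stop: AAA -> TAA
  ec3 <- classify_effect(s, c0, "A", "T", prot2)
  expect_equal(ec3$classification, "NONSYN_NONCONSERVATIVE")
  expect_true(ec3$nonsense)
  ## conservative replacement: CTT (Leu) -> ATT (Ile), both non-polar
  substr(s, c0 + 1, c0 + 3) <- "CTT"
  prot3 <- c(hom = as.character(Biostrings::translate(Biostrings::DNAString(
    substr(s, cc$offset + 1, cc$offset + 180)))))
  ec4 <- classify_effect(s, c0, "C", "A", prot3)
  expect_equal(ec4$classification, "NONSYN_CONSERVATIVE")
})

test_that("effect classification is strand-consistent", {
  cc <- make_coding_contig(seed = 36)
  s <- cc$seq
  c0 <- cc$offset + 3 * 10
  substr(s, c0 + 1, c0 + 3) <- "AAA"
  prot <- c(hom = as.character(Biostrings::translate(Biostrings::DNAString(
    substr(s, cc$offset + 1, cc$offset + 150)))))
  fwd <- classify_effect(s, c0, "A", "G", prot)
  ## same physical molecule read from the other strand
  n <- nchar(s)
  rev <- classify_effect(revcomp(s), n - 1L - c0, "T", "C", prot)
  expect_equal(fwd$classification, rev$classification)
  expect_equal(fwd$aa_ref, rev$aa_ref)
  expect_equal(fwd$aa_alt, rev$aa_alt)
  expect_equal(rev$strand, "-")
})

test_that("effect classification returns UNKNOWN without a coding match", {
  set.seed(37)
  expect_equal(classify_effect(rnd_seq(200), 100L, "A", "G",
                               c(p = "MKLVVDEQQRSTANNNPLVVI"))$classification,
               "UNKNOWN")
  expect_equal(classify_effect(rnd_seq(200), 100L, "A", "G",
                               character(0))$classification, "UNKNOWN")
})

test_that("mitochondrial contigs are flagged by similarity", {
  set.seed(38)
  mito <- rnd_seq(2000)
  contigs <- c(m1 = substr(mito, 301, 500),
               m2 = revcomp(substr(mito, 1201, 1450)),
               n1 = rnd_seq(200), n2 = rnd_seq(250))
  fl <- flag_mitochondrial(contigs, mito)
  expect_equal(unname(fl), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("term enrichment reduces to the hypergeometric closed form", {
  ## identical term frequencies: p = 1 everywhere
  ann <- data.frame(contig_id = paste0("c", 1:10),
                    term = rep(c("GO:1", "GO:2"), 5))
  res <- go_enrichment(ann, ann)
  expect_true(all(res$p == 1))

  ## 2x2 (8,2;2,8): two-sided Fisher equals summed hypergeometric tails
  te <- data.frame(contig_id = paste0("t", 1:10),
                   term = rep(c("X", "other"), c(8, 2)))
  re <- data.frame(contig_id = paste0("r", 1:10),
                   term = rep(c("X", "other"), c(2, 8)))
  res2 <- go_enrichment(te, re)
  d <- dhyper(0:10, 10, 10, 10)
  p_closed <- sum(d[d <= d[8 + 1] * (1 + 1e-7)])
  expect_equal(res2[res2$term == "X", ]$p, p_closed, tolerance = 1e-10)
  expect_true(res2[res2$term == "X", ]$enriched)

  ## permuting contig labels breaks enrichment in nearly all trials
  set.seed(39)
  all_terms <- c(rep("Y", 30), rep("Z", 70))
  broken <- vapply(1:20, function(i) {
    lab <- sample(all_terms)
    t2 <- data.frame(contig_id = paste0("a", 1:40), term = lab[1:40])
    r2 <- data.frame(contig_id = paste0("b", 1:60), term = lab[41:100])
    !any(go_enrichment(t2, r2)$enriched)
  }, logical(1))
  expect_gte(mean(broken), 0.95)
})

test_that("candidate tables are annotated in bulk with cached alignments", {
  set.seed(40)
  ctg1 <- rnd_seq(300); ctg2 <- rnd_seq(300)
  cut <- 150L
  gen1 <- paste0(substr(ctg1, 1, cut), rnd_seq(400),
                 substr(ctg1, cut + 1, 300))
  rs <- reference_set("sp", genome = c(g1 = gen1), transcriptome = c(t2 = ctg2),
                      exon_map = data.frame(transcript_id = "t2",
                                            t_start = 0L, t_end = 300L))
  cand <- data.table(contig_id = c("c1", "c1", "c2", "c2"),
                     pos = c(145L, 70L, 150L, 10L))
  mito <- rnd_seq(1000)
  ann <- annotate_candidates(cand, c(c1 = ctg1, c2 = ctg2), list(rs),
                             mito_reference = mito)
  expect_equal(ann$ie_code, c("0", "1", "1", NA))   # c2:10 lacks flanks
  expect_equal(ann$ie_species_match, c(1L, 1L, 1L, NA))
  expect_equal(ann$is_mito, c(FALSE, FALSE, FALSE, FALSE))
})
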