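test_that("QC removes low call-rate samples and recomputes rates", {
  calls <- rbind(l1 = c("AA", "AB", NA, "BB", "AA"),
                 l2 = c("AA", NA, NA, "BB", "AA"),
                 l3 = c("AB", "AB", NA, NA, "AA"),
                 l4 = c("AA", "AA", NA, "BB", "AA"),
                 l5 = c("BB", "AB", "AA", "AA", "AA"))
  colnames(calls) <- paste0("s", 1:5)
  gm <- genotype_matrix(calls, setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE),
                                        rownames(calls)))
  ## s3 has 1/5 = 20% calls -> removed at the 0.8 rule; others pass
  qc <- apply_qc(gm)
  expect_equal(attr(qc, "removed_samples"), "s3")
  expect_equal(colnames(qc$calls), c("s1", "s2", "s4", "s5"))
  expect_true(all(call_rates(qc) >= 0.6))
  ## cluster_ok survives; poor-clustering locus converts to failure
  st <- compute_locus_stats(qc)
  expect_equal(st[locus_id == "l4", snp_assay_conversion], 0L)

  ## a sample at exactly 79% is removed, at 80% retained
  m <- matrix("AA", nrow = 100, ncol = 2,
              dimnames = list(paste0("x", 1:100), c("lo", "hi")))
  m[1:21, "lo"] <- NA
  m[1:20, "hi"] <- NA
  qc2 <- apply_qc(genotype_matrix(m))
  expect_equal(colnames(qc2$calls), "hi")

  ## identity when everything is complete
  full <- make_gm(a = rep("AB", 4))
  expect_equal(apply_qc(full)$calls, full$calls)
  ## removing everyone is an error
  allbad <- genotype_matrix(matrix(NA_character_, 2, 2,
                                   dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(apply_qc(allbad), "all samples")
})

test_that("QC equals a brute-force filter on random missingness", {
  set.seed(41)
  for (i in 1:10) {
    m <- matrix(sample(c("AA", "AB", "BB", NA), 200, replace = TRUE,
                       prob = c(.3, .3, .2, .2)),
                nrow = 10, dimnames = list(paste0("l", 1:10), paste0("s", 1:20)))
    gm <- genotype_matrix(m)
    keep <- colMeans(!is.na(m)) >= 0.8
    if (!any(keep)) next
    expect_equal(apply_qc(gm)$calls, m[, keep, drop = FALSE])
  }
})

test_that("Yates chi-square has the correction floor and matches chisq.test", {
  ## identical rows give exactly zero
  expect_equal(chi2_yates(7, 7, 7, 7)$statistic, 0)
  ## floored when |ad - bc| <= N/2
  r <- chi2_yates(10, 10, 10, 11)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  ## zero marginal warns
  expect_warning(z <- chi2_yates(0, 0, 5, 5), "marginal")
  expect_equal(z$statistic, 0)
  ## random tables agree with stats::chisq.test (corrected and uncorrected)
  set.seed(42)
  for (i in 1:50) {
    tb <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(chi2_yates(tb)$statistic,
                 unname(suppressWarnings(chisq.test(tb))$statistic),
                 tolerance = 1e-12)
    expect_equal(chi2_yates(tb, correct = FALSE)$statistic,
                 unname(suppressWarnings(chisq.test(tb, correct = FALSE))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney Monte-Carlo p matches exact enumeration", {
  ## identical multisets: p near 1
  x <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_mc(x, x, n_perm = 4000, seed = 1)
  expect_gt(r$p, 0.9)
  ## U + U' identity
  set.seed(43)
  a <- rnorm(12); b <- rnorm(17)
  ua <- mann_whitney_mc(a, b, n_perm = 100, seed = 1)$U
  ub <- mann_whitney_mc(b, a, n_perm = 100, seed = 1)$U
  expect_equal(ua + ub, 12 * 17)
  expect_equal(ua, unname(suppressWarnings(wilcox.test(a, b)$statistic)))
  ## fully separated 5 vs 5: one-sided exact p is 1/choose(10,5)
  lo <- 1:5; hi <- 11:15
  r2 <- mann_whitney_mc(hi, lo, n_perm = 50000, seed = 7,
                        alternative = "greater")
  exact <- 1 / choose(10, 5)
  expect_true(r2$p_ci[1] <= exact && exact <= r2$p_ci[2] + 0.002)
  expect_lt(abs(r2$p - exact), 0.003)
  ## deterministic given the seed
  expect_identical(mann_whitney_mc(a, b, n_perm = 2000, seed = 5),
                   mann_whitney_mc(a, b, n_perm = 2000, seed = 5))
})

test_that("Wilcoxon signed-rank handles zeros, maxima and matches enumeration", {
  x <- c(1, 2, 3)
  expect_equal(wilcoxon_signed_rank(x, x)$p, 1)
  ## six all-positive differences force V = 21
  y0 <- c(5, 6, 7, 8, 9, 10)
  w <- wilcoxon_signed_rank(y0 + c(1, 2, 3, 4, 5, 6), y0)
  expect_equal(w$V, 21)
  ## small-n p equals exhaustive sign-flip enumeration
  set.seed(44)
  d <- c(0.8, -1.3, 2.1, 0.4, -0.2, 1.7, 0.9, -2.6)
  got <- wilcoxon_signed_rank(d + 10, rep(10, 8))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vs <- vapply(0:(2^n - 1), function(mask) {
    sgn <- as.integer(intToBits(mask))[1:n]
    sum(r[sgn == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p_exact <- mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
  expect_equal(got$V, v_obs)
  expect_equal(got$p, p_exact, tolerance = 1e-10)
})

test_that("logistic fits match a direct likelihood maximization", {
  ## 6-row dataset: glm solution vs Nelder-Mead on the hand-written log-lik
  df <- data.frame(x = c(-2, -1, 0, 1, 2, 3), y = c(0, 0, 1, 0, 1, 1))
  fit <- logistic_fit(df, "y", "x", mode = "enter")
  nll <- function(b) {
    eta <- b[1] + b[2] * df$x
    -sum(df$y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$coefficients[term == "(Intercept)", B]),
               opt$par[1], tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[term == "x", B]),
               opt$par[2], tolerance = 1e-4)
  expect_equal(fit$log_lik, -opt$value, tolerance = 1e-6)
})

test_that("backward elimination drops uninformative predictors first", {
  set.seed(45)
  n <- 400
  x1 <- rnorm(n)
  konst <- rep(1, n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x1))
  df <- data.frame(x1 = x1, konst = konst, y = y)
  expect_warning(fit <- logistic_fit(df, "y", c("x1", "konst"),
                                     mode = "backward_wald"),
                 "collinear")
  expect_equal(fit$retained, "x1")
  expect_true("konst" %in% fit$removed)
  ## pure-noise predictor is eliminated by the Wald criterion
  df2 <- data.frame(x1 = x1, noise = rnorm(n), y = y)
  fit2 <- logistic_fit(df2, "y", mode = "backward_wald")
  expect_true("x1" %in% fit2$retained)
  ## enter-mode log-likelihood dominates the nested backward model
  fit_enter <- logistic_fit(df2, "y", mode = "enter")
  expect_gte(fit_enter$log_lik, fit2$log_lik - 1e-9)
  ## Wald = (B/se)^2 invariant
  co <- fit_enter$coefficients[df == 1]
  expect_equal(co$wald, (co$B / co$se)^2)
})

test_that("categorical predictors use the last level as reference", {
  set.seed(46)
  n <- 300
  g <- sample(c("a", "b", "z_ref"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(ifelse(g == "a", 1, ifelse(g == "b", 0, -1))))
  fit <- logistic_fit(data.frame(g = g, y = y), "y", "g", mode = "enter")
  terms <- fit$coefficients$term
  expect_true(any(grepl("^g", terms)))
  expect_false(any(grepl("z_ref", terms)))   # reference level absorbed
  ## the multi-df block Wald row is reported
  expect_true(any(fit$coefficients$df == 2))
})

test_that("complete separation is flagged, not silently reported", {
  df <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(0, 0, 0, 1, 1, 1))
  fit <- logistic_fit(df, "y", "x", mode = "enter")
  expect_true(fit$separation)
})

test_that("ROC analysis equals pair-counting and the U identity", {
  ## perfect separation and pure ties
  expect_equal(roc_analysis(c(1, 2, 3, 11, 12, 13),
                            c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_analysis(rep(5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_analysis(1:4, rep(1, 4)), "both")
  set.seed(47)
  for (i in 1:10) {
    sc <- sample(1:8, 20, replace = TRUE)   # plenty of ties
    lb <- rbinom(20, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- roc_analysis(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    u <- unname(suppressWarnings(wilcox.test(sc[lb == 1], sc[lb == 0])$statistic))
    expect_equal(r$auc, u / (sum(lb == 1) * sum(lb == 0)), tolerance = 1e-12)
  }
})

test_that("the Youden-optimal cutoff classifies score > cutoff as positive", {
  ## mirrors a quality score where low values predict success:
  ## label = 1 for monomorphic, score = Q
  q <- c(0, 0, 0, 1, 1, 2, 3, 4, 5, 6)
  mono <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
  r <- roc_analysis(q, mono)
  j <- r$curve[, sensitivity + specificity - 1]
  expect_equal(max(j), r$sensitivity + r$specificity - 1)
  ## ties in J resolve to the smaller cutoff
  expect_equal(r$optimal_cutoff,
               min(r$curve$cutoff[j >= max(j) - 1e-12]))
  ## DeLong and Hanley variances are both available and positive
  r2 <- roc_analysis(q, mono, se_method = "hanley")
  expect_gt(r$se, 0)
  expect_gt(r2$se, 0)
})

test_that("platform comparison applies the declared test per variable", {
  set.seed(48)
  ta <- data.table(contig_length = rnorm(60, 600, 50),
                   depth = rnorm(60, 80, 10),
                   msaf = runif(60, 0.05, 0.5),
                   snp_assay_conversion = rbinom(60, 1, 0.4),
                   geosites = sample(1:4, 60, TRUE))
  tb <- data.table(contig_length = rnorm(60, 210, 30),
                   depth = rnorm(60, 600, 60),
                   msaf = runif(60, 0.05, 0.5),
                   snp_assay_conversion = rbinom(60, 1, 0.45),
                   geosites = sample(1:4, 60, TRUE))
  rep_ <- compare_platforms(ta, tb, n_perm = 2000, seed = 3)
  expect_equal(nrow(rep_), 5)       # one row per shared declared variable
  expect_setequal(rep_$variable, c("contig_length", "depth", "msaf",
                                   "snp_assay_conversion", "geosites"))
  expect_equal(rep_[variable == "contig_length", test], "t")
  expect_equal(rep_[variable == "snp_assay_conversion", test], "chi2")
  expect_equal(rep_[variable == "msaf", test], "mw")
  ## the planted depth difference is overwhelmingly significant
  expect_lt(rep_[variable == "depth", p], 1e-6)
  ## near-identical tables: no spurious certainty
  rep2 <- compare_platforms(ta, copy(ta), n_perm = 2000, seed = 3)
  expect_true(all(rep2$p > 0.9))
  ## missing variables are skipped with a warning
  expect_warning(compare_platforms(ta[, .(msaf)], tb,
                                   variables = c("msaf", "geosites"),
                                   n_perm = 500, seed = 1),
                 "missing in one table")
})

test_that("a planted depth contrast is detected across repeated simulations", {
  set.seed(49)
  hits <- vapply(1:20, function(i) {
    a <- data.table(depth = rnorm(80, 100, 20))
    b <- data.table(depth = rnorm(80, 500, 100))
    compare_platforms(a, b, variables = "depth")$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("paired discovery/validation comparisons line up loci", {
  set.seed(50)
  n <- 40
  de <- data.table(locus_id = paste0("L", 1:n),
                   msaf = runif(n, 0.1, 0.5))
  ou <- data.table(locus_id = paste0("L", 1:n),
                   snp_assay_conversion = 1L,
                   maf = pmax(0, runif(n, 0.1, 0.5) - 0.05),
                   ho = runif(n))
  pt <- paired_frequency_tests(de, ou)
  expect_equal(pt$comparison, "msaf_vs_maf")
  w <- wilcoxon_signed_rank(de$msaf, ou$maf)
  expect_equal(pt$V, w$V)
  expect_equal(pt$p, w$p)
})
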