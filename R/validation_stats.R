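## validation_stats: genotype QC and the platform-comparison statistical
## battery.

#' Genotyping quality control
#'
#' Removes samples whose call rate is below `min_call_rate`, recomputes call
#' rates on the surviving sample set, and marks loci flagged as poorly
#' clustering (`cluster_ok = FALSE`) as conversion-failed (they are kept in
#' the matrix so downstream conversion statistics see them).
#'
#' @param gm `genotype_matrix`.
#' @param min_call_rate minimum per-sample fraction of non-missing calls
#'   (default 0.8).
#' @return filtered `genotype_matrix` with attribute `removed_samples`.
#' @export
apply_qc <- function(gm, min_call_rate = 0.8) {
  cr <- call_rates(gm)
  keep <- cr >= min_call_rate
  if (!any(keep)) stop("all samples removed by the call-rate filter")
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE], gm$cluster_ok)
  attr(out, "removed_samples") <- names(cr)[!keep]
  out
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected Pearson statistic
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the correction
#' floored: the statistic is exactly 0 when `|ad - bc| <= N/2`. p from the
#' 1-df chi-square upper tail. `correct = FALSE` gives the uncorrected
#' Pearson statistic.
#'
#' @param a,b,c,d cell counts (rows = groups, columns = outcomes), or `a`
#'   may be a 2x2 matrix.
#' @param correct apply the continuity correction (default TRUE).
#' @return list: `statistic`, `p`, `df = 1`.
#' @export
chi2_yates <- function(a, b = NULL, c = NULL, d = NULL, correct = TRUE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal: statistic undefined, reported as 0")
    return(list(statistic = 0, p = 1, df = 1L))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(marg)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Mann-Whitney U test with Monte-Carlo permutation p-value
#'
#' Tie-corrected U via the rank-sum formulation, with a permutation p-value
#' estimated from `n_perm` random relabellings and a 99% confidence interval
#' for the estimate. Reproducible given `seed`.
#'
#' @param x,y the two samples.
#' @param n_perm number of permutations (default 1,000,000; pass fewer for
#'   quick work).
#' @param seed integer seed (required).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to `x` relative to `y`).
#' @return list: `U` (for `x`), `p`, `p_ci` (99% CI), `n_perm`.
#' @export
mann_whitney_mc <- function(x, y, n_perm = 1e6, seed,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0, !missing(seed))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_from_rsum <- function(rsum) rsum - nx * (nx + 1) / 2
  u_obs <- u_from_rsum(sum(r[seq_len(nx)]))
  mu <- nx * ny / 2
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_perm <- as.integer(n_perm)
  exceed <- 0L
  chunk <- 20000L
  done <- 0L
  dev_obs <- switch(alternative,
                    two.sided = abs(u_obs - mu),
                    less = -(u_obs - mu),       # small U extreme
                    greater = u_obs - mu)
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    us <- vapply(seq_len(m), function(i) {
      u_from_rsum(sum(r[sample.int(nx + ny, nx)]))
    }, numeric(1))
    dev <- switch(alternative,
                  two.sided = abs(us - mu),
                  less = -(us - mu),
                  greater = us - mu)
    exceed <- exceed + sum(dev >= dev_obs - 1e-9)
    done <- done + m
  }
  p <- (exceed + 1) / (n_perm + 1)
  se <- sqrt(p * (1 - p) / n_perm)
  ci <- c(max(0, p - qnorm(0.995) * se), min(1, p + qnorm(0.995) * se))
  list(U = u_obs, p = p, p_ci = ci, n_perm = n_perm)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; V is the sum of positive-difference ranks.
#' Exact p for 25 or fewer non-zero pairs without ties, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y paired samples of equal length.
#' @return list: `V`, `p`, `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0) return(list(V = 0, p = 1, n = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    p <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
  } else {
    p <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE)$p.value)
  }
  list(V = v, p = p, n = n)
}

## block Wald chi-square for a set of coefficients of a fitted glm
block_wald <- function(fit, cols) {
  b <- coef(fit)[cols]
  V <- vcov(fit)[cols, cols, drop = FALSE]
  w <- tryCatch(as.numeric(t(b) %*% solve(V) %*% b), error = function(e) NA_real_)
  df <- length(cols)
  list(wald = w, df = df, p = pchisq(w, df = df, lower.tail = FALSE))
}

#' Binomial logistic regression with optional backward Wald elimination
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]). Categorical predictors are expanded to indicator
#' contrasts with the *last* level as reference. In `backward_wald` mode the
#' predictor (factor block) with the largest Wald-test p-value is removed and
#' the model refitted, repeating while any p exceeds `removal_p`. Collinear
#' (aliased) predictors are dropped with a warning; complete separation is
#' flagged.
#'
#' @param data data.frame of predictors and outcome.
#' @param outcome name of the dichotomous outcome column (0/1 or logical).
#' @param predictors character vector of predictor column names (default: all
#'   other columns).
#' @param mode `"enter"` (all predictors) or `"backward_wald"`.
#' @param removal_p stay threshold for backward elimination (default 0.10).
#' @return list of class `logistic_model`: `coefficients` (data.table with
#'   `term`, `B`, `se`, `wald`, `df`, `p`), `retained`, `removed`,
#'   `intercept`, `log_lik`, `model_chi2`, `model_df`, `model_p`,
#'   `classification_rate`, `separation`, `fit` (the final glm).
#' @export
logistic_fit <- function(data, outcome, predictors = NULL,
                         mode = c("enter", "backward_wald"), removal_p = 0.10) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  stopifnot(outcome %in% names(data))
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  data[[outcome]] <- y
  ## last level as reference for categoricals
  for (p in predictors) {
    if (is.character(data[[p]])) data[[p]] <- factor(data[[p]])
    if (is.factor(data[[p]])) {
      lv <- levels(data[[p]])
      stats::contrasts(data[[p]]) <- stats::contr.treatment(length(lv),
                                                            base = length(lv))
    }
  }
  fit_with <- function(preds) {
    fml <- if (length(preds)) {
      as.formula(paste(outcome, "~", paste(sprintf("`%s`", preds), collapse = "+")))
    } else as.formula(paste(outcome, "~ 1"))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fml, data = data, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    attr(fit, "separation") <- sep
    fit
  }
  term_cols <- function(fit, preds) {
    asg <- attr(fit$qr$qr, "assign") %||% attr(stats::model.matrix(fit), "assign")
    labs <- attr(fit$terms, "term.labels")
    cn <- names(coef(fit))
    lapply(setNames(labs, labs), function(l) {
      cn[asg == match(l, labs) & !is.na(coef(fit))]
    })
  }
  preds <- predictors
  removed <- character()
  repeat {
    fit <- fit_with(preds)
    aliased <- names(coef(fit))[is.na(coef(fit))]
    if (length(aliased)) {
      tc <- term_cols(fit, preds)
      bad <- names(tc)[vapply(tc, function(cc) any(cc %in% aliased) ||
                                length(cc) == 0, logical(1))]
      bad <- gsub("`", "", bad)
      warning("dropping collinear predictor(s): ", paste(bad, collapse = ", "))
      preds <- setdiff(preds, bad)
      removed <- c(removed, bad)
      next
    }
    if (mode == "enter" || length(preds) == 0) break
    tc <- term_cols(fit, preds)
    ws <- lapply(tc, function(cc) block_wald(fit, cc))
    pv <- vapply(ws, `[[`, numeric(1), "p")
    if (all(is.na(pv))) break
    worst <- names(pv)[which.max(pv)]
    if (max(pv, na.rm = TRUE) <= removal_p) break
    preds <- setdiff(preds, gsub("`", "", worst))
    removed <- c(removed, gsub("`", "", worst))
  }
  ## per-coefficient table
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  co <- data.table(term = names(cf), B = unname(cf), se = unname(se))
  co[, wald := (B / se)^2]
  co[, df := 1L]
  co[, p := pchisq(wald, 1, lower.tail = FALSE)]
  ## block rows for multi-level factors
  tc <- term_cols(fit, preds)
  blocks <- rbindlist(lapply(names(tc), function(l) {
    bw <- block_wald(fit, tc[[l]])
    data.table(term = paste0(gsub("`", "", l), " (block)"), B = NA_real_,
               se = NA_real_, wald = bw$wald, df = bw$df, p = bw$p)
  }))
  if (nrow(blocks)) blocks <- blocks[blocks$df > 1] else blocks <- co[0]
  null_dev <- fit$null.deviance
  model_chi2 <- null_dev - fit$deviance
  model_df <- fit$df.null - fit$df.residual
  cls_rate <- mean((stats::fitted(fit) > 0.5) == fit$y)
  structure(list(
    coefficients = rbind(co, blocks),
    retained = preds, removed = removed,
    intercept = unname(cf["(Intercept)"]),
    log_lik = as.numeric(stats::logLik(fit)),
    model_chi2 = model_chi2, model_df = model_df,
    model_p = if (model_df > 0) {
      pchisq(model_chi2, model_df, lower.tail = FALSE)
    } else NA_real_,
    classification_rate = cls_rate,
    separation = isTRUE(attr(fit, "separation")),
    fit = fit
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> retained: ",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n model chi2 = ", round(x$model_chi2, 3), " (df ", x$model_df,
      ", p = ", signif(x$model_p, 3), "); correct classification ",
      round(100 * x$classification_rate, 1), "%\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

## DeLong placement-based variance of the empirical AUC
delong_var <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

#' ROC analysis with DeLong variance and Youden-optimal cutoff
#'
#' Builds the empirical ROC curve of `scores` against dichotomous `labels`
#' (higher score = more likely label 1), computes the area under the curve by
#' the trapezoidal rule (equal to the tie-corrected Mann-Whitney U scaled by
#' `n1 * n0`), its standard error (DeLong placement estimator by default,
#' Hanley-McNeil optionally), a z test of AUC against 0.5, and the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1 (ties resolved to
#' the smaller cutoff). A point is classified positive when
#' `score > cutoff`.
#'
#' @param scores numeric predictor.
#' @param labels 0/1 outcome (both classes required).
#' @param se_method `"delong"` (default) or `"hanley"`.
#' @return list of class `roc_result`: `auc`, `se`, `z`, `p`,
#'   `optimal_cutoff`, `sensitivity`, `specificity`, `curve` (data.table of
#'   cutoffs with sens/spec/J).
#' @export
roc_analysis <- function(scores, labels, se_method = c("delong", "hanley")) {
  se_method <- match.arg(se_method)
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  ## candidate cutoffs: each distinct score (classify positive when > cutoff)
  cuts <- sort(unique(scores))
  cuts <- c(min(scores) - 1, cuts)
  sens <- vapply(cuts, function(ct) sum(scores > ct & labels == 1) / n1, numeric(1))
  spec <- vapply(cuts, function(ct) sum(scores <= ct & labels == 0) / n0, numeric(1))
  curve <- data.table(cutoff = cuts, sensitivity = sens, specificity = spec,
                      J = sens + spec - 1)
  ## trapezoid over (FPR, TPR) sorted by cutoff ascending = FPR descending
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  se <- if (se_method == "delong") {
    sqrt(delong_var(scores, labels))
  } else {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
           (n1 * n0))
  }
  z <- (auc - 0.5) / se
  jbest <- which(curve$J >= max(curve$J) - 1e-12)
  jbest <- jbest[which.min(curve$cutoff[jbest])]
  structure(list(auc = auc, se = se, z = z,
                 p = 2 * pnorm(-abs(z)),
                 optimal_cutoff = curve$cutoff[jbest],
                 sensitivity = curve$sensitivity[jbest],
                 specificity = curve$specificity[jbest],
                 curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", round(x$auc, 3), " +/- ", round(x$se, 4),
      " (z = ", round(x$z, 2), ", p = ", signif(x$p, 3), ")\n",
      " optimal cutoff > ", x$optimal_cutoff, ": sensitivity ",
      round(100 * x$sensitivity, 1), "%, specificity ",
      round(100 * x$specificity, 1), "%\n", sep = "")
  invisible(x)
}

## declared test per descriptor variable for the platform comparison
PLATFORM_TESTS <- c(
  contig_length = "t", depth = "t",
  snp_assay_conversion = "chi2", snp_genotype = "chi2", ie_code = "chi2",
  ie_species_match = "mw", geosites = "mw", snp_score = "mw", msaf = "mw",
  individuals = "mw", q_score = "mw", rank = "mw"
)

#' Compare two SNP descriptor datasets variable by variable
#'
#' Applies the declared test per descriptor: Welch t-test for the
#' approximately normal quantitative variables (contig length, depth),
#' Yates-corrected chi-square for categorical ones (assay conversion,
#' polymorphism, intron-exon code), Mann-Whitney U with a Monte-Carlo
#' permutation p for ordinal or skewed quantitative ones (species matches,
#' geosites, design score, MSAF, ...). Variables missing from either table
#' are skipped with a warning.
#'
#' @param table_a,table_b descriptor data.frames (e.g. from
#'   [read_snp_table()], possibly augmented with validation outcomes).
#' @param variables subset of variables to compare (default: all declared
#'   ones present).
#' @param n_perm permutations for the Mann-Whitney Monte-Carlo p.
#' @param seed seed for the permutation tests.
#' @return data.table: `variable`, `test`, `statistic`, `p`, `n_a`, `n_b`.
#' @export
compare_platforms <- function(table_a, table_b, variables = NULL,
                              n_perm = 1e6, seed = 1L) {
  ta <- as.data.table(table_a); tb <- as.data.table(table_b)
  vars <- variables %||% names(PLATFORM_TESTS)
  rows <- list()
  for (v in vars) {
    if (!(v %in% names(PLATFORM_TESTS))) {
      warning("no declared test for variable ", v, "; skipped"); next
    }
    if (!(v %in% names(ta)) || !(v %in% names(tb))) {
      if (v %in% names(ta) || v %in% names(tb)) {
        warning("variable ", v, " missing in one table; skipped")
      }
      next
    }
    xa <- ta[[v]]; xb <- tb[[v]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (!length(xa) || !length(xb)) next
    test <- PLATFORM_TESTS[[v]]
    res <- switch(test,
      t = {
        tt <- t.test(xa, xb)
        list(stat = unname(tt$statistic), p = tt$p.value)
      },
      chi2 = {
        la <- table(factor(as.character(xa)))
        lb <- table(factor(as.character(xb)))
        lev <- union(names(la), names(lb))
        if (length(lev) != 2) {
          warning("variable ", v, " is not dichotomous; skipped")
          NULL
        } else {
          ct <- chi2_yates(sum(xa == lev[1]), sum(xa == lev[2]),
                           sum(xb == lev[1]), sum(xb == lev[2]))
          list(stat = ct$statistic, p = ct$p)
        }
      },
      mw = {
        mw <- mann_whitney_mc(as.numeric(xa), as.numeric(xb),
                              n_perm = n_perm, seed = seed)
        list(stat = mw$U, p = mw$p)
      })
    if (is.null(res)) next
    rows[[v]] <- data.table(variable = v, test = test, statistic = res$stat,
                            p = res$p, n_a = length(xa), n_b = length(xb))
  }
  if (!length(rows)) {
    return(data.table(variable = character(), test = character(),
                      statistic = numeric(), p = numeric(), n_a = integer(),
                      n_b = integer()))
  }
  rbindlist(rows)
}

#' Paired discovery-vs-validation frequency comparisons
#'
#' For loci present in both a descriptor table (sequencing-stage MSAF and,
#' when available, discovery-panel Ho) and validation outcomes (genotype MAF,
#' Ho), runs paired Wilcoxon signed-rank tests of MSAF vs MAF and of
#' discovery vs validation Ho. Sequence-based minor-allele frequencies are
#' typically inflated at low coverage, which these tests quantify.
#'
#' @param descriptors descriptor table with `locus_id` (or `contig_id` +
#'   `pos`) and `msaf` (optionally `ho_discovery`).
#' @param outcomes per-locus validation outcomes from
#'   [compute_locus_stats()].
#' @return data.table of paired tests: `comparison`, `V`, `p`, `n`.
#' @export
paired_frequency_tests <- function(descriptors, outcomes) {
  de <- as.data.table(descriptors)
  ou <- as.data.table(outcomes)
  if (!"locus_id" %in% names(de)) {
    de[, locus_id := paste0(contig_id, ":", to_one_based(pos))]
  }
  m <- ou[de, on = "locus_id", nomatch = NULL]
  m <- m[snp_assay_conversion == 1L]
  rows <- list()
  if (nrow(m) > 1) {
    w <- wilcoxon_signed_rank(m$msaf, m$maf)
    rows$msaf <- data.table(comparison = "msaf_vs_maf", V = w$V, p = w$p, n = w$n)
    if ("ho_discovery" %in% names(m)) {
      w2 <- wilcoxon_signed_rank(m$ho_discovery, m$ho)
      rows$ho <- data.table(comparison = "ho_discovery_vs_validation",
                            V = w2$V, p = w2$p, n = w2$n)
    }
  }
  if (!length(rows)) {
    return(data.table(comparison = character(), V = numeric(), p = numeric(),
                      n = integer()))
  }
  rbindlist(rows)
}
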