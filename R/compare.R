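#' Percent difference against a reference model
#'
#' |test - reference| / reference x 100.
#'
#' @param test_value,reference_value Numeric (vectorized).
#' @return Percent difference(s); NA with a warning where the reference is
#'   zero (excluded from cohort summaries).
#' @export
percent_difference <- function(test_value, reference_value) {
  out <- abs(test_value - reference_value) / reference_value * 100
  zero <- !is.na(reference_value) & reference_value == 0
  if (any(zero)) {
    warning("reference value is zero; percent difference undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped and ties are mid-ranked. The null distribution is exact for
#' n <= `exact_max` (computed by convolution over sign assignments of the
#' doubled midranks, valid with ties); above that a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null is enumerated.
#' @return List with `p_value`, `statistic` (V, sum of positive ranks),
#'   `n` (pairs after zero removal), `method` and `degenerate` flag.
#' @export
paired_wilcoxon <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = 1, statistic = 0, n = 0, method = "degenerate",
                degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null over 2^n sign assignments via convolution on 2*ranks
    # (doubled midranks are integers)
    r2 <- round(2 * r)
    maxw <- sum(r2)
    cnt <- numeric(maxw + 1)
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(maxw + 1 - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * v)
    lo <- sum(probs[seq_len(w2 + 1)])                 # P(W <= v)
    hi <- sum(probs[seq(w2 + 1, maxw + 1)])           # P(W >= v)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(p_value = p, statistic = v, n = n, method = method,
       degenerate = FALSE)
}

#' Cohen's kappa with agreement category
#'
#' Unweighted kappa = (p_o - p_e) / (1 - p_e) over a shared label set,
#' categorized as poor (kappa < 0.4), moderate (0.4 <= kappa <= 0.75) or
#' good (kappa > 0.75); boundaries fall to the lower category.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return List with `kappa`, `agreement_category`, `p_observed`,
#'   `p_expected` and a `degenerate` flag (both raters constant and equal:
#'   kappa defined as 1).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  lv <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lv)
  b <- factor(as.character(labels_b), levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  degenerate <- FALSE
  if (abs(1 - pe) < 1e-12) {
    k <- 1
    degenerate <- TRUE
  } else {
    k <- (po - pe) / (1 - pe)
  }
  category <- if (k > 0.75) "good" else if (k > 0.4) "moderate" else "poor"
  list(kappa = k, agreement_category = category, p_observed = po,
       p_expected = pe, degenerate = degenerate)
}

#' Cohort comparison of modality-specific models against the reference
#'
#' Takes long-format parameter tables (one row per patient x modality x
#' parameter) and, for each parameter and each test modality, computes the
#' per-patient percent differences against the reference modality, their
#' cohort mean and standard error (SD/sqrt(n)), and the paired Wilcoxon
#' p-value on the raw paired values. Optional categorical flow labels are
#' compared with Cohen's kappa.
#'
#' @param values Data frame with columns `patient_id`, `modality`,
#'   `parameter`, `value`.
#' @param flow_labels Optional data frame with columns `patient_id`,
#'   `modality` and one column per categorical characteristic (e.g. FP,
#'   IS, JS).
#' @param reference Reference modality (default "DM").
#' @return A `comparison_result`: list with `differences` (per-parameter,
#'   per-comparison data frame), `per_patient` (long Δ% table, boxplot
#'   ready) and `kappa` (or NULL).
#' @export
summarize_cohort <- function(values, flow_labels = NULL, reference = "DM") {
  req <- c("patient_id", "modality", "parameter", "value")
  stopifnot(all(req %in% names(values)))
  mods <- setdiff(unique(values$modality), reference)
  if (!reference %in% values$modality)
    stop(sprintf("reference modality '%s' absent", reference))
  if (length(unique(values$patient_id)) < 2)
    stop("cohort summary needs n >= 2 patients")
  rows <- list(); pp <- list()
  for (par in unique(values$parameter)) {
    ref <- values[values$parameter == par & values$modality == reference, ]
    for (m in mods) {
      tst <- values[values$parameter == par & values$modality == m, ]
      common <- intersect(ref$patient_id, tst$patient_id)
      dropped <- setdiff(unique(c(ref$patient_id, tst$patient_id)), common)
      if (length(dropped))
        message(sprintf("%s vs %s / %s: excluded patients without both models: %s",
                        m, reference, par, paste(dropped, collapse = ", ")))
      if (length(common) < 2) next
      rv <- ref$value[match(common, ref$patient_id)]
      tv <- tst$value[match(common, tst$patient_id)]
      dp <- suppressWarnings(percent_difference(tv, rv))
      ok <- !is.na(dp)
      wt <- paired_wilcoxon(tv, rv)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, comparison = paste(m, "vs", reference),
        n = sum(ok), mean_pct = mean(dp[ok]),
        se_pct = sd(dp[ok]) / sqrt(sum(ok)),
        wilcoxon_p = wt$p_value, stringsAsFactors = FALSE)
      pp[[length(pp) + 1]] <- data.frame(
        parameter = par, comparison = paste(m, "vs", reference),
        patient_id = common, pct_difference = dp,
        stringsAsFactors = FALSE)
    }
  }
  kap <- NULL
  if (!is.null(flow_labels)) {
    chars <- setdiff(names(flow_labels), c("patient_id", "modality"))
    krows <- list()
    for (ch in chars) for (m in mods) {
      ref <- flow_labels[flow_labels$modality == reference, ]
      tst <- flow_labels[flow_labels$modality == m, ]
      common <- intersect(ref$patient_id, tst$patient_id)
      if (!length(common)) next
      kk <- cohen_kappa(ref[[ch]][match(common, ref$patient_id)],
                        tst[[ch]][match(common, tst$patient_id)])
      krows[[length(krows) + 1]] <- data.frame(
        characteristic = ch, comparison = paste(m, "vs", reference),
        kappa = kk$kappa, agreement = kk$agreement_category,
        stringsAsFactors = FALSE)
    }
    kap <- do.call(rbind, krows)
  }
  structure(list(differences = do.call(rbind, rows),
                 per_patient = do.call(rbind, pp),
                 kappa = kap, reference = reference),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Cohort comparison against %s (mean Δ%% ± SE, paired Wilcoxon p)\n",
              x$reference))
  df <- x$differences
  df$mean_pct <- round(df$mean_pct, 2)
  df$se_pct <- round(df$se_pct, 2)
  df$wilcoxon_p <- round(df$wilcoxon_p, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$kappa)) {
    cat("Flow-characteristic agreement (Cohen's kappa)\n")
    print(x$kappa, row.names = FALSE)
  }
  invisible(x)
}

#' Boxplot of per-patient percent differences
#' @param x A `comparison_result`.
#' @param ... Passed to `boxplot`.
#' @export
plot.comparison_result <- function(x, ...) {
  pp <- x$per_patient
  graphics::boxplot(pct_difference ~ parameter + comparison, data = pp,
                    las = 2, ylab = "difference (%)", ...)
  invisible(x)
}
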