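# independent oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign assignments of the midranks
wilcoxon_enum <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  p_lo <- mean(w <= v + 1e-9)
  p_hi <- mean(w >= v - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("percent difference basics", {
  expect_equal(percent_difference(11, 10), 10)
  expect_equal(percent_difference(10, 10), 0)
  expect_equal(percent_difference(6, 8), 25)
  expect_warning(out <- percent_difference(3, 0), "zero")
  expect_true(is.na(out))
})

test_that("paired Wilcoxon: degenerate, one-sided shift, exact minimum", {
  x <- 1:10
  res <- paired_wilcoxon(x, x)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)

  res2 <- paired_wilcoxon(x + 1, x)
  expect_equal(res2$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_equal(res2$n, 10)
})

test_that("Wilcoxon agrees with enumeration (and wilcox.test) on random paired data", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n), 1)
    y <- round(x + rnorm(n, sd = 0.7), 1)
    if (all(x == y)) next
    got <- paired_wilcoxon(x, y)
    expect_gte(got$p_value, 0)
    expect_lte(got$p_value, 1)
    expect_equal(got$p_value, wilcoxon_enum(x, y), tolerance = 1e-9)
    d <- x - y
    d <- d[d != 0]
    if (length(d) >= 5 && all(x != y) && !any(duplicated(abs(d)))) {
      # tie-free: stats::wilcox.test exact p must match
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      expect_equal(got$p_value, ref, tolerance = 1e-9)
    }
  }
})

test_that("Wilcoxon normal approximation is sane above the exact cut-off", {
  set.seed(8)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.05)
  got <- paired_wilcoxon(x, y)
  expect_equal(got$method, "normal-approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-6)
})

test_that("Cohen's kappa: perfect, chance-level and hand-computed table", {
  a <- c("FP1", "FP2", "FP1", "FP3", "FP2")
  k1 <- cohen_kappa(a, a)
  expect_equal(k1$kappa, 1)
  expect_equal(k1$agreement_category, "good")

  # balanced 2x2 table (25, 25 / 25, 25): kappa 0
  la <- rep(c("x", "x", "y", "y"), 25)
  lb <- rep(c("x", "y", "x", "y"), 25)
  k2 <- cohen_kappa(la, lb)
  expect_equal(k2$kappa, 0, tolerance = 1e-12)
  expect_equal(k2$agreement_category, "poor")

  # 10 cases, 4 categories, 9 agreements: contingency-table oracle
  a3 <- c("A", "A", "A", "B", "B", "C", "C", "D", "D", "D")
  b3 <- c("A", "A", "A", "B", "B", "C", "C", "D", "D", "C")
  tab <- table(a3, b3)
  po <- sum(diag(tab[, rownames(tab)])) / 10
  pe <- sum(rowSums(tab) * colSums(tab)[rownames(tab)]) / 100
  k3 <- cohen_kappa(a3, b3)
  expect_equal(k3$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)

  # symmetry and bounds
  set.seed(2)
  for (rep in 1:20) {
    u <- sample(letters[1:3], 12, replace = TRUE)
    v <- sample(letters[1:3], 12, replace = TRUE)
    kk <- cohen_kappa(u, v)
    expect_equal(kk$kappa, cohen_kappa(v, u)$kappa, tolerance = 1e-12)
    expect_gte(kk$kappa, -1)
    expect_lte(kk$kappa, 1)
  }
  # boundary values fall to the lower category
  expect_equal(with(list(k = 0.4), if (k > 0.75) "good"
                    else if (k > 0.4) "moderate" else "poor"), "poor")
  kc <- cohen_kappa(rep("a", 4), rep("a", 4))
  expect_true(kc$degenerate)
  expect_equal(kc$kappa, 1)
})

test_that("cohort summary arithmetic, exclusions and permutation invariance", {
  vals <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 2),
    modality = rep(c("DM", "CM"), 2),
    parameter = "size",
    value = c(10, 11, 10, 12))
  cs <- summarize_cohort(vals, reference = "DM")
  row <- cs$differences
  expect_equal(row$mean_pct, 15)
  expect_equal(row$se_pct, 5)

  one <- vals[vals$patient_id == "P1", ]
  expect_error(summarize_cohort(one), "n >= 2")

  # patient order must not matter
  cs2 <- summarize_cohort(vals[rev(seq_len(nrow(vals))), ], reference = "DM")
  expect_equal(cs2$differences$mean_pct, cs$differences$mean_pct)
  expect_equal(cs2$differences$wilcoxon_p, cs$differences$wilcoxon_p)

  # a patient missing one modality is excluded from that comparison
  vals3 <- rbind(vals, data.frame(patient_id = "P3", modality = "DM",
                                  parameter = "size", value = 9))
  expect_message(cs3 <- summarize_cohort(vals3, reference = "DM"),
                 "excluded")
  expect_equal(cs3$differences$n, 2)

  # kappa block from flow labels
  fl <- data.frame(patient_id = rep(c("P1", "P2", "P3"), 2),
                   modality = rep(c("DM", "CM"), each = 3),
                   FP = c("I", "II", "III", "I", "II", "II"))
  cs4 <- summarize_cohort(vals3, flow_labels = fl, reference = "DM")
  expect_equal(nrow(cs4$kappa), 1)
  expect_true(cs4$kappa$agreement %in% c("poor", "moderate", "good"))
})
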