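test_that("seropositivity cutoff is mean plus two SD of healthy controls", {
  hc <- c(80, 90, 100, 110, 120)  # mean 100
  expect_equal(seropositivity_cutoff(hc), 100 + 2 * sd(hc))
  expect_equal(seropositivity_cutoff(c(70, 100, 130)), 100 + 2 * 30)
  # constant controls: cutoff equals the constant, any larger value positive
  expect_equal(seropositivity_cutoff(rep(5, 10)), 5)
  expect_equal(sens_spec(6, rep(5, 10), 5)$sensitivity, 1)
  expect_error(seropositivity_cutoff(42), "at least 2")
})

test_that("the mean+2SD cutoff has the normal upper-tail specificity", {
  set.seed(20)
  hc <- rnorm(50000)
  cutoff <- seropositivity_cutoff(hc)
  spec <- mean(hc <= cutoff)
  expect_lt(abs(spec - 0.9772), 0.003)
})

test_that("sensitivity and specificity count strict positives", {
  expect_equal(sens_spec(c(2, 3), c(0, 1), 1.5)[1:2],
               list(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(c(2, 3), c(0, 1), 99)[1:2],
               list(sensitivity = 0, specificity = 1))
  # hand-counted 10 vs 10 toy: 7 cases and 2 controls above the cutoff
  case <- c(5, 6, 7, 8, 9, 10, 11, 1, 2, 3)
  ctrl <- c(1, 2, 3, 4, 0, -1, -2, -3, 6, 7)
  ss <- sens_spec(case, ctrl, 4.5)
  expect_equal(ss$sensitivity, 0.7)
  expect_equal(ss$specificity, 0.8)
  expect_error(sens_spec(numeric(0), ctrl, 1), "non-empty")
})

test_that("monotone cutoff sweep moves sensitivity down and specificity up", {
  set.seed(9)
  case <- rnorm(40, 1); ctrl <- rnorm(40)
  cuts <- sort(c(-Inf, sample(c(case, ctrl), 20), Inf))
  ss <- vapply(cuts, function(ct) {
    s <- sens_spec(case, ctrl, ct)
    c(s$sensitivity, s$specificity)
  }, numeric(2))
  expect_equal(ss[, 1], c(1, 0))
  expect_equal(ss[, ncol(ss)], c(0, 1))
  expect_true(all(diff(ss[1, ]) <= 0))
  expect_true(all(diff(ss[2, ]) >= 0))
})

test_that("nonparametric AUC equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(5, 6), c(1, 2))$auc, 1)
  expect_equal(roc_auc(rep(3, 5), rep(3, 7))$auc, 0.5)
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(1:30, 1); n0 <- sample(1:30, 1)
    # integer-valued draws guarantee ties occur
    case <- sample(0:8, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
    ctrl <- sample(0:8, n0, replace = TRUE)
    expect_identical(roc_auc(case, ctrl)$auc, auc_bruteforce(case, ctrl))
  }
})

test_that("AUC is antisymmetric under group exchange", {
  set.seed(12)
  for (i in 1:25) {
    a <- sample(0:5, sample(2:20, 1), replace = TRUE)
    b <- sample(0:5, sample(2:20, 1), replace = TRUE)
    expect_equal(roc_auc(a, b)$auc + roc_auc(b, a)$auc, 1)
  }
})

test_that("DeLong interval matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    case <- rnorm(sample(10:60, 1), 0.8)
    ctrl <- rnorm(sample(10:60, 1))
    ours <- roc_auc(case, ctrl)
    ref <- suppressMessages(pROC::ci.auc(
      pROC::roc(response = rep(c(1, 0), c(length(case), length(ctrl))),
                predictor = c(case, ctrl), quiet = TRUE),
      method = "delong"))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(ours$ci95[1], max(0, as.numeric(ref[1])), tolerance = 1e-7)
    expect_equal(ours$ci95[2], min(1, as.numeric(ref[3])), tolerance = 1e-7)
  }
})

test_that("prevalence arithmetic reproduces printed subgroup percentages", {
  expect_equal(prevalence(n_positive = 10, n_total = 48)$percent, 20.8)
  expect_equal(prevalence(n_positive = 13, n_total = 48)$percent, 27.1)
  expect_equal(prevalence(n_positive = 0, n_total = 37)$percent, 0)
  p <- prevalence(values = c(1, 2, 10, 20), cutoff = 5)
  expect_equal(p$n_positive, 2L)
  expect_equal(p$percent, 50)
})

test_that("prevalence comparison picks Fisher or chi-square by expected counts", {
  eq <- compare_prevalence(list(pos = 3, total = 10), list(pos = 3, total = 10))
  expect_equal(eq$test_used, "fisher")
  expect_equal(eq$p_value, 1)
  f <- compare_prevalence(list(pos = 6, total = 13), list(pos = 2, total = 35))
  expect_equal(f$test_used, "fisher")
  c2 <- compare_prevalence(list(pos = 50, total = 100),
                           list(pos = 50, total = 100))
  expect_equal(c2$test_used, "chi-square")
  expect_equal(c2$p_value, 1)
})

test_that("clinical correlation grid handles self, null and planted cases", {
  co <- simulate_cohort(small_sim_config(
    seed = 6, group_sizes = list(RA = 90L, HC = 24L, SLE = 10L, OA = 10L),
    n_acpa_negative = 22L))
  man <- co$manifest
  case_ids <- man$sample_id[man$role == "case"]
  serum <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(co$scans[serum], co$layout, man)
  inf <- co$ground_truth$informative_probe_ids

  # an antibody correlated with itself has r = 1
  man2 <- man
  man2$self <- mat$net[match(man2$sample_id, rownames(mat$net)), inf[1]]
  g <- correlate_clinical(mat, man2, inf[1], "self", samples = case_ids)
  expect_equal(g$r, 1)

  # planted coupling: informative antibodies lean positive on ESR/RF/IgG
  g2 <- correlate_clinical(mat, man, inf, c("esr", "rf", "igg"),
                           samples = case_ids)
  expect_gt(mean(g2$r > 0), 0.8)
  expect_true(all(g2$p_bonferroni >= g2$p, na.rm = TRUE))
  expect_true(all(g2$p_bonferroni <= 1, na.rm = TRUE))

  # a variable independent of every antibody stays non-significant
  hits <- replicate(20, {
    man3 <- man
    man3$noise <- NA_real_
    man3$noise[man$role == "case"] <- rnorm(sum(man$role == "case"))
    g3 <- correlate_clinical(mat, man3, inf, "noise", samples = case_ids)
    any(g3$p_bonferroni < 0.05, na.rm = TRUE)
  })
  expect_gte(mean(!hits), 0.9)

  # cells with under 3 pairs are excluded from the Bonferroni count
  man4 <- man
  man4$sparse <- NA_real_
  man4$sparse[match(case_ids[1:2], man4$sample_id)] <- c(1, 2)
  g4 <- correlate_clinical(mat, man4, inf[1:2], c("esr", "sparse"),
                           samples = case_ids)
  expect_true(all(is.na(g4$r[g4$variable == "sparse"])))
  expect_equal(attr(g4, "n_tests"), 2L)
})

test_that("cohort embedding is deterministic and preserves separation", {
  set.seed(44)
  x <- rbind(matrix(rnorm(20 * 5), 20, 5),
             matrix(rnorm(20 * 5, 6), 20, 5))
  rownames(x) <- paste0("s", 1:40)
  e1 <- embed_cohort(x, seed = 3, log_transform = FALSE)
  e2 <- embed_cohort(x, seed = 3, log_transform = FALSE)
  expect_identical(e1, e2)
  d <- as.matrix(dist(cbind(e1$tsne1, e1$tsne2)))
  within <- mean(d[1:20, 1:20][upper.tri(diag(20))])
  between <- mean(d[1:20, 21:40])
  expect_gt(between, within)

  # degenerate input: identical samples still embed to finite coordinates
  same <- matrix(1, 5, 3, dimnames = list(paste0("r", 1:5), NULL))
  e3 <- embed_cohort(same, seed = 1, log_transform = FALSE)
  expect_true(all(is.finite(e3$tsne1)) && all(is.finite(e3$tsne2)))
  expect_error(embed_cohort(same[1:4, ]), "at least 5")
})

test_that("panel report has the focused-array table shape", {
  co <- simulate_cohort(small_sim_config(seed = 2))
  man <- co$manifest
  serum <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(co$scans[serum], co$layout, man)
  inf <- co$ground_truth$informative_probe_ids
  panel <- antibody_panel_report(mat, man, co$layout, inf)
  expect_equal(nrow(panel), length(inf))
  expect_true(all(panel$auc >= 0 & panel$auc <= 1))
  expect_true(all(panel$ci_lo <= panel$auc & panel$auc <= panel$ci_hi))
  expect_true(all(panel$acpa_neg_n <= sum(man$acpa_status == "negative")))
  expect_true(all(grepl("^NM_", panel$accession)))
  # informative antigens separate cases from controls
  expect_gt(mean(panel$auc), 0.55)
})
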