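test_that("cohort split reproduces the published arithmetic and is seeded", {
  cases <- sprintf("RA%03d", 1:182)
  ctrls <- sprintf("CT%03d", 1:261)
  sp <- split_cohort(cases, ctrls, 120, 120, seed = 1)
  expect_length(sp$test$cases, 62L)
  expect_length(sp$test$controls, 141L)
  expect_length(intersect(sp$train$cases, sp$test$cases), 0L)
  expect_setequal(c(sp$train$cases, sp$test$cases), cases)
  sp2 <- split_cohort(cases, ctrls, 120, 120, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_cohort(cases, ctrls, 120, 120, seed = 2)))
  expect_error(split_cohort(cases, ctrls, 200, 120, seed = 1), "exceed")
  expect_warning(split_cohort(cases[1:8], ctrls[1:8], 8, 8, seed = 1), "empty")
})

toy_xy <- function(n = 60, p = 4, shift = 2, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- rep(c("case", "control"), each = n / 2)
  x[y == "case", 1] <- x[y == "case", 1] + shift
  list(x = x, y = y)
}

test_that("grid search finds separating parameters and honours the lattice", {
  d <- toy_xy(n = 48, shift = 6)
  set.seed(1)
  gs <- svm_grid_search(d$x, d$y, default_svm_grid(), cv_folds = 4)
  expect_equal(gs$cv_auc, 1)
  # single-point lattice is returned verbatim
  one <- data.frame(C = 7, gamma = 0.3)
  set.seed(1)
  gs1 <- svm_grid_search(d$x, d$y, one, cv_folds = 4)
  expect_equal(c(gs1$C, gs1$gamma), c(7, 0.3))
  # pure noise hovers at chance
  dn <- toy_xy(n = 60, shift = 0, seed = 9)
  set.seed(2)
  gsn <- svm_grid_search(dn$x, dn$y, data.frame(C = 1, gamma = 0.25))
  expect_lt(abs(gsn$cv_auc - 0.5), 0.2)
  expect_error(svm_grid_search(d$x, rep("case", nrow(d$x))), "per class")
})

test_that("RFE eliminates a constant feature first", {
  d <- toy_xy(n = 40, p = 5, shift = 2)
  x <- cbind(d$x, konst = 0)
  ord <- rfe_rank(x, d$y, C = 1, gamma = 0.2)
  expect_equal(ord[1], "konst")
  expect_setequal(ord, colnames(x))
})

test_that("first RFE elimination matches the brute-force kernel oracle", {
  set.seed(77)
  for (i in 1:12) {
    n <- sample(16:40, 1); p <- sample(3:7, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- sample(rep(c("case", "control"), length.out = n))
    x[y == "case", 1] <- x[y == "case", 1] + runif(1, 0, 2)
    C <- sample(c(0.5, 1, 4, 32), 1); g <- sample(c(0.05, 0.2, 2), 1)
    ours <- rfe_rank(x, y, C, g)[1]
    expect_identical(ours, rfe_first_elimination_oracle(x, y, C, g))
  }
})

test_that("a planted separating feature survives RFE to the end", {
  set.seed(101)
  wins <- replicate(40, {
    n <- 40
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(c("case", "control"), each = n / 2)
    x[y == "case", 3] <- x[y == "case", 3] + 4
    x <- scale(x)
    ord <- rfe_rank(x, y, C = 1, gamma = 1 / 6)
    ord[length(ord)] == "f3"
  })
  expect_gte(mean(wins), 0.95)
})

test_that("near-zero gamma reproduces the linear w-squared ordering", {
  d <- toy_xy(n = 30, p = 4, shift = 3)
  z <- scale(d$x)
  ord <- rfe_rank(z, d$y, C = 10, gamma = 1e-6)
  yf <- factor(d$y, levels = c("control", "case"))
  lin <- e1071::svm(z, yf, kernel = "linear", cost = 10, scale = FALSE)
  w2 <- drop(t(lin$SV) %*% lin$coefs)^2
  # the feature the linear SVM weights most survives longest
  expect_equal(ord[length(ord)], names(which.max(w2)))
})

test_that("feature-count selection recovers planted features and boundaries", {
  set.seed(55)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("case", "control"), each = n / 2)
  # moderate shifts: the fold AUROC must not saturate with a subset of
  # the planted features, otherwise smaller k ties win legitimately
  for (f in c(2, 5, 7)) x[y == "case", f] <- x[y == "case", f] + 1.1
  z <- scale(x)
  hits <- replicate(10, {
    ord <- rfe_rank(z, y, C = 1, gamma = 1 / 8)
    sel <- select_feature_count(z, y, ord, C = 1, gamma = 1 / 8)
    all(c("f2", "f5", "f7") %in% sel$features)
  })
  expect_gte(mean(hits), 0.9)

  # one feature in total forces k = 1
  x1 <- z[, "f2", drop = FALSE]
  set.seed(1)
  sel1 <- select_feature_count(x1, y, "f2", C = 1, gamma = 1)
  expect_equal(sel1$k, 1L)
})

test_that("threshold calibration lands at the target training specificity", {
  scores <- c(1:100, 101:140)  # controls 1..100, cases 101..140
  y <- rep(c("control", "case"), c(100, 40))
  cal <- calibrate_threshold(scores, y, 0.90)
  expect_equal(cal$threshold, 90)
  expect_equal(cal$cv_specificity, 0.90)
  expect_equal(cal$cv_sensitivity, 1)

  # perfectly separated scores exceed the target
  cal2 <- calibrate_threshold(c(rep(0, 10), rep(5, 10)),
                              rep(c("control", "case"), each = 10), 0.9)
  expect_equal(cal2$cv_specificity, 1)
  expect_equal(cal2$cv_sensitivity, 1)

  # unreachable target warns and refuses every call
  expect_warning(
    cal3 <- calibrate_threshold(c(rep(10, 5), rep(0, 5)),
                                rep(c("control", "case"), each = 5), 0.9),
    "unreachable")
  expect_equal(cal3$cv_sensitivity, 0)
})

test_that("trained models satisfy KKT constraints and score consistently", {
  d <- toy_xy()
  m <- train_ra_model(d$x, d$y,
                      model_config(grid = data.frame(C = 2, gamma = 0.25),
                                   seed = 3))
  expect_lt(abs(sum(m$coefs)), 1e-8)
  expect_true(all(abs(m$coefs) <= m$C + 1e-8))
  expect_true(length(m$features) >= 1)

  # manual decision function agrees with the solver's decision values
  z <- sweep(sweep(d$x[, m$features, drop = FALSE], 2, m$center), 2,
             m$scale, "/")
  yf <- factor(d$y, levels = c("control", "case"))
  refit <- e1071::svm(z, yf, kernel = "radial", cost = m$C, gamma = m$gamma,
                      scale = FALSE)
  pr <- predict(refit, z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  if (!startsWith(colnames(attr(pr, "decision.values"))[1], "case")) dv <- -dv
  expect_equal(unname(model_scores(m, d$x)), unname(dv), tolerance = 1e-6)

  # higher scores are case-like
  s <- model_scores(m, d$x)
  expect_gt(mean(s[d$y == "case"]), mean(s[d$y == "control"]))
})

test_that("training is deterministic and blind to test data", {
  d <- toy_xy(n = 80)
  cfg <- model_config(grid = data.frame(C = c(1, 4), gamma = c(0.1, 0.25)),
                      seed = 11)
  tr <- 1:48; te <- 49:80
  m1 <- train_ra_model(d$x[tr, ], d$y[tr], cfg)
  m2 <- train_ra_model(d$x[tr, ], d$y[tr], cfg)
  expect_identical(m1, m2)
  # canary: perturbing held-out rows cannot change the trained model
  x_pert <- d$x
  x_pert[te, ] <- x_pert[te, ] * 3 + 7
  m3 <- train_ra_model(x_pert[tr, ], d$y[tr], cfg)
  expect_identical(m1, m3)

  # self-prediction is at least as good as the cross-validated estimates
  ev_train <- evaluate_model(m1, d$x[tr, ], d$y[tr])
  expect_gte(ev_train$sensitivity + ev_train$specificity,
             m1$cv$sensitivity + m1$cv$specificity)
})

test_that("evaluation reports stratified sensitivity and rejects bad input", {
  d <- toy_xy(n = 80)
  cfg <- model_config(grid = data.frame(C = 2, gamma = 0.25), seed = 5)
  tr <- c(1:24, 41:64)  # cases occupy the first 40 rows
  te <- c(25:40, 65:80)
  m <- train_ra_model(d$x[tr, ], d$y[tr], cfg)
  acpa <- rep(c("positive", "negative", "unknown", "positive"), 8)
  ev <- evaluate_model(m, d$x[te, ], d$y[te], acpa)
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_true(!is.na(ev$sensitivity_acpa_pos))
  expect_error(evaluate_model(m, d$x[te, 2:4], d$y[te]), "lacks model feature")

  # label permutation drives AUROC to chance
  set.seed(6)
  null_auc <- replicate(20, evaluate_model(m, d$x[te, ],
                                           sample(d$y[te]))$auroc)
  expect_lt(abs(mean(null_auc) - 0.5), 0.1)
})

test_that("model serialization round-trips scoring exactly", {
  d <- toy_xy()
  m <- train_ra_model(d$x, d$y,
                      model_config(grid = data.frame(C = 2, gamma = 0.25),
                                   seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$features, m$features)
  expect_equal(model_scores(back, d$x), model_scores(m, d$x))
  expect_equal(back$threshold, m$threshold)
})

test_that("single-marker comparison matches the model rule", {
  set.seed(14)
  y_test <- rep(c("case", "control"), c(40, 60))
  score <- c(rnorm(40, 2), rnorm(60))
  train_ctrl <- data.frame(m1 = rnorm(100))
  test_m <- data.frame(m1 = score)
  out <- compare_single_markers(train_ctrl, test_m, y_test)
  expect_equal(out$cutoff, sort(train_ctrl$m1)[90])

  # two markers positive on disjoint halves of the cases OR-combine
  mk_a <- c(rep(10, 12), rep(0, 28), rep(0, 60))
  mk_b <- c(rep(0, 12), rep(10, 12), rep(0, 16), rep(0, 60))
  tr <- data.frame(a = rnorm(100), b = rnorm(100))
  out2 <- compare_single_markers(tr, data.frame(a = mk_a, b = mk_b), y_test)
  sens <- setNames(out2$sensitivity, out2$marker)
  expect_equal(unname(sens["a"] + sens["b"]), unname(sens["a+b"]))

  # a pure-noise marker detects about one minus the specificity target
  set.seed(15)
  noise_sens <- replicate(40, {
    tr <- data.frame(nz = rnorm(200))
    te <- data.frame(nz = rnorm(100))
    compare_single_markers(tr, te, y_test)$sensitivity
  })
  expect_lt(abs(mean(noise_sens) - 0.10), 0.05)
})
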