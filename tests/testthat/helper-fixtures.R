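# Fixture builders and independent oracles shared across tests.

# Minimal layout: n protein probes in duplicate plus a buffer pair,
# laid out in one block.
tiny_layout <- function(n_protein = 2L) {
  probes <- data.frame(
    probe_id = c(sprintf("P%02d", seq_len(n_protein)), "BUF"),
    name = c(sprintf("AG%02d", seq_len(n_protein)), "buffer"),
    accession = c(sprintf("NM_%06d", seq_len(n_protein)), NA),
    category = c(rep("protein", n_protein), "buffer"),
    stringsAsFactors = FALSE)
  n_spots <- 2L * (n_protein + 1L)
  cols <- ceiling(sqrt(n_spots))
  rows <- ceiling(n_spots / cols)
  slot <- seq_len(n_spots) - 1L
  spots <- data.frame(block = 1L, row = slot %/% cols + 1L,
                      col = slot %% cols + 1L,
                      probe_id = rep(probes$probe_id, each = 2L),
                      stringsAsFactors = FALSE)
  array_layout(probes, spots, 1L, rows, cols)
}

# Scan over a tiny layout with per-probe foregrounds given as a named
# list of length-2 vectors (one value per duplicate spot).
tiny_scan <- function(layout, fg_by_probe, bg = 300, bg_sd = 40,
                      flags = NULL, sample_id = "S1") {
  sp <- layout$spots
  fg <- numeric(nrow(sp))
  for (p in unique(sp$probe_id)) {
    v <- if (p %in% names(fg_by_probe)) fg_by_probe[[p]] else c(bg, bg)
    fg[sp$probe_id == p] <- rep_len(v, sum(sp$probe_id == p))
  }
  spots <- data.frame(block = sp$block, row = sp$row, col = sp$col,
                      probe_id = sp$probe_id, f532 = fg, b532 = bg,
                      b532_sd = bg_sd,
                      flag = if (is.null(flags)) 0L else flags,
                      stringsAsFactors = FALSE)
  array_scan(paste0("scan-", sample_id), sample_id, spots, layout)
}

# Small cohort configuration used wherever full study size is not the
# point: keeps every stage exercised while staying fast.
small_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_probes = 60L, n_informative = 6L,
         group_sizes = list(RA = 40L, HC = 24L, SLE = 10L, OA = 10L),
         n_acpa_negative = 10L, early_subset_size = 3L),
    list(...))
  do.call(sim_config, c(list(seed = seed), args))
}

# Exhaustive pairwise Mann-Whitney concordance (the AUC oracle).
auc_bruteforce <- function(case, control) {
  s <- 0
  for (x in case) for (y in control)
    s <- s + (if (x > y) 1 else if (x == y) 0.5 else 0)
  s / (length(case) * length(control))
}

# Independent recomputation of the first RFE elimination: fit the SVM
# once, then for every feature rebuild the reduced kernel from scratch
# with plain double loops and compare margin criteria.
rfe_first_elimination_oracle <- function(x, y, C, gamma) {
  yf <- factor(y, levels = c("control", "case"))
  m <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                  cost = C, gamma = gamma, scale = FALSE)
  sv <- m$SV
  co <- m$coefs[, 1]
  n <- nrow(sv)
  Jof <- function(cols) {
    J <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      k <- exp(-gamma * sum((sv[i, cols] - sv[j, cols])^2))
      J <- J + co[i] * co[j] * k
    }
    J / 2
  }
  full <- Jof(seq_len(ncol(sv)))
  dJ <- vapply(seq_len(ncol(sv)), function(f)
    abs(full - Jof(setdiff(seq_len(ncol(sv)), f))), numeric(1))
  colnames(x)[which.min(dJ)]
}

# Phase I + II driver used by recovery and acceptance tests.
run_screening <- function(cohort, ...) {
  man <- cohort$manifest
  serum_ids <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(cohort$scans[serum_ids], cohort$layout, man)
  hits <- call_hits_cohort(cohort$scans[serum_ids],
                           cohort$scans[[man$sample_id[man$role == "blank"][1]]],
                           cohort$scans[[man$sample_id[man$role == "secondary-only"][1]]],
                           cohort$layout)
  pa <- aggregate_duplicates(cohort$scans[[man$sample_id[man$role == "pooled-control"][1]]],
                             cohort$layout)
  cand <- select_candidates(hits, mat, stats::setNames(pa$net, pa$probe_id),
                            man, ...)
  list(matrix = mat, hits = hits, candidates = cand,
       pooled = stats::setNames(pa$net, pa$probe_id))
}

# Train/evaluate driver over a screened cohort.
run_model <- function(cohort, screened, n_case_train, n_control_train,
                      seed, features = NULL) {
  man <- cohort$manifest
  case_ids <- man$sample_id[man$role == "case"]
  control_ids <- man$sample_id[man$role == "control"]
  if (is.null(features)) features <- screened$candidates$probe_id
  sp <- split_cohort(case_ids, control_ids, n_case_train, n_control_train,
                     seed = seed + 101L)
  x <- log10(pmax(screened$matrix$net[, features, drop = FALSE], 1))
  tr <- c(sp$train$cases, sp$train$controls)
  te <- c(sp$test$cases, sp$test$controls)
  model <- train_ra_model(x[tr, , drop = FALSE],
                          ifelse(tr %in% case_ids, "case", "control"),
                          model_config(seed = seed))
  eval <- evaluate_model(model, x[te, , drop = FALSE],
                         ifelse(te %in% case_ids, "case", "control"),
                         man$acpa_status[match(te, man$sample_id)])
  list(model = model, eval = eval, split = sp, x = x,
       case_ids = case_ids, train_ids = tr, test_ids = te)
}
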