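## Phase-II diagnostics: seropositivity cutoffs, sensitivity/specificity,
## nonparametric ROC with DeLong confidence intervals, subgroup prevalence
## comparisons, clinical correlation with Bonferroni correction, and a 2-D
## cohort embedding.

# Round half away from zero, the rendering convention of clinical tables.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Seropositivity cutoff from healthy controls
#'
#' Cutoff = mean + 2 SD of the healthy-control intensities (SD with n-1
#' denominator). Downstream positivity is strict: a sample is positive
#' when its value exceeds the cutoff.
#'
#' @param hc_values numeric vector of healthy-control intensities
#'   (at least 2 non-missing).
#' @return the cutoff (fluorescence units).
#' @export
seropositivity_cutoff <- function(hc_values) {
  v <- hc_values[!is.na(hc_values)]
  if (length(v) < 2L)
    stop("need at least 2 healthy-control values to set a cutoff")
  mean(v) + 2 * stats::sd(v)
}

#' Sensitivity and specificity at a cutoff
#'
#' Sensitivity is the fraction of cases strictly above the cutoff;
#' specificity the fraction of controls at or below it.
#'
#' @param case_values,control_values numeric vectors (non-empty after
#'   removing missing values).
#' @param cutoff decision cutoff.
#' @return list with `sensitivity`, `specificity` and the counts.
#' @export
sens_spec <- function(case_values, control_values, cutoff) {
  ca <- case_values[!is.na(case_values)]
  co <- control_values[!is.na(control_values)]
  if (length(ca) == 0L || length(co) == 0L)
    stop("need non-empty case and control groups")
  list(sensitivity = mean(ca > cutoff),
       specificity = mean(co <= cutoff),
       n_case = length(ca), n_control = length(co),
       n_case_positive = sum(ca > cutoff),
       n_control_positive = sum(co > cutoff))
}

#' Nonparametric ROC area with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance: the mean over all
#' (case, control) pairs of 1 if the case value is larger, 0.5 on ties,
#' 0 otherwise (computed via midranks, which is exact). The confidence
#' interval uses the DeLong placement-variance estimator, truncated to
#' `[0, 1]`.
#'
#' @param case_values,control_values numeric vectors (non-empty after
#'   removing missing values).
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci95` (length-2 vector), `se`, `n_case`,
#'   `n_control`.
#' @export
roc_auc <- function(case_values, control_values, conf_level = 0.95) {
  ca <- case_values[!is.na(case_values)]
  co <- control_values[!is.na(control_values)]
  n1 <- length(ca); n0 <- length(co)
  if (n1 == 0L || n0 == 0L)
    stop("need non-empty case and control groups")
  r <- rank(c(ca, co))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements: for each case, the fraction of controls it beats
  # (ties half); symmetrically for controls.
  sco <- sort(co)
  v10 <- ((findInterval(ca, sco, left.open = TRUE) +
             findInterval(ca, sco)) / 2) / n0
  sca <- sort(ca)
  v01 <- 1 - ((findInterval(co, sca, left.open = TRUE) +
                 findInterval(co, sca)) / 2) / n1
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  list(auc = auc, ci95 = ci, se = se, n_case = n1, n_control = n0)
}

#' Seropositivity prevalence
#'
#' Either supply `values` and `cutoff` (positivity is strict) or a
#' precomputed `n_positive`. Percent is reported half-up to 1 decimal.
#'
#' @param values numeric vector, or `NULL` when `n_positive` is given.
#' @param cutoff positivity cutoff (used with `values`).
#' @param n_total denominator (defaults to `length(values)`).
#' @param n_positive precomputed positive count.
#' @return list with `n_positive`, `n_total`, `percent`.
#' @export
prevalence <- function(values = NULL, cutoff = NULL, n_total = NULL,
                       n_positive = NULL) {
  if (is.null(n_positive)) {
    v <- values[!is.na(values)]
    n_positive <- sum(v > cutoff)
    if (is.null(n_total)) n_total <- length(v)
  }
  if (is.null(n_total) || n_total < 1L) stop("n_total must be >= 1")
  list(n_positive = as.integer(n_positive), n_total = as.integer(n_total),
       percent = round_half_up(100 * n_positive / n_total, 1L))
}

#' Compare prevalence between two subgroups
#'
#' Builds the 2x2 table and uses Fisher's exact test when any expected
#' cell count is below 5, otherwise the chi-square test with continuity
#' correction.
#'
#' @param a,b lists with elements `pos` and `total` for the two groups.
#' @return list with `test_used` ("fisher" or "chi-square"),
#'   `statistic` (chi-square statistic or Fisher odds-ratio estimate),
#'   `p_value` and the `table`.
#' @export
compare_prevalence <- function(a, b) {
  stopifnot(a$total >= 1, b$total >= 1,
            a$pos <= a$total, b$pos <= b$total)
  tab <- rbind(c(a$pos, a$total - a$pos), c(b$pos, b$total - b$pos))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(test_used = "fisher", statistic = unname(ft$estimate),
         p_value = ft$p.value, table = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    list(test_used = "chi-square", statistic = unname(ct$statistic),
         p_value = ct$p.value, table = tab)
  }
}

#' Correlate antibody intensities with clinical variables
#'
#' For each (antibody, variable) pair, observations are paired with
#' pairwise deletion of missing values; cells with fewer than 3 pairs are
#' reported missing and excluded from the Bonferroni count. Spearman rank
#' correlation is used by default; Pearson only when both members pass a
#' Shapiro-Wilk normality screen at `alpha_normal`. Corrected p-values
#' multiply by the number of tests actually performed, capped at 1.
#'
#' @param matrix an `intensity_matrix` (or plain samples-x-probes matrix
#'   with rownames).
#' @param manifest cohort manifest holding the clinical variables.
#' @param antibodies probe identifiers (columns of the matrix).
#' @param variables clinical column names in the manifest.
#' @param samples optional subset of sample identifiers (default: all
#'   matrix samples present in the manifest).
#' @param alpha_normal significance level of the normality screen.
#' @return An object of class `correlation_grid`: data.frame with
#'   columns `antibody`, `variable`, `method`, `n`, `r`, `p`,
#'   `p_bonferroni`.
#' @export
correlate_clinical <- function(matrix, manifest, antibodies, variables,
                               samples = NULL, alpha_normal = 0.05) {
  net <- if (inherits(matrix, "intensity_matrix")) matrix$net else matrix
  if (is.null(samples))
    samples <- intersect(rownames(net), manifest$sample_id)
  net <- net[samples, , drop = FALSE]
  man <- manifest[match(samples, manifest$sample_id), , drop = FALSE]
  miss_ab <- setdiff(antibodies, colnames(net))
  if (length(miss_ab)) stop("antibody not in matrix: ",
                            paste(miss_ab, collapse = ", "))
  miss_v <- setdiff(variables, names(man))
  if (length(miss_v)) stop("variable not in manifest: ",
                           paste(miss_v, collapse = ", "))
  normal_ok <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(v) > 5000L || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normal
  }
  rows <- expand.grid(antibody = antibodies, variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    x <- net[, rows$antibody[i]]
    y <- man[[rows$variable[i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L)
      return(list(method = NA_character_, n = n, r = NA_real_, p = NA_real_))
    method <- if (normal_ok(x[ok]) && normal_ok(y[ok])) "pearson" else "spearman"
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    list(method = method, n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(rows,
                    method = vapply(res, `[[`, character(1), "method"),
                    n = vapply(res, `[[`, integer(1), "n"),
                    r = vapply(res, `[[`, numeric(1), "r"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * m)
  structure(out, class = c("correlation_grid", "data.frame"), n_tests = m)
}

#' Two-dimensional cohort embedding
#'
#' Reduces the samples-x-probes intensity profile to two dimensions with
#' t-SNE (Barnes-Hut via Rtsne). Coordinates are deterministic for a
#' fixed seed and carry neighbourhood structure only, no scale guarantee.
#'
#' @param matrix an `intensity_matrix` or plain numeric matrix with
#'   sample rownames; at least 5 samples.
#' @param manifest optional manifest used to label samples by group.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; defaults to
#'   `min(30, (n - 1) / 3 - 1e-6)` to remain valid at small n.
#' @param log_transform log10-transform intensities first (default TRUE).
#' @return data.frame with `sample_id`, `tsne1`, `tsne2` and `group`
#'   (when a manifest is given).
#' @export
embed_cohort <- function(matrix, manifest = NULL, seed = 1L,
                         perplexity = NULL, log_transform = TRUE) {
  net <- if (inherits(matrix, "intensity_matrix")) matrix$net else matrix
  n <- nrow(net)
  if (is.null(n) || n < 5L) stop("need at least 5 samples to embed")
  x <- as.matrix(net)
  x[is.na(x)] <- 1
  if (log_transform) x <- log10(pmax(x, 1))
  if (all(x == rep(x[1, ], each = n))) {
    # all profiles identical: no neighbourhood structure to embed
    out <- data.frame(sample_id = rownames(net) %||% as.character(seq_len(n)),
                      tsne1 = rep(0, n), tsne2 = rep(0, n),
                      stringsAsFactors = FALSE)
    if (!is.null(manifest))
      out$group <- manifest$group[match(out$sample_id, manifest$sample_id)]
    return(out)
  }
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3 - 1e-6)
  # exact (theta = 0) gradients: robust to duplicate profiles, which
  # crash the Barnes-Hut tree, and still fast at cohort scale
  emb <- with_seed(seed, Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity,
                                      check_duplicates = FALSE, theta = 0,
                                      pca = ncol(x) > 50L, verbose = FALSE))
  out <- data.frame(sample_id = rownames(net) %||% as.character(seq_len(n)),
                    tsne1 = emb$Y[, 1], tsne2 = emb$Y[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(manifest))
    out$group <- manifest$group[match(out$sample_id, manifest$sample_id)]
  out
}

#' Per-antibody diagnostic panel report
#'
#' For each probe: a seropositivity cutoff from healthy controls
#' (mean + 2 SD), nonparametric AUC with DeLong confidence interval,
#' sensitivity/specificity over cases versus controls, and
#' ACPA-negative-case prevalence — the shape of a focused-array
#' validation table.
#'
#' @param matrix an `intensity_matrix`.
#' @param manifest cohort manifest.
#' @param layout optional `array_layout` supplying accessions.
#' @param probes probe subset (default: all matrix probes).
#' @param controls `"all"` pools healthy and disease controls in the
#'   specificity/AUC denominator; `"hc"` restricts to healthy controls.
#' @return An object of class `diagnostic_panel`: data.frame with one
#'   row per probe (`probe_id`, `accession`, `cutoff`, `auc`, `ci_lo`,
#'   `ci_hi`, `sensitivity_pct`, `specificity_pct`, `acpa_neg_n`,
#'   `acpa_neg_pct`).
#' @export
antibody_panel_report <- function(matrix, manifest, layout = NULL,
                                  probes = NULL,
                                  controls = c("all", "hc")) {
  controls <- match.arg(controls)
  if (is.null(probes)) probes <- matrix$probe_ids
  man <- manifest[match(matrix$sample_ids, manifest$sample_id), ]
  case_ids <- man$sample_id[man$role == "case"]
  hc_ids <- man$sample_id[man$role == "control" & man$group == "HC"]
  ctl_ids <- if (controls == "all") man$sample_id[man$role == "control"] else hc_ids
  acpa_neg_ids <- man$sample_id[man$role == "case" & man$acpa_status == "negative"]
  rows <- lapply(probes, function(p) {
    v <- matrix$net[, p]
    cutoff <- seropositivity_cutoff(v[hc_ids])
    ss <- sens_spec(v[case_ids], v[ctl_ids], cutoff)
    roc <- roc_auc(v[case_ids], v[ctl_ids])
    prev <- prevalence(v[acpa_neg_ids], cutoff, n_total = length(acpa_neg_ids))
    data.frame(probe_id = p,
               accession = if (!is.null(layout))
                 layout$probes$accession[match(p, layout$probes$probe_id)]
               else NA_character_,
               cutoff = cutoff, auc = roc$auc,
               ci_lo = roc$ci95[1], ci_hi = roc$ci95[2],
               sensitivity_pct = round_half_up(100 * ss$sensitivity, 1L),
               specificity_pct = round_half_up(100 * ss$specificity, 1L),
               acpa_neg_n = prev$n_positive, acpa_neg_pct = prev$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$probe_id), ]
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_panel", "data.frame"))
}
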