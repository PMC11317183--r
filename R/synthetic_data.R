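## Synthetic serum-array cohorts with known ground truth.
##
## The generator emulates a two-phase autoantibody study: a proteome-style
## layout printed in duplicate with control probes, per-sample scans with
## background and duplicate technical noise, reference arrays (pooled
## control, blank, secondary-antibody-only), and clinical covariates
## coupled to the planted antibody signal.

#' Simulation configuration
#'
#' Defaults mirror the cohort structure of a two-phase RA autoantibody
#' study: 182 RA cases (48 ACPA-negative), 103 healthy controls and 158
#' disease controls (48 AS, 47 SLE, 31 SS, 32 OA), probed on an array of
#' `n_probes` antigens printed in duplicate of which `n_informative`
#' carry true case reactivity.
#'
#' Intensities are log10-normal: antigen `a` has a null (control) level
#' `10^N(mu_a, baseline_log_sd)` with `mu_a` drawn uniformly from
#' `baseline_log_mean_range`. Each case reacts to one "primary"
#' informative antigen (shift `effect_size` log10 units, lognormal-like
#' magnitude noise `reaction_cv`) and to each remaining informative
#' antigen with probability `secondary_react_prob`; ACPA-negative cases
#' react at all with probability `acpa_neg_react_prob` and their shifts
#' are attenuated by `acpa_neg_attenuation`. Cases with disease duration
#' under 2 years gain extra reactivity (`early_react_prob`) and an
#' `early_boost` shift on a designated early-antigen subset. Disease
#' controls cross-react sparsely (`dc_react_prob`). Each probe is
#' rendered as two duplicate spots with multiplicative noise of
#' coefficient of variation `duplicate_cv` over a background draw
#' (`background_mean`, `background_sd` fluorescence units). Clinical
#' covariates (ESR, RF, IgG, ...) share a latent factor with the
#' antibody burden at strength `clinical_coupling`.
#'
#' @param seed integer seed; the same config reproduces byte-identical
#'   output files.
#' @param n_probes,n_informative antigen counts.
#' @param group_sizes named list of serum-sample counts per group.
#' @param n_acpa_negative number of ACPA-negative RA cases.
#' @param effect_size case reactivity shift in log10 intensity units.
#' @param acpa_neg_attenuation multiplier on `effect_size` in
#'   ACPA-negative cases.
#' @param acpa_neg_react_prob probability an ACPA-negative case reacts
#'   at all (heterogeneity).
#' @param secondary_react_prob per-antigen probability of reactions
#'   beyond the primary antigen.
#' @param dc_react_prob per-antigen cross-reactivity probability in
#'   disease controls.
#' @param early_boost extra log10 shift on the early-antigen subset for
#'   cases with duration < 2 years.
#' @param early_react_prob extra reaction probability on the early
#'   subset for early cases.
#' @param early_subset_size number of informative antigens in the early
#'   subset.
#' @param reaction_cv relative SD of the per-reaction shift magnitude.
#' @param duplicate_cv coefficient of variation of duplicate technical
#'   noise.
#' @param background_mean,background_sd spot background level and SD
#'   (fluorescence units); `background_sd` is also recorded as the
#'   per-spot background SD used for SNR.
#' @param baseline_log_mean_range,baseline_log_sd per-antigen null
#'   distribution parameters (log10 units).
#' @param qc_log_mean,qc_log_sd log10 parameters of the anti-GST
#'   quality-control signal (all proteins tagged, so all spots light up).
#' @param clinical_coupling correlation strength linking informative
#'   antibody burden to ESR/RF/IgG.
#' @param early_fraction fraction of cases with duration < 2 years.
#' @param missing_duration_prob fraction of cases with unrecorded
#'   duration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 200L,
                       n_informative = 15L,
                       group_sizes = list(RA = 182L, HC = 103L, AS = 48L,
                                          SLE = 47L, SS = 31L, OA = 32L),
                       n_acpa_negative = 48L,
                       effect_size = 1.8,
                       acpa_neg_attenuation = 0.5,
                       acpa_neg_react_prob = 0.6,
                       secondary_react_prob = 0.05,
                       dc_react_prob = 0.03,
                       early_boost = 0.3,
                       early_react_prob = 0.3,
                       early_subset_size = 5L,
                       reaction_cv = 0.3,
                       duplicate_cv = 0.08,
                       background_mean = 300,
                       background_sd = 40,
                       baseline_log_mean_range = c(1.0, 1.35),
                       baseline_log_sd = 0.18,
                       qc_log_mean = 3.55,
                       qc_log_sd = 0.28,
                       clinical_coupling = 0.5,
                       early_fraction = 0.35,
                       missing_duration_prob = 0.16) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              n_informative = as.integer(n_informative),
              group_sizes = lapply(group_sizes, as.integer),
              n_acpa_negative = as.integer(n_acpa_negative),
              effect_size = effect_size,
              acpa_neg_attenuation = acpa_neg_attenuation,
              acpa_neg_react_prob = acpa_neg_react_prob,
              secondary_react_prob = secondary_react_prob,
              dc_react_prob = dc_react_prob,
              early_boost = early_boost,
              early_react_prob = early_react_prob,
              early_subset_size = as.integer(early_subset_size),
              reaction_cv = reaction_cv,
              duplicate_cv = duplicate_cv,
              background_mean = background_mean,
              background_sd = background_sd,
              baseline_log_mean_range = baseline_log_mean_range,
              baseline_log_sd = baseline_log_sd,
              qc_log_mean = qc_log_mean, qc_log_sd = qc_log_sd,
              clinical_coupling = clinical_coupling,
              early_fraction = early_fraction,
              missing_duration_prob = missing_duration_prob)
  if (cfg$n_informative > cfg$n_probes)
    stop("n_informative must not exceed n_probes")
  if (any(unlist(cfg$group_sizes) < 0) || cfg$duplicate_cv < 0)
    stop("counts and duplicate_cv must be non-negative")
  if (!is.null(cfg$group_sizes$RA) && cfg$n_acpa_negative > cfg$group_sizes$RA)
    stop("n_acpa_negative must not exceed the RA group size")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d probes (%d informative), groups %s, seed %d\n",
              x$n_probes, x$n_informative,
              paste(names(x$group_sizes), unlist(x$group_sizes),
                    sep = "=", collapse = " "), x$seed))
  invisible(x)
}

# Local RNG scope: seed once, restore the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

simulate_layout <- function(cfg) {
  n <- cfg$n_probes
  probes <- data.frame(
    probe_id = sprintf("P%04d", seq_len(n)),
    name = sprintf("AG%04d", seq_len(n)),
    accession = sprintf("NM_%06d", 100000L + seq_len(n)),
    category = "protein", stringsAsFactors = FALSE)
  ctl <- data.frame(
    probe_id = paste0("CTL-", seq_along(CONTROL_CATEGORIES)),
    name = CONTROL_CATEGORIES, accession = NA_character_,
    category = CONTROL_CATEGORIES, stringsAsFactors = FALSE)
  probes <- rbind(probes, ctl)
  # duplicate pairs printed adjacently, controls at the end
  order_ids <- c(rep(probes$probe_id[seq_len(n)], each = 2L),
                 rep(ctl$probe_id, each = 2L))
  total <- length(order_ids)
  n_blocks <- if (total >= 48L * 4L) 48L else max(1L, ceiling(total / 16L))
  per_block <- ceiling(total / n_blocks)
  bc <- ceiling(sqrt(per_block))
  br <- ceiling(per_block / bc)
  slot <- seq_len(total) - 1L
  spots <- data.frame(
    block = slot %/% (br * bc) + 1L,
    row = (slot %% (br * bc)) %/% bc + 1L,
    col = slot %% bc + 1L,
    probe_id = order_ids, stringsAsFactors = FALSE)
  array_layout(probes, spots, n_blocks, br, bc)
}

simulate_manifest <- function(cfg) {
  gs <- cfg$group_sizes
  groups <- rep(names(gs), times = unlist(gs))
  if (length(groups) == 0L) stop("empty cohort: group sizes sum to 0")
  ids <- unlist(lapply(names(gs), function(g)
    sprintf("%s%03d", g, seq_len(gs[[g]]))), use.names = FALSE)
  role <- ifelse(groups == "RA", "case", "control")
  n <- length(ids)
  man <- data.frame(sample_id = ids, group = groups, role = role,
                    acpa_status = "unknown", anti_ccp = NA_real_,
                    disease_duration = NA_real_, esr = NA_real_,
                    crp = NA_real_, rf = NA_real_, igg = NA_real_,
                    das28 = NA_real_, sjc = NA_real_, tjc = NA_real_,
                    shs = NA_real_, stringsAsFactors = FALSE)
  is_case <- man$role == "case"
  n_case <- sum(is_case)
  if (n_case > 0L) {
    neg <- sample(which(is_case), min(cfg$n_acpa_negative, n_case))
    man$acpa_status[is_case] <- "positive"
    man$acpa_status[neg] <- "negative"
    titre <- ifelse(man$acpa_status == "positive",
                    pmax(26, exp(stats::rnorm(n, log(120), 0.8))),
                    stats::runif(n, 1, 24.9))
    man$anti_ccp[is_case] <- round(titre[is_case], 1)
    early <- stats::runif(n) < cfg$early_fraction
    dur <- ifelse(early, stats::runif(n, 0.1, 1.9),
                  2 + stats::rlnorm(n, log(7), 0.8))
    dur[stats::runif(n) < cfg$missing_duration_prob] <- NA_real_
    man$disease_duration[is_case] <- round(dur[is_case], 1)
  }
  ref <- data.frame(sample_id = c("POOL1", "BLANK1", "SEC1"),
                    group = c("HC", "HC", "HC"),
                    role = c("pooled-control", "blank", "secondary-only"),
                    acpa_status = "unknown", anti_ccp = NA_real_,
                    disease_duration = NA_real_, esr = NA_real_,
                    crp = NA_real_, rf = NA_real_, igg = NA_real_,
                    das28 = NA_real_, sjc = NA_real_, tjc = NA_real_,
                    shs = NA_real_, stringsAsFactors = FALSE)
  rbind(man, ref)
}

# Per-case x per-informative-antigen log10 shifts.
simulate_reactions <- function(cfg, man) {
  cases <- which(man$role == "case")
  n_inf <- cfg$n_informative
  S <- matrix(0, length(cases), n_inf)
  if (length(cases) == 0L || n_inf == 0L || cfg$effect_size == 0) {
    rownames(S) <- man$sample_id[cases]
    return(S)
  }
  early_set <- seq_len(min(cfg$early_subset_size, n_inf))
  mag <- function(k) cfg$effect_size * pmax(0.2, 1 + stats::rnorm(k, 0, cfg$reaction_cv))
  for (i in seq_along(cases)) {
    r <- cases[i]
    neg <- man$acpa_status[r] == "negative"
    att <- if (neg) cfg$acpa_neg_attenuation else 1
    reacts <- !neg || stats::runif(1) < cfg$acpa_neg_react_prob
    hit <- rep(FALSE, n_inf)
    if (reacts) {
      hit[sample.int(n_inf, 1L)] <- TRUE
      hit <- hit | stats::runif(n_inf) < cfg$secondary_react_prob
    }
    dur <- man$disease_duration[r]
    early <- !is.na(dur) && dur < 2
    if (early)
      hit[early_set] <- hit[early_set] |
        stats::runif(length(early_set)) < cfg$early_react_prob
    S[i, hit] <- mag(sum(hit)) * att
    if (early && any(hit[early_set]))
      S[i, early_set][hit[early_set]] <- S[i, early_set][hit[early_set]] + cfg$early_boost
  }
  rownames(S) <- man$sample_id[cases]
  S
}

# Sparse attenuated cross-reactivity in disease controls: autoimmune
# comparators carry some autoantibody background without the RA pattern.
simulate_dc_reactions <- function(cfg, man) {
  dc <- which(man$role == "control" & man$group != "HC")
  n_inf <- cfg$n_informative
  S <- matrix(0, length(dc), n_inf)
  rownames(S) <- man$sample_id[dc]
  if (length(dc) == 0L || n_inf == 0L || cfg$effect_size == 0) return(S)
  hit <- matrix(stats::runif(length(dc) * n_inf) < cfg$dc_react_prob,
                length(dc), n_inf)
  mag <- cfg$effect_size * cfg$acpa_neg_attenuation *
    pmax(0.2, 1 + stats::rnorm(sum(hit), 0, cfg$reaction_cv))
  S[hit] <- mag
  S
}

simulate_clinical <- function(cfg, man, shifts) {
  cases <- which(man$role == "case")
  if (length(cases) == 0L) return(man)
  burden <- rowSums(shifts)
  A <- if (stats::sd(burden) > 0) as.numeric(scale(burden)) else burden * 0
  cc <- cfg$clinical_coupling
  n <- length(cases)
  latent <- function(w) w * A + sqrt(max(0, 1 - w^2)) * stats::rnorm(n)
  man$esr[cases]   <- round(pmax(2, 45 + 30 * latent(cc)), 1)
  man$rf[cases]    <- round(pmax(1, exp(3.2 + 1.1 * latent(cc))), 1)
  man$igg[cases]   <- round(pmax(4, 13 + 3 * latent(cc)), 2)
  man$crp[cases]   <- round(pmax(0.5, exp(3.0 + 0.9 * latent(0.3 * cc))), 1)
  man$das28[cases] <- round(pmin(9.4, pmax(0.5, 4.3 + 1.4 * latent(0.3 * cc))), 2)
  man$sjc[cases]   <- pmax(0, round(7 + 4 * latent(0.2 * cc)))
  man$tjc[cases]   <- pmax(0, round(8 + 4 * latent(0.2 * cc)))
  man$shs[cases]   <- round(pmax(0, 75 + 50 * stats::rnorm(n)), 1)
  man
}

# Render one sample's latent log10 signals as a duplicate-spotted scan.
render_scan <- function(sample_id, latent_log10, ctl_signal, layout, cfg) {
  sp <- layout$spots
  n_spot <- nrow(sp)
  cat_by_probe <- layout$probes$category[match(sp$probe_id, layout$probes$probe_id)]
  signal <- numeric(n_spot)
  prot <- cat_by_probe == "protein"
  signal[prot] <- 10^latent_log10[sp$probe_id[prot]]
  signal[!prot] <- ctl_signal[cat_by_probe[!prot]]
  noise <- if (cfg$duplicate_cv > 0)
    pmax(0.05, 1 + stats::rnorm(n_spot, 0, cfg$duplicate_cv)) else rep(1, n_spot)
  bg <- pmax(0, stats::rnorm(n_spot, cfg$background_mean, cfg$background_sd))
  spots <- data.frame(block = sp$block, row = sp$row, col = sp$col,
                      probe_id = sp$probe_id,
                      f532 = round(bg + signal * noise, 1),
                      b532 = round(bg, 1),
                      b532_sd = round(rep(cfg$background_sd, n_spot), 1),
                      flag = 0L, stringsAsFactors = FALSE)
  array_scan(paste0("scan-", sample_id), sample_id, spots, layout)
}

# Control-probe signal levels (fluorescence units) per array role.
ctl_levels <- function(role) {
  base <- c(buffer = 0, `human-IgG` = 12000, `human-IgM` = 6000,
            `biotin-BSA` = 9000, BSA = 0, `GST-control` = 800)
  if (role == "blank") base[] <- 0
  if (role == "secondary-only") base[c("biotin-BSA", "GST-control")] <- 0
  base
}

#' Simulate a serum-array cohort with ground truth
#'
#' Generates an array layout, one scan per serum sample plus pooled-
#' control, blank and secondary-antibody-only reference arrays, a cohort
#' manifest with clinical covariates, and the ground truth (informative
#' antigens, per-sample latent intensities, per-case reaction shifts).
#' All randomness flows from a single stream seeded once from
#' `config$seed`, so identical configs reproduce identical cohorts.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements `layout`, `scans`
#'   (named list of `array_scan`), `manifest`, `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    layout <- simulate_layout(cfg)
    man <- simulate_manifest(cfg)
    probes <- protein_probes(layout)
    mu <- stats::runif(cfg$n_probes, cfg$baseline_log_mean_range[1],
                       cfg$baseline_log_mean_range[2])
    names(mu) <- probes
    informative <- sort(sample.int(cfg$n_probes, cfg$n_informative))
    inf_ids <- probes[informative]
    shifts <- simulate_reactions(cfg, man)
    dc_shifts <- simulate_dc_reactions(cfg, man)
    man <- simulate_clinical(cfg, man, shifts)
    validate_manifest(man)

    serum <- man$sample_id[man$role %in% c("case", "control")]
    latent <- matrix(stats::rnorm(length(serum) * cfg$n_probes, 0,
                                  cfg$baseline_log_sd),
                     length(serum), cfg$n_probes,
                     dimnames = list(serum, probes))
    latent <- sweep(latent, 2L, mu, "+")
    case_ids <- rownames(shifts)
    latent[case_ids, inf_ids] <- latent[case_ids, inf_ids] + shifts
    if (nrow(dc_shifts))
      latent[rownames(dc_shifts), inf_ids] <-
        latent[rownames(dc_shifts), inf_ids] + dc_shifts

    hc_ids <- man$sample_id[man$role == "control" & man$group == "HC"]
    pooled_latent <- if (length(hc_ids))
      colMeans(latent[hc_ids, , drop = FALSE]) else mu

    scans <- vector("list", nrow(man))
    names(scans) <- man$sample_id
    for (i in seq_len(nrow(man))) {
      sid <- man$sample_id[i]
      role <- man$role[i]
      lat <- switch(role,
                    `pooled-control` = pooled_latent,
                    blank = ,
                    `secondary-only` = stats::setNames(rep(-Inf, length(probes)), probes),
                    latent[sid, ])
      scans[[i]] <- render_scan(sid, lat, ctl_levels(role), layout, cfg)
    }
    gt <- list(informative_probe_ids = inf_ids,
               early_subset_ids = inf_ids[seq_len(min(cfg$early_subset_size,
                                                      cfg$n_informative))],
               baseline_log_mean = mu,
               latent_log10 = latent,
               shifts = shifts,
               dc_shifts = dc_shifts,
               effect_sizes = stats::setNames(
                 ifelse(probes %in% inf_ids, cfg$effect_size, 0), probes))
    structure(list(layout = layout, scans = scans, manifest = man,
                   ground_truth = gt, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d scans, %d probes (%d informative), seed %d\n",
              length(x$scans), x$config$n_probes, x$config$n_informative,
              x$config$seed))
  invisible(x)
}

#' Simulate anti-GST quality-control scans
#'
#' On the QC array every protein carries a GST tag, so all protein spots
#' light up; foreground intensities are calibrated so that at least 90%
#' fall in the expected 1000-24000 range and at least 90% of duplicate
#' pairs agree within 30% RPD under the default technical noise.
#'
#' @param config a [sim_config()].
#' @param n_scans number of QC scans to generate.
#' @return list of `array_scan` objects (and the layout as attribute
#'   `layout`).
#' @export
simulate_qc_profile <- function(config = sim_config(), n_scans = 1L) {
  cfg <- config
  with_seed(cfg$seed + 1L, {
    layout <- simulate_layout(cfg)
    probes <- protein_probes(layout)
    scans <- lapply(seq_len(n_scans), function(k) {
      lat <- stats::setNames(stats::rnorm(length(probes), cfg$qc_log_mean,
                                          cfg$qc_log_sd), probes)
      render_scan(sprintf("QC%02d", k), lat, ctl_levels("control"), layout, cfg)
    })
    attr(scans, "layout") <- layout
    scans
  })
}

#' Write a simulated cohort to disk in the standard dialects
#'
#' Emits `layout.gal`, `manifest.tsv` and one GPR file per scan under
#' `dir/scans/`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  write_layout(cohort$layout, file.path(dir, "layout.gal"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  for (s in cohort$scans)
    write_scan(s, cohort$layout, file.path(dir, "scans", paste0(s$sample_id, ".gpr")))
  invisible(dir)
}
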