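## Phase-I screening: array QC, per-sample hit calling against blank and
## secondary-antibody-only controls, and candidate-antigen selection.

#' Array quality control
#'
#' Computes, over protein-category spots only, the fraction of unflagged
#' spots whose foreground intensity lies in `[range_lo, range_hi]` and the
#' fraction of duplicate pairs (both spots unflagged) whose relative
#' percentage difference is strictly below `rpd_max`. The scan passes when
#' both fractions reach `pass_fraction`.
#'
#' @param scan an `array_scan`.
#' @param layout companion `array_layout`.
#' @param range_lo,range_hi acceptable foreground range (fluorescence
#'   units; defaults 1000 and 24000).
#' @param rpd_max duplicate-agreement bound in percent (default 30).
#' @param pass_fraction minimum passing fraction for both checks
#'   (default 0.90).
#' @param channel analysis channel.
#' @return An object of class `qc_report`: list with `scan_id`,
#'   `fraction_in_range`, `fraction_rpd_ok`, `passed`, and the counts.
#' @export
qc_array <- function(scan, layout, range_lo = 1000, range_hi = 24000,
                     rpd_max = 30, pass_fraction = 0.90, channel = 532) {
  pairs <- probe_pairs(layout)
  if (nrow(pairs) == 0L) stop("no protein spots on this layout")
  ch <- scan_channel(scan, channel)
  prot_idx <- c(pairs$i1, pairs$i2)
  ok <- scan$spots$flag[prot_idx] >= 0
  fg <- ch$fg[prot_idx][ok]
  if (length(fg) == 0L) stop("no usable protein spots in scan ", scan$scan_id)
  in_range <- fg >= range_lo & fg <= range_hi
  agg <- aggregate_duplicates(scan, layout, channel)
  rpd <- agg$rpd[agg$n_spots == 2L]
  if (length(rpd) == 0L) stop("no complete duplicate pair in scan ", scan$scan_id)
  fr_range <- mean(in_range)
  fr_rpd <- mean(rpd < rpd_max)
  structure(list(scan_id = scan$scan_id,
                 fraction_in_range = fr_range,
                 fraction_rpd_ok = fr_rpd,
                 n_spots = length(fg), n_pairs = length(rpd),
                 range = c(range_lo, range_hi), rpd_max = rpd_max,
                 pass_fraction = pass_fraction,
                 passed = fr_range >= pass_fraction & fr_rpd >= pass_fraction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report %s: %.1f%% in [%g, %g], %.1f%% pairs RPD < %g%% -> %s\n",
              x$scan_id, 100 * x$fraction_in_range, x$range[1], x$range[2],
              100 * x$fraction_rpd_ok, x$rpd_max,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a QC report as a machine-readable key-value file
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  fields <- c(scan_id = report$scan_id,
              fraction_in_range = fmt_fixed(report$fraction_in_range, 4L),
              fraction_rpd_ok = fmt_fixed(report$fraction_rpd_ok, 4L),
              n_spots = report$n_spots, n_pairs = report$n_pairs,
              range_lo = report$range[1], range_hi = report$range[2],
              rpd_max = report$rpd_max, pass_fraction = report$pass_fraction,
              passed = report$passed)
  writeLines(paste(names(fields), fields, sep = "="), path)
  invisible(path)
}

# Per-spot presence under the default rule: net signal at least
# presence_z background SDs above zero, on an unflagged spot.
spot_presence <- function(scan, layout, presence_z, channel) {
  ch <- scan_channel(scan, channel)
  if (anyNA(ch$bg_sd))
    stop("presence rule needs per-spot background SD (B532 SD) in scan ",
         scan$scan_id)
  (ch$fg - ch$bg) >= presence_z * ch$bg_sd & scan$spots$flag >= 0
}

#' Call per-sample hits against blank and secondary-only controls
#'
#' A probe is positive for a sample when both duplicate spots are present
#' on the sample array and no duplicate of that probe is present on
#' either the blank or the secondary-antibody-only control array.
#' "Present" means net signal at least `presence_z` background SDs above
#' zero on an unflagged spot.
#'
#' @param sample_scan,blank_scan,secondary_scan `array_scan` objects
#'   sharing `layout`; both control scans are mandatory.
#' @param layout companion `array_layout`.
#' @param presence_z presence threshold in background-SD units
#'   (default 3).
#' @param channel analysis channel.
#' @return data.frame (one row per protein probe) with columns
#'   `sample_id`, `probe_id`, `positive`, `sample_both_present`,
#'   `blank_any_present`, `secondary_any_present`.
#' @export
call_hits <- function(sample_scan, blank_scan, secondary_scan, layout,
                      presence_z = 3, channel = 532) {
  if (is.null(blank_scan) || is.null(secondary_scan))
    stop("hit calling requires both a blank and a secondary-antibody-only control scan")
  pairs <- probe_pairs(layout)
  ps <- spot_presence(sample_scan, layout, presence_z, channel)
  pb <- spot_presence(blank_scan, layout, presence_z, channel)
  px <- spot_presence(secondary_scan, layout, presence_z, channel)
  both <- ps[pairs$i1] & ps[pairs$i2]
  blank_any <- pb[pairs$i1] | pb[pairs$i2]
  sec_any <- px[pairs$i1] | px[pairs$i2]
  data.frame(sample_id = sample_scan$sample_id, probe_id = pairs$probe_id,
             positive = both & !blank_any & !sec_any,
             sample_both_present = both,
             blank_any_present = blank_any,
             secondary_any_present = sec_any,
             stringsAsFactors = FALSE)
}

#' Call hits for a collection of sample scans
#' @param scans list of `array_scan` objects (serum samples).
#' @inheritParams call_hits
#' @return row-bound hit table across samples.
#' @export
call_hits_cohort <- function(scans, blank_scan, secondary_scan, layout,
                             presence_z = 3, channel = 532) {
  do.call(rbind, lapply(scans, call_hits, blank_scan = blank_scan,
                        secondary_scan = secondary_scan, layout = layout,
                        presence_z = presence_z, channel = channel))
}

#' Select candidate antigens for the focused array
#'
#' A probe becomes a candidate when, in at least `min_case_positive`
#' hit-positive case samples, its SNR strictly exceeds `snr_min` and its
#' net intensity strictly exceeds `fold_min` times the pooled-control
#' net, while it is hit-positive in at most `max_control_positive`
#' healthy-control samples.
#'
#' @param hits hit table from [call_hits_cohort()].
#' @param matrix an `intensity_matrix` covering the hit samples.
#' @param pooled_profile named numeric vector of pooled-control net
#'   intensities per probe (floored like [net_signal()]).
#' @param manifest cohort manifest (identifies case and healthy-control
#'   samples).
#' @param snr_min SNR threshold, exceeded strictly (default 13).
#' @param fold_min fold-over-pooled threshold, exceeded strictly
#'   (default 2.5).
#' @param min_case_positive minimum number of qualifying case samples
#'   (default 2).
#' @param max_control_positive maximum number of hit-positive healthy
#'   controls (default 0).
#' @return An object of class `candidate_set`: data.frame with columns
#'   `probe_id`, `n_case_positive`, `n_control_positive`, `max_snr`,
#'   `max_fold`, sorted by descending `n_case_positive` (ties by
#'   `probe_id`), with the thresholds kept as attributes.
#' @export
select_candidates <- function(hits, matrix, pooled_profile, manifest,
                              snr_min = 13, fold_min = 2.5,
                              min_case_positive = 2, max_control_positive = 0) {
  probes <- matrix$probe_ids
  miss <- setdiff(unique(hits$probe_id), names(pooled_profile))
  if (length(miss))
    stop("pooled-control profile missing probe(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  pos <- matrix(FALSE, length(matrix$sample_ids), length(probes),
                dimnames = list(matrix$sample_ids, probes))
  keep <- hits$sample_id %in% matrix$sample_ids & hits$probe_id %in% probes
  h <- hits[keep, ]
  pos[cbind(match(h$sample_id, matrix$sample_ids),
            match(h$probe_id, probes))] <- h$positive

  case_ids <- intersect(matrix$sample_ids,
                        manifest$sample_id[manifest$role == "case"])
  hc_ids <- intersect(matrix$sample_ids,
                      manifest$sample_id[manifest$role == "control" &
                                           manifest$group == "HC"])
  pooled <- pooled_profile[probes]
  fold <- sweep(matrix$net, 2L, pooled, "/")
  qual <- pos & matrix$snr > snr_min & fold > fold_min
  qual[is.na(qual)] <- FALSE

  n_case_pos <- colSums(qual[case_ids, , drop = FALSE])
  n_ctl_pos <- colSums(pos[hc_ids, , drop = FALSE])
  case_pos <- pos[case_ids, , drop = FALSE]
  max_stat <- function(m) {
    v <- m
    v[!case_pos] <- NA
    suppressWarnings(apply(v, 2L, max, na.rm = TRUE))
  }
  max_snr <- max_stat(matrix$snr[case_ids, , drop = FALSE])
  max_fold <- max_stat(fold[case_ids, , drop = FALSE])
  max_snr[!is.finite(max_snr)] <- NA_real_
  max_fold[!is.finite(max_fold)] <- NA_real_

  sel <- n_case_pos >= min_case_positive & n_ctl_pos <= max_control_positive
  out <- data.frame(probe_id = probes[sel],
                    n_case_positive = as.integer(n_case_pos[sel]),
                    n_control_positive = as.integer(n_ctl_pos[sel]),
                    max_snr = max_snr[sel], max_fold = max_fold[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_case_positive, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            params = list(snr_min = snr_min, fold_min = fold_min,
                          min_case_positive = min_case_positive,
                          max_control_positive = max_control_positive))
}

#' Write a hit table or candidate set as tab-delimited text
#' @param x data.frame (hit table or `candidate_set`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_fixed, digits = 4L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
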