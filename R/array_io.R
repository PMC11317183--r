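# Closed category set for printed probes. Everything not recognisably a
# control is a protein probe printed in duplicate.
PROBE_CATEGORIES <- c("protein", "buffer", "human-IgG", "human-IgM",
                      "biotin-BSA", "BSA", "GST-control")

CONTROL_CATEGORIES <- setdiff(PROBE_CATEGORIES, "protein")

SUBJECT_GROUPS <- c("RA", "HC", "OA", "SLE", "SS", "AS")
SUBJECT_ROLES  <- c("case", "control", "pooled-control", "blank",
                    "secondary-only")
ACPA_LEVELS    <- c("positive", "negative", "unknown")

## ---------------------------------------------------------------------------
## Layout (GAL dialect)
## ---------------------------------------------------------------------------

#' Construct an array layout
#'
#' An array layout maps printed positions (block, row, column) to probes and
#' records probe identity and category. Protein probes must occupy exactly
#' two placements (the duplicate pair); control probes (printing buffer,
#' human IgG, human IgM, biotin-BSA, BSA, GST) may occupy any number.
#'
#' @param probes data.frame with columns `probe_id`, `name`, `accession`,
#'   `category` (one of `r paste(PROBE_CATEGORIES, collapse = ", ")`).
#' @param spots data.frame with columns `block`, `row`, `col`, `probe_id`
#'   (1-based coordinates).
#' @param n_blocks,block_rows,block_cols printed geometry.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(probes, spots, n_blocks, block_rows, block_cols) {
  stopifnot(is.data.frame(probes), is.data.frame(spots))
  need <- c("probe_id", "name", "accession", "category")
  if (!all(need %in% names(probes)))
    stop("layout probes table must have columns: ", paste(need, collapse = ", "))
  if (!all(c("block", "row", "col", "probe_id") %in% names(spots)))
    stop("layout spot table must have columns block, row, col, probe_id")
  if (anyDuplicated(probes$probe_id))
    stop("probe_id must be unique within a layout")
  bad_cat <- setdiff(unique(probes$category), PROBE_CATEGORIES)
  if (length(bad_cat))
    stop("unknown probe category: ", paste(bad_cat, collapse = ", "))
  if (!all(spots$probe_id %in% probes$probe_id))
    stop("layout places probes missing from the probe table")
  out_of_range <- spots$block < 1 | spots$block > n_blocks |
    spots$row < 1 | spots$row > block_rows |
    spots$col < 1 | spots$col > block_cols
  if (any(out_of_range))
    stop("layout placement outside the declared geometry")
  key <- paste(spots$block, spots$row, spots$col)
  if (anyDuplicated(key))
    stop("layout assigns the same coordinate twice")
  prot <- probes$probe_id[probes$category == "protein"]
  n_place <- table(factor(spots$probe_id, levels = prot))
  bad <- names(n_place)[n_place != 2L]
  if (length(bad))
    stop("protein probe(s) not printed in exactly duplicate: ",
         paste(utils::head(bad, 5), collapse = ", "))
  spots <- spots[order(spots$block, spots$row, spots$col), , drop = FALSE]
  rownames(spots) <- NULL
  structure(list(n_blocks = as.integer(n_blocks),
                 block_rows = as.integer(block_rows),
                 block_cols = as.integer(block_cols),
                 probes = probes, spots = spots),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("array_layout: %d blocks (%d x %d), %d placements, %d probes (%d protein)\n",
              x$n_blocks, x$block_rows, x$block_cols, nrow(x$spots),
              nrow(x$probes), sum(x$probes$category == "protein")))
  invisible(x)
}

#' Probe identifiers of protein-category probes
#' @param layout an `array_layout`.
#' @return character vector.
#' @export
protein_probes <- function(layout) {
  layout$probes$probe_id[layout$probes$category == "protein"]
}

# Duplicate-pair index into the canonical (block,row,col ordered) spot table.
probe_pairs <- function(layout) {
  sp <- layout$spots
  prot <- protein_probes(layout)
  idx <- split(seq_len(nrow(sp)), sp$probe_id)[prot]
  data.frame(probe_id = prot,
             i1 = vapply(idx, `[`, integer(1), 1L),
             i2 = vapply(idx, `[`, integer(1), 2L),
             stringsAsFactors = FALSE)
}

read_atf_header <- function(path) {
  lines <- readLines(path, n = 100L, warn = FALSE)
  hdr_row <- grep("^Block\t", lines)[1]
  if (is.na(hdr_row))
    stop("malformed file (no 'Block' column header line): ", path)
  meta_lines <- grep("=", lines[seq_len(hdr_row - 1L)], fixed = TRUE, value = TRUE)
  meta_lines <- gsub('^"|"$', "", meta_lines)
  kv <- regmatches(meta_lines, regexpr("=", meta_lines), invert = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  list(meta = meta, skip = hdr_row - 1L)
}

#' Read an array layout file (GAL dialect)
#'
#' Expects a tab-delimited file with `BlockCount=`, `BlockRows=`,
#' `BlockCols=` header lines followed by a table with columns
#' `Block`, `Row`, `Column`, `ID`, `Name` and optionally `Category`,
#' `Accession`. When `Category` is absent it is inferred from `Name`
#' (recognised control labels; everything else is a protein probe).
#'
#' @param path file path.
#' @return An `array_layout`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  hdr <- read_atf_header(path)
  geom <- suppressWarnings(as.integer(hdr$meta[c("BlockCount", "BlockRows", "BlockCols")]))
  if (anyNA(geom))
    stop("malformed layout header: BlockCount/BlockRows/BlockCols required in ", path)
  tab <- utils::read.delim(path, skip = hdr$skip, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("Block", "Row", "Column", "ID", "Name")
  if (!all(need %in% names(tab)))
    stop("malformed layout table: need columns ", paste(need, collapse = ", "))
  if (is.null(tab$Category)) {
    low <- tolower(tab$Name)
    ctl <- CONTROL_CATEGORIES[match(low, tolower(CONTROL_CATEGORIES))]
    tab$Category <- ifelse(is.na(ctl), "protein", ctl)
  }
  if (is.null(tab$Accession)) tab$Accession <- NA_character_
  probes <- unique(data.frame(probe_id = tab$ID, name = tab$Name,
                              accession = tab$Accession, category = tab$Category,
                              stringsAsFactors = FALSE))
  rownames(probes) <- NULL
  if (anyDuplicated(probes$probe_id))
    stop("probe annotation inconsistent across placements of the same ID")
  spots <- data.frame(block = tab$Block, row = tab$Row, col = tab$Column,
                      probe_id = tab$ID, stringsAsFactors = FALSE)
  array_layout(probes, spots, geom[1], geom[2], geom[3])
}

#' Write an array layout file (GAL dialect)
#' @param layout an `array_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  sp <- layout$spots
  pr <- layout$probes[match(sp$probe_id, layout$probes$probe_id), ]
  hdr <- c("ATF\t1.0", "4\t7", "Type=GenePix ArrayList V1.0",
           paste0("BlockCount=", layout$n_blocks),
           paste0("BlockRows=", layout$block_rows),
           paste0("BlockCols=", layout$block_cols),
           paste(c("Block", "Row", "Column", "ID", "Name", "Category",
                   "Accession"), collapse = "\t"))
  body <- paste(sp$block, sp$row, sp$col, sp$probe_id, pr$name, pr$category,
                ifelse(is.na(pr$accession), "NA", pr$accession), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Scans (GPR dialect)
## ---------------------------------------------------------------------------

#' Construct an array scan
#'
#' One scanned sample: per-spot foreground/background medians (532 channel,
#' optionally 635), background SD and GenePix-style flags (0 = good,
#' negative = excluded).
#'
#' @param scan_id,sample_id identifiers.
#' @param spots data.frame with columns `block`, `row`, `col`, `probe_id`,
#'   `f532`, `b532`, `b532_sd`, `flag` and optionally `f635`, `b635`.
#' @param layout companion `array_layout`; coordinates are validated
#'   against it.
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(scan_id, sample_id, spots, layout) {
  need <- c("block", "row", "col", "probe_id", "f532", "b532", "flag")
  if (!all(need %in% names(spots)))
    stop("scan spot table must have columns: ", paste(need, collapse = ", "))
  if (is.null(spots$b532_sd)) spots$b532_sd <- NA_real_
  key <- paste(spots$block, spots$row, spots$col)
  if (anyDuplicated(key))
    stop("scan has duplicated coordinates within one array")
  lkey <- paste(layout$spots$block, layout$spots$row, layout$spots$col)
  pos <- match(key, lkey)
  if (anyNA(pos))
    stop("scan coordinate(s) absent from the layout: ",
         paste(utils::head(key[is.na(pos)], 3), collapse = "; "))
  mismatch <- spots$probe_id != layout$spots$probe_id[pos]
  if (any(mismatch))
    stop("scan probe ID disagrees with the layout at ",
         paste(utils::head(key[mismatch], 3), collapse = "; "))
  bad <- (!is.na(spots$f532) & spots$f532 < 0) | (!is.na(spots$b532) & spots$b532 < 0)
  if (any(bad)) stop("negative foreground/background median in scan")
  spots <- spots[order(spots$block, spots$row, spots$col), , drop = FALSE]
  rownames(spots) <- NULL
  structure(list(scan_id = as.character(scan_id),
                 sample_id = as.character(sample_id),
                 spots = spots),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s' (sample %s): %d spots, %d flagged\n",
              x$scan_id, x$sample_id, nrow(x$spots), sum(x$spots$flag < 0)))
  invisible(x)
}

GPR_COLUMNS <- c("Block", "Row", "Column", "Name", "ID", "F532 Median",
                 "B532 Median", "B532 SD", "F635 Median", "B635 Median",
                 "Flags")

#' Read a scan result file (GPR dialect)
#'
#' Tab-delimited with columns `Block`, `Row`, `Column`, `Name`, `ID`,
#' `F532 Median`, `B532 Median`, `B532 SD`, `F635 Median`, `B635 Median`,
#' `Flags` (635-channel columns and `B532 SD` optional). Rows whose
#' coordinates are absent from the layout are rejected.
#'
#' @param path file path.
#' @param layout companion `array_layout`.
#' @return An `array_scan`.
#' @export
read_scan <- function(path, layout) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  hdr <- read_atf_header(path)
  tab <- utils::read.delim(path, skip = hdr$skip, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  mandatory <- c("Block", "Row", "Column", "Name", "ID", "F532 Median",
                 "B532 Median", "Flags")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss))
    stop("malformed scan file, missing column(s): ", paste(miss, collapse = ", "))
  spots <- data.frame(block = tab$Block, row = tab$Row, col = tab$Column,
                      probe_id = tab$ID,
                      f532 = tab[["F532 Median"]], b532 = tab[["B532 Median"]],
                      b532_sd = if ("B532 SD" %in% names(tab)) tab[["B532 SD"]] else NA_real_,
                      flag = tab$Flags, stringsAsFactors = FALSE)
  if ("F635 Median" %in% names(tab)) {
    spots$f635 <- tab[["F635 Median"]]
    spots$b635 <- tab[["B635 Median"]]
  }
  scan_id <- if (!is.na(hdr$meta["ScanID"])) hdr$meta[["ScanID"]] else basename(path)
  sample_id <- if (!is.na(hdr$meta["SampleID"])) hdr$meta[["SampleID"]] else scan_id
  array_scan(scan_id, sample_id, spots, layout)
}

fmt_fixed <- function(x, digits = 1L) {
  out <- ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  # trim "-0.0"
  sub("^-(0\\.0+)$", "\\1", out)
}

#' Write a scan result file (GPR dialect)
#'
#' Real-valued intensities are rendered with one fixed decimal, so a
#' write/read round-trip is lossless for data quantised at 0.1
#' fluorescence units.
#'
#' @param scan an `array_scan`.
#' @param layout companion `array_layout` (for probe names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, layout, path) {
  sp <- scan$spots
  nm <- layout$probes$name[match(sp$probe_id, layout$probes$probe_id)]
  has635 <- !is.null(sp$f635)
  hdr <- c("ATF\t1.0", "5\t11", "Type=GenePix Results 3",
           paste0("ScanID=", scan$scan_id),
           paste0("SampleID=", scan$sample_id),
           paste(GPR_COLUMNS, collapse = "\t"))
  body <- paste(sp$block, sp$row, sp$col, nm, sp$probe_id,
                fmt_fixed(sp$f532), fmt_fixed(sp$b532), fmt_fixed(sp$b532_sd),
                if (has635) fmt_fixed(sp$f635) else "NA",
                if (has635) fmt_fixed(sp$b635) else "NA",
                sp$flag, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Net signal and duplicate aggregation
## ---------------------------------------------------------------------------

#' Background-subtracted net signal
#'
#' Net fluorescent signal: foreground median minus background median,
#' floored at `floor` (default 1 fluorescence unit so downstream log
#' transforms are defined).
#'
#' @param fg,bg foreground and background medians (vectorised), or `fg`
#'   may be an `array_scan` in which case `bg` is ignored and `channel`
#'   selects the wavelength.
#' @param floor lower bound applied to the difference.
#' @param channel 532 (default) or 635, used when `fg` is a scan.
#' @return numeric vector of net signals.
#' @export
net_signal <- function(fg, bg = NULL, floor = 1, channel = 532) {
  if (inherits(fg, "array_scan")) {
    ch <- scan_channel(fg, channel)
    return(pmax(ch$fg - ch$bg, floor))
  }
  pmax(fg - bg, floor)
}

scan_channel <- function(scan, channel = 532) {
  sp <- scan$spots
  if (channel == 532) {
    list(fg = sp$f532, bg = sp$b532, bg_sd = sp$b532_sd)
  } else if (channel == 635) {
    if (is.null(sp$f635))
      stop("channel 635 absent from scan ", scan$scan_id)
    list(fg = sp$f635, bg = sp$b635, bg_sd = sp$b635_sd %||% NA_real_)
  } else stop("unknown channel: ", channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate duplicate spots into per-probe summaries
#'
#' For each protein probe, the two duplicate placements are combined:
#' `net` is the mean of the two floored net signals, `rpd` the relative
#' percentage difference `|a - b| / ((a + b)/2) * 100`, and `snr` the mean
#' over duplicates of `(fg - bg) / bg_sd` (undefined when `bg_sd` is
#' absent). Flagged spots (negative flag) are excluded: with one usable
#' spot the probe is reported with `status = "single"` (rpd undefined),
#' with none it is `"missing"`.
#'
#' @param scan an `array_scan`.
#' @param layout companion `array_layout`.
#' @param channel analysis channel (default 532).
#' @param floor net-signal floor.
#' @return data.frame with columns `probe_id`, `net`, `rpd`, `snr`,
#'   `n_spots`, `status`.
#' @export
aggregate_duplicates <- function(scan, layout, channel = 532, floor = 1) {
  pairs <- probe_pairs(layout)
  ch <- scan_channel(scan, channel)
  ok <- scan$spots$flag >= 0 & !is.na(ch$fg) & !is.na(ch$bg)
  net_all <- pmax(ch$fg - ch$bg, floor)
  raw_all <- ch$fg - ch$bg
  snr_all <- raw_all / ch$bg_sd

  a_ok <- ok[pairs$i1]; b_ok <- ok[pairs$i2]
  a <- ifelse(a_ok, net_all[pairs$i1], NA_real_)
  b <- ifelse(b_ok, net_all[pairs$i2], NA_real_)
  n_spots <- a_ok + b_ok
  net <- ifelse(n_spots == 2L, (a + b) / 2,
                ifelse(a_ok, a, ifelse(b_ok, b, NA_real_)))
  rpd <- ifelse(n_spots == 2L, abs(a - b) / ((a + b) / 2) * 100, NA_real_)
  sa <- ifelse(a_ok, snr_all[pairs$i1], NA_real_)
  sb <- ifelse(b_ok, snr_all[pairs$i2], NA_real_)
  snr <- rowMeans(cbind(sa, sb), na.rm = TRUE)
  snr[n_spots == 0L | is.nan(snr)] <- NA_real_
  status <- c("missing", "single", "ok")[n_spots + 1L]
  data.frame(probe_id = pairs$probe_id, net = net, rpd = rpd, snr = snr,
             n_spots = n_spots, status = status, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Manifest
## ---------------------------------------------------------------------------

MANIFEST_COLUMNS <- c("sample_id", "group", "role", "acpa_status", "anti_ccp",
                      "disease_duration", "esr", "crp", "rf", "igg", "das28",
                      "sjc", "tjc", "shs")

#' Validate a cohort manifest
#'
#' Checks the closed group/role/ACPA vocabularies, uniqueness of sample
#' identifiers, non-negative durations, and consistency of `acpa_status`
#' with the anti-CCP titre when one is supplied (positive iff
#' anti-CCP > `acpa_cutoff` U/mL).
#'
#' @param manifest data.frame with at least `sample_id`, `group`, `role`,
#'   `acpa_status`; clinical covariates optional/missing-capable.
#' @param acpa_cutoff anti-CCP positivity cutoff in U/mL (default 25).
#' @return the manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest, acpa_cutoff = 25) {
  need <- c("sample_id", "group", "role", "acpa_status")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest")
  serum <- manifest$role %in% c("case", "control")
  bad_g <- setdiff(unique(manifest$group[serum]), SUBJECT_GROUPS)
  if (length(bad_g)) stop("unknown group: ", paste(bad_g, collapse = ", "))
  bad_r <- setdiff(unique(manifest$role), SUBJECT_ROLES)
  if (length(bad_r)) stop("unknown role: ", paste(bad_r, collapse = ", "))
  bad_a <- setdiff(unique(manifest$acpa_status), ACPA_LEVELS)
  if (length(bad_a)) stop("unknown acpa_status: ", paste(bad_a, collapse = ", "))
  if (!is.null(manifest$disease_duration) &&
      any(manifest$disease_duration < 0, na.rm = TRUE))
    stop("disease_duration must be >= 0")
  if (!is.null(manifest$anti_ccp)) {
    has <- !is.na(manifest$anti_ccp)
    want <- ifelse(manifest$anti_ccp[has] > acpa_cutoff, "positive", "negative")
    if (any(manifest$acpa_status[has] != want))
      stop("acpa_status inconsistent with anti_ccp titre at cutoff ",
           acpa_cutoff, " U/mL")
  }
  invisible(manifest)
}

#' Read a cohort manifest (tab-delimited)
#' @param path file path.
#' @param acpa_cutoff anti-CCP positivity cutoff in U/mL.
#' @return validated data.frame.
#' @export
read_manifest <- function(path, acpa_cutoff = 25) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_manifest(tab, acpa_cutoff)
  tab
}

#' Write a cohort manifest (tab-delimited)
#' @param manifest data.frame of subject records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  for (col in intersect(c("anti_ccp", "disease_duration", "esr", "crp", "rf",
                          "igg", "das28", "sjc", "tjc", "shs"), names(out)))
    out[[col]] <- fmt_fixed(out[[col]], 2L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Intensity matrix
## ---------------------------------------------------------------------------

#' Build a samples-by-probes intensity matrix
#'
#' Aggregates each scan's duplicate spots and assembles net, RPD and SNR
#' matrices over all protein-category probes. Rows are aligned to the
#' manifest order of the supplied scans' samples, so the result does not
#' depend on the order in which scans are given. Missing probes stay `NA`.
#'
#' @param scans list of `array_scan` objects.
#' @param layout companion `array_layout`.
#' @param manifest cohort manifest covering every scan's `sample_id`.
#' @param channel analysis channel (default 532).
#' @param floor net-signal floor.
#' @return An object of class `intensity_matrix`: list with matrices
#'   `net`, `rpd`, `snr` (samples x probes), plus `sample_ids`,
#'   `probe_ids`, `channel`.
#' @export
build_intensity_matrix <- function(scans, layout, manifest, channel = 532,
                                   floor = 1) {
  ids <- vapply(scans, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id across scans: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  miss <- setdiff(ids, manifest$sample_id)
  if (length(miss))
    stop("scan sample_id absent from manifest: ", paste(miss, collapse = ", "))
  ord <- order(match(ids, manifest$sample_id))
  scans <- scans[ord]; ids <- ids[ord]
  probes <- protein_probes(layout)
  n <- length(ids); p <- length(probes)
  net <- rpd <- snr <- matrix(NA_real_, n, p, dimnames = list(ids, probes))
  for (i in seq_len(n)) {
    agg <- aggregate_duplicates(scans[[i]], layout, channel, floor)
    j <- match(agg$probe_id, probes)
    net[i, j] <- agg$net; rpd[i, j] <- agg$rpd; snr[i, j] <- agg$snr
  }
  structure(list(net = net, rpd = rpd, snr = snr, sample_ids = ids,
                 probe_ids = probes, channel = channel),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d samples x %d probes (channel %d), %.1f%% missing\n",
              length(x$sample_ids), length(x$probe_ids), x$channel,
              100 * mean(is.na(x$net))))
  invisible(x)
}
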