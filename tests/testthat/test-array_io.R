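test_that("layout invariants are enforced", {
  lay <- tiny_layout(1)
  expect_s3_class(lay, "array_layout")
  expect_equal(sum(lay$probes$category == "protein"), 1L)

  probes <- data.frame(probe_id = "P1", name = "AG1", accession = NA,
                       category = "protein", stringsAsFactors = FALSE)
  spots3 <- data.frame(block = 1, row = c(1, 1, 2), col = c(1, 2, 1),
                       probe_id = "P1")
  expect_error(array_layout(probes, spots3, 1, 2, 2), "duplicate")
  dup_coord <- data.frame(block = 1, row = c(1, 1), col = c(1, 1),
                          probe_id = "P1")
  expect_error(array_layout(probes, dup_coord, 1, 2, 2), "coordinate")
  outside <- data.frame(block = 1, row = c(1, 3), col = c(1, 1),
                        probe_id = "P1")
  expect_error(array_layout(probes, outside, 1, 2, 2), "geometry")
})

test_that("layout files round-trip and carry declared geometry", {
  lay <- tiny_layout(3)
  path <- withr::local_tempfile(fileext = ".gal")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_equal(back$probes, lay$probes)
  expect_equal(back$spots, lay$spots)
  expect_equal(back$n_blocks, 1L)

  # a 48-block declaration is preserved
  big <- simulate_cohort(small_sim_config())$layout
  expect_error(write_layout(big, path), NA)
  lay48 <- seroscreen:::simulate_layout(sim_config())
  p48 <- withr::local_tempfile(fileext = ".gal")
  write_layout(lay48, p48)
  expect_equal(read_layout(p48)$n_blocks, 48L)

  # malformed header
  bad <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("ATF\t1.0", "Block\tRow\tColumn\tID\tName", "1\t1\t1\tP1\tAG1"),
             bad)
  expect_error(read_layout(bad), "malformed")
})

test_that("scan files round-trip with values preserved exactly", {
  lay <- tiny_layout(2)
  scan <- tiny_scan(lay, list(P01 = c(5000, 5000.5), P02 = c(1600.2, 1610)))
  path <- withr::local_tempfile(fileext = ".gpr")
  write_scan(scan, lay, path)
  back <- read_scan(path, lay)
  expect_equal(back$spots$f532, scan$spots$f532)
  expect_equal(back$spots$b532, scan$spots$b532)
  expect_equal(back$sample_id, scan$sample_id)
  # second write of the re-read scan is byte-identical
  p2 <- withr::local_tempfile(fileext = ".gpr")
  write_scan(back, lay, p2)
  expect_identical(readLines(path), readLines(p2))
})

test_that("scan validation rejects bad coordinates and columns", {
  lay <- tiny_layout(1)
  path <- withr::local_tempfile(fileext = ".gpr")
  writeLines(c("ATF\t1.0", "Block\tRow\tColumn\tName\tID\tF532 Median\tFlags",
               "1\t1\t1\tAG01\tP01\t100\t0"), path)
  expect_error(read_scan(path, lay), "missing column")

  sp <- tiny_scan(lay, list(P01 = c(500, 500)))$spots
  sp$row[1] <- 99L
  expect_error(array_scan("s", "s", sp, lay), "absent from the layout")
})

test_that("net signal follows F-B with a floor of one unit", {
  expect_equal(net_signal(5000, 300), 4700)
  expect_equal(net_signal(100, 300), 1)
  expect_equal(net_signal(1600, 300), 1300)
  expect_equal(net_signal(c(5000, 100), c(300, 300)), c(4700, 1))
})

test_that("duplicate aggregation computes net, RPD and SNR as defined", {
  lay <- tiny_layout(3)
  scan <- tiny_scan(lay, list(P01 = c(4300, 6300),  # nets 4000 / 6000
                              P02 = c(2300, 2300),  # identical duplicates
                              P03 = c(1600, 1600)), # snr boundary
                    bg = 300, bg_sd = 100)
  agg <- aggregate_duplicates(scan, lay)
  agg <- agg[match(c("P01", "P02", "P03"), agg$probe_id), ]
  expect_equal(agg$net, c(5000, 2300 - 300, 1300))
  expect_equal(agg$rpd, c(40, 0, 0))
  expect_equal(agg$snr[3], 13.0)
  expect_true(all(agg$status == "ok"))
})

test_that("duplicate aggregation is symmetric and respects flags", {
  lay <- tiny_layout(2)
  scan <- tiny_scan(lay, list(P01 = c(4300, 6300), P02 = c(900, 1100)))
  swapped <- scan
  idx <- which(scan$spots$probe_id == "P01")
  swapped$spots$f532[idx] <- rev(swapped$spots$f532[idx])
  a <- aggregate_duplicates(scan, lay)
  b <- aggregate_duplicates(swapped, lay)
  expect_equal(a[order(a$probe_id), ], b[order(b$probe_id), ])

  # flagging one duplicate -> single-spot status, rpd undefined,
  # and the aggregate uses only the unflagged spot
  flags <- rep(0L, nrow(scan$spots))
  flags[idx[1]] <- -100L
  flagged <- tiny_scan(lay, list(P01 = c(4300, 6300), P02 = c(900, 1100)),
                       flags = flags)
  fa <- aggregate_duplicates(flagged, lay)
  row <- fa[fa$probe_id == "P01", ]
  expect_equal(row$status, "single")
  expect_equal(row$net, 6000)
  expect_true(is.na(row$rpd))
})

test_that("intensity matrix has stable shape and sample alignment", {
  cfg <- small_sim_config()
  co <- simulate_cohort(cfg)
  man <- co$manifest
  ids <- man$sample_id[man$role %in% c("case", "control")][1:5]
  m1 <- build_intensity_matrix(co$scans[ids], co$layout, man)
  expect_equal(dim(m1$net), c(5L, cfg$n_probes))
  # permuting scan order yields the identical matrix
  m2 <- build_intensity_matrix(co$scans[rev(ids)], co$layout, man)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$snr, m2$snr)
  # duplicated sample rejected
  expect_error(build_intensity_matrix(co$scans[c(ids, ids[1])], co$layout, man),
               "duplicate sample_id")
  # a scan missing from the manifest is rejected
  expect_error(build_intensity_matrix(co$scans[ids], co$layout,
                                      man[-match(ids[1], man$sample_id), ]),
               "absent from manifest")
})

test_that("manifest round-trips and enforces the anti-CCP consistency rule", {
  co <- simulate_cohort(small_sim_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(co$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$sample_id, co$manifest$sample_id)
  expect_equal(back$acpa_status, co$manifest$acpa_status)
  expect_equal(back$anti_ccp, co$manifest$anti_ccp, tolerance = 1e-8)

  bad <- co$manifest
  i <- which(bad$acpa_status == "negative")[1]
  bad$anti_ccp[i] <- 100  # titre says positive
  expect_error(validate_manifest(bad), "inconsistent")
})
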