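test_that("well aggregation reports medians per layout well", {
  records <- data.frame(
    well = c("A01", "A01", "A01", "B01", "B01"),
    marker_nuc_mean = c(10, 20, 90, 5, 7),
    ratio_marker = c(1, 2, 3, 4, 6),
    edu_positive = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  layout <- data.frame(well = c("A01", "B01", "C01"),
                       compound = c("vehicle", "BPAP", "BPAP"),
                       dose = c(0, 1, 2), unit = "uM",
                       combo_agonist = FALSE, replicate = 1L)
  s <- aggregateWells(records, layout)
  expect_equal(s$n_cells, c(3L, 2L, 0L))
  expect_equal(s$median_nuc, c(20, 6, NA))
  expect_equal(s$mean_nuc, c(40, 6, NA))
  expect_equal(s$median_ratio, c(2, 5, NA))
  expect_equal(s$pct_edu_positive, c(100 / 3, 100, NA))
  expect_equal(s$flag, c("", "", "empty_well"))
})

test_that("plate normalization follows the fold and percent formulas", {
  s <- data.frame(well = c("A01", "A02", "B01", "B02", "C01"),
                  compound = c("vehicle", "vehicle", "DHT", "DHT", "BPAP"),
                  dose = c(0, 0, 1e-9, 1e-9, 1e-5), unit = "M",
                  combo_agonist = FALSE, replicate = c(1L, 2L, 1L, 2L, 1L),
                  median_nuc = c(90, 110, 280, 320, 200))
  f <- normalizePlate(s, scale = "fold")
  expect_equal(f$norm_value, s$median_nuc / 100)   # vehicle median = 100
  expect_equal(attr(f, "vehicleMedian"), 100)
  p <- normalizePlate(s, scale = "percent")
  # vehicle 100, agonist 300: (200 - 100) / (300 - 100) -> 50%
  expect_equal(p$norm_value[5], 50)
  expect_equal(p$norm_value[1:2], c(-5, 5))
  # fold change is invariant to a global intensity rescaling
  s2 <- s; s2$median_nuc <- s$median_nuc * 37.5
  expect_equal(normalizePlate(s2, scale = "fold")$norm_value, f$norm_value)
  # missing controls are refused
  noVeh <- s[s$compound != "vehicle", ]
  expect_error(normalizePlate(noVeh, scale = "fold"), "vehicle")
  noAg <- s[s$compound != "DHT", ]
  expect_error(normalizePlate(noAg, scale = "percent"), "DHT")
})

test_that("4PL fitting recovers noiseless curves and declares flat inputs", {
  doses <- c(1, 3, 10, 15, 30, 60)  # uM-scale six-point series
  m <- effectModel(top = 1, bottom = 0.35, ec50 = 15, hillSlope = 1.3)
  y <- hillResponse(doses, m)
  fit <- fitDoseResponse(doses, y, direction = "down")
  expect_false(fit@flat)
  expect_equal(fit@ic50, 15, tolerance = 1e-4)
  expect_equal(fit@top, 1, tolerance = 1e-4)
  expect_equal(fit@bottom, 0.35, tolerance = 1e-4)
  expect_equal(fit@hillSlope, 1.3, tolerance = 1e-4)
  expect_true(fit@ic50InRange)
  # property: random noiseless instances are recovered across the grid
  set.seed(71)
  for (i in 1:25) {
    ec <- 10^runif(1, 0, 1.5); hs <- runif(1, 0.6, 2.5)
    bt <- runif(1, 0.1, 0.5)
    mi <- effectModel(1, bt, ec, hs)
    fi <- fitDoseResponse(doses, hillResponse(doses, mi))
    expect_equal(fi@ic50, ec, tolerance = 1e-3)
    expect_equal(fi@hillSlope, hs, tolerance = 1e-3)
  }
  # flat input (constant, and constant + noise): no activity
  expect_true(fitDoseResponse(doses, rep(0.98, 6))@flat)
  set.seed(72)
  yn <- 1 + rnorm(6, 0, 0.03)
  fitN <- fitDoseResponse(doses, yn)
  expect_true(fitN@flat)
  expect_true(is.na(fitN@ic50))
  # guards
  expect_error(fitDoseResponse(c(-1, 1, 2, 3), 1:4), "negative")
  expect_error(fitDoseResponse(c(1, 2, 3), 1:3), "4 distinct")
  # rising curves fit with direction = "up"
  up <- effectModel(1, 0.2, 5, 1, direction = "up")
  fu <- fitDoseResponse(doses, hillResponse(doses, up), direction = "up")
  expect_equal(fu@ic50, 5, tolerance = 1e-4)
})

test_that("profile matrix assembles conditions x cell lines", {
  g <- expand.grid(compound = paste0("c", 1:8),
                   combo_agonist = c(FALSE, TRUE),
                   cell_line = c("22Rv1", "LNCaP"),
                   stringsAsFactors = FALSE)
  g$norm_value <- seq_len(nrow(g))
  m <- buildProfileMatrix(g)
  expect_equal(dim(m), c(16L, 2L))   # 8 compounds x (alone, +DHT)
  expect_equal(sum(grepl("\\+DHT$", rownames(m))), 8)
  # replicate wells are averaged
  r <- data.frame(compound = "c1", combo_agonist = FALSE,
                  cell_line = "22Rv1", norm_value = c(1, 3),
                  well = c("A01", "A02"))
  expect_equal(as.numeric(buildProfileMatrix(r)), 2)
  # missing combinations become NA
  h <- g[-1, ]
  mh <- buildProfileMatrix(h)
  expect_equal(sum(is.na(mh)), 1L)
  # conflicting non-replicate duplicates are rejected
  bad <- data.frame(compound = "c1", combo_agonist = FALSE,
                    cell_line = "22Rv1", norm_value = c(1, 3))
  expect_error(buildProfileMatrix(bad), "conflicting")
})

test_that("average-linkage clustering matches hand and exhaustive oracles", {
  # worked 3-row example: rows (0,0), (3,4), (0,1)
  mat <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 1))
  hc <- clusterProfiles(mat)
  expect_equal(hc$height[1], 1)                      # first merge: a with c
  expect_equal(hc$height[2], (5 + sqrt(18)) / 2)     # then b joins the pair
  expect_equal(hc$height, oracleUPGMA(mat))
  # property: merge heights equal exhaustive enumeration on small matrices
  set.seed(81)
  for (i in 1:6) {
    n <- sample(3:6, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    expect_equal(clusterProfiles(m)$height, oracleUPGMA(m), tolerance = 1e-12)
  }
  # NA handling: refuse by default, drop on request with bookkeeping
  matNA <- rbind(mat, d = c(NA, 2))
  expect_error(clusterProfiles(matNA), "missing")
  hcd <- clusterProfiles(matNA, naAction = "drop")
  expect_equal(attr(hcd, "dropped"), "d")
  expect_equal(hcd$height, oracleUPGMA(mat))
  # column axis clusters cell lines
  expect_equal(length(clusterProfiles(cbind(mat, mat), axis = "cols")$order),
               4)
})

test_that("vehicle-like and agonist-like profiles split at the top level", {
  set.seed(82)
  veh <- matrix(1 + rnorm(8, 0, 0.05), 4, 2)
  ag <- matrix(3 + rnorm(8, 0, 0.05), 4, 2)
  prof <- rbind(veh, ag)
  rownames(prof) <- c(paste0("veh", 1:4), paste0("ag", 1:4))
  grp <- topLevelSplit(clusterProfiles(prof))
  members <- lapply(grp, sort)
  expect_true(setequal(members[[1]], paste0("veh", 1:4)) ||
                setequal(members[[1]], paste0("ag", 1:4)))
  expect_true(setequal(unlist(members), rownames(prof)))
  # Newick export round-trips through an independent parser
  hc <- clusterProfiles(prof)
  nwk <- dendrogramNewick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(prof))
  tf <- tempfile(fileext = ".nwk")
  dendrogramNewick(hc, tf)
  expect_setequal(ape::read.tree(tf)$tip.label, rownames(prof))
})

test_that("biolog correction and Z-scores follow their definitions", {
  sim <- simulateBiolog(multipliers = 0.5, seed = 91)
  res <- biologAnalyze(sim$vehicle, sim$treated)
  expect_equal(dim(res$corrected), c(90L, 6L))
  # every Z row has mean 0, sd 1
  expect_true(all(abs(rowMeans(res$zscore)) < 1e-9))
  expect_true(all(abs(apply(res$zscore, 1, sd) - 1) < 1e-9))
  # 50% utilization loss: treated-arm Z-scores negative for every source
  simL <- simulateBiolog(multipliers = 0.5, noiseSd = 1, seed = 92)
  resL <- biologAnalyze(simL$vehicle, simL$treated)
  trt <- grepl("^treated_", colnames(resL$zscore))
  expect_true(all(resL$zscore[, trt] < 0))
  expect_true(all(resL$zscore[, !trt] > 0))
  # zero-variance rows are flagged and set to 0
  p <- function(v) list(values = c(v, 0, 0), negativeWells = 5:6,
                        condition = "x")
  resZ <- biologAnalyze(list(p(c(1, 2, 3, 3))), list(p(c(4, 5, 6, 3))))
  expect_equal(resZ$zeroVarianceRows, 4L)
  expect_equal(resZ$zscore[4, ], c(vehicle_1 = 0, treated_1 = 0))
})

test_that("relative cell counts compare against vehicle per timepoint", {
  s <- data.frame(well = sprintf("A%02d", 1:6),
                  compound = c("vehicle", "vehicle", "BPAP",
                               "vehicle", "BPAP", "BPAP"),
                  n_cells = c(90, 110, 40, 200, 80, 0),
                  timepoint = c(1, 1, 1, 2, 2, 2))
  r <- compareCellCounts(s)
  expect_equal(r$relative_count, c(0.9, 1.1, 0.4, 1, 0.4, 0))
  expect_equal(r$count_flag, c("", "", "", "", "", "zero_cells"))
  # without a timepoint column a single vehicle reference is used
  s2 <- s[s$timepoint == 1, setdiff(names(s), "timepoint")]
  expect_equal(compareCellCounts(s2)$relative_count, c(0.9, 1.1, 0.4))
  expect_error(compareCellCounts(data.frame(well = "A01", compound = "x",
                                            n_cells = 5)), "vehicle")
})
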