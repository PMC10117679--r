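test_that("thickness is boundary separation times the axial scale", {
  # uniform 10-sample separations at the default scale: 13.672 um
  tr <- flat_truth(seq(40, 120, by = 10), n_samples = 256,
                   scale = axial_scale())
  th <- compute_thickness(as_boundary_set(tr), axial_scale())
  expect_true(all(abs(th$thickness[, , 1:8] - 13.671875) < 1e-9))
  expect_equal(round(th$thickness[1, 1, 1], 3), 13.672)
  # a TRT span of 146.36 samples is about 200.1 um
  tr2 <- flat_truth(c(40, 40 + cumsum(rep(146.36 / 8, 8))))
  th2 <- compute_thickness(as_boundary_set(tr2), axial_scale())
  expect_equal(th2$thickness[1, 1, 9], 146.36 * 1000 * 1.4 / 1024)
  expect_lt(abs(th2$thickness[1, 1, 9] - 200.1), 0.05)
  # TRT additivity is exact for arbitrary monotone boundaries
  set.seed(4)
  lv <- sort(runif(9, 10, 240))
  tr3 <- flat_truth(lv)
  bs3 <- as_boundary_set(tr3)
  bs3$boundaries <- bs3$boundaries +
    array(runif(length(bs3$boundaries), 0, 0.4), dim(bs3$boundaries))
  bs3$boundaries <- aperm(apply(bs3$boundaries, c(1, 2), sort), c(2, 3, 1))
  th3 <- compute_thickness(bs3, axial_scale())
  expect_equal(apply(th3$thickness[, , 1:8], c(1, 2), sum),
               th3$thickness[, , 9])
})

test_that("crossing boundaries invalidate A-scans instead of going negative", {
  tr <- flat_truth(seq(40, 120, by = 10))
  bs <- as_boundary_set(tr)
  bs$boundaries[2, 3, 4] <- bs$boundaries[2, 3, 5] + 5  # cross one boundary
  th <- compute_thickness(bs, axial_scale())
  expect_false(th$valid[2, 3])
  expect_true(all(is.na(th$thickness[2, 3, ])))
  expect_true(all(th$thickness[th$valid & !is.na(th$thickness[, , 1])] >= 0,
                  na.rm = TRUE))
  expect_true(all(th$valid[-2, ]))
})

test_that("QC criteria catch the defects they are designed for", {
  ph <- small_phantom(dims = c(8, 35, 256), noise = "none")
  bs <- boundaries_from_classmap(oracle_classmap(ph$truth))
  th <- compute_thickness(bs, ph$truth$scale)
  # clean zero-noise phantom: no failures
  qc <- qc_ascan(ph$volume, bs, th)
  expect_equal(sum(!qc$valid), 0)
  # constant (corrupted) A-scan fails the contrast criterion
  cv <- ph$volume
  cv$intensities[4, 10, ] <- mean(cv$intensities[4, 10, ])
  qc2 <- qc_ascan(cv, bs, th)
  expect_false(qc2$pass_contrast[4, 10])
  # a boundary displaced by more than J fails consistency at that A-scan
  bs3 <- bs
  bs3$boundaries[5, 20, 3] <- bs3$boundaries[5, 20, 3] + 16  # J = 15
  th3 <- compute_thickness(bs3, ph$truth$scale)
  qc3 <- qc_ascan(ph$volume, bs3, th3)
  expect_false(qc3$pass_consistency[5, 20])
  fails <- which(!qc3$pass_consistency, arr.ind = TRUE)
  # only the displaced A-scan and its 4-neighbours can fail
  expect_true(all(abs(fails[, 1] - 5) + abs(fails[, 2] - 20) <= 1))
  # an extreme thickness outlier fails the distribution criterion
  bs4 <- bs
  bs4$boundaries[1, 1, 2:9] <- bs4$boundaries[1, 1, 2:9] + 40
  th4 <- compute_thickness(bs4, ph$truth$scale)
  qc4 <- qc_ascan(ph$volume, bs4, th4)
  expect_false(qc4$pass_distribution[1, 1])
  # apply_qc blanks failed A-scans
  filtered <- apply_qc(th4, qc4)
  expect_true(all(is.na(filtered$thickness[1, 1, ])))
})

test_that("tightening QC thresholds never increases the retained count", {
  ph <- generate_phantom(phantom_spec(), dims = c(8, 35, 256),
                         noise = "speckle", seed = 31)
  bs <- boundaries_from_classmap(oracle_classmap(ph$truth))
  th <- compute_thickness(bs, ph$truth$scale)
  loose <- qc_ascan(ph$volume, bs, th, qc_params(c_min = 0.01, J = 30,
                                                 z_star = 6))
  tight <- qc_ascan(ph$volume, bs, th, qc_params(c_min = 0.05, J = 10,
                                                 z_star = 2.5))
  expect_lte(sum(tight$valid), sum(loose$valid))
  expect_true(all(loose$valid[!tight$valid] | !tight$valid[!tight$valid]))
})

test_that("left-eye mirroring is an involution that aligns OS with OD", {
  m <- constant_map()
  m$thickness[, 1:17, 1] <- 99  # mark the left half
  od <- m
  expect_identical(mirror_if_left(od), od)
  os <- m
  os$meta$eye <- "OS"
  once <- mirror_if_left(os)
  expect_equal(once$thickness[, 35:19, 1], os$thickness[, 1:17, 1])
  twice <- mirror_if_left(once)
  twice$meta$eye <- "OS"  # mirror again
  expect_equal(mirror_if_left(twice)$thickness, once$thickness)
  bad <- m
  bad$meta$eye <- NA
  expect_error(mirror_if_left(bad), "eye")
})

test_that("OS/OD phantom pairs agree after mirroring", {
  sc <- axial_scale(1.4 * 256 / 1024, 256)
  pair <- lapply(c("OD", "OS"), function(e) {
    ph <- generate_phantom(phantom_spec(), eye = e, dims = c(35, 35, 256),
                           noise = "none", seed = 12)
    th <- compute_thickness(as_boundary_set(ph$truth), sc)
    mirror_if_left(th)
  })
  expect_equal(pair[[1]]$thickness, pair[[2]]$thickness)
  # temporal (left) half thicker than nasal after mirroring, both eyes
  for (m in pair) {
    trt <- m$thickness[, , 9]
    expect_gt(mean(trt[, 1:17]), mean(trt[, 19:35]))
  }
})

test_that("block means equal a loop-based oracle on random maps", {
  set.seed(8)
  for (rep in 1:6) {
    n <- 35
    th <- array(runif(n * n * 9, 10, 60), c(n, n, 9))
    valid <- matrix(runif(n * n) > 0.05, n, n)
    m <- manual_map(th, valid)
    for (k in 1:9) {
      page <- m$thickness[, , k]
      page[!valid] <- NA
      m$thickness[, , k] <- page
    }
    res <- crop_and_block(m)
    bs <- 11
    for (br in 1:3) {
      for (bc in 1:3) {
        rows <- 1 + ((br - 1) * bs + 1):(br * bs)
        cols <- 1 + ((bc - 1) * bs + 1):(bc * bs)
        # independent nested-loop average
        for (k in c(1, 5, 9)) {
          acc <- c()
          for (r in rows) for (cc in cols) {
            if (valid[r, cc]) acc <- c(acc, th[r, cc, k])
          }
          got <- res$mean_um[res$region == paste0("B", (br - 1) * 3 + bc) &
                               res$layer == retinal_layers(TRUE)[k]]
          if (length(acc) && mean(!valid[rows, cols]) <= 0.10) {
            expect_equal(got, mean(acc))
          }
        }
      }
    }
    whole <- res[res$region == "whole" & res$layer == "TRT", ]
    inner <- th[2:34, 2:34, 9][valid[2:34, 2:34]]
    expect_equal(whole$mean_um, mean(inner))
  }
})

test_that("block exclusion is strictly more-than-10-percent", {
  # a 512 map so blocks have exactly 170^2 = 28900 A-scans
  th <- array(20, c(512, 512, 9))
  th[, , 9] <- 160
  mk <- function(n_excluded) {
    valid <- matrix(TRUE, 512, 512)
    # exclude inside block B1 (cropped rows/cols 1..170 -> map 2..171)
    idx <- arrayInd(seq_len(n_excluded), c(170, 170))
    valid[cbind(idx[, 1] + 1, idx[, 2] + 1)] <- FALSE
    m <- manual_map(th, valid)
    crop_and_block(m)
  }
  at_thresh <- mk(2890)   # exactly 10.0%
  over <- mk(2891)
  b1_at <- at_thresh[at_thresh$region == "B1", ]
  b1_over <- over[over$region == "B1", ]
  expect_true(all(b1_at$retained))
  expect_false(any(b1_over$retained))
  expect_true(all(is.na(b1_over$mean_um)))
  expect_true(all(over$retained[over$region %in% paste0("B", 2:9)]))
  # constant map with no exclusions: all block means equal, SD 0
  clean <- crop_and_block(constant_map())
  expect_true(all(clean$mean_um[clean$layer == "IPL"] == 20))
  expect_true(all(clean$sd_um == 0))
  # grids that cannot be framed and split 3x3 are rejected
  expect_error(crop_and_block(constant_map(34)), "divisible")
})

test_that("a 12-percent corrupted block is excluded by QC, clean blocks stay", {
  ph <- generate_phantom(phantom_spec(), dims = c(35, 35, 256),
                         noise = "none", seed = 13)
  # corrupt 12% of block B5's A-scans (cropped rows/cols 12..22 -> map 13..23)
  cor <- corrupt_volume(ph$volume, 0.12, mode = "low_contrast",
                        region = list(rows = 13:23, cols = 13:23), seed = 14)
  bs <- boundaries_from_classmap(oracle_classmap(ph$truth))
  th <- compute_thickness(bs, ph$truth$scale)
  qc <- qc_ascan(cor$volume, bs, th)
  th <- apply_qc(th, qc)
  res <- crop_and_block(th)
  expect_false(any(res$retained[res$region == "B5"]))
  expect_true(all(res$retained[res$region %in% paste0("B", c(1:4, 6:9))]))
})
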