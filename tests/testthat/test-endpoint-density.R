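mk_set <- function(streamlines, tract = "t", subject = "s") {
  structure(list(tract = tract, subject = subject, streamlines = streamlines),
            class = "streamline_set")
}

# a density_volume built directly from values (for mask-level tests)
mk_vol <- function(values, origin = c(0, 0, 0), n_endpoints = 1) {
  structure(list(values = values, origin = origin, tract = "t",
                 subject = "s", collection = "first",
                 n_endpoints = n_endpoints),
            class = "density_volume")
}

test_that("density maps count endpoints and preserve totals under smoothing", {
  set.seed(61)
  sls <- lapply(1:25, function(i)
    rbind(c(10, 10, 10) + runif(3, 0, 3), c(40, 40, 40) + runif(3, 0, 3)))
  s <- mk_set(sls)
  raw <- endpoint_density_map(s, "first", smoothing_radius = 0)
  expect_equal(sum(raw$values), 25)
  expect_true(all(raw$values == floor(raw$values)))
  sm <- endpoint_density_map(s, "first", smoothing_radius = 3)
  expect_equal(sum(sm$values), 25, tolerance = 1e-9)
  # last-node collection counts the other ends
  last <- endpoint_density_map(s, "last", smoothing_radius = 0)
  expect_equal(sum(last$values), 25)
  nz <- which(last$values > 0, arr.ind = TRUE)
  coords <- sweep(nz - 1, 2, last$origin, "+")   # mm corner of each voxel
  expect_true(all(coords >= 40 & coords <= 43))
})

test_that("the spherical kernel reaches exactly the voxels within its radius", {
  # one endpoint at a voxel center; brute-force distance check over the grid
  s <- mk_set(list(rbind(c(20.5, 20.5, 20.5), c(35, 35, 35))))
  v <- endpoint_density_map(s, "first", smoothing_radius = 3)
  nz <- which(v$values > 0, arr.ind = TRUE)
  centers <- sweep(nz - 0.5, 2, v$origin, "+")
  dist <- sqrt(rowSums(sweep(centers, 2, c(20.5, 20.5, 20.5))^2))
  expect_true(all(dist <= 3))
  # count of touched voxels equals the brute-force ball count
  ball <- 0
  for (dx in -3:3) for (dy in -3:3) for (dz in -3:3)
    if (dx^2 + dy^2 + dz^2 <= 9) ball <- ball + 1
  expect_equal(nrow(nz), ball)
  expect_true(all(abs(v$values[nz] - 1 / ball) < 1e-12))
})

test_that("density maps are invariant to streamline order", {
  set.seed(62)
  sls <- lapply(1:30, function(i) rbind(runif(3, 0, 10), runif(3, 20, 30)))
  a <- endpoint_density_map(mk_set(sls), origin = c(-5, -5, -5),
                            dim = c(45, 45, 45))
  b <- endpoint_density_map(mk_set(sls[sample(30)]), origin = c(-5, -5, -5),
                            dim = c(45, 45, 45))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("group masks threshold strictly, binarize, then sum subjects", {
  dim3 <- c(4, 4, 4)
  v <- array(0, dim3); v[2, 2, 2] <- 0.5; v[3, 3, 3] <- 0.01
  vols <- lapply(1:10, function(i) mk_vol(v, n_endpoints = 1))
  gm <- group_endpoint_mask(vols, density_threshold = 0.01,
                            normalize = FALSE)
  expect_equal(gm$values[2, 2, 2], 10)   # identical suprathreshold subjects
  expect_equal(gm$values[3, 3, 3], 0)    # exactly 0.01 is excluded (strict >)
  expect_equal(gm$n_subjects, 10)
  # disjoint endpoint zones across two subjects never exceed 1
  v2 <- array(0, dim3); v2[1, 1, 1] <- 1
  gm2 <- group_endpoint_mask(list(mk_vol(v, 1), mk_vol(v2, 1)),
                             normalize = FALSE)
  expect_equal(max(gm2$values), 1)
  # normalized thresholding divides by the subject's endpoint total
  gm3 <- group_endpoint_mask(list(mk_vol(v, n_endpoints = 100)),
                             density_threshold = 0.01)
  expect_equal(gm3$values[2, 2, 2], 0)   # 0.5/100 = 0.005 <= 0.01
  expect_error(group_endpoint_mask(list(mk_vol(v), mk_vol(array(0, c(2, 2, 2))))),
               "common grid")
})

test_that("overlap proportions hit constructed 1.0 / 0.5 / 0.0 cases exactly", {
  dim3 <- c(10, 10, 10)
  vals <- array(0L, dim3); vals[1:5, , ] <- 150L
  mask_hi <- structure(list(values = vals, origin = c(0, 0, 0), tract = "hi",
                            collection = "first", n_subjects = 1000),
                       class = "group_endpoint_mask")
  vals99 <- array(99L, dim3)
  mask99 <- structure(list(values = vals99, origin = c(0, 0, 0),
                           tract = "low", collection = "first",
                           n_subjects = 1000),
                      class = "group_endpoint_mask")
  sites <- data.frame(group = rep(c("IOC.Face1", "STC.Face2"), each = 2),
                      x = c(2, 3, 2, 8), y = 2, z = 2)
  ov <- compute_overlap(sites, list(hi = mask_hi, low = mask99))
  expect_equal(ov$matrix["IOC.Face1", "hi"], 1.0)
  expect_equal(ov$matrix["STC.Face2", "hi"], 0.5)
  # a mask whose max support is 99 subjects yields zero overlap everywhere
  expect_equal(ov$dropped, "low")
  # all-miss group: proportion 0; fully-missing masks are dropped
  sites2 <- data.frame(group = "ITC.Face1", x = 8, y = 8, z = 8)
  ov2 <- compute_overlap(sites2, list(hi = mask_hi))
  expect_equal(unname(ov2$matrix), matrix(numeric(0), 1, 0),
               ignore_attr = TRUE)
  expect_equal(ov2$dropped, "hi")
})

test_that("overlap is monotone in the validity threshold and warns off-grid", {
  dim3 <- c(6, 6, 6)
  vals <- array(0L, dim3)
  vals[1:3, , ] <- 120L; vals[4, , ] <- 100L
  mask <- structure(list(values = vals, origin = c(0, 0, 0), tract = "t",
                         collection = "first", n_subjects = 1000),
                    class = "group_endpoint_mask")
  sites <- data.frame(group = "g", x = c(0.5, 2.5, 3.5, 5.5), y = 1, z = 1)
  o100 <- compute_overlap(sites, list(t = mask), validity_threshold = 100)
  o110 <- compute_overlap(sites, list(t = mask), validity_threshold = 110)
  o130 <- compute_overlap(sites, list(t = mask), validity_threshold = 130)
  expect_equal(o100$matrix[1, 1], 0.75)
  expect_equal(o110$matrix[1, 1], 0.5)
  expect_gte(o110$matrix[1, 1], if (ncol(o130$matrix)) o130$matrix[1, 1] else 0)
  far <- data.frame(group = "g", x = 100, y = 100, z = 100)
  expect_warning(compute_overlap(rbind(sites, far), list(t = mask)),
                 "outside")
})

test_that("a tract built to land on an electrode cluster dominates its row", {
  set.seed(63)
  ioc_xyz <- c(42, -88, -8)
  specs <- list(list(name = "to_ioc", from = c(30, -40, 30), to = ioc_xyz,
                     n_streamlines = 40),
                list(name = "away", from = c(30, -40, 30), to = c(-40, 40, 20),
                     n_streamlines = 40))
  sets <- simulate_tract_endpoints(12, specs, scatter_sd = 1.5, rng_seed = 6)
  grids <- list(to_ioc = c(30, -100, -20), away = c(-52, 28, 8))
  masks <- list()
  for (nm in c("to_ioc", "away")) {
    vols <- lapply(Filter(function(s) s$tract == nm, sets), function(s)
      endpoint_density_map(reorient_streamlines(s), "last",
                           origin = grids[[nm]], dim = c(25, 25, 25)))
    masks[[nm]] <- group_endpoint_mask(vols, density_threshold = 1e-4)
  }
  sites <- data.frame(group = rep(c("IOC.Face1", "STC.Face1"), each = 3),
                      x = c(ioc_xyz[1] + c(-1, 0, 1), 55, 56, 57),
                      y = c(rep(ioc_xyz[2], 3), -45, -45, -45),
                      z = c(rep(ioc_xyz[3], 3), 5, 5, 5))
  ov <- suppressWarnings(compute_overlap(sites, masks,
                                         validity_threshold = 10))
  expect_equal(ov$matrix["IOC.Face1", "to_ioc"], 1.0)
  expect_equal(ov$matrix["STC.Face1", "to_ioc"], 0.0)
})

test_that("volumes export to NIfTI with the MNI origin in the affine", {
  skip_if_not_installed("RNifti")
  v <- mk_vol(array(1, c(3, 3, 3)), origin = c(10, -20, 5))
  path <- withr::local_tempfile(fileext = ".nii")
  write_volume_nifti(v, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(3, 3, 3))
  expect_equal(unname(RNifti::xform(img)[1:3, 4]), c(10.5, -19.5, 5.5))
})
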