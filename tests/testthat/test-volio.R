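test_that("geometry validates its invariants", {
  expect_error(geometry(c(1, -1, 1)), "spacing")
  expect_error(geometry(c(1, 1, 1), orientation = matrix(1, 3, 3)),
               "orthonormal")
  g <- geometry(c(0.5, 0.5, 3))
  expect_s3_class(g, "acl_geometry")
  expect_equal(abs(det(geometry_affine(g)[1:3, 1:3])), prod(g$spacing),
               tolerance = 1e-9)
})

test_that("voxel/physical mapping matches the affine and inverts exactly", {
  g <- geometry(c(1, 1, 1))
  expect_equal(voxel_to_physical(g, c(1, 2, 3)), c(1, 2, 3))
  g2 <- geometry(c(0.25, 0.25, 3))
  expect_equal(voxel_to_physical(g2, c(4, 4, 1)), c(1, 1, 3))
  set.seed(1)
  for (i in 1:20) {
    g3 <- geometry(runif(3, 0.2, 4), rnorm(3, 0, 50), random_rotation())
    idx <- runif(3, -5, 60)
    expect_equal(physical_to_voxel(g3, voxel_to_physical(g3, idx)), idx,
                 tolerance = 1e-9)
  }
})

test_that("NIfTI write/read round-trips data and geometry", {
  cs <- generate_phantom(tiny_spec(noise_sd = 0.05), seed = 3)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(cs$volume, path)
  v2 <- read_volume(path)
  expect_equal(v2$data, cs$volume$data, tolerance = 1e-12)
  expect_equal(v2$geometry$spacing, cs$volume$geometry$spacing,
               tolerance = 1e-6)
  expect_equal(v2$geometry$origin, cs$volume$geometry$origin, tolerance = 1e-6)
  expect_equal(v2$geometry$orientation, cs$volume$geometry$orientation,
               tolerance = 1e-6)
  # label maps survive with integer labels intact
  lpath <- tempfile(fileext = ".nii.gz")
  write_volume(cs$labels, lpath)
  l2 <- read_label_map(lpath)
  expect_identical(l2$data, cs$labels$data)
  expect_error(read_volume(tempfile()), "no such file")
})

test_that("cropping preserves physical coordinates", {
  cs <- generate_phantom(tiny_spec(noise_sd = 0), seed = 4)
  vol <- cs$volume
  d <- dim(vol$data)
  full <- crop_patch(vol, list(min = c(0, 0, 0), max = d - 1))
  expect_equal(full$data, vol$data)
  expect_equal(full$geometry$origin, vol$geometry$origin)

  sub <- crop_patch(vol, list(min = c(2, 0, 0), max = d - 1))
  expect_equal(sub$geometry$origin, c(2, 0, 0))

  # a landmark inside the box maps to the same physical point after cropping
  box <- list(min = c(3, 2, 1), max = d - 2)
  sub2 <- crop_patch(vol, box)
  lm <- cs$gt$rupture_point
  v_orig <- physical_to_voxel(vol$geometry, lm)
  v_crop <- physical_to_voxel(sub2$geometry, lm)
  expect_equal(v_orig - box$min, v_crop, tolerance = 1e-9)
  expect_equal(voxel_to_physical(sub2$geometry, v_crop), lm, tolerance = 1e-9)

  expect_error(crop_patch(vol, list(min = c(0, 0, 0), max = d)), "out of bounds")
})

test_that("in-plane resampling is linear and extent-preserving", {
  cs <- generate_phantom(tiny_spec(noise_sd = 0.02), seed = 5)
  vol <- cs$volume
  same <- resample_in_plane(vol, vol$geometry$spacing[1:2])
  expect_equal(same$data, vol$data, tolerance = 1e-6)

  const <- volume(array(2.5, c(8, 8, 3)), geometry(c(1, 1, 3)))
  rs <- resample_in_plane(const, c(0.25, 0.25))
  expect_equal(range(rs$data), c(2.5, 2.5), tolerance = 1e-9)
  expect_equal(rs$geometry$spacing[1:2], c(0.25, 0.25))
  expect_equal(dim(rs$data)[3], 3L)

  # linear interpolation reproduces a linear ramp exactly
  ramp <- volume(array(rep(0:7, times = 8 * 3), c(8, 8, 3)),
                 geometry(c(1, 1, 3)))
  up <- resample_in_plane(ramp, c(0.5, 0.5))
  xs <- (seq_len(dim(up$data)[1]) - 1) * 0.5
  expect_equal(up$data[, 1, 1], xs, tolerance = 1e-6)
  # physical extent preserved within one voxel
  old_ext <- (dim(ramp$data)[1] - 1) * 1
  new_ext <- (dim(up$data)[1] - 1) * 0.5
  expect_lt(abs(old_ext - new_ext), 1)

  expect_error(resample_in_plane(vol, c(0, 1)), "> 0")
})

test_that("DICOM series round-trips through the phantom writer", {
  cs <- generate_phantom(tiny_spec(noise_sd = 0.05), seed = 6)
  vq <- quantize_intensities(cs$volume)
  dcm_dir <- tempfile("dcm_")
  set.seed(1)
  write_dicom_series(vq, dcm_dir, shuffle_names = TRUE)
  v2 <- read_volume(dcm_dir)
  expect_equal(v2$data, vq$data, tolerance = 1e-6)
  expect_equal(v2$geometry$spacing, vq$geometry$spacing, tolerance = 1e-6)
  expect_equal(v2$geometry$origin, vq$geometry$origin, tolerance = 1e-6)

  # NIfTI and DICOM readers agree on the same quantized series
  npath <- tempfile(fileext = ".nii.gz")
  write_volume(vq, npath)
  v3 <- read_volume(npath)
  expect_equal(v2$data, v3$data, tolerance = 1e-6)
  expect_equal(v2$geometry$origin, v3$geometry$origin, tolerance = 1e-6)
})

test_that("DICOM reader rejects mixed and corrupt series", {
  vq <- quantize_intensities(
    generate_phantom(tiny_spec(noise_sd = 0), seed = 7)$volume)
  dir2 <- tempfile("dcm2_")
  set.seed(2)
  write_dicom_series(vq, dir2)
  # second series into the same directory -> mixed-series error
  sub <- crop_patch(vq, list(min = c(0, 0, 0), max = dim(vq$data) - 1))
  set.seed(3)
  f <- list.files(dir2)
  write_dicom_series(sub, tempdir_mixed <- tempfile("dcm3_"))
  file.copy(file.path(tempdir_mixed, list.files(tempdir_mixed)[1]),
            file.path(dir2, "extra.dcm"))
  expect_error(read_volume(dir2), "distinct series")

  # removing an interior slice makes the spacing non-uniform
  dir4 <- tempfile("dcm4_")
  set.seed(4)
  write_dicom_series(vq, dir4)
  files <- sort(list.files(dir4, full.names = TRUE))
  file.remove(files[3])
  expect_error(read_volume(dir4), "non-uniform")
})

test_that("pydicom independently parses the exported series", {
  vq <- quantize_intensities(
    generate_phantom(tiny_spec(noise_sd = 0.05), seed = 8)$volume)
  dcm_dir <- tempfile("dcm_py_")
  set.seed(5)
  write_dicom_series(vq, dcm_dir)
  script <- paste(
    "import sys, glob, pydicom",
    "files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))",
    "ds = [pydicom.dcmread(f) for f in files]",
    "ds.sort(key=lambda d: float(d.ImagePositionPatient[2]))",
    "tot = 0.0",
    "for d in ds:",
    "    arr = d.pixel_array * float(d.RescaleSlope) + float(d.RescaleIntercept)",
    "    tot += float(arr.sum())",
    "print(ds[0].Rows, ds[0].Columns, len(ds), tot)",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, dcm_dir), stdout = TRUE)
  vals <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  d <- dim(vq$data)
  expect_equal(vals[1:3], c(d[2], d[1], d[3]))
  expect_equal(vals[4], sum(vq$data), tolerance = 1e-6)
})
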