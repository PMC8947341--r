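# On-disk formats: k-space dialect, NIfTI volumes, manifests, outputs.

test_that("k-space files round-trip exactly at stored precision", {
  # snap doubles through one write/read cycle (payload is float32), then
  # the cycle must be the identity, byte for byte
  k0 <- rand_kspace(32, seed = 1)
  f1 <- tempfile(fileext = ".kspace")
  write_kspace(k0, f1)
  k1 <- read_kspace(f1)
  expect_equal(dim(k1$data), c(32L, 32L))
  expect_equal(k1$nucleus, "Si29")
  expect_equal(k1$fov_mm, c(64, 64))
  f2 <- tempfile(fileext = ".kspace")
  write_kspace(k1, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(read_kspace(f2)$data, k1$data)
  # float32 quantization error is bounded
  expect_lt(max(Mod(k1$data - k0$data)), 1e-6 * max(Mod(k0$data)))
})

test_that("k-space metadata survives the round trip", {
  k <- rand_kspace(4, seed = 2)
  k$meta <- list(scanner = "7T", sequence = "RARE")
  f <- tempfile()
  write_kspace(k, f)
  expect_equal(read_kspace(f)$meta, k$meta)
})

test_that("header/payload mismatches are reported precisely", {
  k <- rand_kspace(32, seed = 3)
  f <- tempfile()
  write_kspace(k, f)
  # truncate the payload: header says 32 x 32 but fewer values follow
  bytes <- readBin(f, "raw", file.size(f))
  writeBin(bytes[1:(length(bytes) - 64)], f)
  expect_error(read_kspace(f), "truncated")
  # corrupt the header
  writeBin(charToRaw("{\"dims\": [32, 32]}\n"), f)
  expect_error(read_kspace(f), "nucleus")
  writeBin(charToRaw("not json\n"), f)
  expect_error(read_kspace(f), "JSON")
  expect_error(read_kspace(tempfile()), "no such file")
})

test_that("anatomical NIfTI volumes round-trip with spacing intact", {
  set.seed(4)
  vol <- anat_volume(array(runif(16 * 16 * 22), c(16, 16, 22)),
                     c(0.25, 0.25), 0.75)
  f <- tempfile(fileext = ".nii")
  write_anatomical(vol, f)
  back <- read_anatomical(f)
  expect_equal(back$n_slices, 22L)
  expect_equal(back$pixel_spacing_mm, c(0.25, 0.25), tolerance = 1e-6)
  expect_equal(back$slice_thickness_mm, 0.75, tolerance = 1e-6)
  # float32 storage precision
  expect_equal(back$slices, vol$slices, tolerance = 1e-6)
})

test_that("a 2D NIfTI is accepted as a single-slice volume", {
  set.seed(5)
  img <- RNifti::asNifti(matrix(runif(64), 8, 8), internal = FALSE)
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  vol <- read_anatomical(f)
  expect_equal(vol$n_slices, 1L)
  f2 <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti", f2)
  expect_error(read_anatomical(f2), "NIfTI")
})

test_that("manifests parse, validate cohorts and reject duplicates", {
  dir <- withr::local_tempdir()
  rows <- data.frame(
    study_id = sprintf("s%02d", 1:12),
    cohort = rep(c("targeted", "biological_control", "chemical_control",
                   "preblocked"), each = 3),
    silicon_path = "si.kspace", anatomical_path = "anat.nii",
    phantom_reference = 50, display_slice = 10,
    roi_quad = "68 36 188 36 188 236 68 236",
    tumor_rois = "112 176 7; 148 160 7",
    nontumor_rois = "144 72 7",
    body_roi = "70 40 180 40 180 230 100 235 70 230",
    stringsAsFactors = FALSE)
  f <- file.path(dir, "manifest.csv")
  write.csv(rows, f, row.names = FALSE)
  m <- read_manifest(f)
  expect_length(m$studies, 12)
  expect_equal(m$defaults$threshold_multiplier, 5)
  expect_equal(m$defaults$corner_fraction, 0.125)
  expect_equal(m$defaults$tail_percent, 1)
  s <- m$studies[[1]]
  expect_s3_class(s$roi_quad, "quad_roi")
  expect_length(s$tumor_rois, 2)
  expect_equal(s$tumor_rois[[1]]$center, c(112, 176))
  expect_equal(s$tumor_rois[[1]]$diameter_mm, 7)
  expect_equal(dim(s$body_roi), c(5L, 2L))
  # resolved against the manifest directory
  expect_equal(s$silicon_path, file.path(dir, "si.kspace"))

  bad <- rows; bad$study_id[2] <- "s01"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "duplicate")
  bad <- rows; bad$cohort[1] <- "mystery"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "allowed.*targeted|targeted")
  write.csv(rows[0, ], f, row.names = FALSE)
  expect_error(read_manifest(f), "at least one")
  write.csv(rows[, -1], f, row.names = FALSE)
  expect_error(read_manifest(f), "study_id")
})

test_that("CSV and XLSX manifests of the same rows parse identically", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "m.csv")
  xlsx <- file.path(dir, "m.xlsx")
  rows <- data.frame(
    study_id = c("a", "b"),
    cohort = c("targeted", "preblocked"),
    silicon_path = c("a.kspace", "b.kspace"),
    anatomical_path = c("a.nii", "b.nii"),
    phantom_reference = c(48.5, 51.25), display_slice = c(10, 11),
    roi_quad = "68 36 188 36 188 236 68 236",
    tumor_rois = "112 176 7", nontumor_rois = "144 72 7",
    body_roi = "", stringsAsFactors = FALSE)
  write.csv(rows, csv, row.names = FALSE)
  # no xlsx writer is available in R here; build the workbook with the
  # system python + openpyxl
  script <- file.path(dir, "make_xlsx.py")
  writeLines(c(
    "import sys, csv, openpyxl",
    "wb = openpyxl.Workbook(); ws = wb.active",
    "for row in csv.reader(open(sys.argv[1])):",
    "    ws.append(row)",
    "wb.save(sys.argv[2])"), script)
  res <- system2("python", c(script, csv, xlsx))
  expect_identical(res, 0L)
  m_csv <- read_manifest(csv)
  m_xlsx <- read_manifest(xlsx)
  expect_equal(m_xlsx, m_csv)
})

test_that("parameter overrides replace the built-in defaults", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.csv")
  write.csv(data.frame(study_id = "a", cohort = "targeted",
                       silicon_path = "a.kspace",
                       anatomical_path = "a.nii",
                       phantom_reference = 50, display_slice = 0),
            f, row.names = FALSE)
  pf <- file.path(dir, "params.csv")
  write.csv(data.frame(name = "threshold_multiplier", value = 4),
            pf, row.names = FALSE)
  m <- read_manifest(f, parameters_path = pf)
  expect_equal(m$defaults$threshold_multiplier, 4)
  expect_equal(m$defaults$tail_percent, 1)
  write.csv(data.frame(name = "bogus", value = 1), pf, row.names = FALSE)
  expect_error(read_manifest(f, parameters_path = pf), "unknown parameter")
})

test_that("write_outputs names files by study id and is deterministic", {
  dir <- withr::local_tempdir()
  st <- structure(list(study_id = "demo", cohort = "targeted"),
                  class = "study_record")
  img <- rand_image(16, 16, seed = 6)
  anat <- contrast_stretch(rand_image(16, 16, seed = 7), 0)
  si <- set_normalize(list(img))$images[[1]]
  ov <- composite_overlay(anat, si)
  q <- structure(list(study_id = "demo", snr = 3.2, cnr = 1.1,
                      mu_t = 1, mu_b = 0.1, sigma_b = 0.28,
                      mu_m = 0.2, sigma_m = 0.7),
                 class = "quant_result")
  files <- write_outputs(st, si, ov, q, dir)
  expect_gte(length(files), 3)
  expect_true(all(startsWith(basename(files), "demo_")))
  expect_true(all(file.exists(files)))
  # identical contents on a rerun
  sums1 <- tools::md5sum(files)
  files2 <- write_outputs(st, si, ov, q, dir)
  expect_identical(unname(tools::md5sum(files2)), unname(sums1))
  # the processed NIfTI re-reads to the same values at stored precision
  nii <- files[grepl("_silicon[.]nii$", files)]
  back <- read_anatomical(nii)
  expect_equal(back$slices[, , 1], si$pixels, tolerance = 1e-6)
  qj <- jsonlite::fromJSON(files[grepl("quant[.]json$", files)])
  expect_equal(qj$snr, 3.2)
})
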