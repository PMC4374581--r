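test_that("the synthetic AIF is zero pre-bolus with the configured area", {
  times <- study_times()
  aif <- generate_aif(times, bolus_time = 25, area = 100)
  expect_true(all(aif[times <= 25] == 0))
  expect_true(all(aif >= 0))
  # quadrature oracle on a long fine grid reaches the analytic area
  tl <- seq(0, 30000, by = 0.5)
  al <- generate_aif(tl, bolus_time = 25, area = 100)
  area_num <- sum((al[-1] + al[-length(al)]) / 2 * diff(tl))
  expect_equal(area_num, 100, tolerance = 0.01)
  # pointwise linearity in dose
  expect_equal(generate_aif(times, 25, dose = 2), 2 * aif, tolerance = 1e-12)
  expect_error(generate_aif(c(0, 1, 1, 2), 0.5), "strictly increasing")
})

test_that("ground truth is deterministic and encodes the effect directions", {
  cfg <- cohort_config(seed = 42)
  gt1 <- cohort_ground_truth(cfg)
  gt2 <- cohort_ground_truth(cfg)
  expect_identical(gt1, gt2)
  expect_equal(nrow(gt1), 24)

  wide <- function(p) tidyr::pivot_wider(
    gt1[, c("patient", "timepoint", p)],
    names_from = "timepoint", values_from = dplyr::all_of(p))
  for (p in c("gtv_ct", "gtv_mr", "gtv_dw", "suvmax")) {
    w <- wide(p)
    expect_true(all(w$fx11 < w$baseline), info = p)   # shrink / decline
  }
  for (p in c("adc", "pf")) {
    w <- wide(p)
    expect_true(all(w$fx11 > w$baseline), info = p)   # rise
  }
  # derived parameters obey their algebra row-wise
  dk <- derive_ef_ktrans(gt1$pf, gt1$ps)
  expect_equal(gt1$ef, dk$EF)
  expect_equal(gt1$ktrans, dk$Ktrans)
})

test_that("image sets are reproducible and internally consistent", {
  cfg <- tiny_config(seed = 7, pet_sigma = 0.2, dwi_sigma = 1.25,
                     dce_sigma = 0.05)
  a <- generate_patient_timepoint(cfg, 2, "fx11")
  b <- generate_patient_timepoint(cfg, 2, "fx11")
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$dce$data, b$dce$data)
  expect_identical(a$masks$gtv_dw$mask, b$masks$gtv_dw$mask)
})

test_that("noise-free phantoms match their generative equations exactly", {
  cfg <- tiny_config(seed = 5)
  cell <- generate_patient_timepoint(cfg, 1, "baseline")
  tr <- cell$truth

  # PET: uniform lesion at true SUVmax over a warm background
  expect_equal(max(cell$pet$values), tr$suvmax)
  expect_equal(sort(unique(as.numeric(cell$pet$values))), c(2, tr$suvmax))

  # DWI: voxelwise mono-exponential decay at the true ADC inside the lesion
  lesion <- cell$masks$gtv_dw$mask
  s0 <- cell$dwi$b0$values[lesion][1]
  s800 <- cell$dwi$b800$values[lesion][1]
  expect_equal(-log(s800 / s0) / 800 * 1000, tr$adc, tolerance = 1e-9)

  # DCE: tumour voxels carry the shared 2CXM curve; the artery voxel is the
  # unique global maximum of enhancement
  conc <- baseline_subtract(cell$dce, cfg$n_baseline)
  emap <- max_enhancement_map(conc)
  sel <- select_aif(emap, cell$masks$artery, conc)
  expect_equal(sel$aif, cell$aif_true, tolerance = 1e-9)
  expect_equal(which(emap$values == max(emap$values)), sel$linear_index)
  tum_curve <- conc$data[which(cell$masks$gtv_mr$mask)[1] +
                           (seq_along(conc$times) - 1) *
                           prod(dim(conc$data)[1:3])]
  expect_equal(tum_curve,
               simulate_2cxm_tissue(list(PF = tr$pf, PV = tr$pv, ve = tr$ve,
                                         PS = tr$ps),
                                    cell$aif_true, cell$times),
               tolerance = 1e-9)
})

test_that("mask volumes track the configured shrinkage", {
  cfg <- tiny_config(seed = 13)
  base <- generate_patient_timepoint(cfg, 1, "baseline")
  fx11 <- generate_patient_timepoint(cfg, 1, "fx11")
  ratio <- mask_volume_cm3(fx11$masks$gtv_mr, fx11$pet$spacing) /
    mask_volume_cm3(base$masks$gtv_mr, base$pet$spacing)
  truth_ratio <- fx11$truth$gtv_mr / base$truth$gtv_mr
  expect_equal(ratio, truth_ratio, tolerance = 0.12)  # voxelization error
  expect_lt(ratio, 1)
})

test_that("a tumour shrunk below one voxel is refused", {
  cfg <- tiny_config(seed = 3)
  cfg$effect_profile$fx11[cfg$effect_profile$parameter == "gtv_dw"] <- -0.9995
  truth <- cohort_ground_truth(cfg)
  truth$gtv_dw[truth$timepoint == "fx11"] <- 0.001
  expect_error(generate_patient_timepoint(cfg, 1, "fx11", truth = truth),
               "below one voxel")
})

test_that("cohorts write a complete, reproducible directory tree", {
  cfg <- tiny_config(seed = 19, n_patients = 2, n_frames = 30)
  dir1 <- withr::local_tempdir()
  man <- generate_cohort(cfg, dir1, overwrite = TRUE)
  # 2 patients x 2 timepoints x (1 PET + 3 DWI + 1 DCE + 1 times + 6 masks)
  expect_equal(length(man$files), 2 * 2 * 12 + 1)
  expect_true(file.exists(file.path(dir1, "ground_truth.csv")))
  listed <- vapply(man$files, `[[`, "", "path")
  expect_true(all(file.exists(file.path(dir1, listed))))

  expect_error(generate_cohort(cfg, dir1), "overwrite")

  # regenerating from the manifest seed reproduces the ground truth
  cfg2 <- tiny_config(seed = man$seed, n_patients = 2, n_frames = 30)
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg2, dir2, overwrite = TRUE)
  gt1 <- readLines(file.path(dir1, "ground_truth.csv"))
  gt2 <- readLines(file.path(dir2, "ground_truth.csv"))
  expect_identical(gt1, gt2)

  # written cells read back into an analyzable structure
  cell <- read_patient_timepoint(dir1, 1, "baseline")
  ref <- generate_patient_timepoint(cfg, 1, "baseline")
  expect_equal(cell$pet$values, ref$pet$values, tolerance = 1e-6)
  expect_identical(cell$masks$gtv_mr$mask, ref$masks$gtv_mr$mask)
  expect_equal(cell$dce$times, ref$dce$times)
})
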