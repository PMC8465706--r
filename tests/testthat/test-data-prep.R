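mk_points <- function(organ, t, v, sigma = NA_real_, modality = "PET",
                      units = "percent") {
  data.frame(organ = organ, time_h = t, value = v, sigma = sigma,
             modality = modality, units = units, decay = "decay_included",
             stringsAsFactors = FALSE)
}

test_that("mass scaling converts concentrations and round-trips", {
  ds <- biokin_dataset(mk_points("heart_wall", c(1, 2), c(0.01, 0.005),
                                 sigma = c(5e-4, 2.5e-4),
                                 units = "percent_per_gram"),
                       masses = c(heart_wall = 291))
  out <- concentration_to_activity(ds)
  expect_equal(out$points$value, c(2.91, 1.455))
  expect_equal(out$points$sigma, c(0.1455, 0.07275))
  expect_true(all(out$points$units == "percent"))

  # murine liver: 1 %/g * 2.150 g
  mu <- biokin_dataset(mk_points("liver", 1, 1, units = "percent_per_gram"),
                       masses = c(liver = 2.150))
  expect_equal(concentration_to_activity(mu)$points$value, 2.150)

  # zero concentration stays zero; missing mass errors with the organ name
  z <- biokin_dataset(mk_points("liver", 1, 0, units = "percent_per_gram"),
                      masses = c(liver = 2.150))
  expect_equal(concentration_to_activity(z)$points$value, 0)
  expect_error(concentration_to_activity(
    biokin_dataset(mk_points("spleen", 1, 1, units = "percent_per_gram"))),
    "spleen")

  # round trip restores the original values to float tolerance
  back <- out$points$value / 291
  expect_equal(back, c(0.01, 0.005), tolerance = 1e-15)
})

test_that("tumor PET/SPECT merging rescales onto the PET curve", {
  mu <- 0.01
  pet <- data.frame(time_h = c(24, 48, 120),
                    value = exp(-mu * c(24, 48, 120)))
  # SPECT lies on twice the PET exponential: expected scale is 0.5
  spect_t <- c(120, 170, 330, 505)
  spect <- data.frame(time_h = spect_t, value = 2 * exp(-mu * spect_t))
  res <- merge_pet_spect_tumor(pet, spect, junction_time_h = 120)
  expect_equal(res$scale, 0.5, tolerance = 1e-9)
  expect_equal(res$spect_points_dropped, 1)  # in-range point discarded
  # continuity at the junction: rescaled curve passes through PET(120)
  expect_equal(res$A * exp(-res$mu * 120) * res$scale,
               pet$value[pet$time_h == 120], tolerance = 1e-9)
  expect_equal(nrow(res$merged), 3 + 3)

  # SPECT exactly on the PET exponential: identity scale
  spect2 <- data.frame(time_h = spect_t, value = exp(-mu * spect_t))
  expect_equal(merge_pet_spect_tumor(pet, spect2)$scale, 1, tolerance = 1e-9)

  expect_error(merge_pet_spect_tumor(pet, spect[1:2, ]), "two SPECT points")
  expect_error(merge_pet_spect_tumor(pet[1:2, ], spect), "junction")
})

test_that("uncertainty assignment follows the 5%/10% rule", {
  p <- rbind(mk_points("liver", 1, 10),
             mk_points("tumor", c(2, 170), c(2, 1),
                       modality = c("PET", "SPECT")),
             mk_points("blood", 1, 50, sigma = 3, modality = "blood"))
  ds <- assign_uncertainties(biokin_dataset(p))
  pts <- ds$points
  expect_equal(pts$sigma[pts$organ == "liver"], 0.5)
  expect_equal(pts$sigma[pts$organ == "tumor" & pts$modality == "PET"], 0.10)
  expect_equal(pts$sigma[pts$organ == "tumor" & pts$modality == "SPECT"],
               0.10)  # 10% of 1.0
  # explicit sigma (cohort dispersion) is preserved
  expect_equal(pts$sigma[pts$organ == "blood"], 3)
  # zero activity gets the floor, with a warning
  expect_warning(z <- assign_uncertainties(biokin_dataset(
    mk_points("liver", 1, 0))), "floor")
  expect_equal(z$points$sigma, 1e-6)
  # concentrations must be converted first
  expect_error(assign_uncertainties(biokin_dataset(
    mk_points("liver", 1, 1, units = "percent_per_gram"))), "percent")
})

test_that("exclusion rules drop points and series as instructed", {
  p <- rbind(mk_points("bladder", c(24, 120, 170), c(10, 20, 30),
                       modality = "urine"),
             mk_points("spinal_cord", c(24, 48), c(0.1, 0.1)))
  ds <- biokin_dataset(p)
  out <- suppressMessages(filter_points(ds, list(
    list(organ = "bladder", time_h = 120, reason = "unrepresentative"),
    list(organ = "spinal_cord", reason = "low uptake"))))
  expect_equal(nrow(out$points), 2)
  expect_false("spinal_cord" %in% out$points$organ)
  expect_false(120 %in% out$points$time_h[out$points$organ == "bladder"])
  # empty exclusion list is the identity; no-match warns but does not error
  expect_identical(filter_points(ds, list())$points, ds$points)
  expect_warning(filter_points(ds, list(list(organ = "brain"))),
                 "matched nothing")
})

test_that("time-activity CSV round trip preserves the table", {
  ds <- generate_dataset(clr_final_model(), clr_reference_parameters(),
                         seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_csv(ds, path)
  back <- read_tac_csv(path)
  expect_equal(back$points$value, ds$points$value, tolerance = 1e-12)
  expect_identical(back$points$organ, ds$points$organ)
})
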