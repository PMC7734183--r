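# Phantom-cohort generator: determinism, planted effects, null behaviour.

test_that("template generation is seeded, masked and symmetric", {
  a <- make_template(c(20, 20, 20), "full", seed = 1)
  b <- make_template(c(20, 20, 20), "full", seed = 1)
  expect_identical(a$template, b$template)
  expect_false(identical(
    a$template, make_template(c(20, 20, 20), "full", seed = 2)$template))
  expect_true(all(a$mask == 1))
  expect_true(all(a$template[a$mask > 0] != 0))

  e <- make_template(c(20, 20, 20), "ellipsoid", seed = 1)
  # mirror symmetry about the medial sagittal plane: mask(x) = mask(19 - x)
  expect_identical(e$mask, e$mask[20:1, , ])
  expect_true(all(e$template[e$mask == 0] == 0))
  expect_lt(sum(e$mask), length(e$mask))
})

test_that("template rejects too-small dimensions, naming the axis", {
  expect_error(make_template(c(6, 20, 20), "full"), "axis x")
  expect_error(make_template(c(20, 20, 7), "full"), "axis z")
})

test_that("subject simulation honours group, effect and noise", {
  tm <- make_template(c(18, 18, 18), "full", seed = 4, tile_shape = c(6, 6, 6))
  grid <- build_grid(c(18, 18, 18), patch_shape(6, 6, 6))
  boxes <- grid$boxes[5, ]

  # zero noise, control: exact template
  expect_identical(
    simulate_subject(tm$template, tm$mask, 0, boxes, "decorrelate", 1, 0, 9),
    tm$template)
  # zero-magnitude effect on a case: still the template
  expect_identical(
    simulate_subject(tm$template, tm$mask, 1, boxes, "mean_shift", 0, 0, 9),
    tm$template)
  # unknown effect kind
  expect_error(
    simulate_subject(tm$template, tm$mask, 1, boxes, "swap", 1, 0, 9),
    "unknown effect_kind")
  # mean shift moves exactly the patch voxels
  shifted <- simulate_subject(tm$template, tm$mask, 1, boxes, "mean_shift",
                              2, 0, 9)
  d <- shifted - tm$template
  inside <- array(FALSE, dim(d))
  inside[(boxes$x0 + 1):boxes$x1, (boxes$y0 + 1):boxes$y1,
         (boxes$z0 + 1):boxes$z1] <- TRUE
  expect_equal(unique(round(d[inside], 10)),
               round(2 * sd(tm$template[tm$mask > 0]), 10))
  expect_true(all(d[!inside] == 0))
})

test_that("decorrelation lowers the planted patch's correlation in cases", {
  tm <- make_template(c(18, 18, 18), "full", seed = 7, tile_shape = c(6, 6, 6))
  grid <- build_grid(c(18, 18, 18), patch_shape(6, 6, 6))
  planted <- grid$boxes[1, ]
  distant <- grid$boxes[nrow(grid$boxes), ]
  corr_to_distant <- function(group, seeds) {
    vapply(seeds, function(s) {
      v <- simulate_subject(tm$template, tm$mask, group, planted,
                            "decorrelate", 1, 0.5, s)
      abs(cor(patch_vector(v, planted), patch_vector(v, distant)))
    }, numeric(1))
  }
  cases <- corr_to_distant(1, 1:20)
  controls <- corr_to_distant(0, 21:40)
  expect_lt(mean(cases), mean(controls))
  expect_gt(mean(controls), 0.3)  # texture correlation survives the noise
})

test_that("cohort simulation is deterministic with the declared layout", {
  spec <- toy_spec(seed = 11, n_control = 3, n_case = 2)
  co <- simulate_cohort(spec)
  expect_length(co$volumes, 5)
  expect_equal(co$labels$group, c(0L, 0L, 0L, 1L, 1L))
  expect_identical(co, simulate_cohort(spec))
  # a different seed changes the data
  expect_false(identical(
    co$volumes[[1]], simulate_cohort(toy_spec(seed = 12, n_control = 3,
                                              n_case = 2))$volumes[[1]]))
})

test_that("spec validation rejects bad cohorts", {
  expect_error(toy_spec(n_control = 1), "at least 2 subjects")
  expect_error(cohort_spec(c(18, 18, 18), "full", 3, 3,
                           patch_shape = c(6, 6, 6),
                           effect_patches = 99), "inside the grid")
  expect_error(toy_spec(effect_magnitude = -1), "effect_magnitude")
})

test_that("null cohorts show no group difference in patch correlations", {
  # with no planted effect, a fixed patch-pair correlation difference across
  # groups should be non-significant in the vast majority of replicates
  grid <- build_grid(c(18, 18, 18), patch_shape(6, 6, 6))
  b1 <- grid$boxes[1, ]
  b2 <- grid$boxes[14, ]
  pvals <- vapply(1:50, function(s) {
    co <- simulate_cohort(toy_spec(effect_magnitude = 0, seed = 100 + s,
                                   n_control = 4, n_case = 4))
    r <- vapply(co$volumes, function(v) {
      cor(patch_vector(v, b1), patch_vector(v, b2))
    }, numeric(1))
    t.test(r[co$labels$group == 0], r[co$labels$group == 1])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("cohorts round-trip through the NIfTI + CSV + JSON layout", {
  co <- simulate_cohort(toy_spec(seed = 5))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files$path)))
  loaded <- load_cohort(files$path, file.path(dir, "labels.csv"),
                        file.path(dir, "mask.nii.gz"))
  expect_equal(loaded$labels$group, co$labels$group)
  expect_equal(loaded$volumes[[1]], co$volumes[[1]], tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$spec$seed, 5)
})
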