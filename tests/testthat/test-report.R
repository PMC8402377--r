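test_that("localization scores follow their closed forms", {
  v <- matrix(0, 20, 20); v[3:6, 3:6] <- 1
  hm <- new_heatmap(v, "GradCAM", "unit")
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  sc <- localization_score(hm, mask)
  expect_equal(sc$mass_fraction, 1)          # all mass inside the mask
  expect_equal(sc$area_fraction, 0.25)
  expect_equal(sc$enrichment, 4)

  # uniform heatmap, 10% mask: mass 0.10, enrichment 1
  hu <- new_heatmap(matrix(0.7, 20, 20), "unit", "unit")
  m10 <- matrix(FALSE, 20, 20); m10[1:2, 1:20] <- TRUE
  su <- localization_score(hu, m10)
  expect_equal(su$mass_fraction, 0.1)
  expect_equal(su$enrichment, 1)

  # all-zero relevance: mass defined as 0
  hz <- new_heatmap(matrix(-1, 20, 20), "symmetric_signed", "symmetric_signed")
  expect_equal(localization_score(hz, m10)$mass_fraction, 0)

  expect_error(localization_score(hm, matrix(FALSE, 20, 20)), "nonempty")
  expect_error(localization_score(hm, matrix(TRUE, 5, 5)), "shape")
})

test_that("mass fractions over a partition of the image sum to one", {
  set.seed(5)
  hm <- new_heatmap(matrix(runif(24 * 24), 24, 24), "RISE", "min_max")
  seg <- grid_segmentation(24, 24, 2)
  masses <- vapply(seq_len(seg$n_segments), function(s)
    localization_score(hm, seg$labels == s)$mass_fraction, numeric(1))
  expect_equal(sum(masses), 1, tolerance = 1e-12)
})

test_that("relevance respects each scale convention", {
  v <- matrix(seq(-2, 2, length.out = 16), 4, 4)
  expect_equal(biaslens:::relevance_values(new_heatmap(v, "t", "symmetric_signed")),
               pmax(v, 0))
  expect_equal(biaslens:::relevance_values(new_heatmap(v, "t", "magnitude")),
               abs(v))
  expect_equal(biaslens:::relevance_values(new_heatmap(v, "t", "min_max")),
               v - min(v))
})

test_that("rendering follows the per-technique color conventions", {
  # zero signed map: uniform mid-scale color
  hz <- new_heatmap(matrix(0, 10, 10), "LIME", "symmetric_signed")
  r <- render_heatmap(hz)
  expect_equal(length(unique(as.vector(r$heat[, , 1]))), 1)
  # unit convention: single-hue blue, never red-dominant
  hu <- new_heatmap(matrix(runif(100), 10, 10), "GradCAM", "unit")
  ru <- render_heatmap(hu)
  expect_true(all(ru$heat[, , 3] >= ru$heat[, , 1] - 1e-9))
  # magnitude: grayscale (all channels equal)
  hg <- new_heatmap(matrix(runif(100), 10, 10), "VanillaGrad", "magnitude")
  rg <- render_heatmap(hg)
  expect_equal(rg$heat[, , 1], rg$heat[, , 2])
  expect_equal(rg$heat[, , 2], rg$heat[, , 3])
  # rendering is a pure function
  expect_identical(render_heatmap(hu), render_heatmap(hu))
  # NaN rejected
  bad <- new_heatmap(matrix(1, 4, 4), "t", "unit")
  bad$values[2, 2] <- NaN
  expect_error(render_heatmap(bad), "NaN")
})

test_that("the top-decile region has the expected pixel count", {
  set.seed(8)
  hm <- new_heatmap(matrix(rnorm(30 * 30), 30, 30), "LIME", "symmetric_signed")
  m <- top_fraction_mask(hm, 0.1)
  expect_equal(sum(m), ceiling(0.1 * 900))   # continuous values: no ties
})

test_that("the comparison grid covers every cell and records GradCAM's ensemble gap", {
  img <- render_scan(1, "letter", dataset_spec(image_size = c(48, 48)), seed = 6)
  orc1 <- make_region_oracle(img$masks$letter, gain = 5, id = "letter_model")
  orc2 <- make_region_oracle(img$masks$lesion, gain = 5, id = "lesion_model")
  ens <- ensemble_classifier(list(orc1, orc2), id = "ens")
  out <- withr::local_tempdir()
  res <- compare_report(list(orc1, ens), c("gradcam", "vanilla", "lime"),
                        img, out_dir = out, seed = 1,
                        opts = list(n_samples = 60, nslic = 8))
  rep <- res$report
  # ensemble x gradcam -> undefined; ensemble x vanilla -> not differentiable
  expect_equal(rep$status[rep$classifier == "ens" & rep$technique == "gradcam"],
               "undefined for ensembles")
  expect_equal(rep$status[rep$classifier == "ens" & rep$technique == "vanilla"],
               "requires differentiable classifier")
  # computed cells produce one row per artifact mask present in the image
  kinds <- length(img$masks)
  ok_rows <- rep[rep$status == "ok", ]
  computed_cells <- nrow(unique(ok_rows[, c("classifier", "technique")]))
  expect_equal(nrow(ok_rows), computed_cells * kinds)
  # 2 classifiers x 3 techniques attempted in total
  expect_equal(computed_cells + 2, 2 * 3)
  expect_true(file.exists(file.path(out, "localization_report.csv")))
  expect_gt(length(res$files), 0)
})
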