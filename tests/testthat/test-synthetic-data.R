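test_that("generated datasets match the requested composition exactly", {
  spec <- tiny_spec(seed = 11,
                    splits = list(train = c(5L, 3L), val = c(2L, 4L),
                                  test = c(1L, 0L)))
  ds <- generate_dataset(spec)
  expect_length(ds, 15)
  tab <- table(split = vapply(ds, function(i) i$split, character(1)),
               label = vapply(ds, function(i) i$label, numeric(1)))
  expect_equal(as.integer(tab["train", ]), c(5L, 3L))
  expect_equal(as.integer(tab["val", ]), c(2L, 4L))
  expect_equal(as.integer(tab["test", "0"]), 1L)

  # all-zero composition yields an empty list
  empty <- generate_dataset(tiny_spec(splits = list(train = c(0L, 0L))))
  expect_length(empty, 0)

  # the default composition is the published 746-image layout
  d <- dataset_spec()
  expect_equal(vapply(d$split_sizes, sum, numeric(1)),
               c(train = 425, val = 118, test = 203))
  expect_equal(d$split_sizes$val, c(58L, 60L))
})

test_that("rendering is deterministic, bounded, and masks track planted artifacts", {
  spec <- dataset_spec(image_size = c(224, 224))
  kinds <- c("letter", "colored_marking", "round_frame", "support_structure")
  img <- render_scan(1, kinds, spec, seed = 5)
  img2 <- render_scan(1, kinds, spec, seed = 5)
  expect_identical(img$pixels, img2$pixels)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_setequal(names(img$masks), c(kinds, "lesion"))
  expect_true(all(vapply(img$masks, any, logical(1))))
  # letter and marking regions never overlap
  expect_equal(sum(img$masks$letter & img$masks$colored_marking), 0)
  # letter mask occupies between 0.1% and 4% of the pixels
  area <- mean(img$masks$letter)
  expect_gt(area, 0.001)
  expect_lt(area, 0.04)

  # class 1 with no artifacts carries only the lesion mask
  clean <- render_scan(1, character(), tiny_spec(), seed = 2)
  expect_identical(names(clean$masks), "lesion")
  # class 0 never gets a lesion
  neg <- render_scan(0, "round_frame", tiny_spec(), seed = 3)
  expect_false("lesion" %in% names(neg$masks))

  expect_error(render_scan(1, "sticker", tiny_spec()), "sticker")
})

test_that("class-conditional artifact frequencies converge to the configured rates", {
  n <- 300L
  rates <- list(letter = c(0.05, 0.6), support_structure = c(0.3, 0.7))
  spec <- dataset_spec(split_sizes = list(train = c(n, n)),
                       image_size = c(32, 32), artifact_rates = rates,
                       seed = 21)
  ds <- generate_dataset(spec)
  labs <- vapply(ds, function(i) i$label, numeric(1))
  for (k in names(rates)) for (cls in 0:1) {
    hit <- vapply(ds[labs == cls], function(i) k %in% names(i$masks), logical(1))
    p <- rates[[k]][cls + 1]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_gt(mean(hit), p - half - 1e-9)
    expect_lt(mean(hit), p + half + 1e-9)
  }
})

test_that("dataset generation is order-independent via per-image substreams", {
  spec <- tiny_spec(seed = 31)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(lapply(a, function(i) i$pixels),
                   lapply(b, function(i) i$pixels))
})

test_that("write/read round trip preserves pixels to 8-bit quantization", {
  ds <- generate_dataset(tiny_spec(seed = 4, splits = list(train = c(2L, 1L))))
  dir <- withr::local_tempdir()
  man <- write_dataset(ds, dir)
  expect_equal(nrow(man), 3)
  expect_true(all(c("image_id", "path", "label", "split", artifact_kinds)
                  %in% names(man)))
  back <- read_dataset(dir)
  dev <- max(mapply(function(a, b) max(abs(a$pixels - b$pixels)), ds, back))
  expect_lte(dev, 1 / 255 + 1e-12)
  # flags consistent with masks
  for (i in seq_along(ds)) {
    expect_identical(sort(as.character(names(back[[i]]$masks))),
                     sort(as.character(names(ds[[i]]$masks))))
    for (k in names(ds[[i]]$masks))
      expect_identical(unname(back[[i]]$masks[[k]]), unname(ds[[i]]$masks[[k]]))
  }
  # empty dataset still produces a valid, empty manifest
  man0 <- write_dataset(list(), file.path(dir, "empty"))
  expect_equal(nrow(man0), 0)
  expect_true(file.exists(file.path(dir, "empty", "manifest.csv")))
})

test_that("dataset specs round-trip through their JSON config", {
  spec <- tiny_spec(seed = 17)
  p <- withr::local_tempfile(fileext = ".json")
  write_dataset_spec(spec, p)
  back <- read_dataset_spec(p)
  expect_equal(back$split_sizes, spec$split_sizes)
  expect_equal(back$artifact_rates, spec$artifact_rates)
  expect_identical(generate_dataset(back)[[1]]$pixels,
                   generate_dataset(spec)[[1]]$pixels)
})

test_that("invalid specs are rejected", {
  expect_error(dataset_spec(image_size = c(16, 64)), ">= 32")
  expect_error(dataset_spec(artifact_rates = list(halo = c(0.1, 0.2))), "halo")
  expect_error(dataset_spec(artifact_rates = list(letter = c(-0.1, 0.5))))
  expect_error(dataset_spec(split_sizes = list(train = c(-1L, 2L))))
})
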