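# Synthetic dermoscopy generator: reproducibility, mask semantics,
# difficulty spanning, dataset writing.

test_that("generation is bit-reproducible from the seed", {
  s1 <- generate_sample(synth_spec(image_size = 64, seed = 5))
  s2 <- generate_sample(synth_spec(image_size = 64, seed = 5))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_sample(synth_spec(image_size = 64, seed = 6))
  expect_false(identical(s3$mask, s1$mask))
})

test_that("masks are binary, connected, single-blob, with admissible area", {
  set.seed(81)
  for (i in 1:8) {
    smp <- generate_sample(synth_spec(image_size = 64, seed = 500 + i))
    m <- smp$mask
    expect_true(all(m %in% c(0, 1)))
    frac <- mean(m)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.6)
    labels <- EBImage::bwlabel(EBImage::Image(m))
    expect_equal(max(labels), 1)  # one connected component
  }
})

test_that("artifacts perturb the image but never the ground truth", {
  base <- synth_spec(image_size = 64, hair = FALSE, glue = FALSE,
                     ruler = FALSE, seed = 9)
  witharticles <- synth_spec(image_size = 64, hair = TRUE, glue = TRUE,
                             ruler = TRUE, seed = 9)
  a <- generate_sample(base)
  b <- generate_sample(withArtifacts <- witharticles)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$image, b$image))
})

test_that("easy crisp scenes are nearly solvable by Otsu thresholding", {
  jas <- sapply(1:6, function(i) otsu_baseline(generate_sample(easy_spec(i))))
  expect_gte(mean(jas), 0.9)
})

test_that("Otsu-baseline difficulty decreases from easy to hard scenes", {
  seeds <- 1:8
  easy <- mean(sapply(seeds, function(i)
    otsu_baseline(generate_sample(easy_spec(i)))))
  medium <- mean(sapply(seeds, function(i)
    otsu_baseline(generate_sample(synth_spec(image_size = 64, fuzziness = 2,
                                             contrast = 0.45, seed = i)))))
  hard <- mean(sapply(seeds, function(i)
    otsu_baseline(generate_sample(hard_spec(i)))))
  expect_gt(easy, medium)
  expect_gt(medium, hard)
})

test_that("dataset writing produces PNG pairs, a manifest, and disjoint splits", {
  dir <- file.path(tempdir(), "synds")
  man <- generate_dataset(10, synth_spec(image_size = 32), dir, seed = 3,
                          train_frac = 0.7)
  expect_equal(nrow(man), 10)
  expect_length(list.files(dir, pattern = "_mask\\.png$"), 10)
  expect_length(list.files(dir, pattern = "^img\\d+\\.png$"), 10)
  expect_length(intersect(man$image_id[man$split == "train"],
                          man$image_id[man$split == "val"]), 0)
  # byte-identical across runs of the same call
  dir2 <- file.path(tempdir(), "synds2")
  generate_dataset(10, synth_spec(image_size = 32), dir2, seed = 3,
                   train_frac = 0.7)
  f1 <- file.path(dir, "img00004.png")
  f2 <- file.path(dir2, "img00004.png")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # loading round-trips the binary mask
  ds <- load_dataset(dir, split = "train")
  expect_length(ds, 7)
  expect_true(all(ds[[1]]$mask %in% c(0, 1)))
})
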