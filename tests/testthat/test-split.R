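test_that("split sizes follow the half-up rounding rule at the study scale", {
  # 13 identities, 3,772 items total (11 classes of 290, 2 of 291)
  man <- fake_manifest(c(rep(290, 11), 291, 291))
  expect_equal(nrow(man), 3772)
  sp <- split_dataset(man, seed = 5)
  expect_equal(sum(sp$split == "train"), 2640)
  expect_equal(sum(sp$split == "val"), 754)
  expect_equal(sum(sp$split == "test"), 378)
})

test_that("a 10-item class splits 7/2/1", {
  man <- fake_manifest(10)
  sp <- split_dataset(man, seed = 1)
  expect_equal(unname(c(sum(sp$split == "train"), sum(sp$split == "val"),
                        sum(sp$split == "test"))), c(7, 2, 1))
})

test_that("splits are disjoint, exhaustive, stratified and reproducible", {
  set.seed(31)
  for (rep in 1:5) {
    sizes <- sample(5:40, sample(3:8, 1), replace = TRUE)
    man <- fake_manifest(sizes)
    s1 <- split_dataset(man, seed = rep)
    s2 <- split_dataset(man, seed = rep)
    expect_identical(s1$split, s2$split)           # same seed, same plan
    expect_equal(nrow(s1), sum(sizes))             # exhaustive
    expect_true(all(s1$split %in% c("train", "val", "test")))
    n <- nrow(s1)
    expect_equal(sum(s1$split == "train"), floor(0.7 * n + 0.5))
    expect_equal(sum(s1$split == "val"), floor(0.2 * n + 0.5))
    # every class is represented in training
    expect_true(all(table(s1$identity[s1$split == "train"]) >= 1))
    # stratification: per-class training share close to 70%
    shares <- tapply(s1$split == "train", s1$identity, mean)
    expect_true(all(abs(shares - 0.7) < 0.25))
  }
  s3 <- split_dataset(fake_manifest(c(20, 20)), seed = 99)
  s4 <- split_dataset(fake_manifest(c(20, 20)), seed = 100)
  expect_false(identical(s3$split, s4$split))
})

test_that("degenerate split inputs are rejected", {
  expect_error(split_dataset(fake_manifest(c(8, 2)), seed = 1), "fewer items")
  expect_error(split_dataset(fake_manifest(5), seed = 1), "at least 10")
  expect_error(split_dataset(fake_manifest(20), fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("rotation augmentation exactly triples the training manifest and spares val/test", {
  man <- split_dataset(fake_manifest(c(12, 12, 12)), seed = 2)
  n_train <- sum(man$split == "train")
  aug <- augment_rotations(man, seed = 3)
  expect_equal(nrow(aug), nrow(man) + 2 * n_train)
  expect_equal(sum(aug$split == "train"), 3 * n_train)
  expect_equal(sum(aug$split != "train"), sum(man$split != "train"))
  expect_true(all(aug$rot[aug$split != "train"] == 0))
  # each original contributes itself (rot 0) plus two distinct angles
  for (p in unique(aug$path[aug$split == "train"])) {
    rots <- sort(aug$rot[aug$path == p & aug$split == "train"])
    expect_equal(rots[1], 0)
    expect_length(rots, 3)
    expect_length(unique(rots), 3)
    expect_true(all(rots[-1] %in% c(90, 180, 270)))
  }
  # empty input passes through
  expect_equal(nrow(augment_rotations(man[0, ], seed = 1)), 0)
  expect_error(augment_rotations(man, angles = c(90, 180)), "smaller than 3")
  # same seed, same angles
  expect_identical(augment_rotations(man, seed = 7)$rot,
                   augment_rotations(man, seed = 7)$rot)
})

test_that("right-angle rotation is lossless and 0 degrees is the identity", {
  img <- array(runif(8 * 6 * 3), c(8, 6, 3))
  expect_identical(rotate_rgb(img, 0), img)
  r <- img
  for (i in 1:4) r <- rotate_rgb(r, 90)
  expect_equal(r, img)
  expect_equal(rotate_rgb(rotate_rgb(img, 90), 270), img)
  expect_equal(dim(rotate_rgb(img, 90)), c(6L, 8L, 3L))
  expect_error(rotate_rgb(img, 45), "right-angle")
})
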