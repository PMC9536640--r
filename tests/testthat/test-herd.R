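test_that("coat patterns are deterministic, balanced, and identity-distinct", {
  p1 <- generate_coat_pattern(7, 1, 64)
  expect_identical(p1, generate_coat_pattern(7, 1, 64))
  expect_true(all(p1 %in% c(0, 1)))
  # median thresholding keeps the black fraction near one half
  fracs <- vapply(1:12, function(s)
    mean(generate_coat_pattern(s, 1 + s %% 5, 64)), numeric(1))
  expect_true(all(fracs >= 0.45 & fracs <= 0.55))
  # different identities disagree on a substantial pixel fraction
  pats <- lapply(1:6, function(i) generate_coat_pattern(7, i, 64))
  for (i in 1:5) for (j in (i + 1):6)
    expect_gte(mean(pats[[i]] != pats[[j]]), 0.2)
  expect_error(generate_coat_pattern(1, 1, 32), "at least 64")
})

test_that("rendering honors the zero-perturbation and brightness contracts", {
  pat <- generate_coat_pattern(3, 2, 64)
  img <- render_instance(pat)
  expect_identical(dim(img), c(64L, 64L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  # zero perturbation: the pattern disc over the clean mid-gray background
  g <- 0.08 + 0.84 * pat
  ctr <- (64 + 1) / 2
  dd <- outer(seq_len(64) - ctr, seq_len(64) - ctr, function(a, b) sqrt(a^2 + b^2))
  inside <- dd <= 0.46 * 64
  expect_equal(img[, , 1][inside], g[inside])
  expect_true(all(img[, , 1][!inside] == 0.5))
  # brightness 1 leaves the pattern-region mean unchanged within 1/255
  b1 <- render_instance(pat, list(angle = 5, scale = 1, brightness = 1,
                                  clutter = 0, bg_seed = 1))
  b2 <- render_instance(pat, list(angle = 5, scale = 1, brightness = 1.0,
                                  clutter = 0, bg_seed = 1))
  expect_lt(abs(mean(b1[, , 1][inside]) - mean(b2[, , 1][inside])), 1 / 255)
  # identical records render identical images
  rec <- list(angle = -8, scale = 0.95, brightness = 1.2, clutter = 0.3,
              bg_seed = 42)
  expect_identical(render_instance(pat, rec), render_instance(pat, rec))
  expect_error(render_instance(pat, list(scale = 0)), "positive")
  expect_error(render_instance(pat, list(clutter = 2)), "range")
})

test_that("dataset generation writes the folder layout, manifest, and is bit-reproducible", {
  spec <- herd_spec(n_identities = 4, images_per_identity = 3,
                    master_seed = 5, side = 64)
  d1 <- file.path(tempdir(), "herd_a")
  unlink(d1, recursive = TRUE)
  man <- generate_dataset(spec, d1)
  expect_equal(nrow(man), 12)
  files <- list.files(d1, pattern = "\\.png$", recursive = TRUE)
  expect_length(files, 12)
  expect_length(list.dirs(d1, recursive = FALSE), 4)
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_setequal(unique(man$identity), sprintf("cow_%02d", 1:4))
  # refuses to clobber, regenerates identically with overwrite
  expect_error(generate_dataset(spec, d1), "not empty")
  h1 <- vapply(file.path(d1, sort(files)), function(f)
    digest_file(f), character(1))
  d2 <- file.path(tempdir(), "herd_b")
  unlink(d2, recursive = TRUE)
  generate_dataset(spec, d2)
  h2 <- vapply(file.path(d2, sort(files)), function(f)
    digest_file(f), character(1))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("identity signal survives perturbation: a raw-pixel centroid classifier beats chance", {
  accs <- vapply(1:3, function(s) {
    root <- herd_dir(per_id = 6, seed = 10 + s)
    man <- read_manifest(file.path(root, "manifest.csv"))
    dat <- load_manifest_images(man, root, 24)
    v <- t(apply(dat$x, 4, as.vector))
    test_idx <- which(seq_along(dat$y) %% 6 == 0)   # one held-out per class
    cent <- sapply(sort(unique(dat$y)), function(k)
      colMeans(v[setdiff(which(dat$y == k), test_idx), , drop = FALSE]))
    pred <- apply(v[test_idx, , drop = FALSE], 1, function(z)
      which.min(colSums((cent - z)^2)))
    mean(pred == dat$y[test_idx])
  }, numeric(1))
  expect_gt(mean(accs), 3 / 13)
})

test_that("within-identity images correlate more than between-identity images", {
  root <- herd_dir(per_id = 6, seed = 11)
  man <- read_manifest(file.path(root, "manifest.csv"))
  dat <- load_manifest_images(man, root, 24)
  v <- t(apply(dat$x, 4, as.vector))
  cors <- stats::cor(t(v))
  same <- outer(dat$y, dat$y, "==") & upper.tri(cors)
  diff <- outer(dat$y, dat$y, "!=") & upper.tri(cors)
  expect_gt(mean(cors[same]), mean(cors[diff]))
})
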