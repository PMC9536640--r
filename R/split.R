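# ---------------------------------------------------------------------------
# Dataset splitting and rotation augmentation.
# ---------------------------------------------------------------------------

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Stratified train/validation/test split
#'
#' Splits a manifest into train, validation and test sets. Global set sizes
#' follow the rounding rule: train and validation sizes are the half-up
#' rounded fractions of the total; the test set takes the remainder. Items
#' are allocated per identity (stratified) by largest-remainder apportionment
#' so each class keeps close to the global proportions while the global
#' sizes are met exactly. Reproducible for a fixed seed; the three sets are
#' disjoint and exhaustive.
#'
#' @param manifest Data frame with at least an `identity` column.
#' @param fractions Numeric length-3 `(train, val, test)` summing to 1.
#' @param seed Integer seed controlling the within-class shuffle.
#' @return The manifest with a `split` column (`"train"`, `"val"`, `"test"`);
#'   attributes `fractions` and `seed` record the plan.
#' @export
split_dataset <- function(manifest, fractions = c(0.7, 0.2, 0.1), seed = 1) {
  stopifnot(is.data.frame(manifest), "identity" %in% names(manifest))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  n <- nrow(manifest)
  if (n < 10) stop("at least 10 items are required to split")
  cls <- as.character(manifest$identity)
  tab <- table(cls)
  if (any(tab < 3))
    stop(sprintf("class '%s' has fewer items than split bins",
                 names(tab)[which(tab < 3)[1]]))

  n_tr <- floor(n * fractions[1] + 0.5)
  n_va <- floor(n * fractions[2] + 0.5)
  n_te <- n - n_tr - n_va
  target <- c(train = n_tr, val = n_va, test = n_te)

  # per-class quotas: floor of the ideal, then largest-remainder top-up
  # constrained to the global totals
  classes <- names(tab)
  q <- outer(as.numeric(tab), fractions)          # ideal counts, K x 3
  base <- floor(q)
  rem <- q - base
  # ensure every class keeps at least one training item
  for (k in seq_along(classes)) if (base[k, 1] == 0) {
    base[k, 1] <- 1
    rem[k, 1] <- 0
  }
  need <- target - colSums(base)
  # distribute leftover items class by class, preferring the split with the
  # largest unmet remainder that still has capacity
  leftover <- as.numeric(tab) - rowSums(base)
  ord <- order(-leftover)
  for (k in ord) {
    while (leftover[k] > 0) {
      s <- which(need > 0)
      if (!length(s)) break
      pick <- s[which.max(rem[k, s])]
      base[k, pick] <- base[k, pick] + 1
      leftover[k] <- leftover[k] - 1
      need[pick] <- need[pick] - 1
    }
  }
  # repair: a half-up rounding coincidence can over-fill one split by one
  # item; move it to the under-filled split from the class holding most there
  while (any(need > 0) && any(need < 0)) {
    s_over <- which.min(need)
    s_under <- which.max(need)
    donor <- which.max(base[, s_over])
    base[donor, s_over] <- base[donor, s_over] - 1
    base[donor, s_under] <- base[donor, s_under] + 1
    need[s_over] <- need[s_over] + 1
    need[s_under] <- need[s_under] - 1
  }

  split <- character(n)
  with_seed(seed, {
    for (k in seq_along(classes)) {
      idx <- sample(which(cls == classes[k]))
      counts <- base[k, ]
      split[idx] <- rep(c("train", "val", "test"), times = counts)
    }
  })
  manifest$split <- split
  attr(manifest, "fractions") <- fractions
  attr(manifest, "seed") <- seed
  manifest
}

#' Triple the training set by lossless rotations
#'
#' Every training item contributes itself plus two rotated copies whose
#' angles are drawn without replacement from `angles` (right-angle rotations
#' are pixel-lossless). Validation and test items are never augmented. The
#' expanded manifest gains a `rot` column (degrees, 0 for originals).
#'
#' @param manifest Manifest data frame; rows with `split == "train"` (or all
#'   rows when no `split` column is present) are expanded.
#' @param angles Candidate rotation angles; at least 3 are required for the
#'   tripling.
#' @param seed Integer seed for the angle draws.
#' @return The expanded manifest: `3 x` the training rows plus untouched
#'   validation/test rows.
#' @export
augment_rotations <- function(manifest, angles = c(90, 180, 270), seed = 1) {
  stopifnot(is.data.frame(manifest))
  if (length(angles) < 3)
    stop("angle set smaller than 3: cannot triple the training set")
  is_train <- if ("split" %in% names(manifest))
    manifest$split == "train" else rep(TRUE, nrow(manifest))
  manifest$rot <- if (nrow(manifest)) 0 else numeric()
  tr <- manifest[is_train, , drop = FALSE]
  rest <- manifest[!is_train, , drop = FALSE]
  if (nrow(tr) == 0) return(manifest)
  extra <- with_seed(seed, {
    picks <- lapply(seq_len(nrow(tr)), function(i) sample(angles, 2))
    do.call(rbind, lapply(1:2, function(j) {
      cp <- tr
      cp$rot <- vapply(picks, `[`, numeric(1), j)
      cp
    }))
  })
  out <- rbind(tr, extra, rest)
  rownames(out) <- NULL
  out
}

#' Exact right-angle rotation of an image array
#'
#' Rotates an `(H, W)` or `(H, W, C)` array counter-clockwise by a multiple
#' of 90 degrees without any resampling; 0 degrees is the identity
#' transform, pixel for pixel.
#'
#' @param img Image array.
#' @param angle One of 0, 90, 180, 270 (mod 360).
#' @return The rotated array.
#' @export
rotate_rgb <- function(img, angle) {
  k <- (as.integer(angle) %/% 90L) %% 4L
  if (as.integer(angle) %% 90L != 0L)
    stop("rotate_rgb only performs lossless right-angle rotations")
  if (k == 0L) return(img)
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  rotk <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (length(dim(img)) == 2) return(rotk(img))
  d <- dim(img)
  out <- NULL
  for (ch in seq_len(d[3])) {
    r <- rotk(img[, , ch])
    if (is.null(out)) out <- array(0, c(dim(r), d[3]))
    out[, , ch] <- r
  }
  out
}
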