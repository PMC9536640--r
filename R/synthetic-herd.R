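# ---------------------------------------------------------------------------
# Synthetic Holstein-like coat-pattern herd.
#
# Each identity is a persistent black-and-white blob pattern (thresholded
# low-pass-filtered noise); instances are rendered under rotation, scale,
# brightness and background-clutter perturbations. The generator emulates
# the statistical structure of side-view coat patterns -- individually
# distinctive high-contrast blobs -- not photorealistic cattle.
# ---------------------------------------------------------------------------

#' Synthetic herd specification
#'
#' The default emulates the reference dataset's shape: 13 identities with a
#' desk-scale 32 images each (use `paper_scale = TRUE` for 290 images each,
#' about 3,772 images, to rehearse the full recipe).
#'
#' @param n_identities Number of cow identities.
#' @param images_per_identity Rendered instances per identity.
#' @param side Rendered image side in pixels (>= 64).
#' @param master_seed Integer seed; every pattern and perturbation is a pure
#'   function of it.
#' @param rotation_deg Instance rotation is drawn uniformly from
#'   `+/- rotation_deg` degrees.
#' @param scale_range Uniform zoom range of the pattern disc.
#' @param brightness_range Uniform multiplicative brightness range
#'   (lighting variation).
#' @param clutter Background clutter density in `[0, 1]` (0 = clean
#'   mid-gray background).
#' @param paper_scale Use 290 images per identity.
#' @return A `herd_spec` list.
#' @export
herd_spec <- function(n_identities = 13, images_per_identity = 32, side = 96,
                      master_seed = 1, rotation_deg = 15,
                      scale_range = c(0.9, 1.1),
                      brightness_range = c(0.7, 1.3),
                      clutter = 0.3, paper_scale = FALSE) {
  if (isTRUE(paper_scale)) images_per_identity <- 290
  s <- list(n_identities = chk_posint(n_identities, "n_identities"),
            images_per_identity = chk_posint(images_per_identity,
                                             "images_per_identity"),
            side = chk_posint(side, "side"),
            master_seed = as.integer(master_seed),
            rotation_deg = rotation_deg,
            scale_range = scale_range,
            brightness_range = brightness_range,
            clutter = clutter)
  if (s$side < 64) stop("side must be at least 64")
  if (clutter < 0 || clutter > 1) stop("clutter must lie in [0, 1]")
  structure(s, class = "herd_spec")
}

# deterministic per-(seed, identity[, instance]) stream seed, kept < 2^31
derive_seed <- function(master, a, b = 0L) {
  as.integer((as.double(master) * 48271 + a * 99991 + b * 101 + 7) %%
               2147483629)
}

#' Generate the persistent coat pattern of one identity
#'
#' Seeded uniform noise is low-pass filtered with a Gaussian kernel
#' (`sigma = side / 12`) and thresholded at its median, yielding a binary
#' black/white blob pattern with an approximately even black fraction. The
#' pattern is a pure function of `(master_seed, identity_index)`.
#'
#' @param master_seed Herd master seed.
#' @param identity_index Identity number (1-based).
#' @param side Pattern side in pixels (>= 64).
#' @return A `side x side` matrix with values in `{0, 1}`.
#' @export
generate_coat_pattern <- function(master_seed, identity_index, side = 96) {
  if (side < 64) stop("side must be at least 64")
  with_seed(derive_seed(master_seed, identity_index), {
    noise <- matrix(stats::runif(side * side), side, side)
    sm <- EBImage::gblur(noise, sigma = side / 12)
    (sm > stats::median(sm)) * 1
  })
}

# inverse-mapping bilinear sampler: rotate by `angle` degrees and zoom by
# `scale` about the image center; cells mapping outside return NA
warp_pattern <- function(img, angle, scale) {
  side <- nrow(img)
  if (angle == 0 && scale == 1) return(img)
  ctr <- (side + 1) / 2
  th <- -angle * pi / 180
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  dr <- (g$r - ctr) / scale
  dc <- (g$c - ctr) / scale
  sr <- cos(th) * dr - sin(th) * dc + ctr
  sc <- sin(th) * dr + cos(th) * dc + ctr
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  pick <- function(rr, cc) {
    ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
    v <- rep(NA_real_, length(rr))
    v[ok] <- img[cbind(rr[ok], cc[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * pick(r0, c0) + fr * (1 - fc) * pick(r0 + 1, c0) +
    (1 - fr) * fc * pick(r0, c0 + 1) + fr * fc * pick(r0 + 1, c0 + 1)
  matrix(v, side, side)
}

#' Render one perturbed instance of a coat pattern
#'
#' The pattern fills a central disc, rotated and zoomed per the perturbation
#' record, with its intensity scaled by the brightness factor; the
#' surroundings are a seeded clutter background (flat mid-gray at clutter
#' density 0). A record with zero perturbation reproduces the pattern over
#' the clean background exactly.
#'
#' @param pattern Binary matrix from [generate_coat_pattern()].
#' @param record List with `angle` (degrees), `scale`, `brightness`,
#'   `clutter` (density in `[0,1]`), `bg_seed` (integer).
#' @return RGB array of dim `(side, side, 3)` with values in `[0, 1]`.
#' @export
render_instance <- function(pattern,
                            record = list(angle = 0, scale = 1,
                                          brightness = 1, clutter = 0,
                                          bg_seed = 0)) {
  side <- nrow(pattern)
  angle <- record$angle %||% 0
  scale <- record$scale %||% 1
  bright <- record$brightness %||% 1
  clutter <- record$clutter %||% 0
  if (scale <= 0) stop("scale must be positive")
  if (clutter < 0 || clutter > 1) stop("clutter out of range [0, 1]")

  g <- 0.08 + 0.84 * pattern              # black ~0.08, white ~0.92
  gw <- warp_pattern(g, angle, scale)
  ctr <- (side + 1) / 2
  rad <- 0.46 * side * min(scale, 1)
  dd <- outer(seq_len(side) - ctr, seq_len(side) - ctr,
              function(a, b) sqrt(a^2 + b^2))
  inside <- dd <= rad & !is.na(gw)

  bg <- if (clutter > 0) {
    with_seed(record$bg_seed %||% 0, {
      bn <- matrix(stats::runif(side * side), side, side)
      bb <- EBImage::gblur(bn, sigma = side / 24)
      bb <- (bb - min(bb)) / max(1e-12, diff(range(bb)))
      (1 - clutter) * 0.5 + clutter * bb
    })
  } else matrix(0.5, side, side)

  out <- bg
  out[inside] <- pmin(1, pmax(0, gw[inside] * bright))
  array(rep(out, 3), c(side, side, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic herd dataset on disk
#'
#' Writes `n_identities x images_per_identity` PNGs in a
#' class-per-subdirectory layout (`cow_01/ ... cow_13/`) plus a
#' `manifest.csv` recording each file's identity and perturbation record.
#' Fully deterministic: the same spec regenerates a bit-identical tree.
#'
#' @param spec A [herd_spec()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest data.frame (`path`, `identity`, `angle`, `scale`,
#'   `brightness`, `bg_seed`), invisibly carrying the spec as an attribute.
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "herd_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !isTRUE(overwrite))
    stop("output directory exists and is not empty (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", spec$n_identities * spec$images_per_identity)
  k <- 0L
  for (id in seq_len(spec$n_identities)) {
    cls <- sprintf("cow_%02d", id)
    dir.create(file.path(out_dir, cls), showWarnings = FALSE)
    pat <- generate_coat_pattern(spec$master_seed, id, spec$side)
    for (j in seq_len(spec$images_per_identity)) {
      rec <- with_seed(derive_seed(spec$master_seed, id, j), list(
        angle = stats::runif(1, -spec$rotation_deg, spec$rotation_deg),
        scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
        brightness = stats::runif(1, spec$brightness_range[1],
                                  spec$brightness_range[2]),
        clutter = spec$clutter,
        bg_seed = derive_seed(spec$master_seed, id, j + 1000000L)))
      img <- render_instance(pat, rec)
      rel <- file.path(cls, sprintf("img_%03d.png", j))
      png::writePNG(img, file.path(out_dir, rel))
      k <- k + 1L
      rows[[k]] <- data.frame(path = rel, identity = cls,
                              angle = rec$angle, scale = rec$scale,
                              brightness = rec$brightness,
                              bg_seed = rec$bg_seed,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "herd_spec") <- spec
  invisible(manifest)
}
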