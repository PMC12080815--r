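#' Rendering parameters for one synthetic fruit class
#'
#' Describes how images of one class are drawn: the fruit's hue and shape,
#' which lesion operator (if any) is applied and how much of the fruit it
#' covers, and the scene difficulty (background clutter, pixel noise).
#'
#' @param base_hue Fruit hue in degrees on the colour wheel, `[0, 360)`.
#' @param shape_eccentricity Unitless ellipse elongation in `[0, 0.6]`;
#'   0 is a circle.
#' @param lesion_kind One of `"none"`, `"blotch"`, `"brown_rot"`,
#'   `"cork_spot"`, `"powdery_mildew"`, `"rot"`, `"scab"`.
#' @param lesion_severity Nominal fraction of the fruit area covered by the
#'   lesion, in `[0, 1]`. A severity of 0 renders identically to
#'   `lesion_kind = "none"`.
#' @param background_clutter Intensity of the distractor background texture,
#'   `[0, 1]`.
#' @param noise_sd Standard deviation of additive per-pixel Gaussian noise,
#'   in `[0, 1]` intensity units.
#' @return An object of class `"fruit_image_spec"`.
#' @export
fruit_image_spec <- function(base_hue = 10, shape_eccentricity = 0.15,
                             lesion_kind = "none", lesion_severity = 0,
                             background_clutter = 0.5, noise_sd = 0.03) {
  lesion_kind <- match.arg(lesion_kind, lesion_kinds())
  if (lesion_severity < 0 || lesion_severity > 1)
    stop("`lesion_severity` must lie in [0, 1]", call. = FALSE)
  if (base_hue < 0 || base_hue >= 360)
    stop("`base_hue` must lie in [0, 360)", call. = FALSE)
  structure(list(base_hue = base_hue,
                 shape_eccentricity = shape_eccentricity,
                 lesion_kind = lesion_kind,
                 lesion_severity = lesion_severity,
                 background_clutter = background_clutter,
                 noise_sd = noise_sd),
            class = "fruit_image_spec")
}

#' @rdname fruit_image_spec
#' @export
lesion_kinds <- function() {
  c("none", "blotch", "brown_rot", "cork_spot", "powdery_mildew", "rot",
    "scab")
}

# Uniform point inside the ellipse (cx, cy, rx, ry), via polar sampling.
ellipse_point <- function(cx, cy, rx, ry, scale = 1) {
  t <- stats::runif(1, 0, 2 * pi)
  u <- sqrt(stats::runif(1))
  c(cx + scale * rx * u * cos(t), cy + scale * ry * u * sin(t))
}

# Blend `col` into img over `where` with opacity `alpha` (matrix or scalar).
blend <- function(img, where, col, alpha) {
  if (!any(where)) return(img)
  a <- if (length(alpha) == 1L) alpha else alpha[where]
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[where] <- (1 - a) * layer[where] + a * col[ch]
    img[, , ch] <- layer
  }
  img
}

# Lesion operators. Each draws its randomness from the current stream and
# modifies fruit pixels only. `geom` carries the pixel grids and fruit
# geometry in normalised [0, 1] image coordinates.
apply_lesion <- function(img, spec, geom) {
  sev <- spec$lesion_severity
  X <- geom$X; Y <- geom$Y; mask <- geom$mask
  rx <- geom$rx; ry <- geom$ry
  switch(spec$lesion_kind,
    rot = ,
    brown_rot = {
      ctr <- ellipse_point(geom$cx, geom$cy, rx, ry, scale = 0.4)
      r <- sqrt(sev * rx * ry)
      edge <- smooth_field(nrow(X), cells = 8)
      d <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
      lmask <- (d <= r * (1 + 0.35 * (edge - 0.5))) & mask
      if (spec$lesion_kind == "rot") {
        blend(img, lmask, c(0.42, 0.24, 0.07), 0.85)
      } else {
        rings <- 0.75 + 0.25 * cos(d / max(r, 1e-6) * 9)
        blend(img, lmask, c(0.30, 0.12, 0.04), 0.9 * rings)
      }
    },
    blotch = {
      edge <- smooth_field(nrow(X), cells = 10)
      for (i in 1:4) {
        ctr <- ellipse_point(geom$cx, geom$cy, rx, ry, scale = 0.75)
        r <- sqrt(sev * rx * ry / 4)
        d <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
        lmask <- (d <= r * (1 + 0.5 * (edge - 0.5))) & mask
        img <- blend(img, lmask, c(0.13, 0.07, 0.03), 0.9)
      }
      img
    },
    scab = {
      rd <- max(1.6 / nrow(X), 0.012)
      n <- min(400L, max(1L, ceiling(sev * rx * ry / rd^2)))
      for (i in seq_len(n)) {
        ctr <- ellipse_point(geom$cx, geom$cy, rx, ry, scale = 0.92)
        lmask <- ((X - ctr[1])^2 + (Y - ctr[2])^2 <= rd^2) & mask
        img <- blend(img, lmask, c(0.18, 0.14, 0.06), 0.85)
      }
      img
    },
    cork_spot = {
      rd <- max(3.2 / nrow(X), 0.03)
      n <- min(80L, max(1L, ceiling(sev * rx * ry / rd^2)))
      for (i in seq_len(n)) {
        ctr <- ellipse_point(geom$cx, geom$cy, rx, ry, scale = 0.85)
        d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
        ring <- (d2 <= rd^2) & (d2 > (0.45 * rd)^2) & mask
        core <- (d2 <= (0.45 * rd)^2) & mask
        img <- blend(img, ring, c(0.25, 0.18, 0.08), 0.6)
        img <- blend(img, core, c(0.75, 0.72, 0.45), 0.35)
      }
      img
    },
    powdery_mildew = {
      fine <- smooth_field(nrow(X), cells = 12)
      vals <- fine[mask]
      thr <- stats::quantile(vals, probs = 1 - sev, names = FALSE)
      lmask <- mask & (fine >= thr)
      blend(img, lmask, c(0.96, 0.96, 0.92), 0.65)
    },
    img)
}

#' Render one synthetic fruit image
#'
#' Draws an elliptical fruit of the class hue on a cluttered background,
#' applies the class's lesion operator at its severity, and adds pixel
#' noise. The output is a deterministic function of `(spec, rng_seed)`:
#' the same pair always yields the identical array, and the caller's RNG
#' stream is left untouched.
#'
#' @param spec A [fruit_image_spec()].
#' @param rng_seed Integer seed for this image.
#' @param image_size Side length in pixels (square images).
#' @return An `image_size` x `image_size` x 3 array of RGB intensities in
#'   `[0, 1]`.
#' @export
#' @examples
#' img <- render_fruit(fruit_image_spec(base_hue = 120), rng_seed = 7,
#'                     image_size = 32)
#' dim(img)
render_fruit <- function(spec, rng_seed, image_size = 96) {
  stopifnot(inherits(spec, "fruit_image_spec"))
  S <- as.integer(image_size)
  with_local_seed(rng_seed, {
    X <- matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S)   # column coord
    Y <- matrix(rep((seq_len(S) - 0.5) / S, times = S), S, S)  # row coord
    # background: green-brown base whose value is modulated by a smooth field
    bg_hue <- stats::runif(1, 70, 130)
    field <- smooth_field(S, cells = 6)
    bg_v <- clip01(0.32 + spec$background_clutter * 0.9 * (field - 0.5))
    bg_rgb <- hsv_unit(bg_hue, 0.4)
    img <- array(0, c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- bg_rgb[ch] * bg_v
    # fruit ellipse with jittered centre/size and radial shading
    cx <- 0.5 + stats::runif(1, -0.05, 0.05)
    cy <- 0.5 + stats::runif(1, -0.05, 0.05)
    r0 <- 0.33 + stats::runif(1, -0.02, 0.02)
    rx <- r0 * (1 + spec$shape_eccentricity / 2)
    ry <- r0 * (1 - spec$shape_eccentricity / 2)
    d2 <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
    mask <- d2 <= 1
    hue <- (spec$base_hue + stats::runif(1, -8, 8)) %% 360
    sat <- clip01(0.75 + stats::runif(1, -0.08, 0.08))
    fruit_rgb <- hsv_unit(hue, sat)
    shade <- clip01(0.95 - 0.45 * d2)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[mask] <- (fruit_rgb[ch] * shade)[mask]
      img[, , ch] <- layer
    }
    # specular highlight towards the upper-left of the fruit
    hd2 <- ((X - (cx - 0.35 * rx))^2 + (Y - (cy - 0.35 * ry))^2) / (0.3 * r0)^2
    gl <- exp(-hd2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.25 * gl * mask
    if (spec$lesion_kind != "none" && spec$lesion_severity > 0) {
      geom <- list(X = X, Y = Y, mask = mask, cx = cx, cy = cy,
                   rx = rx, ry = ry)
      img <- apply_lesion(img, spec, geom)
    }
    img <- img + array(stats::rnorm(S * S * 3, 0, spec$noise_sd), c(S, S, 3))
    clip01(img)
  })
}

# The fruit mask of an image's draw, re-derived deterministically (used by
# tests to measure lesion effect over the fruit area only).
fruit_mask <- function(spec, rng_seed, image_size = 96) {
  S <- as.integer(image_size)
  with_local_seed(rng_seed, {
    X <- matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S)
    Y <- matrix(rep((seq_len(S) - 0.5) / S, times = S), S, S)
    stats::runif(1)            # background hue draw
    smooth_field(S, cells = 6) # background field draws
    cx <- 0.5 + stats::runif(1, -0.05, 0.05)
    cy <- 0.5 + stats::runif(1, -0.05, 0.05)
    r0 <- 0.33 + stats::runif(1, -0.02, 0.02)
    rx <- r0 * (1 + spec$shape_eccentricity / 2)
    ry <- r0 * (1 - spec$shape_eccentricity / 2)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  })
}

# --- dataset designs ---------------------------------------------------------

#' Describe a labelled dataset design
#'
#' A design fixes the class list and the per-class train/test image counts;
#' [generate_dataset()] realises it as images. Scalar counts are recycled
#' across classes.
#'
#' @param name Design name.
#' @param classes Character vector of unique class labels.
#' @param per_class_train,per_class_test Non-negative counts, scalar or one
#'   per class.
#' @param image_size Side length in pixels of emitted images.
#' @param easy Logical; easy designs use low clutter and noise (a
#'   sanity-check regime in which mean colour alone separates classes).
#' @return An object of class `"dataset_design"`.
#' @export
dataset_design <- function(name, classes, per_class_train, per_class_test,
                           image_size = 96, easy = FALSE) {
  if (anyDuplicated(classes)) stop("class labels must be unique", call. = FALSE)
  k <- length(classes)
  per_class_train <- rep_len(as.integer(per_class_train), k)
  per_class_test <- rep_len(as.integer(per_class_test), k)
  if (any(per_class_train < 0) || any(per_class_test < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(name = name, classes = classes,
                 per_class_train = per_class_train,
                 per_class_test = per_class_test,
                 image_size = as.integer(image_size), easy = easy,
                 total = sum(per_class_train) + sum(per_class_test)),
            class = "dataset_design")
}

#' @export
print.dataset_design <- function(x, ...) {
  cat(sprintf("<dataset_design> %s: %d classes, %d train + %d test = %d images (%dpx)\n",
              x$name, length(x$classes), sum(x$per_class_train),
              sum(x$per_class_test), x$total, x$image_size))
  invisible(x)
}

#' Built-in dataset designs
#'
#' The three study designs: `afvc` — 85 fruit-variety classes with 315
#' train / 35 test images each (29,750 images); `afqc` — fresh vs rotten,
#' 1,044 train / 116 test per class (2,320 images); `adec` — seven disease
#' phenotypes (normal, blotch, brown rot, cork spot, powdery mildew, rot,
#' scab) with 2,682 train / 294 test in total. The published per-class
#' breakdown of `adec` is not available, so train counts are spread as
#' evenly as 2,682/7 allows (384 for `normal`, 383 elsewhere) and test
#' counts are 42 per class.
#'
#' @param name One of `"afvc"`, `"afqc"`, `"adec"`.
#' @param image_size Side length in pixels; default 96 keeps generation
#'   desk-scale (pass e.g. 70 for the classifier's native input size).
#' @return A [dataset_design()].
#' @export
#' @examples
#' design_presets("afqc")
design_presets <- function(name = c("afvc", "afqc", "adec"),
                           image_size = 96) {
  name <- match.arg(name)
  switch(name,
    afvc = dataset_design("afvc", sprintf("variety_%02d", 1:85),
                          per_class_train = 315, per_class_test = 35,
                          image_size = image_size),
    afqc = dataset_design("afqc", c("fresh", "rotten"),
                          per_class_train = 1044, per_class_test = 116,
                          image_size = image_size),
    adec = dataset_design("adec",
                          c("normal", "blotch", "brown_rot", "cork_spot",
                            "powdery_mildew", "rot", "scab"),
                          per_class_train = c(384, rep(383, 6)),
                          per_class_test = 42,
                          image_size = image_size))
}

#' Class-imbalanced dataset design
#'
#' Builds a design in which a stated fraction of the classes are minority
#' classes (receiving `minority_count` training images) and the rest are
#' majority classes, for loss-comparison experiments.
#'
#' @param n_classes Number of classes.
#' @param majority_count,minority_count Training images per majority /
#'   minority class.
#' @param minority_fraction_of_classes Fraction in `(0, 1)` of classes that
#'   are minority (at least one, never all).
#' @param per_class_test Test images per class (equal across classes so
#'   minority recall is measured on the same support).
#' @param image_size Side length in pixels.
#' @param easy Passed to [dataset_design()].
#' @return A [dataset_design()] with a logical `minority` field marking the
#'   minority classes.
#' @export
#' @examples
#' d <- imbalance_design(2, 950, 50, 0.5)
#' d$per_class_train  # 950 50
imbalance_design <- function(n_classes, majority_count, minority_count,
                             minority_fraction_of_classes = 0.5,
                             per_class_test = 20, image_size = 32,
                             easy = TRUE) {
  if (minority_fraction_of_classes <= 0 || minority_fraction_of_classes >= 1)
    stop("`minority_fraction_of_classes` must lie in (0, 1)", call. = FALSE)
  if (majority_count <= 0 || minority_count <= 0)
    stop("counts must be positive", call. = FALSE)
  n_min <- min(n_classes - 1L, max(1L, round(minority_fraction_of_classes *
                                               n_classes)))
  n_maj <- n_classes - n_min
  classes <- c(sprintf("major_%d", seq_len(n_maj)),
               sprintf("minor_%d", seq_len(n_min)))
  d <- dataset_design("imbalance", classes,
                      per_class_train = c(rep(majority_count, n_maj),
                                          rep(minority_count, n_min)),
                      per_class_test = per_class_test,
                      image_size = image_size, easy = easy)
  d$minority <- c(rep(FALSE, n_maj), rep(TRUE, n_min))
  d
}

#' @rdname dataset_design
#' @param n_classes,per_class_train,per_class_test,image_size See
#'   [dataset_design()].
#' @details `easy_design()` is a convenience for the sanity-check regime:
#'   `n_classes` hue-separated variety classes (360/n degrees apart) with
#'   low clutter and noise.
#' @export
easy_design <- function(n_classes = 3, per_class_train = 64,
                        per_class_test = 16, image_size = 32) {
  dataset_design("easy", sprintf("class_%d", seq_len(n_classes)),
                 per_class_train, per_class_test, image_size, easy = TRUE)
}

#' Default per-class rendering specs for a design
#'
#' Classes named after a lesion kind (or `"rotten"`) get a red fruit with
#' that lesion; `"fresh"`/`"normal"` get a clean red fruit; all other
#' (variety) classes are distinguished by evenly spaced hues and cycling
#' eccentricities. Easy designs use reduced clutter and noise.
#'
#' @param design A [dataset_design()].
#' @return A named list of [fruit_image_spec()], one per class.
#' @export
default_class_specs <- function(design) {
  clutter <- if (isTRUE(design$easy)) 0.15 else 0.5
  noise <- if (isTRUE(design$easy)) 0.01 else 0.03
  k <- length(design$classes)
  specs <- vector("list", k)
  names(specs) <- design$classes
  for (i in seq_len(k)) {
    cl <- design$classes[i]
    specs[[i]] <- if (cl %in% setdiff(lesion_kinds(), "none")) {
      fruit_image_spec(base_hue = 10, lesion_kind = cl, lesion_severity = 0.35,
                       background_clutter = clutter, noise_sd = noise)
    } else if (cl == "rotten") {
      fruit_image_spec(base_hue = 10, lesion_kind = "rot",
                       lesion_severity = 0.5,
                       background_clutter = clutter, noise_sd = noise)
    } else if (cl %in% c("fresh", "normal")) {
      fruit_image_spec(base_hue = 10, background_clutter = clutter,
                       noise_sd = noise)
    } else {
      fruit_image_spec(base_hue = (i - 1) * 360 / k,
                       shape_eccentricity = 0.08 + 0.24 * ((i - 1) %% 5) / 4,
                       background_clutter = clutter, noise_sd = noise)
    }
  }
  specs
}

# --- manifests and generation ------------------------------------------------

# Per-image seed derivation: every image gets a stable integer id from its
# (class, split, index) position, and seed = (master_seed + 69069 * id)
# mod 2147483629. Independent of generation order, so any subset of the
# dataset regenerates identically.
image_seed <- function(master_seed, class_index, is_test, index) {
  id <- (class_index - 1) * 2e5 + as.integer(is_test) * 1e5 + index
  (master_seed + 69069 * id) %% 2147483629
}

#' Build the file manifest of a dataset design
#'
#' One row per image that [generate_dataset()] would emit, with its relative
#' path, class label, split and derived per-image seed. Pure bookkeeping: no
#' images are rendered.
#'
#' @param design A [dataset_design()].
#' @param master_seed Integer master seed.
#' @return A data frame with columns `path`, `label`, `split`, `seed`.
#' @export
build_manifest <- function(design, master_seed) {
  rows <- vector("list", 2L * length(design$classes))
  r <- 0L
  for (i in seq_along(design$classes)) {
    cl <- design$classes[i]
    for (split in c("train", "test")) {
      n <- if (split == "train") design$per_class_train[i]
           else design$per_class_test[i]
      if (n == 0L) next
      idx <- seq_len(n)
      r <- r + 1L
      rows[[r]] <- data.frame(
        path = file.path(split, cl, sprintf("img_%05d.png", idx)),
        label = cl, split = split,
        seed = image_seed(master_seed, i, split == "test", idx))
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  rownames(out) <- NULL
  out
}

#' Generate a synthetic labelled image dataset on disk
#'
#' Realises a [dataset_design()] as a directory-per-class tree
#' `out_dir/{train,test}/{class}/img_#####.png` plus a `manifest.csv`
#' (columns `path,label,split,seed`). Output is byte-identical across runs
#' with the same `(design, master_seed)`: PNG is lossless and every image's
#' seed is a stable function of its position (see [build_manifest()]).
#'
#' @param design A [dataset_design()].
#' @param out_dir Output directory; refuses a non-empty existing directory
#'   unless `overwrite = TRUE`.
#' @param master_seed Integer master seed.
#' @param class_specs Named list of [fruit_image_spec()] per class; defaults
#'   to [default_class_specs()].
#' @param overwrite Allow writing into a non-empty directory.
#' @param manifest_only If `TRUE`, return the manifest without rendering or
#'   writing anything (`out_dir` may be `NULL`).
#' @return The manifest data frame, invisibly when files are written.
#' @export
generate_dataset <- function(design, out_dir, master_seed,
                             class_specs = default_class_specs(design),
                             overwrite = FALSE, manifest_only = FALSE) {
  manifest <- build_manifest(design, master_seed)
  if (manifest_only) return(manifest)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("`out_dir` exists and is not empty; pass overwrite = TRUE",
         call. = FALSE)
  for (p in unique(dirname(manifest$path)))
    dir.create(file.path(out_dir, p), recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(nrow(manifest))) {
    img <- render_fruit(class_specs[[manifest$label[k]]], manifest$seed[k],
                        design$image_size)
    png::writePNG(img, file.path(out_dir, manifest$path[k]))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate a dataset design in memory
#'
#' Renders the same images as [generate_dataset()] (identical seeds and
#' pixel values) but returns them as arrays instead of writing PNG files.
#'
#' @inheritParams generate_dataset
#' @return A list with `classes` and per-split lists `train`/`test`, each
#'   holding `images` (list of arrays) and `labels` (integer class indices).
#' @export
synth_data <- function(design, master_seed,
                       class_specs = default_class_specs(design)) {
  manifest <- build_manifest(design, master_seed)
  out <- list(classes = design$classes)
  for (split in c("train", "test")) {
    m <- manifest[manifest$split == split, ]
    images <- vector("list", nrow(m))
    for (k in seq_len(nrow(m)))
      images[[k]] <- render_fruit(class_specs[[m$label[k]]], m$seed[k],
                                  design$image_size)
    out[[split]] <- list(images = images,
                         labels = match(m$label, design$classes))
  }
  out
}

#' Load a directory-per-class image dataset
#'
#' Reads the `split` subtree of a dataset laid out as
#' `data_dir/{train,test}/{class}/*.png` (the [generate_dataset()] layout,
#' also the common layout for photographic collections). Class order is the
#' sorted directory order.
#'
#' @param data_dir Dataset root.
#' @param split `"train"` or `"test"`.
#' @return A list with `images` (list of H x W x 3 arrays), `labels`
#'   (integer indices), and `classes`.
#' @export
load_image_dataset <- function(data_dir, split = c("train", "test")) {
  split <- match.arg(split)
  root <- file.path(data_dir, split)
  if (!dir.exists(root))
    stop("missing split directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class directories in ", root,
                                 call. = FALSE)
  images <- list(); labels <- integer(0)
  for (i in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
      images[[length(images) + 1L]] <- img[, , 1:3, drop = FALSE]
      labels <- c(labels, i)
    }
  }
  list(images = images, labels = labels, classes = classes)
}
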