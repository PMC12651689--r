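# Seeded generators for prompt-conditioned synthetic scenes emulating two
# benchmark regimes: single-lesion "brain-like" images (three lesion
# morphologies) and multi-organ "abdomen-like" images (four disjoint organs
# of differing size, shape and intensity). Shapes are star-convex regions
# with Fourier-perturbed radius functions, rasterized analytically, so every
# sample is reproducible bit-for-bit from its seed.

#' Scene specification for the synthetic generators
#'
#' @param image_size Side length in pixels; must be divisible by 16.
#' @param classes List of class descriptors as produced by [class_spec()].
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   the `[-1, 1]` intensity scale.
#' @param background Length-2 numeric: base intensity and the amplitude of a
#'   smooth low-frequency background variation.
#' @return An object of class `promptseg_scene_spec`.
#' @export
scene_spec <- function(image_size = 128L, classes, noise_sigma = 0.05,
                       background = c(-0.75, 0.08)) {
  image_size <- as.integer(image_size)
  if (image_size %% 16L != 0L) ps_stop("image_size must be divisible by 16")
  nms <- vapply(classes, function(cl) cl$name, "")
  if (anyDuplicated(nms)) ps_stop("class names must be unique")
  for (cl in classes)
    if (cl$size_range[1L] > cl$size_range[2L])
      ps_stop("degenerate size range for class ", cl$name)
  structure(list(image_size = image_size, classes = classes,
                 noise_sigma = noise_sigma, background = background),
            class = "promptseg_scene_spec")
}

#' Class descriptor for synthetic scenes
#'
#' @param name Class label.
#' @param family Shape family: `"irregular_blob"` (low-order Fourier
#'   perturbation of a circle, infiltrative margins), `"smooth_disc"`
#'   (near-circular, encapsulated), `"small_ellipse"` (small compact), or
#'   `"large_lobe"` (large elongated, organ-like).
#' @param intensity Length-2 range of the region's mean intensity.
#' @param size_range Length-2 range of the region radius as a fraction of
#'   the image side.
#' @param x_range Horizontal placement band for the region center, as
#'   fractions of the image width (used to lateralize e.g. left vs right
#'   kidney).
#' @return A plain list descriptor.
#' @export
class_spec <- function(name, family = c("irregular_blob", "smooth_disc",
                                        "small_ellipse", "large_lobe"),
                       intensity, size_range, x_range = c(0.2, 0.8)) {
  family <- match.arg(family)
  list(name = name, family = family, intensity = intensity,
       size_range = size_range, x_range = x_range)
}

#' Default single-lesion ("brain-like") scene specification
#'
#' Three lesion morphologies: irregular infiltrative (glioma-like), smooth
#' encapsulated (meningioma-like) and small compact (pituitary-like), on a
#' dark smoothly varying background.
#' @param image_size Side length in pixels.
#' @param noise_sigma Additive noise level.
#' @return A [scene_spec()].
#' @export
single_lesion_spec <- function(image_size = 128L, noise_sigma = 0.05) {
  scene_spec(image_size, list(
    class_spec("glioma", "irregular_blob", c(0.30, 0.60), c(0.12, 0.20)),
    class_spec("meningioma", "smooth_disc", c(0.45, 0.75), c(0.10, 0.16)),
    class_spec("pituitary", "small_ellipse", c(0.55, 0.85), c(0.05, 0.09))),
    noise_sigma = noise_sigma)
}

#' Default multi-organ ("abdomen-like") scene specification
#'
#' Four disjoint organ-like regions of differing size, shape and intensity:
#' a large lobe (liver-like), a mid-sized disc (spleen-like) and two small
#' ellipses (kidney-like, lateralized to opposite halves of the image).
#' Every scene contains all four classes, so the correct mask cannot be
#' recovered from the image alone — the prompt selects the target.
#' @inheritParams single_lesion_spec
#' @return A [scene_spec()].
#' @export
multi_organ_spec <- function(image_size = 128L, noise_sigma = 0.05) {
  scene_spec(image_size, list(
    class_spec("liver", "large_lobe", c(-0.05, 0.10), c(0.18, 0.24),
               x_range = c(0.32, 0.68)),
    class_spec("spleen", "smooth_disc", c(0.38, 0.50), c(0.10, 0.14),
               x_range = c(0.35, 0.65)),
    class_spec("right_kidney", "small_ellipse", c(0.72, 0.85), c(0.06, 0.09),
               x_range = c(0.62, 0.82)),
    class_spec("left_kidney", "small_ellipse", c(-0.42, -0.30), c(0.06, 0.09),
               x_range = c(0.18, 0.38))),
    noise_sigma = noise_sigma)
}

## ---- shape machinery ----------------------------------------------------

# Radius function r(theta) for one shape draw; returns function + max radius.
draw_shape <- function(family, r0) {
  phase <- stats::runif(4L, 0, 2 * pi)
  switch(family,
    irregular_blob = {
      amp <- stats::runif(4L, 0.05, 0.22) / (1:4)^0.5
      f <- function(th) r0 * (1 + amp[1L] * cos(2 * th + phase[1L]) +
                                amp[2L] * cos(3 * th + phase[2L]) +
                                amp[3L] * cos(4 * th + phase[3L]) +
                                amp[4L] * cos(5 * th + phase[4L]))
      list(rfun = f, rmax = r0 * (1 + sum(amp)))
    },
    smooth_disc = {
      amp <- stats::runif(1L, 0, 0.05)
      f <- function(th) r0 * (1 + amp * cos(2 * th + phase[1L]))
      list(rfun = f, rmax = r0 * (1 + amp))
    },
    small_ellipse = ,
    large_lobe = {
      ecc <- if (family == "large_lobe") stats::runif(1L, 1.3, 1.8)
             else stats::runif(1L, 1.2, 1.6)
      a <- r0 * sqrt(ecc); b <- r0 / sqrt(ecc)
      rot <- phase[1L]
      wob <- if (family == "large_lobe") stats::runif(1L, 0.03, 0.10) else 0
      f <- function(th) {
        t2 <- th - rot
        re <- a * b / sqrt((b * cos(t2))^2 + (a * sin(t2))^2)
        re * (1 + wob * cos(3 * th + phase[2L]))
      }
      list(rfun = f, rmax = a * (1 + wob))
    })
}

rasterize_star <- function(cx, cy, rfun, size) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  dx <- xs - cx
  dy <- ys - cy
  th <- atan2(dy, dx)
  (sqrt(dx * dx + dy * dy) <= rfun(th)) + 0L
}

smooth_background <- function(size, base, amp) {
  ph <- stats::runif(4L, 0, 2 * pi)
  x <- seq(0, 2 * pi, length.out = size)
  base +
    amp * (outer(sin(x + ph[1L]), cos(x + ph[2L])) +
           outer(cos(2 * x + ph[3L]), sin(x + ph[4L]))) / 2
}

# 4-connected binary dilation, repeated `times` (used to keep a small gap
# between placed regions).
dilate4 <- function(m, times = 2L) {
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(times)) {
    m <- m |
      rbind(m[-1L, , drop = FALSE], FALSE) |
      rbind(FALSE, m[-H, , drop = FALSE]) |
      cbind(m[, -1L, drop = FALSE], FALSE) |
      cbind(FALSE, m[, -W, drop = FALSE])
  }
  m
}

# Rejection sampling against the exact occupancy of already-placed regions:
# a candidate is accepted when its rasterized mask does not touch the
# 2-pixel-dilated union of the existing masks and stays off the border.
place_region <- function(cl, size, occupied, max_tries = 200L) {
  blocked <- dilate4(occupied > 0L, 2L)
  for (i in seq_len(max_tries)) {
    r0 <- stats::runif(1L, cl$size_range[1L], cl$size_range[2L]) * size
    shp <- draw_shape(cl$family, r0)
    margin <- min(shp$rmax + 2, size / 2 - 1)
    lo_x <- max(margin, cl$x_range[1L] * size)
    hi_x <- min(size - margin, cl$x_range[2L] * size)
    if (lo_x >= hi_x) next
    cx <- stats::runif(1L, lo_x, hi_x)
    cy <- stats::runif(1L, margin, size - margin)
    mask <- rasterize_star(cx, cy, shp$rfun, size)
    if (!any(mask == 1L)) next
    if (any(mask[c(1L, size), ] == 1L) || any(mask[, c(1L, size)] == 1L)) next
    if (any(mask == 1L & blocked)) next
    return(mask)
  }
  ps_stop("could not place region for class ", cl$name,
          " without overlap; relax its size_range or x_range",
          class = "promptseg_placement_error")
}

finish_image <- function(img, sigma) {
  img <- img + stats::rnorm(length(img), 0, sigma)
  pmin(pmax(img, -1), 1)
}

new_sample <- function(image, masks, labels) {
  structure(list(image = image, masks = masks, labels = labels,
                 prompt = NULL, target = NULL),
            class = "promptseg_sample")
}

## ---- generators ---------------------------------------------------------

#' Generate single-lesion scenes
#'
#' Each sample contains at most one lesion of a uniformly chosen class (a
#' configurable fraction carries no lesion), with intensity contrast over a
#' smooth background and additive Gaussian noise. Reproducible per seed.
#'
#' @param n Number of samples.
#' @param spec A [scene_spec()]; default [single_lesion_spec()].
#' @param seed Integer seed.
#' @param no_lesion_fraction Fraction of lesion-free samples.
#' @return List of `promptseg_sample` objects (fields `image`, `masks`,
#'   `labels`).
#' @export
generate_single_lesion <- function(n, spec = single_lesion_spec(), seed = 1L,
                                   no_lesion_fraction = 0) {
  if (n < 1L) ps_stop("n must be at least 1")
  size <- spec$image_size
  with_seed(seed, lapply(seq_len(n), function(i) {
    img <- smooth_background(size, spec$background[1L], spec$background[2L])
    if (stats::runif(1L) < no_lesion_fraction) {
      return(new_sample(finish_image(img, spec$noise_sigma),
                        stats::setNames(list(), character()), character()))
    }
    cl <- spec$classes[[sample.int(length(spec$classes), 1L)]]
    mask <- place_region(cl, size, matrix(0L, size, size))
    val <- stats::runif(1L, cl$intensity[1L], cl$intensity[2L])
    img[mask == 1L] <- val
    masks <- stats::setNames(list(mask), cl$name)
    new_sample(finish_image(img, spec$noise_sigma), masks, cl$name)
  }))
}

#' Generate multi-organ scenes
#'
#' Every sample contains all classes of the scene specification, placed
#' without overlap by
#' rejection sampling; per-class masks are pairwise disjoint.
#'
#' @inheritParams generate_single_lesion
#' @param spec A [scene_spec()]; default [multi_organ_spec()].
#' @return List of `promptseg_sample` objects.
#' @export
generate_multi_organ <- function(n, spec = multi_organ_spec(), seed = 1L) {
  if (n < 1L) ps_stop("n must be at least 1")
  size <- spec$image_size
  with_seed(seed, lapply(seq_len(n), function(i) {
    img <- smooth_background(size, spec$background[1L], spec$background[2L])
    masks <- NULL
    for (attempt in 1:25) {
      masks <- tryCatch({
        occupied <- matrix(0L, size, size)
        ms <- list()
        for (cl in spec$classes) {
          mask <- place_region(cl, size, occupied)
          occupied <- occupied + mask
          ms[[cl$name]] <- mask
        }
        ms
      }, promptseg_placement_error = function(e) NULL)
      if (!is.null(masks)) break
    }
    if (is.null(masks))
      ps_stop("could not lay out a scene after 25 attempts; the class ",
              "size/x ranges are too crowded for image_size ", size,
              class = "promptseg_placement_error")
    for (cl in spec$classes) {
      val <- stats::runif(1L, cl$intensity[1L], cl$intensity[2L])
      img[masks[[cl$name]] == 1L] <- val
    }
    new_sample(finish_image(img, spec$noise_sigma), masks, names(masks))
  }))
}

#' Attach prompts to generated samples
#'
#' Chooses a target class per sample (uniformly among the classes present),
#' builds a prompt for it from the synonym table, and records the paired
#' target mask as the supervision signal.
#'
#' @param samples List of `promptseg_sample`.
#' @param table A [synonym_table()] covering every class present.
#' @param seed Integer seed.
#' @return The samples with `prompt` and `target` fields set.
#' @export
attach_prompts <- function(samples, table, seed = 1L) {
  all_labels <- unique(unlist(lapply(samples, function(s) s$labels)))
  missing <- setdiff(all_labels, names(table$synonyms))
  if (length(missing))
    ps_stop("no synonym entry for class(es): ", paste(missing, collapse = ", "),
            class = "promptseg_lookup_error")
  with_seed(seed, lapply(samples, function(s) {
    if (!length(s$labels)) return(s)
    s$target <- s$labels[[sample.int(length(s$labels), 1L)]]
    s$prompt <- draw_prompt(s$target, table)
    s
  }))
}

# Supervision mask for a sample's target class (all-zero when no target,
# e.g. lesion-free scenes).
target_mask <- function(sample) {
  if (!is.null(sample$target) && sample$target %in% names(sample$masks))
    sample$masks[[sample$target]]
  else matrix(0L, nrow(sample$image), ncol(sample$image))
}

#' Stable fingerprint of a dataset
#' @param samples List of `promptseg_sample`.
#' @return Character hash.
#' @export
dataset_hash <- function(samples) content_hash(samples)

## ---- on-disk layout -----------------------------------------------------

#' Write a dataset to disk
#'
#' Layout: `images/<id>.png` (intensities quantized from `[-1, 1]` to 8
#' bits), `masks/<class>/<id>.png`, a `manifest.csv` with sample id, classes,
#' target and prompt, and a full-precision `samples.rds` archive that
#' round-trips exactly.
#'
#' @param samples List of `promptseg_sample`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("s%04d", seq_along(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    png::writePNG((s$image + 1) / 2, file.path(dir, "images",
                                               paste0(ids[i], ".png")))
    for (cl in names(s$masks)) {
      d <- file.path(dir, "masks", cl)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_mask(s$masks[[cl]], file.path(d, paste0(ids[i], ".png")))
    }
    data.frame(id = ids[i], classes = paste(s$labels, collapse = ";"),
               target = s$target %||% "", prompt = s$prompt %||% "")
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  saveRDS(samples, file.path(dir, "samples.rds"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Prefers the full-precision archive; falls back to the PNG layout.
#' @param dir Dataset directory.
#' @return List of `promptseg_sample`.
#' @export
read_dataset <- function(dir) {
  rds <- file.path(dir, "samples.rds")
  if (file.exists(rds)) return(readRDS(rds))
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$id[i]
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    labels <- strsplit(man$classes[i], ";")[[1L]]
    masks <- stats::setNames(lapply(labels, function(cl)
      read_mask(file.path(dir, "masks", cl, paste0(id, ".png")))), labels)
    s <- new_sample(img * 2 - 1, masks, labels)
    if (nzchar(man$target[i])) s$target <- man$target[i]
    if (nzchar(man$prompt[i])) s$prompt <- man$prompt[i]
    s
  })
}
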