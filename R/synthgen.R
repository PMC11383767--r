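# Procedural generator of labeled synthetic cotton-leaf pest images.
# Stands in for the unreleased field dataset: every image is a cluttered
# soil/weed background plus a green leaf polygon, with one of three
# class-specific damage motifs painted on top. The motifs follow the field
# symptom descriptions qualitatively (aphid: curled edge + clustered
# white/black dots; leaf mite: yellow-white stipples with a reddening
# patch; mirid: sparse black spots + ragged holes); none of the parameters
# claim biological calibration.

#' The three pest damage class labels, in canonical order
#' @export
pest_labels <- function() c("aphid", "mite", "mirid")

#' Synthetic dataset configuration
#'
#' @param per_class_counts integer triple: images per class in the order
#'   of [pest_labels()]. Defaults to the field study's class sizes.
#' @param image_size square image side in pixels (default 448; downstream
#'   processing resizes to the model input).
#' @param seed integer RNG seed; a fixed seed makes output byte-identical.
#' @param clutter_level background complexity in `[0, 1]`.
#' @param motif_intensity lesion salience in `[0, 1]`; at 0 the motif
#'   layer is empty and classes are indistinguishable in expectation.
#' @return a `synth_config` list.
#' @export
synth_config <- function(per_class_counts = c(1112L, 703L, 890L),
                         image_size = 448L, seed = 7L,
                         clutter_level = 0.6, motif_intensity = 1.0) {
  stopifnot(length(per_class_counts) == 3L, all(per_class_counts >= 0),
            image_size >= 32L, motif_intensity >= 0, motif_intensity <= 1,
            clutter_level >= 0, clutter_level <= 1)
  structure(list(per_class_counts = as.integer(per_class_counts),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 clutter_level = clutter_level,
                 motif_intensity = motif_intensity),
            class = "synth_config")
}

# Deterministic per-image seed below 2^31, derived from (seed, label, index).
image_seed <- function(seed, label_id, index) {
  as.integer((as.numeric(seed) * 100003 + label_id * 10007 + index) %% 2147483647)
}

# Coarse value-noise plane: random lattice upsampled bilinearly.
noise_plane <- function(n, cells) {
  g <- matrix(stats::runif((cells + 1)^2), cells + 1)
  pos <- (seq_len(n) - 0.5) / n * cells + 0.5
  i0 <- pmin(pmax(floor(pos), 1), cells); u <- pos - i0
  a <- g[i0, i0] * outer(1 - u, 1 - u) + g[i0 + 1, i0] * outer(u, 1 - u) +
       g[i0, i0 + 1] * outer(1 - u, u) + g[i0 + 1, i0 + 1] * outer(u, u)
  a
}

# Paint filled circles onto a 0/1 mask (vectorized over the bounding box).
paint_disc <- function(mask, cy, cx, r) {
  n <- nrow(mask)
  ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

#' Render one synthetic leaf image
#'
#' Draws a soil-textured cluttered background with distractor leaf
#' fragments, a perturbed-ellipse green leaf with veins, then the
#' class-specific damage motif. Fully deterministic given
#' `(cfg$seed, label, index)`; the caller's RNG state is left untouched.
#'
#' @param label one of [pest_labels()].
#' @param index image index within the class (seeds the per-image RNG).
#' @param cfg a [synth_config()].
#' @return an [image_array()] of size `cfg$image_size` squared.
#' @export
generate_leaf_image <- function(label, index, cfg = synth_config()) {
  lid <- match(label, pest_labels())
  if (is.na(lid)) stop("generate_leaf_image: unknown label '", label, "'")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(image_seed(cfg$seed, lid, index))

  n <- cfg$image_size
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)

  # --- background: brownish soil with coarse+fine texture ---
  soil <- noise_plane(n, 8) * 0.6 + noise_plane(n, 32) * 0.4
  r_bg <- 110 + 70 * soil + stats::rnorm(1, 0, 6)
  g_bg <- 85 + 55 * soil + stats::rnorm(1, 0, 6)
  b_bg <- 60 + 40 * soil + stats::rnorm(1, 0, 6)

  # distractor weed/leaf fragments in the clutter layer
  n_frag <- round(cfg$clutter_level * 6)
  if (n_frag > 0) {
    for (i in seq_len(n_frag)) {
      cy <- stats::runif(1, 1, n); cx <- stats::runif(1, 1, n)
      rad <- stats::runif(1, 0.04, 0.10) * n
      frag <- ((yy - cy)^2 / stats::runif(1, 0.5, 2) + (xx - cx)^2) <= rad^2
      shade <- stats::runif(1, 0.3, 0.8)
      r_bg[frag] <- r_bg[frag] * (1 - shade) + 70 * shade
      g_bg[frag] <- g_bg[frag] * (1 - shade) + 110 * shade
      b_bg[frag] <- b_bg[frag] * (1 - shade) + 55 * shade
    }
  }

  # --- leaf: perturbed ellipse around the center ---
  cy <- n / 2 + stats::rnorm(1, 0, n * 0.03)
  cx <- n / 2 + stats::rnorm(1, 0, n * 0.03)
  theta <- atan2(yy - cy, xx - cx)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  ph <- stats::runif(3, 0, 2 * pi)
  rad0 <- n * stats::runif(1, 0.32, 0.40)
  radius <- rad0 * (1 + 0.12 * sin(3 * theta + ph[1]) +
                        0.06 * sin(5 * theta + ph[2]) +
                        0.04 * sin(7 * theta + ph[3]))
  leaf <- dist <= radius

  leaf_tex <- noise_plane(n, 16)
  r_lf <- 55 + 30 * leaf_tex
  g_lf <- 125 + 45 * leaf_tex
  b_lf <- 45 + 25 * leaf_tex

  # veins: darken thin sectors radiating from the center
  vein_ang <- stats::runif(1, 0, pi) + (0:4) * (2 * pi / 5)
  vein <- matrix(FALSE, n, n)
  for (a in vein_ang) {
    d_ang <- abs(((theta - a + pi) %% (2 * pi)) - pi)
    vein <- vein | (d_ang < 0.018 & dist < radius * 0.95)
  }
  r_lf[vein] <- r_lf[vein] * 0.75
  g_lf[vein] <- g_lf[vein] * 0.75
  b_lf[vein] <- b_lf[vein] * 0.75

  # --- class motif ---
  mi <- cfg$motif_intensity
  if (mi > 0) {
    if (lid == 1L) {                        # aphid: edge curl + dot clusters
      curl <- dist > radius * 0.82 & leaf
      shade_amt <- 0.45 * mi
      curl_shade <- 1 - shade_amt * (0.5 + 0.5 * sin(6 * theta + ph[1]))
      r_lf[curl] <- r_lf[curl] * curl_shade[curl]
      g_lf[curl] <- g_lf[curl] * curl_shade[curl]
      b_lf[curl] <- b_lf[curl] * curl_shade[curl]
      n_cl <- round(mi * stats::runif(1, 4, 7))
      for (i in seq_len(n_cl)) {
        a0 <- stats::runif(1, 0, 2 * pi); d0 <- stats::runif(1, 0.2, 0.8)
        ccy <- cy + d0 * rad0 * sin(a0); ccx <- cx + d0 * rad0 * cos(a0)
        dark <- stats::runif(1) < 0.5
        m <- matrix(FALSE, n, n)
        for (j in seq_len(round(stats::runif(1, 8, 16)))) {
          m <- paint_disc(m, ccy + stats::rnorm(1, 0, n * 0.015),
                          ccx + stats::rnorm(1, 0, n * 0.015),
                          stats::runif(1, 1, 2) * n / 224)
        }
        m <- m & leaf
        v <- if (dark) 25 else 235
        r_lf[m] <- v; g_lf[m] <- v; b_lf[m] <- v
      }
    } else if (lid == 2L) {                 # mite: stipples + reddening patch
      n_st <- round(mi * stats::runif(1, 120, 200) * (n / 224)^1.2)
      st <- matrix(FALSE, n, n)
      for (i in seq_len(n_st)) {
        a0 <- stats::runif(1, 0, 2 * pi); d0 <- sqrt(stats::runif(1)) * 0.9
        st <- paint_disc(st, cy + d0 * rad0 * sin(a0), cx + d0 * rad0 * cos(a0),
                         stats::runif(1, 0.6, 1.4) * n / 224)
      }
      st <- st & leaf
      r_lf[st] <- 225; g_lf[st] <- 215; b_lf[st] <- 140
      pr <- rad0 * (0.25 + 0.35 * mi)
      a0 <- stats::runif(1, 0, 2 * pi); d0 <- stats::runif(1, 0.1, 0.4)
      pcy <- cy + d0 * rad0 * sin(a0); pcx <- cx + d0 * rad0 * cos(a0)
      pd <- sqrt((yy - pcy)^2 + (xx - pcx)^2)
      w <- pmax(0, 1 - pd / pr) * mi
      w[!leaf] <- 0
      r_lf <- r_lf * (1 - w) + 190 * w
      g_lf <- g_lf * (1 - w) + 75 * w
      b_lf <- b_lf * (1 - w) + 55 * w
    } else {                                # mirid: black spots + ragged holes
      n_sp <- round(mi * stats::runif(1, 6, 12))
      sp <- matrix(FALSE, n, n)
      for (i in seq_len(n_sp)) {
        a0 <- stats::runif(1, 0, 2 * pi); d0 <- sqrt(stats::runif(1)) * 0.85
        sp <- paint_disc(sp, cy + d0 * rad0 * sin(a0), cx + d0 * rad0 * cos(a0),
                         stats::runif(1, 1.5, 3) * n / 224)
      }
      sp <- sp & leaf
      r_lf[sp] <- 20; g_lf[sp] <- 20; b_lf[sp] <- 18
      n_holes <- max(1, round(mi * stats::runif(1, 2, 5)))
      for (i in seq_len(n_holes)) {
        a0 <- stats::runif(1, 0, 2 * pi); d0 <- stats::runif(1, 0.3, 0.85)
        hcy <- cy + d0 * rad0 * sin(a0); hcx <- cx + d0 * rad0 * cos(a0)
        hth <- atan2(yy - hcy, xx - hcx)
        hph <- stats::runif(2, 0, 2 * pi)
        hr <- mi * n * stats::runif(1, 0.03, 0.07) *
          (1 + 0.4 * sin(5 * hth + hph[1]) + 0.25 * sin(9 * hth + hph[2]))
        hole <- sqrt((yy - hcy)^2 + (xx - hcx)^2) <= hr
        leaf <- leaf & !hole
      }
    }
  }

  out <- array(0, c(n, n, 3L))
  out[, , 1] <- ifelse(leaf, r_lf, r_bg)
  out[, , 2] <- ifelse(leaf, g_lf, g_bg)
  out[, , 3] <- ifelse(leaf, b_lf, b_bg)
  image_array(pmin(pmax(round(out), 0), 255))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic labeled dataset on disk
#'
#' Writes class-per-directory PNG images (`<out_dir>/<label>/<id>.png`)
#' plus a manifest CSV, with per-class counts taken from the config.
#'
#' @param cfg a [synth_config()].
#' @param out_dir writable output directory.
#' @param overwrite overwrite an existing manifest (default FALSE).
#' @return the dataset manifest (see [new_manifest()]), invisibly written
#'   to `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(cfg, out_dir, overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("generate_dataset: manifest exists at ", manifest_path,
         " (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- pest_labels()
  rows <- list()
  for (lid in seq_along(labels)) {
    lab <- labels[lid]
    dir.create(file.path(out_dir, lab), showWarnings = FALSE)
    cnt <- cfg$per_class_counts[lid]
    for (i in seq_len(cnt)) {
      id <- sprintf("%s_%05d", lab, i)
      path <- file.path(out_dir, lab, paste0(id, ".png"))
      write_image(generate_leaf_image(lab, i, cfg), path)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, path = path, label = lab, split = "unassigned",
        source_id = id, transform = "original", stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else empty_manifest()
  write_manifest(manifest, manifest_path)
  manifest
}
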