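# Manifest construction, per-class 7:2:1 splitting, and augmentation
# orchestration. A manifest is a plain data.frame with one row per image:
# image_id, path, label, split, source_id, transform. Derived (augmented)
# records always inherit the split of their source, so splitting must
# happen before augmentation (no train/test leakage through transformed
# copies of the same leaf).

manifest_cols <- c("image_id", "path", "label", "split", "source_id", "transform")

empty_manifest <- function() {
  df <- data.frame(image_id = character(), path = character(),
                   label = character(), split = character(),
                   source_id = character(), transform = character(),
                   stringsAsFactors = FALSE)
  df
}

#' Construct a dataset manifest
#'
#' @param image_id character vector of unique image ids.
#' @param path file paths.
#' @param label class labels (see [pest_labels()]).
#' @param split one of `train`, `val`, `test`, `unassigned`.
#' @param source_id id of the original this record derives from (equals
#'   `image_id` for originals).
#' @param transform augmentation op name, or `"original"`.
#' @return a manifest `data.frame`.
#' @export
new_manifest <- function(image_id, path, label, split = "unassigned",
                         source_id = image_id, transform = "original") {
  df <- data.frame(image_id = as.character(image_id), path = as.character(path),
                   label = as.character(label), split = as.character(split),
                   source_id = as.character(source_id),
                   transform = as.character(transform), stringsAsFactors = FALSE)
  validate_manifest(df)
  df
}

validate_manifest <- function(m) {
  if (!all(manifest_cols %in% names(m)))
    stop("manifest must have columns: ", paste(manifest_cols, collapse = ", "))
  bad <- (m$transform == "original") != (m$source_id == m$image_id)
  if (any(bad))
    stop("manifest: source_id must equal image_id iff transform is 'original'")
  ok <- m$split %in% c("train", "val", "test", "unassigned")
  if (!all(ok)) stop("manifest: invalid split value(s)")
  invisible(m)
}

#' Read / write a manifest CSV
#'
#' @param path CSV file path.
#' @return the manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(m[, manifest_cols])
}

#' @rdname read_manifest
#' @param manifest a manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest[, manifest_cols], path, row.names = FALSE)
  invisible(path)
}

#' Import a class-per-directory image tree as a manifest
#'
#' Expects `<root>/<label>/<file>` layout; every image found becomes an
#' unassigned original record.
#'
#' @param root directory whose subdirectories are class labels.
#' @return a manifest `data.frame`.
#' @export
import_image_tree <- function(root) {
  labs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  rows <- list()
  for (lab in labs) {
    files <- sort(list.files(file.path(root, lab),
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
    for (f in files) {
      id <- tools::file_path_sans_ext(f)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, path = file.path(root, lab, f), label = lab,
        split = "unassigned", source_id = id, transform = "original",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_manifest())
  do.call(rbind, rows)
}

#' Split specification
#'
#' @param ratios length-3 numeric `(train, val, test)` proportions summing
#'   to 1; default 7:2:1.
#' @param explicit_counts optional named list mapping each class label to
#'   an integer `(train, val, test)` triple that overrides the ratios for
#'   that class. The triple must sum to the class total. Used to reproduce
#'   a published split exactly when no rounding rule regenerates it.
#' @param seed integer seed for the within-class shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(ratios = c(0.7, 0.2, 0.1), explicit_counts = NULL,
                       seed = 42L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9, all(ratios >= 0))
  structure(list(ratios = ratios, explicit_counts = explicit_counts,
                 seed = as.integer(seed)), class = "split_spec")
}

# Largest-remainder apportionment of n into 3 splits; ties broken toward
# the earlier split (train before val before test).
apportion_counts <- function(n, ratios) {
  exact <- round(n * ratios, 9)   # snap float noise so ties break by rule
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- round(exact - base, 9)
    ord <- order(-frac, seq_along(frac))   # largest remainder, ties -> earlier
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign train/val/test splits per class
#'
#' Every original record is assigned to a split. Per-class counts follow
#' `spec$explicit_counts` when given; otherwise the ratios are apportioned
#' by the largest-remainder rule (ties to the earlier split). Which image
#' lands in which split is a seeded uniform shuffle within each class, so
#' the assignment is deterministic given manifest order and seed.
#'
#' @param manifest manifest of originals, all with split `"unassigned"`.
#' @param spec a [split_spec()].
#' @return the manifest with splits assigned.
#' @export
split_manifest <- function(manifest, spec = split_spec()) {
  validate_manifest(manifest)
  if (nrow(manifest) == 0L) return(manifest)
  if (any(manifest$split != "unassigned"))
    stop("split_manifest: all records must be unassigned")
  if (any(!nzchar(manifest$label)))
    stop("split_manifest: labels must be nonempty")
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(spec$seed)
  out <- manifest
  for (lab in unique(manifest$label)) {
    idx <- which(manifest$label == lab)
    n <- length(idx)
    cnt <- if (!is.null(spec$explicit_counts) && !is.null(spec$explicit_counts[[lab]])) {
      ec <- as.integer(spec$explicit_counts[[lab]])
      if (length(ec) != 3L || sum(ec) != n)
        stop("split_manifest: explicit_counts for '", lab,
             "' must be a triple summing to the class total (", n, ")")
      ec
    } else apportion_counts(n, spec$ratios)
    perm <- sample(idx, n)
    out$split[perm] <- rep(c("train", "val", "test"), times = cnt)
  }
  out
}

#' Expand a split manifest with augmented copies
#'
#' Each original yields one derived record per augmentation op, inheriting
#' its source's label and split. With the default six ops and
#' `keep_original = FALSE`, the output has exactly 6x the input records
#' (the originals remain on disk but are not listed). When `out_dir` is
#' given the transformed images are materialized as PNG files; otherwise
#' only the bookkeeping is produced.
#'
#' @param manifest manifest with all splits assigned.
#' @param ops augmentation ops (default [default_augment_ops()]).
#' @param keep_original also retain the original records (default FALSE).
#' @param out_dir directory for materialized images, or NULL for
#'   bookkeeping only.
#' @return the augmented manifest.
#' @export
augment_manifest <- function(manifest, ops = default_augment_ops(),
                             keep_original = FALSE, out_dir = NULL) {
  validate_manifest(manifest)
  if (any(manifest$split == "unassigned"))
    stop("augment_manifest: split before augmenting (derived records inherit splits)")
  if (nrow(manifest) == 0L)
    return(manifest[manifest$transform != "original" | keep_original, ])
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  op_names <- names(ops)
  pieces <- if (keep_original) list(manifest) else list()
  for (k in seq_along(ops)) {
    d <- manifest
    d$source_id <- manifest$image_id
    d$image_id <- paste0(manifest$image_id, "_", op_names[k])
    d$transform <- op_names[k]
    if (!is.null(out_dir)) {
      d$path <- file.path(out_dir, manifest$label, paste0(d$image_id, ".png"))
    } else {
      d$path <- file.path(dirname(manifest$path), paste0(d$image_id, ".png"))
    }
    pieces[[length(pieces) + 1L]] <- d
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    for (lab in unique(manifest$label))
      dir.create(file.path(out_dir, lab), showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      img <- read_image(manifest$path[i])
      for (k in seq_along(ops)) {
        write_image(apply_augment(img, ops[[k]]),
                    file.path(out_dir, manifest$label[i],
                              paste0(manifest$image_id[i], "_", op_names[k], ".png")))
      }
    }
  }
  validate_manifest(out)
  out
}

#' Per-class x per-split count table with margins
#'
#' Renders the bookkeeping tables of a dataset: rows are classes (plus a
#' Total row), columns are train/val/test counts plus a Total column.
#'
#' @param manifest a manifest `data.frame`.
#' @return integer matrix with dimnames.
#' @export
summarize_manifest <- function(manifest) {
  validate_manifest(manifest)
  labs <- if (all(manifest$label %in% pest_labels()))
    intersect(pest_labels(), unique(manifest$label)) else sort(unique(manifest$label))
  splits <- c("train", "val", "test")
  tab <- matrix(0L, nrow = length(labs) + 1L, ncol = 4L,
                dimnames = list(c(labs, "Total"), c(splits, "Total")))
  for (i in seq_along(labs)) for (j in seq_along(splits))
    tab[i, j] <- sum(manifest$label == labs[i] & manifest$split == splits[j])
  tab[, 4] <- rowSums(tab[, 1:3, drop = FALSE])
  tab[length(labs) + 1L, ] <- colSums(tab[seq_along(labs), , drop = FALSE])
  tab
}
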