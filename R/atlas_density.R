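## Probability-weighted regional density extraction.
##
## A regional gray-matter density is the w-weighted mean of the voxelwise
## modulated gray-matter field g over a cytoarchitectonic probability map w,
## pooled across hemispheres before division:
##   GMD_region = [sum_v g_v w_v(L) + sum_v g_v w_v(R)] /
##                [sum_v   w_v(L) + sum_v   w_v(R)]

#' Construct a probabilistic region map
#'
#' A single-hemisphere cytoarchitectonic probability volume: for each voxel,
#' the probability (0-1) that the voxel belongs to the named region.
#'
#' @param probabilities 3D numeric array with values in \[0, 1\].
#' @param region Region label.
#' @param hemisphere `"left"` or `"right"`.
#' @param affine 4x4 voxel-to-mm affine; defaults to identity with origin 0.
#' @return Object of class `prob_region_map`.
#' @export
prob_region_map <- function(probabilities, region = "region",
                            hemisphere = c("left", "right"),
                            affine = diag(4)) {
  hemisphere <- match.arg(hemisphere)
  if (length(dim(probabilities)) != 3L) stop("probability map must be a 3D volume")
  if (anyNA(probabilities) || any(probabilities < 0)) {
    stop("probability map contains negative or missing values")
  }
  if (max(probabilities) == 0) stop("empty probability map")
  if (max(probabilities) > 1) stop("probabilities exceed 1 after rescaling")
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(
    list(region = region, hemisphere = hemisphere,
         probabilities = probabilities, affine = affine),
    class = "prob_region_map"
  )
}

#' Construct a gray-matter density map
#'
#' A 3D nonnegative modulated gray-matter density volume, with optional
#' subject/session/replicate identifiers.
#'
#' @param values 3D numeric array, all values >= 0.
#' @param affine 4x4 voxel-to-mm affine.
#' @param subject,session_month,replicate Optional identifiers.
#' @return Object of class `gm_map`.
#' @export
gm_map <- function(values, affine = diag(4), subject = NA_character_,
                   session_month = NA_real_, replicate = 1L) {
  if (length(dim(values)) != 3L) stop("gray-matter map must be a 3D volume")
  if (anyNA(values) || any(values < 0)) {
    stop("gray-matter map contains negative or missing values")
  }
  structure(
    list(values = values, affine = affine, subject = subject,
         session_month = session_month, replicate = replicate),
    class = "gm_map"
  )
}

#' Load a cytoarchitectonic probability map from a NIfTI file
#'
#' Reads a 3D NIfTI volume and normalises it to the internal \[0, 1\]
#' probability scale. Atlas distributions store probabilities either as
#' fractions (0-1) or as percentages (0-100); `scale_hint = "auto"` divides
#' by 100 whenever the maximum exceeds 1.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param scale_hint `"auto"` (default), `"unit"` (already 0-1) or
#'   `"percent"` (stored 0-100).
#' @param region,hemisphere Passed to [prob_region_map()].
#' @return A [prob_region_map()] with the file's voxel-to-mm affine.
#' @export
load_probability_map <- function(path, scale_hint = c("auto", "unit", "percent"),
                                 region = NULL, hemisphere = "left") {
  scale_hint <- match.arg(scale_hint)
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vol)) != 3L) stop("expected a 3D volume: ", path)
  if (anyNA(vol) || any(vol < 0)) stop("negative values in probability map: ", path)
  if (max(vol) == 0) stop("empty probability map: ", path)
  if (scale_hint == "percent" || (scale_hint == "auto" && max(vol) > 1)) {
    vol <- vol / 100
  }
  if (is.null(region)) region <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- structure(RNifti::xform(img), class = "matrix")
  prob_region_map(vol, region = region, hemisphere = hemisphere,
                  affine = matrix(as.numeric(aff), 4, 4))
}

#' Load a gray-matter density map from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @inheritParams gm_map
#' @return A [gm_map()].
#' @export
load_gm_map <- function(path, subject = NA_character_, session_month = NA_real_,
                        replicate = 1L) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vol)) != 3L) stop("expected a 3D volume: ", path)
  aff <- RNifti::xform(img)
  gm_map(vol, affine = matrix(as.numeric(aff), 4, 4), subject = subject,
         session_month = session_month, replicate = replicate)
}

#' Translate an atlas map along the y and z axes
#'
#' Applies a rigid translation (in mm) to the map's affine placement,
#' moving the atlas map toward the data. This is the adjustment used to
#' correct probabilistic maps for normalisation into standard MNI space
#' (the conventional correction is +4 mm along y and +5 mm along z). The
#' voxel data are untouched; only the affine origin changes, so the shift is
#' exactly invertible.
#'
#' @param map A [prob_region_map()].
#' @param dy_mm,dz_mm Translation in mm along the y and z world axes.
#' @return The translated map.
#' @export
apply_atlas_translation <- function(map, dy_mm = 4, dz_mm = 5) {
  stopifnot(inherits(map, "prob_region_map"))
  if (!is.finite(dy_mm) || !is.finite(dz_mm)) stop("translations must be finite")
  map$affine[1:3, 4] <- map$affine[1:3, 4] + c(0, dy_mm, dz_mm)
  map
}

## Nearest-neighbour resampling of an atlas map onto the gray-matter grid,
## via the two affines. Off by default: grid mismatch is usually a
## registration bug, not something to paper over.
resample_nearest <- function(map, target_dim, target_affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(target_dim[1]) - 1,
    j = seq_len(target_dim[2]) - 1,
    k = seq_len(target_dim[3]) - 1
  ))
  # target voxel -> mm -> atlas voxel
  mm <- target_affine %*% rbind(t(idx), 1)
  src <- solve(map$affine) %*% mm
  src <- round(t(src[1:3, , drop = FALSE])) + 1
  d <- dim(map$probabilities)
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
    src[, 2] >= 1 & src[, 2] <= d[2] &
    src[, 3] >= 1 & src[, 3] <= d[3]
  out <- numeric(nrow(src))
  out[ok] <- map$probabilities[src[ok, , drop = FALSE]]
  map$probabilities <- array(out, dim = target_dim)
  map$affine <- target_affine
  map
}

#' Extract the standardized regional gray-matter density
#'
#' Multiplies each gray-matter voxel by the probability weighting of the
#' region map, sums bilaterally, and standardizes by the summed weighting:
#' \deqn{GMD = \frac{\sum_v g_v w^L_v + \sum_v g_v w^R_v}
#'                  {\sum_v w^L_v + \sum_v w^R_v}.}
#' By construction the result is a weighted mean of `g` over the region's
#' support, hence bounded by the min and max of `g` there, invariant to
#' rescaling the weights, and linear in `g`.
#'
#' @param gm A [gm_map()].
#' @param left,right [prob_region_map()]s for the two hemispheres. `right`
#'   may be `NULL` for a single-hemisphere extraction.
#' @param combine `"pooled"` (default: numerator and denominator pooled
#'   across hemispheres before division) or `"per_hemisphere"` (a value per
#'   hemisphere).
#' @param resample If `TRUE`, nearest-neighbour resample atlas maps onto the
#'   gray-matter grid using the two affines; the default is a hard error on
#'   any shape mismatch.
#' @return For `"pooled"`: a one-row data frame `region`, `gmd`. For
#'   `"per_hemisphere"`: one row per hemisphere with a `hemisphere` column.
#' @export
extract_regional_density <- function(gm, left, right = NULL,
                                     combine = c("pooled", "per_hemisphere"),
                                     resample = FALSE) {
  combine <- match.arg(combine)
  stopifnot(inherits(gm, "gm_map"), inherits(left, "prob_region_map"))
  maps <- list(left)
  if (!is.null(right)) {
    stopifnot(inherits(right, "prob_region_map"))
    maps <- c(maps, list(right))
  }
  gdim <- dim(gm$values)
  maps <- lapply(maps, function(m) {
    if (!identical(dim(m$probabilities), gdim)) {
      if (!resample) {
        stop("grid mismatch between gray-matter map and atlas map '",
             m$region, "' (", m$hemisphere, "); set resample = TRUE to ",
             "resample the atlas by nearest neighbour")
      }
      m <- resample_nearest(m, gdim, gm$affine)
    }
    m
  })
  region <- left$region
  if (combine == "pooled") {
    num <- 0
    den <- 0
    for (m in maps) {
      num <- num + sum(gm$values * m$probabilities)
      den <- den + sum(m$probabilities)
    }
    if (den == 0) stop("zero total weight for region '", region, "'")
    data.frame(region = region, gmd = num / den, stringsAsFactors = FALSE)
  } else {
    out <- lapply(maps, function(m) {
      den <- sum(m$probabilities)
      if (den == 0) stop("zero total weight for region '", region, "' (",
                         m$hemisphere, ")")
      data.frame(region = region, hemisphere = m$hemisphere,
                 gmd = sum(gm$values * m$probabilities) / den,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}

#' Extract standardized densities for a whole atlas
#'
#' Applies [extract_regional_density()] to every region of an atlas and
#' returns one long-format row per region, in the atlas's stable order.
#'
#' @param gm A [gm_map()].
#' @param atlas Named list; each element a list with components `left` and
#'   (optionally) `right`, both [prob_region_map()]s.
#' @param ... Passed to [extract_regional_density()].
#' @return Data frame with columns `subject`, `session_month`, `replicate`,
#'   `region`, `gmd`.
#' @export
extract_all_regions <- function(gm, atlas, ...) {
  if (length(atlas) == 0L) stop("atlas is empty")
  if (is.null(names(atlas))) names(atlas) <- paste0("region", seq_along(atlas))
  rows <- lapply(names(atlas), function(nm) {
    pair <- atlas[[nm]]
    val <- tryCatch(
      extract_regional_density(gm, pair$left, pair$right, ...),
      error = function(e) stop("region '", nm, "': ", conditionMessage(e),
                               call. = FALSE)
    )
    data.frame(subject = gm$subject, session_month = gm$session_month,
               replicate = gm$replicate, region = nm, gmd = val$gmd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
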