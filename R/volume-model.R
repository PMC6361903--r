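#' SUV volume container
#'
#' Wraps a 3-D grid of body-weight standardized uptake values (SUV) together
#' with its voxel spacing. The axis convention is `(slice, row, col)`: the
#' first array dimension indexes axial slices (the 2-D planes on which
#' slice-wise texture matrices are computed), the second and third the
#' in-plane rows and columns. Spacing is given as `(dx, dy, dz)` in mm,
#' where `dx` is the in-plane column spacing, `dy` the in-plane row spacing
#' and `dz` the slice spacing.
#'
#' @param voxels numeric 3-D array of finite, non-negative SUV values.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in mm, all positive.
#' @return An object of class `suv_volume`: a list with elements `voxels`,
#'   `spacing` and `voxel_volume_cc` (`dx*dy*dz / 1000`).
#' @examples
#' vol <- suv_volume(array(1, c(4, 4, 4)), spacing = c(10, 10, 10))
#' vol$voxel_volume_cc  # 1 cc per voxel
#' @export
suv_volume <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("SUV grid contains ", sum(!is.finite(voxels)), " non-finite voxel(s)")
  n_neg <- sum(voxels < 0)
  if (n_neg > 0)
    stop("SUV grid contains ", n_neg, " negative voxel(s); SUV must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three positive values (dx, dy, dz) in mm")
  structure(
    list(voxels = voxels, spacing = spacing,
         voxel_volume_cc = prod(spacing) / 1000),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<suv_volume> %d x %d x %d (slice x row x col), spacing %s mm, voxel %.4g cc\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              x$voxel_volume_cc))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Anatomic-site mask
#'
#' A boolean grid congruent with its SUV volume, marking the hand-contoured
#' extent of one anatomic site (mediastinum, left neck, ...). A mask may
#' contain several disconnected components; all of them are pooled into one
#' feature set for the site.
#'
#' @param voxels logical (or 0/1 numeric) 3-D array.
#' @param site_label character scalar naming the site.
#' @return An object of class `site_mask`.
#' @export
site_mask <- function(voxels, site_label = "mediastinum") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3-D array")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("numeric mask must contain only 0/1 values")
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask must be logical or 0/1 numeric")
  if (anyNA(voxels)) stop("mask contains NA")
  structure(list(site_label = as.character(site_label)[1], voxels = voxels),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat(sprintf("<site_mask> '%s': %d of %d voxels\n",
              x$site_label, sum(x$voxels), length(x$voxels)))
  invisible(x)
}

#' Validate a volume/mask pair
#'
#' Checks that a mask is shape-congruent with its SUV volume and returns the
#' pair. An all-false mask is accepted (downstream segmentation then yields
#' an empty metabolic volume, MTV 0).
#'
#' @param vol an [suv_volume].
#' @param mask a [site_mask].
#' @return `list(vol = vol, mask = mask)` invisibly usable downstream.
#' @export
attach_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "site_mask"))
  dv <- dim(vol$voxels); dm <- dim(mask$voxels)
  if (!identical(dv, dm))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dm, collapse = "x"), paste(dv, collapse = "x")))
  list(vol = vol, mask = mask)
}

# ---- on-disk formats --------------------------------------------------------

# Internal (slice,row,col) <-> NIfTI (x=col, y=row, z=slice) axis shuffle.
.to_nifti_order <- function(a) aperm(a, c(3L, 2L, 1L))
.from_nifti_order <- function(a) aperm(a, c(3L, 2L, 1L))

#' Save an SUV volume or mask
#'
#' Two formats are supported, chosen by extension: NIfTI (`.nii` / `.nii.gz`)
#' for interoperability, and a plain-text array format (`.suvtxt`) whose
#' round-trip is bit-exact, used for fixtures. Masks are stored as 0/1
#' volumes.
#'
#' @param x an [suv_volume] or [site_mask]. A mask needs `spacing` supplied.
#' @param path output path ending in `.nii`, `.nii.gz` or `.suvtxt`.
#' @param spacing spacing override (required when saving a bare mask).
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "site_mask")) {
    if (is.null(spacing)) stop("saving a mask requires `spacing`")
    arr <- array(as.double(x$voxels), dim(x$voxels))
  } else if (inherits(x, "suv_volume")) {
    arr <- x$voxels
    spacing <- x$spacing
  } else stop("`x` must be an suv_volume or site_mask")

  if (grepl("\\.suvtxt$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste("dim", paste(dim(arr), collapse = " ")),
                 paste("spacing", paste(sprintf("%.17g", spacing), collapse = " "))),
               con)
    writeLines(sprintf("%.17g", as.vector(arr)), con)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(.to_nifti_order(arr))
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else stop("unsupported extension (use .nii, .nii.gz or .suvtxt): ", path)
  invisible(path)
}

#' Load an SUV volume
#'
#' Reads a volume saved by [save_volume()] and validates it: spacing must be
#' present and positive, and no voxel may be negative (the loader reports the
#' offending voxel count).
#'
#' @param path file ending in `.nii`, `.nii.gz` or `.suvtxt`.
#' @return An [suv_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.suvtxt$", path)) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1:2], " ")
    if (hdr[[1]][1] != "dim" || hdr[[2]][1] != "spacing")
      stop("malformed .suvtxt header in ", path)
    d <- as.integer(hdr[[1]][-1])
    sp <- as.numeric(hdr[[2]][-1])
    vals <- as.numeric(lines[-(1:2)])
    if (length(vals) != prod(d)) stop("value count does not match dim in ", path)
    suv_volume(array(vals, d), sp)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    if (anyNA(sp) || any(sp <= 0))
      stop("NIfTI header carries missing/non-positive spacing: ",
           paste(sp, collapse = ", "))
    suv_volume(.from_nifti_order(as.array(img)), sp)
  } else stop("unsupported extension: ", path)
}

#' Load a site mask from disk
#'
#' Masks are stored as 0/1 volumes in either supported format.
#'
#' @param path file path.
#' @param site_label site name to attach.
#' @return A [site_mask].
#' @export
load_mask <- function(path, site_label = "mediastinum") {
  vol <- load_volume(path)
  site_mask(vol$voxels, site_label = site_label)
}

# ---- cohort tables ----------------------------------------------------------

#' Assemble a patient record
#'
#' Bundles one patient's imaging sites with their clinical outcome flags.
#' Refractory disease (persistence during or within 90 days of upfront
#' therapy) and relapse (progression later than that window) are mutually
#' exclusive by definition, and death from Hodgkin lymphoma implies one of
#' the two.
#'
#' @param patient_id identifier.
#' @param sites list of `list(vol = suv_volume, mask = site_mask)` pairs.
#' @param refractory,relapsed,death_from_hl logical outcome flags.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, sites,
                           refractory = FALSE, relapsed = FALSE,
                           death_from_hl = FALSE) {
  if (refractory && relapsed)
    stop("refractory and relapsed are mutually exclusive")
  if (death_from_hl && !(refractory || relapsed))
    stop("death_from_hl requires refractory or relapsed disease")
  for (s in sites) attach_mask(s$vol, s$mask)
  structure(list(patient_id = as.character(patient_id), sites = sites,
                 refractory = isTRUE(refractory), relapsed = isTRUE(relapsed),
                 death_from_hl = isTRUE(death_from_hl)),
            class = "patient_record")
}

#' Read / write the cohort outcome table
#'
#' The outcome table is a CSV with columns `patient_id`, `site_label`,
#' `refractory`, `relapsed`, `death_from_hl` (one row per analyzable site).
#'
#' @param x data.frame with those columns.
#' @param path CSV path.
#' @return `read_outcomes` returns the data.frame with logical flags.
#' @export
write_outcomes <- function(x, path) {
  need <- c("patient_id", "site_label", "refractory", "relapsed", "death_from_hl")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(x[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("refractory", "relapsed", "death_from_hl"))
    x[[f]] <- as.logical(x[[f]])
  bad <- x$refractory & x$relapsed
  if (any(bad))
    stop("rows with both refractory and relapsed set: ",
         paste(x$patient_id[bad], collapse = ", "))
  x
}
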