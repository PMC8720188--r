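# Volume censoring, tissue masking, nuisance cleaning and band-pass
# filtering: the path from a raw run to clean regional time series.

#' Construct a motion trace
#'
#' Per-volume head-motion summaries used for volume censoring: framewise
#' displacement (FD, mm) and DVARS (spatial standard deviation of the
#' volume-to-volume BOLD difference, in percent of the run-mean intensity).
#' The first volume has no predecessor, so its FD and DVARS are defined as 0.
#'
#' @param fd numeric vector of framewise displacements (mm), non-negative.
#' @param dvars numeric vector of DVARS values (percent), non-negative;
#'   same length as `fd`.
#' @return An object of class `motion_trace` with fields `fd`, `dvars`
#'   and `n_volumes`.
#' @export
motion_trace <- function(fd, dvars) {
  fd <- as.numeric(fd)
  dvars <- as.numeric(dvars)
  if (length(fd) == 0L) stop("motion trace is empty")
  if (length(fd) != length(dvars))
    stop("fd and dvars must have the same length")
  if (anyNA(fd) || anyNA(dvars)) stop("fd/dvars contain NA")
  if (any(fd < 0) || any(dvars < 0)) stop("fd and dvars must be non-negative")
  if (fd[1L] != 0 || dvars[1L] != 0)
    stop("first volume must have fd = 0 and dvars = 0 (no predecessor)")
  structure(list(fd = fd, dvars = dvars, n_volumes = length(fd)),
            class = "motion_trace")
}

#' Compute framewise displacement from rigid-body realignment parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (radians) converted to arc length
#' on a sphere of radius `radius` mm. The first volume gets FD = 0.
#'
#' @param params volumes x 6 matrix: three translations (mm) followed by
#'   three rotations (radians).
#' @param radius head-radius approximation in mm (default 50).
#' @return numeric vector of FD values, one per volume.
#' @export
framewise_displacement <- function(params, radius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("expected 6 rigid-body parameters per volume")
  scaled <- params
  scaled[, 4:6] <- scaled[, 4:6] * radius
  d <- abs(diff(scaled))
  c(0, rowSums(d))
}

#' Censor motion-corrupted volumes (scrubbing)
#'
#' Flags every volume whose FD or DVARS exceeds its threshold and removes it
#' together with the `before` preceding and `after` following volumes
#' (windows clipped at run boundaries; windows from multiple triggers are
#' unioned). A subject is retained for analysis only when at least
#' `min_retained` of the run survives.
#'
#' @param motion a [motion_trace()].
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param dvars_thresh DVARS threshold in percent (default 3).
#' @param before,after guard-window extent around each trigger (defaults 1
#'   and 2 volumes).
#' @param min_retained minimum retained fraction for subject inclusion
#'   (default 0.5).
#' @return An object of class `censor_result`: `keep_mask` (logical per
#'   volume), `retained_fraction`, `include_subject`, `n_censored` and
#'   `triggers` (indices that exceeded a threshold).
#' @export
censor_volumes <- function(motion, fd_thresh = 0.5, dvars_thresh = 3,
                           before = 1L, after = 2L, min_retained = 0.5) {
  if (!inherits(motion, "motion_trace"))
    motion <- motion_trace(motion$fd, motion$dvars)
  n <- motion$n_volumes
  triggers <- which(motion$fd > fd_thresh | motion$dvars > dvars_thresh)
  keep <- rep(TRUE, n)
  for (t in triggers) {
    lo <- max(1L, t - before)
    hi <- min(n, t + after)
    keep[lo:hi] <- FALSE
  }
  frac <- mean(keep)
  structure(list(keep_mask = keep,
                 retained_fraction = frac,
                 include_subject = frac >= min_retained,
                 n_censored = sum(!keep),
                 triggers = triggers),
            class = "censor_result")
}

#' Compute DVARS from a volume series
#'
#' DVARS at volume t is the spatial standard deviation of the voxelwise
#' difference between volumes t and t-1 inside the brain mask, expressed as
#' a percent of the run-mean within-mask intensity. The first element is 0.
#'
#' @param volumes a 4D array (x, y, z, time) or a voxels x time matrix.
#' @param mask logical array/vector selecting brain voxels; `NULL` uses all.
#' @return numeric vector of percent DVARS, one per volume.
#' @export
compute_dvars <- function(volumes, mask = NULL) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    d <- dim(volumes)
    volumes <- matrix(volumes, nrow = prod(d[1:3]), ncol = d[4L])
  }
  volumes <- as.matrix(volumes)
  if (ncol(volumes) < 2L) stop("need at least 2 volumes")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (!any(mask)) stop("brain mask is empty")
    volumes <- volumes[mask, , drop = FALSE]
  }
  ref <- mean(volumes)
  if (ref == 0) stop("run-mean intensity is zero; percent DVARS undefined")
  sds <- apply(volumes[, -1L, drop = FALSE] -
                 volumes[, -ncol(volumes), drop = FALSE], 2L, stats::sd)
  c(0, sds / ref * 100)
}

#' Mask an atlas label image by grey-matter probability
#'
#' A voxel keeps its atlas label only when its grey-matter probability is at
#' least as large as both its white-matter and CSF probabilities; a voxel
#' with P(GM) strictly below either is reassigned to background (0). Ties
#' retain the voxel.
#'
#' @param labels integer array of atlas labels (0 = background).
#' @param p_gm,p_wm,p_csf tissue-probability arrays in \[0, 1\], same shape
#'   as `labels`.
#' @return the label array with non-grey-matter voxels set to 0.
#' @export
mask_atlas_by_gm <- function(labels, p_gm, p_wm, p_csf) {
  if (!all(length(labels) == c(length(p_gm), length(p_wm), length(p_csf))))
    stop("labels and tissue probability maps must have identical shapes")
  rng <- range(p_gm, p_wm, p_csf)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("tissue probabilities must lie in [0, 1]")
  out <- labels
  out[p_gm < p_wm | p_gm < p_csf] <- 0L
  out
}

#' Construct a regional run
#'
#' One run's regions x volumes signal matrix with its sampling interval and
#' a per-volume retention mask.
#'
#' @param signals regions x volumes numeric matrix.
#' @param tr repetition time in seconds.
#' @param region_ids region labels (defaults to row names or 1..R).
#' @param keep_mask logical per volume; defaults to all retained.
#' @return An object of class `regional_run`.
#' @export
regional_run <- function(signals, tr, region_ids = NULL, keep_mask = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  if (tr <= 0) stop("tr must be positive (seconds)")
  if (is.null(region_ids)) {
    region_ids <- rownames(signals)
    if (is.null(region_ids)) region_ids <- seq_len(nrow(signals))
  }
  if (length(region_ids) != nrow(signals))
    stop("region_ids must match the number of rows")
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, ncol(signals))
  if (length(keep_mask) != ncol(signals))
    stop("keep_mask must match the number of volumes")
  structure(list(signals = signals, tr = tr,
                 region_ids = region_ids, keep_mask = as.logical(keep_mask)),
            class = "regional_run")
}

#' @export
print.regional_run <- function(x, ...) {
  cat(sprintf("<regional_run> %d regions x %d volumes, TR = %g s (%d retained)\n",
              nrow(x$signals), ncol(x$signals), x$tr, sum(x$keep_mask)))
  invisible(x)
}

#' Average voxel series into regional series
#'
#' @param voxels voxels x volumes matrix.
#' @param labels per-voxel atlas label (0 = background), typically after
#'   [mask_atlas_by_gm()].
#' @param region_ids regions to extract (default: sorted non-zero labels).
#' @return regions x volumes matrix of mean series; a region with no
#'   retained voxels yields a row of `NA` with a warning.
#' @export
regional_average <- function(voxels, labels, region_ids = NULL) {
  voxels <- as.matrix(voxels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(voxels))
    stop("one label per voxel row required")
  if (is.null(region_ids)) region_ids <- sort(unique(labels[labels != 0L]))
  out <- matrix(NA_real_, length(region_ids), ncol(voxels),
                dimnames = list(region_ids, NULL))
  empty <- character()
  for (k in seq_along(region_ids)) {
    idx <- which(labels == region_ids[k])
    if (length(idx) == 0L) { empty <- c(empty, as.character(region_ids[k])); next }
    out[k, ] <- colMeans(voxels[idx, , drop = FALSE])
  }
  if (length(empty))
    warning("regions with zero retained voxels set to missing: ",
            paste(empty, collapse = ", "))
  out
}

#' Drop censored volumes and regress out nuisance signals
#'
#' Censored volumes are removed first (the retained series is concatenated;
#' no interpolation). Each regional series is then residualised by ordinary
#' least squares against a joint design of intercept, linear trend and the
#' supplied nuisance regressors (e.g. CSF, WM and motion series).
#'
#' @param run a [regional_run()].
#' @param nuisance volumes x k matrix of nuisance regressors aligned with
#'   the *original* volumes (censored rows are dropped internally), or
#'   `NULL` for detrending only.
#' @param censor optional [censor_volumes()] result; defaults to the run's
#'   own `keep_mask`.
#' @return a `regional_run` containing only retained volumes, cleaned.
#' @export
clean_regional_series <- function(run, nuisance = NULL, censor = NULL) {
  stopifnot(inherits(run, "regional_run"))
  keep <- if (is.null(censor)) run$keep_mask else censor$keep_mask
  if (length(keep) != ncol(run$signals))
    stop("censor mask length does not match the number of volumes")
  x <- run$signals[, keep, drop = FALSE]
  nt <- ncol(x)
  if (nt < 3L) stop("fewer than 3 retained volumes; cannot clean")
  design <- cbind(intercept = 1, trend = seq_len(nt))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) == length(keep)) {
      nuisance <- nuisance[keep, , drop = FALSE]
    } else if (nrow(nuisance) != nt) {
      stop("nuisance rows must align with original or retained volumes")
    }
    design <- cbind(design, nuisance)
  }
  qr_d <- qr(design)
  resid <- t(qr.resid(qr_d, t(x)))
  regional_run(resid, tr = run$tr, region_ids = run$region_ids)
}

#' Band-pass filter regional series
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order `order`,
#' applied to the retained, concatenated series of each region. The default
#' 0.01-0.1 Hz band isolates the low-frequency fluctuations carrying
#' resting-state connectivity.
#'
#' @param run a [regional_run()].
#' @param low,high band edges in Hz (defaults 0.01 and 0.1); must satisfy
#'   `0 < low < high < 1/(2 * tr)`.
#' @param order Butterworth order (default 4) before the forward-backward
#'   pass doubles the effective attenuation.
#' @return a filtered `regional_run`.
#' @export
bandpass <- function(run, low = 0.01, high = 0.1, order = 4L) {
  stopifnot(inherits(run, "regional_run"))
  fs <- 1 / run$tr
  nyq <- fs / 2
  if (low <= 0 || high >= nyq || low >= high)
    stop(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz (Nyquist)",
                 low, high, nyq))
  x <- run$signals[, run$keep_mask, drop = FALSE]
  n <- ncol(x)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # odd-reflection padding of about one low-cutoff period per side tames
  # the start-up transients of the forward-backward pass
  npad <- min(n - 1L, as.integer(ceiling(fs / low)))
  filt <- t(apply(x, 1L, function(s) {
    s <- s - mean(s)
    head_pad <- 2 * s[1L] - s[(npad + 1L):2L]
    tail_pad <- 2 * s[n] - s[(n - 1L):(n - npad)]
    out <- signal::filtfilt(bf, c(head_pad, s, tail_pad))
    out[(npad + 1L):(npad + n)]
  }))
  regional_run(filt, tr = run$tr, region_ids = run$region_ids)
}

#' Read a NIfTI volume as a plain array
#'
#' Thin wrapper for the voxel-level entry points ([compute_dvars()],
#' [mask_atlas_by_gm()], [regional_average()]); requires the RNifti package.
#'
#' @param path NIfTI file path.
#' @return a numeric array.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  as.array(RNifti::readNifti(path))
}
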