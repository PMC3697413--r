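#' Read a 3D image volume
#'
#' Reads NIfTI (.nii, .nii.gz) or MetaImage (.mha, single-file uncompressed)
#' volumes into an [Image3D-class]. Only 3D scalar data are accepted.
#'
#' @param path file path.
#' @return An [Image3D-class].
#' @export
readImage3D <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- arr[, , , 1, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("format error: expected 3D scalar data, got ",
           length(dim(arr)), "D (property: dim)")
    spacing <- RNifti::pixdim(nii)[1:3]
    xf <- RNifti::xform(nii)
    origin <- as.numeric(xf[1:3, 4])
    # we store axis-aligned voxel-center coordinates; RNifti xforms follow
    # the NIfTI RAS convention with possibly negated columns -- for the
    # axis-aligned volumes this package writes, the translation column is
    # the first voxel center up to axis sign, which we take as magnitudes
    Image3D(arr, spacing = abs(spacing), origin = origin)
  } else if (ext == ".mha") {
    readMetaImage(path)
  } else {
    stop("format error: unsupported image format (property: extension): ",
         path)
  }
}

#' Write a 3D image volume
#'
#' @param img an [Image3D-class].
#' @param path destination path (.nii, .nii.gz or .mha).
#' @return Invisibly, \code{path}.
#' @export
writeImage3D <- function(img, path) {
  stopifnot(is(img, "Image3D"))
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::asNifti(img@voxels)
    RNifti::pixdim(nii) <- img@spacing
    # axis-aligned sform with the voxel-center origin as translation
    xf <- diag(c(img@spacing, 1))
    xf[1:3, 4] <- img@origin
    RNifti::qform(nii) <- structure(xf, code = 2L)
    RNifti::writeNifti(nii, path)
  } else if (ext == ".mha") {
    writeMetaImage(img, path)
  } else {
    stop("format error: unsupported image format (property: extension): ",
         path)
  }
  invisible(path)
}

# MetaImage (.mha) local single-file format: ASCII key = value header
# terminated by ElementDataFile = LOCAL, followed by the raw voxel block.
readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format error: truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("format error: malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop("format error: expected 3D scalar data (property: NDims = ",
         hdr[["NDims"]], ")")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  vox <- switch(type,
    "MET_DOUBLE" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "MET_FLOAT" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "MET_SHORT" = as.numeric(readBin(con, "integer", n = n, size = 2,
                                     endian = "little")),
    stop("format error: unsupported ElementType (property: ElementType = ",
         type, ")"))
  if (length(vox) != n) stop("format error: truncated MetaImage data block")
  Image3D(array(vox, dims), spacing = spacing, origin = origin)
}

writeMetaImage <- function(img, path) {
  d <- dim(img@voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(img@origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(img@spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.numeric(img@voxels), con, size = 8, endian = "little")
  invisible(path)
}

# Locate points in the voxel grid; returns list of base indices and
# fractional coordinates, with an inside mask (cells fully in the grid).
.locate <- function(img, points) {
  d <- dim(img@voxels)
  # continuous voxel coordinate (1-based at voxel centers)
  g <- sweep(sweep(points, 2, img@origin, "-"), 2, img@spacing, "/") + 1
  i0 <- floor(g)
  f <- g - i0
  inside <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
            i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
            i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  # boundary band: clamp points that sit exactly on the upper faces
  on_hi <- abs(g[, 1] - d[1]) < 1e-9 | abs(g[, 2] - d[2]) < 1e-9 |
           abs(g[, 3] - d[3]) < 1e-9
  fix <- on_hi & !inside &
    g[, 1] >= 1 - 1e-9 & g[, 1] <= d[1] + 1e-9 &
    g[, 2] >= 1 - 1e-9 & g[, 2] <= d[2] + 1e-9 &
    g[, 3] >= 1 - 1e-9 & g[, 3] <= d[3] + 1e-9
  if (any(fix)) {
    for (ax in 1:3) {
      hi <- fix & i0[, ax] >= d[ax]
      i0[hi, ax] <- d[ax] - 1
      f[hi, ax] <- 1
      lo <- fix & i0[, ax] < 1
      i0[lo, ax] <- 1
      f[lo, ax] <- 0
    }
    inside <- inside | fix
  }
  list(i0 = i0, f = f, inside = inside, dims = d)
}

# --- cubic B-spline interpolation machinery ---------------------------------
# Unser's recursive prefilter (pole sqrt(3) - 2, gain 6), mirror boundaries,
# run along the first dimension of a matrix (vectorized over columns).
.bsplinePrefilterDim1 <- function(M) {
  z <- sqrt(3) - 2
  n <- nrow(M)
  M <- M * 6
  # causal init over the mirror-extended signal (period 2n - 2), so short
  # axes are handled exactly
  K <- ceiling(log(1e-14) / log(abs(z)))
  idx <- if (n > 1) rep_len(c(1:n, (n - 1):2), K) else rep(1L, K)
  cp <- M
  cp[1, ] <- as.numeric(z^(0:(K - 1)) %*% M[idx, , drop = FALSE])
  for (i in 2:n) cp[i, ] <- M[i, ] + z * cp[i - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

# B-spline coefficient volume, mirror-padded by 2 voxels per axis.
.splineCoeffs <- function(img) {
  v <- img@voxels
  d <- dim(v)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(v, perm), nrow = d[ax])
    m <- .bsplinePrefilterDim1(m)
    v <- aperm(array(m, dim(v)[perm]), order(perm))
  }
  mir <- function(n) c(3, 2, 1:n, n - 1, n - 2) # mirror about end samples
  cf <- v[mir(d[1]), mir(d[2]), mir(d[3])]
  list(coeff = cf, spacing = img@spacing, origin = img@origin, dims = d)
}

.bsplineBasis <- function(t, deriv = 0L) {
  if (deriv == 0L) {
    cbind((1 - t)^3 / 6,
          (3 * t^3 - 6 * t^2 + 4) / 6,
          (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
          t^3 / 6)
  } else if (deriv == 1L) {
    cbind(-(1 - t)^2 / 2,
          (3 * t^2 - 4 * t) / 2,
          (-3 * t^2 + 2 * t + 1) / 2,
          t^2 / 2)
  } else {
    cbind(1 - t, 3 * t - 2, 1 - 3 * t, t)
  }
}

# Sample the cubic interpolant at world points; same inside/outside policy
# as the trilinear sampler. what = "value" | "gradient" | "hessian"
# (hessian: n x 6 columns xx, yy, zz, xy, xz, yz).
.splineSample <- function(sp, points, gradient = FALSE,
                          what = if (gradient) "gradient" else "value") {
  d <- sp$dims
  g <- sweep(sweep(points, 2, sp$origin, "-"), 2, sp$spacing, "/") + 1
  i0 <- floor(g)
  t <- g - i0
  inside <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
            i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
            i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  ncols <- switch(what, value = 1L, gradient = 3L, hessian = 6L)
  out <- if (ncols == 1L) numeric(nrow(points))
         else matrix(0, nrow(points), ncols)
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  t <- t[inside, , drop = FALSE]
  B <- lapply(1:3, function(ax) lapply(0:2, function(dv)
    .bsplineBasis(t[, ax], dv)))
  cf <- sp$coeff
  pd <- dim(cf)
  acc <- function(dx, dy, dz) {
    wx <- B[[1]][[dx + 1L]]; wy <- B[[2]][[dy + 1L]]; wz <- B[[3]][[dz + 1L]]
    s <- 0
    for (a in 1:4) for (b in 1:4) for (c in 1:4) {
      # padded coords: unpadded index i + 2; taps at i0 - 1 + (a - 1) etc.
      idx <- (i0[, 1] + a) + pd[1] * (i0[, 2] + b - 1) +
             pd[1] * pd[2] * (i0[, 3] + c - 1)
      s <- s + cf[idx] * wx[, a] * wy[, b] * wz[, c]
    }
    s
  }
  sp1 <- sp$spacing
  if (what == "value") {
    out[inside] <- acc(0, 0, 0)
  } else if (what == "gradient") {
    out[inside, 1] <- acc(1, 0, 0) / sp1[1]
    out[inside, 2] <- acc(0, 1, 0) / sp1[2]
    out[inside, 3] <- acc(0, 0, 1) / sp1[3]
  } else {
    out[inside, 1] <- acc(2, 0, 0) / sp1[1]^2
    out[inside, 2] <- acc(0, 2, 0) / sp1[2]^2
    out[inside, 3] <- acc(0, 0, 2) / sp1[3]^2
    out[inside, 4] <- acc(1, 1, 0) / (sp1[1] * sp1[2])
    out[inside, 5] <- acc(1, 0, 1) / (sp1[1] * sp1[3])
    out[inside, 6] <- acc(0, 1, 1) / (sp1[2] * sp1[3])
  }
  out
}

#' Sample image intensities at world coordinates
#'
#' Interpolates the voxel grid at arbitrary world points (mm): trilinear by
#' default, or an interpolating C2 cubic B-spline (Unser prefilter, mirror
#' boundaries), which the registration functional uses so that its forces
#' are continuously differentiable. Points outside the grid return 0
#' (air/blood background policy).
#'
#' @param img an [Image3D-class].
#' @param points n x 3 matrix of world coordinates, mm.
#' @param interp "linear" or "cubic".
#' @return numeric vector of n intensities.
#' @export
sampleIntensity <- function(img, points, interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  points <- matrix(as.numeric(points), ncol = 3)
  if (interp == "cubic")
    return(.splineSample(.splineCoeffs(img), points))
  loc <- .locate(img, points)
  out <- numeric(nrow(points))
  if (!any(loc$inside)) return(out)
  i0 <- loc$i0[loc$inside, , drop = FALSE]
  f <- loc$f[loc$inside, , drop = FALSE]
  d <- loc$dims
  v <- img@voxels
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * (i0[, 2] + dy - 1) + d[1] * d[2] * (i0[, 3] + dz - 1)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  val <-
    v[idx(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(1, 0, 0)] * fx       * (1 - fy) * (1 - fz) +
    v[idx(0, 1, 0)] * (1 - fx) * fy       * (1 - fz) +
    v[idx(1, 1, 0)] * fx       * fy       * (1 - fz) +
    v[idx(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(1, 0, 1)] * fx       * (1 - fy) * fz +
    v[idx(0, 1, 1)] * (1 - fx) * fy       * fz +
    v[idx(1, 1, 1)] * fx       * fy       * fz
  out[loc$inside] <- val
  out
}

#' Sample image intensity gradients at world coordinates
#'
#' Analytic spatial gradient of the chosen interpolant (trilinear by
#' default, cubic B-spline optionally), in intensity/mm. Outside the grid
#' the gradient is the zero vector.
#'
#' @param img an [Image3D-class].
#' @param points n x 3 matrix of world coordinates, mm.
#' @param interp "linear" or "cubic".
#' @return n x 3 matrix of gradients.
#' @export
sampleGradient <- function(img, points, interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  points <- matrix(as.numeric(points), ncol = 3)
  if (interp == "cubic")
    return(.splineSample(.splineCoeffs(img), points, gradient = TRUE))
  loc <- .locate(img, points)
  out <- matrix(0, nrow(points), 3)
  if (!any(loc$inside)) return(out)
  i0 <- loc$i0[loc$inside, , drop = FALSE]
  f <- loc$f[loc$inside, , drop = FALSE]
  d <- loc$dims
  v <- img@voxels
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * (i0[, 2] + dy - 1) + d[1] * d[2] * (i0[, 3] + dz - 1)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c000 <- v[idx(0, 0, 0)]; c100 <- v[idx(1, 0, 0)]
  c010 <- v[idx(0, 1, 0)]; c110 <- v[idx(1, 1, 0)]
  c001 <- v[idx(0, 0, 1)]; c101 <- v[idx(1, 0, 1)]
  c011 <- v[idx(0, 1, 1)]; c111 <- v[idx(1, 1, 1)]
  gx <- ((c100 - c000) * (1 - fy) * (1 - fz) + (c110 - c010) * fy * (1 - fz) +
         (c101 - c001) * (1 - fy) * fz       + (c111 - c011) * fy * fz) /
        img@spacing[1]
  gy <- ((c010 - c000) * (1 - fx) * (1 - fz) + (c110 - c100) * fx * (1 - fz) +
         (c011 - c001) * (1 - fx) * fz       + (c111 - c101) * fx * fz) /
        img@spacing[2]
  gz <- ((c001 - c000) * (1 - fx) * (1 - fy) + (c101 - c100) * fx * (1 - fy) +
         (c011 - c010) * (1 - fx) * fy       + (c111 - c110) * fx * fy) /
        img@spacing[3]
  out[loc$inside, ] <- cbind(gx, gy, gz)
  out
}

#' Add Gaussian noise at a fixed signal-to-noise ratio
#'
#' Draws an i.i.d. zero-mean Gaussian noise field with standard deviation
#' sigma_n = sigma_i / snr, where sigma_i is the standard deviation of the
#' image intensities over the whole volume, and adds it to the image.
#' Reproducible under the spec's seed. An effectively infinite SNR
#' (>= 1e12) returns the image unchanged with a zero noise field.
#'
#' @param img an [Image3D-class] with nonzero intensity standard deviation.
#' @param spec a [NoiseSpec-class].
#' @return list with elements \code{noisy} and \code{noise_field}, both
#'   [Image3D-class].
#' @export
addNoise <- function(img, spec) {
  stopifnot(is(img, "Image3D"), is(spec, "NoiseSpec"))
  sigma_i <- stats::sd(img@voxels)
  if (sigma_i == 0)
    stop("degenerate image: intensity standard deviation is zero")
  if (spec@snr >= 1e12) {
    nf <- Image3D(array(0, dim(img@voxels)), img@spacing, img@origin)
    return(list(noisy = img, noise_field = nf))
  }
  sigma_n <- sigma_i / spec@snr
  n <- length(img@voxels)
  field <- withr::with_seed(spec@seed,
                            stats::rnorm(n, mean = 0, sd = sigma_n))
  nf <- Image3D(array(field, dim(img@voxels)), img@spacing, img@origin)
  noisy <- Image3D(img@voxels + nf@voxels, img@spacing, img@origin)
  list(noisy = noisy, noise_field = nf)
}

#' Scale image intensities down by a fraction
#'
#' Multiplies every voxel by (1 - reduction_fraction), emulating reduced
#' tracer uptake.
#'
#' @param img an [Image3D-class].
#' @param reduction_fraction real in [0, 1).
#' @return An [Image3D-class].
#' @export
scaleIntensity <- function(img, reduction_fraction) {
  if (!is.numeric(reduction_fraction) || length(reduction_fraction) != 1L ||
      reduction_fraction < 0 || reduction_fraction >= 1)
    stop("reduction_fraction must lie in [0, 1)")
  Image3D(img@voxels * (1 - reduction_fraction), img@spacing, img@origin)
}

#' Full-volume intensity statistics
#'
#' @param img an [Image3D-class].
#' @param nbins number of fixed-width histogram bins.
#' @return list with \code{mean}, \code{sd}, \code{histogram} (bin counts)
#'   and \code{breaks}.
#' @export
intensityStats <- function(img, nbins = 64L) {
  v <- as.numeric(img@voxels)
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = nbins)
  list(mean = mean(v), sd = stats::sd(v), histogram = counts, breaks = breaks)
}
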