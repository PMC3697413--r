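# Green-Lagrange strain extraction, region-by-depth sampling, and the
# method-comparison statistics (R^2, %RMSE, Bland-Altman, paired t-test).

#' Green-Lagrange strain tensor
#'
#' E = 1/2 (F'F - I); symmetric and invariant under superposed rigid
#' motion.
#'
#' @param F 3 x 3 deformation gradient.
#' @return 3 x 3 strain tensor.
#' @export
greenLagrange <- function(F) {
  if (any(!is.finite(F))) stop("F must be finite")
  0.5 * (crossprod(F) - diag(3))
}

#' Directional (projected) strain
#'
#' @param E 3 x 3 strain tensor.
#' @param direction unit 3-vector.
#' @return scalar d . E d.
#' @export
projectStrain <- function(E, direction) {
  if (abs(sum(direction^2) - 1) > 1e-8)
    stop("direction must be unit length")
  as.numeric(t(direction) %*% E %*% direction)
}

#' Circumferential and radial strains at quadrature points
#'
#' Vectorized Green-Lagrange projection of per-quadrature-point deformation
#' gradients onto the reference cardiac frames.
#'
#' @param Fflat nqp x 9 column-major flattened deformation gradients.
#' @param frames a [LocalFrame-class].
#' @return nqp x 2 matrix with columns \code{circumferential},
#'   \code{radial}.
#' @export
projectedStrains <- function(Fflat, frames) {
  # E = 1/2 (F'F - I); d' E d computed without materializing tensors
  proj <- function(d) {
    # (F d) . (F d): F columns are Fflat[, 1:3], [,4:6], [,7:9]
    fd1 <- Fflat[, 1] * d[, 1] + Fflat[, 4] * d[, 2] + Fflat[, 7] * d[, 3]
    fd2 <- Fflat[, 2] * d[, 1] + Fflat[, 5] * d[, 2] + Fflat[, 8] * d[, 3]
    fd3 <- Fflat[, 3] * d[, 1] + Fflat[, 6] * d[, 2] + Fflat[, 9] * d[, 3]
    0.5 * (fd1^2 + fd2^2 + fd3^2 - 1)
  }
  cbind(circumferential = proj(frames@circumferential),
        radial = proj(frames@radial))
}

#' Recovered strains of a registration
#'
#' Deformation gradients from the nodal displacement field, projected onto
#' the reference cardiac frames.
#'
#' @param mesh a [HexMesh-class].
#' @param u N x 3 nodal displacements (e.g. [finalDisplacement()]).
#' @param frames a [LocalFrame-class].
#' @return nqp x 2 strain matrix as in [projectedStrains()].
#' @export
recoveredStrains <- function(mesh, u, frames = localFrames(mesh)) {
  Fflat <- .cppDefGrad(mesh@nodes, mesh@elements, u)
  projectedStrains(Fflat, frames)
}

.depthLabel <- function(depth) {
  cut(depth, breaks = c(-1e-9, 1 / 3, 2 / 3, 1 + 1e-9),
      labels = c("epicardial", "midwall", "endocardial"))
}

#' Region-by-depth strain sampling
#'
#' For every sampled short-axis band, the projected strains are averaged
#' over the quadrature points of each (region, depth) cell of the 4 regions
#' x 3 transmural depths partition, yielding exactly 12 circumferential and
#' 12 radial values per band.
#'
#' @param mesh a [HexMesh-class] carrying regions and slice bands.
#' @param strains nqp x 2 matrix (columns circumferential, radial).
#' @param slices integer vector of short-axis bands to sample (default:
#'   all).
#' @return data.frame with columns slice, region, depth, direction, value.
#' @export
sampleHarpGrid <- function(mesh, strains, slices = NULL) {
  if (is.null(slices)) slices <- sort(unique(mesh@slice_index))
  nqp <- nrow(strains)
  qp_slice <- rep(mesh@slice_index, each = 8L)
  qp_region <- rep(mesh@region, each = 8L)
  qp_depth <- as.character(.depthLabel(mesh@wall_depth))
  regions <- c("anterior", "lateral", "posterior", "septal")
  depths <- c("epicardial", "midwall", "endocardial")
  out <- expand.grid(depth = depths, region = regions, slice = slices,
                     direction = c("circumferential", "radial"),
                     stringsAsFactors = FALSE)[, c(3, 2, 1, 4)]
  out$value <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- qp_slice == out$slice[i] & qp_region == out$region[i] &
           qp_depth == out$depth[i]
    if (!any(sel))
      stop(sprintf("sampling error: empty cell (slice %s, %s, %s)",
                   out$slice[i], out$region[i], out$depth[i]))
    col <- if (out$direction[i] == "circumferential") 1L else 2L
    out$value[i] <- mean(strains[sel, col])
  }
  rownames(out) <- NULL
  out
}

#' Percent root-mean-square error of strain predictions
#'
#' sqrt of the mean over entries of (ref - pred)^2 / ref^2, the reference
#' (tagged-MRI-style) values being the gold standard. Near-zero references
#' (|ref| below \code{floor}) are excluded and counted; the ratio-of-sums
#' variant sqrt(sum (ref - pred)^2 / sum ref^2) is available via
#' \code{variant}.
#'
#' @param reference,predicted equal-length numeric vectors.
#' @param floor exclusion threshold on |reference|.
#' @param variant "mean_ratio" (default) or "ratio_of_sums".
#' @return scalar; attribute \code{n_excluded} carries the exclusion count.
#' @export
percentRMSE <- function(reference, predicted, floor = 0.01,
                        variant = c("mean_ratio", "ratio_of_sums")) {
  variant <- match.arg(variant)
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  keep <- abs(reference) >= floor
  if (!any(keep))
    stop("metric error: all reference entries below the exclusion floor")
  r <- reference[keep]; p <- predicted[keep]
  val <- if (variant == "mean_ratio") sqrt(mean((r - p)^2 / r^2))
         else sqrt(sum((r - p)^2) / sum(r^2))
  structure(val, n_excluded = sum(!keep))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param x,y paired samples, n >= 3; x must have nonzero variance.
#' @return scalar in [0, 1].
#' @export
rSquared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("metric error: zero variance")
  stats::cor(x, y)^2
}

#' Bland-Altman agreement analysis
#'
#' Differences d = y - x against means m = (x + y)/2: mean difference,
#' limits of agreement (mean +/- 1.96 sd), and the least-squares slope of d
#' on m (trend detection).
#'
#' @param x,y paired samples (x = reference), n >= 3.
#' @return list with mean_diff, sd_diff, loa_lower, loa_upper, slope.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired samples")
  d <- y - x
  m <- (x + y) / 2
  sdd <- stats::sd(d)
  slope <- if (stats::sd(m) == 0) 0
           else unname(stats::coef(stats::lm(d ~ m))[2])
  list(mean_diff = mean(d), sd_diff = sdd,
       loa_lower = mean(d) - 1.96 * sdd, loa_upper = mean(d) + 1.96 * sdd,
       slope = slope)
}

#' Two-sided paired t-test p-value
#'
#' Zero-variance differences return 1 (zero mean) or the 0 sentinel
#' (nonzero mean).
#'
#' @param x,y paired samples, n >= 3.
#' @return p-value.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired samples")
  d <- y - x
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  stats::t.test(x, y, paired = TRUE)$p.value
}

#' Compare two strain sample tables
#'
#' Joins reference and predicted tables on (slice, region, depth,
#' direction) and reports R^2, %RMSE, Bland-Altman statistics and the
#' paired t-test p-value per direction and pooled. Degenerate inputs
#' (e.g. zero variance when the pair is perfectly registered) yield NA for
#' the affected statistics instead of an error.
#'
#' @param reference,predicted strain sample tables ([sampleHarpGrid()]
#'   layout).
#' @return nested list: one entry per direction plus \code{pooled}, each
#'   with r_squared, percent_rmse, n_excluded, bland_altman, t_test_p, n.
#' @export
compareStrains <- function(reference, predicted) {
  key <- c("slice", "region", "depth", "direction")
  m <- merge(reference, predicted, by = key, suffixes = c("_ref", "_pred"))
  if (nrow(m) == 0L) stop("tables share no sampling locations")
  one <- function(rows) {
    x <- m$value_ref[rows]; y <- m$value_pred[rows]
    r2 <- tryCatch(rSquared(x, y), error = function(e) NA_real_)
    rmse <- tryCatch(percentRMSE(x, y), error = function(e) NA_real_)
    list(r_squared = r2,
         percent_rmse = as.numeric(rmse),
         n_excluded = if (is.na(rmse[1])) NA_integer_
                      else attr(rmse, "n_excluded"),
         bland_altman = blandAltman(x, y),
         t_test_p = pairedTTest(x, y),
         n = length(x))
  }
  res <- list()
  for (dir in unique(m$direction)) res[[dir]] <- one(m$direction == dir)
  res$pooled <- one(rep(TRUE, nrow(m)))
  res
}

#' Read/write strain sample tables as CSV
#'
#' @param path CSV path with header slice, region, depth, direction, value.
#' @return data.frame.
#' @export
readStrainTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice", "region", "depth", "direction", "value")
  if (!all(need %in% names(tab)))
    stop("strain table must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

#' @param table strain sample table.
#' @rdname readStrainTable
#' @export
writeStrainTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
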