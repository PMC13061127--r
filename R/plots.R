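#' Plot a posterior origin map
#'
#' Displays the posterior probability of each candidate origin box on
#' the partition grid, with the maximum likelihood estimate and,
#' optionally, the observed bloom boxes outlined.  A root transform
#' (`root = 2` for a square root) compresses the dynamic range for
#' display only; stored values are never transformed.
#'
#' @param x an [origin_posterior()] with a partition attached.
#' @param root root transform applied for display (1 = none).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.origin_posterior <- function(x, root = 1, ...) {
  part <- x$partition
  if (is.null(part)) stop("this posterior has no partition to draw on")
  z <- matrix(NA_real_, part$nx, part$ny)
  ctr <- box_centers(part)
  idx <- cbind(((x$candidates - 1) %% part$nx) + 1,
               ((x$candidates - 1) %/% part$nx) + 1)
  z[idx] <- if (x$no_path) 0 else x$posterior^(1 / root)
  xs <- part$x0 + part$h * (seq_len(part$nx) - 0.5)
  ys <- part$y0 + part$h * (seq_len(part$ny) - 0.5)
  graphics::image(xs, ys, z, xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("origin posterior (k_obs = %d)", x$k_obs),
                  useRaster = TRUE, ...)
  if (!x$no_path)
    graphics::points(ctr[x$mle, 1], ctr[x$mle, 2], pch = 0, cex = 2, lwd = 2)
  graphics::points(ctr[x$target, 1], ctr[x$target, 2], pch = 4, lwd = 2)
  invisible(x)
}

#' Plot an effective-current vector field
#'
#' Draws the box-center vectors of the effective transition current at
#' one chain step as arrows; magnitudes may be root-transformed for
#' display (the stored currents are untouched).
#'
#' @param x a [tpt_current()] computed on a chain with a partition.
#' @param k 1-based step index into the current series.
#' @param root display-only root transform of the arrow lengths.
#' @param scale arrow length of the largest current, in box sides.
#' @param ... passed to [graphics::arrows()].
#' @return `x`, invisibly.
#' @export
plot.tpt_current <- function(x, k = 1, root = 4, scale = 1.5, ...) {
  if (is.null(x$vector_field) || is.null(x$partition))
    stop("this analysis has no box vector field to draw")
  vf <- x$vector_field$vf
  if (k < 1 || k > dim(vf)[1]) stop("k out of range")
  part <- x$partition
  ctr <- box_centers(part)
  fx <- vf[k, , 1]; fy <- vf[k, , 2]
  mag <- sqrt(fx^2 + fy^2)
  graphics::plot(NA, xlim = c(part$x0, part$x0 + part$nx * part$h),
                 ylim = c(part$y0, part$y0 + part$ny * part$h),
                 xlab = "x (m)", ylab = "y (m)", asp = 1,
                 main = sprintf("effective current, step %d", k))
  nz <- which(mag > 0)
  if (!length(nz)) return(invisible(x))
  disp <- mag^(1 / root)
  len <- scale * part$h * disp / max(disp)
  graphics::arrows(ctr[nz, 1], ctr[nz, 2],
                   ctr[nz, 1] + len[nz] * fx[nz] / mag[nz],
                   ctr[nz, 2] + len[nz] * fy[nz] / mag[nz],
                   length = 0.05, ...)
  invisible(x)
}
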