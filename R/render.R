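## Gaussian rendering of localization tables.

#' Render a localization table as a summed-Gaussian image
#'
#' Each localization contributes a unit-mass 2D Gaussian whose standard
#' deviation is its own localization precision (per axis); pixel values
#' are the sums of the overlapping contributions, evaluated as
#' pixel-integrated masses. Gaussians are truncated at 4 sigma, losing
#' under 0.01 percent of their mass.
#'
#' @param table a localization table (positions and precisions in nm).
#' @param pixel_size output pixel size in nm.
#' @param xlim,ylim image extent in nm (default: the field spanned by the
#'   data padded by 5 render pixels).
#' @param trunc truncation radius in units of sigma (default 4).
#' @return A numeric matrix (rows = y, columns = x) with attributes
#'   `pixel_size`, `xlim`, `ylim`.
#' @export
render_gaussian <- function(table, pixel_size, xlim = NULL, ylim = NULL,
                            trunc = 4) {
  if (!is_pos_num(pixel_size)) stop_arg("pixel_size must be positive")
  n <- nrow(table)
  if (n > 0) validate_loc_table(table)
  if (is.null(xlim)) xlim <- if (n) range(table$x) + c(-5, 5) * pixel_size else c(0, pixel_size)
  if (is.null(ylim)) ylim <- if (n) range(table$y) + c(-5, 5) * pixel_size else c(0, pixel_size)
  ncol_px <- max(1L, ceiling((xlim[2] - xlim[1]) / pixel_size))
  nrow_px <- max(1L, ceiling((ylim[2] - ylim[1]) / pixel_size))
  img <- matrix(0, nrow_px, ncol_px)
  if (n) {
    xe <- xlim[1] + (0:ncol_px) * pixel_size
    ye <- ylim[1] + (0:nrow_px) * pixel_size
    for (i in seq_len(n)) {
      sx <- table$sigma_loc_x[i]; sy <- table$sigma_loc_y[i]
      ci <- which(xe[-1] >= table$x[i] - trunc * sx &
                    xe[-(ncol_px + 1)] <= table$x[i] + trunc * sx)
      ri <- which(ye[-1] >= table$y[i] - trunc * sy &
                    ye[-(nrow_px + 1)] <= table$y[i] + trunc * sy)
      if (!length(ci) || !length(ri)) next
      dx <- pnorm((xe[ci + 1] - table$x[i]) / sx) - pnorm((xe[ci] - table$x[i]) / sx)
      dy <- pnorm((ye[ri + 1] - table$y[i]) / sy) - pnorm((ye[ri] - table$y[i]) / sy)
      img[ri, ci] <- img[ri, ci] + outer(dy, dx)
    }
  }
  attr(img, "pixel_size") <- pixel_size
  attr(img, "xlim") <- xlim
  attr(img, "ylim") <- ylim
  img
}
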