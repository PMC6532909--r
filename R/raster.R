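# Shared raster helpers. Image slices are matrices indexed [row, col] with
# row 1 at the top; physical coordinates are x_um = (col - 0.5) * pixel_size,
# y_um = (row - 0.5) * pixel_size, so renderer and segmentation share one
# convention and sub-pixel positions are well defined.

px_x <- function(cols, pixel_size) (cols - 0.5) * pixel_size
px_y <- function(rows, pixel_size) (rows - 0.5) * pixel_size

# Soft-edged disk rasterized into a patch: per-pixel value is a linear ramp
# of the signed distance to the circle, approximating area coverage over a
# one-pixel transition band.
soft_disk_patch <- function(nrow, ncol, cx_px, cy_px, r_px) {
  xc <- matrix(seq_len(ncol) - 0.5, nrow, ncol, byrow = TRUE)
  yc <- matrix(seq_len(nrow) - 0.5, nrow, ncol)
  dist <- sqrt((xc - cx_px)^2 + (yc - cy_px)^2)
  pmin(pmax(r_px - dist + 0.5, 0), 1)
}

# Intensity-weighted sub-pixel centroid of a set of pixels (global indices).
weighted_centroid <- function(rows, cols, weights) {
  w <- sum(weights)
  c(x = sum((cols - 0.5) * weights) / w, y = sum((rows - 0.5) * weights) / w)
}

# Normalized cross-correlation of an image patch with an ideal disk template
# of the given radius centred at the given sub-pixel position (patch-local,
# pixels). Returns a confidence in [0, 1]: negative correlations clip to 0.
disk_template_energy <- function(patch, cx_px, cy_px, r_px) {
  tmpl <- soft_disk_patch(nrow(patch), ncol(patch), cx_px, cy_px, r_px)
  if (stats::sd(patch) == 0 || stats::sd(tmpl) == 0) return(0)
  max(0, stats::cor(as.vector(patch), as.vector(tmpl)))
}
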