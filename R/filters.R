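# Internal separable filtering in physical units. All kernels are normalized
# discrete Gaussians; boundaries are handled by symmetric reflection, which
# conserves total intensity for symmetric kernels.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# sigma in um, recycled per axis; sigma = 0 on an axis skips that axis
gaussian_smooth <- function(data, voxel_size, sigma_um) {
  nd <- length(dim(data))
  sigma_um <- rep_len(sigma_um, nd)
  if (any(sigma_um < 0)) stop("sigma must be nonnegative")
  out <- data
  for (a in seq_len(nd)) {
    sv <- sigma_um[a] / voxel_size[a]
    if (sv <= 0) next
    k <- gaussian_kernel_1d(sv)
    out <- array(cpp_conv_axis(as.numeric(out), dim(data), k, a - 1L),
                 dim(data))
  }
  out
}

# gradient magnitude by central differences in physical units (per um)
gradient_magnitude <- function(data, voxel_size) {
  nd <- length(dim(data))
  acc <- array(0, dim(data))
  for (a in seq_len(nd)) {
    k <- c(-0.5, 0, 0.5) / voxel_size[a]
    g <- array(cpp_conv_axis(as.numeric(data), dim(data), k, a - 1L),
               dim(data))
    acc <- acc + g^2
  }
  sqrt(acc)
}
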