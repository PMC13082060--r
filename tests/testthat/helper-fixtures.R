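# Shared fixture builders; everything is generated in code, no files.

uniform_tissue <- function(eal_um = 300) {
  tissue_optics_model(data.frame(thickness_um = Inf, eal_um = eal_um))
}

# per-slice signal/background ROI pairs read off a generator ground truth
truth_roi_pairs <- function(stack, mask) {
  sig_px <- which(mask, arr.ind = TRUE) - 1
  bg_px <- which(!mask, arr.ind = TRUE) - 1
  lapply(seq_len(dim(stack$voxels)[1]), function(k) {
    list(signal = roi("mask", sig_px, slice_index = k - 1,
                      label = sprintf("v%02d", k)),
         background = roi("mask", bg_px, slice_index = k - 1,
                          label = sprintf("bg%02d", k)))
  })
}

# mean in-geometry photon count per slice
slice_signal_means <- function(stack, mask) {
  vapply(seq_len(dim(stack$voxels)[1]),
         function(k) mean(stack$voxels[k, , ][mask]), numeric(1))
}

# constant-count movie
flat_movie <- function(value = 5, nt = 40, ny = 8, nx = 8, fs = 6.18) {
  activity_movie(array(value, dim = c(nt, ny, nx)), frame_rate_hz = fs)
}

# square mask ROI covering rows/cols [r0, r1] x [c0, c1], 0-based
square_roi <- function(r0, r1, c0, c1, slice = 0, label = "sq") {
  roi("mask", as.matrix(expand.grid(r0:r1, c0:c1)), slice_index = slice,
      label = label)
}
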