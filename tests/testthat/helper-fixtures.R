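# Shared fixtures, built in code at test time.

# Deterministic noise-free multi-scanner cohort obeying the proportional
# model exactly: hui = gain * h, icg = slope1 * h, albi = b_s * h with the
# route-ratio perturbation on non-reference scanners. Independent of the
# simulator module so it can serve as its oracle.
zero_noise_cohort <- function(gains, n_per = 12, slope1 = -0.173,
                              slope1_prime = -1.425, route_ratio = 0.955,
                              ref = names(gains)[1]) {
  do.call(rbind, lapply(names(gains), function(s) {
    h <- seq(0.4, 1.6, length.out = n_per)
    b <- if (identical(s, ref)) slope1_prime else slope1_prime / route_ratio
    data.frame(patient_id = paste0(s, "-", seq_len(n_per)),
               scanner_id = s,
               hui = gains[[s]] * h,
               icg_pdr = slope1 * h,
               albi_lp = b * h,
               stringsAsFactors = FALSE)
  }))
}

# Small block image: liver region at one intensity, spleen at another,
# background at a third; returns image plus the two masks.
block_phantom <- function(liver_value = 200, spleen_value = 100,
                          dims = c(10L, 10L, 4L), voxel = c(2, 2, 5)) {
  img <- array(10, dims)
  liver <- array(FALSE, dims); liver[2:5, 2:7, 1:3] <- TRUE
  spleen <- array(FALSE, dims); spleen[7:9, 2:4, 2:3] <- TRUE
  img[liver] <- liver_value
  img[spleen] <- spleen_value
  list(image = volumetric_image(img, voxel),
       liver = roi_mask(liver, "liver"),
       spleen = roi_mask(spleen, "spleen"))
}

# Independent NIfTI-1 writer used as an oracle for read_nifti(): int16 data
# with scl_slope/scl_inter, written field by field.
write_nifti_int16_oracle <- function(values3d, path, voxel = c(1, 1, 1),
                                     scl_slope = 1, scl_inter = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(348L, 4L); writeBin(raw(36L), con)
  wi(c(3L, dim(values3d), 1L, 1L, 1L, 1L), 2L)
  wf(c(0, 0, 0)); wi(0L, 2L)                   # intent_p1..3, intent_code
  wi(4L, 2L); wi(16L, 2L); wi(0L, 2L)          # datatype int16, bitpix, slice_start
  wf(c(0, voxel, 1, 1, 1, 1))
  wf(352); wf(scl_slope); wf(scl_inter)
  wi(0L, 2L); writeBin(raw(2L), con)
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)
  writeBin(raw(104L), con)                      # descrip + aux_file
  wi(c(0L, 0L), 2L); wf(rep(0, 18))
  writeBin(raw(16L), con)
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  writeBin(raw(4L), con)
  wi(as.vector(values3d), 2L)
  invisible(path)
}

published_cf_pairs <- function() {
  tab <- scanner_reference_values()
  tab[!tab$is_reference, c("scanner_id", "cf1", "cf2")]
}
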