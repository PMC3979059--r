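# Shared in-code fixtures: small analytic solids voxelised independently of
# the phantom generator, used as oracles.

# logical 3D array of a digital ball: voxel centres within radius r (voxels)
# of centre `cen` (defaults to the grid centre)
ballArray <- function(d, r, cen = (d + 1) / 2) {
  i2 <- (seq_len(d[1]) - cen[1])^2
  lat <- outer((seq_len(d[2]) - cen[2])^2, (seq_len(d[3]) - cen[3])^2, "+")
  b <- outer(i2, lat, "+") <= r^2
  dim(b) <- d
  b
}

# annulus (hollow cylinder) along the slice axis, radii in voxels
tubeArray <- function(d, Router, Rinner) {
  c2 <- (d[2] + 1) / 2; c3 <- (d[3] + 1) / 2
  lat <- outer((seq_len(d[2]) - c2)^2, (seq_len(d[3]) - c3)^2, "+")
  latB <- lat <= Router^2 & lat > Rinner^2
  aperm(array(latB, c(d[2], d[3], d[1])), c(3, 1, 2))
}

# density array from a bone mask using the default calibration
densityFromMask <- function(bone, bd = 900, bg = 100) {
  array(ifelse(bone, bd, bg), dim(bone))
}

fullRoi <- function(vol, label = "custom") {
  RoiMask(array(TRUE, dim(vol)), voxelSize(vol), label = label)
}

stdFilter <- function() filterParams(0.8, 1)
strongFilter <- function() filterParams(2.5, 5)
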