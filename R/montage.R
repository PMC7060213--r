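#' Idealized 32-channel 10-20 montage
#'
#' Unit-sphere electrode positions for a 32-channel extended 10-20 layout
#' (the cap geometry typical of MR-compatible recordings). Coordinates use
#' the convention x = right, y = anterior, z = superior; every electrode sits
#' on the unit sphere. Positions are idealized ring placements (inclination
#' from the vertex, azimuth from the nasion), adequate for spherical-spline
#' interpolation and current-source-density estimation.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @examples
#' m <- standard_montage_32()
#' stopifnot(all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-12))
#' @export
standard_montage_32 <- function() {
  # label, inclination theta (deg, 0 = vertex), azimuth alpha (deg, 0 = nasion,
  # positive toward the right ear)
  tbl <- rbind(
    c("Fp1",  92,  -18), c("Fp2",  92,   18),
    c("F7",   92,  -54), c("F3",   62,  -39), c("Fz",  46,    0),
    c("F4",   62,   39), c("F8",   92,   54),
    c("FC5",  77,  -67), c("FC1",  37,  -25), c("FC2", 37,   25), c("FC6", 77, 67),
    c("T7",   92,  -90), c("C3",   46,  -90), c("Cz",   0,    0),
    c("C4",   46,   90), c("T8",   92,   90),
    c("CP5",  77, -113), c("CP1",  37, -155), c("CP2", 37,  155), c("CP6", 77, 113),
    c("P7",   92, -126), c("P3",   62, -141), c("Pz",  46,  180),
    c("P4",   62,  141), c("P8",   92,  126),
    c("O1",   92, -162), c("Oz",   92,  180), c("O2",  92,  162),
    c("TP9", 108, -108), c("TP10", 108, 108),
    c("FT9", 108,  -72), c("FT10", 108,  72)
  )
  theta <- as.numeric(tbl[, 2]) * pi / 180
  alpha <- as.numeric(tbl[, 3]) * pi / 180
  data.frame(
    label = tbl[, 1],
    x = sin(theta) * sin(alpha),
    y = sin(theta) * cos(alpha),
    z = cos(theta),
    stringsAsFactors = FALSE
  )
}
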