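#' Camera specification
#'
#' @param sensor_width_mm,sensor_height_mm physical sensor size, mm
#' @param image_width_px,image_height_px image resolution, pixels
#' @param focal_mm focal length, mm
#' @param fov_deg published field of view, degrees; when absent it is
#'   derived from the sensor diagonal as `2 atan(diag / (2 focal))`
#' @return class `camera_spec`
#' @export
camera_spec <- function(sensor_width_mm, sensor_height_mm,
                        image_width_px, image_height_px, focal_mm,
                        fov_deg = NULL) {
  stopifnot(sensor_width_mm > 0, sensor_height_mm > 0,
            image_width_px > 0, image_height_px > 0, focal_mm > 0)
  if (is.null(fov_deg)) {
    diag <- sqrt(sensor_width_mm^2 + sensor_height_mm^2)
    fov_deg <- 2 * atan(diag / (2 * focal_mm)) * 180 / pi
  }
  structure(list(sensor_width_mm = sensor_width_mm,
                 sensor_height_mm = sensor_height_mm,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px,
                 focal_mm = focal_mm, fov_deg = fov_deg),
            class = "camera_spec")
}

#' Built-in camera presets
#'
#' `"p1"`: 45 MP full-frame camera (8192 x 5460 px, 35.9 mm x 24 mm
#' sensor) with a 35 mm lens, published field of view 63.5 degrees.
#' `"ixm100"`: 100 MP camera (11664 x 8750 px) with an 80 mm lens,
#' published field of view 30.4 degrees.
#'
#' @param name preset name
#' @export
camera_preset <- function(name = c("p1", "ixm100")) {
  name <- match.arg(name)
  switch(name,
         p1 = camera_spec(35.9, 24, 8192, 5460, 35, fov_deg = 63.5),
         ixm100 = camera_spec(53.4, 40, 11664, 8750, 80, fov_deg = 30.4))
}

#' Ground sample distance
#'
#' `GSD = pixel_pitch * altitude / focal`, with the pixel pitch taken as
#' sensor width over image width. The 45 MP full-frame preset at 15 m
#' altitude gives 1.88, i.e. about 1.9 mm/pixel.
#'
#' @param cam a [camera_spec]
#' @param altitude_m flight altitude, meters
#' @return GSD in mm/pixel
#' @export
ground_sample_distance <- function(cam, altitude_m) {
  stopifnot(altitude_m > 0)
  (cam$sensor_width_mm / cam$image_width_px) *
    (altitude_m * 1000 / cam$focal_mm)
}

#' Areal coverage-rate ratio of two cameras
#'
#' At equal altitude, speed and overlaps, the area covered per unit time
#' scales with the ground footprint, i.e. with the squared tangent of the
#' half field of view: `ratio = (tan(fov_a / 2) / tan(fov_b / 2))^2`. The
#' 63.5 vs 30.4 degree pairing gives about 5.2.
#'
#' @param fov_a_deg,fov_b_deg fields of view in degrees, in `(0, 180)`
#' @return dimensionless ratio (camera a relative to camera b)
#' @export
coverage_rate_ratio <- function(fov_a_deg, fov_b_deg) {
  stopifnot(fov_a_deg > 0, fov_a_deg < 180, fov_b_deg > 0, fov_b_deg < 180)
  (tan(fov_a_deg / 2 * pi / 180) / tan(fov_b_deg / 2 * pi / 180))^2
}
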