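suppressMessages({library(tibble); library(rlang); library(dplyr)})
source("/root/pkg/R/lightspd-package.R"); source("/root/pkg/R/spectra.R")

# CIE D65 relative SPD, canonical 10-nm tabulation (100 at 560 nm)
wl10 <- seq(300, 830, 10)
d65_10 <- c(
  0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383, 52.0891,
  49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823, 104.865, 117.008,
  117.812, 114.861, 115.923, 108.811, 109.354, 107.802, 104.79, 107.689,
  104.405, 104.046, 100, 96.3342, 95.788, 88.6856, 90.0062, 89.5991,
  87.6987, 83.2886, 83.6992, 80.0268, 80.2146, 82.2778, 78.2842, 69.7213,
  71.6091, 74.349, 61.604, 69.8856, 75.087, 63.5927, 46.4182, 66.8054,
  63.3828, 64.304, 59.4519, 51.959, 57.4406, 60.3125
)
stopifnot(length(d65_10) == length(wl10))
wl5 <- seq(300, 830, 5)
d65_5 <- approx(wl10, d65_10, xout = wl5)$y
write.csv(data.frame(wavelength_nm = wl5, value = round(d65_5, 4)),
          "/root/pkg/inst/extdata/cie_d65_5nm.csv", row.names = FALSE, quote = FALSE)

# synthetic RGB camera, 400-1000 at 5 nm (usable after resampling on any band)
cam <- synthetic_rgb_camera(wavelength_grid(400, 1000, 5), nir_tail = TRUE)
cam[-1] <- lapply(cam[-1], function(v) round(v, 6))
write.csv(as.data.frame(cam), "/root/pkg/inst/extdata/camera_rgb_synthetic.csv",
          row.names = FALSE, quote = FALSE)

# synthetic stand-in for the 24-LED panel, 400-830 at 5 nm
led <- led_sublights()
led[-1] <- lapply(led[-1], function(v) round(v, 6))
write.csv(as.data.frame(led), "/root/pkg/inst/extdata/sublights_led24_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("sizes:\n"); print(file.info(list.files("/root/pkg/inst/extdata", full.names=TRUE))["size"])
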