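#!/usr/bin/env Rscript
# Simulate one virtual disc of the two-region benchmark scene (organizer
# half-life 45 min vs non-organizer 30 min, Hill -2.3, drug at 10 min) and
# write the raw two-channel stack, the donor-only calibration pair, the
# ground truth and the landmark sidecar under results/.

suppressPackageStartupMessages(library(fretkin))

out <- "results"
dir.create(out, showWarnings = FALSE)

bench <- default_two_region_scene(seed = 1L)
labels <- build_pouch_labels(bench$scene, bench$geometry)
truth <- scene_truth(labels, bench$kinetics)

raw <- render_frames(bench$scene, truth)
print(raw)
# quantize to camera counts (16-bit storage; a real detector clips at 0)
raw$donor[] <- pmax(round(raw$donor), 0)
raw$fret[] <- pmax(round(raw$fret), 0)
write_stack(raw, file.path(out, "disc01_stack.tif"))

cal_spec <- bench$scene
cal_spec$seed <- 999L
pair <- render_calibration_pair(cal_spec)
cal <- raw_timelapse(pmax(round(pair$donor), 0),
                     pmax(round(pair$bleedthrough), 0))
write_stack(cal, file.path(out, "calibration_pair.tif"))

write_truth(truth, file.path(out, "truth.csv"))
write_scene_config(bench$scene, bench$kinetics, bench$geometry,
                   file.path(out, "scene.json"))

g <- labels$geometry
scheme <- make_roi_scheme(
  intersection = c(g$dv_center_um, g$ap_center_um) / bench$scene$pixel_size_um,
  spacing_um = 30, diameter_um = 20,
  pixel_size_um = bench$scene$pixel_size_um,
  image_shape = c(bench$scene$height_px, bench$scene$width_px))
write_landmarks(scheme, file.path(out, "landmarks.json"))

cat(sprintf(
  "Simulated %d frames (%d x %d px); regions: %s\nOutputs in %s/\n",
  bench$scene$n_frames, bench$scene$height_px, bench$scene$width_px,
  paste(names(labels$masks), collapse = " "), out))
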