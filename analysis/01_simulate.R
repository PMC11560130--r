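#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset with known ground truth.
#
# Emulates the experimental inputs: super-resolved cross-section profiles
# of a contracting midpiece (two initiation foci), STORM-style localization
# tables for intact and reacted actin helices, fluorescence-diameter pairs,
# ROI traces for the AE and fusion scenarios, and a fluctuation stack for
# number & brightness.

suppressPackageStartupMessages(library(midpiece))
seed <- 7L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Rendering contracting midpiece (amplitude 0.25, foci at 3 and 16 um)")
geom <- make_geometry(list(
  contraction_amplitude = 0.25,
  foci = data.frame(position_um = c(3, 16), onset_s = c(60, 65),
                    spread_um = 1)))
csk <- render_cross_profiles(geom, positions_um = seq(0, 20, by = 2.5),
                             times_s = seq(0, 240, by = 2),
                             noise_sd = 0.05, seed = seed,
                             channels = c("membrane", "actin"))
# profile renders are regenerated by later stages from the same seed;
# only the ground truth is persisted here
write_result_json(list(geometry = unclass(geom),
                       true_onset_s = csk$truth$onset_s,
                       positions_um = csk$positions_um),
                  file.path(out, "ground_truth.json"))

message("Simulating localization tables (5e4 points, 15 nm precision)")
write_localizations(
  simulate_localizations(make_geometry(), 5e4, 15, seed = seed + 1L),
  file.path(out, "localizations_intact.csv"))
write_localizations(
  simulate_localizations(
    make_geometry(list(helix_pitch_nm = 159, helix_radius_nm = 252)),
    5e4, 15, seed = seed + 2L),
  file.path(out, "localizations_reacted.csv"))

message("Simulating fluorescence-diameter pairs (n = 2000, target R^2 0.32)")
write.csv(simulate_regression_pairs(n = 2000L, seed = seed + 3L),
          file.path(out, "regression_pairs.csv"), row.names = FALSE)

message("Simulating AE and fusion ROI traces")
write_traces(simulate_traces(ae_trace_spec(), noise_sd = 0.02,
                             seed = seed + 4L),
             file.path(out, "traces_ae.csv"))
write_traces(simulate_traces(fusion_trace_spec(), noise_sd = 0.02,
                             seed = seed + 5L),
             file.path(out, "traces_fusion.csv"))

message("Simulating fluctuation stack for number & brightness")
write_image_stack(
  simulate_nb_stack(matrix(50, 16, 16), brightness_counts = 4,
                    n_frames = 300, seed = seed + 6L),
  file.path(out, "nb_stack.tif"))

message("Done: inputs under ", out)
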