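#!/usr/bin/env Rscript

# Step 1 — synthetic study design.
#
# Builds the cell-level generation configuration that emulates the field
# trial (2 species x 9 varieties x 4 phenological stages, stress targets
# and stem-elongation cover fractions taken from the published summary
# tables), writes it to results/, and writes a small set of demonstration
# frames to disk so the file-based segmentation path can be inspected.
# The full-size study is generated in-memory (streaming) by step 02.

library(thermowheat)

dir.create("results", showWarnings = FALSE)

cfg <- study_config(c("durum", "common"))
write.csv(cfg, "results/study_config.csv", row.names = FALSE)
cat(sprintf("study design: %d cells (%d species x 9 varieties x %d stages)\n",
            nrow(cfg), length(unique(cfg$species)),
            length(unique(cfg$stage))))
cat(sprintf("stem-elongation cover range: %.2f-%.2f (published WCI values)\n",
            min(cfg$cover_fraction[cfg$stage == "stem_elongation"]),
            max(cfg$cover_fraction[cfg$stage == "stem_elongation"])))

# demonstration frames: one durum landrace and one modern variety at
# stem elongation, 2 sessions x 2 frames, written as CSV rasters
demo <- cfg[cfg$species == "durum" & cfg$variety %in% c("SC", "SV") &
              cfg$stage == "stem_elongation", ]
st <- generate_study(demo, frames_per_session = 2, sessions_per_stage = 2,
                     height = 120, width = 160, seed = 2024,
                     dir = "results/demo_frames")
cat(sprintf("wrote %d demonstration frames + manifest to results/demo_frames/\n",
            nrow(st$manifest)))
cat(sprintf("realised cover: SC %.3f, SV %.3f (targets %.2f, %.2f)\n",
            mean(st$truth$cover_true[st$truth$variety == "SC"]),
            mean(st$truth$cover_true[st$truth$variety == "SV"]),
            demo$cover_fraction[demo$variety == "SC"],
            demo$cover_fraction[demo$variety == "SV"]))
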