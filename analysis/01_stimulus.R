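#!/usr/bin/env Rscript
# Builds the three stimulus conditions driving the retinotopic mapping
# session: the combined wedge+ring mapping run (both apertures cycling at
# independent frequencies, 21 and 15 volumes per revolution, plus 24 blank
# volumes) and the photic-burst schedule used for HRF estimation.
# Writes a composition summary and the mapping apertures as NIfTI.

suppressPackageStartupMessages(library(orseg))
dir.create("results", showWarnings = FALSE)

cfg <- stimulus_config()
run <- make_mapping_run(cfg)
burst <- make_burst_schedule(10, 1, 14)

summary_df <- data.frame(
  quantity = c("field_radius_deg", "wedge_width_deg", "wedge_step_deg",
               "wedge_vols_per_rev", "ring_vols_per_rev",
               "mapping_stimulation_vols", "mapping_blank_vols",
               "mapping_total_vols", "burst_total_vols",
               "burst_stimulus_vols"),
  value = c(cfg$field_radius_deg, cfg$wedge_width_deg,
            360 / cfg$wedge_vols_per_rev, cfg$wedge_vols_per_rev,
            cfg$ring_vols_per_rev,
            sum(run$schedule$labels == "stimulus"),
            sum(run$schedule$labels == "blank"),
            length(run$schedule$labels),
            length(burst$labels), sum(burst$labels == "stimulus")))
write.csv(summary_df, "results/stimulus_summary.csv", row.names = FALSE)
write_apertures_nifti(run$apertures, "results/mapping_apertures.nii.gz")

rws <- ring_width_schedule(cfg)
write.csv(rws, "results/ring_width_schedule.csv", row.names = FALSE)

cat("Mapping run:", length(run$schedule$labels), "volumes (",
    sum(run$schedule$labels == "stimulus"), "stimulation +",
    sum(run$schedule$labels == "blank"), "blank );",
    "burst condition:", length(burst$labels), "volumes.\n")
cat("Ring width spans", min(rws$width), "to", max(rws$width),
    "deg; wedge steps", round(360 / cfg$wedge_vols_per_rev, 2),
    "deg per volume.\n")
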