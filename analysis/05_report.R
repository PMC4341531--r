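#!/usr/bin/env Rscript
# Step 5: aggregate the per-cell results into the final report tables and
# run the group statistics.

suppressPackageStartupMessages(library(dcvtrace))

ev_root <- file.path("results", "events")
out_root <- file.path("results", "report")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

summaries <- read.csv(file.path(ev_root, "cell_summaries.csv"))
events <- read.csv(file.path(ev_root, "all_events.csv"))

grp <- summarize_cells(summaries)
lines <- c(
  sprintf("cells analysed: %d", grp$n_cells),
  sprintf("non-secreting cells: %.0f%%", grp$pct_non_secreting),
  sprintf("events per secreting cell: %.1f", grp$mean_events),
  sprintf("fusion rate during stimulation: %.3f vesicles/s", grp$mean_rate),
  sprintf("events in the first 4 bursts: %.0f%%",
          100 * sum(summaries$n_events_first4bursts) /
            max(1, sum(summaries$n_events))),
  sprintf("synaptic events: %.0f%%", 100 * mean(events$synaptic == "synaptic")),
  sprintf("persistent / transient: %d / %d",
          sum(events$mode == "persistent"), sum(events$mode == "transient")),
  sprintf("released fraction of the labeled pool: %.0f%%",
          100 * sum(summaries$n_events) / sum(summaries$pool_count)))

# amplitude comparison: synaptic vs extra-synaptic peak dF/F0
syn <- events$peak_dff[events$synaptic == "synaptic"]
ext <- events$peak_dff[events$synaptic == "extra-synaptic"]
if (length(syn) >= 3 && length(ext) >= 3) {
  st <- compare_groups(syn, ext)
  lines <- c(lines, sprintf(
    "peak dF/F0 synaptic (%.2f, n=%d) vs extra-synaptic (%.2f, n=%d): %s, p = %.3g",
    mean(syn), length(syn), mean(ext), length(ext), st$test, st$p_value))
}

writeLines(lines, file.path(out_root, "summary.txt"))
cat(paste(lines, collapse = "\n"), "\n")
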