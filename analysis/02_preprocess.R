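#!/usr/bin/env Rscript
# Applies the correction chain to the artifact-laden phantom: background
# phase (eddy current) removal fitted on static tissue, then venc
# anti-aliasing, and verifies both against the recorded ground truth.

suppressMessages(library(aortaflow))
src <- "results/phantoms/artifacts"
if (!dir.exists(src)) stop("run analysis/01_simulate.R first")
ds <- read_dataset(src)
aux <- readRDS(file.path(src, "truth.rds"))

ds <- correct_maxwell_terms(ds)

ec <- correct_eddy_currents(ds, aux$static, order = 1)
err <- max(vapply(1:3, function(c)
  max(abs(sweep(ec$coeffs[[c]], 2, aux$spec$eddy_coeffs[[c]]))), numeric(1)))
message(sprintf("eddy coefficients recovered to %.2e m/s", err))

ua <- unalias_velocity(ec$ds)
wr <- aux$truth$wrapped_voxels
hit <- sum(vapply(1:3, function(c) sum(wr[[c]] %in% ua$corrected_idx[[c]]),
                  numeric(1)))
message(sprintf("unaliasing: %d corrections, %.1f%% of %d injected wraps hit",
                sum(ua$correction_count), 100 * hit / sum(lengths(wr)),
                sum(lengths(wr))))

pk <- find_peak_systole(ua$ds, aux$lumen)
message(sprintf("peak systole frame %d (truth %d), window5 = {%s}",
                pk$t_peak, aux$truth$t_peak,
                paste(pk$window5, collapse = ",")))

out <- "results/phantoms/artifacts_corrected"
write_dataset(ua$ds, out)
saveRDS(list(peak = pk, eddy_coeffs = ec$coeffs,
             correction_count = ua$correction_count),
        file.path(out, "preprocess.rds"))
message("corrected dataset written to ", out)
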