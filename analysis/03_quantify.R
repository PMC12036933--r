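#!/usr/bin/env Rscript
# Stereological quantification per bird and region: pooled areal densities of
# the counted phenotypes, Cavalieri region volumes from the section outline
# areas (thickness 6 um, sampling interval 8), and extrapolated total cells.

library(somamorph)

study <- read_study("results/study")
quant <- quantify_regions(study)
readr::write_tsv(quant, "results/quantification.tsv")

agg <- dplyr::summarise(
  dplyr::group_by(quant, region, phenotype, group),
  mean_density = mean(density_per_mm2),
  mean_volume = mean(volume_mm3),
  mean_total = mean(total_cells), .groups = "drop")
print(as.data.frame(agg), digits = 4)
cat("per-bird quantification written to results/quantification.tsv\n")
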