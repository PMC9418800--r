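#!/usr/bin/env Rscript
# Propagate the attribution ratios through dietary methylmercury exposure
# to the two health endpoints: IQ decrements of the newborn cohort and
# fatal heart attacks of adults, monetized per country-year.

library(asgmrisk)
library(dplyr)

world <- reference_world()
res <- run_pipeline(world)

dir.create("results", showWarnings = FALSE)
write.csv(res$country_year, "results/country_year.csv", row.names = FALSE)
write.csv(res$global_year, "results/global_year.csv", row.names = FALSE)

g12 <- res$global_year |> filter(year == 2012)
cat(sprintf("2012 global ASGM burden: %.3g IQ points, %.0f FHA deaths\n",
            g12$dIQ, g12$dCF))
cat(sprintf("2012 monetized loss: $%.2fB (IQ $%.2fB, FHA $%.2fB)\n",
            g12$H_total / 1e9, g12$H_IQ / 1e9, g12$H_FHA / 1e9))

by_region <- aggregate_impacts(res, world, "region", years = 2012)
print(arrange(by_region, desc(share)))
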