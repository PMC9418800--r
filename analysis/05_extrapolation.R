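#!/usr/bin/env Rscript
# Extend the ASGM emission estimate beyond the 2012 inventory using four
# gold-market proxies (price, mine production, demand, supply), each
# rebased on its 2012 value, and their unweighted mean.

library(asgmrisk)

world <- reference_world()
ex <- extrapolate_by_proxy(world$emissions, world$proxies, 2013:2021)

dir.create("results", showWarnings = FALSE)
write.csv(ex, "results/emissions_extrapolated.csv", row.names = FALSE)

m <- ex[ex$proxy == "multi_proxy_mean", ]
pp <- ex[ex$proxy != "multi_proxy_mean", ]
cat(sprintf("multi-proxy mean emission 2021: %.0f t (per-proxy %.0f-%.0f t over 2013-2021)\n",
            m$mass_t[m$year == 2021], min(pp$mass_t), max(pp$mass_t)))
print(tidyr::pivot_wider(ex[ex$year %in% c(2013, 2017, 2021), ],
                         names_from = "proxy", values_from = "mass_t"))
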