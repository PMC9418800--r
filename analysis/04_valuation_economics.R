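#!/usr/bin/env Rscript
# Compare the discounted health losses against gold-mining revenue, and
# recompute the headline economic identities from the published inputs:
# the 6.1%/yr loss growth, the 48.3% cumulative loss-to-earning ratio, the
# ~20% 2012 ratio, the 53% IQ share, the 1.5x miner-risk comparison and
# the $300M retort program cost.

library(asgmrisk)

world <- reference_world()
res <- run_pipeline(world)
a <- function(q) world$published$value[world$published$quantity == q]

cat(sprintf("pipeline cumulative discounted loss: $%.0fB, revenue: $%.0fB (ratio %.0f%%)\n",
            res$economics$cumulative_loss / 1e9,
            res$economics$cumulative_revenue / 1e9,
            100 * res$economics$loss_earning$cumulative))

growth <- geometric_growth_rate(a("loss_1970"), a("loss_2012"), 42)
cat(sprintf("loss growth 1970-2012 from published endpoints: %.1f%%/yr\n",
            100 * growth))
cum <- loss_earning_ratio(a("cumulative_loss_1970_2012"),
                          a("cumulative_revenue_1970_2012"))$cumulative
cat(sprintf("published cumulative loss:earning: %.1f%%; 2012: %.1f%%\n",
            100 * cum,
            100 * loss_earning_ratio(a("loss_2012"), a("revenue_2012"))$cumulative))
comp <- monetize(1, 1, el = a("h_iq_2012"), vsl = a("h_fha_2012"))
cat(sprintf("IQ share of the 2012 loss: %.0f%%\n", 100 * comp$H_IQ / comp$H_total))
cat(sprintf("general-population vs miner risk: %.1fx\n",
            miner_vs_global_ratio(a("loss_2012"),
                                  a("total_mehg_loss_all_sources"),
                                  a("miner_risk_fraction"))))
cat(sprintf("retort program (15M miners at $20): $%.0fM\n",
            intervention_cost(a("n_miners"), a("retort_unit_cost")) / 1e6))
cat(sprintf("gold revenue: $%.0fM (1970) -> $%.1fB (2012)\n",
            world$gold$revenue_usd[1] / 1e6,
            world$gold$revenue_usd[world$gold$year == 2012] / 1e9))
write_results(res, "results")
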