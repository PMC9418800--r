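# Calibrated defaults for the six-compartment annual mercury cycle.
# Annual first-order transfer fractions (yr^-1, applied to start-of-year
# mass). Calibration anchors: atmospheric lifetime ~0.6 yr; a large legacy
# soil reservoir; 2012 ASGM attribution ratios near 12.2% (deposition),
# 10.4% (plankton MeHg) and 0.63% (soil Hg) when driven by the packaged
# 1970-2012 ASGM emission series against the all-sources steady baseline.
atm_dep: 0.80          # fraction of atmospheric Hg deposited per year
f_land: 0.40           # land share of deposition (ocean gets 1 - f_land)
land_split: [0.60, 0.30, 0.10]   # deposition split fast/slow/armored soil
r_fast: 0.02           # fast-soil re-emission to atmosphere
a_fs: 0.10             # fast -> slow soil aging
r_slow: 0.01           # slow-soil re-emission
a_sa: 0.0022           # slow -> armored soil aging
r_arm: 0.001           # armored-soil re-emission
k_ev: 0.10             # surface-ocean evasion to atmosphere
k_dw: 0.40             # surface -> subsurface downwelling
k_up: 0.0045           # subsurface -> surface upwelling
k_bur: 0.02            # subsurface burial (permanent loss)
all_sources_emission_t: 3595.4   # constant all-sources emission, t/yr
earth_area_m2: 5.1e+14  # for deposition flux in ug m-2 yr-1
p_yield: 5.1536e-04     # plankton MeHg (fmol/L) per t surface-ocean Hg
s_yield: 5.0723e-05     # soil Hg concentration (ng/g) per t soil Hg
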