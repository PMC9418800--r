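# Shared fixtures, built once per test run.
small_cfg <- synthetic_world_config(n_countries = 6, seed = 7)
small_world <- generate_world(small_cfg)

ref_world <- reference_world()
ref_pipeline <- run_pipeline(ref_world)

# a hand-checkable demography: one country, equal genders
toy_demog <- tibble::tibble(gender = c("male", "female"),
                            pop = c(1e6, 1e6),
                            fha_incidence = c(2e-3, 1e-3))
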