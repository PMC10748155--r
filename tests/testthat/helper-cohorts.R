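# Shared fixtures are generated in code; no data files.

# 1/8-scale page used by the tiny compute profile
TINY_PAGE_W <- round(3187 / 8)
TINY_PAGE_H <- round(1840 / 8)

# Cohort with severe-AS prevalence 0.3 and no other disease, with the
# disease signature planted in the chosen modalities.
make_as_cohort <- function(n, seed, pcg_effect = 1, ecg_effect = 0,
                           severe = 0.3) {
  generate_cohort(
    n,
    prevalences = list(
      AS = c(none = 1 - severe, mild = 0, moderate = 0, severe = severe),
      MR = c(none = 1, mild = 0, moderate = 0, severe = 0),
      LVD = c(none = 1, mild = 0, moderate = 0, severe = 0)),
    seed = seed,
    effect_size = list(pcg = pcg_effect, ecg = ecg_effect),
    page_width = TINY_PAGE_W, page_height = TINY_PAGE_H)
}

random_logmel_grid <- function(nt = 40, nm = 16) {
  matrix(rnorm(nt * nm), nt, nm)
}
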