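# compact builder for subject rows in tests; defaults are a well-formed
# asymptomatic volunteer with nothing detected and a negative panel
make_subjects <- function(n = 1, id = sprintf("T%03d", seq_len(n)),
                          cohort = "asymptomatic", age = 70, sex = "female",
                          freq = 0, urg = 0, dys = 0, pain = 0, blood = 0,
                          mpcr_bact = 0, mpcr_yeast = 0,
                          suc_bact = 0, suc_yeast = 0,
                          ngal = 1, il8 = 1, il1b = 4) {
  tibble::tibble(
    id = id, cohort = cohort, age = age, sex = sex,
    freq = freq, urg = urg, dys = dys, pain = pain, blood = blood,
    mpcr_bact_density = mpcr_bact, mpcr_yeast_density = mpcr_yeast,
    suc_bact_density = suc_bact, suc_yeast_density = suc_yeast,
    ngal_ng_ml = ngal, il8_pg_ml = il8, il1b_pg_ml = il1b
  )
}
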