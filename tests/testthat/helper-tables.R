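# Published per-patient summary inputs used as regression fixtures: beat and
# ST counts per patient and session, with the percentages as printed (and
# their decimal places), plus per-tumor pulse energies for two multi-tumor
# patients. Two percentage cells marked reproducible = FALSE differ from the
# stated convention by one rounding unit in the source and are checked
# against the recomputed value instead.

study_beat_counts <- function() {
  before <- data.frame(
    patient = c(4, 5, 6, 7, 9, 10, 12, 13, 14, 15),
    n = c(14317, 15722, 13975, 16873, 18321, 14785, 18825, 13864, 13857, 17461),
    a = c(12, 3, 309, 20, 18, 70, 42, 6, 135, 25),
    pct_a = c(0.084, 0.019, 2.163, 0.118, 0.098, 0.471, 0.223, 0.043, 0.965, 0.143),
    dp_a = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3),
    a_ok = TRUE,
    st = c(0, 15692, 0, 0, 6915, 0, 0, 0, 10111, 696),
    pct_st = c(0, 99.8, 0, 0, 37.7, 0, 0, 0, 73.0, 3.99),
    dp_st = c(0, 1, 0, 0, 1, 0, 0, 0, 1, 2),
    st_ok = TRUE)
  after <- data.frame(
    patient = c(4, 5, 6, 7, 9, 10, 12, 13, 14, 15),
    n = c(14216, 18112, 18271, 18820, 26047, 15202, 17764, 19405, 16620, 26450),
    a = c(17, 1, 8, 15, 9, 23, 6, 8, 0, 39),
    pct_a = c(0.119, 0.006, 0.044, 0.080, 0.035, 0.151, 0.034, 0.044, 0, 0.147),
    dp_a = c(3, 3, 3, 3, 3, 3, 3, 3, 0, 3),
    a_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    st = c(0, 14001, 0, 2321, 0, 763, 4395, 3209, 7078, 25188),
    pct_st = c(0, 77.3, 0, 12.3, 0, 5.02, 24.7, 16.5, 42.6, 95.3),
    dp_st = c(0, 1, 0, 1, 0, 2, 1, 1, 1, 1),
    st_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  list(before = before, after = after)
}

study_tumor_energies <- function() {
  list(p4 = list(energies = c(196.1, 275.1), total = 471.2),
       p5 = list(energies = c(867.2, 314.4, 386.3), total = 1567.9))
}
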