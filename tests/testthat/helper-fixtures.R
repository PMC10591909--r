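# Fixtures are built in code: exact-exponential curves (for which eGR has a
# closed form) and small simulated studies.

exp_curve <- function(mouse, group, k, tv0 = 200,
                      days = c(0, 4, 7, 10, 14, 18, 21)) {
  tibble::tibble(mouse = mouse, group = group, day = days,
                 tv = tv0 * exp(k * days))
}

# Four-group study of exact exponentials with the given per-group rates;
# each group has length(k) == 1 rate replicated n times, or one rate per
# mouse if a vector is supplied.
exp_study <- function(k = c(C = 0.099, A = 0.066, B = 0.073, AB = 0.030),
                      n = 3, tv0 = 200, days = c(0, 4, 7, 10, 14, 18, 21)) {
  rows <- list()
  for (g in names(k)) {
    kg <- rep_len(k[[g]], n)
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <-
        exp_curve(paste0(g, i), g, kg[i], tv0 = tv0, days = days)
    }
  }
  as_study_dataset(dplyr::bind_rows(rows))
}

# A noisy-but-analyzable study for property tests (mouse-level rate jitter).
jitter_study <- function(seed, n = 4, k = c(C = 0.10, A = 0.07, B = 0.08, AB = 0.04),
                         sd = 0.015) {
  set.seed(seed)
  rows <- list()
  for (g in names(k)) {
    for (i in seq_len(n)) {
      ki <- stats::rnorm(1, k[[g]], sd)
      rows[[length(rows) + 1L]] <-
        exp_curve(paste0(g, i), g, ki,
                  tv0 = stats::rlnorm(1, log(200), 0.2))
    }
  }
  as_study_dataset(dplyr::bind_rows(rows))
}
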