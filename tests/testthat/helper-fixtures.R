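## shared fixtures: everything is generated in code at test time

default_kc <- kinetic_constants()

## ten noise-free records spanning the physiological range, some with SPAD
make_records <- function(n = 10, seed = 42) {
  withr::local_seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    p <- sim_leaf_params(vcmax = runif(1, 80, 150), j = runif(1, 120, 200),
                         gm = runif(1, 0.1, 0.4), gsw = runif(1, 0.3, 1.0))
    r <- simulate_record(p, record_id = sprintf("r%02d", i),
                         line_id = sprintf("L%02d", i))
    if (i %% 3 == 0) r$spad <- round(runif(1, 35, 48), 1)
    r
  })
  dplyr::bind_rows(rows)
}

## RuBP-regeneration-limited parameter draws (J well below what Rubisco
## supports), the regime where the variable-J inversion is exact
draw_rubp_limited <- function(n, seed) {
  withr::local_seed(seed)
  tibble::tibble(
    vcmax = runif(n, 150, 250),
    j = runif(n, 90, 160),
    gm = runif(n, 0.1, 0.4),
    gsw = runif(n, 0.3, 1.0),
    rd = runif(n, 0.5, 1.5)
  )
}
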