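# shared fixtures built in code

meth_cols <- paste0("cg17330251_", 1:12)

# a small default-config cohort, scored
small_scored_cohort <- function(n = 120, seed = 11) {
  score_cohort(generate_cohort(cohort_config(n = n, seed = seed)))
}

# a null configuration: genotype-independent methylation, no methylation
# effect on the DAS28 improvement
null_config <- function(n = 240, seed = 1) {
  cohort_config(
    n = n,
    meth_median = c(CC = 0.363, CT = 0.363, TT = 0.363),
    meth_q25 = c(CC = 0.332, CT = 0.332, TT = 0.332),
    meth_q75 = c(CC = 0.395, CT = 0.395, TT = 0.395),
    meth_effect_on_delta = 0,
    seed = seed
  )
}

# random contingency table with all margins positive
random_table <- function(nr = 2, nc = 2, lambda = 8) {
  repeat {
    m <- matrix(stats::rpois(nr * nc, lambda) + 1L, nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
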