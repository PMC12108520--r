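# shared fixtures built in code

small_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_herd(generator_config(n_records = 2000, seed = 1))
    }
    cache
  }
})

published_optimum <- function(temperature = 20) {
  c(tmr_dm_pct = 46.77, lactation_number = 5, lactation_day = 6,
    gestation_day = 230, age_months = 55.8, temperature_c = temperature)
}

# random 3-factor bi-objective problem over a random box; anchors span the
# exact attainable range of each linear objective (vertex extremes)
random_problem <- function(seed) {
  withr::with_seed(seed, {
    k <- 3
    nm <- c("a", "b", "c")
    lb <- setNames(runif(k, -1, 0), nm)
    ub <- lb + runif(k, 0.5, 2)
    make_model <- function() {
      fixed_herd_model(setNames(c(runif(1, -1, 1), runif(k, -2, 2)),
                                c("(Intercept)", nm)))
    }
    vertex_range <- function(m) {
      v <- as.matrix(expand.grid(purrr::map(seq_len(k),
                                            function(j) c(lb[j], ub[j]))))
      range(m$coefficients[1] + v %*% m$coefficients[-1])
    }
    m1 <- make_model(); m2 <- make_model()
    r1 <- vertex_range(m1); r2 <- vertex_range(m2)
    optimization_problem(
      list(objective_spec(m1, "maximize", r1[1], r1[2], name = "y1"),
           objective_spec(m2, "minimize", r2[1], r2[2], name = "y2")),
      lb, ub
    )
  })
}
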