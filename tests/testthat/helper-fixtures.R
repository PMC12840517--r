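# Shared fixtures: tiny hand-built cohorts and small simulated benchmarks.

# a minimal manifest row
make_stay <- function(stay_id = "A", age = 50, gender = "male",
                      icu_los_h = 48, death_time_h = NA_real_,
                      trauma_flag = TRUE,
                      suspected_infection_time_h = NA_real_) {
  data.frame(stay_id = stay_id, age = age, gender = gender,
             icu_los_h = icu_los_h, death_time_h = death_time_h,
             trauma_flag = trauma_flag,
             suspected_infection_time_h = suspected_infection_time_h)
}

make_events <- function(stay_id, time_h, variable, value, unit = "") {
  data.frame(stay_id = stay_id, time_h = time_h, variable = variable,
             value = value, unit = unit)
}

empty_events <- function() {
  data.frame(stay_id = character(), time_h = numeric(),
             variable = character(), value = numeric(), unit = character())
}

# a small labeled synthetic split reused by model-level tests; built once
# per test run
small_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- transfer_benchmark(pool_n = 120, cohort_n = 90, seed = 404)
      cache <<- prepare_benchmark_data(bench, seed = 404)
    }
    cache
  }
})

# independent SOFA cut-off oracle: explicit if-chains, written separately
# from the implementation's findInterval bands
oracle_sofa <- function(organ, x) {
  if (is.na(x)) return(0L)
  switch(organ,
    respiration = if (x < 100) 4L else if (x < 200) 3L else if (x < 300) 2L
                  else if (x < 400) 1L else 0L,
    coagulation = if (x < 20) 4L else if (x < 50) 3L else if (x < 100) 2L
                  else if (x < 150) 1L else 0L,
    liver = if (x >= 12) 4L else if (x >= 6) 3L else if (x >= 2) 2L
            else if (x >= 1.2) 1L else 0L,
    cns = if (x < 6) 4L else if (x < 10) 3L else if (x < 13) 2L
          else if (x < 15) 1L else 0L,
    renal = if (x >= 5) 4L else if (x >= 3.5) 3L else if (x >= 2) 2L
            else if (x >= 1.2) 1L else 0L)
}

# naive probability-space binary cross-entropy (oracle for the stable
# logit-space implementation)
oracle_bce <- function(logits, labels) {
  p <- 1 / (1 + exp(-logits))
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}
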