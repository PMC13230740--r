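# Run-spec parsing, simulated rig execution, triggers, flow monitoring.

test_that("a minimal spec parses with defaulted round conditions", {
  spec <- parse_run_spec(minimal_spec_text(3))
  expect_s3_class(spec, "run_spec")
  expect_equal(spec$n_rounds, 3L)
  expect_equal(length(spec$steps), 3L)
  expect_identical(spec$steps[[1]]$rounds, "all")
})

test_that("parse errors name the offending step", {
  bad_buf <- "
n_rounds: 2
buffers: {wash: {kind: syringe, address: 1}}
steps:
  - {id: oops, action: flush, buffer: nope, volume_ml: 1, rate_ml_per_min: 1}
"
  expect_error(parse_run_spec(bad_buf), "oops.*unknown buffer")
  bad_round <- "
n_rounds: 2
buffers: {wash: {kind: syringe, address: 1}}
steps:
  - {id: late, action: flush, buffer: wash, volume_ml: 1, rate_ml_per_min: 1,
     rounds: [5]}
"
  expect_error(parse_run_spec(bad_round), "late.*out of range")
  expect_error(parse_run_spec("n_rounds: 0\nbuffers: {a: {kind: syringe, address: 1}}\nsteps: []"),
               "n_rounds")
})

test_that("round-conditioned steps execute in exactly their rounds", {
  txt <- "
n_rounds: 3
buffers:
  wash: {kind: syringe, address: 1}
  dapi: {kind: syringe, address: 2}
steps:
  - {id: wash,  action: flush, buffer: wash, volume_ml: 0.5, rate_ml_per_min: 1}
  - {id: stain, action: flush, buffer: dapi, volume_ml: 0.2, rate_ml_per_min: 1,
     rounds: [1]}
  - {id: image, action: image}
"
  spec <- parse_run_spec(txt)
  log <- run_experiment(simulated_rig(seed = 1), spec, ttl_trigger_mock())
  stain_starts <- log[log$kind == "pump_start" & log$step_id == "stain", ]
  expect_equal(nrow(stain_starts), 1)
  expect_equal(stain_starts$round, 1)
})

test_that("flush arithmetic: durations, volumes and bookkeeping are exact", {
  txt <- "
n_rounds: 1
buffers: {w: {kind: syringe, address: 1}}
steps:
  - {id: f, action: flush, buffer: w, volume_ml: 0.5, rate_ml_per_min: 0.5}
"
  rig <- simulated_rig(seed = 1)
  log <- run_experiment(rig, txt |> parse_run_spec(), ttl_trigger_mock())
  t_start <- log$t[log$kind == "pump_start"]
  t_stop <- log$t[log$kind == "pump_stop"]
  expect_equal(t_stop - t_start, 60)          # 0.5 mL at 0.5 mL/min
  expect_equal(rig$syringes[["1"]], 50 - 0.5, tolerance = 1e-12)
  expect_equal(unname(attr(log, "dispensed_ml")["w"]), 0.5,
               tolerance = 1e-12)
})

test_that("overdrawing a 2 mL well halts with an error event", {
  txt <- "
n_rounds: 2
buffers: {hyb: {kind: plate, address: A1}}
steps:
  - {id: h, action: flush, buffer: hyb, volume_ml: 1.2, rate_ml_per_min: 1}
"
  rig <- simulated_rig(seed = 1)
  log <- run_experiment(rig, parse_run_spec(txt), ttl_trigger_mock())
  expect_true(rig$halted)
  err <- log[log$kind == "error", ]
  expect_equal(nrow(err), 1)
  expect_match(err$payload, "well_overdraw")
  expect_match(err$payload, "0.4")           # deficit: 2.4 requested of 2.0
  # first flush succeeded, second never pumped
  expect_equal(sum(log$kind == "pump_start"), 1)
})

test_that("templated plate wells resolve per round", {
  spec <- parse_run_spec(minimal_spec_text(3))
  rig <- simulated_rig(seed = 2)
  log <- run_experiment(rig, spec, ttl_trigger_mock())
  asp <- log[log$kind == "aspirate", ]
  expect_equal(nrow(asp), 3)
  expect_true(all(vapply(1:3, function(r)
    grepl(sprintf('"well":"A%d"', r), asp$payload[asp$round == r]),
    logical(1))))
  expect_setequal(names(rig$wells), c("A1", "A2", "A3"))
})

test_that("a full 20-round run pairs armed/done strictly and in order", {
  spec <- parse_run_spec(minimal_spec_text(20))
  log <- run_experiment(simulated_rig(seed = 3), spec,
                        ttl_trigger_mock(delay_s = 3))
  armed <- which(log$kind == "trigger_armed")
  done <- which(log$kind == "acquisition_done")
  expect_equal(length(armed), 20)
  expect_equal(length(done), 20)
  expect_true(all(done - armed == 1))         # strict alternation
  expect_true(all(diff(log$t) >= 0))          # monotone clock
})

test_that("clock advance equals the sum of step durations", {
  txt <- "
n_rounds: 2
buffers: {w: {kind: syringe, address: 1}}
steps:
  - {id: f, action: flush, buffer: w, volume_ml: 1, rate_ml_per_min: 2}
  - {id: i, action: incubate, incubate_s: 300}
  - {id: p, action: pause, duration_s: 12.5}
  - {id: image, action: image}
"
  rig <- simulated_rig(seed = 4)
  run_experiment(rig, parse_run_spec(txt), ttl_trigger_mock(delay_s = 7))
  expect_equal(rig$t, 2 * (30 + 300 + 12.5 + 7), tolerance = 1e-12)
})

test_that("volume conservation holds to 1e-9 mL over a long run", {
  spec <- parse_run_spec(minimal_spec_text(20))
  rig <- simulated_rig(seed = 5)
  log <- run_experiment(rig, spec, ttl_trigger_mock())
  disp <- attr(log, "dispensed_ml")
  # wash: 20 x 1.0 from the syringe; hyb: 0.5 per round from plate wells
  expect_lt(abs(disp[["wash"]] - 20), 1e-9)
  expect_lt(abs(disp[["hyb"]] - 10), 1e-9)
  expect_lt(abs((50 - rig$syringes[["1"]]) - 20), 1e-9)
  expect_lt(abs(sum(2 - unlist(rig$wells)) - 10), 1e-9)
  # dispensed = sum(rate x pump interval) from the log itself
  starts <- log[log$kind == "pump_start", ]
  stops <- log[log$kind == "pump_stop", ]
  rates <- vapply(starts$payload, function(p)
    jsonlite::fromJSON(p)$rate_ml_per_min, numeric(1))
  expect_lt(abs(sum(rates * (stops$t - starts$t) / 60) - sum(disp)), 1e-9)
})

test_that("identical seeds give byte-identical serialized logs", {
  spec <- parse_run_spec(minimal_spec_text(5))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_event_log(run_experiment(simulated_rig(seed = 9), spec,
                                 ttl_trigger_mock()), f1)
  write_event_log(run_experiment(simulated_rig(seed = 9), spec,
                                 ttl_trigger_mock()), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fuzzed random specs keep the log invariants", {
  set.seed(6)
  for (i in 1:200) {
    n_rounds <- sample(1:4, 1)
    n_steps <- sample(1:4, 1)
    steps <- lapply(seq_len(n_steps), function(k) {
      act <- sample(c("flush", "incubate", "image", "pause"), 1)
      s <- switch(act,
        flush = list(id = paste0("s", k), action = "flush", buffer = "w",
                     volume_ml = round(runif(1, 0.1, 0.4), 3),
                     rate_ml_per_min = round(runif(1, 0.5, 2), 3)),
        incubate = list(id = paste0("s", k), action = "incubate",
                        incubate_s = sample(1:60, 1)),
        pause = list(id = paste0("s", k), action = "pause",
                     duration_s = sample(1:30, 1)),
        image = list(id = paste0("s", k), action = "image"))
      if (runif(1) < 0.3)
        s$rounds <- sort(sample(seq_len(n_rounds),
                                sample(seq_len(n_rounds), 1)))
      s
    })
    spec <- parse_run_spec(yaml::as.yaml(list(
      n_rounds = n_rounds,
      buffers = list(w = list(kind = "syringe", address = 1)),
      steps = steps)))
    log <- run_experiment(simulated_rig(seed = i), spec, ttl_trigger_mock())
    expect_true(all(diff(log$t) >= 0))
    armed <- which(log$kind == "trigger_armed")
    done <- which(log$kind == "acquisition_done")
    expect_equal(length(armed), length(done))
    if (length(armed)) expect_true(all(done > armed))
    # round-conditional correctness: each step appears |rounds| times
    for (s in steps) {
      expected <- if (is.null(s$rounds)) n_rounds else length(s$rounds)
      kind0 <- switch(s$action, flush = "pump_start", incubate = "incubate",
                      pause = "incubate", image = "trigger_armed")
      expect_equal(sum(log$kind == kind0 & log$step_id == s$id), expected)
    }
  }
})

test_that("flow anomalies are detected with duration and tolerance gates", {
  mk_trace <- function(mult, t0, t1, noise = 0.02, dur = 60, seed = 1) {
    set.seed(seed)
    t <- 1:dur
    m <- ifelse(t >= t0 & t < t1, mult, 1)
    data.frame(t = t, measured = 1 * m * (1 + rnorm(dur, 0, noise)),
               expected = 1)
  }
  # clean traces: no false alarms over 100 runs
  fa <- vapply(1:100, function(s)
    nrow(detect_flow_anomaly(mk_trace(1, 0, 0, seed = s), 0.2, 5)),
    numeric(1))
  expect_equal(sum(fa), 0)
  # a 10 s, 90% drop: one interval within a sample of its extent
  a <- detect_flow_anomaly(mk_trace(0.1, 20, 30), 0.2, 5)
  expect_equal(nrow(a), 1)
  expect_lte(abs(a$t0 - 20), 1)
  expect_lte(abs(a$t1 + 1 - 30), 1)
  # 3 s drop under a 5 s minimum: nothing
  expect_equal(nrow(detect_flow_anomaly(mk_trace(0.1, 20, 23), 0.2, 5)), 0)
  # pump-off samples (expected 0) are excluded
  tr <- mk_trace(0.1, 20, 30)
  tr$expected[1:10] <- 0
  expect_equal(nrow(detect_flow_anomaly(tr, 0.2, 5)), 1)
  # scheduled rig anomaly surfaces as an anomaly event during the flush
  rig <- simulated_rig(seed = 2,
                       anomalies = data.frame(t0 = 10, t1 = 20,
                                              multiplier = 0.1))
  txt <- "
n_rounds: 1
buffers: {w: {kind: syringe, address: 1}}
steps:
  - {id: f, action: flush, buffer: w, volume_ml: 1, rate_ml_per_min: 1}
"
  log <- run_experiment(rig, parse_run_spec(txt), ttl_trigger_mock())
  expect_equal(sum(log$kind == "anomaly"), 1)
  expect_false(rig$halted)                    # run continues, flagged
})

test_that("file triggers handshake in both content and existence modes", {
  td <- withr::local_tempdir()
  trig <- file_trigger(td, "content", responder = mock_acquirer(5))
  spec <- parse_run_spec(minimal_spec_text(2))
  log <- run_experiment(simulated_rig(seed = 7), spec, trig)
  expect_equal(sum(log$kind == "acquisition_done"), 2)
  done_t <- log$t[log$kind == "acquisition_done"]
  armed_t <- log$t[log$kind == "trigger_armed"]
  expect_equal(done_t - armed_t, c(5, 5))
  # existence mode: file created by arm, deleted by the mock
  trig2 <- file_trigger(td, "existence", responder = mock_acquirer(2))
  log2 <- run_experiment(simulated_rig(seed = 8), spec, trig2)
  expect_equal(sum(log2$kind == "acquisition_done"), 2)
  expect_false(file.exists(trig2$path))
  # no responder: timeout error, clean abort with the log intact
  trig3 <- file_trigger(td, "content")
  rig3 <- simulated_rig(seed = 9, trigger_timeout_s = 10)
  log3 <- run_experiment(rig3, spec, trig3)
  expect_true(rig3$halted)
  expect_match(log3$payload[log3$kind == "error"], "trigger_timeout")
  expect_equal(sum(log3$kind == "trigger_armed"), 1)
})

test_that("the TTL mock pulses strictly alternate and timeouts abort", {
  spec <- parse_run_spec(minimal_spec_text(2))
  trig <- ttl_trigger_mock(delay_s = 3)
  log <- run_experiment(simulated_rig(seed = 10), spec, trig)
  expect_equal(length(trig$state$out_pulses), 2)
  expect_equal(length(trig$state$in_pulses), 2)
  expect_equal(trig$state$in_pulses - trig$state$out_pulses, c(3, 3))
  # in/out pulses interleave: out1 < in1 < out2 < in2
  seqs <- c(rbind(trig$state$out_pulses, trig$state$in_pulses))
  expect_true(all(diff(seqs) > 0))
  # a missing in-pulse aborts with the log intact
  trig2 <- ttl_trigger_mock(delay_s = 3, respond_rounds = 1)
  rig2 <- simulated_rig(seed = 11, trigger_timeout_s = 30)
  log2 <- run_experiment(rig2, spec, trig2)
  expect_true(rig2$halted)
  expect_equal(sum(log2$kind == "acquisition_done"), 1)
  expect_equal(sum(log2$kind == "error"), 1)
})
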