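# fluidics: declarative run specifications executed on a fully simulated
# rig (valve, peristaltic pump, flow sensor, plate robot) in simulated
# time, with acquisition-trigger handshakes and a complete event log.
#
# Run specs are YAML (documented schema, version 1):
#   n_rounds: 3
#   buffers:
#     wash:    {kind: syringe, address: 1}
#     hyb:     {kind: plate,   address: "A{round}"}
#   steps:
#     - {id: hyb,    action: flush, buffer: hyb, volume_ml: 0.5,
#        rate_ml_per_min: 0.5}
#     - {id: inc,    action: incubate, incubate_s: 600}
#     - {id: wash,   action: flush, buffer: wash, volume_ml: 1.0,
#        rate_ml_per_min: 1.0}
#     - {id: image,  action: image}
#     - {id: dapi,   action: flush, buffer: wash, volume_ml: 0.2,
#        rate_ml_per_min: 0.5, rounds: [1]}
# `rounds` is "all" (default) or an explicit round list; `{round}` in a
# plate address resolves per round. `volume_ml` or `duration_s` defines a
# flush, together with `rate_ml_per_min`.

#' Parse a fluidic run specification
#'
#' Validates the YAML schema above into a `run_spec`. Buffer references,
#' step fields and round conditions are checked eagerly; `{round}`
#' templates in plate addresses resolve lazily at execution time.
#'
#' @param text YAML text, or a path to a YAML file.
#' @return A `run_spec` object.
#' @export
parse_run_spec <- function(text) {
  raw <- if (length(text) == 1L && file.exists(text) &&
             !grepl("\n", text)) yaml::read_yaml(text)
  else yaml::yaml.load(paste(text, collapse = "\n"))
  perr <- function(...) stop("run spec: ", ..., call. = FALSE)
  if (is.null(raw$n_rounds) || raw$n_rounds < 1) perr("n_rounds must be >= 1")
  n_rounds <- as.integer(raw$n_rounds)
  if (is.null(raw$buffers) || length(raw$buffers) == 0L)
    perr("at least one buffer required")
  buffers <- lapply(names(raw$buffers), function(bn) {
    b <- raw$buffers[[bn]]
    if (is.null(b$kind) || !b$kind %in% c("syringe", "plate"))
      perr("buffer '", bn, "': kind must be \"syringe\" or \"plate\"")
    if (is.null(b$address)) perr("buffer '", bn, "': address missing")
    if (b$kind == "syringe" && !grepl("^[0-9]+$", as.character(b$address)))
      perr("buffer '", bn, "': syringe address must be a port integer")
    list(name = bn, kind = b$kind, address = as.character(b$address))
  })
  names(buffers) <- names(raw$buffers)
  if (is.null(raw$steps) || length(raw$steps) == 0L) perr("no steps")
  steps <- lapply(seq_along(raw$steps), function(i) {
    s <- raw$steps[[i]]
    id <- s$id %||% paste0("step", i)
    serr <- function(...) perr("step '", id, "': ", ...)
    action <- s$action %||% serr("action missing")
    if (!action %in% c("flush", "incubate", "image", "pause"))
      serr("unknown action '", action, "'")
    rounds <- s$rounds %||% "all"
    if (!identical(rounds, "all")) {
      rounds <- as.integer(unlist(rounds))
      if (any(rounds < 1 | rounds > n_rounds))
        serr("round index out of range 1..", n_rounds)
    }
    if (action == "flush") {
      if (is.null(s$buffer)) serr("flush requires a buffer")
      if (!s$buffer %in% names(buffers))
        serr("unknown buffer reference '", s$buffer, "'")
      if (is.null(s$volume_ml) && is.null(s$duration_s))
        serr("flush requires volume_ml or duration_s")
      if (is.null(s$rate_ml_per_min) || s$rate_ml_per_min <= 0)
        serr("flush requires positive rate_ml_per_min")
      if (!is.null(s$volume_ml) && s$volume_ml <= 0) serr("volume_ml must be positive")
      if (!is.null(s$duration_s) && s$duration_s <= 0) serr("duration_s must be positive")
    }
    if (action == "incubate" &&
        (is.null(s$incubate_s) || s$incubate_s < 0))
      serr("incubate requires nonnegative incubate_s")
    if (action == "pause" && (is.null(s$duration_s) || s$duration_s < 0))
      serr("pause requires nonnegative duration_s")
    list(id = id, action = action, buffer = s$buffer,
         volume_ml = s$volume_ml, duration_s = s$duration_s,
         rate_ml_per_min = s$rate_ml_per_min, incubate_s = s$incubate_s,
         rounds = rounds)
  })
  structure(list(n_rounds = n_rounds, buffers = buffers, steps = steps,
                 schema_version = 1L),
            class = "run_spec")
}

#' Create a simulated fluidics rig
#'
#' Models the hardware only through its observable behaviour: a selector
#' valve, a peristaltic pump with a flow sensor sampling at a fixed period,
#' syringe reservoirs, a 96-well buffer plate (2 mL per well) reached by a
#' pipetting robot, and a monotone simulated clock. Time advances by step
#' durations only — nothing sleeps.
#'
#' @param n_ports Valve ports.
#' @param syringe_volume_ml Initial volume of each syringe reservoir.
#' @param well_capacity_ml Plate well capacity (and initial fill).
#' @param flow_noise_frac Relative SD of flow-sensor noise.
#' @param flow_sample_period_s Flow-sensor sampling period (s).
#' @param anomalies Optional data.frame `(t0, t1, multiplier)` of scheduled
#'   flow anomalies (e.g. a bubble: multiplier 0.1), in simulated seconds.
#' @param trigger_timeout_s Acquisition handshake timeout (simulated s).
#' @param seed Optional RNG seed, making logs byte-identical across runs.
#' @return A `simulated_rig` (environment).
#' @export
simulated_rig <- function(n_ports = 12L, syringe_volume_ml = 50,
                          well_capacity_ml = 2.0, flow_noise_frac = 0.02,
                          flow_sample_period_s = 1,
                          anomalies = NULL, trigger_timeout_s = 600,
                          seed = NULL) {
  rig <- new.env(parent = emptyenv())
  rig$t <- 0
  rig$valve_port <- NA_integer_
  rig$n_ports <- as.integer(n_ports)
  rig$pump_rate <- 0; rig$pump_running <- FALSE
  rig$syringes <- setNames(rep(syringe_volume_ml, n_ports),
                           as.character(seq_len(n_ports)))
  rig$well_capacity_ml <- well_capacity_ml
  rig$wells <- numeric(0)           # lazily initialised at capacity
  rig$flow_noise_frac <- flow_noise_frac
  rig$flow_sample_period_s <- flow_sample_period_s
  rig$anomalies <- anomalies
  rig$trigger_timeout_s <- trigger_timeout_s
  rig$seed <- seed
  rig$events <- list()
  rig$flow <- list()
  rig$dispensed <- numeric(0)       # per buffer name
  rig$halted <- FALSE
  class(rig) <- "simulated_rig"
  rig
}

rig_event <- function(rig, kind, ...) {
  payload <- list(...)
  rig$events[[length(rig$events) + 1L]] <- c(list(t = rig$t, kind = kind),
                                             payload)
  invisible(NULL)
}

anomaly_multiplier <- function(rig, t) {
  a <- rig$anomalies
  if (is.null(a) || nrow(a) == 0L) return(1)
  hit <- a$t0 <= t & t < a$t1
  if (any(hit)) prod(a$multiplier[hit]) else 1
}

resolve_template <- function(x, round) gsub("{round}", round, x, fixed = TRUE)

#' Execute one run-spec step on the rig
#'
#' `flush` selects the buffer's valve port (aspirating from the plate via
#' the robot if needed), runs the pump for `volume/rate` (or the given
#' duration), records flow-sensor samples, monitors them for anomalies, and
#' deducts the dispensed volume from the source. Over-aspirating a plate
#' well emits an `error` event and halts the rig. `incubate`/`pause`
#' advance the clock. `image` arms the acquisition trigger and waits
#' (in simulated time) for completion or timeout.
#'
#' @param rig A [simulated_rig()].
#' @param spec The parsed `run_spec` (for buffer lookups).
#' @param step One element of `spec$steps`.
#' @param round Current round (resolves `{round}` templates).
#' @param trigger Trigger object for `image` steps (see [file_trigger()],
#'   [ttl_trigger_mock()]).
#' @return `TRUE` if the run may continue, `FALSE` on halt.
#' @export
execute_step <- function(rig, spec, step, round, trigger = NULL) {
  if (rig$halted) return(FALSE)
  switch(step$action,
    incubate = {
      rig_event(rig, "incubate", step_id = step$id, round = round,
                duration_s = step$incubate_s)
      rig$t <- rig$t + step$incubate_s
      TRUE
    },
    pause = {
      rig_event(rig, "incubate", step_id = step$id, round = round,
                duration_s = step$duration_s, action = "pause")
      rig$t <- rig$t + step$duration_s
      TRUE
    },
    image = {
      if (is.null(trigger)) stop("image step requires a trigger")
      rig_event(rig, "trigger_armed", step_id = step$id, round = round)
      delay <- trigger$arm_and_wait(round, rig$t)
      if (is.finite(delay) && delay <= rig$trigger_timeout_s) {
        rig$t <- rig$t + delay
        rig_event(rig, "acquisition_done", step_id = step$id, round = round)
        TRUE
      } else {
        rig$t <- rig$t + rig$trigger_timeout_s
        rig_event(rig, "error", step_id = step$id, round = round,
                  reason = "trigger_timeout")
        rig$halted <- TRUE
        FALSE
      }
    },
    flush = {
      buf <- spec$buffers[[step$buffer]]
      address <- resolve_template(buf$address, round)
      if (!is.null(step$volume_ml)) {
        volume <- step$volume_ml
        duration <- volume / step$rate_ml_per_min * 60
      } else {
        duration <- step$duration_s
        volume <- step$rate_ml_per_min * duration / 60
      }
      if (buf$kind == "syringe") {
        port <- as.integer(address)
        rig$valve_port <- port
        rig_event(rig, "valve_select", step_id = step$id, round = round,
                  port = port, buffer = buf$name)
        if (rig$syringes[address] < volume - 1e-9) {
          rig_event(rig, "error", step_id = step$id, round = round,
                    reason = "syringe_empty", buffer = buf$name,
                    deficit_ml = volume - rig$syringes[address])
          rig$halted <- TRUE
          return(FALSE)
        }
      } else {
        if (!address %in% names(rig$wells))
          rig$wells[address] <- rig$well_capacity_ml
        rig_event(rig, "aspirate", step_id = step$id, round = round,
                  well = address, buffer = buf$name)
        rig$valve_port <- rig$n_ports      # plate line on the last port
        rig_event(rig, "valve_select", step_id = step$id, round = round,
                  port = rig$n_ports, buffer = buf$name)
        if (rig$wells[address] < volume - 1e-9) {
          rig_event(rig, "error", step_id = step$id, round = round,
                    reason = "well_overdraw", well = address,
                    deficit_ml = volume - rig$wells[address])
          rig$halted <- TRUE
          return(FALSE)
        }
      }
      rig$pump_rate <- step$rate_ml_per_min; rig$pump_running <- TRUE
      rig_event(rig, "pump_start", step_id = step$id, round = round,
                rate_ml_per_min = step$rate_ml_per_min)
      t0 <- rig$t
      ts <- seq(rig$flow_sample_period_s, duration,
                by = rig$flow_sample_period_s)
      if (length(ts)) {
        mult <- vapply(t0 + ts, function(tt) anomaly_multiplier(rig, tt),
                       numeric(1))
        measured <- step$rate_ml_per_min * mult *
          (1 + rnorm(length(ts), 0, rig$flow_noise_frac))
        rig$flow[[length(rig$flow) + 1L]] <- data.frame(
          t = t0 + ts, measured = measured,
          expected = step$rate_ml_per_min, step_id = step$id, round = round)
        anom <- detect_flow_anomaly(
          data.frame(t = t0 + ts, measured = measured,
                     expected = step$rate_ml_per_min),
          tolerance_frac = 0.2, min_duration_s = 5,
          sample_period_s = rig$flow_sample_period_s)
        for (k in seq_len(nrow(anom)))
          rig_event(rig, "anomaly", step_id = step$id, round = round,
                    t0 = anom$t0[k], t1 = anom$t1[k],
                    duration_s = anom$duration_s[k])
      }
      rig$t <- t0 + duration
      rig$pump_running <- FALSE
      rig_event(rig, "pump_stop", step_id = step$id, round = round,
                dispensed_ml = volume)
      if (buf$kind == "syringe") {
        rig$syringes[address] <- rig$syringes[address] - volume
      } else {
        rig$wells[address] <- rig$wells[address] - volume
      }
      rig$dispensed[buf$name] <- (rig$dispensed[buf$name] %||% 0)
      if (is.na(rig$dispensed[buf$name])) rig$dispensed[buf$name] <- 0
      rig$dispensed[buf$name] <- rig$dispensed[buf$name] + volume
      TRUE
    },
    stop("unknown action: ", step$action)
  )
}

#' Run a full sequential experiment on the simulated rig
#'
#' Executes the spec round by round: every step whose round condition
#' includes the current round runs in order; `image` steps perform the
#' trigger handshake. On a trigger timeout or an over-drawn well the run
#' aborts cleanly with the log intact. Deterministic given the rig seed.
#'
#' @param rig A [simulated_rig()].
#' @param spec A [parse_run_spec()] result.
#' @param trigger Trigger object ([file_trigger()] / [ttl_trigger_mock()]).
#' @return An `event_log` data.frame `(t, kind, round, step_id, payload)`
#'   with attributes `flow_trace` (data.frame) and `dispensed_ml`
#'   (named vector per buffer).
#' @export
run_experiment <- function(rig, spec, trigger) {
  stopifnot(inherits(rig, "simulated_rig"), inherits(spec, "run_spec"))
  if (!is.null(rig$seed)) set.seed(rig$seed)
  for (round in seq_len(spec$n_rounds)) {
    for (step in spec$steps) {
      applicable <- identical(step$rounds, "all") || round %in% step$rounds
      if (!applicable) next
      if (!execute_step(rig, spec, step, round, trigger)) break
    }
    if (rig$halted) break
  }
  event_log(rig)
}

#' Extract the event log of a rig as a data.frame
#'
#' @param rig A [simulated_rig()].
#' @return An `event_log` data.frame (see [run_experiment()]).
#' @export
event_log <- function(rig) {
  rows <- lapply(rig$events, function(e) {
    extra <- e[setdiff(names(e), c("t", "kind", "round", "step_id"))]
    data.frame(t = e$t, kind = e$kind,
               round = e$round %||% NA_integer_,
               step_id = e$step_id %||% NA_character_,
               payload = if (length(extra))
                 jsonlite::toJSON(extra, auto_unbox = TRUE, digits = NA)
               else "{}",
               stringsAsFactors = FALSE)
  })
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = numeric(0), kind = character(0), round = integer(0),
               step_id = character(0), payload = character(0))
  structure(log, class = c("event_log", "data.frame"),
            flow_trace = flow_trace(rig),
            dispensed_ml = rig$dispensed)
}

#' Flow-sensor trace of a rig
#'
#' @param rig A [simulated_rig()].
#' @return data.frame `(t, measured, expected, step_id, round)`.
#' @export
flow_trace <- function(rig) {
  if (length(rig$flow) == 0L)
    return(data.frame(t = numeric(0), measured = numeric(0),
                      expected = numeric(0), step_id = character(0),
                      round = integer(0)))
  do.call(rbind, rig$flow)
}

#' Write an event log as JSON lines
#'
#' One event per line: `{"t": <s>, "kind": ..., "round": ...,
#' "step_id": ..., ...payload}`. Deterministic: identical logs serialize
#' byte-identically.
#'
#' @param log An `event_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    extra <- jsonlite::fromJSON(log$payload[i])
    jsonlite::toJSON(c(list(t = log$t[i], kind = log$kind[i],
                            round = log$round[i], step_id = log$step_id[i]),
                       extra),
                     auto_unbox = TRUE, digits = NA, null = "null",
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Detect flow anomalies in a sensor trace
#'
#' Flags maximal intervals where the relative deviation of the measured
#' from the expected flow exceeds `tolerance_frac` for at least
#' `min_duration_s` (an interval's extent counts one sample period per
#' sample); neighbouring intervals separated by less than one sample
#' period are merged. Samples with expected rate 0 (pump off) are excluded.
#'
#' @param trace data.frame `(t, measured, expected)`.
#' @param tolerance_frac Relative tolerance in (0, 1).
#' @param min_duration_s Minimum anomaly duration (s).
#' @param sample_period_s Sensor sampling period (s).
#' @return data.frame `(t0, t1, duration_s)` of detected intervals.
#' @export
detect_flow_anomaly <- function(trace, tolerance_frac = 0.2,
                                min_duration_s = 5, sample_period_s = 1) {
  stopifnot(tolerance_frac > 0, tolerance_frac < 1)
  none <- data.frame(t0 = numeric(0), t1 = numeric(0),
                     duration_s = numeric(0))
  tr <- trace[trace$expected > 0, , drop = FALSE]
  if (nrow(tr) == 0L) return(none)
  tr <- tr[order(tr$t), , drop = FALSE]
  bad <- abs(tr$measured - tr$expected) / tr$expected > tolerance_frac
  if (!any(bad)) return(none)
  tb <- tr$t[bad]
  # split where the gap between consecutive bad samples exceeds the period
  grp <- cumsum(c(1, diff(tb) > sample_period_s + 1e-9))
  out <- do.call(rbind, lapply(split(tb, grp), function(ts)
    data.frame(t0 = min(ts), t1 = max(ts),
               duration_s = max(ts) - min(ts) + sample_period_s)))
  out <- out[out$duration_s >= min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' File-synchronization acquisition trigger
#'
#' Mirrors microscope handshaking through a shared text file. In `content`
#' mode arming writes `"1"` to the sync file and completion is the switch
#' back to `"0"`; in `existence` mode arming creates the file and
#' completion is its deletion. A mock acquirer (see [mock_acquirer()])
#' plays the microscope in tests; without a responder the trigger times
#' out.
#'
#' @param directory Writable directory holding the sync file.
#' @param mode `"content"` or `"existence"`.
#' @param responder Optional `function(path, mode, round)` performing the
#'   microscope's side and returning its simulated delay in seconds (or
#'   `Inf` to never respond).
#' @param sync_file Sync file name.
#' @return A trigger object with `arm_and_wait(round, t)`.
#' @export
file_trigger <- function(directory, mode = c("content", "existence"),
                         responder = NULL, sync_file = "sync.txt") {
  mode <- match.arg(mode)
  if (!dir.exists(directory)) stop("directory does not exist")
  path <- file.path(directory, sync_file)
  list(
    kind = paste0("file_", mode),
    path = path,
    arm_and_wait = function(round, t) {
      if (mode == "content") writeLines("1", path) else file.create(path)
      delay <- if (is.null(responder)) Inf else responder(path, mode, round)
      done <- if (mode == "content") {
        file.exists(path) && identical(readLines(path, warn = FALSE)[1], "0")
      } else {
        !file.exists(path)
      }
      if (done) delay else Inf
    }
  )
}

#' Mock acquirer for the file trigger
#'
#' Simulates the microscope: after `delay_s` simulated seconds it flips the
#' sync file content from 1 to 0 (content mode) or deletes it (existence
#' mode).
#'
#' @param delay_s Simulated acquisition duration (s).
#' @return A responder function for [file_trigger()].
#' @export
mock_acquirer <- function(delay_s = 5) {
  function(path, mode, round) {
    if (mode == "content") writeLines("0", path) else unlink(path)
    delay_s
  }
}

#' TTL acquisition trigger (in-process mock)
#'
#' Line-level model of TTL handshaking: arming raises the outgoing line
#' (one out-pulse); a mock microscope answers with an incoming pulse after
#' a configurable delay. Rounds excluded from `respond_rounds` never get an
#' in-pulse, producing a timeout.
#'
#' @param delay_s Simulated acquisition duration (s).
#' @param respond_rounds Rounds the mock answers (`NULL` = all).
#' @return A trigger object with `arm_and_wait(round, t)` and a `state`
#'   environment recording `out_pulses` / `in_pulses` times.
#' @export
ttl_trigger_mock <- function(delay_s = 3, respond_rounds = NULL) {
  state <- new.env(parent = emptyenv())
  state$out_pulses <- numeric(0)
  state$in_pulses <- numeric(0)
  list(
    kind = "ttl",
    state = state,
    arm_and_wait = function(round, t) {
      state$out_pulses <- c(state$out_pulses, t)
      if (!is.null(respond_rounds) && !round %in% respond_rounds)
        return(Inf)
      state$in_pulses <- c(state$in_pulses, t + delay_s)
      delay_s
    }
  )
}
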