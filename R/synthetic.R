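#' Default waveform archetypes
#'
#' Each archetype is a qualitative template of one waveform class: baseline
#' offset, oscillation amplitude, dominant frequency band, additive noise
#' level, and the range of episode durations the behavioural grammar draws
#' from. The values are package conventions chosen to make the seven classes
#' separable but overlapping, reflecting the classes' published qualitative
#' descriptions: NP is near-flat around 0 mV, C is a complex mixture of
#' mid-frequency components interrupted by brief pd drops, E1 and E2 are
#' periodic at distinct low frequencies, F and G are regular high-amplitude
#' oscillations at higher frequencies.
#'
#' @return named list of archetypes; each has `baseline` (mV), `amplitude`
#'   (mV), `freq_range` (Hz, dominant band), `noise_sd` (mV) and
#'   `duration_range` (s).
#' @export
default_archetypes <- function() {
  list(
    NP = list(baseline = 0.0, amplitude = 0.05, freq_range = c(0.05, 0.8),
              noise_sd = 0.010, duration_range = c(30, 180)),
    C  = list(baseline = 1.5, amplitude = 0.40, freq_range = c(4, 8),
              noise_sd = 0.050, duration_range = c(40, 240)),
    pd = list(baseline = -0.8, amplitude = 0.10, freq_range = c(7, 11),
              noise_sd = 0.030, duration_range = c(3, 8)),
    E1 = list(baseline = 1.0, amplitude = 0.45, freq_range = c(1.6, 2.6),
              noise_sd = 0.040, duration_range = c(15, 60)),
    E2 = list(baseline = 0.7, amplitude = 0.50, freq_range = c(0.7, 1.3),
              noise_sd = 0.040, duration_range = c(60, 400)),
    F  = list(baseline = 1.2, amplitude = 0.80, freq_range = c(13, 17),
              noise_sd = 0.050, duration_range = c(40, 200)),
    G  = list(baseline = 1.0, amplitude = 0.70, freq_range = c(9, 11),
              noise_sd = 0.050, duration_range = c(40, 200))
  )
}

#' Behavioural grammar for synthetic feeding sequences
#'
#' Encodes the sequential constraints of aphid probing: the insect must be
#' in pathway phase (C) before any phloem/xylem activity (E1, E2, G) or
#' stylet derailment (F), potential drops (pd) occur only as interruptions
#' strictly inside C, and non-probing (NP) alternates with probing bouts.
#'
#' @param targets named numeric vector of target time shares per class,
#'   summing to 1. The default resembles the class balance of a combined
#'   multi-species corpus (C about 0.24, E2 about 0.29) for the six episode
#'   classes; the pd share is a small time fraction (0.015) because pd
#'   events are brief 3-8 s interruptions that occur frequently but occupy
#'   a negligible proportion of recording time - corpus-level pd ratios of
#'   0.1-0.3 describe segment databases after pd oversampling, which the
#'   preprocessing pipeline reproduces, not time on the clock.
#' @param pd_within_c expected number of pd interruptions per second of C
#'   time. The default is calibrated so that pd time / C time matches the
#'   target ratio given a mean pd duration of 5.5 s.
#' @param successors named list: allowed follow-up classes after each
#'   episode (pd is handled separately via interruption of C).
#' @return object of class `epg_grammar`.
#' @export
epg_grammar <- function(targets = c(NP = 0.30, C = 0.24, pd = 0.015, E1 = 0.04,
                                    E2 = 0.29, F = 0.04, G = 0.075),
                        pd_within_c = NULL,
                        successors = list(
                          NP = c("C"),
                          C  = c("NP", "E1", "E2", "F", "G"),
                          E1 = c("E2", "C"),
                          E2 = c("C", "NP"),
                          F  = c("C", "NP"),
                          G  = c("C", "NP"))) {
  targets <- targets[EPG_LABELS]
  names(targets) <- EPG_LABELS
  targets[is.na(targets)] <- 0
  if (any(targets < 0)) stopf("grammar targets must be non-negative")
  if (sum(targets) <= 0) stopf("grammar targets must not all be zero")
  targets <- targets / sum(targets)
  if (targets[["pd"]] > 0 && targets[["C"]] <= 0) {
    stopf("grammar invalid: pd requires a positive C share (pd occurs only inside C)")
  }
  bad <- vapply(names(successors), function(s) "pd" %in% successors[[s]], logical(1))
  if (any(bad)) stopf("grammar invalid: pd may not appear as an episode successor")
  if (is.null(pd_within_c)) {
    pd_within_c <- if (targets[["C"]] > 0) {
      (targets[["pd"]] / targets[["C"]]) / 5.5
    } else {
      0
    }
  }
  structure(list(targets = targets, pd_within_c = pd_within_c,
                 successors = successors),
            class = "epg_grammar")
}

#' Configuration of the synthetic recording generator
#'
#' @param duration recording duration in seconds (default 28,800 = 8 h,
#'   the standard EPG session length).
#' @param rate sampling rate in Hz (default 100).
#' @param seed integer seed; the generator is a pure function of the
#'   configuration.
#' @param grammar an [epg_grammar()].
#' @param archetypes per-class waveform templates, see [default_archetypes()].
#' @return object of class `epg_sim_config`.
#' @export
epg_sim_config <- function(duration = 28800, rate = 100, seed = 1,
                           grammar = epg_grammar(),
                           archetypes = default_archetypes()) {
  if (duration <= 0 || rate <= 0) stopf("duration and rate must be positive")
  n <- duration * rate
  if (abs(n - round(n)) > 1e-8) stopf("duration * rate must be an integer sample count")
  missing <- setdiff(EPG_LABELS, names(archetypes))
  if (length(missing) > 0) stopf("missing archetype for label '%s'", missing[1])
  structure(list(duration = duration, rate = rate, seed = as.integer(seed),
                 grammar = grammar, archetypes = archetypes),
            class = "epg_sim_config")
}

# Draw an episode duration for `label` from its archetype range.
draw_duration <- function(config, label) {
  r <- config$archetypes[[label]]$duration_range
  stats::runif(1, r[1], r[2])
}

#' Sample a behavioural annotation track
#'
#' Simulates a feeding session as a sequence of behavioural episodes. The
#' next episode class is drawn among the grammar's allowed successors with
#' weights proportional to each class's remaining deficit against its target
#' time share, which makes long recordings self-correct towards the target
#' class balance. C episodes are interrupted by pd events (duration drawn
#' from the pd archetype) so that every pd interval is strictly preceded and
#' followed by C. The track is truncated to the configured duration; if the
#' truncation would leave a pd as final interval it is dropped (its C host
#' extends to the end).
#'
#' @param config an [epg_sim_config()].
#' @return a gap-free [epg_track()] of exactly `config$duration` seconds.
#' @export
sample_behavior_sequence <- function(config) {
  with_seed(mix_seed(config$seed, 1L), sample_behavior_impl(config))
}

sample_behavior_impl <- function(config) {
  g <- config$grammar
  targets <- g$targets
  # pd rides inside C; merge their targets for episode scheduling.
  etarget <- targets
  etarget[["C"]] <- etarget[["C"]] + etarget[["pd"]]
  etarget[["pd"]] <- 0
  time_in <- stats::setNames(numeric(7), EPG_LABELS)

  labs <- character(0)
  durs <- numeric(0)
  emit <- function(lab, dur) {
    labs[[length(labs) + 1L]] <<- lab
    durs[[length(durs) + 1L]] <<- dur
    time_in[[lab]] <<- time_in[[lab]] + dur
  }

  starters <- intersect(c("NP", "C"), EPG_LABELS[etarget > 0])
  if (length(starters) == 0) starters <- EPG_LABELS[which(etarget > 0)][1]
  state <- if (length(starters) == 1) starters else {
    sample(starters, 1, prob = etarget[starters])
  }

  total <- 0
  while (total < config$duration) {
    dur <- draw_duration(config, state)
    # shrink or stretch the episode towards the class's remaining deficit,
    # so long sessions self-correct to the target time shares
    if (total > 0) {
      lab_share <- (time_in[[state]] +
                    if (state == "C") time_in[["pd"]] else 0) / total
      def <- etarget[[state]] - lab_share
      dur <- dur * min(2, max(0.3, 1 + 2 * def / max(etarget[[state]], 0.01)))
    }
    if (state == "C") {
      parts <- c_episode_with_pd(config, dur)
      for (p in parts) emit(p$label, p$dur)
      dur <- sum(vapply(parts, `[[`, numeric(1), "dur"))
    } else {
      emit(state, dur)
    }
    total <- total + dur
    # pick the next state among allowed successors by target deficit
    allowed <- intersect(g$successors[[state]] %||% character(0),
                         EPG_LABELS[etarget > 0])
    if (length(allowed) == 0) allowed <- state  # absorbing (e.g. NP-only grammar)
    share <- (time_in + time_in[["pd"]] * (EPG_LABELS == "C")) / max(total, 1e-9)
    share <- stats::setNames(as.numeric(share), EPG_LABELS)
    deficit <- pmax(etarget[allowed] - share[allowed], 0.02 * etarget[allowed])
    if (sum(deficit) <= 0) deficit <- etarget[allowed] + 1e-9
    state <- if (length(allowed) == 1) allowed else sample(allowed, 1, prob = deficit)
  }

  # truncate to the configured duration
  starts <- cumsum(c(0, durs[-length(durs)]))
  keep <- starts < config$duration - 1e-9
  labs <- labs[keep]; starts <- starts[keep]
  while (length(labs) > 1 && labs[length(labs)] == "pd") {
    labs <- labs[-length(labs)]
    starts <- starts[-length(starts)]
  }
  # merge adjacent equal labels introduced by pd removal
  if (length(labs) > 1) {
    same <- c(FALSE, labs[-1] == labs[-length(labs)])
    labs <- labs[!same]; starts <- starts[!same]
  }
  # snap starts to the sample grid so track<->labels is an exact bijection
  starts <- round(starts * config$rate) / config$rate
  dup <- c(FALSE, diff(starts) <= 0)
  labs <- labs[!dup]; starts <- starts[!dup]
  epg_track(labs, starts, end_time = config$duration)
}

# Split a pathway episode of total duration dur into C chunks interleaved
# with pd interruptions; first and last chunks are always C, and pd time is
# counted inside the episode's duration budget.
c_episode_with_pd <- function(config, dur) {
  g <- config$grammar
  pr <- config$archetypes$pd$duration_range
  mean_pd <- mean(pr)
  # insertion rate is per second of C; expected C fraction of the episode
  c_frac <- 1 / (1 + g$pd_within_c * mean_pd)
  n_pd <- if (g$pd_within_c > 0) {
    stats::rpois(1, g$pd_within_c * c_frac * dur)
  } else {
    0L
  }
  min_gap <- 2  # seconds of C guaranteed around each pd
  pd_durs <- if (n_pd > 0) stats::runif(n_pd, pr[1], pr[2]) else numeric(0)
  while (n_pd > 0 && sum(pd_durs) + min_gap * (n_pd + 1L) > dur) {
    n_pd <- n_pd - 1L
    pd_durs <- pd_durs[seq_len(n_pd)]
  }
  if (n_pd == 0) return(list(list(label = "C", dur = dur)))
  c_total <- dur - sum(pd_durs)
  w <- stats::runif(n_pd + 1L, 0.5, 1.5)
  chunks <- min_gap + (c_total - min_gap * (n_pd + 1L)) * w / sum(w)
  out <- list()
  for (i in seq_len(n_pd)) {
    out[[length(out) + 1L]] <- list(label = "C", dur = chunks[i])
    out[[length(out) + 1L]] <- list(label = "pd", dur = pd_durs[i])
  }
  out[[length(out) + 1L]] <- list(label = "C", dur = chunks[n_pd + 1L])
  out
}

#' Render a recording from an annotation track
#'
#' Synthesises the voltage trace interval by interval from each label's
#' archetype: NP as a near-zero baseline with slow drift and sparse spikes;
#' C as a sum of 2-3 mid-frequency sinusoids with jittered phases; pd as a
#' brief sharp negative excursion below baseline; E1/E2 as periodic waves
#' with harmonics at their characteristic frequencies; F and G as regular
#' high-amplitude oscillations. A short linear cross-fade (0.1 s) at each
#' interval start keeps the trace continuous at boundaries up to noise.
#' Rendering is a pure function of `(track, config)`.
#'
#' @param track a gap-free [epg_track()].
#' @param config an [epg_sim_config()].
#' @return an [epg_recording()] of `config$duration * config$rate` samples.
#' @export
render_recording <- function(track, config) {
  with_seed(mix_seed(config$seed, 2L), render_recording_impl(track, config))
}

render_recording_impl <- function(track, config) {
  rate <- config$rate
  n_total <- round(config$duration * rate)
  bounds <- round(c(track$start_time, track_end_time(track)) * rate)
  bounds[length(bounds)] <- n_total
  pieces <- vector("list", nrow(track))
  prev_last <- 0
  for (k in seq_len(nrow(track))) {
    n <- bounds[k + 1] - bounds[k]
    if (n <= 0) { pieces[[k]] <- numeric(0); next }
    lab <- as.character(track$label[k])
    a <- config$archetypes[[lab]]
    if (is.null(a)) stopf("missing archetype for label '%s'", lab)
    y <- render_interval(lab, n, rate, a)
    # cross-fade from the previous interval's final value
    r <- min(n, max(2L, round(0.1 * rate)))
    w <- seq(0, 1, length.out = r)
    y[1:r] <- y[1:r] * w + prev_last * (1 - w)
    prev_last <- y[n]
    pieces[[k]] <- y
  }
  epg_recording(unlist(pieces, use.names = FALSE), rate = rate,
                id = sprintf("synthetic-seed%d", config$seed))
}

render_interval <- function(lab, n, rate, a) {
  t <- (seq_len(n) - 1) / rate
  f <- stats::runif(1, a$freq_range[1], min(a$freq_range[2], rate / 2 - 1e-6))
  noise <- stats::rnorm(n, 0, a$noise_sd)
  base <- a$baseline
  y <- switch(lab,
    NP = {
      drift <- a$amplitude * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      spikes <- numeric(n)
      n_spk <- stats::rpois(1, 0.02 * n / rate)
      if (n_spk > 0) {
        at <- sample.int(n, min(n_spk, n))
        spikes[at] <- stats::runif(length(at), -0.3, 0.3)
      }
      base + drift + spikes
    },
    C = {
      k <- sample(2:3, 1)
      osc <- 0
      for (i in seq_len(k)) {
        fi <- stats::runif(1, a$freq_range[1], a$freq_range[2])
        osc <- osc + (a$amplitude / i) * sin(2 * pi * fi * t + stats::runif(1, 0, 2 * pi))
      }
      base + osc
    },
    pd = {
      # sharp drop, plateau with faint ripple, sharp recovery
      edge <- max(2L, round(0.15 * rate))
      env <- rep(1, n)
      env[seq_len(min(edge, n))] <- seq(0, 1, length.out = min(edge, n))
      env[seq(max(1, n - edge + 1), n)] <- seq(1, 0, length.out = min(edge, n))
      depth <- 1.5 + stats::runif(1, 0, 0.6)
      ripple <- a$amplitude * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      1.5 - depth * env + env * ripple
    },
    E1 = {
      ph <- stats::runif(1, 0, 2 * pi)
      base + a$amplitude * (sin(2 * pi * f * t + ph) +
                            0.5 * sin(4 * pi * f * t + 2 * ph))
    },
    E2 = {
      ph <- stats::runif(1, 0, 2 * pi)
      base + a$amplitude * (sin(2 * pi * f * t + ph) +
                            0.35 * sin(4 * pi * f * t + ph / 2) +
                            0.15 * sin(6 * pi * f * t))
    },
    F = {
      ph <- stats::runif(1, 0, 2 * pi)
      base + a$amplitude * sin(2 * pi * f * t + ph)
    },
    G = {
      ph <- stats::runif(1, 0, 2 * pi)
      am <- 1 + 0.25 * sin(2 * pi * 0.5 * t)
      base + a$amplitude * am * sin(2 * pi * f * t + ph)
    },
    stopf("no renderer for label '%s'", lab))
  y + noise
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n` independent (recording, track) pairs using seeds
#' `config$seed, config$seed + 1, ...`. For `n >= 20` the empirical class
#' time shares land within about 0.1 of the grammar targets.
#'
#' @param n number of recordings (>= 1).
#' @param config an [epg_sim_config()]; its `seed` seeds the first pair.
#' @return list of `n` elements, each `list(recording =, track =)`.
#' @export
generate_dataset <- function(n, config = epg_sim_config()) {
  if (n < 1) stopf("n must be >= 1")
  lapply(seq_len(n) - 1L, function(k) {
    ck <- config
    ck$seed <- config$seed + k
    track <- sample_behavior_sequence(ck)
    list(recording = render_recording(track, ck), track = track)
  })
}

#' Check a track against the behavioural grammar
#'
#' Independent validity scan used in tests and quality control: counts pd
#' intervals not strictly surrounded by C, and E1/E2/F/G intervals occurring
#' before any C has been observed.
#'
#' @param track an [epg_track()].
#' @return integer count of violations (0 for a valid track).
#' @export
count_grammar_violations <- function(track) {
  labs <- as.character(track$label)
  n <- length(labs)
  v <- 0L
  seen_c <- FALSE
  for (i in seq_len(n)) {
    if (labs[i] == "pd") {
      ok <- i > 1 && i < n && labs[i - 1] == "C" && labs[i + 1] == "C"
      if (!ok) v <- v + 1L
    } else if (labs[i] %in% c("E1", "E2", "F", "G") && !seen_c) {
      v <- v + 1L
    }
    if (labs[i] == "C") seen_c <- TRUE
  }
  v
}
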