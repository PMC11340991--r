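#' Design of a longitudinal (repeated-measures) Numt accumulation study
#'
#' One row per cultured cell line (donor x treatment arm): first and last
#' collection day, number of collection time points, and the per-day Numt
#' integration rate. Interior collection days are evenly spaced between the
#' first and last day (sampling frequency in such designs is roughly
#' constant), rounded to whole days.
#'
#' @param series `data.frame` with columns `donor`, `treatment`,
#'   `day_first`, `day_last`, `n_points`, `rate_per_day`.
#' @param detection_prob Probability that an integrated event is detected at
#'   any given collection (default 1: every planted event is seen, so rate
#'   recovery is unconfounded by dropout).
#' @return An object of class `numt_longitudinal_design`.
#' @export
longitudinal_design <- function(series, detection_prob = 1) {
  need <- c("donor", "treatment", "day_first", "day_last", "n_points",
            "rate_per_day")
  stopifnot(is.data.frame(series), all(need %in% names(series)))
  if (any(series$rate_per_day < 0)) stop("rates must be non-negative")
  if (detection_prob < 0 || detection_prob > 1)
    stop("'detection_prob' must be in [0, 1]")
  if (any(series$day_last < series$day_first) || any(series$n_points < 2))
    stop("each series needs day_last >= day_first and at least 2 points")
  structure(list(series = series, detection_prob = detection_prob),
            class = "numt_longitudinal_design")
}

#' Fibroblast lifespan study design preset
#'
#' The 12-series design of the fibroblast aging experiment: 3 healthy donors
#' each cultured untreated, under dexamethasone (Dex), and under oligomycin
#' (Oligo), plus 3 SURF1-mutant patient lines. Collection-day ranges and
#' point counts follow the published experimental design; default per-day
#' integration rates are the published per-10-day accumulation rates divided
#' by 10 (control 0.79, Dex 1.07, Oligo 2.15, SURF1 3.71 per 10 days).
#'
#' @param control_rate,dex_rate,oligo_rate,surf1_rate Per-day integration
#'   rates for the four arms.
#' @param detection_prob See [longitudinal_design()].
#' @return A `numt_longitudinal_design` with 12 series.
#' @export
longitudinal_design_lifespan <- function(control_rate = 0.079,
                                         dex_rate = 0.107,
                                         oligo_rate = 0.215,
                                         surf1_rate = 0.371,
                                         detection_prob = 1) {
  series <- data.frame(
    donor = c("Donor1", "Donor1", "Donor1", "Donor2", "Donor2", "Donor2",
              "Donor3", "Donor3", "Donor3",
              "Patient1", "Patient2", "Patient3"),
    treatment = c("none", "Dex", "Oligo", "none", "Dex", "Oligo",
                  "none", "Dex", "Oligo", "SURF1", "SURF1", "SURF1"),
    day_first = c(7, 27, 27, 8, 43, 28, 3, 28, 28, 16, 8, 8),
    day_last  = c(211, 166, 103, 189, 211, 189, 189, 90, 105, 90, 152, 58),
    n_points  = c(8, 8, 6, 8, 10, 8, 10, 4, 4, 5, 8, 5),
    stringsAsFactors = FALSE)
  series$rate_per_day <- c(control = control_rate, Dex = dex_rate,
                           Oligo = oligo_rate,
                           SURF1 = surf1_rate)[
    ifelse(series$treatment == "none", "control", series$treatment)]
  longitudinal_design(series, detection_prob = detection_prob)
}

#' Collection days of a longitudinal design
#' @param design A `numt_longitudinal_design`.
#' @return A `data.frame` with one row per (series, day).
#' @export
collection_days <- function(design) {
  stopifnot(inherits(design, "numt_longitudinal_design"))
  s <- design$series
  out <- lapply(seq_len(nrow(s)), function(i) {
    days <- unique(round(seq(s$day_first[i], s$day_last[i],
                             length.out = s$n_points[i])))
    data.frame(donor = s$donor[i], treatment = s$treatment[i],
               day = days, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate longitudinal Numt accumulation
#'
#' For each series, unique Numt events arrive as a Poisson process at
#' `rate_per_day` from day 0; events persist once integrated, and each
#' integrated event is re-detected independently at every collection with
#' probability `detection_prob`. All event identities (nuclear position +
#' mtDNA segment) are distinct, emulating the observation that every Numt
#' recovered in such experiments is unique. Uses the current R RNG.
#'
#' @param model A `numt_genome`.
#' @param design A [longitudinal_design()].
#' @param length_model Length model for planted events; defaults to the
#'   fibroblast-like calibrated mixture.
#' @param vaf VAF model for planted events (fibroblast preset by default).
#' @return A list:
#'   \describe{
#'     \item{series}{`data.frame(donor, treatment, group, day, count)` of
#'       detected counts per collection.}
#'     \item{events}{planted events with `donor`, `treatment`, `event_id`,
#'       `arrival_day`, genomic coordinates, `vaf`.}
#'     \item{detections}{long `data.frame(event_id, day, detected)`.}
#'   }
#' @export
simulate_longitudinal <- function(model, design,
                                  length_model = numt_length_model(),
                                  vaf = vaf_model("fibroblast")) {
  stopifnot(inherits(model, "numt_genome"),
            inherits(design, "numt_longitudinal_design"))
  days_df <- collection_days(design)
  s <- design$series
  p_det <- design$detection_prob
  ev_list <- list()
  det_list <- list()
  ser_list <- list()
  for (i in seq_len(nrow(s))) {
    days <- days_df$day[days_df$donor == s$donor[i] &
                          days_df$treatment == s$treatment[i]]
    n_ev <- stats::rpois(1, s$rate_per_day[i] * max(days))
    arrivals <- sort(stats::runif(n_ev, 0, max(days)))
    ev <- sample_numt_event(model, length_model, n = n_ev)
    if (n_ev > 0) {
      ev$vaf <- round(rvaf(n_ev, vaf), 4)
      ev$donor <- s$donor[i]
      ev$treatment <- s$treatment[i]
      ev$event_id <- sprintf("%s_%s_E%04d", s$donor[i], s$treatment[i],
                             seq_len(n_ev))
      ev$arrival_day <- arrivals
      ev_list[[i]] <- ev
    }
    counts <- integer(length(days))
    for (j in seq_along(days)) {
      present <- which(arrivals <= days[j])
      det <- if (p_det >= 1) {
        rep(TRUE, length(present))
      } else {
        stats::runif(length(present)) < p_det
      }
      counts[j] <- sum(det)
      if (length(present)) {
        det_list[[length(det_list) + 1L]] <- data.frame(
          event_id = ev$event_id[present], day = days[j], detected = det)
      }
    }
    ser_list[[i]] <- data.frame(
      donor = s$donor[i], treatment = s$treatment[i],
      group = paste(s$donor[i], s$treatment[i], sep = ":"),
      day = days, count = counts, stringsAsFactors = FALSE)
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else NULL
  # positions are continuous-uniform draws; duplicated identities are
  # theoretically possible but astronomically unlikely -- enforce anyway
  if (!is.null(events)) {
    key <- paste(events$chrom, events$pos, events$mt_start, events$mt_end)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      redo <- sample_numt_event(model, length_model, n = length(dup))
      events[dup, names(redo)] <- redo
      key <- paste(events$chrom, events$pos, events$mt_start, events$mt_end)
    }
    rownames(events) <- NULL
  }
  list(series = do.call(rbind, ser_list), events = events,
       detections = if (length(det_list)) do.call(rbind, det_list) else NULL)
}
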