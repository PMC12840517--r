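# Hourly six-organ SOFA scoring, Sepsis-3 detection and MODS onset.
#
# Sub-scores follow the standard Sepsis-3 consensus SOFA cut-off table.
# Renal scoring uses creatinine only and respiration uses the PaO2/FiO2
# ratio without a ventilation qualifier, because urine output and
# ventilation status are not part of the 41-feature input set. A missing
# organ input scores 0 (no evidence of dysfunction), the conservative
# convention for retrospective scoring.

SOFA_ORGANS <- c("respiration", "coagulation", "liver", "cardiovascular",
                 "cns", "renal")

#' SOFA organ sub-score
#'
#' Scores a single organ system on the standard 0-4 SOFA scale.
#'
#' * `respiration`: PaO2/FiO2 ratio (mmHg), bands 400/300/200/100.
#' * `coagulation`: platelet count (K/uL), bands 150/100/50/20.
#' * `liver`: total bilirubin (mg/dL), bands 1.2/2.0/6.0/12.0.
#' * `cns`: Glasgow Coma Scale total (3-15), bands 15 / 13-14 / 10-12 /
#'   6-9 / <6.
#' * `renal`: creatinine (mg/dL), bands 1.2/2.0/3.5/5.0.
#' * `cardiovascular`: mean arterial pressure (mmHg) plus vasoactive drug
#'   doses in ug/kg/min. MAP < 70 scores 1; any dobutamine or dopamine <= 5
#'   scores 2; dopamine > 5 or norepinephrine/epinephrine <= 0.1 scores 3;
#'   dopamine > 15 or norepinephrine/epinephrine > 0.1 scores 4.
#'
#' Missing inputs (`NA`) contribute no evidence of dysfunction, so an organ
#' with no data scores 0.
#'
#' @param organ one of `"respiration"`, `"coagulation"`, `"liver"`,
#'   `"cardiovascular"`, `"cns"`, `"renal"`.
#' @param value the organ's driving measurement (PaO2/FiO2, platelets,
#'   bilirubin, GCS or creatinine); ignored for the cardiovascular system.
#' @param map,dopamine,dobutamine,epinephrine,norepinephrine cardiovascular
#'   inputs; doses default to 0 (not administered).
#' @return integer vector of sub-scores in 0-4.
#' @export
sofa_subscore <- function(organ, value = NULL, map = NULL,
                          dopamine = 0, dobutamine = 0,
                          epinephrine = 0, norepinephrine = 0) {
  organ <- match.arg(organ, SOFA_ORGANS)
  band <- function(x, cuts, scores, right = FALSE) {
    # cuts ascending; right=FALSE: score[i] applies on [cuts[i-1], cuts[i])
    s <- scores[findInterval(x, cuts, left.open = right,
                             rightmost.closed = FALSE) + 1L]
    s[is.na(x)] <- 0L
    as.integer(s)
  }
  if (organ == "respiration") {
    check_domain(value, 0, Inf, "PaO2/FiO2")
    return(band(value, c(100, 200, 300, 400), c(4L, 3L, 2L, 1L, 0L)))
  }
  if (organ == "coagulation") {
    check_domain(value, 0, Inf, "platelet count")
    return(band(value, c(20, 50, 100, 150), c(4L, 3L, 2L, 1L, 0L)))
  }
  if (organ == "liver") {
    check_domain(value, 0, Inf, "bilirubin")
    return(band(value, c(1.2, 2, 6, 12), c(0L, 1L, 2L, 3L, 4L)))
  }
  if (organ == "renal") {
    check_domain(value, 0, Inf, "creatinine")
    return(band(value, c(1.2, 2, 3.5, 5), c(0L, 1L, 2L, 3L, 4L)))
  }
  if (organ == "cns") {
    check_domain(value, 3, 15, "GCS")
    return(band(value, c(6, 10, 13, 15), c(4L, 3L, 2L, 1L, 0L)))
  }
  # cardiovascular
  n <- max(length(map), length(dopamine), length(dobutamine),
           length(epinephrine), length(norepinephrine), 1L)
  rep_or <- function(x, fill) {
    if (is.null(x)) x <- fill
    x <- rep_len(x, n)
    x[is.na(x)] <- fill
    x
  }
  map <- rep_or(map, Inf)  # unknown MAP: no evidence of hypotension
  dop <- rep_or(dopamine, 0); dob <- rep_or(dobutamine, 0)
  epi <- rep_or(epinephrine, 0); nor <- rep_or(norepinephrine, 0)
  check_domain(c(dop, dob, epi, nor), 0, Inf, "vasoactive dose")
  s <- integer(n)
  s[map < 70] <- 1L
  s[(dop > 0 & dop <= 5) | dob > 0] <- 2L
  s[(dop > 5) | (epi > 0 & epi <= 0.1) | (nor > 0 & nor <= 0.1)] <- 3L
  s[(dop > 15) | (epi > 0.1) | (nor > 0.1)] <- 4L
  s
}

check_domain <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad))
    stop("out-of-domain ", what, ": ", paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(x)
}

# last observation carried forward evaluated at integer hours, with a
# lookback limit beyond which a stale value is treated as missing
locf_at_hours <- function(times, values, hours, lookback) {
  if (length(times) == 0L) return(rep(NA_real_, length(hours)))
  o <- order(times)
  times <- times[o]; values <- values[o]
  idx <- findInterval(hours, times)  # last obs with time <= hour
  out <- rep(NA_real_, length(hours))
  has <- idx > 0L
  out[has] <- values[idx[has]]
  stale <- has & (hours - times[pmax(idx, 1L)]) > lookback
  out[stale] <- NA_real_
  out
}

#' Hourly SOFA timeline for one stay
#'
#' Evaluates the six organ sub-scores at every integer hour from 1 to
#' `ceiling(icu_los_h)`. Each organ input is taken as the most recent
#' plausibility-clipped observation, carried forward within a lookback limit
#' (24 h for labs and GCS, 4 h for vitals and drug doses, per the registry);
#' beyond the lookback the input is treated as missing and the organ scores
#' 0. The CNS input is the GCS total, reconstructed from the three component
#' scores when the total itself was not charted.
#'
#' @param stay either a single-stay view as returned internally (a list with
#'   `stay` and `events`), or a `cohort_table` together with `stay_id`.
#' @param registry feature registry.
#' @param stay_id stay identifier when `stay` is a `cohort_table`.
#' @return a data.frame of class `sofa_timeline` with columns `stay_id`,
#'   `hour`, the six organ sub-scores and `total`.
#' @export
compute_sofa_timeline <- function(stay, registry = feature_registry(),
                                  stay_id = NULL) {
  if (inherits(stay, "cohort_table")) stay <- cohort_stay(stay, stay_id)
  manifest <- stay$stay
  ev <- stay$events
  hours <- seq_len(max(1L, ceiling(manifest$icu_los_h)))

  series <- function(var) {
    rows <- ev[ev$variable == var, , drop = FALSE]
    reg <- registry[registry$variable == var, , drop = FALSE]
    if (nrow(reg) == 0L) return(rep(NA_real_, length(hours)))
    v <- clip_to_plausible(rows$value, var, registry)
    keep <- !is.na(v)
    locf_at_hours(rows$time_h[keep], v[keep], hours, reg$lookback_h)
  }

  gcs <- series("GCS")
  comp <- series("GCS_Motor") + series("GCS_Verbal") + series("GCS_Eyes")
  gcs[is.na(gcs)] <- comp[is.na(gcs)]

  tl <- data.frame(
    stay_id = manifest$stay_id,
    hour = hours,
    respiration = sofa_subscore("respiration", series("PaO2FiO2")),
    coagulation = sofa_subscore("coagulation", series("Platelet")),
    liver = sofa_subscore("liver", series("Bilirubin")),
    cardiovascular = sofa_subscore("cardiovascular",
                                   map = series("MBP"),
                                   dopamine = series("Dopamine"),
                                   dobutamine = series("Dobutamine"),
                                   epinephrine = series("Epinephrine"),
                                   norepinephrine = series("Norepinephrine")),
    cns = sofa_subscore("cns", pmin(pmax(round(gcs), 3), 15)),
    renal = sofa_subscore("renal", series("Creatinine"))
  )
  tl$total <- tl$respiration + tl$coagulation + tl$liver +
    tl$cardiovascular + tl$cns + tl$renal
  class(tl) <- c("sofa_timeline", "data.frame")
  tl
}

#' First hour meeting the MODS criterion
#'
#' MODS is operationalized as a SOFA sub-score of 2 or higher in at least
#' two organ systems; the onset `t_mods_h` is the earliest hour at which
#' this holds.
#'
#' @param timeline a `sofa_timeline`.
#' @return list with `t_mods_h` (integer hour, or `NA` if the criterion is
#'   never met) and `n_organs` at onset.
#' @export
detect_mods_onset <- function(timeline) {
  organs <- as.matrix(timeline[, SOFA_ORGANS])
  n_dysf <- rowSums(organs >= 2L)
  hit <- which(n_dysf >= 2L)
  if (length(hit) == 0L) return(list(t_mods_h = NA_integer_, n_organs = 0L))
  list(t_mods_h = as.integer(timeline$hour[hit[1L]]),
       n_organs = as.integer(n_dysf[hit[1L]]))
}

#' Sepsis-3 determination for one stay
#'
#' Sepsis is present when infection is suspected and the total SOFA score
#' rises acutely by at least 2 points. The baseline is the minimum total
#' SOFA over the 24 h preceding the suspicion time (falling back to the
#' first charted hour when suspicion occurs at admission), and the
#' qualifying rise must occur between 48 h before and 24 h after suspicion.
#'
#' @param timeline a `sofa_timeline`.
#' @param suspected_infection_time_h hours since ICU admission at which
#'   infection was first suspected, or `NA` if never (then not septic).
#' @return list with `septic` (logical) and `onset_h` (first qualifying
#'   hour, or `NA`).
#' @export
detect_sepsis <- function(timeline, suspected_infection_time_h) {
  t_susp <- suspected_infection_time_h
  if (is.null(t_susp) || is.na(t_susp))
    return(list(septic = FALSE, onset_h = NA_integer_))
  h <- timeline$hour
  base_idx <- h <= t_susp & h >= t_susp - 24
  baseline <- if (any(base_idx)) min(timeline$total[base_idx])
              else timeline$total[1L]
  win <- h >= t_susp - 48 & h <= t_susp + 24
  qual <- which(win & (timeline$total - baseline) >= 2)
  if (length(qual) == 0L) return(list(septic = FALSE, onset_h = NA_integer_))
  list(septic = TRUE, onset_h = as.integer(h[qual[1L]]))
}

#' Per-stay SOFA summary for a whole cohort
#'
#' Convenience wrapper computing, for every stay, the MODS onset time and
#' the Sepsis-3 determination. Used by the cohort filters and the dataset
#' builder.
#'
#' @param cohort a `cohort_table`.
#' @param registry feature registry.
#' @return data.frame with columns `stay_id`, `t_mods_h`, `septic`,
#'   `sepsis_onset_h`.
#' @export
cohort_sofa_summary <- function(cohort, registry = feature_registry()) {
  ids <- cohort$stays$stay_id
  out <- lapply(seq_along(ids), function(i) {
    tl <- compute_sofa_timeline(cohort_stay(cohort, ids[i]), registry)
    mods <- detect_mods_onset(tl)
    sep <- detect_sepsis(tl, cohort$stays$suspected_infection_time_h[i])
    data.frame(stay_id = ids[i], t_mods_h = mods$t_mods_h,
               septic = sep$septic, sepsis_onset_h = sep$onset_h)
  })
  do.call(rbind, out)
}

#' Write a SOFA timeline audit CSV
#'
#' @param timelines a `sofa_timeline` or a list of them (row-bound).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_sofa_timeline <- function(timelines, path) {
  if (!is.data.frame(timelines)) timelines <- do.call(rbind, timelines)
  utils::write.csv(timelines, path, row.names = FALSE)
  invisible(path)
}
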