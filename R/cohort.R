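# Cohort container, CSV readers/writers and inclusion filtering.
#
# Stays and events are kept in long (tidy) form: one row per measurement.
# Hourly matrices are always derived downstream, never stored, because lab
# sampling is irregular (12-24 h) while vitals arrive hourly.

#' Construct a validated cohort table
#'
#' Bundles a stay manifest with its long-format observation events and
#' validates both against the feature registry. Events naming variables
#' outside the registry, carrying non-finite values, or timestamped outside
#' the stay (`time_h < 0` or beyond `icu_los_h`) are dropped with a warning
#' reporting the count.
#'
#' @param stays data.frame with columns `stay_id`, `age`, `gender`,
#'   `icu_los_h`, `death_time_h` (NA when the patient survived),
#'   `trauma_flag`, `suspected_infection_time_h` (NA when infection was never
#'   suspected).
#' @param events data.frame with columns `stay_id`, `time_h`, `variable`,
#'   `value`, `unit`.
#' @param registry feature registry; defaults to [feature_registry()].
#' @param role `"finetune_cohort"` or `"pretrain_pool"`.
#' @return an object of class `cohort_table`: a list with elements `stays`,
#'   `events` and `role`.
#' @export
cohort_table <- function(stays, events, registry = feature_registry(),
                         role = c("finetune_cohort", "pretrain_pool")) {
  role <- match.arg(role)
  req_stays <- c("stay_id", "age", "gender", "icu_los_h", "death_time_h",
                 "trauma_flag", "suspected_infection_time_h")
  req_events <- c("stay_id", "time_h", "variable", "value", "unit")
  miss <- setdiff(req_stays, names(stays))
  if (length(miss))
    stop("stay manifest is missing required columns: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(req_events, names(events))
  if (length(miss))
    stop("event table is missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(stays$stay_id))
    stop("duplicate stay_id in manifest: ",
         paste(unique(stays$stay_id[duplicated(stays$stay_id)]), collapse = ", "))
  if (any(!is.finite(stays$icu_los_h)) || any(stays$icu_los_h <= 0))
    stop("icu_los_h must be positive and finite for every stay")
  dt <- any(!is.na(stays$death_time_h) & stays$death_time_h < 0)
  if (dt) stop("death_time_h must be non-negative when present")

  events <- as.data.frame(events)[, req_events]
  n0 <- nrow(events)
  known <- events$variable %in% event_vars(registry)
  if (any(!known)) {
    warning(sum(!known), " event row(s) with variables outside the registry ",
            "dropped (e.g. ", paste(utils::head(unique(events$variable[!known]), 3),
                                    collapse = ", "), ")")
    events <- events[known, , drop = FALSE]
  }
  ok_val <- is.finite(events$value) & is.finite(events$time_h)
  if (any(!ok_val)) {
    warning(sum(!ok_val), " event row(s) with unparseable or non-finite ",
            "values dropped")
    events <- events[ok_val, , drop = FALSE]
  }
  los <- stays$icu_los_h[match(events$stay_id, stays$stay_id)]
  in_stay <- !is.na(los) & events$time_h >= 0 & events$time_h <= los
  if (any(!in_stay)) {
    warning(sum(!in_stay), " event row(s) outside their stay interval (or ",
            "with unknown stay_id) dropped")
    events <- events[in_stay, , drop = FALSE]
  }
  rownames(events) <- NULL
  rownames(stays) <- NULL
  structure(list(stays = as.data.frame(stays)[, req_stays],
                 events = events, role = role),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> role:", x$role, "\n")
  cat("  stays: ", nrow(x$stays), ", events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Read a cohort from its stay-manifest and event CSV files
#'
#' @param stays_path path to the stay manifest CSV.
#' @param events_path path to the long-format event CSV.
#' @inheritParams cohort_table
#' @return a validated [cohort_table()].
#' @export
read_events <- function(stays_path, events_path,
                        registry = feature_registry(),
                        role = "finetune_cohort") {
  stays <- utils::read.csv(stays_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  if ("trauma_flag" %in% names(stays))
    stays$trauma_flag <- as.logical(stays$trauma_flag)
  cohort_table(stays, events, registry = registry, role = role)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_events()]: values representable in the CSV dialect
#' round-trip bit-exactly (numbers are written with full precision).
#'
#' @param cohort a `cohort_table`.
#' @param stays_path,events_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_events <- function(cohort, stays_path, events_path) {
  stopifnot(inherits(cohort, "cohort_table"))
  for (p in c(stays_path, events_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(cohort$stays, stays_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$events, events_path, row.names = FALSE, quote = FALSE)
  invisible(c(stays = stays_path, events = events_path))
}

# shared age / length-of-stay inclusion bounds (adult, 12 h to 28 d)
passes_inclusion_bounds <- function(stays, min_age = 18,
                                    min_los_h = 12, max_los_h = 672) {
  stays$age >= min_age & stays$icu_los_h >= min_los_h &
    stays$icu_los_h <= max_los_h
}

# per-stay sepsis flags, computed from the SOFA engine unless supplied;
# `need` restricts computation to stays whose filter decision depends on it
resolve_sepsis_flags <- function(cohort, sepsis_flags, registry,
                                 need = rep(TRUE, nrow(cohort$stays))) {
  if (!is.null(sepsis_flags)) {
    stopifnot(all(c("stay_id", "septic") %in% names(sepsis_flags)))
    flag <- sepsis_flags$septic[match(cohort$stays$stay_id, sepsis_flags$stay_id)]
    flag[is.na(flag)] <- FALSE
    return(flag)
  }
  flag <- rep(FALSE, nrow(cohort$stays))
  for (i in which(need)) {
    sid <- cohort$stays$stay_id[i]
    tl <- compute_sofa_timeline(cohort_stay(cohort, sid), registry)
    flag[i] <- detect_sepsis(tl,
                             cohort$stays$suspected_infection_time_h[i])$septic
  }
  flag
}

# single-stay view used by per-stay computations
cohort_stay <- function(cohort, stay_id) {
  s <- cohort$stays[cohort$stays$stay_id == stay_id, , drop = FALSE]
  if (nrow(s) != 1L) stop("unknown stay_id: ", stay_id)
  ev <- cohort$events[cohort$events$stay_id == stay_id, , drop = FALSE]
  list(stay = s, events = ev)
}

#' Select the trauma sepsis fine-tuning cohort
#'
#' Retains adult stays (age >= 18) with ICU length of stay between 12 hours
#' and 28 days, a trauma diagnosis, and Sepsis-3 sepsis (suspected infection
#' plus an acute SOFA rise of at least 2 points, determined by
#' [detect_sepsis()] unless precomputed flags are supplied). The operation is
#' idempotent.
#'
#' @param cohort a `cohort_table`.
#' @param sepsis_flags optional data.frame `stay_id`, `septic` with
#'   precomputed sepsis determinations (avoids recomputing SOFA timelines).
#' @param registry feature registry used when sepsis must be computed.
#' @return the filtered `cohort_table` with role `finetune_cohort`.
#' @export
filter_finetune_cohort <- function(cohort, sepsis_flags = NULL,
                                   registry = feature_registry()) {
  stopifnot(inherits(cohort, "cohort_table"))
  candidate <- passes_inclusion_bounds(cohort$stays) & cohort$stays$trauma_flag
  septic <- resolve_sepsis_flags(cohort, sepsis_flags, registry,
                                 need = candidate)
  subset_cohort(cohort, candidate & septic, role = "finetune_cohort")
}

#' Select the general-ICU pre-training pool
#'
#' Returns every stay that is NOT a trauma sepsis stay (the fine-tuning
#' cohort and the pre-training pool are disjoint by construction). By default
#' the same adult and length-of-stay bounds as the fine-tuning cohort are
#' applied; set `apply_bounds = FALSE` to keep the pool unbounded.
#'
#' @inheritParams filter_finetune_cohort
#' @param apply_bounds apply the shared age and length-of-stay bounds.
#' @return the filtered `cohort_table` with role `pretrain_pool`.
#' @export
filter_pretrain_pool <- function(cohort, sepsis_flags = NULL,
                                 registry = feature_registry(),
                                 apply_bounds = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  septic <- resolve_sepsis_flags(cohort, sepsis_flags, registry,
                                 need = cohort$stays$trauma_flag)
  trauma_sepsis <- cohort$stays$trauma_flag & septic
  keep <- !trauma_sepsis
  if (apply_bounds) keep <- keep & passes_inclusion_bounds(cohort$stays)
  subset_cohort(cohort, keep, role = "pretrain_pool")
}

subset_cohort <- function(cohort, keep, role) {
  stays <- cohort$stays[keep, , drop = FALSE]
  events <- cohort$events[cohort$events$stay_id %in% stays$stay_id, ,
                          drop = FALSE]
  rownames(stays) <- rownames(events) <- NULL
  structure(list(stays = stays, events = events, role = role),
            class = "cohort_table")
}
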