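#' Construct a staining-protocol schedule
#'
#' @param name Schedule identifier.
#' @param sample_type Free-text sample description (e.g. "MCF7 in Collagen").
#' @param steps Tibble/data frame with columns stage (dehydration, blocking,
#'   primary, nuclear, wash), solution, duration_min (> 0),
#'   temperature_c.
#' @param method One of "microwave", "benchtop", "longform".
#' @param fixation_min Fixation duration in minutes, stored separately and
#'   excluded from totals unless requested.
#' @return Object of class `protocol_schedule`.
#' @export
protocol_schedule <- function(name, sample_type, steps, method, fixation_min = NA_real_) {
  steps <- as_tibble(steps)
  required <- c("stage", "solution", "duration_min", "temperature_c")
  if (!all(required %in% names(steps))) {
    abort(paste0("steps must have columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(steps) == 0) abort("schedule has no steps")
  if (any(!is.finite(steps$duration_min)) || any(steps$duration_min <= 0)) {
    abort("every step duration must be a positive number of minutes")
  }
  stages <- c("dehydration", "blocking", "primary", "nuclear", "wash")
  if (!all(steps$stage %in% stages)) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(unique(steps$stage), stages), collapse = ", ")))
  }
  if (!method %in% c("microwave", "benchtop", "longform")) {
    abort("method must be microwave, benchtop or longform")
  }
  structure(
    list(name = name, sample_type = sample_type, steps = steps,
         method = method, fixation_min = fixation_min),
    class = "protocol_schedule"
  )
}

#' @export
print.protocol_schedule <- function(x, ...) {
  tot <- total_duration(x)
  cat(sprintf("<protocol_schedule> %s (%s, %s): %d steps, %g min = %.1f h%s\n",
              x$name, x$sample_type, x$method, nrow(x$steps),
              tot$minutes, tot$hours,
              if (is.finite(x$fixation_min)) {
                sprintf(" (+%g min fixation)", x$fixation_min)
              } else ""))
  invisible(x)
}

meoh_series <- function(durations, temp) {
  tibble(
    stage = "dehydration",
    solution = paste0(c(25, 50, 75, 95, 75, 50, 25), "% MeOH in 1x DPBS+/+"),
    duration_min = durations,
    temperature_c = temp
  )
}

standard_steps <- function(method, primary_min) {
  if (method %in% c("microwave", "benchtop")) {
    dplyr::bind_rows(
      meoh_series(c(2, 2, 2, 4, 2, 2, 2), if (method == "microwave") 10 else 4),
      tibble(stage = "blocking",
             solution = c("1x DPBS+/+, 0.2% TX-100",
                          "1x DPBS+/+, 0.2% TX-100, 1% BSA"),
             duration_min = c(5, 10), temperature_c = 21),
      tibble(stage = "primary",
             solution = "blocking buffer + primary antibodies",
             duration_min = primary_min,
             temperature_c = if (method == "microwave") 10 else 4),
      tibble(stage = "nuclear", solution = "1x DPBS+/+, 0.2% TX-100, DAPI",
             duration_min = 10,
             temperature_c = if (method == "microwave") 10 else 4),
      tibble(stage = "wash",
             solution = c("1x DPBS+/+, 0.2% TX-100", "1x DPBS+/+, 0.2% TX-100",
                          "1x DPBS+/+"),
             duration_min = c(10, 10, 5),
             temperature_c = if (method == "microwave") 10 else 4)
    )
  } else { # longform benchtop
    dplyr::bind_rows(
      meoh_series(c(30, 30, 30, 60, 30, 30, 30), 4),
      tibble(stage = "blocking",
             solution = c("1x DPBS+/+, 0.2% TX-100",
                          "1x DPBS+/+, 0.2% TX-100, 1% BSA"),
             duration_min = c(5, 60), temperature_c = 4),
      tibble(stage = "primary",
             solution = "blocking buffer + primary antibodies",
             duration_min = primary_min, temperature_c = 4),
      tibble(stage = "nuclear", solution = "1x DPBS+/+, 0.2% TX-100, DAPI",
             duration_min = 30, temperature_c = 4),
      tibble(stage = "wash",
             solution = c("1x DPBS+/+, 0.2% TX-100", "1x DPBS+/+, 0.2% TX-100",
                          "1x DPBS+/+"),
             duration_min = c(30, 30, 5), temperature_c = 4)
    )
  }
}

#' Built-in staining-protocol schedules
#'
#' The microwave, benchtop and longform-benchtop whole-mount
#' immunostaining schedules for hydrogel-embedded spheroids, as structured
#' step tables. Primary staining times differ by sample: 120 min for
#' MCF10A in collagen, 90 min for MCF10A in Matrigel, 40 min for MCF7 in
#' collagen, plus a 120-min microwave schedule used for the head-to-head
#' comparison against the 15-h longform benchtop protocol. Fixation (45 min
#' MCF10A, 20 min MCF7) is stored separately and excluded from totals by
#' default.
#'
#' @return Named list of [protocol_schedule()] objects.
#' @examples
#' sched <- builtin_schedules()
#' total_duration(sched$microwave_mcf7_longform_comparison)$hours
#' @export
builtin_schedules <- function() {
  mk <- function(name, sample, method, primary, fixation) {
    protocol_schedule(name, sample, standard_steps(method, primary),
                      method = method, fixation_min = fixation)
  }
  list(
    microwave_mcf10a_collagen =
      mk("microwave_mcf10a_collagen", "MCF10A in Collagen", "microwave", 120, 45),
    microwave_mcf10a_matrigel =
      mk("microwave_mcf10a_matrigel", "MCF10A in Matrigel", "microwave", 90, 45),
    microwave_mcf7_collagen =
      mk("microwave_mcf7_collagen", "MCF7 in Collagen", "microwave", 40, 20),
    microwave_mcf7_longform_comparison =
      mk("microwave_mcf7_longform_comparison", "MCF7 in Collagen (Longform comparison)",
         "microwave", 120, 20),
    benchtop_mcf10a_collagen =
      mk("benchtop_mcf10a_collagen", "MCF10A in Collagen", "benchtop", 120, 45),
    benchtop_mcf10a_matrigel =
      mk("benchtop_mcf10a_matrigel", "MCF10A in Matrigel", "benchtop", 90, 45),
    benchtop_mcf7_collagen =
      mk("benchtop_mcf7_collagen", "MCF7 in Collagen", "benchtop", 40, 20),
    longform_benchtop_mcf7 =
      mk("longform_benchtop_mcf7", "MCF7 in Collagen (Longform)", "longform",
         15 * 60, 20)
  )
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Total processing time of a schedule
#'
#' Sum of all step durations. Fixation is excluded by default (it is
#' performed on the bench in all protocol variants, so the schedule totals
#' compare the staining workflows themselves); set `include_fixation = TRUE`
#' for end-to-end totals. Hours are rounded half-up to one decimal.
#'
#' @param schedule A [protocol_schedule()].
#' @param include_fixation Add the stored fixation duration.
#' @return List with `minutes` (exact) and `hours` (one decimal).
#' @export
total_duration <- function(schedule, include_fixation = FALSE) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  mins <- sum(schedule$steps$duration_min)
  if (include_fixation) {
    if (!is.finite(schedule$fixation_min)) {
      abort("schedule has no recorded fixation duration")
    }
    mins <- mins + schedule$fixation_min
  }
  list(minutes = mins, hours = round_half_up(mins / 60, 1))
}

#' Ratio of total processing times of two schedules
#'
#' Returns `total(b) / total(a)`: how many times longer schedule `b` takes
#' than schedule `a`.
#'
#' @param a,b [protocol_schedule()] objects.
#' @param include_fixation Include fixation in both totals.
#' @param digits Optional rounding of the ratio (half-up).
#' @return Scalar ratio.
#' @examples
#' s <- builtin_schedules()
#' compare_schedules(s$microwave_mcf7_longform_comparison, s$longform_benchtop_mcf7)
#' @export
compare_schedules <- function(a, b, include_fixation = FALSE, digits = NULL) {
  ta <- total_duration(a, include_fixation)$minutes
  tb <- total_duration(b, include_fixation)$minutes
  if (ta <= 0 || tb <= 0) abort("schedule totals must be positive")
  ratio <- tb / ta
  if (!is.null(digits)) ratio <- round_half_up(ratio, digits)
  ratio
}

#' Read / write schedule files
#'
#' Schedules are stored as plain tab-separated text with one step per
#' record (columns stage, solution, duration_min, temperature_c) preceded
#' by `#`-prefixed header lines carrying name, sample_type, method and
#' fixation_min. [read_schedule()] inverts [write_schedule()] bit-exactly
#' for the built-in schedules.
#'
#' @param schedule A [protocol_schedule()].
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a [protocol_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  header <- c(
    paste0("# name: ", schedule$name),
    paste0("# sample_type: ", schedule$sample_type),
    paste0("# method: ", schedule$method),
    paste0("# fixation_min: ", schedule$fixation_min)
  )
  body <- c(
    paste(c("stage", "solution", "duration_min", "temperature_c"), collapse = "\t"),
    apply(schedule$steps, 1, function(r) {
      paste(c(r[["stage"]], r[["solution"]],
              format(as.numeric(r[["duration_min"]])),
              format(as.numeric(r[["temperature_c"]]))), collapse = "\t")
    })
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key, default = NA_character_) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) default else sub(paste0("^# ", key, ": "), "", m[1])
  }
  steps <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                                 invert = TRUE)),
                             sep = "\t", stringsAsFactors = FALSE)
  protocol_schedule(
    name = pick("name", "schedule"),
    sample_type = pick("sample_type", ""),
    steps = tibble(stage = steps$stage, solution = steps$solution,
                   duration_min = as.numeric(steps$duration_min),
                   temperature_c = as.numeric(steps$temperature_c)),
    method = pick("method", "benchtop"),
    fixation_min = as.numeric(pick("fixation_min", "NA"))
  )
}

#' Two-layer hydrogel thickness reference
#'
#' Mean measured thicknesses of the two collagen layers of the embedding
#' hydrogel (second-harmonic-generation z-stack measurements, mean and SD
#' over replicate wells): a 35-ul bottom layer of 197.5 +/- 51.4 um and a
#' 100-ul top layer of 607.7 +/- 16.9 um, summing to roughly 800 um of gel
#' the stains must traverse.
#'
#' @return Tibble: layer, volume_ul, mean_thickness_um, sd_thickness_um.
#' @export
hydrogel_layers <- function() {
  tibble(
    layer = c("bottom", "top"),
    volume_ul = c(35, 100),
    mean_thickness_um = c(197.5, 607.7),
    sd_thickness_um = c(51.4, 16.9)
  )
}

#' Total two-layer hydrogel thickness (um)
#'
#' @return Sum of the mean layer thicknesses from [hydrogel_layers()].
#' @export
total_gel_thickness <- function() {
  sum(hydrogel_layers()$mean_thickness_um)
}
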