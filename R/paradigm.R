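#' Sample jittered inter-stimulus intervals (truncated negative exponential)
#'
#' ISIs are drawn as `min + E` where `E` follows an exponential distribution
#' truncated at `max - min`; the exponential scale is solved numerically so
#' that the truncated mean equals `mean - min`. This is the standard
#' jittering scheme used to decorrelate event regressors in event-related
#' fMRI designs.
#'
#' @param n number of ISIs to draw.
#' @param isi_min,isi_max,isi_mean distribution parameters in seconds
#'   (defaults 14, 24, 18).
#' @param seed optional integer seed (local RNG, does not disturb the global
#'   stream when supplied).
#' @return Numeric vector of `n` ISIs in `[isi_min, isi_max]`.
#' @export
sample_isis <- function(n, isi_min = 14, isi_max = 24, isi_mean = 18,
                        seed = NULL) {
  if (!(isi_min < isi_mean && isi_mean < isi_max))
    stop("infeasible ISI parameters: need min < mean < max")
  if (n == 0) return(numeric(0))
  cap <- isi_max - isi_min
  target <- isi_mean - isi_min
  # truncated-exponential mean: 1/l - cap * exp(-l*cap) / (1 - exp(-l*cap))
  trunc_mean <- function(l) 1 / l - cap * exp(-l * cap) / (1 - exp(-l * cap))
  rate <- stats::uniroot(function(l) trunc_mean(l) - target,
                         interval = c(1e-6, 100), tol = 1e-12)$root
  draw <- function() {
    u <- stats::runif(n)
    excess <- -log(1 - u * (1 - exp(-rate * cap))) / rate
    isi_min + excess
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# Evaluate expr under a local RNG seed, restoring the global stream after.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build one run's event paradigm
#'
#' A run presents 5 events of each of the 3 conditions (centre stimulus,
#' medium annulus, large annulus), 2 s each, in a pseudorandom order with
#' truncated-exponential jittered ISIs, after a blank period covering the
#' dummy scan (~42 s) and baseline (30 s). Two timing variants with
#' different orders and ISIs are used to limit predictability; both are
#' reproducible from `(variant, seed)`.
#'
#' @param variant timing variant, 1 or 2.
#' @param seed integer seed.
#' @param conditions condition labels.
#' @param n_per_condition events per condition per run (default 5).
#' @param duration stimulus duration (s).
#' @param dummy,baseline pre-stimulus blank components (s).
#' @param run_length total run length (s), default 420 (7 min).
#' @param isi_min,isi_max,isi_mean ISI parameters (s).
#' @param max_retries bounded ISI resampling attempts when the schedule
#'   overflows the run.
#' @return An object of class `paradigm`: data.frame `events` with columns
#'   `onset`, `duration`, `trial_type`, plus timing metadata.
#' @export
build_paradigm <- function(variant = 1, seed = 1,
                           conditions = c("center", "medium", "large"),
                           n_per_condition = 5, duration = 2,
                           dummy = 42, baseline = 30, run_length = 420,
                           isi_min = 14, isi_max = 24, isi_mean = 18,
                           max_retries = 20) {
  stopifnot(variant %in% c(1, 2))
  n_events <- n_per_condition * length(conditions)
  # derived sub-seed keeps the two variants distinct but reproducible
  sub_seed <- (as.integer(seed) %% 10000000L) * 10L + as.integer(variant)
  build <- function() {
    order <- sample(rep(conditions, n_per_condition))
    for (attempt in seq_len(max_retries)) {
      isis <- sample_isis(n_events - 1, isi_min, isi_max, isi_mean)
      onsets <- dummy + baseline + c(0, cumsum(duration + isis))
      # last epoch needs onset + 14 s of data inside the run
      if (onsets[n_events] + duration + 14 <= run_length)
        return(list(order = order, onsets = onsets))
    }
    stop("paradigm schedule overflow: could not fit events in the run")
  }
  sched <- withr_seed(sub_seed, build())
  events <- data.frame(onset = sched$onsets, duration = duration,
                       trial_type = sched$order,
                       stringsAsFactors = FALSE)
  structure(list(events = events, timing_variant = variant,
                 run_length = run_length, dummy = dummy, baseline = baseline,
                 isi_min = isi_min, isi_max = isi_max, isi_mean = isi_mean,
                 seed = seed),
            class = "paradigm")
}

#' Write / read BIDS-style events tables
#'
#' Events are stored as tab-separated `events.tsv` with columns
#' `onset`, `duration`, `trial_type`.
#'
#' @param paradigm a [build_paradigm()] object (or a data.frame of events).
#' @param path file path.
#' @return `read_events_tsv` returns a data.frame of events.
#' @export
write_events_tsv <- function(paradigm, path) {
  events <- if (inherits(paradigm, "paradigm")) paradigm$events else paradigm
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
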