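#' Classify 2-back trials into signal-detection counts
#'
#' Scoreable trials are the third onwards; a trial is a target when its letter
#' equals the letter two positions back (validated against the stored
#' `is_target` flags). A "match" response on a target is a hit, any other
#' response (including no response) a miss; on non-targets, "match" is a false
#' alarm and anything else a correct rejection.
#'
#' @param trials data frame of trial records with columns `index`, `letter`,
#'   `is_target`, `response` and `rt_ms`, as produced by
#'   [generate_nback_session()].
#' @return An object of class `sdt_counts`: list with `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`.
#' @export
#' @examples
#' trials <- data.frame(index = 1:6,
#'                      letter = c("A", "B", "A", "C", "B", "C"),
#'                      is_target = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
#'                      response = "match", rt_ms = 500)
#' # trial 5 is not a 2-back match (B != A): validation fails
#' trials$is_target <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
#' classify_trials(trials)
classify_trials <- function(trials) {
  needed <- c("index", "letter", "is_target", "response")
  if (!all(needed %in% names(trials))) {
    stop("'trials' must contain columns: ", paste(needed, collapse = ", "))
  }
  trials <- trials[order(trials$index), , drop = FALSE]
  n <- nrow(trials)
  if (n < 3L) stop("at least 3 trials are required")
  expect_target <- c(FALSE, FALSE,
                     trials$letter[3:n] == trials$letter[1:(n - 2L)])
  if (!identical(as.logical(trials$is_target), expect_target)) {
    bad <- which(as.logical(trials$is_target) != expect_target)
    stop("'is_target' inconsistent with the letter sequence at trial(s): ",
         paste(trials$index[bad], collapse = ", "))
  }
  sc <- trials[3:n, , drop = FALSE]
  match_resp <- sc$response == "match"
  structure(list(
    hits = sum(sc$is_target & match_resp),
    misses = sum(sc$is_target & !match_resp),
    false_alarms = sum(!sc$is_target & match_resp),
    correct_rejections = sum(!sc$is_target & !match_resp)),
    class = "sdt_counts")
}

#' @export
print.sdt_counts <- function(x, ...) {
  cat(sprintf("sdt_counts: hits %d, misses %d, false alarms %d, correct rejections %d\n",
              x$hits, x$misses, x$false_alarms, x$correct_rejections))
  invisible(x)
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(H) - qnorm(FA)` from the hit rate `H = hits / (hits + misses)`
#' and false-alarm rate `FA = false_alarms / (false_alarms +
#' correct_rejections)`. Rates of exactly 0 or 1 are undefined under the
#' normal quantile; the default correction replaces 0 with `1/(2N)` and 1 with
#' `1 - 1/(2N)`, where `N` is the number of trials of that type.
#'
#' @param counts an `sdt_counts` object (or a list with the same fields).
#' @param correction `"adjust"` (the `1/(2N)` rule, default) or `"none"`
#'   (extreme rates give infinite d').
#' @return Sensitivity d', in z-score units.
#' @export
#' @examples
#' dprime(list(hits = 9772, misses = 228,
#'             false_alarms = 228, correct_rejections = 9772))  # ~4
dprime <- function(counts, correction = c("adjust", "none")) {
  correction <- match.arg(correction)
  n_t <- counts$hits + counts$misses
  n_n <- counts$false_alarms + counts$correct_rejections
  if (n_t < 1L || n_n < 1L) {
    stop("at least one target and one non-target trial are required")
  }
  h <- counts$hits / n_t
  fa <- counts$false_alarms / n_n
  if (correction == "adjust") {
    clamp <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    h <- clamp(h, n_t)
    fa <- clamp(fa, n_n)
  }
  stats::qnorm(h) - stats::qnorm(fa)
}

#' Mean reaction time on correct trials, with 3-SD outlier exclusion
#'
#' Restricts to correct trials carrying an explicit response (hits and correct
#' rejections answered "nonmatch"), computes the mean and SD of their RTs, and
#' excludes RTs outside mean +/- 3 SD in a single pass before returning the
#' mean of the survivors. This is the standard per-subject speed control used
#' when response speed must not confound an accuracy outcome.
#'
#' @param trials data frame of trial records (see [classify_trials()]).
#' @return Mean correct RT in milliseconds, with attribute `n_excluded_rt`
#'   giving the number of outlying RTs removed.
#' @export
mean_correct_rt <- function(trials) {
  counts <- classify_trials(trials)  # also validates the trial log
  n <- nrow(trials)
  sc <- trials[order(trials$index), , drop = FALSE][3:n, , drop = FALSE]
  correct <- (sc$is_target & sc$response == "match") |
    (!sc$is_target & sc$response == "nonmatch")
  rt <- sc$rt_ms[correct & sc$response != "none"]
  rt <- rt[!is.na(rt)]
  if (!length(rt)) stop("no correct responded trials; mean RT undefined")
  m <- mean(rt)
  s <- stats::sd(rt)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(rt)) else abs(rt - m) <= 3 * s
  out <- mean(rt[keep])
  attr(out, "n_excluded_rt") <- sum(!keep)
  out
}

#' Per-subject behavioural summary as JSON
#'
#' @param trials data frame of trial records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_json <- function(trials, path) {
  counts <- classify_trials(trials)
  rt <- mean_correct_rt(trials)
  jsonlite::write_json(
    list(hits = counts$hits, misses = counts$misses,
         fa = counts$false_alarms, cr = counts$correct_rejections,
         dprime = dprime(counts), mean_rt = as.numeric(rt),
         n_excluded_rt = attr(rt, "n_excluded_rt")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
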