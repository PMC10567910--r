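#' Simulate a scored hypnogram
#'
#' Draws a semi-Markov sleep-wake sequence on the scoring-epoch grid: each
#' state visit lasts a geometric number of epochs (mean
#' `state_mean_dwell_s / epoch_s`), after which the next state is drawn from
#' `transition_probs`. Labels are WAKE/NREM/REM; if `artifact_fraction > 0`
#' that fraction of epochs is relabelled ARTIFACT at random, mimicking
#' epochs a scorer marks for exclusion.
#'
#' @param cfg A [synth_config()].
#' @param duration_s Total duration (s); must be a multiple of `cfg$epoch_s`.
#' @param init_state Optional starting state (default: drawn uniformly).
#' @return A hypnogram tibble with columns `epoch` (1-based), `start_s`
#'   (epoch start on the EEG clock) and `state`, plus attributes `epoch_s`
#'   and `t0_s`.
#' @examples
#' hyp <- generate_hypnogram(synth_config(seed = 2), duration_s = 600)
#' table(hyp$state)
#' @export
generate_hypnogram <- function(cfg, duration_s, init_state = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n_epochs <- duration_s / cfg$epoch_s
  if (abs(n_epochs - round(n_epochs)) > 1e-9)
    stop("duration_s must be a multiple of epoch_s", call. = FALSE)
  n_epochs <- as.integer(round(n_epochs))
  withr_seed(cfg$seed, "hypnogram", {
    states <- sleep_states()
    P <- cfg$transition_probs[states, states]
    cur <- if (is.null(init_state)) sample(states, 1) else match.arg(init_state, states)
    labels <- character(0)
    while (length(labels) < n_epochs) {
      mean_ep <- max(cfg$state_mean_dwell_s[[cur]] / cfg$epoch_s, 1)
      # geometric number of epochs with the stated mean (support >= 1)
      dwell <- 1L + stats::rgeom(1, prob = 1 / mean_ep)
      labels <- c(labels, rep(cur, dwell))
      cur <- sample(states, 1, prob = P[cur, ])
    }
    labels <- labels[seq_len(n_epochs)]
    if (cfg$artifact_fraction > 0) {
      n_art <- round(cfg$artifact_fraction * n_epochs)
      if (n_art > 0)
        labels[sample.int(n_epochs, n_art)] <- "ARTIFACT"
    }
    new_hypnogram(labels, epoch_s = cfg$epoch_s)
  })
}

#' Construct a hypnogram from epoch labels
#'
#' @param labels Character vector of epoch labels (WAKE/NREM/REM/ARTIFACT).
#' @param epoch_s Epoch duration in seconds (default 10).
#' @param t0_s Start time of the first epoch on the EEG clock.
#' @return A hypnogram tibble (see [generate_hypnogram()]).
#' @export
new_hypnogram <- function(labels, epoch_s = 10, t0_s = 0) {
  stopifnot(length(labels) > 0, epoch_s > 0)
  bad <- setdiff(unique(labels), c(sleep_states(), "ARTIFACT"))
  if (length(bad))
    stop("unknown hypnogram labels: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    epoch = seq_along(labels),
    start_s = t0_s + (seq_along(labels) - 1) * epoch_s,
    state = as.character(labels)
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "t0_s") <- t0_s
  class(out) <- c("hypnogram", class(out))
  out
}

hyp_epoch_s <- function(hyp) attr(hyp, "epoch_s") %||% 10
hyp_t0_s <- function(hyp) attr(hyp, "t0_s") %||% 0
hyp_end_s <- function(hyp) hyp_t0_s(hyp) + nrow(hyp) * hyp_epoch_s(hyp)

# state label at given EEG-clock times; NA outside the scored span
hyp_state_at <- function(hyp, t_s) {
  idx <- floor((t_s - hyp_t0_s(hyp)) / hyp_epoch_s(hyp)) + 1
  idx[idx < 1 | idx > nrow(hyp)] <- NA_integer_
  hyp$state[idx]
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", nrow(x), " epochs x ", hyp_epoch_s(x), " s (",
      nrow(x) * hyp_epoch_s(x), " s total)\n", sep = "")
  print(table(x$state))
  invisible(x)
}

# run body with a stream-specific RNG state, restoring the caller's RNG.
# Each generator draws from its own substream so that e.g. regenerating the
# hypnogram does not perturb the photometry noise.
withr_seed <- function(seed, stream, body) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  # fold the stream name into the seed, keeping it inside 32-bit range
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  set.seed((as.integer(seed) %% 100000L) * 19777L + h)
  force(body)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
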