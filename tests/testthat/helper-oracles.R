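# Independent brute-force oracles used to validate the package's
# algorithmic primitives. These deliberately use naive formulations
# (full-vector scans, explicit loops) rather than the package's own code
# paths.

# Exhaustive peak/prominence/width computation: for each interior local
# maximum (leftmost sample of plateaus), find the nearest strictly higher
# samples by full scans, take interval minima for the prominence, and scan
# for the half-prominence crossings.
oracle_peaks <- function(x, fs = 1) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- width <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    higher <- which(x > x[p])
    lh <- higher[higher < p]
    rh <- higher[higher > p]
    lb <- if (length(lh)) max(lh) else 1L
    rb <- if (length(rh)) min(rh) else n
    min_l <- min(x[lb:p])
    min_r <- min(x[p:rb])
    prom[k] <- x[p] - max(min_l, min_r)
    ref <- x[p] - prom[k] / 2
    # left crossing within (lb, p]
    lx <- lb
    for (j in (p - 1L):lb) {
      if (x[j] <= ref) {
        lx <- j + (ref - x[j]) / (x[j + 1L] - x[j])
        break
      }
    }
    rx <- rb
    for (j in (p + 1L):rb) {
      if (x[j] <= ref) {
        rx <- j - (ref - x[j]) / (x[j - 1L] - x[j])
        break
      }
    }
    width[k] <- (rx - lx) / fs
  }
  tibble::tibble(index = peaks, prominence = prom, width_s = width)
}

# Run-length bout enumeration by explicit looping.
oracle_bouts <- function(labels, epoch_s, min_duration_s = 30) {
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
    dur <- (j - i + 1L) * epoch_s
    if (labels[i] != "ARTIFACT" && dur > min_duration_s)
      out[[length(out) + 1L]] <- data.frame(
        state = labels[i], start_s = (i - 1L) * epoch_s,
        end_s = j * epoch_s, duration_s = dur
      )
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(state = character(), start_s = numeric(),
               end_s = numeric(), duration_s = numeric())
}

# Brute-force consolidated-transition scan.
oracle_transitions <- function(labels, epoch_s, consolidation_s = 15) {
  k <- as.integer(ceiling(consolidation_s / epoch_s))
  kinds <- c("NREM->WAKE", "WAKE->NREM", "NREM->REM", "REM->WAKE")
  hits <- list()
  for (i in seq_len(length(labels) - 1L)) {
    kind <- paste0(labels[i], "->", labels[i + 1L])
    if (!kind %in% kinds) next
    if (i < k || i + k > length(labels)) next
    ok <- TRUE
    for (m in 1:k) {
      if (labels[i - m + 1L] != labels[i]) ok <- FALSE
      if (labels[i + m] != labels[i + 1L]) ok <- FALSE
    }
    if (ok)
      hits[[length(hits) + 1L]] <- data.frame(kind = kind,
                                              time_s = i * epoch_s)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(), time_s = numeric())
}

# Naive spike scan: walk the trace sample by sample.
oracle_spikes <- function(vm, fs, threshold_mv = -20, refractory_s = 0.002) {
  times <- numeric(0)
  last <- -Inf
  for (i in 2:length(vm)) {
    if (vm[i] >= threshold_mv && vm[i - 1] < threshold_mv) {
      tt <- (i - 1) / fs
      if (tt - last >= refractory_s) {
        times <- c(times, tt)
        last <- tt
      }
    }
  }
  times
}

# Event-detection scoring: a true event is recalled if any detection lies
# within tol of it; a detection is false if no true event lies within tol.
match_events <- function(truth, detected, tol_s = 1) {
  recalled <- vapply(truth, function(tt)
    any(abs(detected - tt) <= tol_s), TRUE)
  false_det <- vapply(detected, function(d)
    !any(abs(truth - d) <= tol_s), TRUE)
  list(sensitivity = if (length(truth)) mean(recalled) else NA_real_,
       fdr = if (length(detected)) mean(false_det) else 0)
}

# Random hypnogram labels (iid) for property tests.
random_labels <- function(n, p_artifact = 0.1) {
  sample(c("WAKE", "NREM", "REM", "ARTIFACT"), n, replace = TRUE,
         prob = c((1 - p_artifact) / 3, (1 - p_artifact) / 3,
                  (1 - p_artifact) / 3, p_artifact))
}
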