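# Basecaller backends. Real neural-network basecallers are closed or
# heavyweight; the pipeline only requires the backend contract (a pure
# function from signal reads to basecall results), so a deterministic
# pore-level mock is bundled for end-to-end testing and simulation.

#' Read-level mean qscore
#'
#' The phred transform of the mean per-base error probability:
#' `-10 * log10(mean(10^(-q_i / 10)))`. This is the convention production
#' basecallers use for read-level quality (it is monotone in the read's
#' expected error rate), not the arithmetic mean of the per-base scores.
#'
#' @param qualities Non-empty numeric vector of phred scores.
#' @return A single numeric value.
#' @examples
#' mean_qscore(c(20, 30, 40))  # ~24.33, pulled down by the worst bases
#' @export
mean_qscore <- function(qualities) {
  if (!length(qualities)) stop("mean_qscore is undefined for empty input")
  qualities <- as.numeric(qualities)
  if (anyNA(qualities)) stop("qualities must not contain NA")
  -10 * log10(mean(10^(-qualities / 10)))
}

#' Deterministic pore-level mock model
#'
#' Defines a toy pore chemistry shared by the signal simulator and the mock
#' basecaller: one current level per base, a fixed dwell (samples per base),
#' Gaussian noise, and the calibration used to map picoamps to raw ADC
#' units. The default levels are 20 pA apart so that the default noise
#' (sd 2 pA) leaves a wide, analysable recovery margin.
#'
#' @param level_pA Named numeric vector of per-base current levels (pA) for
#'   `A`, `C`, `G`, `T`; all pairwise distinct.
#' @param dwell Samples produced per base (>= 1).
#' @param noise_sd Gaussian noise standard deviation in pA (>= 0).
#' @param digitisation,offset,range,sampling_rate Calibration scalars
#'   (plausible nanopore-era constants by default).
#' @param seed Integer seed making simulation fully reproducible.
#' @return An object of class `mock_model`.
#' @export
mock_model <- function(level_pA = c(A = 80, C = 100, G = 120, T = 140),
                       dwell = 10L, noise_sd = 2,
                       digitisation = 8192, offset = 10, range = 1402.882,
                       sampling_rate = 4000, seed = 1L) {
  stopifnot(setequal(names(level_pA), c("A", "C", "G", "T")))
  level_pA <- level_pA[c("A", "C", "G", "T")]
  if (min(dist(level_pA)) <= 0) stop("per-base levels must be pairwise distinct")
  dwell <- as.integer(dwell)
  stopifnot(dwell >= 1L, noise_sd >= 0, digitisation > 0, range > 0,
            sampling_rate > 0)
  structure(
    list(level_pA = level_pA, dwell = dwell, noise_sd = as.numeric(noise_sd),
         digitisation = as.numeric(digitisation), offset = as.numeric(offset),
         range = as.numeric(range), sampling_rate = as.numeric(sampling_rate),
         seed = as.integer(seed)),
    class = "mock_model")
}

#' @export
print.mock_model <- function(x, ...) {
  cat(sprintf("<mock_model> levels %s pA; dwell %d; noise sd %g pA; seed %d\n",
              paste(sprintf("%s=%g", names(x$level_pA), x$level_pA),
                    collapse = " "),
              x$dwell, x$noise_sd, x$seed))
  invisible(x)
}

#' Basecall one read with the mock model
#'
#' Converts the signal to picoamps, partitions it into consecutive windows
#' of `dwell` samples, and assigns each window the base whose model level is
#' nearest the window median (ties break to the lexicographically smaller
#' base). The per-base quality is `min(40, max(2, round(margin)))` where
#' `margin` is the pA distance to the second-nearest level minus the
#' distance to the nearest. A trailing remainder shorter than one dwell is
#' discarded with a logged count.
#'
#' @param read A [signal_read()].
#' @param model A [mock_model()].
#' @return A [basecall_result()]; empty signal gives an empty sequence with
#'   `mean_qscore = NaN`.
#' @export
mock_basecall <- function(read, model) {
  stopifnot(inherits(read, "signal_read"), inherits(model, "mock_model"))
  D <- model$dwell
  pA <- to_pA(read)
  n_win <- length(pA) %/% D
  rem <- length(pA) - n_win * D
  if (rem > 0L)
    message(sprintf("read %s: discarding %d trailing sample(s) shorter than one dwell",
                    read$read_id, rem))
  if (n_win == 0L) return(basecall_result(read$read_id, "", integer()))
  m <- matrix(pA[seq_len(n_win * D)], nrow = D)
  med <- apply(m, 2L, median)
  d <- abs(outer(med, model$level_pA, "-"))      # n_win x 4, columns A,C,G,T
  nearest <- max.col(-d, ties.method = "first")  # "first" = lexicographic tie-break
  d_min <- d[cbind(seq_len(n_win), nearest)]
  d[cbind(seq_len(n_win), nearest)] <- Inf
  d_second <- do.call(pmin, as.data.frame(d))
  q <- as.integer(pmin(40, pmax(2, round(d_second - d_min))))
  basecall_result(read$read_id,
                  paste(names(model$level_pA)[nearest], collapse = ""),
                  q)
}

#' Create a basecaller backend
#'
#' A backend is the pluggable unit the pipeline dispatches batches to: a
#' name plus a pure `call(reads)` function returning one
#' [basecall_result()] per input read. `mock_backend()` wraps
#' [mock_basecall()] over a [mock_model()].
#'
#' @param name Backend name.
#' @param call Function taking a list of [signal_read()] and returning a
#'   list of [basecall_result()], one per read, in order.
#' @return An object of class `basecaller_backend`.
#' @export
basecaller_backend <- function(name, call) {
  stopifnot(is.character(name), length(name) == 1L, is.function(call))
  structure(list(name = name, call = call), class = "basecaller_backend")
}

#' @rdname basecaller_backend
#' @param model A [mock_model()].
#' @export
mock_backend <- function(model = mock_model()) {
  stopifnot(inherits(model, "mock_model"))
  b <- basecaller_backend("mock",
                          function(reads)
                            lapply(reads, mock_basecall, model = model))
  b$model <- model
  b
}
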