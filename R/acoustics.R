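#' Dynamic time warping distance between two fundamental-frequency traces
#'
#' Aligns two univariate F0 contours with dynamic time warping and returns
#' the alignment cost. The local cost is the absolute frequency difference,
#' steps are the symmetric set (match, insertion, deletion), and the total
#' cost is divided by the warping-path length so that traces of different
#' durations are comparable. Traces are mean-centred first by default, so
#' the distance reflects contour shape rather than absolute pitch.
#'
#' Among equally cheap warping paths the shortest is used for the
#' normalisation, which makes the value a deterministic function of the
#' two traces (no tie-break ambiguity).
#'
#' @param trace_a,trace_b numeric vectors of F0 values sampled at a uniform
#'   step (Hz). Length >= 2.
#' @param normalize divide total cost by warping-path length (default TRUE).
#' @param center subtract each trace's mean before aligning (default TRUE).
#' @return a single non-negative number; 0 exactly when one (centred)
#'   trace is a time-warping of the other.
#' @export
dtw_distance <- function(trace_a, trace_b, normalize = TRUE, center = TRUE) {
  trace_a <- as.numeric(trace_a)
  trace_b <- as.numeric(trace_b)
  if (length(trace_a) < 2 || length(trace_b) < 2)
    stop("traces must have length >= 2")
  if (anyNA(trace_a) || anyNA(trace_b))
    stop("traces must not contain missing values")
  if (center) {
    trace_a <- trace_a - mean(trace_a)
    trace_b <- trace_b - mean(trace_b)
  }
  dtw_core(trace_a, trace_b, normalize)
}

unordered_pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

check_calls <- function(calls) {
  need <- c("call_id", "individual_id", "recording_id", "call_type", "f0")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(calls$call_id)) stop("call_id must be unique")
  invisible(calls)
}

#' Pairwise acoustic distances between calls of different individuals
#'
#' Computes the DTW distance for every unordered pair of calls of the given
#' type coming from two different individuals, attaching the dyad (unordered
#' individual pair) and recording identifiers needed by the dyadic distance
#' model. The number of call pairs per dyad can be capped to bound the
#' quadratic growth in pair count; pairs are then subsampled
#' deterministically under `seed`.
#'
#' @param calls data.frame with columns `call_id`, `individual_id`,
#'   `recording_id`, `call_type` and a list-column `f0` holding the numeric
#'   F0 trace of each call.
#' @param type_filter call type to keep (default `"contact"`); `NULL` keeps
#'   all types.
#' @param max_pairs_per_dyad cap on call pairs per dyad (default `Inf`).
#' @param seed used only when subsampling capped dyads.
#' @param ... passed to [dtw_distance()].
#' @return data.frame with one row per call pair: `call_i`, `call_j`,
#'   `distance`, `dyad_id`, `id_i`, `id_j`, `rec_i`, `rec_j`,
#'   `same_recording` (always FALSE here).
#' @export
between_individual_distances <- function(calls, type_filter = "contact",
                                         max_pairs_per_dyad = Inf,
                                         seed = 1L, ...) {
  check_calls(calls)
  if (!is.null(type_filter)) calls <- calls[calls$call_type %in% type_filter, ]
  n <- nrow(calls)
  if (n < 2) return(empty_distance_table())
  idx <- t(utils::combn(n, 2))
  keep <- calls$individual_id[idx[, 1]] != calls$individual_id[idx[, 2]]
  idx <- idx[keep, , drop = FALSE]
  if (!nrow(idx)) return(empty_distance_table())
  dyad <- unordered_pair_id(calls$individual_id[idx[, 1]],
                            calls$individual_id[idx[, 2]])
  if (is.finite(max_pairs_per_dyad)) {
    sel <- with_seed(seed, {
      unlist(lapply(split(seq_along(dyad), dyad), function(k) {
        if (length(k) <= max_pairs_per_dyad) k
        else sort(sample(k, max_pairs_per_dyad))
      }), use.names = FALSE)
    })
    sel <- sort(sel)
    idx <- idx[sel, , drop = FALSE]
    dyad <- dyad[sel]
  }
  dist <- vapply(seq_len(nrow(idx)), function(k) {
    dtw_distance(calls$f0[[idx[k, 1]]], calls$f0[[idx[k, 2]]], ...)
  }, numeric(1))
  data.frame(call_i = calls$call_id[idx[, 1]],
             call_j = calls$call_id[idx[, 2]],
             distance = dist,
             dyad_id = dyad,
             id_i = calls$individual_id[idx[, 1]],
             id_j = calls$individual_id[idx[, 2]],
             rec_i = calls$recording_id[idx[, 1]],
             rec_j = calls$recording_id[idx[, 2]],
             same_recording = FALSE,
             stringsAsFactors = FALSE)
}

#' Pairwise acoustic distances within individuals
#'
#' DTW distances for every unordered pair of same-type calls from the same
#' individual; the input to the within-individual diversity model. Pairs of
#' calls from the same recording are flagged, since those tend to be more
#' similar than cross-recording pairs.
#'
#' @inheritParams between_individual_distances
#' @param max_pairs_per_individual cap on call pairs per individual.
#' @return data.frame as in [between_individual_distances()], with `id_i ==
#'   id_j` and `same_recording` set where `rec_i == rec_j`.
#' @export
within_individual_distances <- function(calls, type_filter = "contact",
                                        max_pairs_per_individual = Inf,
                                        seed = 1L, ...) {
  check_calls(calls)
  if (!is.null(type_filter)) calls <- calls[calls$call_type %in% type_filter, ]
  out <- lapply(split(seq_len(nrow(calls)), calls$individual_id), function(rows) {
    if (length(rows) < 2) return(NULL)
    idx <- t(utils::combn(length(rows), 2))
    if (is.finite(max_pairs_per_individual) &&
        nrow(idx) > max_pairs_per_individual) {
      sel <- with_seed(seed + length(rows),# differ across individuals
                       sort(sample(nrow(idx), max_pairs_per_individual)))
      idx <- idx[sel, , drop = FALSE]
    }
    i <- rows[idx[, 1]]; j <- rows[idx[, 2]]
    dist <- vapply(seq_along(i), function(k) {
      dtw_distance(calls$f0[[i[k]]], calls$f0[[j[k]]], ...)
    }, numeric(1))
    data.frame(call_i = calls$call_id[i], call_j = calls$call_id[j],
               distance = dist,
               dyad_id = unordered_pair_id(calls$individual_id[i],
                                           calls$individual_id[j]),
               id_i = calls$individual_id[i], id_j = calls$individual_id[j],
               rec_i = calls$recording_id[i], rec_j = calls$recording_id[j],
               same_recording = calls$recording_id[i] == calls$recording_id[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_distance_table())
  rownames(out) <- NULL
  out
}

empty_distance_table <- function() {
  data.frame(call_i = character(), call_j = character(), distance = numeric(),
             dyad_id = character(), id_i = character(), id_j = character(),
             rec_i = character(), rec_j = character(),
             same_recording = logical(), stringsAsFactors = FALSE)
}

#' Count amplitude-modulation peaks in a smoothed trace
#'
#' Information-content proxy for a call: the number of prominent local
#' maxima in its smoothed trace. A local maximum counts as a peak when its
#' prominence — its height above the higher of the two flanking troughs
#' (the minima separating it from the neighbouring maxima or the trace
#' ends) — reaches `min_height`. Endpoints are never peaks, and the count
#' is invariant to adding a constant offset to the whole trace.
#'
#' @param trace numeric vector (smoothed amplitude or F0 trace).
#' @param min_height minimum prominence for a peak (default 30, in trace
#'   units).
#' @return integer peak count.
#' @export
count_am_peaks <- function(trace, min_height = 30) {
  trace <- as.numeric(trace)
  if (length(trace) == 0) stop("empty trace")
  if (anyNA(trace)) stop("trace must not contain missing values")
  if (length(trace) < 3) return(0L)
  # collapse plateaus so a flat-topped bump counts once
  r <- rle(trace)
  v <- r$values
  if (length(v) < 3) return(0L)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  peaks <- which(is_max)
  if (!length(peaks)) return(0L)
  # troughs between consecutive maxima and between the ends and the
  # outermost maxima
  bounds <- c(1L, peaks, n)
  count <- 0L
  for (k in seq_along(peaks)) {
    left <- min(v[bounds[k]:peaks[k]])
    right <- min(v[peaks[k]:bounds[k + 2]])
    prom <- v[peaks[k]] - max(left, right)
    if (prom >= min_height) count <- count + 1L
  }
  count
}
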