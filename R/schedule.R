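# Acquisition schedules: the 7T glutamate-CEST protocol and WASSR.

# 43 offsets, sampled asymmetrically between -5 and +5 ppm: coarser 0.3/0.4
# ppm steps on the negative side beyond -1 ppm, uniform 0.2 ppm from -1 to +5.
.CEST_OFFSETS <- c(
  -5.0, -4.6, -4.3, -4.0, -3.6, -3.3, -3.0, -2.6, -2.3, -2.0, -1.6, -1.3,
  -1.0, -0.8, -0.6, -0.4, -0.2, 0.0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4,
  1.6, 1.8, 2.0, 2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0, 4.2,
  4.4, 4.6, 4.8, 5.0)

#' The canonical glutamate-CEST acquisition schedule
#'
#' Returns the 7T protocol schedule: 43 saturation offsets sampled
#' asymmetrically between -5.0 and +5.0 ppm with 13 unsaturated reference
#' (S0) dynamics interspersed at evenly spaced acquisition positions, 56
#' dynamics in total. The references allow correction of slow scanner signal
#' drift over the ~22 minute scan.
#'
#' @return an [OffsetSchedule-class]
#' @examples
#' sched <- canonicalSchedule()
#' length(scheduleOffsets(sched))   # 43
#' length(referenceIndices(sched))  # 13
#' @export
canonicalSchedule <- function() {
  nSat <- length(.CEST_OFFSETS)
  nRef <- 13L
  nDyn <- nSat + nRef
  refPos <- round(seq(1L, nDyn, length.out = nRef))  # 1-based, evenly spaced
  isRef <- seq_len(nDyn) %in% refPos
  off <- rep(NA_real_, nDyn)
  off[!isRef] <- .CEST_OFFSETS
  offsetSchedule(data.frame(index = seq_len(nDyn) - 1L, offset_ppm = off,
                            is_reference = isRef))
}

#' The WASSR B0-mapping schedule
#'
#' Low-power water saturation shift referencing offsets: +/-1.5 ppm with a
#' 0.1 ppm step outside +/-1.0 ppm and a 0.05 ppm step inside, giving 51
#' offsets, plus reference dynamics at the start and end of the series.
#'
#' @return an [OffsetSchedule-class]
#' @export
wassrSchedule <- function() {
  off <- c(seq(-1.5, -1.1, by = 0.1), seq(-1.0, 1.0, by = 0.05),
           seq(1.1, 1.5, by = 0.1))
  off <- round(off, 10)
  nDyn <- length(off) + 2L
  isRef <- c(TRUE, rep(FALSE, length(off)), TRUE)
  offv <- rep(NA_real_, nDyn)
  offv[!isRef] <- off
  offsetSchedule(data.frame(index = seq_len(nDyn) - 1L, offset_ppm = offv,
                            is_reference = isRef))
}

#' Read / write a schedule as TSV
#'
#' The on-disk format has columns `index`, `offset_ppm` (empty for
#' references) and `is_reference` (0/1).
#'
#' @param path file path
#' @param x an [OffsetSchedule-class]
#' @return `readSchedule`: an `OffsetSchedule`; `writeSchedule`: `path`,
#'   invisibly.
#' @export
readSchedule <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$is_reference <- df$is_reference != 0
  offsetSchedule(df)
}

#' @rdname readSchedule
#' @export
writeSchedule <- function(x, path) {
  e <- x@entries
  e$is_reference <- as.integer(e$is_reference)
  write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
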