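# Humidity correction and pass merging: raw transect records -> clean points.

#' Hygroscopic-growth correction factor
#'
#' Optical particle counters over-read at high humidity because droplets
#' scatter like particles.  The standard correction is
#' `CF(RH) = 1 + 0.25 RH^2 / (1 - RH)` with RH a fraction;
#' corrected = raw / CF.  CF is >= 1 and strictly increasing on `[0, 1)`.
#'
#' @param rh relative humidity as a fraction in `[0, 1)` (vectorised).
#' @return Correction factor(s) `>= 1`.
#' @examples
#' correction_factor(c(0, 0.5, 0.85)) # 1, 1.125, 2.204167
#' @export
correction_factor <- function(rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh >= 1))
    mk_stop("RH must be a fraction in [0, 1)")
  1 + 0.25 * rh^2 / (1 - rh)
}

#' Humidity-correct raw PM readings
#'
#' Divides `pm25_raw` and `pm10_raw` by [correction_factor()] of each
#' record's RH, adding `pm25` / `pm10` columns.  Record order is preserved.
#'
#' @param records transect data.frame with columns `pm25_raw`, `pm10_raw`,
#'   `rh` (fraction).
#' @return The records with corrected `pm25`, `pm10` columns appended.
#' @export
rh_correction <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) {
    records$pm25 <- numeric(0); records$pm10 <- numeric(0)
    return(records)
  }
  need <- c("pm25_raw", "pm10_raw", "rh")
  miss <- setdiff(need, names(records))
  if (length(miss)) mk_stop("records are missing column(s): ",
                            paste(miss, collapse = ", "))
  bad <- which(!is.finite(records$rh) | records$rh < 0 | records$rh >= 1)
  if (length(bad))
    mk_stop("invalid RH at record(s) ", paste(head(bad, 5), collapse = ", "))
  cf <- correction_factor(records$rh)
  records$pm25 <- records$pm25_raw / cf
  records$pm10 <- records$pm10_raw / cf
  records
}

#' Merge forward/backward passes into clean points
#'
#' Greedy spatial clustering in data order: each record joins the first
#' existing cluster whose seed lies within `merge_radius`, otherwise it opens
#' a new cluster at its own position.  Cluster coordinates and PM values are
#' arithmetic means of the members.  Deterministic for a fixed input order.
#'
#' @param records humidity-corrected records (from [rh_correction()]) with
#'   columns `x`, `y`, `pm25`, `pm10`.
#' @param merge_radius clustering radius (m, default 2.0 -- about the sample
#'   spacing at walking speed; keeps opposite street sides separate).
#' @return data.frame of clean points: `x`, `y`, `pm25`, `pm10`, `n_merged`.
#' @export
merge_passes <- function(records, merge_radius = 2.0) {
  records <- as.data.frame(records)
  need <- c("x", "y", "pm25", "pm10")
  miss <- setdiff(need, names(records))
  if (length(miss)) mk_stop("records are missing column(s): ",
                            paste(miss, collapse = ", "))
  n <- nrow(records)
  if (!n) return(data.frame(x = numeric(0), y = numeric(0),
                            pm25 = numeric(0), pm10 = numeric(0),
                            n_merged = integer(0)))
  seeds_x <- numeric(n); seeds_y <- numeric(n)
  assign_ <- integer(n); k <- 0L
  r2 <- merge_radius^2
  for (i in seq_len(n)) {
    if (k > 0L) {
      d2 <- (seeds_x[1:k] - records$x[i])^2 + (seeds_y[1:k] - records$y[i])^2
      hit <- which(d2 <= r2)
    } else hit <- integer(0)
    if (length(hit)) {
      assign_[i] <- hit[1]
    } else {
      k <- k + 1L
      seeds_x[k] <- records$x[i]; seeds_y[k] <- records$y[i]
      assign_[i] <- k
    }
  }
  f <- factor(assign_, levels = seq_len(k))
  out <- data.frame(
    x = as.vector(tapply(records$x, f, mean)),
    y = as.vector(tapply(records$y, f, mean)),
    pm25 = as.vector(tapply(records$pm25, f, mean)),
    pm10 = as.vector(tapply(records$pm10, f, mean)),
    n_merged = as.integer(table(f)))
  rownames(out) <- NULL
  out
}

#' Full preprocessing: correct, merge
#'
#' @param records raw transect records.
#' @param merge_radius see [merge_passes()].
#' @return Clean points data.frame.
#' @export
preprocess_transect <- function(records, merge_radius = 2.0) {
  merge_passes(rh_correction(records), merge_radius)
}
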