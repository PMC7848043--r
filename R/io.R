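TRACE_HEADER <- c("time_s", "phase", "fio2_pct", "fisevo_pct",
                  "fin2o_pct", "fico2_pct")

#' Write a gas trace to CSV
#'
#' Writes the monitor-facing view of a trace: time in seconds, phase label,
#' and inspired O2 / sevoflurane / N2O / CO2 in percent (4 decimal places,
#' the declared round-trip precision). Nitrogen is not written; it is the
#' balance to 100% and is reconstructed on read.
#'
#' @param trace A [gas_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gas_trace"))
  df <- data.frame(time_s = round(trace$time_min * 60, 6),
                   phase = trace$phase,
                   fio2_pct = round(100 * trace$o2, 4),
                   fisevo_pct = round(100 * trace$sevo, 4),
                   fin2o_pct = round(100 * trace$n2o, 4),
                   fico2_pct = round(100 * trace$co2, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gas trace from CSV
#'
#' Inverse of [write_trace()]: validates the header, numeric fields,
#' monotone time and percentage ranges (reporting the offending line on
#' failure), reconstructs nitrogen as the balance to 100%, and returns a
#' [gas_trace()]. `write_trace()` then `read_trace()` is the identity up to
#' the declared precision (1e-4 percentage points).
#'
#' @param path CSV path with header
#'   `time_s,phase,fio2_pct,fisevo_pct,fin2o_pct,fico2_pct`.
#' @return A [gas_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L)
    stop("parse error in ", path, ": empty file", call. = FALSE)
  hdr <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), TRACE_HEADER))
    stop("parse error in ", path, " line 1: expected header ",
         paste(TRACE_HEADER, collapse = ","), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- setdiff(TRACE_HEADER, "phase")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad))
      stop("parse error in ", path, " line ", bad[1] + 1L,
           ": non-numeric ", cn, call. = FALSE)
    df[[cn]] <- v
  }
  if (nrow(df) == 0L)
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1]
    stop("validation error in ", path, " line ", bad + 2L,
         ": time_s must be increasing", call. = FALSE)
  }
  pct <- as.matrix(df[, c("fio2_pct", "fin2o_pct", "fisevo_pct", "fico2_pct")])
  if (any(pct < 0 | pct > 100)) {
    bad <- which(apply(pct < 0 | pct > 100, 1, any))[1]
    stop("validation error in ", path, " line ", bad + 1L,
         ": percentages must lie in [0, 100]", call. = FALSE)
  }
  frac <- pct / 100
  n2 <- pmax(0, 1 - rowSums(frac))
  comp <- cbind(frac, n2)
  colnames(comp) <- c("o2", "n2o", "sevo", "co2", "n2")
  comp <- comp / rowSums(comp)
  dt_s <- if (nrow(df) > 1L) df$time_s[2] - df$time_s[1] else 5
  gas_trace(df$time_s / 60, df$phase, comp, sample_interval = dt_s / 60)
}
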