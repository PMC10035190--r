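#' Validate a replicated time-course abundance table
#'
#' The canonical data layout is long format with columns `isotopomer`,
#' `time`, `replicate`, `abundance`: strictly positive abundances on a
#' complete isotopomer x time x replicate grid, with at least two time
#' points and two replicates (replicates are needed to estimate the
#' per-cell sample variances that drive the shrinkage prior).
#'
#' @param data A data frame in long format.
#' @return The validated data, invisibly, as a tibble.
#' @export
validate_dataset <- function(data) {
  invisible(dataset_internal(data)$tbl)
}

# internal representation used by likelihood evaluation and the sampler:
# logy is a (T*m) x n matrix with rows ordered replicate-major
# (row (j-1)*T + t), columns in `isotopomers` order; row_idx maps each row
# to its time index so that logy - logmu[row_idx, ] gives residuals.
dataset_internal <- function(data, model = NULL) {
  data <- tibble::as_tibble(data)
  needed <- c("isotopomer", "time", "replicate", "abundance")
  if (!all(needed %in% names(data))) {
    stop_kb(paste0("data must have columns ", paste(needed, collapse = ", ")),
            "kb_schema_error")
  }
  if (any(!is.finite(data$abundance)) || any(data$abundance <= 0)) {
    bad <- which(!is.finite(data$abundance) | data$abundance <= 0)[1]
    stop_kb(sprintf("abundance must be finite and > 0 (row %d: %s, t=%s, rep=%s)",
                    bad, data$isotopomer[bad], format(data$time[bad]),
                    format(data$replicate[bad])),
            "kb_validation_error")
  }
  key <- paste(data$isotopomer, data$time, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop_kb("duplicate (isotopomer, time, replicate) records", "kb_schema_error")
  }
  isotopomers <- unique(as.character(data$isotopomer))
  if (!is.null(model)) {
    if (!setequal(isotopomers, model$observed)) {
      stop_kb("dataset isotopomers do not match the model's observed states",
              "kb_schema_error")
    }
    isotopomers <- model$observed
  }
  times <- sort(unique(data$time))
  reps <- sort(unique(data$replicate))
  Tn <- length(times); m <- length(reps); n <- length(isotopomers)
  if (nrow(data) != Tn * m * n) {
    stop_kb("incomplete isotopomer x time x replicate grid", "kb_schema_error")
  }
  if (Tn < 2L) stop_kb("need at least 2 time points", "kb_validation_error")
  if (m < 2L) stop_kb("need at least 2 replicates", "kb_validation_error")

  ti <- match(data$time, times)
  ji <- match(data$replicate, reps)
  ii <- match(as.character(data$isotopomer), isotopomers)
  logy <- matrix(NA_real_, Tn * m, n)
  logy[cbind((ji - 1L) * Tn + ti, ii)] <- log(data$abundance)
  row_idx <- rep(seq_len(Tn), m)

  # per-cell sample variances s_it^2 of log-abundance over replicates,
  # returned as a T x n matrix
  cellvar <- matrix(NA_real_, Tn, n)
  for (i in seq_len(n)) {
    yi <- matrix(logy[, i], Tn, m)
    cellvar[, i] <- apply(yi, 1L, stats::var)
  }

  list(tbl = data, isotopomers = isotopomers, times = times,
       m = m, T = Tn, n = n, logy = logy, row_idx = row_idx,
       cellvar = cellvar)
}
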