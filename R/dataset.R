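#' Expression datasets with per-sample experiment metadata
#'
#' An `expression_dataset` couples a genes x samples expression matrix with a
#' metadata table describing how each sample was obtained: steady-state
#' samples record the perturbed gene and its knockdown fraction delta; time
#' series samples record the replicate and the sampling time in hours.
#'
#' @param matrix Numeric genes x samples matrix; row names are gene
#'   identifiers, column names sample identifiers.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `kind` (`"steady_state"` or `"time_series"`), `replicate`
#'   (integer, time series only), `time_h` (hours, time series only),
#'   `perturbed_gene` (gene id, steady state only) and `knockdown_fraction`
#'   (delta in \[0, 1\], steady state only).
#' @param noise_level Multiplicative Gaussian noise level already applied to
#'   the matrix (0 for noiseless data).
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, sample_meta, noise_level = 0) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop_mikana("matrix needs gene row names")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("s%04d", seq_len(ncol(matrix)))
  }
  sample_meta <- as.data.frame(sample_meta)
  need <- c("sample_id", "kind", "replicate", "time_h", "perturbed_gene",
            "knockdown_fraction")
  for (col in setdiff(need, names(sample_meta))) {
    sample_meta[[col]] <- switch(col,
      sample_id = colnames(matrix),
      kind = NA_character_,
      replicate = NA_integer_,
      time_h = NA_real_,
      perturbed_gene = NA_character_,
      knockdown_fraction = NA_real_)
  }
  sample_meta <- sample_meta[, need]
  ds <- structure(list(matrix = matrix, sample_meta = sample_meta,
                       noise_level = noise_level),
                  class = "expression_dataset")
  validate_expression_dataset(ds)
  ds
}

validate_expression_dataset <- function(ds) {
  m <- ds$matrix
  meta <- ds$sample_meta
  if (ncol(m) != nrow(meta)) {
    stop_mikana("metadata rows (%d) do not match sample columns (%d)",
                nrow(meta), ncol(m))
  }
  if (nrow(meta)) {
    if (!identical(as.character(meta$sample_id), colnames(m))) {
      stop_mikana("sample_id order must match matrix columns")
    }
    if (anyDuplicated(meta$sample_id)) stop_mikana("duplicated sample ids")
    if (!all(meta$kind %in% c("steady_state", "time_series"))) {
      stop_mikana("sample kind must be steady_state or time_series")
    }
    ss <- meta$kind == "steady_state"
    if (any(ss & (is.na(meta$perturbed_gene)))) {
      stop_mikana("every steady-state sample needs a perturbed_gene")
    }
    kd <- meta$knockdown_fraction[ss]
    if (any(!is.na(kd) & (kd < 0 | kd > 1))) {
      stop_mikana("knockdown fractions must lie in [0, 1]")
    }
    ts <- meta$kind == "time_series"
    if (any(ts & is.na(meta$time_h))) {
      stop_mikana("every time-series sample needs a time")
    }
    for (rep in unique(meta$replicate[ts])) {
      tt <- meta$time_h[ts & meta$replicate == rep]
      if (any(diff(tt) <= 0)) {
        stop_mikana("time points must strictly increase within replicate %s",
                    rep)
      }
    }
  }
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  meta <- x$sample_meta
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d steady-state, %d time-series), noise level %.3g\n",
    nrow(x$matrix), ncol(x$matrix),
    sum(meta$kind == "steady_state"), sum(meta$kind == "time_series"),
    x$noise_level))
  invisible(x)
}

#' Subset an expression dataset by sample
#' @param x An `expression_dataset`.
#' @param samples Logical, integer or character index into the samples.
#' @return The dataset restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  keep <- if (is.character(samples)) {
    match(samples, x$sample_meta$sample_id)
  } else if (is.logical(samples)) {
    which(samples)
  } else {
    as.integer(samples)
  }
  expression_dataset(x$matrix[, keep, drop = FALSE],
                     x$sample_meta[keep, , drop = FALSE],
                     noise_level = x$noise_level)
}

# Restrict to a single experiment kind.
samples_of_kind <- function(x, kind) {
  subset_samples(x, x$sample_meta$kind == kind)
}

#' Add multiplicative Gaussian measurement noise
#'
#' Each expression value x is replaced by `x + eps` with
#' `eps ~ N(0, (level * x)^2)`, i.e. noise proportional to signal ("percent
#' of signal" noise). Values are independent across the matrix; the input is
#' not modified. Noisy values may go below zero, as measurement noise can;
#' they are floored at zero only when entering a Hill basis downstream.
#'
#' @param data An `expression_dataset`.
#' @param level Noise level as a fraction of signal (e.g. 0.1 for 10%).
#' @param seed Integer seed for reproducibility.
#' @return A new `expression_dataset` with noisy values and `noise_level`
#'   set to `level`.
#' @export
add_noise <- function(data, level, seed = NULL) {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) || level < 0) {
    stop_mikana("noise level must be a single non-negative number")
  }
  if (level == 0) return(data)
  with_seed(seed, {
    x <- data$matrix
    eps <- stats::rnorm(length(x), mean = 0, sd = level * abs(x))
    noisy <- x + matrix(eps, nrow(x), ncol(x), dimnames = dimnames(x))
    expression_dataset(noisy, data$sample_meta, noise_level = level)
  })
}

# Column-bind two datasets over the same gene universe.
bind_datasets <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!identical(rownames(a$matrix), rownames(b$matrix))) {
    stop_mikana("datasets cover different gene universes")
  }
  ids <- make.unique(c(colnames(a$matrix), colnames(b$matrix)))
  m <- cbind(a$matrix, b$matrix)
  colnames(m) <- ids
  meta <- rbind(a$sample_meta, b$sample_meta)
  meta$sample_id <- ids
  expression_dataset(m, meta, noise_level = max(a$noise_level, b$noise_level))
}
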