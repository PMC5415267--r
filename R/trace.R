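#' @title Time-binned population activity traces
#' @description The common result container of all three simulators. The
#' population activity of population \eqn{\alpha} in the bin starting at
#' \eqn{t_k} is \eqn{A_N^\alpha(t_k) = \Delta n^\alpha(t_k) / (N^\alpha
#' \Delta t)}, where \eqn{\Delta n} is the spike count of the bin.
#' @param dt bin width in s.
#' @param counts steps x M matrix of spike counts \eqn{\Delta n}.
#' @param N length-M vector of population sizes.
#' @param expected optional steps x M matrix of expected activities
#'   \eqn{\bar A(t)} in 1/s.
#' @param raster optional data frame (`time_s`, `population`, `neuron`).
#' @param pop_names optional population labels.
#' @return An object of class `activity_trace` with fields `dt`, `time`
#'   (bin start times), `counts`, `activity` (1/s), `N`, and optionally
#'   `expected` and `raster`.
#' @export
activity_trace <- function(dt, counts, N, expected = NULL, raster = NULL,
                           pop_names = NULL) {
  counts <- as.matrix(counts)
  N <- as.numeric(N)
  stopifnot(ncol(counts) == length(N))
  if (nrow(counts)) {
    over <- sweep(counts, 2, N, ">")
    if (any(counts < 0) || any(over)) {
      stop("spike counts must lie in [0, N] for every bin")
    }
  }
  activity <- sweep(counts, 2, N * dt, "/")
  if (!is.null(pop_names)) {
    colnames(counts) <- colnames(activity) <- pop_names
    if (!is.null(expected)) colnames(expected) <- pop_names
  }
  structure(list(dt = dt, time = (seq_len(nrow(counts)) - 1L) * dt,
                 counts = counts, activity = activity, N = N,
                 expected = expected, raster = raster,
                 pop_names = pop_names),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %d bins of %g s, %d population(s)\n",
              nrow(x$counts), x$dt, ncol(x$counts)))
  if (nrow(x$counts)) {
    cat("mean activity [1/s]:", paste(signif(colMeans(x$activity), 4),
                                      collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read an activity trace as delimited text
#'
#' The file stores one header line of metadata (`# dt=... N=... seed=...`)
#' followed by tab-separated columns `time_s` and one count column per
#' population.
#'
#' @param trace an [activity_trace()].
#' @param path file path.
#' @param seed optional seed to record in the metadata line.
#' @export
write_activity <- function(trace, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.12g N=%s seed=%s", trace$dt,
                     paste(trace$N, collapse = ","), seed), con)
  df <- data.frame(time_s = trace$time, trace$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  header <- readLines(path, n = 1L)
  dt <- as.numeric(sub(".*dt=([0-9.eE+-]+).*", "\\1", header))
  N <- as.numeric(strsplit(sub(".*N=([0-9,]+).*", "\\1", header), ",")[[1]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          check.names = FALSE)
  activity_trace(dt = dt, counts = as.matrix(df[, -1, drop = FALSE]), N = N,
                 pop_names = colnames(df)[-1])
}

#' Write a spike raster as delimited text
#'
#' Columns: `time_s`, `population`, `neuron`.
#' @param trace an [activity_trace()] carrying a raster.
#' @param path file path.
#' @export
write_raster <- function(trace, path) {
  if (is.null(trace$raster)) stop("trace carries no raster")
  utils::write.table(trace$raster, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Evaluate a chunk of code under a fixed seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
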