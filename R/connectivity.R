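#' Fixed in-degree random connectivity
#'
#' Draws, for every target neuron in population \eqn{\alpha}, a set of
#' exactly \eqn{C^{\alpha\beta} = \mathrm{round}(p^{\alpha\beta}
#' N^\beta)} presynaptic neurons from each source population
#' \eqn{\beta}, uniformly without replacement (no multapses). Within a
#' population the neuron itself is excluded from the candidate pool (no
#' autapses), except at full connectivity (`p = 1`), where honoring the
#' fixed in-degree of exactly `N` synapses requires the self-connection;
#' this keeps the realized coupling identical to the mesoscopic
#' effective coupling \eqn{J = pNw}, to which strongly coupled small
#' networks are very sensitive.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed; the result is deterministic given
#'   (`spec`, `seed`).
#' @return An object of class `connectivity`: a list with element
#'   `pre[[alpha]][[beta]]`, an in-degree x `N^alpha` integer matrix of
#'   presynaptic indices (1-based; 0 columns when the in-degree is 0),
#'   and `in_degree`, the realized M x M in-degree matrix.
#' @export
build_connectivity <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  M <- n_populations(spec)
  N <- pop_sizes(spec)
  pre <- vector("list", M)
  in_deg <- matrix(0L, M, M)
  with_seed(seed, {
    for (a in seq_len(M)) {
      pre[[a]] <- vector("list", M)
      for (b in seq_len(M)) {
        C <- round(spec$p[a, b] * N[b])
        if (abs(C - spec$p[a, b] * N[b]) > 1e-9) {
          message(sprintf(
            "in-degree p[%d,%d]*N[%d] = %g rounded to %d", a, b, b,
            spec$p[a, b] * N[b], as.integer(C)))
        }
        allow_autapse <- a == b && C == N[b]
        avail <- N[b] - as.integer(a == b && !allow_autapse)
        if (C > avail) {
          stop(sprintf(
            "required in-degree %d from population %d exceeds the %d available neurons",
            as.integer(C), b, avail))
        }
        C <- as.integer(C)
        in_deg[a, b] <- C
        mat <- matrix(0L, nrow = C, ncol = N[a])
        if (C > 0L) {
          for (i in seq_len(N[a])) {
            pool <- if (a == b && !allow_autapse) seq_len(N[b])[-i]
                    else seq_len(N[b])
            mat[, i] <- if (C == N[b]) pool else sample(pool, C,
                                                        replace = FALSE)
          }
        }
        pre[[a]][[b]] <- mat
      }
    }
  })
  structure(list(pre = pre, in_degree = in_deg, N = N), class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity> fixed in-degree matrix (target rows x source columns):\n")
  print(x$in_degree)
  invisible(x)
}
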