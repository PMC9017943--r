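#' Quality-control planning parameters
#'
#' Parameters of the finite-population sample-size formula used to size the
#' per-algorithm review samples: margin of error `e` (default 0.10), normal
#' score `z` (default 1.65), planning proportion `p` (default 0.50, the most
#' unfavorable hypothesis), and the confidence level of the exact binomial
#' interval (default 0.95).
#'
#' @param e margin of error, in (0, 1).
#' @param z normal score, > 0.
#' @param p planning proportion, in `[0, 1]`.
#' @param conf confidence level of the Clopper-Pearson interval, in (0, 1).
#' @return list of class `qc_params`.
#' @export
qc_params <- function(e = 0.10, z = 1.65, p = 0.50, conf = 0.95) {
  if (!is.numeric(e) || e <= 0 || e >= 1) stop("e must be in (0, 1)", call. = FALSE)
  if (!is.numeric(z) || z <= 0) stop("z must be > 0", call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (!is.numeric(conf) || conf <= 0 || conf >= 1) stop("conf must be in (0, 1)", call. = FALSE)
  structure(list(e = e, z = z, p = p, conf = conf), class = "qc_params")
}

#' Finite-population-corrected sample size
#'
#' Evaluates
#' \deqn{n = \frac{z^2 p (1-p) / e^2}{1 + z^2 p (1-p) / (e^2 N)}}
#' and rounds up. With the default parameters the size is about 60 for a
#' population of a few hundred patients and converges to 68 (the ceiling of
#' the uncorrected 68.0625) as N grows. Monotone non-decreasing in N,
#' decreasing in `e`, and never exceeds N.
#'
#' @param params a [qc_params()].
#' @param N population size (patients touched by the algorithm), >= 1.
#' @return integer sample size.
#' @export
qc_sample_size <- function(params = qc_params(), N) {
  stopifnot(inherits(params, "qc_params"))
  if (!is.numeric(N) || any(N < 1)) stop("N must be >= 1", call. = FALSE)
  n0 <- params$z^2 * params$p * (1 - params$p) / params$e^2
  as.integer(ceiling(n0 / (1 + n0 / N)))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (conservative) interval from Beta quantiles:
#' lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with lower = 0 when k = 0 and upper = 1 when k = n.
#'
#' @param k number of successes, 0 <= k <= n.
#' @param n number of trials, >= 1.
#' @param conf confidence level.
#' @return tibble with columns `lower`, `upper` (vectorized over `k`, `n`).
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  alpha <- 1 - conf
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(lower = lower, upper = upper)
}

#' Audit one inference algorithm by sampling against ground truth
#'
#' Draws a simple random sample (without replacement) of patients touched by
#' the given algorithm, of size [qc_sample_size()] for the touched population
#' (all of them when the population is smaller), and scores each sampled
#' patient as correctly processed when every value the algorithm wrote equals
#' the ground truth for that field and record. In a production program this
#' review is a human chart review; the sampling and estimation machinery is
#' the same.
#'
#' @param audit inference audit tibble (from [run_inference()]).
#' @param truth an `epr_truth` (from [generate_extract()]).
#' @param algorithm_id one of the stage/line algorithm ids.
#' @param params a [qc_params()].
#' @param seed integer seed making the sample reproducible.
#' @return tibble of class `qc_result`: `algorithm_id`, `N`, `n`, `k`,
#'   `proportion`, `ci_lower`, `ci_upper`, `conf`.
#' @export
run_algorithm_qc <- function(audit, truth, algorithm_id, params = qc_params(),
                             seed = 1L) {
  entries <- audit[audit$algorithm_id == algorithm_id, , drop = FALSE]
  pkeys <- unique(patient_key(entries$center_id, entries$patient_id))
  N <- length(pkeys)
  if (N == 0) {
    return(structure(tibble(algorithm_id = algorithm_id, N = 0L, n = 0L, k = NA_integer_,
                            proportion = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, conf = params$conf),
                     class = c("qc_result", class(tibble()))))
  }
  n <- min(qc_sample_size(params, N), N)
  sampled <- withr::with_seed(seed, sample(pkeys, n))

  truth_rec <- truth$records
  field_truth <- function(field, row_id) {
    i <- match(row_id, truth_rec$row_id)
    if (field == "disease_stage") as.character(truth_rec$true_stage[i])
    else as.character(truth_rec$true_line[i])
  }
  entry_pkey <- patient_key(entries$center_id, entries$patient_id)
  correct <- vapply(sampled, function(pk) {
    e <- entries[entry_pkey == pk, , drop = FALSE]
    expected <- mapply(field_truth, e$field, e$row_id)
    all(!is.na(e$after) & e$after == expected)
  }, logical(1))
  k <- sum(correct)
  ci <- clopper_pearson(k, n, params$conf)
  structure(tibble(algorithm_id = algorithm_id, N = as.integer(N), n = as.integer(n),
                   k = as.integer(k), proportion = k / n,
                   ci_lower = ci$lower, ci_upper = ci$upper, conf = params$conf),
            class = c("qc_result", class(tibble())))
}

#' Audit every algorithm present in an inference run
#'
#' @inheritParams run_algorithm_qc
#' @return tibble with one `qc_result` row per algorithm id found in the
#'   audit, mirroring a per-algorithm quality-control summary table.
#' @export
qc_all_algorithms <- function(audit, truth, params = qc_params(), seed = 1L) {
  ids <- sort(unique(audit$algorithm_id))
  bind_rows(lapply(seq_along(ids), function(i) {
    run_algorithm_qc(audit, truth, ids[i], params, seed + i)
  }))
}
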