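#' Fit first-order decay from transcription-shutoff time courses
#'
#' Abundances are normalized to t = 0 within each replicate, so the
#' model is `log(abundance / abundance_0) = -k * t` and the log-linear
#' least-squares fit is constrained through the origin (a free-intercept
#' fit is available behind `free_intercept`). Per replicate the rate is
#' the negative slope, clipped at 0 (no negative decay); the pooled
#' rate is the replicate mean with `se_k = SD / sqrt(n)`, and the
#' half-life is `ln(2) / k` (infinite when k is 0). Zeros are floored
#' at `epsilon` times the t = 0 abundance before taking logs, which
#' absorbs count dropouts at late timepoints.
#'
#' @param series Long tibble with columns `ref_id`, `replicate`, `time`
#'   (hours) and `abundance`; an optional `condition` column adds a
#'   grouping level. See [simulate_decay()].
#' @param epsilon Flooring fraction for zero abundances.
#' @param free_intercept Fit an unconstrained intercept instead of
#'   forcing the fit through the origin.
#' @return An object of class `decay_fit`: a tibble with one row per
#'   (`ref_id`, `condition`) carrying `k` (per hour), `half_life`
#'   (hours), `se_k`, `r_squared`, `n_replicates` and the per-replicate
#'   rates in the list-column `rep_k`.
#' @export
#' @examples
#' sim <- simulate_decay(c(mirA = log(2) / 4), noise_cv = 0, seed = 1)
#' fit_decay(sim$counts)   # recovers a 4 h half-life exactly
fit_decay <- function(series, epsilon = 1e-6, free_intercept = FALSE) {
  stopifnot(all(c("ref_id", "replicate", "time", "abundance") %in% names(series)))
  if (!"condition" %in% names(series)) series$condition <- "all"
  groups <- dplyr::distinct(series, .data$ref_id, .data$condition)
  fits <- purrr::pmap_dfr(groups, function(ref_id, condition) {
    sub <- series[series$ref_id == ref_id & series$condition == condition, ]
    rep_k <- vapply(split(sub, sub$replicate), function(d) {
      fit_one_replicate(d, epsilon, free_intercept)
    }, numeric(1))
    k <- mean(rep_k)
    se_k <- if (length(rep_k) > 1) stats::sd(rep_k) / sqrt(length(rep_k)) else NA_real_
    tibble(
      ref_id = ref_id,
      condition = condition,
      k = k,
      half_life = if (k > 1e-12) log(2) / k else Inf,
      se_k = se_k,
      r_squared = pooled_r_squared(sub, k, epsilon),
      n_replicates = length(rep_k),
      rep_k = list(unname(rep_k))
    )
  })
  structure(fits, class = c("decay_fit", class(fits)))
}

fit_one_replicate <- function(d, epsilon, free_intercept) {
  d <- d[order(d$time), ]
  if (anyDuplicated(d$time)) stop("duplicate timepoints within replicate", call. = FALSE)
  if (!0 %in% d$time) stop("replicate series lacks a t = 0 point", call. = FALSE)
  if (nrow(d) < 2) stop("single timepoint: cannot fit a rate", call. = FALSE)
  a0 <- d$abundance[d$time == 0]
  if (a0 <= 0) stop("all-zero or zero-start series", call. = FALSE)
  a <- d$abundance / a0
  if (any(a <= 0)) {
    warning("zero abundances floored at epsilon * t0 before log", call. = FALSE)
    a[a <= 0] <- epsilon
  }
  y <- log(a)
  t <- d$time
  slope <- if (free_intercept) {
    stats::coef(stats::lm(y ~ t))[["t"]]
  } else {
    sum(t * y) / sum(t^2)
  }
  k <- -slope
  if (k < 0) {
    warning("upward drift in series (negative rate clipped at 0)", call. = FALSE)
    k <- 0
  }
  k
}

pooled_r_squared <- function(sub, k, epsilon) {
  ys <- unlist(lapply(split(sub, sub$replicate), function(d) {
    a0 <- d$abundance[d$time == 0]
    a <- d$abundance / a0
    a[a <= 0] <- epsilon
    log(a)
  }))
  ts <- unlist(lapply(split(sub, sub$replicate), function(d) d$time))
  fitted <- -k * ts
  ss_res <- sum((ys - fitted)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}

#' Compare decay rates between two conditions
#'
#' Reports the rate ratio `k_b / k_a` per reference and a Welch
#' two-sided t-test on the replicate-level rates.
#'
#' @param fit_a,fit_b `decay_fit` objects from [fit_decay()] with >= 2
#'   replicates each; references are matched by `ref_id`.
#' @return Tibble with `ref_id`, `k_a`, `k_b`, `ratio`, `p_value`.
#' @export
compare_decay <- function(fit_a, fit_b) {
  shared <- intersect(fit_a$ref_id, fit_b$ref_id)
  if (length(shared) == 0) stop("no shared ref_id between fits", call. = FALSE)
  purrr::map_dfr(shared, function(id) {
    a <- fit_a[fit_a$ref_id == id, ]
    b <- fit_b[fit_b$ref_id == id, ]
    ka <- a$rep_k[[1]]
    kb <- b$rep_k[[1]]
    if (length(ka) < 2 || length(kb) < 2) {
      stop("compare_decay needs >= 2 replicates per condition", call. = FALSE)
    }
    p <- if (identical(ka, kb) || (stats::sd(ka) == 0 && stats::sd(kb) == 0 &&
                                   mean(ka) == mean(kb))) {
      1
    } else if (stats::sd(ka) == 0 && stats::sd(kb) == 0) {
      warning("zero variance in both conditions with unequal rates; p unavailable",
              call. = FALSE)
      NA_real_
    } else {
      stats::t.test(ka, kb)$p.value
    }
    tibble(
      ref_id = id,
      k_a = a$k, k_b = b$k,
      ratio = b$k / a$k,
      p_value = p
    )
  })
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  out <- x[, c("ref_id", "condition", "k", "half_life", "se_k",
               "r_squared", "n_replicates")]
  class(out) <- setdiff(class(out), "decay_fit")
  out
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    n_series = nrow(x),
    mean_k = mean(x$k),
    mean_r_squared = mean(x$r_squared),
    n_replicates = sum(x$n_replicates)
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order decay fit (through-origin log-linear)\n")
  print(tidy(x), ...)
  invisible(x)
}
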