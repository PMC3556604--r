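#' Construct a concentration-response function record
#'
#' A concentration-response (C-R) function is the log-linear model
#' `y = B * exp(beta * x)` estimated by an epidemiological study: `beta` is
#' the log-rate coefficient per ppb of the stated ozone metric and `se` its
#' standard error. The intercept `B` (incidence at zero ozone) cancels in
#' the health impact function and is not stored.
#'
#' @param study Study label.
#' @param endpoint Health endpoint (e.g. "nonaccidental mortality").
#' @param metric Ozone metric the coefficient is expressed per ppb of:
#'   one of `"MDA8"`, `"24h-mean"`, `"1h-max"`.
#' @param beta Coefficient (per ppb).
#' @param se Standard error of `beta` (per ppb), > 0.
#' @param age_lo,age_hi Age range the function applies to (years,
#'   half-open; `Inf` allowed).
#' @return A one-row tibble of class `o3_crf`.
#' @export
crf <- function(study, endpoint, metric, beta, se, age_lo = 0, age_hi = Inf) {
  metric <- match.arg(metric, crf_metrics())
  if (!is.finite(beta)) stop("`beta` must be finite", call. = FALSE)
  if (!is.finite(se) || se <= 0) stop("`se` must be finite and > 0", call. = FALSE)
  if (age_lo < 0 || age_lo > age_hi) stop("invalid age range", call. = FALSE)
  out <- tibble::tibble(study = study, endpoint = endpoint, metric = metric,
                        beta = beta, se = se, age_lo = age_lo, age_hi = age_hi)
  class(out) <- c("o3_crf", class(out))
  out
}

#' @rdname crf
#' @export
crf_metrics <- function() c("MDA8", "24h-mean", "1h-max")

#' Default ozone-metric conversion ratios
#'
#' Ratios `r` such that a coefficient per ppb of `from` becomes a
#' coefficient per ppb of `to` via `beta_to = beta_from * r`. These
#' defaults are illustrative only (used by the synthetic fixtures), not
#' authoritative conversion factors; supply study-specific ratios for real
#' analyses. The table is closed under inversion (`r(a,b) * r(b,a) = 1`)
#' and contains the identity.
#'
#' @return Tibble `from`, `to`, `ratio`.
#' @export
default_metric_conversions <- function() {
  base <- tibble::tribble(
    ~from,      ~to,     ~ratio,
    "24h-mean", "MDA8",  0.67,
    "1h-max",   "MDA8",  0.90
  )
  inv <- tibble::tibble(from = base$to, to = base$from, ratio = 1 / base$ratio)
  ident <- tibble::tibble(from = crf_metrics(), to = crf_metrics(), ratio = 1)
  dplyr::bind_rows(base, inv, ident)
}

#' Convert a C-R coefficient to another ozone metric
#'
#' Scales `beta` and `se` by the conversion ratio from the function's
#' current metric to `target` and relabels the metric. Study and endpoint
#' are unchanged.
#'
#' @param f A C-R function (see [crf()]); multi-row tibbles are converted
#'   row-wise.
#' @param target Target metric.
#' @param conversions Conversion table (`from`, `to`, `ratio`); default
#'   [default_metric_conversions()].
#' @return The converted C-R tibble.
#' @export
convert_metric <- function(f, target, conversions = default_metric_conversions()) {
  target <- match.arg(target, crf_metrics())
  ratio <- vapply(f$metric, function(m) {
    hit <- conversions$ratio[conversions$from == m & conversions$to == target]
    if (length(hit) != 1) NA_real_ else hit
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(ratio)) {
    stop("no conversion ratio from ",
         paste(unique(f$metric[is.na(ratio)]), collapse = ", "),
         " to ", target, call. = FALSE)
  }
  out <- f
  out$beta <- f$beta * ratio
  out$se <- f$se * ratio
  out$metric <- target
  out
}

#' Pool several C-R estimates for one endpoint
#'
#' Combines two or more study coefficients for the same endpoint and metric
#' into a single estimate. `method = "fixed"` is the inverse-variance
#' weighted mean with `w_i = 1/se_i^2` and pooled
#' `se = (sum w_i)^(-1/2)`. `method = "random"` (the default, the usual
#' convention for multi-city mortality studies) adds a DerSimonian-Laird
#' moment estimate of between-study variance to each study variance before
#' inverse-variance weighting.
#'
#' @param functions Tibble of >= 2 C-R rows sharing `endpoint` and `metric`.
#' @param method `"random"` (default) or `"fixed"`.
#' @return A one-row pooled `o3_crf`; the pooled coefficient lies within
#'   the range of the inputs. The age range is the union of input ranges.
#' @export
pool_crf <- function(functions, method = c("random", "fixed")) {
  method <- match.arg(method)
  if (nrow(functions) < 2) stop("pooling needs at least two functions", call. = FALSE)
  if (dplyr::n_distinct(functions$endpoint) != 1 ||
      dplyr::n_distinct(functions$metric) != 1) {
    stop("all functions must share one endpoint and one metric", call. = FALSE)
  }
  b <- functions$beta
  v <- functions$se^2
  w <- 1 / v
  tau2 <- 0
  if (method == "random") {
    k <- length(b)
    mu_fixed <- sum(w * b) / sum(w)
    q <- sum(w * (b - mu_fixed)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / denom)
    w <- 1 / (v + tau2)
  }
  beta_p <- sum(w * b) / sum(w)
  se_p <- sqrt(1 / sum(w))
  out <- crf(
    study = paste0("pooled(", paste(functions$study, collapse = " + "), ")"),
    endpoint = functions$endpoint[1],
    metric = functions$metric[1],
    beta = beta_p, se = se_p,
    age_lo = min(functions$age_lo), age_hi = max(functions$age_hi)
  )
  attr(out, "tau2") <- tau2
  attr(out, "method") <- method
  out
}
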