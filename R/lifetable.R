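#' Age-specific life table
#'
#' @param ages Strictly increasing integer ages in years.
#' @param qx Annual death probabilities, each in `[0, 1)`.
#' @return A `life_table` object (data.frame with columns `age`, `qx`).
#' @export
life_table <- function(ages, qx) {
  ages <- as.numeric(ages)
  qx <- as.numeric(qx)
  if (length(ages) != length(qx)) stop("`ages` and `qx` lengths differ", call. = FALSE)
  if (length(ages) == 0L) stop("empty life table", call. = FALSE)
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing", call. = FALSE)
  if (any(qx < 0 | qx >= 1)) stop("qx must lie in [0, 1)", call. = FALSE)
  structure(data.frame(age = ages, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read a life table from a delimited file with columns `age` and `qx`
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return A [life_table()].
#' @export
read_life_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  if (!all(c("age", "qx") %in% names(tab))) {
    stop("life-table file must have columns `age` and `qx`", call. = FALSE)
  }
  life_table(tab$age, tab$qx)
}

#' Fit a logistic mortality curve to a life table
#'
#' Least-squares fit of the three-parameter logistic
#' `q(a) = L / (1 + exp(-k (a - a0)))` to annual death probabilities. A flat
#' table (no variation in `qx`) degenerates to the limiting flat curve
#' `L = 2 * mean(qx)`, `k -> 0`.
#'
#' @param table A [life_table()] with at least 4 distinct ages.
#' @return A `logistic_mortality` object with fields `L`, `k`, `a0`, plus the
#'   fitted table range.
#' @export
fit_logistic_mortality <- function(table) {
  stopifnot(inherits(table, "life_table"))
  if (nrow(table) < 4L) stop("need at least 4 ages to fit", call. = FALSE)
  if (all(table$qx == 0)) stop("degenerate life table: all qx are zero", call. = FALSE)
  a <- table$age
  q <- table$qx

  flat <- function() {
    new_logistic_mortality(L = min(2 * mean(q), 1), k = 1e-8,
                           a0 = mean(range(a)), age_range = range(a))
  }
  if (stats::sd(q) < 1e-12) return(flat())

  L0 <- min(max(q) * 1.05, 1)
  a00 <- a[which.min(abs(q - L0 / 2))]
  # crude slope start from a logit-linearization
  z <- pmin(pmax(q / L0, 1e-6), 1 - 1e-6)
  k0 <- tryCatch(max(stats::coef(stats::lm(stats::qlogis(z) ~ a))[[2]], 1e-4),
                 error = function(e) 0.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      q ~ L / (1 + exp(-k * (a - a0))),
      start = list(L = L0, k = k0, a0 = a00),
      lower = c(L = 1e-8, k = 1e-8, a0 = -Inf),
      upper = c(L = 1, k = Inf, a0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flat())
  cf <- stats::coef(fit)
  new_logistic_mortality(cf[["L"]], cf[["k"]], cf[["a0"]], range(a))
}

new_logistic_mortality <- function(L, k, a0, age_range) {
  if (L <= 0 || L > 1 || k <= 0) stop("invalid logistic mortality parameters", call. = FALSE)
  structure(list(L = L, k = k, a0 = a0, age_range = age_range),
            class = "logistic_mortality")
}

#' Construct a logistic mortality model from known parameters
#' @param L Asymptote on the probability scale, in `(0, 1]`.
#' @param k Steepness per year, `> 0`.
#' @param a0 Midpoint age in years.
#' @param age_range Modelled age range (informational), default `c(0, 120)`.
#' @return A `logistic_mortality` object.
#' @export
logistic_mortality <- function(L, k, a0, age_range = c(0, 120)) {
  new_logistic_mortality(L, k, a0, age_range)
}

#' @export
print.logistic_mortality <- function(x, ...) {
  cat(sprintf("Logistic mortality: q(a) = %.4g / (1 + exp(-%.4g (a - %.4g)))\n",
              x$L, x$k, x$a0))
  invisible(x)
}

#' Annual death probability at an attained age
#'
#' @param model A `logistic_mortality` object, or a [life_table()] (linear
#'   interpolation with flat extrapolation beyond the table's range).
#' @param age Attained age in years (vectorized).
#' @return Annual death probabilities in `[0, 1)`.
#' @export
annual_death_prob <- function(model, age) {
  if (inherits(model, "life_table")) {
    return(stats::approx(model$age, model$qx, xout = age, rule = 2)$y)
  }
  stopifnot(inherits(model, "logistic_mortality"))
  pmin(model$L / (1 + exp(-model$k * (age - model$a0))), 1 - 1e-12)
}

#' Per-cycle death probability at an attained age
#'
#' Converts the annual death probability into a per-cycle probability under a
#' constant hazard within the year, with a hazard ratio applied on the hazard
#' scale: `p = 1 - exp(-hr * (-log(1 - q)) * cycle_length / 365.25)`.
#'
#' @param model A `logistic_mortality` or [life_table()].
#' @param age Attained age in years (vectorized).
#' @param hr Hazard ratio (`> 0`), default 1.
#' @param cycle_length Cycle length in days, default 28.
#' @return Per-cycle death probabilities in `[0, 1]`.
#' @examples
#' m <- logistic_mortality(0.7, 0.09, 97)
#' cycle_death_prob(m, 68, hr = 2.39)
#' @export
cycle_death_prob <- function(model, age, hr = 1, cycle_length = 28) {
  hr <- if (is.list(hr)) hr$value else hr
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  if (cycle_length <= 0) stop("cycle_length must be > 0", call. = FALSE)
  q <- annual_death_prob(model, age)
  if (any(q >= 1)) stop("annual death probability >= 1", call. = FALSE)
  1 - exp(-hr * (-log1p(-q)) * cycle_length / 365.25)
}
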