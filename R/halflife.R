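#' Spike-in normalization of a decay time course
#'
#' Converts raw per-sample expression to concentrations comparable across
#' time points: each sample's scale factor is the known total spike-in input
#' amount divided by the observed total spike-in signal in that sample, and
#' every gene's value is multiplied by it. Spike-in rows are identified by a
#' name prefix (default `"ERCC-"`).
#'
#' @param counts Numeric matrix, genes + spike-ins in rows, samples
#'   (time points) in columns.
#' @param spikein_amounts Named vector of known spike-in input amounts; the
#'   names select the spike-in rows.
#' @param timepoints Numeric time in hours for each column (taken from
#'   column names of the form "t<h>" when missing).
#' @param prefix Spike-in row-name prefix used for validation.
#' @return A `decay_course` list: `concentrations` (gene rows only, spike-in
#'   rows dropped), `timepoints`, `scale_factors`.
#' @export
spikein_normalize <- function(counts, spikein_amounts, timepoints = NULL,
                              prefix = "ERCC-") {
  counts <- as.matrix(counts)
  spk <- intersect(names(spikein_amounts), rownames(counts))
  if (length(spk) == 0L)
    stop("no spike-in rows found in `counts`", call. = FALSE)
  obs <- colSums(counts[spk, , drop = FALSE])
  if (any(obs <= 0))
    stop("zero spike-in counts in sample(s): ",
         paste(colnames(counts)[obs <= 0], collapse = ", "), call. = FALSE)
  scale <- sum(spikein_amounts[spk]) / obs
  genes <- setdiff(rownames(counts), spk)
  genes <- genes[!startsWith(genes, prefix)]
  conc <- sweep(counts[genes, , drop = FALSE], 2, scale, `*`)
  if (is.null(timepoints)) {
    tp <- suppressWarnings(as.numeric(sub("^t", "", colnames(counts))))
    if (any(is.na(tp)))
      stop("give `timepoints` or name columns t0, t1, ...", call. = FALSE)
    timepoints <- tp
  }
  structure(list(concentrations = conc, timepoints = timepoints,
                 scale_factors = scale),
            class = "decay_course")
}

#' Fit an exponential decay to one gene's time course
#'
#' Least-squares fit of `y(t) = Asym + (R0 - Asym) exp(-k_decay * t)` via
#' `nls` with the `SSasymp` self-start (falling back to a Levenberg-
#' Marquardt fit with log-linear initialization when the self-start fails),
#' returning the decay constant in 1/h and the half-life `log(2)/k_decay`
#' in hours. With `asymptote = FALSE` the floor is pinned at 0 and the pure
#' exponential `R0 exp(-k t)` is fitted by linear least squares on the log
#' scale (the efficient estimator under multiplicative noise; the raw-scale
#' fit is used when non-positive values preclude logs).
#'
#' @param y Concentrations at the time points (replicate points allowed:
#'   supply matching `t` of equal length).
#' @param t Time in hours (must include 0; at least 4 finite points).
#' @param asymptote Fit a free asymptote (default `TRUE`, as in `SSasymp`).
#' @return A one-row tibble: `Asym`, `R0`, `k_decay_per_hour`,
#'   `half_life_hours`, `rss`, `converged`. Non-convergence (or a
#'   non-positive decay constant) yields `converged = FALSE` and `NA`
#'   half-life.
#' @export
fit_decay <- function(y, t, asymptote = TRUE) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 4L)
    return(decay_row(NA, NA, NA, NA, NA, FALSE))
  df <- data.frame(t = t, y = y)
  fit <- NULL
  if (asymptote) {
    fit <- tryCatch(nls(y ~ SSasymp(t, Asym, R0, lrc), data = df),
                    error = function(e) NULL)
    if (is.null(fit)) {
      st <- decay_start(y, t)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * t),
                          data = df,
                          start = list(Asym = st$Asym, R0 = st$R0,
                                       lrc = st$lrc)),
        error = function(e) NULL)
    }
    if (is.null(fit)) return(decay_row(NA, NA, NA, NA, NA, FALSE))
    cf <- coef(fit)
    k <- exp(cf[["lrc"]])
    asym <- cf[["Asym"]]; r0 <- cf[["R0"]]
  } else if (all(y > 0)) {
    # pinned zero asymptote: least squares of log y on t (the efficient
    # estimator under multiplicative log-normal noise)
    fitl <- lm(log(y) ~ t)
    k <- -coef(fitl)[[2]]
    r0 <- exp(coef(fitl)[[1]])
    asym <- 0
    fit <- fitl
  } else {
    st <- decay_start(y, t, asym0 = 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ R0 * exp(-exp(lrc) * t), data = df,
                        start = list(R0 = st$R0, lrc = st$lrc)),
      error = function(e) NULL)
    if (is.null(fit)) return(decay_row(NA, NA, NA, NA, NA, FALSE))
    cf <- coef(fit)
    k <- exp(cf[["lrc"]])
    asym <- 0; r0 <- cf[["R0"]]
  }
  rss <- sum(stats::residuals(fit)^2)
  conv <- is.finite(k) && k > 0 && r0 > asym
  decay_row(asym, r0, k, if (conv) log(2) / k else NA_real_, rss, conv)
}

decay_row <- function(Asym, R0, k, hl, rss, conv) {
  tibble::tibble(Asym = Asym, R0 = R0, k_decay_per_hour = k,
                 half_life_hours = hl, rss = rss, converged = conv)
}

# log-linear self-start: floor estimate from the late time points, then a
# regression of log(y - floor) on t for the rate
decay_start <- function(y, t, asym0 = NULL) {
  if (is.null(asym0)) asym0 <- 0.5 * min(y[t >= stats::median(t)])
  z <- pmax(y - asym0, max(y) * 1e-6)
  fitl <- lm(log(z) ~ t)
  k0 <- max(-coef(fitl)[[2]], 1e-4)
  list(Asym = asym0, R0 = max(y), lrc = log(k0))
}

#' Estimate mRNA half-lives for every gene of a time course
#'
#' Runs [fit_decay()] on each row of a spike-in-normalized decay course.
#'
#' @param course A `decay_course` from [spikein_normalize()] (or a
#'   `decay_sim`, which is normalized first).
#' @param asymptote Passed to [fit_decay()].
#' @return A tibble: `gene`, `k_decay_per_hour`, `half_life_hours`, `Asym`,
#'   `R0`, `converged`.
#' @export
estimate_half_lives <- function(course, asymptote = TRUE) {
  if (inherits(course, "decay_sim"))
    course <- spikein_normalize(course$counts, course$spikein_amounts,
                                timepoints = course$timepoints)
  stopifnot(inherits(course, "decay_course"))
  conc <- course$concentrations
  purrr::map_dfr(seq_len(nrow(conc)), function(i) {
    row <- fit_decay(conc[i, ], course$timepoints, asymptote = asymptote)
    dplyr::bind_cols(tibble::tibble(gene = rownames(conc)[i]),
                     row[, c("k_decay_per_hour", "half_life_hours", "Asym",
                             "R0", "converged")])
  })
}
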