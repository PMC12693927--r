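#' Normalized root mean squared error
#'
#' `sqrt(mean((truth - estimate)^2) / var_pop(truth))` with the population
#' variance (divide by n) of the truth in the denominator — so an estimator
#' that predicts the mean everywhere scores exactly 1.
#'
#' @param truth,estimate equal-length numeric vectors (length >= 2).
#' @return nonnegative scalar.
#' @examples
#' nrmse(c(1, 2, 3, 4), c(1, 2, 3, 5))  # sqrt(0.2)
#' @export
nrmse <- function(truth, estimate) {
  stopifnot(is.numeric(truth), is.numeric(estimate))
  if (length(truth) != length(estimate) || length(truth) < 2L)
    stop("nrmse(): inputs must have equal length >= 2", call. = FALSE)
  v <- mean((truth - mean(truth))^2)
  if (v == 0) stop("nrmse(): truth has zero variance", call. = FALSE)
  sqrt(mean((truth - estimate)^2) / v)
}

# calendar/time predictors available for every record (never missing):
# days after transplant, day of year, sin/cos-encoded clock hour, day/night
# indicator and the phenological stage as an integer code.
impute_features <- function(records, calendar, day_start = 6, day_end = 18) {
  lt <- as.POSIXlt(records$timestamp)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  date <- as.Date(records$timestamp)
  dat <- days_after_transplant(date, calendar)
  data.frame(
    dat = dat,
    doy = as.integer(strftime(date, "%j")),
    hour_sin = sin(2 * pi * h / 24),
    hour_cos = cos(2 * pi * h / 24),
    is_day = as.numeric(period_of(records$timestamp, day_start, day_end) == "day"),
    stage = match(stage_of_dat(pmin(dat, calendar$cycle_days), calendar),
                  calendar$stages$stage))
}

# one bagged ensemble of regression trees: returns imputations for the
# missing rows and out-of-bag predictions for the observed rows
bagged_regression <- function(x_obs, y_obs, x_mis, n_trees, mtry,
                              min_split, min_leaf, max_depth) {
  n <- nrow(x_obs)
  pred_mis <- matrix(NA_real_, nrow = nrow(x_mis), ncol = n_trees)
  oob_sum <- numeric(n); oob_cnt <- integer(n)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    fit <- grow_tree(x_obs[boot, , drop = FALSE], y_obs[boot],
                     type = "regression", min_split = min_split,
                     min_leaf = min_leaf, max_depth = max_depth, mtry = mtry)
    if (nrow(x_mis)) pred_mis[, b] <- predict(fit, x_mis)
    if (length(oob)) {
      p <- predict(fit, x_obs[oob, , drop = FALSE])
      oob_sum[oob] <- oob_sum[oob] + p
      oob_cnt[oob] <- oob_cnt[oob] + 1L
    }
  }
  has_oob <- oob_cnt > 0L
  oob_pred <- ifelse(has_oob, oob_sum / pmax(oob_cnt, 1L), NA_real_)
  list(imputed = rowMeans(pred_mis),
       oob_nrmse = nrmse(y_obs[has_oob], oob_pred[has_oob]))
}

#' Iterative tree-ensemble imputation of sensor gaps
#'
#' missForest-style gap filling for one sensor's temperature/relative
#' humidity series. Missing entries are initialised with column means, then
#' variables are revisited in order of increasing missingness: each is
#' regressed on the co-observed climate variable plus calendar/time
#' predictors with a bagged ensemble of the package's regression trees
#' (bootstrap resampling, `mtry = floor(sqrt(p))` features per node), and
#' its missing entries are replaced by the ensemble mean. Iteration stops
#' when the summed out-of-bag NRMSE stops improving — the previous
#' iteration's values are returned — or after `max_iterations`. Observed
#' values are never altered; the run is fully determined by `seed`.
#'
#' @param records one sensor's record table (`timestamp`, `temp_c`,
#'   `rh_pct`, gaps as `NA`).
#' @param calendar a [phenology_calendar()] supplying stage/DAT predictors.
#' @param n_trees trees per ensemble (default 100).
#' @param max_iterations iteration cap (default 10).
#' @param mtry features per split; `NULL` means `floor(sqrt(p))`.
#' @param seed integer seed.
#' @param variables columns to impute.
#' @param day_start,day_end day/night boundary for the indicator predictor.
#' @param min_split,min_leaf,max_depth regression-tree growth controls.
#' @return object of class `imputation_result`: list with `records`
#'   (completed), `iterations_run`, `oob_nrmse_trace` (iterations x
#'   variables matrix) and `converged`.
#' @export
impute_series <- function(records, calendar, n_trees = 100L,
                          max_iterations = 10L, mtry = NULL, seed = 1L,
                          variables = c("temp_c", "rh_pct"),
                          day_start = 6, day_end = 18,
                          min_split = 10L, min_leaf = 5L, max_depth = 25L) {
  stopifnot(is.data.frame(records), all(variables %in% names(records)),
            n_trees >= 1L, max_iterations >= 1L)
  n <- nrow(records)
  miss <- lapply(records[variables], is.na)
  frac <- vapply(miss, mean, numeric(1))
  if (any(frac >= 0.5))
    stop("impute_series(): a variable is >= 50% missing; imputation contract violated",
         call. = FALSE)
  if (any(frac == 1))
    stop("impute_series(): a variable is entirely missing", call. = FALSE)
  if (all(frac == 0)) {
    return(structure(list(records = records, iterations_run = 1L,
                          oob_nrmse_trace = matrix(numeric(0), ncol = length(variables),
                                                   dimnames = list(NULL, variables)),
                          converged = TRUE),
                     class = "imputation_result"))
  }
  feats <- impute_features(records, calendar, day_start, day_end)
  var_order <- variables[order(frac)]
  x <- cbind(records[variables], feats)
  for (v in variables) x[[v]][miss[[v]]] <- mean(records[[v]], na.rm = TRUE)

  with_seed(as.integer(seed), {
    trace <- NULL
    prev_total <- Inf
    prev_x <- x
    converged <- FALSE
    iter <- 0L
    while (iter < max_iterations) {
      iter <- iter + 1L
      it_nrmse <- stats::setNames(numeric(length(variables)), variables)
      for (v in var_order) {
        obs <- !miss[[v]]
        preds <- setdiff(names(x), v)
        xp <- x[preds]
        y_obs <- records[[v]][obs]
        if (all(vapply(xp[obs, , drop = FALSE], function(z) length(unique(z)) == 1L,
                       logical(1)))) {
          warning(sprintf("impute_series(): constant predictors for %s; falling back to mean imputation", v))
          x[[v]][miss[[v]]] <- mean(y_obs)
          it_nrmse[v] <- NA_real_
          next
        }
        p <- ncol(xp)
        m <- if (is.null(mtry)) max(1L, floor(sqrt(p))) else as.integer(mtry)
        fit <- bagged_regression(xp[obs, , drop = FALSE], y_obs,
                                 xp[miss[[v]], , drop = FALSE],
                                 n_trees = n_trees, mtry = m,
                                 min_split = min_split, min_leaf = min_leaf,
                                 max_depth = max_depth)
        x[[v]][miss[[v]]] <- fit$imputed
        it_nrmse[v] <- fit$oob_nrmse
      }
      trace <- rbind(trace, it_nrmse)
      total <- sum(it_nrmse, na.rm = TRUE)
      if (total >= prev_total) {      # no further improvement: keep previous pass
        x <- prev_x
        converged <- TRUE
        break
      }
      prev_total <- total
      prev_x <- x
    }
    out <- records
    for (v in variables) out[[v]][miss[[v]]] <- x[[v]][miss[[v]]]
    rownames(trace) <- NULL
    structure(list(records = out, iterations_run = iter,
                   oob_nrmse_trace = trace, converged = converged),
              class = "imputation_result")
  })
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputation: %d iteration(s), %s\n", x$iterations_run,
              if (x$converged) "converged (OOB NRMSE stopped improving)"
              else "stopped at iteration cap"))
  if (nrow(x$oob_nrmse_trace)) {
    cat("OOB NRMSE trace:\n")
    print(round(x$oob_nrmse_trace, 4))
  }
  invisible(x)
}
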