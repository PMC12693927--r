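#' Suitability threshold table
#'
#' A threshold table holds, for every (stage, period, variable) combination,
#' four cut points: the closed optimal interval `[opt_lo, opt_hi]` and the
#' outer critical cuts `crit_lo`/`crit_hi`. The suboptimal band is implied:
#' `[crit_lo, opt_lo)` on the low side and `(opt_hi, crit_hi]` on the high
#' side; values strictly below `crit_lo` or above `crit_hi` are critical.
#' The three categories therefore partition the real line, with typographic
#' gaps in published range tables (e.g. an optimal bound of 28 followed by a
#' suboptimal bound of 28.1) closed by extending the suboptimal band up to
#' the optimal bound.
#'
#' @param entries data frame with columns `stage`, `period` (`day`/`night`),
#'   `variable` (`T`, `RH`, `VPD`), `opt_lo`, `opt_hi`, `crit_lo`, `crit_hi`.
#' @param stages character vector of stage names the table must cover
#'   (defaults to the tomato stages).
#' @return object of class `threshold_table` (validated data frame).
#' @seealso [default_thresholds()], [classify_value()]
#' @export
threshold_table <- function(entries,
                            stages = c("vegetative", "reproductive", "harvest")) {
  need <- c("stage", "period", "variable", "opt_lo", "opt_hi", "crit_lo", "crit_hi")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    stop("threshold_table(): entries must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  entries <- entries[need]
  keys <- expand.grid(stage = stages, period = c("day", "night"),
                      variable = c("T", "RH", "VPD"),
                      stringsAsFactors = FALSE)
  have <- paste(entries$stage, entries$period, entries$variable)
  want <- paste(keys$stage, keys$period, keys$variable)
  missing_keys <- setdiff(want, have)
  if (length(missing_keys))
    stop("threshold_table(): missing keys: ", paste(missing_keys, collapse = "; "),
         call. = FALSE)
  if (anyDuplicated(have))
    stop("threshold_table(): duplicated keys", call. = FALSE)
  bad <- with(entries, !(crit_lo <= opt_lo & opt_lo <= opt_hi & opt_hi <= crit_hi))
  if (any(bad))
    stop("threshold_table(): inverted intervals for keys: ",
         paste(have[bad], collapse = "; "), call. = FALSE)
  structure(entries, class = c("threshold_table", "data.frame"))
}

#' Default tomato suitability thresholds
#'
#' Stage- and period-specific optimal/suboptimal/critical ranges for air
#' temperature (degrees C), relative humidity (%) and VPD (kPa, absolute
#' value) of greenhouse tomato, as used for the vegetative (0--50 DAT),
#' reproductive (51--109 DAT) and harvest (110--190 DAT) stages.
#'
#' @return a [threshold_table()].
#' @examples
#' th <- default_thresholds()
#' subset(th, stage == "vegetative" & period == "day")
#' @export
default_thresholds <- function() {
  e <- rbind(
    # stage, period, variable, opt_lo, opt_hi, crit_lo, crit_hi
    data.frame(stage = "vegetative", period = "day",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(20, 55, 0.5), opt_hi = c(28, 75, 1.1),
               crit_lo = c(18, 50, 0.4), crit_hi = c(34, 85, 2.0)),
    data.frame(stage = "vegetative", period = "night",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(15, 50, 0.5), opt_hi = c(19, 75, 0.9),
               crit_lo = c(12, 45, 0.3), crit_hi = c(20, 80, 1.5)),
    data.frame(stage = "reproductive", period = "day",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(19, 50, 0.5), opt_hi = c(26, 80, 1.2),
               crit_lo = c(17, 45, 0.4), crit_hi = c(34, 89, 2.0)),
    data.frame(stage = "reproductive", period = "night",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(15, 50, 0.5), opt_hi = c(19, 75, 0.9),
               crit_lo = c(13, 45, 0.3), crit_hi = c(20, 85, 1.5)),
    data.frame(stage = "harvest", period = "day",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(19, 50, 0.5), opt_hi = c(24, 80, 1.2),
               crit_lo = c(17, 45, 0.4), crit_hi = c(34, 89, 2.0)),
    data.frame(stage = "harvest", period = "night",
               variable = c("T", "RH", "VPD"),
               opt_lo = c(15, 50, 0.5), opt_hi = c(19, 75, 0.9),
               crit_lo = c(13, 45, 0.3), crit_hi = c(20, 85, 1.5)))
  threshold_table(e)
}

#' Classify values against the threshold table
#'
#' Assigns each value one of the categories `optimal`, `suboptimal`,
#' `critical` and a side tag (`low`, `in`, `high`). The optimal interval is
#' closed; suboptimal runs from the critical cut to the optimal bound
#' (closed at the critical cut, open toward optimal); critical lies strictly
#' beyond the critical cuts. VPD is classified on its absolute value.
#'
#' @param variable one of `"T"`, `"RH"`, `"VPD"` (scalar or vector recycled
#'   against `value`).
#' @param value numeric vector; `NA` yields `NA` category.
#' @param stage,period stage and period labels (scalar or vector).
#' @param thresholds a [threshold_table()].
#' @return data frame with columns `category` (factor with levels
#'   optimal < suboptimal < critical) and `side` (`low`/`in`/`high`).
#' @examples
#' th <- default_thresholds()
#' classify_value("T", c(25, 17.5, 28.05), "vegetative", "day", th)
#' @export
classify_value <- function(variable, value, stage, period, thresholds) {
  stopifnot(inherits(thresholds, "threshold_table"))
  n <- max(length(variable), length(value), length(stage), length(period))
  variable <- rep_len(as.character(variable), n)
  value <- rep_len(as.numeric(value), n)
  stage <- rep_len(as.character(stage), n)
  period <- rep_len(as.character(period), n)
  value <- ifelse(variable == "VPD", abs(value), value)

  key <- paste(stage, period, variable)
  tkey <- paste(thresholds$stage, thresholds$period, thresholds$variable)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    stop("classify_value(): unknown (stage, period, variable) key: ",
         unique(key[is.na(idx)])[1L], call. = FALSE)
  }
  olo <- thresholds$opt_lo[idx]; ohi <- thresholds$opt_hi[idx]
  clo <- thresholds$crit_lo[idx]; chi <- thresholds$crit_hi[idx]

  category <- rep(NA_character_, n)
  side <- rep(NA_character_, n)
  ok <- !is.na(value)
  v <- value
  category[ok & v >= olo & v <= ohi] <- "optimal"
  side[ok & v >= olo & v <= ohi] <- "in"
  sub_lo <- ok & v >= clo & v < olo
  sub_hi <- ok & v > ohi & v <= chi
  category[sub_lo | sub_hi] <- "suboptimal"
  side[sub_lo] <- "low"; side[sub_hi] <- "high"
  cr_lo <- ok & v < clo
  cr_hi <- ok & v > chi
  category[cr_lo | cr_hi] <- "critical"
  side[cr_lo] <- "low"; side[cr_hi] <- "high"

  data.frame(category = factor(category, levels = category_levels()),
             side = side, stringsAsFactors = FALSE)
}

#' Category severity order used throughout the package
#'
#' @return `c("optimal", "suboptimal", "critical")`, from benign to severe.
#' @export
category_levels <- function() c("optimal", "suboptimal", "critical")
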