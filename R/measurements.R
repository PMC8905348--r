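#' @include network.R
NULL

#' Construct a MeasurementSet
#'
#' @param intervals data.frame with columns \code{metabolite_id},
#'   \code{delta_min}, \code{delta_max}; the sign column is derived. Each
#'   interval must be strictly positive or strictly negative: the direction of
#'   change of every measured metabolite must be known, because the objective
#'   linearises |S phi| on measured metabolites through that sign.
#' @param epsilon non-negative relaxation granted to non-measured metabolites.
#' @param epsilon_overrides optional data.frame (\code{metabolite_id},
#'   \code{eps_min}, \code{eps_max}).
#' @param sources,sinks optional data.frames (\code{metabolite_id},
#'   \code{magnitude}); magnitude \code{NA} requests the default of 10 times
#'   the largest measured |delta|, keeping virtual pools within the order of
#'   magnitude of the data.
#' @param drop_zero_spanning when TRUE (default), measured intervals that span
#'   zero are dropped with a warning (a non-significant change carries no
#'   direction information); when FALSE they raise an error.
#' @return a \linkS4class{MeasurementSet}.
#' @export
MeasurementSet <- function(intervals, epsilon = 0,
                           epsilon_overrides = NULL,
                           sources = NULL, sinks = NULL,
                           drop_zero_spanning = TRUE) {
  stopifnot(is.data.frame(intervals))
  need <- c("metabolite_id", "delta_min", "delta_max")
  if (!all(need %in% names(intervals)))
    stop("intervals must have columns: ", paste(need, collapse = ", "))
  iv <- intervals[, need]
  if (any(iv$delta_min > iv$delta_max)) {
    bad <- iv$metabolite_id[iv$delta_min > iv$delta_max]
    stop("delta_min > delta_max for: ", paste(bad, collapse = ", "))
  }
  spans <- iv$delta_min <= 0 & iv$delta_max >= 0
  if (any(spans)) {
    bad <- iv$metabolite_id[spans]
    if (drop_zero_spanning) {
      warning("dropping non-significant (zero-spanning) intervals for: ",
              paste(bad, collapse = ", "))
      iv <- iv[!spans, , drop = FALSE]
    } else {
      stop("interval spans zero (change must be strictly positive or ",
           "strictly negative) for: ", paste(bad, collapse = ", "))
    }
  }
  iv$sign <- sign(iv$delta_min)
  rownames(iv) <- NULL

  default_M <- if (nrow(iv)) 10 * max(abs(c(iv$delta_min, iv$delta_max))) else 10
  fix_ms <- function(x) {
    if (is.null(x))
      return(data.frame(metabolite_id = character(), magnitude = numeric()))
    stopifnot(is.data.frame(x), "metabolite_id" %in% names(x))
    if (is.null(x$magnitude)) x$magnitude <- NA_real_
    x$magnitude[is.na(x$magnitude)] <- default_M
    x[, c("metabolite_id", "magnitude")]
  }
  if (is.null(epsilon_overrides))
    epsilon_overrides <- data.frame(metabolite_id = character(),
                                    eps_min = numeric(), eps_max = numeric())
  new("MeasurementSet", intervals = iv, epsilon = as.numeric(epsilon),
      epsilonOverrides = epsilon_overrides,
      sources = fix_ms(sources), sinks = fix_ms(sinks))
}

#' Read measured concentration-change intervals from TSV
#'
#' Expects tab-separated columns \code{metabolite_id}, \code{delta_min},
#' \code{delta_max} (header required, \code{#} comment lines allowed). Each
#' row is the interval of moles accumulated (positive) or depleted (negative)
#' by one measured metabolite between the two conditions.
#'
#' @param path TSV file path.
#' @param drop_zero_spanning passed to \code{\link{MeasurementSet}} semantics:
#'   when FALSE, zero-spanning rows are an error.
#' @return data.frame of validated intervals with a derived \code{sign}
#'   column.
#' @export
readDeltas <- function(path, drop_zero_spanning = FALSE) {
  tbl <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("metabolite_id", "delta_min", "delta_max")
  if (!all(need %in% names(tbl)))
    stop("deltas file '", path, "' must have columns: ",
         paste(need, collapse = ", "), " (found: ",
         paste(names(tbl), collapse = ", "), ")")
  if (!is.numeric(tbl$delta_min) || !is.numeric(tbl$delta_max))
    stop("deltas file '", path, "': delta_min/delta_max must be numeric")
  if (anyDuplicated(tbl$metabolite_id))
    stop("duplicate metabolite id(s) in '", path, "': ",
         paste(unique(tbl$metabolite_id[duplicated(tbl$metabolite_id)]),
               collapse = ", "))
  ms <- MeasurementSet(tbl, drop_zero_spanning = drop_zero_spanning)
  ms@intervals
}

#' Write intervals to TSV
#'
#' Inverse of \code{\link{readDeltas}}; full-precision round trip.
#'
#' @param intervals data.frame with metabolite_id, delta_min, delta_max.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDeltas <- function(intervals, path) {
  out <- intervals[, c("metabolite_id", "delta_min", "delta_max")]
  out$delta_min <- sprintf("%.17g", out$delta_min)
  out$delta_max <- sprintf("%.17g", out$delta_max)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a change interval from a baseline measurement and a fold change
#'
#' Converts a baseline concentration (mean and replicate deviation) plus the
#' fold change observed in the second condition into an interval for the
#' difference: the centre is \code{mean * (fold_change - 1)} and the deviation
#' is attributed to the baseline only, giving
#' \code{[centre - dev, centre + dev]}. The convention is isolated here so an
#' alternative propagation (e.g. multiplicative) can be swapped in.
#'
#' @param baseline_mean baseline concentration (> 0).
#' @param baseline_dev replicate deviation of the baseline (>= 0).
#' @param fold_change concentration ratio second/baseline (> 0).
#' @param metabolite_id optional id attached to the result.
#' @return one-row data.frame (metabolite_id, delta_min, delta_max, sign).
#'   Errors when the interval spans zero: such a change is not significant
#'   and the metabolite should be dropped from the input.
#' @examples
#' deltaFromBaseline(10, 1, 2)    # [9, 11]
#' @export
deltaFromBaseline <- function(baseline_mean, baseline_dev, fold_change,
                              metabolite_id = NA_character_) {
  stopifnot(baseline_mean > 0, baseline_dev >= 0, fold_change > 0)
  centre <- baseline_mean * (fold_change - 1)
  lo <- centre - baseline_dev
  hi <- centre + baseline_dev
  if (lo <= 0 && hi >= 0)
    stop("change not significant: interval [", signif(lo, 6), ", ",
         signif(hi, 6), "] spans zero",
         if (!is.na(metabolite_id)) paste0(" for ", metabolite_id) else "")
  data.frame(metabolite_id = metabolite_id, delta_min = lo, delta_max = hi,
             sign = sign(lo), stringsAsFactors = FALSE)
}

#' Assemble the full bound vectors over a network
#'
#' Builds Delta_min and Delta_max aligned to the network's metabolite order:
#' measured metabolites take their intervals, every other metabolite the
#' epsilon relaxation [-epsilon, +epsilon] (or its per-metabolite override),
#' and declared virtual sources/sinks widen single components (a source
#' lowers delta_min to -magnitude, a sink raises delta_max to +magnitude).
#'
#' @param net a \linkS4class{SplitNetwork}.
#' @param ms a \linkS4class{MeasurementSet}.
#' @return a \linkS4class{BoundVectors}.
#' @export
buildBoundVectors <- function(net, ms) {
  stopifnot(is(net, "SplitNetwork"), is(ms, "MeasurementSet"))
  mids <- metaboliteIds(net)
  m <- length(mids)
  check_known <- function(ids, what) {
    unknown <- setdiff(ids, mids)
    if (length(unknown))
      stop(what, " metabolite(s) absent from network: ",
           paste(unknown, collapse = ", "))
  }
  check_known(ms@intervals$metabolite_id, "measured")
  check_known(ms@epsilonOverrides$metabolite_id, "epsilon-override")
  check_known(ms@sources$metabolite_id, "source")
  check_known(ms@sinks$metabolite_id, "sink")

  dmin <- rep(-ms@epsilon, m); dmax <- rep(ms@epsilon, m)
  measured <- rep(FALSE, m); sgn <- rep(0, m)
  names(dmin) <- names(dmax) <- names(measured) <- names(sgn) <- mids

  ov <- ms@epsilonOverrides
  if (nrow(ov)) {
    i <- match(ov$metabolite_id, mids)
    dmin[i] <- ov$eps_min; dmax[i] <- ov$eps_max
  }
  iv <- ms@intervals
  if (nrow(iv)) {
    i <- match(iv$metabolite_id, mids)
    dmin[i] <- iv$delta_min; dmax[i] <- iv$delta_max
    measured[i] <- TRUE; sgn[i] <- iv$sign
  }
  if (nrow(ms@sources)) {
    i <- match(ms@sources$metabolite_id, mids)
    dmin[i] <- pmin(dmin[i], -ms@sources$magnitude)
  }
  if (nrow(ms@sinks)) {
    i <- match(ms@sinks$metabolite_id, mids)
    dmax[i] <- pmax(dmax[i], ms@sinks$magnitude)
  }
  new("BoundVectors", deltaMin = dmin, deltaMax = dmax,
      measured = measured, sign = sgn)
}
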